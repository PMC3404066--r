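#' Negative binomial log probability mass (mean/dispersion form)
#'
#' Parameterized by mean \code{mu} and dispersion \code{r}:
#' \deqn{P(Y=y) = \frac{\Gamma(y+r)}{\Gamma(r)\, y!}
#'   \left(\frac{r}{r+\mu}\right)^r \left(\frac{\mu}{r+\mu}\right)^y,}
#' the Poisson limit as \eqn{r \to \infty}.
#'
#' @param y Counts.
#' @param mu Mean.
#' @param r Dispersion (size); larger is closer to Poisson.
#' @return Log probability.
#' @export
nb_log_pmf <- function(y, mu, r) {
  dnbinom(y, size = r, mu = mu, log = TRUE)
}

.design_matrix <- function(data) {
  cbind(`(Intercept)` = 1, C1 = data$C1, C2 = data$C2, trend = data$trend)
}

#' Fixed-effects count models of pupal abundance
#'
#' Fits a Poisson, negative binomial or zero-inflated Poisson regression of
#' the pupal counts on the flux dummies and the temporal trend, the
#' pre-screening step before the hierarchical model. Poisson and negative
#' binomial fits use [stats::glm()] and [MASS::glm.nb()]; the ZIP fit is a
#' direct maximum-likelihood optimization (BFGS) with logit/log linear
#' predictors on the same covariates in both components.
#'
#' @param data A \code{zip_model_data}.
#' @param family \code{"poisson"}, \code{"negbin"} or \code{"zip"}.
#' @return An object of class \code{count_glm}: list with \code{family},
#'   \code{coefficients} (count component), \code{zero_coefficients}
#'   (ZIP only; logit of the structural-zero probability), \code{theta}
#'   (negative binomial dispersion), \code{log_lik}, \code{k} (free
#'   parameters), \code{logpmf} (per-observation log probabilities) and
#'   \code{n}.
#' @export
fit_count_glm <- function(data, family = c("poisson", "negbin", "zip")) {
  family <- match.arg(family)
  stopifnot(inherits(data, "zip_model_data"))
  X <- .design_matrix(data)
  y <- data$y
  df <- data.frame(y = y, C1 = data$C1, C2 = data$C2, trend = data$trend)
  if (family == "poisson") {
    fit <- glm(y ~ C1 + C2 + trend, family = stats::poisson(), data = df)
    co <- coef(fit)
    co[is.na(co)] <- 0          # aliased columns (constant covariates)
    logpmf <- dpois(y, exp(drop(X %*% co)), log = TRUE)
    out <- list(family = family, coefficients = co, zero_coefficients = NULL,
                theta = NULL, log_lik = sum(logpmf), k = length(co),
                logpmf = logpmf, n = length(y))
  } else if (family == "negbin") {
    out <- .fit_negbin(y, X, df)
  } else {
    out <- .fit_zip_ml(y, X)
  }
  if (!is.finite(out$log_lik)) {
    stop("count model fit failed: non-finite log-likelihood", call. = FALSE)
  }
  class(out) <- "count_glm"
  out
}

# Negative binomial MLE: glm.nb when it converges, otherwise direct
# optimization over (coefficients, log dispersion) -- glm.nb's theta
# iteration diverges on equi-/under-dispersed data where r -> infinity.
.fit_negbin <- function(y, X, df) {
  fit <- tryCatch(suppressWarnings(MASS::glm.nb(y ~ C1 + C2 + trend,
                                                data = df)),
                  error = function(e) NULL)
  if (!is.null(fit) && fit$converged && is.finite(fit$theta)) {
    co <- coef(fit)
    co[is.na(co)] <- 0
    theta <- fit$theta
  } else {
    p <- ncol(X)
    start <- coef(glm(y ~ X - 1, family = stats::poisson()))
    start[!is.finite(start)] <- 0
    nll <- function(par) {
      mu <- exp(drop(X %*% par[1:p]))
      r <- exp(min(par[p + 1], 15))
      -sum(nb_log_pmf(y, mu, r))
    }
    opt <- optim(c(start, log(10)), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    co <- opt$par[1:p]
    names(co) <- colnames(X)
    theta <- exp(min(opt$par[p + 1], 15))
  }
  logpmf <- nb_log_pmf(y, exp(drop(X %*% co)), theta)
  list(family = "negbin", coefficients = co, zero_coefficients = NULL,
       theta = theta, log_lik = sum(logpmf),
       k = length(co) + 1L, logpmf = logpmf, n = length(y))
}

# ZIP maximum likelihood: params = c(gamma (zero logit), coefs (count log)).
.fit_zip_ml <- function(y, X) {
  p <- ncol(X)
  nll <- function(par) {
    g <- par[1:p]; b <- par[(p + 1):(2 * p)]
    pz <- plogis(drop(X %*% g))
    lam <- exp(drop(X %*% b))
    -sum(zip_log_pmf(y, pz, lam))
  }
  # moment-based starts: logistic fit of the zero indicator, Poisson fit
  # of the positive counts
  z <- as.numeric(y == 0)
  g0 <- tryCatch(coef(glm(z ~ X - 1, family = stats::binomial())),
                 warning = function(w) suppressWarnings(
                   coef(glm(z ~ X - 1, family = stats::binomial()))))
  pos <- y > 0
  b0 <- if (any(pos)) {
    coef(glm(y ~ X - 1, family = stats::poisson(), subset = pos))
  } else rep(0, p)
  b0[!is.finite(b0)] <- 0; g0[!is.finite(g0)] <- 0
  opt <- optim(c(g0, b0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  if (!is.finite(opt$value)) stop("ZIP optimization failed", call. = FALSE)
  g <- opt$par[1:p]; b <- opt$par[(p + 1):(2 * p)]
  names(g) <- names(b) <- colnames(X)
  logpmf <- zip_log_pmf(y, plogis(drop(X %*% g)), exp(drop(X %*% b)))
  list(family = "zip", coefficients = b, zero_coefficients = g,
       theta = NULL, log_lik = sum(logpmf), k = 2L * p,
       logpmf = logpmf, n = length(y))
}

#' @export
print.count_glm <- function(x, ...) {
  cat(sprintf("<count_glm> family = %s, logLik = %.2f, k = %d, AIC = %.2f\n",
              x$family, x$log_lik, x$k, aic(x)))
  invisible(x)
}

#' Akaike information criterion
#'
#' \eqn{-2 \log L + 2k} for a fitted count model.
#'
#' @param model A \code{count_glm}.
#' @return AIC value.
#' @export
aic <- function(model) {
  stopifnot(inherits(model, "count_glm"))
  -2 * model$log_lik + 2 * model$k
}

#' Vuong statistic for non-nested count models
#'
#' For models 1 and 2 fitted to the same observations, with pointwise
#' log-likelihood differences \eqn{m_i = \log f_1(y_i) - \log f_2(y_i)},
#' the statistic is \eqn{V = \sqrt{n}\,\bar{m}/s_m}, asymptotically
#' standard normal under the null of equivalent fit (uncorrected variant,
#' no AIC/BIC penalty). \eqn{V > 1.96} prefers model 1, \eqn{V < -1.96}
#' model 2, otherwise the test is indeterminate.
#'
#' @param m1,m2 Fitted \code{count_glm} objects on identical data.
#' @return List with \code{V}, \code{p_value} (two-sided) and
#'   \code{preferred} (\code{"m1"}, \code{"m2"} or
#'   \code{"indeterminate"}).
#' @export
vuong_statistic <- function(m1, m2) {
  stopifnot(inherits(m1, "count_glm"), inherits(m2, "count_glm"))
  if (m1$n != m2$n) stop("models fitted to different observations",
                         call. = FALSE)
  m <- m1$logpmf - m2$logpmf
  s <- sd(m)
  if (s == 0) stop("identical pointwise fits; Vuong statistic undefined",
                   call. = FALSE)
  V <- sqrt(m1$n) * mean(m) / s
  list(V = V, p_value = 2 * pnorm(-abs(V)),
       preferred = if (V > 1.96) "m1" else if (V < -1.96) "m2"
                   else "indeterminate")
}

#' Compare the three candidate count models
#'
#' Fits Poisson, negative binomial and ZIP models on the same design and
#' tabulates log-likelihood, parameter count and AIC, together with the
#' pairwise Vuong statistics.
#'
#' @param data A \code{zip_model_data}.
#' @return List with \code{table} (data frame: family, log_lik, k, aic)
#'   and \code{vuong} (named list of pairwise results).
#' @export
compare_count_models <- function(data) {
  fits <- lapply(c("poisson", "negbin", "zip"), fit_count_glm, data = data)
  names(fits) <- c("poisson", "negbin", "zip")
  tab <- data.frame(
    family = names(fits),
    log_lik = vapply(fits, `[[`, numeric(1), "log_lik"),
    k = vapply(fits, `[[`, integer(1), "k"),
    aic = vapply(fits, aic, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  vu <- list(
    zip_vs_poisson = vuong_statistic(fits$zip, fits$poisson),
    zip_vs_negbin = vuong_statistic(fits$zip, fits$negbin),
    negbin_vs_poisson = vuong_statistic(fits$negbin, fits$poisson))
  list(table = tab, vuong = vu, fits = fits)
}
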