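#' MCMC configuration for the hierarchical ZIP model
#'
#' Defaults follow the analysis protocol of the source survey: a burn-in of
#' 5,000 iterations followed by 100,000 sampling iterations thinned to every
#' 10th draw (10,000 stored draws); vague normal priors (mean 0, precision
#' 1/10,000) on all fixed effects; and vague gamma priors (shape = rate =
#' 0.01) on the random-effect precisions. Shorter chains for tests and
#' quick exploration are obtained by lowering \code{burn_in} and
#' \code{n_iter}.
#'
#' @param burn_in Burn-in iterations (adaptation of proposal scales happens
#'   here and is frozen afterwards).
#' @param n_iter Post-burn-in iterations.
#' @param thin Keep every \code{thin}-th draw; \code{n_iter} must be a
#'   multiple.
#' @param seed Optional integer; when given, \code{set.seed(seed)} is called
#'   at the start of the fit so runs are exactly reproducible.
#' @param prior_precision_fixed Normal prior precision for fixed effects.
#' @param re_precision_shape,re_precision_rate Gamma prior (shape, rate) on
#'   each random-effect precision.
#' @param init_beta,init_delta Initial fixed effects (length 4 each;
#'   intercept, increase, decrease, trend). Default all zero.
#' @param init_variance Initial random-effect variances.
#' @param proposal_scale Initial random-walk proposal standard deviation;
#'   adapted per parameter toward 44\% acceptance during burn-in.
#' @param update_beta,update_delta,update_re,update_variances Logical
#'   switches holding blocks fixed at their initial values; used for
#'   reductions (e.g. a fixed-effects-only model) and validation against
#'   low-dimensional quadrature.
#' @param n_batches Batch count for Monte Carlo error estimation.
#' @return An object of class \code{zip_mcmc_config}.
#' @export
mcmc_config <- function(burn_in = 5000, n_iter = 100000, thin = 10,
                        seed = NULL,
                        prior_precision_fixed = 1e-4,
                        re_precision_shape = 0.01,
                        re_precision_rate = 0.01,
                        init_beta = c(0, 0, 0, 0),
                        init_delta = c(0, 0, 0, 0),
                        init_variance = 1,
                        proposal_scale = 0.5,
                        update_beta = TRUE, update_delta = TRUE,
                        update_re = TRUE, update_variances = TRUE,
                        n_batches = 50) {
  stopifnot(burn_in >= 0, n_iter >= 1, thin >= 1,
            n_iter %% thin == 0,
            prior_precision_fixed > 0,
            re_precision_shape > 0, re_precision_rate > 0,
            length(init_beta) == 4, length(init_delta) == 4,
            init_variance > 0, proposal_scale > 0, n_batches >= 2)
  structure(list(
    burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
    thin = as.integer(thin), seed = seed,
    prior_precision_fixed = prior_precision_fixed,
    re_precision_shape = re_precision_shape,
    re_precision_rate = re_precision_rate,
    init_beta = as.numeric(init_beta),
    init_delta = as.numeric(init_delta),
    init_variance = init_variance,
    proposal_scale = proposal_scale,
    update_beta = update_beta, update_delta = update_delta,
    update_re = update_re, update_variances = update_variances,
    n_batches = as.integer(n_batches)),
    class = "zip_mcmc_config")
}

.zip_param_names <- function(nC, nH) {
  c("beta0", "beta1_increase", "beta2_decrease", "beta3_trend",
    "delta0", "delta1_increase", "delta2_decrease", "delta3_trend",
    "var_u", "var_v", "var_w", "var_z",
    if (nC) paste0("u[", seq_len(nC), "]"),
    if (nH) paste0("v[", seq_len(nH), "]"),
    if (nC) paste0("w[", seq_len(nC), "]"),
    if (nH) paste0("z[", seq_len(nH), "]"))
}

#' Fit the hierarchical zero-inflated Poisson mixed model
#'
#' The observation model for the pupal count in container \eqn{i},
#' household \eqn{j}, survey \eqn{k} is a zero-inflated Poisson. The
#' zero-inflation component is parameterized through the logit of the
#' probability that a container-survey is in the productive (Poisson)
#' state,
#' \deqn{\mathrm{logit}(\pi_{ijk}) = \beta_0 + \beta_1 C1 + \beta_2 C2 +
#'   \beta_3 k + u_i + v_j,}
#' so the structural-zero probability is \eqn{1 - \pi_{ijk}}; the count
#' component is
#' \deqn{\log(\lambda_{ijk}) = \delta_0 + \delta_1 C1 + \delta_2 C2 +
#'   \delta_3 k + w_i + z_j.}
#' \eqn{C1}/\eqn{C2} are the water-volume increase/decrease dummies and
#' \eqn{k} the temporal trend. All four random-effect vectors are normal
#' with mean zero and component-specific variances carrying gamma-prior
#' precisions.
#'
#' Sampling is by data augmentation and Metropolis-within-Gibbs: for each
#' zero count a latent productive-state indicator is drawn from its exact
#' conditional; fixed effects and random effects are updated by adaptive
#' scalar random-walk Metropolis (target acceptance 0.44, adaptation frozen
#' after burn-in); random-effect precisions use conjugate gamma Gibbs
#' updates. Draws are deterministic given \code{cfg$seed}.
#'
#' @param data A \code{zip_model_data} from [build_model_data()].
#' @param cfg A \code{zip_mcmc_config} from [mcmc_config()].
#' @return An object of class \code{zip_fit}: list with \code{draws}
#'   (matrix, stored iterations x parameters, named columns),
#'   \code{accept} (post-burn-in acceptance rates), \code{cfg},
#'   \code{n_containers}, \code{n_households}, \code{n_obs}.
#' @export
fit_zip_mixed <- function(data, cfg = mcmc_config()) {
  stopifnot(inherits(data, "zip_model_data"), inherits(cfg, "zip_mcmc_config"))
  if (data$n_obs < 1) stop("empty model data", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  X <- cbind(1, data$C1, data$C2, data$trend)
  res <- zip_sampler_cpp(
    as.integer(data$y), X,
    as.integer(data$container - 1L), as.integer(data$household - 1L),
    as.integer(data$n_containers), as.integer(data$n_households),
    cfg$burn_in, cfg$n_iter, cfg$thin,
    cfg$prior_precision_fixed,
    cfg$re_precision_shape, cfg$re_precision_rate,
    cfg$init_beta, cfg$init_delta, cfg$init_variance,
    cfg$proposal_scale,
    cfg$update_beta, cfg$update_delta, cfg$update_re, cfg$update_variances)
  draws <- res$draws
  if (any(!is.finite(draws))) {
    stop("non-finite values in MCMC draws; sampler diverged", call. = FALSE)
  }
  colnames(draws) <- .zip_param_names(data$n_containers, data$n_households)
  structure(list(draws = draws, accept = res$accept, cfg = cfg,
                 n_containers = data$n_containers,
                 n_households = data$n_households,
                 n_obs = data$n_obs,
                 container_ids = data$container_ids,
                 household_ids = data$household_ids),
            class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  cat(sprintf(
    "<zip_fit> %d stored draws, %d containers, %d households, %d obs\n",
    nrow(x$draws), x$n_containers, x$n_households, x$n_obs))
  s <- summarize_posterior(x)
  print(s[1:8, c("parameter", "mean", "lower", "upper", "mce_sd")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Unnormalized log posterior of the hierarchical ZIP model
#'
#' Direct evaluation of the target density the sampler explores (with the
#' latent productive-state indicators integrated out): the ZIP
#' log-likelihood plus normal priors on fixed effects, normal
#' random-effect terms, and gamma terms on the random-effect precisions
#' (evaluated at precision = 1/variance).
#'
#' @param params List with \code{beta}, \code{delta} (length 4), \code{u},
#'   \code{w} (length \code{n_containers}), \code{v}, \code{z} (length
#'   \code{n_households}), and scalars \code{var_u}, \code{var_v},
#'   \code{var_w}, \code{var_z}.
#' @param data A \code{zip_model_data}.
#' @param cfg A \code{zip_mcmc_config} (prior settings are used).
#' @return Log posterior density up to an additive constant.
#' @export
log_posterior <- function(params, data, cfg = mcmc_config()) {
  stopifnot(inherits(data, "zip_model_data"))
  X <- cbind(1, data$C1, data$C2, data$trend)
  eta0 <- drop(X %*% params$beta) +
    params$u[data$container] + params$v[data$household]
  etac <- drop(X %*% params$delta) +
    params$w[data$container] + params$z[data$household]
  ll <- sum(zip_log_pmf(data$y, p = plogis(-eta0), lambda = exp(etac)))
  sd_fixed <- 1 / sqrt(cfg$prior_precision_fixed)
  lp <- sum(dnorm(c(params$beta, params$delta), 0, sd_fixed, log = TRUE))
  lre <- sum(dnorm(params$u, 0, sqrt(params$var_u), log = TRUE)) +
         sum(dnorm(params$v, 0, sqrt(params$var_v), log = TRUE)) +
         sum(dnorm(params$w, 0, sqrt(params$var_w), log = TRUE)) +
         sum(dnorm(params$z, 0, sqrt(params$var_z), log = TRUE))
  taus <- 1 / c(params$var_u, params$var_v, params$var_w, params$var_z)
  lpr <- sum(dgamma(taus, shape = cfg$re_precision_shape,
                    rate = cfg$re_precision_rate, log = TRUE))
  ll + lp + lre + lpr
}

#' Batch-means Monte Carlo error
#'
#' Standard error of a chain's mean accounting for autocorrelation: the
#' chain is split into \code{n_batches} consecutive batches and the MCE is
#' \code{sd(batch means) / sqrt(n_batches)}.
#'
#' @param x Numeric chain.
#' @param n_batches Number of batches (default 50).
#' @return Monte Carlo error of the mean.
#' @export
batch_mce <- function(x, n_batches = 50) {
  n <- length(x)
  if (n < 2 * n_batches) stop("chain too short for ", n_batches, " batches",
                              call. = FALSE)
  b <- n %/% n_batches
  x <- x[(n - n_batches * b + 1):n]        # drop remainder at the front
  bm <- colMeans(matrix(x, nrow = b))
  sd(bm) / sqrt(n_batches)
}

#' Posterior summary table
#'
#' Per parameter: posterior mean, SD, equal-tailed 95\% credible interval
#' (2.5/97.5 percentiles), batch-means Monte Carlo error, the MCE/SD
#' convergence diagnostic (rule of thumb: < 0.05 means the chain is long
#' enough), and a significance flag (credible interval excludes zero).
#' Chains with zero SD are flagged degenerate.
#'
#' @param x A \code{zip_fit}, or a numeric matrix of draws with named
#'   columns.
#' @param prob Credible-interval mass (default 0.95).
#' @param n_batches Batches for the MCE (default from the fit config, or
#'   50).
#' @return Data frame with columns \code{parameter}, \code{mean},
#'   \code{sd}, \code{lower}, \code{upper}, \code{mce}, \code{mce_sd},
#'   \code{converged}, \code{significant}, \code{degenerate}.
#' @export
summarize_posterior <- function(x, prob = 0.95, n_batches = NULL) {
  draws <- if (inherits(x, "zip_fit")) x$draws else as.matrix(x)
  if (is.null(n_batches)) {
    n_batches <- if (inherits(x, "zip_fit")) x$cfg$n_batches else 50L
  }
  if (nrow(draws) < 100) stop("need at least 100 draws", call. = FALSE)
  a <- (1 - prob) / 2
  mean_ <- colMeans(draws)
  sd_ <- apply(draws, 2, sd)
  qs <- apply(draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  mce <- apply(draws, 2, batch_mce, n_batches = n_batches)
  degenerate <- sd_ == 0
  ratio <- ifelse(degenerate, NaN, mce / sd_)
  data.frame(
    parameter = colnames(draws),
    mean = mean_, sd = sd_,
    lower = qs[1, ], upper = qs[2, ],
    mce = mce, mce_sd = ratio,
    converged = ifelse(degenerate, FALSE, ratio < 0.05),
    significant = qs[1, ] > 0 | qs[2, ] < 0,
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Count significant random effects
#'
#' A random effect is significant at the 5\% level when its 95\% credible
#' interval excludes zero: above the overall mean when the lower bound is
#' positive, below when the upper bound is negative (random effects are
#' centered on zero by construction).
#'
#' @param x A \code{zip_fit}.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame with one row per component (\code{zero},
#'   \code{count}) and level (\code{container}, \code{household}):
#'   \code{n_below}, \code{n_above}, \code{n_total}.
#' @export
significant_random_effects <- function(x, prob = 0.95) {
  stopifnot(inherits(x, "zip_fit"))
  a <- (1 - prob) / 2
  groups <- list(
    list("zero", "container", "^u\\["),
    list("zero", "household", "^v\\["),
    list("count", "container", "^w\\["),
    list("count", "household", "^z\\["))
  out <- do.call(rbind, lapply(groups, function(g) {
    cols <- grep(g[[3]], colnames(x$draws))
    if (!length(cols)) return(NULL)
    qs <- apply(x$draws[, cols, drop = FALSE], 2, quantile,
                probs = c(a, 1 - a), names = FALSE)
    data.frame(component = g[[1]], level = g[[2]],
               n_below = sum(qs[2, ] < 0), n_above = sum(qs[1, ] > 0),
               n_total = length(cols), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Table-2-style summary of the fixed effects and variances
#'
#' Arranges the posterior summary in the layout used for reporting:
#' one row per variable, columns for the zero-inflated and count
#' components.
#'
#' @param fit A \code{zip_fit}.
#' @return Data frame with columns \code{variable}, \code{component},
#'   \code{mean}, \code{lower}, \code{upper}, \code{significant}.
#' @export
fixed_effect_table <- function(fit) {
  s <- summarize_posterior(fit)
  pick <- c(beta0 = "Intercept", beta1_increase = "Increasing volume",
            beta2_decrease = "Decreasing volume", beta3_trend = "Temporal trend",
            var_u = "Variance container RE", var_v = "Variance household RE",
            delta0 = "Intercept", delta1_increase = "Increasing volume",
            delta2_decrease = "Decreasing volume", delta3_trend = "Temporal trend",
            var_w = "Variance container RE", var_z = "Variance household RE")
  comp <- c(rep("zero_inflated", 6), rep("count", 6))
  idx <- match(names(pick), s$parameter)
  data.frame(variable = unname(pick), component = comp,
             mean = s$mean[idx], lower = s$lower[idx], upper = s$upper[idx],
             significant = s$significant[idx], stringsAsFactors = FALSE)
}
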