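#' Zero-inflated Poisson log probability mass
#'
#' The ZIP distribution is a two-component mixture: with probability
#' \code{p} the observation is a structural zero; otherwise it is Poisson
#' with mean \code{lambda}, so
#' \deqn{P(Y = y) = p \, 1\{y = 0\} + (1 - p)\, e^{-\lambda}\lambda^y / y!.}
#' Evaluation of the \code{y = 0} mixture term is done on the log scale
#' (log-sum-exp) so it is overflow-safe for extreme \code{p} or
#' \code{lambda}.
#'
#' @param y Non-negative integer counts.
#' @param p Structural-zero probability in \code{[0, 1]}.
#' @param lambda Poisson mean, >= 0.
#' @return Log probability, vectorized over arguments.
#' @examples
#' zip_log_pmf(0, 0.3, 2)                      # log(0.3 + 0.7 exp(-2))
#' sum(exp(zip_log_pmf(0:200, 0.3, 2)))        # == 1
#' @export
zip_log_pmf <- function(y, p, lambda) {
  n <- max(length(y), length(p), length(lambda))
  y <- rep_len(y, n); p <- rep_len(p, n); lambda <- rep_len(lambda, n)
  if (any(y < 0 | y != round(y))) {
    stop("`y` must be non-negative integers", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  out <- log1p(-p) + dpois(y, lambda, log = TRUE)
  z <- y == 0
  if (any(z)) {
    # log(p + (1 - p) e^-lambda), stable via pairwise logsumexp
    a <- log(p[z]); b <- log1p(-p[z]) - lambda[z]
    m <- pmax(a, b)
    lz <- m + log(exp(a - m) + exp(b - m))
    lz[p[z] == 1] <- 0                       # point mass at zero
    lz[p[z] == 0] <- b[p[z] == 0]
    out[z] <- lz
  }
  out
}
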