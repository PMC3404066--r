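#' Synthetic-survey configuration
#'
#' Defaults emulate the study design the package targets: 41 households
#' with a truncated-Poisson number of containers (mean 4.8, at least 1),
#' 119/171 of containers large, 15 surveys at 2-day intervals (29 days),
#' per-day fill/draw-down event probabilities 0.05/0.07 (large) and
#' 0.11/0.13 (small), and zero-inflated Poisson pupal counts generated
#' from the hierarchical model with the published posterior means as true
#' parameters: zero component \eqn{\beta = (-3.58, -0.48, 0.16, 0.04)}
#' (logit of the productive-state probability), count component
#' \eqn{\delta = (1.45, 0.95, 0.06, 0.06)}, random-effect variances
#' \eqn{\sigma^2_u = 2.43}, \eqn{\sigma^2_v = 0.06} (zero part, container /
#' household) and \eqn{\sigma^2_w = 0.78}, \eqn{\sigma^2_z = 0.03} (count
#' part).
#'
#' Water-dynamics magnitudes: a fill adds U(20, 60) percentage points
#' (capped at 100), a draw-down removes U(20, 60) points (floored at 0),
#' and each container consumes water at a constant rate drawn once from
#' U(0, 1.75) points/day on days without an event. Containers start wet
#' with probability 0.80 at U(30, 85) percent of capacity. These values
#' are calibrated so the realized daily >=20-point event rates and the
#' per-survey wet fractions match the published figures.
#'
#' @param n_households Number of households.
#' @param mean_containers Mean containers per household (zero-truncated
#'   Poisson).
#' @param containers_per_household Optional exact container count per
#'   household (overrides the truncated-Poisson draw; used by fixtures).
#' @param p_large Probability a container is large (>= 500 L).
#' @param n_surveys Number of survey rounds (>= 2).
#' @param interval_days Days between surveys.
#' @param fill_prob,draw_prob Named per-day event probabilities with
#'   elements \code{large} and \code{small}.
#' @param fill_range,draw_range Event magnitudes (percentage points),
#'   uniform bounds.
#' @param drift_max Upper bound of the per-container daily consumption
#'   rate (points/day).
#' @param init_wet_prob Probability a container starts wet.
#' @param init_volume_range Uniform bounds of the initial volume (percent
#'   of capacity) for containers starting wet.
#' @param beta,delta True fixed effects (intercept, increase, decrease,
#'   trend) of the zero and count components.
#' @param var_u,var_v,var_w,var_z True random-effect variances.
#' @param trend Trend covariate passed to the generative model:
#'   \code{"survey"} index (default) or \code{"day"}.
#' @param seed Optional seed applied by [simulate_survey()].
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_households = 41,
                       mean_containers = 4.8,
                       containers_per_household = NULL,
                       p_large = 119 / 171,
                       n_surveys = 15,
                       interval_days = 2,
                       fill_prob = c(large = 0.05, small = 0.11),
                       draw_prob = c(large = 0.07, small = 0.13),
                       fill_range = c(20, 60),
                       draw_range = c(20, 60),
                       drift_max = 1.75,
                       init_wet_prob = 0.80,
                       init_volume_range = c(30, 85),
                       beta = c(-3.58, -0.48, 0.16, 0.04),
                       delta = c(1.45, 0.95, 0.06, 0.06),
                       var_u = 2.43, var_v = 0.06,
                       var_w = 0.78, var_z = 0.03,
                       trend = c("survey", "day"),
                       seed = NULL) {
  trend <- match.arg(trend)
  stopifnot(n_households >= 1, mean_containers > 1 ||
              !is.null(containers_per_household),
            p_large >= 0, p_large <= 1, n_surveys >= 2, interval_days >= 1,
            all(unlist(c(fill_prob, draw_prob)) >= 0),
            all(unlist(c(fill_prob, draw_prob)) <= 1),
            drift_max >= 0, init_wet_prob >= 0, init_wet_prob <= 1,
            length(beta) == 4, length(delta) == 4,
            var_u >= 0, var_v >= 0, var_w >= 0, var_z >= 0)
  structure(list(
    n_households = as.integer(n_households),
    mean_containers = mean_containers,
    containers_per_household = containers_per_household,
    p_large = p_large, n_surveys = as.integer(n_surveys),
    interval_days = as.integer(interval_days),
    fill_prob = fill_prob, draw_prob = draw_prob,
    fill_range = fill_range, draw_range = draw_range,
    drift_max = drift_max, init_wet_prob = init_wet_prob,
    init_volume_range = init_volume_range,
    beta = as.numeric(beta), delta = as.numeric(delta),
    var_u = var_u, var_v = var_v, var_w = var_w, var_z = var_z,
    trend = trend, seed = seed),
    class = "sim_config")
}

# lambda of a zero-truncated Poisson with the requested mean
.ztpois_lambda <- function(m) {
  uniroot(function(l) l / (1 - exp(-l)) - m, c(1e-6, m * 2))$root
}

.rztpois <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- rpois(sum(x == 0), lambda)
  x
}

#' Generate the static container table
#'
#' Draws households, container counts, size classes, and capacities/types
#' consistent with the survey's container inventory (moulded tanks of
#' 2000 L, cylindrical tanks of 1000-2000 L, box tanks, jars/drums, and
#' small jars under 100 L); 98\% of containers are outdoors.
#'
#' @param cfg A \code{sim_config}.
#' @return Data frame of containers (see [survey_dataset()]).
#' @export
make_containers <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nh <- cfg$n_households
  n_per <- if (!is.null(cfg$containers_per_household)) {
    rep_len(cfg$containers_per_household, nh)
  } else {
    .rztpois(nh, .ztpois_lambda(cfg$mean_containers))
  }
  n <- sum(n_per)
  household_id <- rep(sprintf("H%03d", seq_len(nh)), n_per)
  large <- runif(n) < cfg$p_large
  # type mix within class follows the observed inventory proportions
  type <- character(n)
  capacity <- numeric(n)
  tl <- sample(c("moulded_tank", "cylindrical_tank", "box_tank"),
               sum(large), replace = TRUE, prob = c(17, 91, 11))
  type[large] <- tl
  capacity[large] <- ifelse(tl == "moulded_tank", 2000,
                     ifelse(tl == "cylindrical_tank",
                            round(runif(length(tl), 1000, 2000)),
                            round(runif(length(tl), 500, 10000))))
  ts <- sample(c("jar_drum", "small_jar"), sum(!large), replace = TRUE,
               prob = c(42, 7))
  type[!large] <- ts
  capacity[!large] <- ifelse(ts == "jar_drum",
                             round(runif(length(ts), 100, 499)),
                             round(runif(length(ts), 20, 99)))
  data.frame(
    container_id = sprintf("C%04d", seq_len(n)),
    household_id = household_id,
    container_type = type,
    capacity_l = capacity,
    location = sample(c("outdoor", "indoor"), n, replace = TRUE,
                      prob = c(0.98, 0.02)),
    lid = sample(c("full", "partial", "none"), n, replace = TRUE,
                 prob = c(0.25, 0.25, 0.5)),
    stringsAsFactors = FALSE)
}

#' Simulate daily water-volume trajectories
#'
#' Each container evolves daily: with the class-specific fill probability
#' a fill event adds U(20, 60) percentage points (capped at 100); otherwise
#' with the draw-down probability an event removes U(20, 60) points
#' (floored at 0); on days with neither event the container loses its
#' consumption rate (drawn once per container from U(0, drift_max)).
#'
#' @param cfg A \code{sim_config}.
#' @param containers Container table from [make_containers()].
#' @return List with \code{volume} (containers x days matrix of percent of
#'   capacity), \code{days} (1..study length) and \code{survey_days}.
#' @export
simulate_water_dynamics <- function(cfg, containers) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(containers)
  days <- 1 + cfg$interval_days * (cfg$n_surveys - 1)
  cls <- classify_size(containers$capacity_l)
  fill_p <- unname(cfg$fill_prob[cls])
  draw_p <- unname(cfg$draw_prob[cls])
  vol <- matrix(0, n, days)
  vol[, 1] <- ifelse(runif(n) < cfg$init_wet_prob,
                     runif(n, cfg$init_volume_range[1],
                           cfg$init_volume_range[2]), 0)
  drift <- runif(n, 0, cfg$drift_max)
  for (d in 2:days) {
    f <- runif(n) < fill_p
    dr <- !f & runif(n) < draw_p
    v <- vol[, d - 1]
    v2 <- v
    if (any(f)) v2[f] <- pmin(100, v[f] +
      runif(sum(f), cfg$fill_range[1], cfg$fill_range[2]))
    if (any(dr)) v2[dr] <- pmax(0, v[dr] -
      runif(sum(dr), cfg$draw_range[1], cfg$draw_range[2]))
    idle <- !f & !dr
    v2[idle] <- pmax(0, v[idle] - drift[idle])
    vol[, d] <- v2
  }
  rownames(vol) <- containers$container_id
  list(volume = vol, days = seq_len(days),
       survey_days = seq(1, days, by = cfg$interval_days))
}

#' Simulate pupal counts and assemble a survey dataset
#'
#' Applies the hierarchical zero-inflated Poisson model to the simulated
#' trajectories: flux dummies are derived from the survey-day volumes with
#' the same >=20-point rule the analysis uses; container- and
#' household-level random effects are drawn once from their variances; at
#' each wet container-survey the productive state is Bernoulli with
#' probability \eqn{\mathrm{logit}^{-1}(\eta_0)} and the count Poisson
#' with mean \eqn{e^{\eta_c}} when productive. Dry records carry zero
#' pupae. Survey 1 counts use C1 = C2 = 0. Larval-stage observations are
#' generated from simple presence models tied to the pupal count (see the
#' methods vignette) and predator presence is rare (2\%).
#'
#' @param traj Trajectories from [simulate_water_dynamics()].
#' @param containers Container table.
#' @param cfg A \code{sim_config}.
#' @return A validated \code{survey_dataset} with an attribute
#'   \code{truth} holding the generating parameters and random effects.
#' @export
simulate_pupal_counts <- function(traj, containers, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(containers)
  S <- cfg$n_surveys
  sdays <- traj$survey_days
  vols <- traj$volume[, sdays, drop = FALSE]
  house_ids <- sort(unique(containers$household_id))
  hidx <- match(containers$household_id, house_ids)
  nH <- length(house_ids)
  u <- rnorm(n, 0, sqrt(cfg$var_u)); v <- rnorm(nH, 0, sqrt(cfg$var_v))
  w <- rnorm(n, 0, sqrt(cfg$var_w)); z <- rnorm(nH, 0, sqrt(cfg$var_z))
  rec <- vector("list", S)
  for (k in seq_len(S)) {
    volk <- vols[, k]
    wet <- volk > 0
    if (k >= 2) {
      d <- volk - vols[, k - 1]
      C1 <- as.numeric(d >= 20); C2 <- as.numeric(d <= -20)
    } else {
      C1 <- C2 <- numeric(n)
    }
    tk <- if (cfg$trend == "survey") k else sdays[k]
    eta0 <- cfg$beta[1] + cfg$beta[2] * C1 + cfg$beta[3] * C2 +
      cfg$beta[4] * tk + u + v[hidx]
    etac <- cfg$delta[1] + cfg$delta[2] * C1 + cfg$delta[3] * C2 +
      cfg$delta[4] * tk + w + z[hidx]
    productive <- runif(n) < plogis(eta0)
    y <- integer(n)
    draw <- wet & productive
    if (any(draw)) y[draw] <- rpois(sum(draw), exp(etac[draw]))
    # larval stages: simple presence models anchored to the pupal count
    i12 <- wet & (runif(n) < plogis(-2.3 + 1.3 * (y > 0)))
    m34 <- integer(n)
    if (any(wet)) m34[wet] <- rpois(sum(wet), 1.5 * y[wet] + 0.25)
    cat34 <- cut(m34, c(-0.5, 0.5, 10.5, 100.5, 1000.5, Inf),
                 labels = .instar_cats)
    rec[[k]] <- data.frame(
      container_id = containers$container_id,
      survey_index = k,
      day = sdays[k],
      wet = wet,
      volume_pct = ifelse(wet, volk, 0),
      instar_i_ii = i12,
      instar_iii_iv_cat = as.character(cat34),
      pupae = y,
      predators = wet & (runif(n) < 0.02),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  records <- records[order(records$container_id, records$survey_index), ]
  rownames(records) <- NULL
  ds <- survey_dataset(containers, records, n_surveys = S)
  attr(ds, "truth") <- list(
    beta = cfg$beta, delta = cfg$delta,
    var_u = cfg$var_u, var_v = cfg$var_v,
    var_w = cfg$var_w, var_z = cfg$var_z,
    u = u, v = v, w = w, z = z,
    container_ids = containers$container_id, household_ids = house_ids)
  ds
}

#' Simulate a full synthetic survey
#'
#' Convenience wrapper: containers, water dynamics, pupal counts. Applies
#' \code{cfg$seed} when set, making the dataset fully reproducible.
#'
#' @param cfg A \code{sim_config}.
#' @return A \code{survey_dataset} with a \code{truth} attribute.
#' @export
simulate_survey <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  containers <- make_containers(cfg)
  traj <- simulate_water_dynamics(cfg, containers)
  simulate_pupal_counts(traj, containers, cfg)
}

#' Ready-made synthetic fixtures
#'
#' \code{"tiny"} is a 3-household, 6-container, 4-survey dataset for fast
#' tests; \code{"study"} uses the full default configuration (41
#' households, ~170 containers, 15 surveys).
#'
#' @param size \code{"tiny"} or \code{"study"}.
#' @param seed Seed (default 42).
#' @return A \code{survey_dataset}.
#' @export
make_fixture <- function(size = c("tiny", "study"), seed = 42) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    sim_config(n_households = 3, containers_per_household = 2,
               n_surveys = 4, seed = seed)
  } else {
    sim_config(seed = seed)
  }
  simulate_survey(cfg)
}
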