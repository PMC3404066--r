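#' Water-flux categories between consecutive surveys
#'
#' Water volume is recorded as a percentage of container capacity; the flux
#' between consecutive surveys is the difference in those percentage points.
#' A change of at least +20 points is an \code{increase} event, at most
#' -20 points a \code{decrease} event, anything in between \code{stable}
#' (the reference category). Because flux is relative to the previous
#' survey, categories exist only for survey rounds 2 onwards.
#'
#' @param x A \code{survey_dataset}.
#' @param threshold Event threshold in percentage points of capacity
#'   (default 20); the threshold is inclusive.
#' @return Data frame with columns \code{container_id}, \code{survey_index}
#'   (>= 2), \code{delta} (percentage-point change) and \code{flux}
#'   (factor with levels \code{stable}, \code{increase}, \code{decrease}).
#'   Records whose previous-survey volume is missing are skipped with a
#'   warning.
#' @export
compute_flux <- function(x, threshold = 20) {
  validate_survey_dataset(x)
  re <- x$records[order(x$records$container_id, x$records$survey_index),
                  c("container_id", "survey_index", "volume_pct")]
  prev <- re
  prev$survey_index <- prev$survey_index + 1L
  names(prev)[3] <- "volume_prev"
  cur <- re[re$survey_index >= 2L, ]
  m <- merge(cur, prev, by = c("container_id", "survey_index"),
             all.x = TRUE, sort = FALSE)
  if (anyNA(m$volume_prev)) {
    warning(sum(is.na(m$volume_prev)),
            " record(s) skipped: previous survey missing", call. = FALSE)
    m <- m[!is.na(m$volume_prev), ]
  }
  delta <- m$volume_pct - m$volume_prev
  flux <- factor(ifelse(delta >= threshold, "increase",
                 ifelse(delta <= -threshold, "decrease", "stable")),
                 levels = c("stable", "increase", "decrease"))
  out <- data.frame(container_id = m$container_id,
                    survey_index = m$survey_index,
                    delta = delta, flux = flux,
                    stringsAsFactors = FALSE)
  out <- out[order(out$container_id, out$survey_index), ]
  rownames(out) <- NULL
  out
}

#' Build the model design data
#'
#' Assembles the arrays used by the zero-inflated Poisson mixed model and
#' the fixed-effects count fits: pupal counts, the two flux dummies
#' (C1 = volume increase >= 20 points, C2 = decrease >= 20 points, reference
#' stable), a temporal-trend covariate, and container/household index maps.
#' Only containers examined at every survey contribute, and only survey
#' rounds 2 onwards (flux is undefined at round 1).
#'
#' @param x A \code{survey_dataset}.
#' @param trend Temporal trend covariate: \code{"survey"} (survey index,
#'   default) or \code{"day"} (calendar day).
#' @return An object of class \code{zip_model_data}: list with numeric
#'   vectors \code{y}, \code{C1}, \code{C2}, \code{trend}, integer vectors
#'   \code{container}, \code{household} (1-based indices into
#'   \code{container_ids} / \code{household_ids}), and counts
#'   \code{n_obs}, \code{n_containers}, \code{n_households}.
#' @export
build_model_data <- function(x, trend = c("survey", "day")) {
  trend <- match.arg(trend)
  validate_survey_dataset(x)
  keep <- complete_containers(x)
  if (!length(keep)) stop("no complete containers in dataset", call. = FALSE)
  fl <- compute_flux(x)
  fl <- fl[fl$container_id %in% keep, ]
  re <- x$records[x$records$container_id %in% keep &
                  x$records$survey_index >= 2L, ]
  m <- merge(re, fl, by = c("container_id", "survey_index"), sort = FALSE)
  m <- merge(m, x$containers[, c("container_id", "household_id")],
             by = "container_id", sort = FALSE)
  m <- m[order(m$container_id, m$survey_index), ]
  container_ids <- sort(unique(m$container_id))
  household_ids <- sort(unique(m$household_id))
  structure(list(
    y = as.integer(m$pupae),
    C1 = as.numeric(m$flux == "increase"),
    C2 = as.numeric(m$flux == "decrease"),
    trend = if (trend == "survey") as.numeric(m$survey_index)
            else as.numeric(m$day),
    container = match(m$container_id, container_ids),
    household = match(m$household_id, household_ids),
    container_ids = container_ids,
    household_ids = household_ids,
    n_obs = nrow(m),
    n_containers = length(container_ids),
    n_households = length(household_ids)),
    class = "zip_model_data")
}

#' @export
print.zip_model_data <- function(x, ...) {
  cat(sprintf(paste0("<zip_model_data> %d observations, %d containers, ",
                     "%d households\n  nonzero counts: %d (%.1f%%)\n"),
              x$n_obs, x$n_containers, x$n_households,
              sum(x$y > 0), 100 * mean(x$y > 0)))
  invisible(x)
}
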