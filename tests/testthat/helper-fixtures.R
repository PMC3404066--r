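# Hand-built fixtures: datasets constructed from explicit volume / count
# matrices so expected flux categories and descriptives are known by
# construction.

hand_containers <- function(ids, households, capacity = 1500) {
  data.frame(
    container_id = ids,
    household_id = households,
    container_type = ifelse(capacity >= 500, "cylindrical_tank", "jar_drum"),
    capacity_l = rep_len(capacity, length(ids)),
    location = "outdoor",
    lid = "none",
    stringsAsFactors = FALSE)
}

# vol, pupae: containers x surveys matrices (rownames = container ids)
make_dataset <- function(vol, pupae = NULL, households = NULL,
                         capacity = 1500, interval_days = 2) {
  ids <- rownames(vol)
  if (is.null(ids)) ids <- sprintf("C%02d", seq_len(nrow(vol)))
  if (is.null(pupae)) pupae <- matrix(0L, nrow(vol), ncol(vol))
  if (is.null(households)) households <- ids
  S <- ncol(vol)
  records <- do.call(rbind, lapply(seq_len(S), function(k) {
    data.frame(
      container_id = ids,
      survey_index = k,
      day = 1L + interval_days * (k - 1L),
      wet = vol[, k] > 0,
      volume_pct = vol[, k],
      instar_i_ii = FALSE,
      instar_iii_iv_cat = "0",
      pupae = as.integer(pupae[, k]),
      predators = FALSE,
      stringsAsFactors = FALSE)
  }))
  survey_dataset(hand_containers(ids, households, capacity), records,
                 n_surveys = S)
}

# minimal zip_model_data built directly from arrays (bypasses the survey
# layer) for sampler and likelihood tests
raw_model_data <- function(y, C1 = NULL, C2 = NULL, trend = NULL,
                           container = NULL, household = NULL) {
  n <- length(y)
  if (is.null(C1)) C1 <- numeric(n)
  if (is.null(C2)) C2 <- numeric(n)
  if (is.null(trend)) trend <- numeric(n)
  if (is.null(container)) container <- rep(1L, n)
  if (is.null(household)) household <- rep(1L, n)
  nC <- max(container); nH <- max(household)
  structure(list(y = as.integer(y), C1 = C1, C2 = C2, trend = trend,
                 container = as.integer(container),
                 household = as.integer(household),
                 container_ids = sprintf("C%d", seq_len(nC)),
                 household_ids = sprintf("H%d", seq_len(nH)),
                 n_obs = n, n_containers = nC, n_households = nH),
            class = "zip_model_data")
}
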