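test_that("capacity classification uses the 500 L boundary", {
  expect_equal(classify_size(2000), "large")
  expect_equal(classify_size(100), "small")
  expect_equal(classify_size(500), "large")   # boundary goes to large
  expect_equal(classify_size(c(499, 501)), c("small", "large"))
  expect_error(classify_size(0), "positive")
  expect_error(classify_size(-10), "positive")
})

test_that("flux categories follow the inclusive 20-point rule", {
  vol <- rbind(A = c(50, 75, 56, 36), B = c(50, 31, 31, 90))
  fl <- compute_flux(make_dataset(vol))
  get <- function(id, k) as.character(fl$flux[fl$container_id == id &
                                              fl$survey_index == k])
  expect_equal(get("A", 2), "increase")   # +25
  expect_equal(get("A", 3), "stable")     # -19
  expect_equal(get("A", 4), "decrease")   # -20, threshold inclusive
  expect_equal(get("B", 2), "stable")     # -19
  expect_equal(get("B", 3), "stable")     # 0
  expect_equal(get("B", 4), "increase")   # +59
  expect_equal(nrow(fl), 2 * 3)           # surveys 2..4 only
})

test_that("a refill of a dry container is an increase event", {
  vol <- rbind(A = c(30, 0, 45))
  fl <- compute_flux(make_dataset(vol))
  expect_equal(as.character(fl$flux), c("decrease", "increase"))
})

test_that("flux categories partition all records from survey 2 on", {
  for (seed in 1:3) {
    ds <- make_fixture("study", seed = seed)
    fl <- compute_flux(ds)
    expect_equal(nrow(fl),
                 sum(ds$records$survey_index >= 2))
    expect_equal(sum(table(fl$flux)), nrow(fl))
  }
})

test_that("flux is invariant to container capacity rescaling", {
  ds <- make_fixture("tiny", seed = 5)
  fl1 <- compute_flux(ds)
  ds$containers$capacity_l <- ds$containers$capacity_l * 10
  fl2 <- compute_flux(ds)
  expect_equal(fl1$flux, fl2$flux)
})

test_that("model data covers complete containers at surveys 2..S", {
  ds <- make_fixture("study", seed = 1)
  md <- build_model_data(ds)
  n_complete <- length(complete_containers(ds))
  expect_equal(md$n_obs, n_complete * (ds$n_surveys - 1))
  expect_true(all(md$C1 + md$C2 <= 1))
  expect_setequal(unique(md$trend), 2:15)
  expect_true(all(md$container %in% seq_len(md$n_containers)))
  expect_true(all(md$household %in% seq_len(md$n_households)))
  # stable rows have both dummies zero
  fl <- compute_flux(ds)
  expect_equal(sum(md$C1 == 0 & md$C2 == 0),
               sum(fl$flux == "stable" & fl$container_id %in%
                     complete_containers(ds)))
})

test_that("incomplete containers are excluded from model data", {
  vol <- rbind(A = c(50, 75, 60), B = c(40, 40, 40))
  ds <- make_dataset(vol)
  ds$records <- ds$records[!(ds$records$container_id == "B" &
                             ds$records$survey_index == 3), ]
  md <- build_model_data(ds)
  expect_equal(md$container_ids, "A")
  expect_equal(md$n_obs, 2)
})

test_that("a two-survey dataset yields rows only for survey 2", {
  vol <- rbind(A = c(50, 75), B = c(40, 40))
  md <- build_model_data(make_dataset(vol))
  expect_equal(md$n_obs, 2)
  expect_equal(unique(md$trend), 2)
})

test_that("survey CSV round-trips exactly", {
  ds <- make_fixture("tiny", seed = 3)
  f <- tempfile(fileext = ".csv")
  write_survey_csv(ds, f, header = "test")
  ds2 <- read_survey_csv(f)
  expect_equal(ds2$records, ds$records)
  expect_equal(ds2$containers, ds$containers)
  f2 <- tempfile(fileext = ".csv")
  write_survey_csv(ds2, f2)
  expect_equal(read_survey_csv(f2)$records, ds2$records)
})

test_that("fixture CSV of 2 containers x 3 surveys yields 6 records", {
  vol <- rbind(A = c(50, 75, 60), B = c(40, 40, 40))
  f <- tempfile(fileext = ".csv")
  write_survey_csv(make_dataset(vol), f)
  expect_equal(nrow(read_survey_csv(f)$records), 6)
})

test_that("malformed CSV rows are rejected with line numbers", {
  ds <- make_fixture("tiny", seed = 3)
  f <- tempfile(fileext = ".csv")
  write_survey_csv(ds, f)
  lines <- readLines(f)
  # corrupt the second data row: volume_pct out of range
  row <- strsplit(lines[3], ",")[[1]]
  row[10] <- "120"; row[9] <- "TRUE"
  lines[3] <- paste(row, collapse = ",")
  writeLines(lines, f)
  expect_error(read_survey_csv(f), "line")
})

test_that("dataset invariants are enforced", {
  vol <- rbind(A = c(50, 75, 60))
  ds <- make_dataset(vol)
  bad <- ds
  bad$records$volume_pct[1] <- 120
  expect_error(validate_survey_dataset(bad), "volume_pct")
  bad <- ds
  bad$records$pupae[2] <- -1L
  expect_error(validate_survey_dataset(bad), "pupae")
  bad <- ds
  bad$records$wet[1] <- FALSE   # volume stays 50 -> inconsistent
  expect_error(validate_survey_dataset(bad), "dry")
  bad <- ds
  bad$records$survey_index[3] <- 2L  # duplicate pair
  expect_error(validate_survey_dataset(bad), "duplicated")
})
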