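#' Container size classes, types and categorical levels
#'
#' Storage containers are classified as \code{"large"} (capacity >= 500 L)
#' or \code{"small"} (< 500 L). The 500 L boundary itself is assigned to the
#' large class. Container types follow the survey protocol: moulded tanks,
#' cylindrical tanks, box tanks, jars/drums and small jars (incl. buckets).
#'
#' @name survey-levels
#' @keywords internal
NULL

.size_classes <- c("large", "small")
.container_types <- c("moulded_tank", "cylindrical_tank", "box_tank",
                      "jar_drum", "small_jar")
.locations <- c("indoor", "outdoor")
.lids <- c("full", "partial", "none")
.instar_cats <- c("0", "1-10", "11-100", "101-1000", "1000+")

#' Classify a container by capacity
#'
#' @param capacity_l Container capacity in liters; must be positive.
#' @return Character vector, \code{"large"} for capacities >= 500 L,
#'   \code{"small"} otherwise.
#' @examples
#' classify_size(c(2000, 100, 500))
#' @export
classify_size <- function(capacity_l) {
  if (!is.numeric(capacity_l) || any(!is.finite(capacity_l)) ||
      any(capacity_l <= 0)) {
    stop("`capacity_l` must be positive and finite", call. = FALSE)
  }
  ifelse(capacity_l >= 500, "large", "small")
}

#' Assemble a container survey dataset
#'
#' Bundles the static container table and the longitudinal survey records
#' into a validated \code{survey_dataset} object, the common input of the
#' flux, descriptive and modelling functions.
#'
#' @param containers Data frame with one row per container and columns
#'   \code{container_id}, \code{household_id}, \code{container_type},
#'   \code{capacity_l}, \code{location}, \code{lid}.
#' @param records Data frame with one row per container per survey and
#'   columns \code{container_id}, \code{survey_index}, \code{day},
#'   \code{wet}, \code{volume_pct}, \code{instar_i_ii},
#'   \code{instar_iii_iv_cat}, \code{pupae}, \code{predators}.
#' @param n_surveys Number of survey rounds; defaults to the maximum
#'   \code{survey_index} present.
#' @return An object of class \code{survey_dataset}: a list with elements
#'   \code{containers} (with a derived \code{size_class} column),
#'   \code{records} and \code{n_surveys}.
#' @export
survey_dataset <- function(containers, records, n_surveys = NULL) {
  containers <- as.data.frame(containers, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(n_surveys)) n_surveys <- max(records$survey_index)
  containers$size_class <- classify_size(containers$capacity_l)
  rownames(containers) <- NULL
  rownames(records) <- NULL
  x <- structure(
    list(containers = containers, records = records,
         n_surveys = as.integer(n_surveys)),
    class = "survey_dataset")
  validate_survey_dataset(x)
  x
}

#' Validate a survey dataset
#'
#' Checks the structural invariants: unique container ids, consistent
#' household references, volumes within \code{[0, 100]}, non-negative integer
#' pupal counts, dry records carrying zero volume and zero pupae, and
#' size classes consistent with capacity.
#'
#' @param x A \code{survey_dataset}.
#' @return \code{x}, invisibly; errors describe every violated invariant.
#' @export
validate_survey_dataset <- function(x) {
  stopifnot(inherits(x, "survey_dataset"))
  co <- x$containers; re <- x$records
  need_co <- c("container_id", "household_id", "container_type",
               "capacity_l", "location", "lid")
  need_re <- c("container_id", "survey_index", "day", "wet", "volume_pct",
               "instar_i_ii", "instar_iii_iv_cat", "pupae", "predators")
  miss <- c(setdiff(need_co, names(co)), setdiff(need_re, names(re)))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  if (anyDuplicated(co$container_id)) {
    problems <- c(problems, "duplicated container_id in container table")
  }
  if (any(!re$container_id %in% co$container_id)) {
    problems <- c(problems, "records reference unknown container_id")
  }
  if (any(!co$container_type %in% .container_types)) {
    problems <- c(problems, "invalid container_type")
  }
  if (any(!co$location %in% .locations)) problems <- c(problems, "invalid location")
  if (any(!co$lid %in% .lids)) problems <- c(problems, "invalid lid status")
  if (any(co$capacity_l <= 0)) problems <- c(problems, "non-positive capacity")
  if (any(re$volume_pct < 0 | re$volume_pct > 100)) {
    problems <- c(problems, "volume_pct outside [0, 100]")
  }
  if (any(re$pupae < 0 | re$pupae != round(re$pupae))) {
    problems <- c(problems, "pupae must be non-negative integers")
  }
  dry <- !re$wet
  if (any(dry & (re$volume_pct != 0 | re$pupae != 0))) {
    problems <- c(problems, "dry records must have volume_pct = 0 and pupae = 0")
  }
  if (any(!re$instar_iii_iv_cat %in% .instar_cats)) {
    problems <- c(problems, "invalid instar_iii_iv_cat level")
  }
  if (any(re$survey_index < 1 | re$survey_index > x$n_surveys)) {
    problems <- c(problems, "survey_index outside 1..n_surveys")
  }
  if (anyDuplicated(re[c("container_id", "survey_index")])) {
    problems <- c(problems, "duplicated (container_id, survey_index) pair")
  }
  if (length(problems)) {
    stop("invalid survey dataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.survey_dataset <- function(x, ...) {
  nh <- length(unique(x$containers$household_id))
  cat("<survey_dataset>\n")
  cat(sprintf("  %d containers (%d large, %d small) in %d households\n",
              nrow(x$containers), sum(x$containers$size_class == "large"),
              sum(x$containers$size_class == "small"), nh))
  cat(sprintf("  %d survey rounds, %d records\n", x$n_surveys, nrow(x$records)))
  invisible(x)
}

#' Container ids observed at every survey round
#'
#' Containers not examined at every round are excluded from modelling,
#' mirroring the exclusion of containers switched out of water storage
#' during the study.
#'
#' @param x A \code{survey_dataset}.
#' @return Character vector of complete container ids.
#' @export
complete_containers <- function(x) {
  tab <- table(x$records$container_id)
  sort(names(tab)[tab == x$n_surveys])
}

.survey_csv_cols <- c("household_id", "container_id", "container_type",
                      "capacity_l", "location", "lid", "survey_index", "day",
                      "wet", "volume_pct", "instar_i_ii", "instar_iii_iv_cat",
                      "pupae", "predators")

#' Read a survey CSV file
#'
#' The file holds one record per row in long format with the documented
#' column set; the static container fields are repeated on every row.
#' Lines starting with \code{#} (provenance headers) are ignored.
#'
#' @param path Path to a CSV file.
#' @return A validated \code{survey_dataset}.
#' @export
read_survey_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(.survey_csv_cols, names(df))
  if (length(miss)) {
    stop("survey CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # file line numbers: account for leading provenance comments + header
  n_comment <- sum(cumprod(startsWith(readLines(path, n = 20), "#")))
  bad <- which(
    !is.finite(df$capacity_l) | df$capacity_l <= 0 |
    !is.finite(df$volume_pct) | df$volume_pct < 0 | df$volume_pct > 100 |
    !is.finite(df$pupae) | df$pupae < 0 | df$pupae != round(df$pupae) |
    is.na(df$wet) | is.na(df$survey_index))
  if (length(bad)) {
    stop("malformed survey rows at line(s): ",
         paste(bad + 1L + n_comment, collapse = ", "), call. = FALSE)
  }
  containers <- unique(df[c("container_id", "household_id", "container_type",
                            "capacity_l", "location", "lid")])
  if (anyDuplicated(containers$container_id)) {
    stop("inconsistent container attributes across rows", call. = FALSE)
  }
  records <- df[c("container_id", "survey_index", "day", "wet", "volume_pct",
                  "instar_i_ii", "instar_iii_iv_cat", "pupae", "predators")]
  records$wet <- as.logical(records$wet)
  records$instar_i_ii <- as.logical(records$instar_i_ii)
  records$predators <- as.logical(records$predators)
  records$survey_index <- as.integer(records$survey_index)
  records$day <- as.integer(records$day)
  records$pupae <- as.integer(records$pupae)
  records <- records[order(records$container_id, records$survey_index), ]
  rownames(records) <- NULL
  survey_dataset(containers[order(containers$container_id), ], records)
}

#' Write a survey dataset to CSV
#'
#' Inverse of [read_survey_csv()]: \code{read_survey_csv(write_survey_csv(x))}
#' reproduces the dataset.
#'
#' @param x A \code{survey_dataset}.
#' @param path Output path.
#' @param header Optional character vector written as \code{#}-prefixed
#'   provenance lines before the column header.
#' @return \code{path}, invisibly.
#' @export
write_survey_csv <- function(x, path, header = NULL) {
  validate_survey_dataset(x)
  df <- merge(x$records, x$containers[, c("container_id", "household_id",
              "container_type", "capacity_l", "location", "lid")],
              by = "container_id", sort = FALSE)
  df <- df[order(df$container_id, df$survey_index), .survey_csv_cols]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
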