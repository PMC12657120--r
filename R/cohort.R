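# Cohort data model: per-patient transplant records stratified by HLA match
# fraction, plus CSV I/O and the data-completeness gate.

#' The seven canonical HLA match-fraction levels
#'
#' Low-resolution matching over the HLA-A, -B and -DRB1 loci gives an antigen
#' match count between 0 and 6; the count is conventionally reported as a
#' fraction of 6, rounded to two decimals.
#'
#' @return Numeric vector `c(0, 0.17, 0.33, 0.5, 0.67, 0.83, 1)`.
#' @export
#' @examples
#' match_levels()
match_levels <- function() round(0:6 / 6, 2)

#' Encode an antigen match count as a match fraction
#'
#' Maps a count of matched HLA antigens (0--6 over A/B/DRB1) to the
#' two-decimal match-fraction label used for stratification. The integer
#' count is the quantity stored on records; the fraction is always derived
#' from it, so 0.17 and 1/6 can never drift apart.
#'
#' @param match_count Integer vector with values in 0..6.
#' @return Numeric vector of match fractions in `match_levels()`.
#' @export
#' @examples
#' encode_match_fraction(0:6)
encode_match_fraction <- function(match_count) {
  if (!is.numeric(match_count)) {
    stop("match_count must be numeric (integer-valued)", call. = FALSE)
  }
  bad <- is.na(match_count) | match_count != floor(match_count) |
    match_count < 0 | match_count > 6
  if (any(bad)) {
    stop("match_count must be an integer in 0..6; offending value(s): ",
         paste(utils::head(match_count[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  round(match_count / 6, 2)
}

#' Construct a stratified transplant cohort
#'
#' A cohort is a data frame with one row per patient carrying `patient_id`,
#' `match_count` (0--6), `dose_mg` (daily tacrolimus dose) and `rejected`
#' (binary outcome, possibly `NA` in raw data). A derived `match_fraction`
#' column stratifies the records into the seven canonical match levels.
#' Doses outside the 20--300 mg range typical of this setting are admitted
#' with a warning, not rejected: the range describes a cohort, not a
#' physical bound.
#'
#' @param data Data frame with columns `patient_id`, `match_count`,
#'   `dose_mg` and optionally `rejected`. `match_count` and `dose_mg` may
#'   contain `NA` (counted by [completeness_report()]); non-missing values
#'   must satisfy the invariants.
#' @return An object of class `transplant_cohort` (a data frame).
#' @seealso [read_cohort_csv()], [generate_cohort()], [cohort_strata()]
#' @export
transplant_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("patient_id", "match_count", "dose_mg")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"rejected" %in% names(data)) data$rejected <- NA_integer_

  data$patient_id <- as.character(data$patient_id)
  data$match_count <- as.numeric(data$match_count)
  data$dose_mg <- as.numeric(data$dose_mg)
  data$rejected <- as.integer(data$rejected)

  ok <- !is.na(data$match_count)
  if (any(ok)) encode_match_fraction(data$match_count[ok])  # validates range
  bad_rej <- !is.na(data$rejected) & !data$rejected %in% c(0L, 1L)
  if (any(bad_rej)) {
    stop("rejected must be 0/1 (or missing); offending value(s): ",
         paste(unique(data$rejected[bad_rej]), collapse = ", "), call. = FALSE)
  }
  bad_dose <- !is.na(data$dose_mg) & data$dose_mg <= 0
  if (any(bad_dose)) {
    stop("dose_mg must be positive; offending value(s): ",
         paste(utils::head(data$dose_mg[bad_dose], 5L), collapse = ", "),
         call. = FALSE)
  }
  out_of_range <- !is.na(data$dose_mg) &
    (data$dose_mg < 20 | data$dose_mg > 300)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " dose(s) outside the typical 20-300 mg range", call. = FALSE)
  }

  data$match_fraction <- rep(NA_real_, nrow(data))
  data$match_fraction[ok] <- encode_match_fraction(data$match_count[ok])

  keep <- c("patient_id", "match_count", "match_fraction", "dose_mg",
            "rejected")
  out <- data[, keep, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transplant_cohort", "data.frame")
  out
}

#' @export
print.transplant_cohort <- function(x, ...) {
  cat("Transplant cohort:", nrow(x), "records\n")
  sizes <- stratum_sizes(x)
  cat("Stratum sizes (match fraction):\n")
  print(sizes)
  n_na <- sum(is.na(x$match_fraction))
  if (n_na > 0L) cat("Records with missing match level:", n_na, "\n")
  invisible(x)
}

#' Stratum sizes of a cohort
#'
#' @param cohort A `transplant_cohort`.
#' @return Named integer vector over the seven match levels (zero for empty
#'   strata); records with a missing match level are not counted.
#' @export
stratum_sizes <- function(cohort) {
  stopifnot(inherits(cohort, "transplant_cohort"))
  lv <- match_levels()
  tab <- table(factor(cohort$match_fraction, levels = lv))
  out <- as.integer(tab)
  names(out) <- as.character(lv)
  out
}

#' Row indices of each match stratum
#'
#' @param cohort A `transplant_cohort`.
#' @return Named list of integer row-index vectors, one per match level, in
#'   low-to-high order; together they partition the rows with a non-missing
#'   match level.
#' @export
cohort_strata <- function(cohort) {
  stopifnot(inherits(cohort, "transplant_cohort"))
  lv <- match_levels()
  out <- lapply(lv, function(m) which(!is.na(cohort$match_fraction) &
                                        cohort$match_fraction == m))
  names(out) <- as.character(lv)
  out
}

.default_column_map <- function() {
  c(patient_id = "patient_id", match_count = "match_count",
    dose_mg = "dose_mg", rejected = "rejected")
}

.na_strings <- c("", "NA", "NaN", "na", "nan", "NAN", "Na", "NAN")

#' Read a cohort from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row. Empty cells,
#' `NA` and `NaN` (case-insensitive) are treated as missing. Unparsable
#' numeric cells are reported with their file line number.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping the internal names
#'   `patient_id`, `match_count`, `dose_mg`, `rejected` to the file's column
#'   names. The `rejected` column may be absent from the file.
#' @return A `transplant_cohort`.
#' @export
read_cohort_csv <- function(path, column_map = .default_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- .default_column_map()
  map[names(column_map)] <- column_map
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = .na_strings, check.names = FALSE,
                         fileEncoding = "UTF-8")
  need <- map[c("patient_id", "match_count", "dose_mg")]
  found <- names(raw)
  absent <- need[!need %in% found]
  if (length(absent) > 0L) {
    stop("schema error: expected column(s) [",
         paste(absent, collapse = ", "), "] not found in [",
         paste(found, collapse = ", "), "]", call. = FALSE)
  }

  parse_num <- function(col, label) {
    x <- raw[[col]]
    val <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(val)
    if (any(bad)) {
      # +1 for the header row
      stop("unparsable ", label, " value(s) at file line(s): ",
           paste(utils::head(which(bad) + 1L, 5L), collapse = ", "),
           call. = FALSE)
    }
    val
  }

  data <- data.frame(
    patient_id = raw[[map[["patient_id"]]]],
    match_count = parse_num(map[["match_count"]], "match_count"),
    dose_mg = parse_num(map[["dose_mg"]], "dose_mg"),
    stringsAsFactors = FALSE
  )
  if (map[["rejected"]] %in% found) {
    data$rejected <- parse_num(map[["rejected"]], "rejected")
  }
  if (nrow(raw) == 0L) {
    data <- data[0L, , drop = FALSE]
  }
  transplant_cohort(data)
}

#' Write a cohort to CSV
#'
#' Writes `patient_id`, `match_count`, `dose_mg` and `rejected` with full
#' numeric precision so that [read_cohort_csv()] round-trips the cohort
#' (doses to well below 1e-9).
#'
#' @param cohort A `transplant_cohort`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "transplant_cohort"))
  out <- data.frame(
    patient_id = cohort$patient_id,
    match_count = cohort$match_count,
    dose_mg = vapply(cohort$dose_mg, function(d) {
      if (is.na(d)) NA_character_ else format(d, digits = 17)
    }, character(1L)),
    rejected = cohort$rejected,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Data-completeness report
#'
#' Tabulates, for the dose and match-level variables, the number of
#' observations, the number missing, and the percentage valid. The cohort
#' passes the completeness gate when no value of either variable is missing.
#'
#' @param cohort A `transplant_cohort`.
#' @return A `completeness_report`: data frame with columns `variable`,
#'   `observations`, `missing`, `valid_percent` (NA for an empty cohort) and
#'   attribute `passes_gate`.
#' @export
completeness_report <- function(cohort) {
  stopifnot(inherits(cohort, "transplant_cohort"))
  vars <- list(Immunosuppressant = cohort$dose_mg,
               `Match Levels` = cohort$match_count)
  n <- nrow(cohort)
  rows <- lapply(names(vars), function(v) {
    miss <- sum(is.na(vars[[v]]))
    data.frame(variable = v, observations = n, missing = miss,
               valid_percent = if (n == 0L) NA_real_ else 100 * (n - miss) / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "passes_gate") <- n > 0L && all(out$missing == 0L)
  class(out) <- c("completeness_report", "data.frame")
  out
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("Data completeness\n")
  print.data.frame(x, row.names = FALSE)
  cat(if (isTRUE(attr(x, "passes_gate"))) "Gate: PASS (no missing values)\n"
      else "Gate: FLAG (missing values present or empty cohort)\n")
  invisible(x)
}
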