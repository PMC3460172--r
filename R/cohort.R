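#' @keywords internal
"_PACKAGE"

# Controlled vocabularies shared by every stage. Antigen codes follow the
# EarlyCDT-Lung naming; SOX2-B and SOX2-N are the two tagged constructs of the
# same protein and are carried as distinct codes.
ANTIGENS <- c("p53", "NY-ESO-1", "CAGE", "GBU4-5", "AnnexinI",
              "SOX2-B", "SOX2-N", "MAGEA4", "HuD")
COHORT_LEVELS  <- c("cancer", "control", "at_risk")
STATUS_LEVELS  <- c("confirmed", "none", "unknown")
SUBTYPE_LEVELS <- c("NSCLC", "SCLC", "other", "none")
STAGE_LEVELS   <- c("early", "late", "unknown")
GENDER_LEVELS  <- c("male", "female")
SMOKING_LEVELS <- c("current", "ex", "never", "unknown")

#' Antigens of the seven-autoantibody panel
#'
#' The updated seven-marker panel: p53, NY-ESO-1, CAGE, GBU4-5, MAGEA4,
#' SOX2-B and HuD. Panel positivity is the OR over these antigens.
#' @export
panel7_antigens <- c("p53", "NY-ESO-1", "CAGE", "GBU4-5", "MAGEA4", "SOX2-B", "HuD")

#' Antigens of the original six-autoantibody panel
#'
#' The original six-marker panel: p53, NY-ESO-1, CAGE, GBU4-5, AnnexinI and
#' SOX2-N.
#' @export
panel6_antigens <- c("p53", "NY-ESO-1", "CAGE", "GBU4-5", "AnnexinI", "SOX2-N")

SUBJECT_COLS <- c("subject_id", "cohort", "cancer_status", "subtype",
                  "stage_group", "age", "gender", "smoking",
                  "smoking_years", "quit_years")
MEASUREMENT_COLS <- c("subject_id", "antigen", "coat_level", "ru")

#' Construct a serology cohort
#'
#' Bundles a subject table and a long-format measurement table (one row per
#' subject x antigen x titration coat level, signal in calibrated reference
#' units, RU) into a validated cohort object. Coat levels are indexed
#' `0..n_coat_levels-1` in order of increasing antigen coat concentration;
#' the reference level (default: the highest, full-strength coat) supplies
#' the RU value compared against cutoffs.
#'
#' @param subjects data.frame with columns `subject_id`, `cohort`
#'   (cancer/control/at_risk), `cancer_status` (confirmed/none/unknown),
#'   `subtype` (NSCLC/SCLC/other/none), `stage_group` (early/late/unknown),
#'   `age` (years, >= 18), `gender` (male/female), `smoking`
#'   (current/ex/never/unknown), `smoking_years`, `quit_years`.
#' @param measurements data.frame with columns `subject_id`, `antigen`,
#'   `coat_level` (integer index), `ru` (calibrated reference units, >= 0).
#' @param n_coat_levels number of titration points per series (default 4).
#' @param reference_level coat-level index whose RU is the reference signal;
#'   defaults to the highest index.
#' @param truth optional truth table for synthetic cohorts (see
#'   [truth_table()]).
#' @return an object of class `aab_cohort`: a list with elements `subjects`,
#'   `measurements` and `meta`.
#' @seealso [read_cohort()], [generate_cohort()]
#' @export
aab_cohort <- function(subjects, measurements, n_coat_levels = 4L,
                       reference_level = n_coat_levels - 1L, truth = NULL) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  obj <- structure(list(
    subjects = subjects,
    measurements = measurements,
    meta = list(n_coat_levels = as.integer(n_coat_levels),
                reference_level = as.integer(reference_level),
                synthetic = !is.null(truth),
                truth = truth)
  ), class = "aab_cohort")
  validate_cohort(obj)
  obj
}

fail_rows <- function(bad, what, where) {
  if (any(bad)) {
    rows <- which(bad)
    stop(sprintf("%s: %s (row%s %s)", where, what,
                 if (length(rows) > 1) "s" else "",
                 paste(utils::head(rows, 5), collapse = ", ")),
         call. = FALSE)
  }
}

check_enum <- function(x, levels, field, where) {
  fail_rows(!(as.character(x) %in% levels),
            sprintf("field '%s' outside {%s}", field, paste(levels, collapse = ", ")),
            where)
}

#' Validate a cohort object
#'
#' Checks column presence, controlled vocabularies, value ranges,
#' cohort/status consistency (cancer implies confirmed status and a subtype;
#' control implies no cancer diagnosis), uniqueness of
#' (subject, antigen, coat level) rows, and that every measured subject
#' exists in the subject table. Errors name the offending field and row.
#'
#' @param cohort an `aab_cohort`.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "aab_cohort"))
  s <- cohort$subjects
  m <- cohort$measurements
  missing <- setdiff(SUBJECT_COLS, names(s))
  if (length(missing))
    stop("subjects table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(MEASUREMENT_COLS, names(m))
  if (length(missing))
    stop("measurements table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  if (nrow(s)) {
    fail_rows(is.na(s$subject_id) | s$subject_id == "", "empty subject_id", "subjects")
    fail_rows(duplicated(s$subject_id), "duplicate subject_id", "subjects")
    check_enum(s$cohort, COHORT_LEVELS, "cohort", "subjects")
    check_enum(s$cancer_status, STATUS_LEVELS, "cancer_status", "subjects")
    check_enum(s$subtype, SUBTYPE_LEVELS, "subtype", "subjects")
    check_enum(s$stage_group, STAGE_LEVELS, "stage_group", "subjects")
    check_enum(s$gender, GENDER_LEVELS, "gender", "subjects")
    check_enum(s$smoking, SMOKING_LEVELS, "smoking", "subjects")
    fail_rows(!is.na(s$age) & (s$age < 18), "field 'age' below 18", "subjects")
    fail_rows(s$cohort == "cancer" &
                (s$cancer_status != "confirmed" | s$subtype == "none"),
              "cancer cohort requires cancer_status=confirmed and a subtype",
              "subjects")
    fail_rows(s$cohort == "control" & s$cancer_status != "none",
              "control cohort requires cancer_status=none", "subjects")
    for (col in c("smoking_years", "quit_years"))
      fail_rows(!is.na(s[[col]]) & s[[col]] < 0,
                sprintf("field '%s' negative", col), "subjects")
  }
  if (nrow(m)) {
    check_enum(m$antigen, ANTIGENS, "antigen", "measurements")
    fail_rows(!is.finite(m$ru), "field 'ru' non-numeric or missing", "measurements")
    fail_rows(m$ru < 0, "field 'ru' negative", "measurements")
    fail_rows(m$coat_level < 0 | m$coat_level >= cohort$meta$n_coat_levels,
              "field 'coat_level' outside titration range", "measurements")
    fail_rows(duplicated(m[c("subject_id", "antigen", "coat_level")]),
              "duplicate (subject_id, antigen, coat_level)", "measurements")
    fail_rows(!(m$subject_id %in% s$subject_id),
              "measurement for unknown subject_id", "measurements")
  }
  invisible(cohort)
}

#' @export
print.aab_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Serology cohort: %d subjects (%d cancer, %d control, %d at-risk)\n",
              nrow(s), sum(s$cohort == "cancer"), sum(s$cohort == "control"),
              sum(s$cohort == "at_risk")))
  cat(sprintf("  %d measurements over %d antigen(s), %d coat levels (reference level %d)\n",
              nrow(x$measurements), length(unique(x$measurements$antigen)),
              x$meta$n_coat_levels, x$meta$reference_level))
  if (x$meta$synthetic) cat("  synthetic cohort with truth table\n")
  invisible(x)
}

order_measurements <- function(m) {
  m[order(m$subject_id, match(m$antigen, ANTIGENS), m$coat_level), , drop = FALSE]
}

#' Read a cohort from delimited text files
#'
#' Reads the comma-delimited subject and measurement tables written by
#' [write_cohort()] and returns a validated [aab_cohort()]. The number of
#' coat levels is inferred from the measurement table unless given.
#'
#' @param subjects_path,measurements_path paths to CSV files with headers.
#' @param n_coat_levels override the inferred number of titration points.
#' @param reference_level reference coat-level index (default: highest).
#' @return an `aab_cohort`.
#' @export
read_cohort <- function(subjects_path, measurements_path,
                        n_coat_levels = NULL, reference_level = NULL) {
  for (p in c(subjects_path, measurements_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  s <- utils::read.csv(subjects_path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character"))
  m <- utils::read.csv(measurements_path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character"))
  if (!"ru" %in% names(m))
    stop("measurements table missing column(s): ru", call. = FALSE)
  if (!is.numeric(m$ru))
    stop("measurements: field 'ru' non-numeric (row ",
         which(is.na(suppressWarnings(as.numeric(m$ru))))[1], ")", call. = FALSE)
  if (is.null(n_coat_levels))
    n_coat_levels <- if (nrow(m)) max(m$coat_level) + 1L else 4L
  if (is.null(reference_level)) reference_level <- n_coat_levels - 1L
  aab_cohort(s, m, n_coat_levels = n_coat_levels, reference_level = reference_level)
}

#' Write a cohort to delimited text files
#'
#' Writes the subject and measurement tables as comma-delimited UTF-8 with a
#' header row, in a deterministic row order (subject id, antigen, coat
#' level), so identical cohorts produce byte-identical files.
#'
#' @param cohort an `aab_cohort`.
#' @param subjects_path,measurements_path output CSV paths.
#' @return the paths, invisibly.
#' @export
write_cohort <- function(cohort, subjects_path, measurements_path) {
  validate_cohort(cohort)
  s <- cohort$subjects[order(cohort$subjects$subject_id), SUBJECT_COLS, drop = FALSE]
  m <- order_measurements(cohort$measurements)[, MEASUREMENT_COLS, drop = FALSE]
  utils::write.csv(s, subjects_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(m, measurements_path, row.names = FALSE, quote = FALSE)
  invisible(c(subjects_path, measurements_path))
}

#' Define a diagnostic panel
#'
#' A panel is an ordered antigen list with one RU cutoff per antigen and a
#' dose-response policy. A subject is panel positive when any antigen call
#' is positive (OR rule); an antigen call is positive when the reference RU
#' strictly exceeds the cutoff and, if required, the titration series shows
#' a dose response.
#'
#' @param name panel label, e.g. `"panel7"`.
#' @param antigens ordered character vector of antigen codes.
#' @param cutoffs named numeric vector of RU cutoffs (> 0), one per antigen.
#' @param dose_response_required must a positive call also pass the
#'   dose-response check? Default `TRUE`.
#' @return an object of class `aab_panel`.
#' @export
panel_definition <- function(name, antigens, cutoffs, dose_response_required = TRUE) {
  antigens <- as.character(antigens)
  bad <- setdiff(antigens, ANTIGENS)
  if (length(bad)) stop("unknown antigen(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(antigens))
    stop("duplicate antigen in panel: ",
         antigens[duplicated(antigens)][1], call. = FALSE)
  if (is.null(names(cutoffs)) || !setequal(names(cutoffs), antigens))
    stop("cutoffs must be a named vector covering exactly the panel antigens",
         call. = FALSE)
  cutoffs <- cutoffs[antigens]
  if (any(!is.finite(cutoffs) & cutoffs != Inf) || any(cutoffs <= 0))
    stop("all cutoffs must be positive", call. = FALSE)
  structure(list(name = as.character(name), antigens = antigens,
                 cutoffs = cutoffs,
                 dose_response_required = isTRUE(dose_response_required)),
            class = "aab_panel")
}

#' @export
print.aab_panel <- function(x, ...) {
  cat(sprintf("Panel '%s' (%d antigens, dose response %s)\n", x$name,
              length(x$antigens),
              if (x$dose_response_required) "required" else "not required"))
  print(round(x$cutoffs, 4))
  invisible(x)
}

#' Read or write a panel definition
#'
#' Panel definitions are stored as a small structured-text (YAML) document
#' with fields `name`, `dose_response_required` and a `cutoffs` map. Reading
#' validates that every antigen has exactly one positive cutoff; write then
#' read is the identity.
#'
#' @param path file path.
#' @return `read_panel()` returns an `aab_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$cutoffs) || !length(doc$cutoffs))
    stop("panel file has no cutoffs", call. = FALSE)
  cuts <- unlist(doc$cutoffs)
  if (any(is.na(cuts))) {
    stop("antigen missing a cutoff: ",
         paste(names(cuts)[is.na(cuts)], collapse = ", "), call. = FALSE)
  }
  panel_definition(name = doc$name %||% "panel",
                   antigens = names(cuts), cutoffs = cuts,
                   dose_response_required = isTRUE(doc$dose_response_required))
}

#' @rdname read_panel
#' @param panel an `aab_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "aab_panel"))
  yaml::write_yaml(list(name = panel$name,
                        dose_response_required = panel$dose_response_required,
                        cutoffs = as.list(panel$cutoffs)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
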