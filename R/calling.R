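# Positivity calling. A per-antigen call is positive iff the reference-level
# RU strictly exceeds the cutoff (ties at the cutoff are negative) and, where
# the panel requires it, the titration series shows a dose response. Panel
# positivity is the OR over the panel's antigens.

# Spearman correlation of each matrix row against 1..k, midranks for ties.
# Constant rows have undefined correlation and are returned as NA.
row_spearman <- function(m) {
  k <- ncol(m)
  r <- matrix(1, nrow(m), k)
  for (j in seq_len(k)) {
    for (l in seq_len(k)) {
      if (l == j) next
      r[, j] <- r[, j] + (m[, l] < m[, j]) + 0.5 * (m[, l] == m[, j])
    }
  }
  g <- seq_len(k)
  rc <- r - rowMeans(r)
  gc <- g - mean(g)
  denom <- sqrt(rowSums(rc^2) * sum(gc^2))
  out <- as.vector(rc %*% gc) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Dose-response check for one titration series
#'
#' A genuine autoantibody signal tracks the antigen titration: RU rises with
#' the coat concentration. The check requires the Spearman rank correlation
#' between RU and coat level to reach a threshold (default 0.8). A constant
#' series has no rank correlation and fails.
#'
#' @param titration numeric RU values ordered by increasing coat level
#'   (at least 3 points).
#' @param threshold minimum Spearman correlation. Default 0.8.
#' @return `TRUE` or `FALSE`.
#' @export
dose_response_ok <- function(titration, threshold = 0.8) {
  if (length(titration) < 3)
    stop("dose-response check needs at least 3 titration points", call. = FALSE)
  rho <- row_spearman(matrix(titration, nrow = 1))
  !is.na(rho) && rho >= threshold
}

#' Call one antigen measurement against a cutoff
#'
#' @param titration numeric RU series ordered by increasing coat level.
#' @param cutoff RU cutoff; the call is positive only if the reference RU
#'   strictly exceeds it (a tie at the cutoff is negative).
#' @param dose_response_required must the series also pass
#'   [dose_response_ok()]?
#' @param reference_index 1-based position of the reference coat level in
#'   `titration` (default: last, the full-strength coat).
#' @param threshold dose-response Spearman threshold.
#' @return list with `positive`, `ru_reference`, `dose_response_ok`.
#' @export
call_antigen <- function(titration, cutoff, dose_response_required = TRUE,
                         reference_index = length(titration), threshold = 0.8) {
  ru_ref <- titration[reference_index]
  dr <- dose_response_ok(titration, threshold)
  list(positive = (ru_ref > cutoff) && (dr || !dose_response_required),
       ru_reference = ru_ref,
       dose_response_ok = dr)
}

# Reference-RU and dose-response matrices (subjects x panel antigens) for a
# cohort, computed once so that cutoff search can re-score candidates
# cheaply. Errors name the first missing (subject, antigen) series.
cohort_call_matrices <- function(cohort, antigens, threshold = 0.8) {
  validate_cohort(cohort)
  bad <- setdiff(antigens, ANTIGENS)
  if (length(bad))
    stop("antigen not in the known set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ids <- cohort$subjects$subject_id
  m <- cohort$measurements[cohort$measurements$antigen %in% antigens, ,
                           drop = FALSE]
  k <- cohort$meta$n_coat_levels
  n <- length(ids)
  A <- length(antigens)
  i <- match(m$subject_id, ids)
  j <- match(m$antigen, antigens)
  ru <- array(NA_real_, c(n, A, k))
  ru[cbind(i, j, m$coat_level + 1L)] <- m$ru
  if (anyNA(ru)) {
    miss <- which(is.na(ru), arr.ind = TRUE)[1, ]
    stop(sprintf("missing measurement: subject %s, antigen %s, coat level %d",
                 ids[miss[1]], antigens[miss[2]], miss[3] - 1L), call. = FALSE)
  }
  flat <- matrix(ru, n * A, k)            # series in rows, coat level in cols
  rho <- row_spearman(flat)
  dr <- matrix(!is.na(rho) & rho >= threshold, n, A)
  ru_ref <- matrix(flat[, cohort$meta$reference_level + 1L], n, A)
  dimnames(ru_ref) <- dimnames(dr) <- list(ids, antigens)
  list(ru_ref = ru_ref, dr = dr)
}

#' Call a whole cohort against a panel
#'
#' Applies the per-antigen cutoff rule (and, if the panel requires it, the
#' dose-response check) to every subject, and combines antigen calls into
#' panel positivity by the any-positive (OR) rule.
#'
#' @param cohort an `aab_cohort` containing a full titration series for
#'   every subject x panel antigen.
#' @param panel an [panel_definition()].
#' @param threshold dose-response Spearman threshold. Default 0.8.
#' @return an `aab_calls` data.frame: `subject_id`, one logical column per
#'   panel antigen, and `panel_positive`.
#' @export
call_panel <- function(cohort, panel, threshold = 0.8) {
  stopifnot(inherits(panel, "aab_panel"))
  cm <- cohort_call_matrices(cohort, panel$antigens, threshold)
  pos <- sweep(cm$ru_ref, 2, panel$cutoffs, ">")
  if (panel$dose_response_required) pos <- pos & cm$dr
  calls <- data.frame(subject_id = rownames(cm$ru_ref),
                      pos, check.names = FALSE,
                      panel_positive = rowSums(pos) > 0,
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  class(calls) <- c("aab_calls", "data.frame")
  attr(calls, "antigens") <- panel$antigens
  attr(calls, "panel") <- panel$name
  calls
}

#' Concordance between two call sets
#'
#' Percentage of subjects with the same panel outcome under two assay
#' versions. Symmetric; subjects are matched by id.
#'
#' @param calls_a,calls_b `aab_calls` data.frames over the same subjects.
#' @return percent agreement in `[0, 100]`.
#' @export
concordance <- function(calls_a, calls_b) {
  if (!setequal(calls_a$subject_id, calls_b$subject_id))
    stop("call sets cover different subjects", call. = FALSE)
  b <- calls_b[match(calls_a$subject_id, calls_b$subject_id), ]
  100 * mean(calls_a$panel_positive == b$panel_positive)
}
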