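# Fixture builders shared across tests. Cohorts are constructed in code;
# nothing is read from disk unless the test is about file I/O.

default_subject_row <- function(subject_id, cohort = "control",
                                cancer_status = if (cohort == "cancer") "confirmed" else "none",
                                subtype = if (cohort == "cancer") "NSCLC" else "none",
                                stage_group = "unknown", age = 60,
                                gender = "male", smoking = "ex",
                                smoking_years = 30, quit_years = 5) {
  data.frame(subject_id = subject_id, cohort = cohort,
             cancer_status = cancer_status, subtype = subtype,
             stage_group = stage_group, age = age, gender = gender,
             smoking = smoking, smoking_years = smoking_years,
             quit_years = quit_years, stringsAsFactors = FALSE)
}

# Cohort from a reference-RU matrix (subjects x antigens). Titration series
# rise monotonically toward the full-strength coat (dose response present)
# unless the (subject, antigen) pair is listed in `flat`, whose series are
# constant (no dose response).
cohort_from_ru <- function(ru_ref, cohorts, flat = NULL, n_coat_levels = 4) {
  n <- nrow(ru_ref)
  antigens <- colnames(ru_ref)
  ids <- sprintf("X%04d", seq_len(n))
  subjects <- do.call(rbind, lapply(seq_len(n), function(i)
    default_subject_row(ids[i], cohorts[i])))
  profile <- seq(0.25, 1, length.out = n_coat_levels)
  rows <- list()
  for (j in seq_along(antigens)) {
    for (lv in seq_len(n_coat_levels) - 1L) {
      f <- rep(profile[lv + 1L], n)
      if (!is.null(flat)) {
        is_flat <- paste(ids, antigens[j]) %in% flat
        f[is_flat] <- 1
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ids, antigen = antigens[j], coat_level = lv,
        ru = ru_ref[, j] * f, stringsAsFactors = FALSE)
    }
  }
  aab_cohort(subjects, do.call(rbind, rows), n_coat_levels = n_coat_levels)
}

# Two-subject, two-antigen cohort used by the I/O round-trip tests.
tiny_cohort <- function() {
  ru <- matrix(c(5, 40, 2, 3), nrow = 2,
               dimnames = list(NULL, c("p53", "HuD")))
  cohort_from_ru(ru, c("cancer", "control"))
}

# Exhaustive cutoff search: the independent oracle mc_search is checked
# against. Same feasibility band and tie-break (free metric desc,
# constrained desc, lexicographically smallest cutoffs).
exhaustive_search <- function(cohort, antigens, grids, mode, target,
                              tolerance) {
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(combos) <- antigens
  res <- t(apply(combos, 1, function(cut) {
    panel <- panel_definition("cand", antigens, stats::setNames(cut, antigens))
    op <- validate_cutoffs(cohort, panel)
    c(sens = op$sensitivity, spec = op$specificity)
  }))
  constrained <- if (mode == "fix_specificity") res[, "spec"] else res[, "sens"]
  free <- if (mode == "fix_specificity") res[, "sens"] else res[, "spec"]
  feasible <- abs(constrained - target) <= tolerance
  ord <- do.call(order, c(list(-free, -constrained),
                          lapply(seq_along(antigens), function(j) combos[, j])))
  ord <- ord[feasible[ord]]
  list(cutoffs = stats::setNames(as.numeric(combos[ord[1], ]), antigens),
       sens = unname(res[ord[1], "sens"]), spec = unname(res[ord[1], "spec"]),
       n_feasible = sum(feasible))
}
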