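# Monte-Carlo direct search over per-antigen cutoff sets. Candidate cutoff
# vectors are drawn uniformly (with replacement, independently per antigen)
# from per-antigen grids anchored to the control RU distribution; each
# candidate is scored by panel calling; among candidates whose constrained
# metric lands within a tolerance band of the target, the one maximizing the
# free metric wins. This is the package's central fitting routine.

#' Configure the cutoff search
#'
#' @param mode `"fix_specificity"` (maximize sensitivity at a target
#'   specificity) or `"fix_sensitivity"` (maximize specificity at a target
#'   sensitivity).
#' @param target target value of the constrained metric, percent.
#' @param tolerance half-width of the acceptance band around `target`,
#'   percentage points. With a finite cohort exact equality is generically
#'   unattainable; default 0.5.
#' @param n_candidates number of random cutoff sets to evaluate. Default
#'   10000.
#' @param grid_quantiles probabilities defining the default per-antigen
#'   candidate grid as empirical quantiles of control RU. Default: 0.800 to
#'   0.999 in steps of 0.001 (the 80th-99.9th percentiles at 0.1-percentile
#'   steps).
#' @param candidate_grid optional named list of explicit sorted cutoff
#'   vectors per antigen, overriding the quantile grid.
#' @param adjust_occult evaluate candidate specificity after the
#'   occult-cancer adjustment ([adjusted_specificity()])?
#' @param risk_config [risk_model_config()] used when `adjust_occult=TRUE`.
#' @param dose_response_required,threshold calling policy for candidate
#'   panels.
#' @param top_k number of best candidates kept in the audit log.
#' @param seed integer seed for the candidate draw.
#' @return an object of class `search_config`.
#' @export
search_config <- function(mode = c("fix_specificity", "fix_sensitivity"),
                          target = 90, tolerance = 0.5,
                          n_candidates = 10000L,
                          grid_quantiles = seq(0.800, 0.999, by = 0.001),
                          candidate_grid = NULL,
                          adjust_occult = FALSE,
                          risk_config = risk_model_config(),
                          dose_response_required = TRUE,
                          threshold = 0.8,
                          top_k = 10L,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (target <= 0 || target >= 100)
    stop("target must be a percentage in (0, 100)", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  if (n_candidates < 1) stop("n_candidates must be at least 1", call. = FALSE)
  if (!is.null(candidate_grid)) {
    for (a in names(candidate_grid)) {
      g <- candidate_grid[[a]]
      if (!length(g) || is.unsorted(g))
        stop("candidate grid for ", a, " must be nonempty and sorted",
             call. = FALSE)
    }
  }
  structure(list(mode = mode, target = target, tolerance = tolerance,
                 n_candidates = as.integer(n_candidates),
                 grid_quantiles = grid_quantiles,
                 candidate_grid = candidate_grid,
                 adjust_occult = isTRUE(adjust_occult),
                 risk_config = risk_config,
                 dose_response_required = isTRUE(dose_response_required),
                 threshold = threshold,
                 top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Occult-cancer-adjusted specificity
#'
#' A nominally disease-free high-risk control group contains some occult
#' (undiagnosed) cancers, which deflate apparent specificity: a true signal
#' in an occult case is counted as a false positive. Given per-control
#' 5-year risks, the expected occult count is `E = sum(risks)`; the expected
#' number of observed false positives attributable to occult disease is
#' `sensitivity * E`, so the adjusted false-positive count is
#' `max(0, FP - sensitivity*E)` over an effective disease-free denominator
#' `N - E`.
#'
#' @param fp observed false-positive count among the controls.
#' @param n_controls number of controls.
#' @param risks per-control absolute risks in `[0, 1]` (length `n_controls`
#'   or a single value recycled).
#' @param sensitivity panel sensitivity as a fraction in `[0, 1]`.
#' @return adjusted specificity in percent.
#' @export
adjusted_specificity <- function(fp, n_controls, risks, sensitivity) {
  if (any(risks < 0 | risks > 1)) stop("risks must lie in [0, 1]", call. = FALSE)
  if (sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must be a fraction in [0, 1]", call. = FALSE)
  risks <- rep_len(risks, n_controls)
  E <- sum(risks)
  if (E >= n_controls)
    stop("expected occult count reaches the control group size", call. = FALSE)
  adj_fp <- max(0, fp - sensitivity * E)
  100 * (1 - adj_fp / (n_controls - E))
}

# Evaluate sens/spec (and optionally adjusted spec) for candidate cutoff
# matrices against precomputed call matrices. `cuts` is n_cand x A.
score_candidates <- function(cuts, ru_ref, dr, is_cancer, is_control,
                             dose_required, risks = NULL) {
  n <- nrow(ru_ref)
  ncase <- sum(is_cancer); nctrl <- sum(is_control)
  sens <- spec <- adj <- numeric(nrow(cuts))
  use_dr <- if (dose_required) dr else matrix(TRUE, n, ncol(ru_ref))
  E <- if (!is.null(risks)) sum(risks) else NULL
  for (c_i in seq_len(nrow(cuts))) {
    pos <- rowSums(use_dr &
                     (ru_ref > rep(cuts[c_i, ], each = n))) > 0
    tp <- sum(pos & is_cancer)
    fp <- sum(pos & is_control)
    sens[c_i] <- 100 * tp / ncase
    spec[c_i] <- 100 * (nctrl - fp) / nctrl
    if (!is.null(E))
      adj[c_i] <- {
        afp <- max(0, fp - (tp / ncase) * E)
        100 * (1 - afp / (nctrl - E))
      }
  }
  list(sens = sens, spec = spec, adj = if (!is.null(E)) adj else NULL)
}

#' Fit panel cutoffs by Monte-Carlo direct search
#'
#' The package's central estimator. Draws `n_candidates` cutoff sets
#' uniformly (with replacement, independently per antigen) from per-antigen
#' grids — by default, percentiles of the control RU distribution — scores
#' every candidate by panel calling on the cohort, and among candidates
#' whose constrained metric (specificity or sensitivity; specificity taken
#' occult-adjusted when `adjust_occult`) lies within `tolerance` of
#' `target`, returns the candidate maximizing the free metric. Ties are
#' broken by the better constrained metric, then by the lexicographically
#' smallest cutoff vector, so a given seed fully determines the result.
#'
#' @param cohort an `aab_cohort` containing cancer and control subjects.
#' @param antigens character vector of panel antigens to optimize over.
#' @param config a [search_config()].
#' @return an object of class `cutoff_fit` with components `cutoffs` (named
#'   vector), `panel` (an [panel_definition()]), `achieved` (an
#'   [operating_point()] recomputed from the fitted panel), `n_feasible`,
#'   `audit_log` (top-k candidates), `config` and `seed`. Supports
#'   [coef()], [print()], [summary()], [predict()] and [plot()].
#' @examples
#' cfg <- cohort_sim_config(n_cancer = 120, n_control = 150, seed = 7)
#' cohort <- generate_cohort(cfg)
#' fit <- mc_search(cohort, panel7_antigens,
#'                  search_config(mode = "fix_specificity", target = 90,
#'                                n_candidates = 500, seed = 7))
#' coef(fit)
#' @export
mc_search <- function(cohort, antigens, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  validate_cohort(cohort)
  s <- cohort$subjects
  is_cancer <- s$cohort == "cancer"
  is_control <- s$cohort == "control"
  if (!any(is_cancer) || !any(is_control))
    stop("mc_search needs both cancer and control subjects", call. = FALSE)

  cm <- cohort_call_matrices(cohort, antigens, config$threshold)
  A <- length(antigens)

  grids <- lapply(antigens, function(a) {
    if (!is.null(config$candidate_grid)) {
      g <- config$candidate_grid[[a]]
      if (is.null(g)) stop("no candidate grid for antigen ", a, call. = FALSE)
      g
    } else {
      ctrl_ru <- cm$ru_ref[is_control, a]
      unique(stats::quantile(ctrl_ru, config$grid_quantiles, type = 1,
                             names = FALSE))
    }
  })
  names(grids) <- antigens

  risks <- NULL
  if (config$adjust_occult) {
    risks <- cohort_risks(cohort, config$risk_config,
                          subset = s$subject_id[is_control])
    if (length(risks) < sum(is_control))
      warning(sum(is_control) - length(risks),
              " control subject(s) without evaluable risk excluded from the ",
              "occult adjustment denominator")
    is_control <- is_control & s$subject_id %in% names(risks)
  }

  set.seed(config$seed)
  idx <- vapply(grids, function(g)
    sample.int(length(g), config$n_candidates, replace = TRUE),
    integer(config$n_candidates))
  idx <- matrix(idx, ncol = A)
  cuts <- matrix(0, config$n_candidates, A, dimnames = list(NULL, antigens))
  for (j in seq_len(A)) cuts[, j] <- grids[[j]][idx[, j]]

  sc <- score_candidates(cuts, cm$ru_ref, cm$dr, is_cancer, is_control,
                         config$dose_response_required, risks)
  constrained <- if (config$mode == "fix_specificity") {
    if (config$adjust_occult) sc$adj else sc$spec
  } else sc$sens
  free <- if (config$mode == "fix_specificity") sc$sens else {
    if (config$adjust_occult) sc$adj else sc$spec
  }

  feasible <- abs(constrained - config$target) <= config$tolerance
  if (!any(feasible)) {
    nearest <- which.min(abs(constrained - config$target))
    stop(sprintf(
      "no candidate met %s within %.3g points of %.3g%%; nearest miss: %.2f%% (cutoffs %s)",
      config$mode, config$tolerance, config$target, constrained[nearest],
      paste(signif(cuts[nearest, ], 4), collapse = ", ")), call. = FALSE)
  }

  # Rank: free metric desc, constrained desc, then lexicographically
  # smallest cutoff vector.
  ord <- do.call(order, c(list(-free, -constrained),
                          lapply(seq_len(A), function(j) cuts[, j])))
  ord <- ord[feasible[ord]]
  best <- ord[1]

  top <- utils::head(ord, config$top_k)
  audit <- data.frame(cuts[top, , drop = FALSE],
                      sensitivity = sc$sens[top], specificity = sc$spec[top],
                      check.names = FALSE)
  if (!is.null(sc$adj)) audit$adjusted_specificity <- sc$adj[top]

  best_cutoffs <- cuts[best, ]
  panel <- panel_definition(
    name = sprintf("mc_%s_%g", sub("fix_", "", config$mode), config$target),
    antigens = antigens, cutoffs = best_cutoffs,
    dose_response_required = config$dose_response_required)

  achieved <- validate_cutoffs(cohort, panel, threshold = config$threshold)
  if (config$adjust_occult)
    achieved$adjusted_specificity <-
      adjusted_specificity(achieved$fp, achieved$fp + achieved$tn, risks,
                           achieved$sensitivity / 100)

  structure(list(cutoffs = best_cutoffs, panel = panel, achieved = achieved,
                 n_feasible = sum(feasible),
                 n_candidates = config$n_candidates,
                 audit_log = audit, grids = grids,
                 candidates = data.frame(sensitivity = sc$sens,
                                         specificity = sc$spec,
                                         feasible = feasible),
                 config = config, seed = config$seed),
            class = "cutoff_fit")
}

#' Evaluate a fixed panel on a cohort
#'
#' Computes the operating point of a panel with fixed cutoffs on an
#' evaluation cohort — typically one disjoint from the cohort the cutoffs
#' were fitted on (held-out validation).
#'
#' @param cohort an `aab_cohort` with cancer and control subjects.
#' @param panel an [panel_definition()].
#' @param threshold dose-response Spearman threshold.
#' @param search_subjects optional subject ids used during fitting; overlap
#'   with the evaluation cohort triggers a warning.
#' @return an [operating_point()].
#' @export
validate_cutoffs <- function(cohort, panel, threshold = 0.8,
                             search_subjects = NULL) {
  s <- cohort$subjects
  if (!is.null(search_subjects)) {
    ov <- intersect(search_subjects, s$subject_id)
    if (length(ov))
      warning(length(ov), " subject(s) overlap between the search and ",
              "validation cohorts; the operating point is not held-out")
  }
  calls <- call_panel(cohort, panel, threshold)
  labelled <- s$cohort %in% c("cancer", "control")
  truth <- data.frame(subject_id = s$subject_id,
                      true_cancer = s$cohort == "cancer")
  operating_point(calls[labelled[match(calls$subject_id, s$subject_id)], ],
                  truth)
}

#' @export
coef.cutoff_fit <- function(object, ...) object$cutoffs

#' @export
print.cutoff_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo cutoff search (%s at %g%% +/- %g, %d candidates, seed %d)\n",
              cfg$mode, cfg$target, cfg$tolerance, x$n_candidates, x$seed))
  cat(sprintf("  %d feasible candidate(s); best cutoffs:\n", x$n_feasible))
  print(signif(x$cutoffs, 4))
  print(x$achieved)
  invisible(x)
}

#' @export
summary.cutoff_fit <- function(object, ...) {
  print(object)
  cat("\nTop candidates (audit log):\n")
  print(cbind(round(object$audit_log[, object$panel$antigens, drop = FALSE], 3),
              round(object$audit_log[, setdiff(names(object$audit_log),
                                               object$panel$antigens),
                                     drop = FALSE], 2)))
  cat(sprintf("\nCalling policy: dose response %s (Spearman >= %g), ties at the cutoff negative\n",
              if (object$config$dose_response_required) "required" else "off",
              object$config$threshold))
  invisible(object)
}

#' Apply a fitted panel to a (new) cohort
#'
#' @param object a `cutoff_fit`.
#' @param cohort an `aab_cohort`; the calls are computed with the fitted
#'   cutoffs and calling policy.
#' @param ... ignored.
#' @return an `aab_calls` data.frame.
#' @export
predict.cutoff_fit <- function(object, cohort, ...) {
  call_panel(cohort, object$panel, object$config$threshold)
}

#' Candidate cloud of a cutoff search
#'
#' Scatter of every evaluated candidate's (specificity, sensitivity), with
#' the feasibility band and the selected optimum highlighted.
#'
#' @param x a `cutoff_fit`.
#' @param ... ignored.
#' @export
plot.cutoff_fit <- function(x, ...) {
  d <- x$candidates
  graphics::plot(d$specificity, d$sensitivity, pch = 16, cex = 0.4,
                 col = ifelse(d$feasible, "firebrick", "grey70"),
                 xlab = "Specificity (%)", ylab = "Sensitivity (%)",
                 main = "Monte-Carlo cutoff search candidates")
  if (x$config$mode == "fix_specificity" && !x$config$adjust_occult)
    graphics::abline(v = x$config$target + c(-1, 1) * x$config$tolerance,
                     lty = 3)
  if (x$config$mode == "fix_sensitivity")
    graphics::abline(h = x$config$target + c(-1, 1) * x$config$tolerance,
                     lty = 3)
  graphics::points(x$achieved$specificity, x$achieved$sensitivity, pch = 8,
                   cex = 1.5, col = "blue")
  invisible(x)
}
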