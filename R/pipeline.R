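# Orchestration: a single structured-text (YAML) config drives
# simulate -> optimize -> validate -> report, with per-stage seeds derived
# from one master seed by fixed offsets so stages are independently
# reproducible. Every run writes a manifest.

stage_seed <- function(master, stage) {
  # Fixed offsets keep stage streams distinct yet fully determined by the
  # master seed; kept small so derived seeds stay within integer range.
  offsets <- c(simulate = 101L, holdout = 202L, optimize = 303L)
  master + offsets[[stage]]
}

read_sim_block <- function(block, seed) {
  args <- block[intersect(names(block), names(formals(cohort_sim_config)))]
  args$seed <- seed
  do.call(cohort_sim_config, args)
}

#' Run an end-to-end panel-design pipeline from a config file
#'
#' The config is a YAML document with a master `seed`, an `antigens` list,
#' and optional `simulate`, `optimize` and `report` blocks. The pipeline
#' generates a training and a held-out synthetic cohort, fits cutoffs by
#' [mc_search()], evaluates the fitted panel held-out, and writes
#' `subjects.csv`/`measurements.csv`/`truth.csv`, `panel.yaml`,
#' `report.json` and `manifest.json` under `out_dir`. Reruns with an
#' identical config produce identical artifacts.
#'
#' @param config_path path to the YAML config.
#' @param out_dir output directory (default: `out_dir` from the config,
#'   else a tempdir).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the fitted `cutoff_fit`, the held-out
#'   [operating_point()] and the report list.
#' @export
run_pipeline <- function(config_path, out_dir = NULL, quiet = FALSE) {
  if (!file.exists(config_path))
    stop("config not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$seed)) stop("pipeline config: missing 'seed'", call. = FALSE)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("serodx_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("serodx: ", sprintf(...))
  master <- as.integer(cfg$seed)
  antigens <- unlist(cfg$antigens) %||% panel7_antigens

  if (is.null(cfg$simulate))
    stop("pipeline config: missing 'simulate' block", call. = FALSE)
  sim_cfg <- read_sim_block(cfg$simulate, stage_seed(master, "simulate"))
  say("simulate stage=simulate seed=%d n=%d", sim_cfg$seed,
      sim_cfg$n_cancer + sim_cfg$n_control + sim_cfg$n_at_risk)
  cohort <- generate_cohort(sim_cfg)
  write_cohort(cohort, file.path(out_dir, "subjects.csv"),
               file.path(out_dir, "measurements.csv"))
  utils::write.csv(truth_table(cohort), file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)

  fit <- NULL
  holdout_op <- NULL
  report <- list(seed = master, antigens = antigens)
  if (!is.null(cfg$optimize)) {
    ob <- cfg$optimize
    scfg <- search_config(
      mode = ob$mode %||% "fix_specificity",
      target = ob$target %||% 90,
      tolerance = ob$tolerance %||% 0.5,
      n_candidates = ob$n_candidates %||% 10000L,
      adjust_occult = isTRUE(ob$adjust_occult),
      dose_response_required = ob$dose_response_required %||% TRUE,
      threshold = ob$threshold %||% 0.8,
      seed = stage_seed(master, "optimize"))
    say("optimize mode=%s target=%g n_candidates=%d seed=%d dr_threshold=%g ci=clopper-pearson tie_break=free,constrained,lexicographic",
        scfg$mode, scfg$target, scfg$n_candidates, scfg$seed, scfg$threshold)
    fit <- mc_search(cohort, antigens, scfg)
    write_panel(fit$panel, file.path(out_dir, "panel.yaml"))

    holdout_cfg <- read_sim_block(cfg$simulate, stage_seed(master, "holdout"))
    holdout <- generate_cohort(holdout_cfg)
    holdout_op <- validate_cutoffs(holdout, fit$panel,
                                   threshold = scfg$threshold)
    report$fitted <- list(cutoffs = as.list(fit$cutoffs),
                          n_feasible = fit$n_feasible,
                          achieved = unclass_op(fit$achieved))
    report$holdout <- unclass_op(holdout_op)
  }

  if (!is.null(cfg$report$prevalence) && !is.null(holdout_op)) {
    pv <- as.numeric(cfg$report$prevalence)
    s <- holdout_op$sensitivity / 100
    sp <- holdout_op$specificity / 100
    report$scenarios <- lapply(pv, function(p) list(
      prevalence = p,
      ppv = ppv(s, sp, p),
      one_in_n = one_in_n(ppv(s, sp, p)),
      accuracy = accuracy(s, sp, p)))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(command = "run_pipeline",
                   config = cfg,
                   config_digest = digest_file(config_path),
                   seeds = list(master = master,
                                simulate = stage_seed(master, "simulate"),
                                holdout = stage_seed(master, "holdout"),
                                optimize = stage_seed(master, "optimize")),
                   package_version = as.character(utils::packageVersion("serodx")),
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done out_dir=%s", out_dir)
  invisible(list(fit = fit, holdout = holdout_op, report = report,
                 out_dir = out_dir))
}

unclass_op <- function(op) {
  list(tp = op$tp, fn = op$fn, fp = op$fp, tn = op$tn,
       sensitivity = op$sensitivity,
       sensitivity_ci = as.list(op$sensitivity_ci),
       specificity = op$specificity,
       specificity_ci = as.list(op$specificity_ci),
       adjusted_specificity = op$adjusted_specificity)
}

digest_file <- function(path) {
  # Cheap content fingerprint (sum of bytes); enough to tie a manifest to
  # the config text without extra dependencies.
  bytes <- readBin(path, "raw", file.info(path)$size)
  sprintf("size=%d;sum=%.0f", length(bytes), sum(as.integer(bytes)))
}

#' Recompute the published panel performance figures
#'
#' Recomputes, from the published 2x2 audit counts and operating
#' characteristics of the six- and seven-autoantibody EarlyCDT-Lung panels,
#' every headline figure this package's statistics reproduce: audit
#' sensitivity/specificity, the positive-test cancer fraction, PPV and
#' accuracy under the published prevalence scenarios, "1 in N" PPV
#' expressions, false-positive reductions, the panel-comparison chi-squared
#' p-values, and example exact binomial intervals. Each row compares the
#' recomputed value with the published one at presentation precision.
#'
#' @return data.frame with columns `figure`, `computed`, `published`,
#'   `pass`.
#' @export
reproduce_published_figures <- function() {
  rows <- list()
  add <- function(figure, computed, published, pass = NULL) {
    rows[[length(rows) + 1]] <<- data.frame(
      figure = figure, computed = computed, published = published,
      pass = pass %||% isTRUE(all.equal(computed, published)))
  }

  # Audit 2x2 tables: panel of 6 (25 cancers, 10 positive; 751 non-cancers,
  # 135 positive) and panel of 7 (19 cancers, 9 positive; 817 non-cancers,
  # 78 positive).
  op6 <- operating_point_from_counts(tp = 10, fn = 15, fp = 135, tn = 616)
  op7 <- operating_point_from_counts(tp = 9, fn = 10, fp = 78, tn = 739)
  add("panel6 audit sensitivity (%)", percent_round(op6$sensitivity), 40)
  add("panel6 audit specificity (%)", percent_round(op6$specificity), 82)
  add("panel7 audit sensitivity (%)", percent_round(op7$sensitivity), 47)
  add("panel7 audit specificity (%)", percent_round(op7$specificity), 90)
  add("panel7 positive-test cancer fraction (%)",
      percent_round(100 * 9 / (9 + 78), 1), 10.3)

  # PPV / accuracy scenarios.
  add("PPV s=41 sp=93 prev=2.4 (%)", percent_round(ppv(.41, .93, .024)), 13)
  add("PPV s=41 sp=93 prev=2.4 (1 in N)", one_in_n(ppv(.41, .93, .024)), 8)
  add("PPV s=41 sp=93 prev=1.3 (%)", percent_round(ppv(.41, .93, .013)), 7)
  add("PPV s=41 sp=93 prev=1.3 (1 in N)", one_in_n(ppv(.41, .93, .013)), 14)
  add("PPV s=39 sp=90 prev=2.4 (%)", percent_round(ppv(.39, .90, .024)), 9)
  add("PPV s=39 sp=90 prev=2.4 (1 in N)", one_in_n(ppv(.39, .90, .024)), 11)
  add("audit PPV panel6 s=40 sp=82 prev=3.1 (1 in N)",
      one_in_n(ppv(.40, .82, .031)), 15)
  add("audit PPV panel7 s=47 sp=90 prev=2.4 (1 in N)",
      one_in_n(ppv(.47, .90, .024)), 10)
  add("accuracy s=41 sp=93 prev=2.4 (%)", percent_round(accuracy(.41, .93, .024)), 92)
  add("accuracy s=39 sp=90 prev=2.4 (%)", percent_round(accuracy(.39, .90, .024)), 89)

  # False-positive reductions.
  add("FP reduction 90 -> 93 (%)",
      percent_round(reduction_in_false_positives(90, 93)), 30)
  add("FP reduction 82 -> 90 (%)",
      percent_round(reduction_in_false_positives(82, 90)), 44)

  # Panel comparison tests (Pearson chi-squared, no continuity correction).
  p_spec <- compare_proportions(135, 751, 78, 817)$p
  add("specificity comparison p < 0.0001", p_spec, 1e-4, pass = p_spec < 1e-4)
  p_sens <- compare_proportions(10, 25, 9, 19)$p
  add("sensitivity comparison p (~0.63)", round(p_sens, 2), 0.63,
      pass = abs(p_sens - 0.63) <= 0.01)

  # Exact binomial intervals at whole-percent presentation.
  ci1 <- percent_round(binomial_ci(9, 53))
  add("CI 9/53 lower (%)", ci1[["lower"]], 8)
  add("CI 9/53 upper (%)", ci1[["upper"]], 30)
  ci2 <- percent_round(binomial_ci(31, 235))
  add("CI 31/235 lower (%)", ci2[["lower"]], 9)
  add("CI 31/235 upper (%)", ci2[["upper"]], 18)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
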