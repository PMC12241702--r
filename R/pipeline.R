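# ---- end-to-end pipeline ---------------------------------------------------

#' Pipeline run configuration
#'
#' @param input_trials,input_transactions Paths to input CSVs, or `NULL` to
#'   simulate a cohort instead.
#' @param sim_spec A [cohort_spec()] used when no input files are given.
#' @param seed Root seed for the run.
#' @param n_levels Confidence scale length.
#' @param convention Learning-point convention (see [detect_learning()]).
#' @param censoring How censored (never-learning) subjects enter the
#'   correlations: `"rank_cap"` (default; assigned phase length + 1, i.e.
#'   tied at the worst rank) or `"exclude"`.
#' @param hierarchical If `TRUE`, also run the hierarchical Bayesian
#'   M-ratio fit and use its posterior-mean subject M-ratios in the group
#'   comparison (per-subject MLE is the default pathway).
#' @param hier_chains,hier_draws,hier_warmup MCMC layout for the
#'   hierarchical fit when enabled.
#' @param out_dir Output directory (created if needed).
#' @return List of class `run_config`.
#' @export
run_config <- function(input_trials = NULL, input_transactions = NULL,
                       sim_spec = NULL, seed = 1L, n_levels = 4L,
                       convention = "run_end",
                       censoring = c("rank_cap", "exclude"),
                       hierarchical = FALSE,
                       hier_chains = 4L, hier_draws = 2000L,
                       hier_warmup = 1000L,
                       out_dir = tempfile("metaflex_")) {
  censoring <- match.arg(censoring)
  structure(list(input_trials = input_trials,
                 input_transactions = input_transactions,
                 sim_spec = sim_spec, seed = as.integer(seed),
                 n_levels = as.integer(n_levels), convention = convention,
                 censoring = censoring, hierarchical = hierarchical,
                 hier_chains = as.integer(hier_chains),
                 hier_draws = as.integer(hier_draws),
                 hier_warmup = as.integer(hier_warmup),
                 out_dir = out_dir), class = "run_config")
}

#' Validate an input CSV
#'
#' Checks the header, value domains (confidence within the scale, rewards
#' in {5, 10, 20}, aliens 1-3, minerals 1-4) and per-subject trial counts
#' (72 rotation trials, 68 game trials expected).
#'
#' @param path File path.
#' @param type `"trials"` or `"transactions"`.
#' @param n_levels Confidence scale length.
#' @param expected_trials Expected per-subject rows (default 72 / 68).
#' @return List with `ok` (logical), `errors`, `warnings` (character
#'   vectors naming offending rows).
#' @export
validate_input <- function(path, type = c("trials", "transactions"),
                           n_levels = 4L, expected_trials = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) abort("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  errs <- character(); warns <- character()
  chk <- function(bad, what) {
    if (length(bad))
      errs <<- c(errs, sprintf("%s in row %s", what,
                               paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (type == "trials") {
    expected_trials <- expected_trials %||% 72L
    need <- c("subject_id", "stimulus", "response", "confidence")
    miss <- setdiff(need, names(d))
    if (length(miss))
      return(list(ok = FALSE,
                  errors = sprintf("missing columns: %s",
                                   paste(miss, collapse = ", ")),
                  warnings = character()))
    lv <- c("identical", "different")
    chk(which(!(d$stimulus %in% lv)), "invalid stimulus")
    chk(which(!(d$response %in% lv)), "invalid response")
    chk(which(!(d$confidence %in% seq_len(n_levels))),
        sprintf("confidence outside 1..%d", n_levels))
  } else {
    expected_trials <- expected_trials %||% 68L
    need <- c("subject_id", "trial_index", "mineral", "alien", "reward")
    miss <- setdiff(need, names(d))
    if (length(miss))
      return(list(ok = FALSE,
                  errors = sprintf("missing columns: %s",
                                   paste(miss, collapse = ", ")),
                  warnings = character()))
    chk(which(!(d$mineral %in% 1:4)), "mineral outside 1..4")
    chk(which(!(d$alien %in% 1:3)), "alien outside 1..3")
    chk(which(!(d$reward %in% c(5L, 10L, 20L))), "reward not in {5,10,20}")
  }
  cnt <- table(d$subject_id)
  off <- names(cnt)[cnt != expected_trials]
  if (length(off))
    warns <- c(warns, sprintf("subject %s has %d rows, expected %d",
                              off, as.integer(cnt[off]), expected_trials))
  list(ok = length(errs) == 0L, errors = errs, warnings = warns)
}

# correlation-ready re-learning / learning values under the censoring policy
apply_censoring <- function(speed, learned, phase_len, policy) {
  if (policy == "rank_cap") ifelse(learned, speed, phase_len + 1L)
  else ifelse(learned, speed, NA_integer_)
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, fits per-subject type-2 SDT, scores the
#' trading game, and runs the inference layer: group x region ANOVAs on d'
#' and M-ratio, the mixed accuracy x group x region ANOVA on confidence,
#' the ANCOVA on re-learning speed with learning speed as covariate, and
#' the Spearman / partial Spearman correlation battery with Fisher-z group
#' comparisons. Writes `fits.csv`, `game_metrics.csv`, `stats_report.csv`,
#' `correlations.csv` and `run.log` to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with elements `fits`, `game`,
#'   `cohort`, `anova` (named list of `anova_result`), `correlations`
#'   (data frame), `comparisons` (data frame), `hierarchical` (or `NULL`),
#'   `config`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$input_trials)) {
    trials <- read_trials(config$input_trials, config$n_levels)
    tx <- read_transactions(config$input_transactions)
  } else {
    spec <- config$sim_spec %||% cohort_spec(seed = config$seed)
    spec$seed <- as.integer(config$seed)
    sim <- simulate_cohort(spec)
    trials <- sim$trials; tx <- sim$transactions
  }
  fits <- fit_subjects(trials, config$n_levels)
  game <- score_subjects(tx, convention = config$convention)
  cohort <- merge(fits, game, by = "subject_id", sort = TRUE)
  conf_acc <- confidence_by_accuracy(trials)
  cohort <- merge(cohort, conf_acc[, c("subject_id", "conf_correct",
                                       "conf_incorrect")], by = "subject_id")
  phase_post <- 20L; phase_pre <- 48L
  cohort$relearn_cor <- apply_censoring(cohort$relearning_speed,
                                        cohort$learned_post, phase_post,
                                        config$censoring)
  cohort$learn_cor <- apply_censoring(cohort$learning_speed,
                                      cohort$learned_pre, phase_pre,
                                      config$censoring)

  hier <- NULL
  mratio_col <- "m_ratio"
  if (isTRUE(config$hierarchical)) {
    ids <- cohort$subject_id
    t2s <- lapply(ids, function(id)
      tabulate_type2(trials[trials$subject_id == id, , drop = FALSE],
                     config$n_levels))
    hier <- fit_meta_d_hierarchical(t2s, cohort$group,
                                    seed = split_seed(config$seed, 601L),
                                    n_chains = config$hier_chains,
                                    n_draws = config$hier_draws,
                                    n_warmup = config$hier_warmup)
    cohort$m_ratio_hier <- hier$subject_mratios
    mratio_col <- "m_ratio_hier"
  }

  anovas <- list(
    d_prime = two_way_anova(cohort$d_prime, cohort$group, cohort$region),
    m_ratio = two_way_anova(cohort[[mratio_col]], cohort$group, cohort$region),
    confidence_by_accuracy = mixed_anova(
      cohort[, c("conf_correct", "conf_incorrect")],
      cohort$group, cohort$region),
    relearning_ancova = two_way_anova(cohort$relearn_cor, cohort$group,
                                      cohort$region,
                                      covariate = cohort$learn_cor))

  corr_rows <- list()
  add_corr <- function(label, res) {
    corr_rows[[length(corr_rows) + 1L]] <<- data.frame(
      analysis = label, rho = res$rho, z = res$z, p = res$p, n = res$n,
      stringsAsFactors = FALSE)
    res
  }
  add_corr("learning_vs_relearning_all",
           spearman_corr(cohort$learn_cor, cohort$relearn_cor))
  per_group <- list()
  for (g in sort(unique(cohort$group))) {
    cg <- cohort[cohort$group == g, , drop = FALSE]
    per_group[[g]] <- list(
      mratio_relearning = add_corr(
        paste0("mratio_vs_relearning_", g),
        spearman_corr(cg[[mratio_col]], cg$relearn_cor)),
      mratio_learning = add_corr(
        paste0("mratio_vs_learning_", g),
        spearman_corr(cg[[mratio_col]], cg$learn_cor)),
      bias_learning = add_corr(
        paste0("bias_vs_learning_", g),
        spearman_corr(cg$meta_bias, cg$learn_cor)),
      bias_relearning = add_corr(
        paste0("bias_vs_relearning_", g),
        spearman_corr(cg$meta_bias, cg$relearn_cor)),
      partial_bias_relearning = add_corr(
        paste0("partial_bias_vs_relearning_", g),
        partial_spearman(cg$meta_bias, cg$relearn_cor, cg$learn_cor)))
  }
  comparisons <- NULL
  gs <- sort(unique(cohort$group))
  if (length(gs) == 2L) {
    cmp_row <- function(label, a, b) {
      z <- compare_correlations(a$rho, a$n, b$rho, b$n)
      data.frame(analysis = label, rho1 = a$rho, rho2 = b$rho,
                 z_observed = z$z_observed, p = z$p, stringsAsFactors = FALSE)
    }
    comparisons <- rbind(
      cmp_row("mratio_vs_relearning", per_group[[gs[1]]]$mratio_relearning,
              per_group[[gs[2]]]$mratio_relearning),
      cmp_row("mratio_vs_learning", per_group[[gs[1]]]$mratio_learning,
              per_group[[gs[2]]]$mratio_learning),
      cmp_row("bias_vs_relearning", per_group[[gs[1]]]$bias_relearning,
              per_group[[gs[2]]]$bias_relearning),
      cmp_row("partial_bias_vs_relearning",
              per_group[[gs[1]]]$partial_bias_relearning,
              per_group[[gs[2]]]$partial_bias_relearning))
  }
  correlations <- do.call(rbind, corr_rows)

  # outputs
  od <- config$out_dir
  utils::write.csv(fits, file.path(od, "fits.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(game, file.path(od, "game_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  stats_report <- do.call(rbind, lapply(names(anovas), function(nm) {
    a <- anovas[[nm]]
    data.frame(analysis = nm, as.data.frame(a), stringsAsFactors = FALSE)
  }))
  utils::write.csv(stats_report, file.path(od, "stats_report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(correlations, file.path(od, "correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg_flat <- config[setdiff(names(config), "sim_spec")]
  cfg_flat <- lapply(cfg_flat, function(v) if (is.null(v)) "NULL" else v)
  log_lines <- c(
    sprintf("metaflex %s", tryCatch(
      as.character(utils::packageVersion("metaflex")),
      error = function(e) "dev")),
    sprintf("seed: %d", config$seed),
    sprintf("config: %s", jsonlite::toJSON(cfg_flat, auto_unbox = TRUE)),
    sprintf("subjects: %d", nrow(cohort)),
    sprintf("timestamp-free deterministic run"))
  writeLines(log_lines, file.path(od, "run.log"))
  if (!is.null(hier)) {
    hier_report <- list(group_summary = hier$group_summary,
                        contrast = hier$contrast,
                        max_rhat = max(hier$rhat),
                        converged = hier$converged)
    jsonlite::write_json(hier_report, file.path(od, "hierarchical.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(list(fits = fits, game = game, cohort = cohort, anova = anovas,
                 correlations = correlations, comparisons = comparisons,
                 hierarchical = hier, config = config, out_dir = od),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("metaflex pipeline run: %d subjects, seed %d\n",
              nrow(x$cohort), x$config$seed))
  cat("\nANOVA (M-ratio ~ group * region):\n")
  print(as.data.frame(x$anova$m_ratio), row.names = FALSE, digits = 3)
  cat("\nCorrelations:\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  cat(sprintf("\noutputs in %s\n", x$out_dir))
  invisible(x)
}
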