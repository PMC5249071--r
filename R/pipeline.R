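#' Build a run configuration
#'
#' Assembles and validates the full set of knobs for one end-to-end run.
#' All defaults are the package's reference study conditions: the
#' calibrated 70-SNP panel, the published coarse pre-test marginals, a
#' 200,000-woman cohort, 5000 + 5000 AUC arms, prevalence 0.05, treatment
#' threshold 3%, and the five tiered testing strategies plus test-everyone.
#'
#' @param panel_path path to a panel file, or `NULL` to generate the
#'   reference panel.
#' @param risk_distribution_path path to a binned risk-distribution file,
#'   or `"coarse-marginals"` (default) for [bcsc_pretest_marginals()].
#' @param prevalence disease prevalence K in (0, 0.10].
#' @param treat_threshold treatment threshold on 5-year risk.
#' @param strategies list of strategy specs (see [benefit_curve()]).
#' @param n cohort size.
#' @param n_cases,n_controls AUC simulation arm sizes.
#' @param fh_rate family-history-positive rate in the cohort.
#' @param fh_relative_risk marginal family-history relative risk.
#' @param seed root seed; every stage seed is derived from it
#'   deterministically (stage index i uses `derive_seed(seed, i)`), so
#'   stages are independently reproducible.
#' @return a validated `run_config` list.
#' @export
run_config <- function(panel_path = NULL,
                       risk_distribution_path = "coarse-marginals",
                       prevalence = 0.05,
                       treat_threshold = 0.03,
                       strategies = list(
                         list(test_lower = 0.025, test_upper = 0.040),
                         list(test_lower = 0.025),
                         list(test_lower = 0.020),
                         list(test_lower = 0.015),
                         list(test_lower = 0.010),
                         list(test_lower = 0.000)
                       ),
                       n = 200000,
                       n_cases = 5000, n_controls = 5000,
                       fh_rate = 0.114,
                       fh_relative_risk = 2,
                       seed) {
  check_prevalence(prevalence)
  check_prob(treat_threshold, "treat_threshold")
  check_prob(fh_rate, "fh_rate", open_low = FALSE, open_high = FALSE)
  if (missing(seed)) stop("`seed` is mandatory: no silent nondeterminism",
                          call. = FALSE)
  cfg <- list(panel_path = panel_path,
              risk_distribution_path = risk_distribution_path,
              prevalence = prevalence, treat_threshold = treat_threshold,
              strategies = strategies, n = as.integer(n),
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              fh_rate = fh_rate, fh_relative_risk = fh_relative_risk,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value YAML matching the arguments of [run_config()];
#' `strategies` is a list of maps with `test_lower` / `test_upper`. Keys
#' not present fall back to the defaults. `overrides` (named list) wins
#' over the file.
#'
#' @param path YAML file path.
#' @param overrides named list of values that override the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes panel load/generation, the genotype model, discrimination
#' assessment, cohort synthesis and reclassification analysis, and writes
#' machine-readable outputs to `output_dir`:
#' \describe{
#'   \item{table1.csv}{proportion above the treatment threshold pre/post
#'     testing, overall and by family-history stratum}
#'   \item{table2.csv}{reclassification matrix with marginals}
#'   \item{table3.csv}{per-strategy tested/up/down percentages}
#'   \item{fig2.csv}{benefit-curve points (tested fraction vs benefit)}
#'   \item{auc.csv}{simulated and closed-form AUC with arm means}
#'   \item{manifest.yaml}{exact configuration echo, sufficient to
#'     reproduce the run}
#' }
#' Percentages are written both raw and rounded to one decimal. Identical
#' configurations produce byte-identical outputs.
#'
#' @param config a `run_config`.
#' @param output_dir directory for outputs (created if missing).
#' @return invisibly, a list with the in-memory results
#'   (`panel`, `discrimination`, `cohort`, `reclass`, `strategies`,
#'   `table1`).
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  panel <- pipeline_stage("panel", {
    if (is.null(config$panel_path)) {
      generate_reference_panel(seed = derive_seed(config$seed, 1))
    } else {
      read_panel(config$panel_path)
    }
  })
  dist <- pipeline_stage("risk-distribution", {
    if (identical(config$risk_distribution_path, "coarse-marginals")) {
      bcsc_pretest_marginals()
    } else {
      read_risk_distribution(config$risk_distribution_path)
    }
  })
  disc <- pipeline_stage("discrimination", {
    assess_discrimination(panel, config$n_cases, config$n_controls,
                          config$prevalence,
                          seed = derive_seed(config$seed, 2))
  })
  cohort <- pipeline_stage("cohort", {
    fh_adj <- if (config$fh_rate > 0) {
      fh_adjustment(
        config$fh_relative_risk,
        estimate_proportion_explained(panel, config$fh_relative_risk,
                                      config$prevalence)
      )
    }
    sample_cohort(dist, config$n, panel, fh_rate = config$fh_rate,
                  fh_adj = fh_adj, prevalence = config$prevalence,
                  seed = derive_seed(config$seed, 3))
  })
  reclass <- pipeline_stage("reclassification",
                            reclass_matrix(cohort, category_scheme()))
  strat <- pipeline_stage("strategies", {
    benefit_curve(cohort, config$strategies, config$treat_threshold)
  })
  table1 <- pipeline_stage("threshold-summary", {
    summarize_above_threshold(cohort, config$treat_threshold,
                              by = if (config$fh_rate > 0) "fh_positive")
  })

  pipeline_stage("write-outputs", {
    pct <- function(x) round(100 * x, 1)
    t1 <- transform(table1, pct_pre_raw = pct_pre, pct_post_raw = pct_post,
                    pct_pre = pct(pct_pre), pct_post = pct(pct_post))
    utils::write.csv(t1, file.path(output_dir, "table1.csv"),
                     row.names = FALSE)
    m <- unclass(reclass)
    t2 <- data.frame(pre_category = rownames(m),
                     round(100 * m, 4), check.names = FALSE,
                     row_total = round(100 * rowSums(m), 4))
    utils::write.csv(t2, file.path(output_dir, "table2.csv"),
                     row.names = FALSE)
    t3 <- transform(strat,
                    pct_tested_raw = pct_tested, pct_up_raw = pct_up,
                    pct_down_raw = pct_down,
                    benefit_raw = benefit_fraction,
                    pct_tested = pct(pct_tested), pct_up = pct(pct_up),
                    pct_down = pct(pct_down),
                    benefit_fraction = pct(benefit_fraction))
    utils::write.csv(t3, file.path(output_dir, "table3.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(pct_tested = strat$pct_tested,
                 benefit_fraction = strat$benefit_fraction),
      file.path(output_dir, "fig2.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(auc = disc$auc, closed_form_auc = disc$closed_form_auc,
                 n_cases = disc$n_cases, n_controls = disc$n_controls,
                 log_lr_case_mean = disc$log_lr_case_mean,
                 log_lr_control_mean = disc$log_lr_control_mean),
      file.path(output_dir, "auc.csv"), row.names = FALSE)
    manifest <- unclass(config)
    manifest$panel_n_snps <- nrow(panel)
    manifest$panel_or_range <- range(panel$odds_ratio)
    manifest$closed_form_auc <- disc$closed_form_auc
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  })

  message(sprintf(
    "pipeline done: %d SNPs | AUC %.3f (closed form %.3f) | cohort %d | %d strategies",
    nrow(panel), disc$auc, disc$closed_form_auc, config$n, nrow(strat)))
  invisible(list(panel = panel, discrimination = disc, cohort = cohort,
                 reclass = reclass, strategies = strat, table1 = table1))
}
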