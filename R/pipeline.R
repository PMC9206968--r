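#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one master seed into distinct per-stage seeds,
#' keeping values in the 32-bit signed integer range.
#'
#' @param master master seed (integer).
#' @param stage stage name (string).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(master) * 7919 + h) %% 2147483629) + 1L
}

#' Full-run configuration
#'
#' A serializable bundle of every tunable that affects a pipeline run. A
#' saved configuration re-executes to identical outputs.
#'
#' @param outdir output directory for the run.
#' @param master_seed single seed from which all stage seeds derive.
#' @param sim a [sim_config()], or `NULL` when loading from files.
#' @param cohort_path,meta_path CSV paths (used when `sim` is `NULL`).
#' @param kappa,threshold_mode,weights,n_restarts,min_report_size
#'   clustering settings, see [run_tpc()].
#' @param gnn named list of [stratification_analysis()] settings
#'   (`epochs`, `hidden_units`, `learning_rate`, `split_fraction`,
#'   `replicates`, `features`, `slices`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(outdir, master_seed = 42, sim = sim_config(),
                       cohort_path = NULL, meta_path = NULL, kappa = 0.5,
                       threshold_mode = "fraction", weights = NULL,
                       n_restarts = 20, min_report_size = 10,
                       gnn = list()) {
  gnn_defaults <- list(epochs = 100, hidden_units = 64,
                       learning_rate = 0.01, split_fraction = 0.7,
                       replicates = 10, features = "onehot",
                       slices = c("all", "treated", "placebo"))
  gnn <- utils::modifyList(gnn_defaults, gnn)
  structure(list(outdir = outdir, master_seed = as.integer(master_seed),
                 sim = sim, cohort_path = cohort_path,
                 meta_path = meta_path, kappa = kappa,
                 threshold_mode = threshold_mode, weights = weights,
                 n_restarts = n_restarts,
                 min_report_size = min_report_size, gnn = gnn),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Report subtype profiles to disk
#'
#' Writes each *reportable* subtype's affected-fraction profile as an
#' item-by-timepoint CSV, plus a text summary listing community sizes and,
#' when arm labels are available, the treated fraction per subtype.
#' Non-reportable communities appear in the labels output of the pipeline
#' but not here.
#'
#' @param partition a `subtype_partition` with profiles attached.
#' @param dir output directory (created if needed).
#' @param arm optional named arm labels (`"treated"`/`"placebo"`).
#' @return Paths of the files written, invisibly.
#' @export
render_profile_report <- function(partition, dir, arm = NULL) {
  stopifnot(inherits(partition, "subtype_partition"))
  if (is.null(partition$subtype_profiles))
    stop("partition has no subtype profiles; run subtype_profiles() first")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  lines <- character(0)
  for (l in seq_len(partition$n_communities)) {
    n_l <- partition$sizes[l]
    if (!partition$reportable[l]) next
    info <- sprintf("subtype %d: N=%d", l, n_l)
    if (!is.null(arm)) {
      fr <- mean(arm[partition$communities[[l]]] == "treated")
      info <- sprintf("%s, treated fraction=%.3f", info, fr)
    }
    lines <- c(lines, info)
    f <- file.path(dir, sprintf("subtype_%02d_profile.csv", l))
    s <- partition$subtype_profiles[[l]]
    rn <- rownames(s)
    if (is.null(rn)) rn <- paste0("item_", seq_len(nrow(s)))
    utils::write.csv(data.frame(item = rn, s, check.names = FALSE),
                     f, row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  hidden <- sum(!partition$reportable)
  if (hidden > 0)
    lines <- c(lines, sprintf(
      "%d communit%s with fewer than %d patients not shown", hidden,
      if (hidden == 1) "y" else "ies", partition$min_report_size))
  summary_path <- file.path(dir, "subtype_summary.txt")
  writeLines(lines, summary_path)
  invisible(c(paths, summary_path))
}

#' Run the full subtyping pipeline
#'
#' Simulate (or load) a cohort, cluster trajectories into subtypes, run the
#' per-timepoint stratification analysis, and write all outputs plus a
#' machine-readable manifest to the run directory. Stage failures carry
#' the stage name. Outputs: `cohort.csv`, `catalog.csv` (and `truth.csv`
#' for simulated cohorts), `labels.csv`, per-subtype profile CSVs with a
#' text summary, `accuracy.csv`, and `manifest.json`.
#'
#' @param config a [run_config()].
#' @return The run directory path, invisibly; the partition and the
#'   accuracy curve are attached as attributes `partition` and `curve`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (!is.null(config$sim)) {
    gen <- with_stage("simulate", {
      sim <- config$sim
      sim$seed <- derive_seed(config$master_seed, "simulate")
      generate_cohort(sim)
    })
    cohort <- gen$cohort
    truth <- gen$archetype
    write_cohort(cohort, file.path(out, "cohort.csv"))
    write_catalog(cohort$items, file.path(out, "catalog.csv"))
    utils::write.csv(data.frame(patient = names(truth), archetype = truth),
                     file.path(out, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  } else {
    cohort <- with_stage("load",
      load_cohort(config$cohort_path, config$meta_path))
    write_catalog(cohort$items, file.path(out, "catalog.csv"))
  }
  part <- with_stage("tpc", run_tpc(
    cohort, kappa = config$kappa, weights = config$weights,
    seed = derive_seed(config$master_seed, "tpc"),
    n_restarts = config$n_restarts,
    min_report_size = config$min_report_size,
    threshold_mode = config$threshold_mode))
  utils::write.csv(
    data.frame(patient = names(part$labels), community = part$labels,
               reportable = part$reportable[part$labels]),
    file.path(out, "labels.csv"), row.names = FALSE, quote = FALSE)
  render_profile_report(part, out, arm = cohort$arm)
  g <- config$gnn
  curve <- with_stage("stratify", stratification_analysis(
    cohort, part, slices = g$slices, replicates = g$replicates,
    seed = derive_seed(config$master_seed, "stratify"), epochs = g$epochs,
    hidden_units = g$hidden_units, learning_rate = g$learning_rate,
    split_fraction = g$split_fraction, features = g$features))
  utils::write.csv(curve, file.path(out, "accuracy.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "tpcstroke",
    version = as.character(utils::packageVersion("tpcstroke")),
    master_seed = config$master_seed,
    stage_seeds = list(simulate = derive_seed(config$master_seed, "simulate"),
                       tpc = derive_seed(config$master_seed, "tpc"),
                       stratify = derive_seed(config$master_seed, "stratify")),
    kappa = config$kappa, threshold_mode = config$threshold_mode,
    n_restarts = config$n_restarts,
    min_report_size = config$min_report_size,
    sim = if (!is.null(config$sim)) list(
      n_patients = config$sim$n_patients,
      n_templates = length(config$sim$templates),
      treatment_fraction = config$sim$treatment_fraction,
      treatment_recovery_boost = config$sim$treatment_recovery_boost,
      noise_sd = config$sim$noise_sd),
    gnn = g[c("epochs", "hidden_units", "learning_rate", "split_fraction",
              "replicates", "features")],
    n_communities = part$n_communities,
    n_reportable = sum(part$reportable),
    modularity = part$modularity,
    sizes = part$sizes,
    accuracy = curve
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  res <- out
  attr(res, "partition") <- part
  attr(res, "curve") <- curve
  invisible(res)
}
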