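## Orchestration of the full analysis from one configuration: diagnostics,
## phylogenetic signal, single-tree model battery (consensus and ML trees),
## tree-sample aggregation, and a reproducible report bundle.

#' Build an analysis configuration
#'
#' @param trees path to the Newick/Nexus file holding the posterior tree
#'   sample (optional).
#' @param consensus path to the consensus tree file.
#' @param ml_tree path to the maximum-likelihood tree file (optional).
#' @param traits path to the trait TSV (see [read_trait_table()]).
#' @param alignment optional path to a FASTA/Nexus alignment for the
#'   saturation diagnostic.
#' @param models model labels (default all seven).
#' @param seed master seed.
#' @param nx,tstep numerical settings forwarded to the likelihood engine.
#' @param root_mode,condition root treatment switches (see
#'   [quasse_loglik()]).
#' @param signal_mode `"ml"` or `"mcmc"` for the lambda stage.
#' @param signal_iterations MCMC iterations for the lambda stage.
#' @param fit_control extra [fit_quasse()] control entries (e.g.
#'   `n_starts`, `maxit`) merged over the pipeline's `nx`/`tstep`/`seed`.
#' @return validated config list of class `analysis_config`.
#' @export
analysis_config <- function(trees = NULL, consensus, ml_tree = NULL,
                            traits, alignment = NULL,
                            models = c("Full", "Linear", "Sigmoidal", "Hump",
                                       "Drift Linear", "Drift Sigmoidal",
                                       "Drift Hump"),
                            seed = 1, nx = 1024, tstep = 0.01,
                            root_mode = "obs", condition = TRUE,
                            signal_mode = "mcmc", signal_iterations = 2e4,
                            fit_control = list()) {
  cfg <- list(trees = trees, consensus = consensus, ml_tree = ml_tree,
              traits = traits, alignment = alignment,
              models = models, seed = as.integer(seed),
              nx = as.integer(nx), tstep = tstep, root_mode = root_mode,
              condition = condition, signal_mode = signal_mode,
              signal_iterations = signal_iterations,
              fit_control = fit_control)
  for (f in c("trees", "consensus", "ml_tree", "traits", "alignment")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured path does not exist: ", f, " = ", cfg[[f]])
  }
  if (!length(cfg$models)) stop("model list must be non-empty")
  parse_model_labels(cfg$models)  # validates
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML file holds the same fields as [analysis_config()].
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

#' Run the full analysis
#'
#' Stages: (1) saturation and node-density diagnostics, (2) phylogenetic
#' signal (Pagel's lambda) on the consensus tree, (3) the model battery with
#' AIC/chi-square tables on the consensus and (if given) ML trees, (4)
#' tree-sample fits with drift aggregation and sample-level Bayes factors.
#' A failing stage leaves a machine-readable entry in `bundle$failures`
#' instead of aborting; missing inputs skip the stage with a notice.  All
#' seeds and numerical settings are recorded in `bundle$metadata` so the run
#' can be reproduced exactly.
#'
#' @param cfg an [analysis_config()] (or path to its YAML file).
#' @param progress print stage banners?
#' @return a `report_bundle` list: `diagnostics`, `signal`,
#'   `single_tree` (per-tree [compare_models()] tables), `sample`
#'   (fit table, drift summary, BF matrix), `skipped`, `failures`,
#'   `metadata`.
#' @export
run_analysis <- function(cfg, progress = FALSE) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  stopifnot(inherits(cfg, "analysis_config"))
  say <- function(...) if (progress) message(...)
  bundle <- list(diagnostics = NULL, signal = NULL, single_tree = list(),
                 sample = NULL, skipped = character(0),
                 failures = list(),
                 metadata = list(seed = cfg$seed, nx = cfg$nx,
                                 tstep = cfg$tstep, root_mode = cfg$root_mode,
                                 condition = cfg$condition,
                                 models = cfg$models,
                                 version = as.character(
                                   utils::packageVersion("driftshift"))))
  fail <- function(stage, e) {
    bundle$failures[[stage]] <<- conditionMessage(e)
    say("stage ", stage, " FAILED: ", conditionMessage(e))
  }

  traits <- read_trait_table(cfg$traits)
  consensus <- read_tree_sample(cfg$consensus, provenance = "consensus")[[1]]
  models <- parse_model_labels(cfg$models)
  ctrl <- utils::modifyList(list(nx = cfg$nx, tstep = cfg$tstep,
                                 seed = cfg$seed), cfg$fit_control)

  ## (1) diagnostics
  say("stage 1: diagnostics")
  tryCatch({
    diag <- list()
    if (!is.null(cfg$alignment)) {
      diag$saturation <- saturation_test(read_alignment(cfg$alignment),
                                         seed = cfg$seed)
    } else {
      bundle$skipped <- c(bundle$skipped,
                          "saturation (no alignment configured)")
    }
    diag$node_density <- node_density_test(consensus, seed = cfg$seed)
    if (!is.null(cfg$trees)) {
      diag$node_density_sample <- node_density_sample(
        read_tree_sample(cfg$trees, provenance = "posterior sample"),
        seed = cfg$seed)
    }
    bundle$diagnostics <- diag
  }, error = function(e) fail("diagnostics", e))

  ## (2) lambda signal on the consensus tree
  say("stage 2: phylogenetic signal")
  tryCatch({
    bundle$signal <- fit_lambda(consensus, traits, mode = cfg$signal_mode,
                                iterations = cfg$signal_iterations,
                                seed = cfg$seed)
  }, error = function(e) fail("signal", e))

  ## (3) single-tree model batteries
  single <- list(consensus = consensus)
  if (!is.null(cfg$ml_tree))
    single$ml <- read_tree_sample(cfg$ml_tree, provenance = "ML")[[1]]
  for (nm in names(single)) {
    say("stage 3: model battery on ", nm, " tree")
    tryCatch({
      bundle$single_tree[[nm]] <- fit_battery(
        single[[nm]], traits, models, root_mode = cfg$root_mode,
        condition = cfg$condition, control = ctrl)
    }, error = function(e) fail(paste0("single_tree_", nm), e))
  }

  ## (4) tree-sample aggregation
  if (is.null(cfg$trees)) {
    bundle$skipped <- c(bundle$skipped,
                        "tree-sample stage (no tree sample configured)")
    say("stage 4 skipped: no tree sample")
  } else {
    say("stage 4: tree-sample fits")
    tryCatch({
      sample <- read_tree_sample(cfg$trees, provenance = "posterior sample")
      sft <- fit_over_sample(sample, traits, models,
                             root_mode = cfg$root_mode,
                             condition = cfg$condition, control = ctrl)
      bundle$sample <- list(
        fits = sft$table,
        drift = if (any(models$drift)) aggregate_drift(sft) else NULL,
        bf = sample_bf_matrix(sft))
    }, error = function(e) fail("sample", e))
  }

  class(bundle) <- "report_bundle"
  bundle
}

#' Write a report bundle to a directory of TSV/JSON files
#'
#' Emits `signal.tsv` (lambda report), `model_table_<tree>.tsv` per
#' single-tree battery, `sample_fits.tsv`, `drift_summary.tsv`,
#' `bf_matrix.tsv`, `diagnostics.json` and `metadata.json` (plus
#' `failures.json` when any stage failed).
#'
#' @param bundle a `report_bundle` from [run_analysis()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$signal)) {
    s <- bundle$signal
    tsv(data.frame(model = c("Observed lambda", "Forced lambda = 0",
                             "Forced lambda = 1"),
                   lambda = c(s$lambda, 0, 1),
                   hpd_lower = c(s$interval[1], NA, NA),
                   hpd_upper = c(s$interval[2], NA, NA),
                   ln_marginal = c(s$loglik, s$loglik0, s$loglik1),
                   bayes_factor = c(NA, s$bf0, s$bf1)),
        "signal.tsv")
  }
  for (nm in names(bundle$single_tree))
    tsv(bundle$single_tree[[nm]], paste0("model_table_", nm, ".tsv"))
  if (!is.null(bundle$sample)) {
    tsv(bundle$sample$fits, "sample_fits.tsv")
    if (!is.null(bundle$sample$drift))
      tsv(bundle$sample$drift, "drift_summary.tsv")
    bf <- bundle$sample$bf
    tsv(cbind(model = rownames(bf), as.data.frame(bf)), "bf_matrix.tsv")
  }
  if (!is.null(bundle$diagnostics)) {
    d <- bundle$diagnostics
    out <- list()
    if (!is.null(d$saturation))
      out$saturation <- d$saturation[c("iss", "iss_c", "p_value",
                                       "saturated", "n_otu", "n_sites")]
    if (!is.null(d$node_density))
      out$node_density <- d$node_density[c("beta", "delta", "p_beta",
                                           "verdict")]
    if (!is.null(d$node_density_sample))
      out$node_density_sample <- as.list(
        attr(d$node_density_sample, "summary"))
    jsonlite::write_json(out, file.path(dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  jsonlite::write_json(bundle$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(bundle$failures))
    jsonlite::write_json(bundle$failures, file.path(dir, "failures.json"),
                         auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report bundle\n")
  if (!is.null(x$signal))
    cat(sprintf("  lambda = %.3f (%.3f, %.3f)\n", x$signal$lambda,
                x$signal$interval[1], x$signal$interval[2]))
  for (nm in names(x$single_tree))
    cat("  best model on", nm, "tree:", attr(x$single_tree[[nm]], "best"),
        "\n")
  if (!is.null(x$sample) && !is.null(x$sample$drift)) {
    d <- x$sample$drift
    cat("  sample mean drift:",
        paste(sprintf("%s %.3f", d$model, d$mean_theta), collapse = ", "),
        "\n")
  }
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  if (length(x$failures))
    cat("  FAILED stages:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
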