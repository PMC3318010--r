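## Run the model battery over a Bayesian posterior sample of trees and
## aggregate: mean and HPD of the drift estimates (the "was there a trend,
## averaged over phylogenetic uncertainty" summary) and sample-level Bayes
## factors between models.

#' Fit a set of models on every tree of a sample
#'
#' Independent [fit_quasse()] calls per tree x model.  Per-tree failures are
#' recorded rather than fatal, but more than `max_fail_frac` failures abort
#' with an aggregate error.  Results are deterministic given the seed and
#' independent of execution order.
#'
#' @param sample a [tree_sample()] of ultrametric trees.
#' @param traits `trait_table` covering the shared tip set.
#' @param models data.frame with columns `kind` and `drift` (or a character
#'   vector of labels such as `"Drift Linear"`; see [parse_model_labels()]).
#' @param root_mode,condition,control passed to [fit_quasse()].
#' @param max_fail_frac failure fraction above which an error is raised.
#' @param progress print one line per completed tree?
#' @return object of class `sample_fit_table`: list with `table` (data.frame
#'   of tree, model, df, lnLik, AIC, theta, converged) and `fits` (nested
#'   list of `quasse_fit`s, `NULL` where a fit failed).
#' @export
fit_over_sample <- function(sample, traits, models,
                            root_mode = "obs", condition = TRUE,
                            control = list(), max_fail_frac = 0.1,
                            progress = FALSE) {
  stopifnot(inherits(sample, "tree_sample"))
  models <- as_model_spec(models)
  ntree <- length(sample)
  rows <- list(); fits <- vector("list", ntree)
  nfail <- 0L; failures <- character(0)
  for (i in seq_len(ntree)) {
    tree <- sample[[i]]
    ## all models of one tree share a grid and warm starts (fit_battery)
    batt <- tryCatch(
      fit_battery(tree, traits, models, root_mode = root_mode,
                  condition = condition, control = control),
      error = function(e) e)
    if (inherits(batt, "error")) {
      nfail <- nfail + nrow(models)
      failures <- c(failures, sprintf("tree %d: %s", i,
                                      conditionMessage(batt)))
      rows[[length(rows) + 1L]] <- data.frame(
        tree = i, model = models$label,
        df = mapply(model_df, models$kind, models$drift),
        lnLik = NA_real_, AIC = NA_real_, theta = NA_real_,
        converged = FALSE)
      fits[[i]] <- stats::setNames(vector("list", nrow(models)),
                                   models$label)
    } else {
      bf <- attr(batt, "fits")[models$label]
      fits[[i]] <- bf
      rows[[length(rows) + 1L]] <- data.frame(
        tree = i, model = models$label,
        df = vapply(bf, `[[`, 0L, "df"),
        lnLik = vapply(bf, `[[`, 0, "loglik"),
        AIC = vapply(bf, `[[`, 0, "aic"),
        theta = vapply(bf, `[[`, 0, "theta"),
        converged = vapply(bf, function(f)
          identical(f$convergence, 0L), TRUE))
    }
    if (progress)
      message(sprintf("tree %d/%d done", i, ntree))
  }
  total <- ntree * nrow(models)
  if (nfail > max_fail_frac * total)
    stop(nfail, "/", total, " fits failed:\n",
         paste(utils::head(failures, 10), collapse = "\n"))
  structure(list(table = do.call(rbind, rows), fits = fits,
                 models = models, failures = failures),
            class = "sample_fit_table")
}

#' Parse model labels into a (kind, drift) specification
#'
#' Accepts labels like `"Full"`, `"Linear"`, `"Drift Hump"` (case and
#' hyphen/space insensitive), or a data.frame already holding `kind` and
#' `drift` columns.
#'
#' @param models character vector or data.frame.
#' @return data.frame with columns `kind`, `drift`, `label`.
#' @export
parse_model_labels <- function(models) as_model_spec(models)

as_model_spec <- function(models) {
  if (is.data.frame(models)) {
    stopifnot(all(c("kind", "drift") %in% names(models)))
    models$label <- mapply(model_label, models$kind, models$drift)
    return(models)
  }
  key <- gsub("[-_ ]", "", tolower(models))
  map <- list(
    full = c("constant", FALSE), constant = c("constant", FALSE),
    linear = c("linear", FALSE), sigmoidal = c("sigmoidal", FALSE),
    hump = c("hump", FALSE),
    driftlinear = c("linear", TRUE), driftsigmoidal = c("sigmoidal", TRUE),
    drifthump = c("hump", TRUE))
  bad <- setdiff(key, names(map))
  if (length(bad)) stop("unknown model label(s): ", paste(bad, collapse = ", "))
  kind <- vapply(map[key], `[[`, "", 1)
  drift <- vapply(map[key], function(z) as.logical(z[[2]]), TRUE)
  data.frame(kind = kind, drift = drift,
             label = mapply(model_label, kind, drift),
             stringsAsFactors = FALSE)
}

#' All seven speciation-rate models
#'
#' Convenience constant: Full, Linear, Sigmoidal, Hump and the three drift
#' variants, in the conventional table order.
#' @return model specification data.frame (see [parse_model_labels()]).
#' @export
seven_models <- function() {
  parse_model_labels(c("Full", "Linear", "Sigmoidal", "Hump",
                       "Drift Linear", "Drift Sigmoidal", "Drift Hump"))
}

#' Summarize drift estimates over a tree sample
#'
#' Mean and 95% HPD (shortest interval) of the per-tree ML drift estimates,
#' per drift model.
#'
#' @param table a `sample_fit_table` from [fit_over_sample()], or a
#'   data.frame with columns `model`, `theta` and a logical `drift` marker
#'   inferred from the label.
#' @param prob interval mass (default 0.95).
#' @return data.frame of class `drift_summary` with columns `model`,
#'   `mean_theta`, `hpd_lower`, `hpd_upper`, `n`, `skewed` (flag set when
#'   the HPD does not bracket the mean).
#' @export
aggregate_drift <- function(table, prob = 0.95) {
  tab <- if (inherits(table, "sample_fit_table")) table$table else table
  tab <- tab[grepl("^Drift", tab$model) & is.finite(tab$theta), , drop = FALSE]
  if (!nrow(tab)) stop("no drift-model estimates to aggregate")
  out <- do.call(rbind, lapply(split(tab, tab$model), function(d) {
    h <- hpd_interval(d$theta, prob)
    m <- mean(d$theta)
    data.frame(model = d$model[1], mean_theta = m,
               hpd_lower = h[1], hpd_upper = h[2], n = nrow(d),
               skewed = !(h[1] <= m && m <= h[2]))
  }))
  rownames(out) <- NULL
  class(out) <- c("drift_summary", "data.frame")
  out
}

#' Sample-level Bayes factor between two models
#'
#' `BF = 2 * (mean lnL of m1 over trees - mean lnL of m2 over trees)`,
#' the primary statistic used to rank models while averaging over the tree
#' sample.  Antisymmetric by construction; with a single tree it reduces to
#' twice the log-likelihood difference of the two fits.
#'
#' @param table a `sample_fit_table` (or its `table` data.frame).
#' @param m1,m2 model labels (e.g. `"Drift Linear"`).
#' @return the Bayes factor (2 delta-ln scale).
#' @export
sample_bayes_factor <- function(table, m1, m2) {
  tab <- if (inherits(table, "sample_fit_table")) table$table else table
  pick <- function(m) {
    d <- tab[tab$model == m, , drop = FALSE]
    if (!nrow(d)) stop("model '", m, "' not present in the fit table")
    if (any(!is.finite(d$lnLik)))
      stop("model '", m, "' has missing fits; cannot aggregate")
    d[order(d$tree), "lnLik"]
  }
  l1 <- pick(m1); l2 <- pick(m2)
  if (length(l1) != length(l2))
    stop("models were not fitted on the same trees")
  2 * (mean(l1) - mean(l2))
}

#' Pairwise sample-level Bayes-factor matrix
#'
#' @param table a `sample_fit_table`.
#' @return antisymmetric matrix of [sample_bayes_factor()] values, zero
#'   diagonal, with an `aic_wins` attribute giving the fraction of trees on
#'   which each model attains the minimum AIC (a second, assumption-free way
#'   to read the sample-level ranking).
#' @export
sample_bf_matrix <- function(table) {
  tab <- if (inherits(table, "sample_fit_table")) table$table else table
  models <- unique(tab$model)
  bf <- matrix(0, length(models), length(models),
               dimnames = list(models, models))
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      if (i < j) {
        v <- sample_bayes_factor(tab, models[i], models[j])
        bf[i, j] <- v
        bf[j, i] <- -v
      }
    }
  }
  wins <- vapply(split(tab, tab$tree), function(d) {
    d$model[which.min(d$AIC)]
  }, "")
  attr(bf, "aic_wins") <- vapply(models, function(m) mean(wins == m), 0)
  bf
}
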