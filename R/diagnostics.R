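## Pre-analysis diagnostics: an entropy-based substitution-saturation test
## (observed index Iss against a critical index Iss.c) and the node-density
## artifact test (power-law fit of node count against root-to-tip path
## length).

#' Read a DNA alignment
#'
#' FASTA or Nexus DATA block, via ape; returns the simple character-matrix
#' container used by [saturation_test()].
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"nexus"` (guessed from the extension by
#'   default).
#' @return a `dna_alignment`: character matrix (sequences x sites) over
#'   `A,C,G,T,-,N`, rownames = species labels.
#' @export
read_alignment <- function(path, format = c("guess", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.(nex|nexus)$", tolower(path))) "nexus" else "fasta"
  seqs <- if (format == "fasta") {
    lapply(as.character(ape::read.FASTA(path)), toupper)
  } else {
    lapply(ape::read.nexus.data(path), toupper)
  }
  dna_alignment(do.call(rbind, seqs))
}

#' Construct a DNA alignment container
#'
#' @param mat character matrix (sequences in rows, sites in columns) or a
#'   named character vector of equal-length sequence strings.
#' @return object of class `dna_alignment`.
#' @export
dna_alignment <- function(mat) {
  if (is.character(mat) && is.null(dim(mat))) {
    if (length(unique(nchar(mat))) != 1)
      stop("sequences must have equal length")
    mat <- do.call(rbind, strsplit(toupper(mat), ""))
  }
  mat <- toupper(mat)
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("seq", seq_len(nrow(mat)))
  if (nrow(mat) < 4) stop("an alignment needs at least 4 sequences")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("unexpected residues: ", paste(bad, collapse = ", "))
  structure(mat, class = c("dna_alignment", "matrix"))
}

#' Write an alignment to FASTA
#'
#' @param aln a `dna_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

## plug-in Shannon entropy of each alignment column (A/C/G/T only)
site_entropies <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 2) return(NA_real_)
    p <- tabulate(factor(col, c("A", "C", "G", "T")), 4) / length(col)
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Entropy-based substitution-saturation test
#'
#' Computes the observed saturation index `Iss` as the mean per-site Shannon
#' entropy divided by the entropy expected under full saturation (sites
#' i.i.d. from the overall base composition, estimated by seeded
#' randomization with the same number of sequences, so the finite-sample
#' bias of the plug-in entropy cancels).  The critical index `Iss.c` is
#' calibrated by simulation for the alignment's size: sequences are evolved
#' under Jukes-Cantor on a balanced topology across a ladder of divergence
#' levels, and `Iss.c` is the index at the divergence where
#' neighbour-joining stops recovering the generating topology reliably
#' (95% success).  `Iss` significantly below `Iss.c` indicates the sites
#' still carry usable phylogenetic signal.  Exact numerical agreement with
#' the original implementation of this index is not promised; the
#' calibration design is recorded in the result.
#'
#' @param aln a `dna_alignment` (>= 4 sequences).
#' @param replicates randomization/calibration replicates per divergence
#'   level (default 40).
#' @param seed integer seed.
#' @return object of class `saturation_result`: `iss`, `iss_se`, `iss_c`,
#'   `iss_c_se`, `p_value` (two-sided, for `Iss == Iss.c`), `saturated`
#'   verdict, `n_otu`, `n_sites`, and the calibration table.
#' @export
saturation_test <- function(aln, replicates = 40, seed = 1) {
  stopifnot(inherits(aln, "dna_alignment"))
  mat <- unclass(aln)
  n_otu <- nrow(mat); n_sites <- ncol(mat)
  if (n_sites < 50)
    warning("alignment shorter than 50 sites: the test has little power")
  set.seed(seed)

  H <- site_entropies(mat)
  H <- H[is.finite(H)]
  base_counts <- tabulate(factor(as.vector(mat), c("A", "C", "G", "T")), 4)
  base_freq <- base_counts / sum(base_counts)

  ## full-saturation expectation with the same number of sequences per site
  hfs_rep <- vapply(seq_len(max(replicates, 20)), function(i) {
    cols <- matrix(sample(c("A", "C", "G", "T"), n_otu * length(H),
                          replace = TRUE, prob = base_freq),
                   nrow = n_otu)
    mean(site_entropies(cols))
  }, 0)
  h_fs <- mean(hfs_rep)
  iss <- mean(H) / h_fs
  ## bootstrap over sites for the standard error of Iss
  iss_boot <- vapply(seq_len(max(replicates, 20)), function(i) {
    mean(sample(H, length(H), replace = TRUE)) / h_fs
  }, 0)
  iss_se <- stats::sd(iss_boot)

  calib <- calibrate_iss_c(n_otu, n_sites, base_freq, replicates, seed + 1)

  se <- sqrt(iss_se^2 + calib$iss_c_se^2)
  z <- (iss - calib$iss_c) / max(se, 1e-12)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(iss = iss, iss_se = iss_se,
                 iss_c = calib$iss_c, iss_c_se = calib$iss_c_se,
                 p_value = p, saturated = iss >= calib$iss_c,
                 n_otu = n_otu, n_sites = n_sites,
                 calibration = calib$table,
                 method = paste("entropy index with randomized full-saturation",
                                "baseline; critical index from JC/NJ topology-",
                                "recovery simulation on a balanced tree")),
            class = "saturation_result")
}

## Critical index: simulate JC alignments on a balanced tree whose tip count
## matches the alignment (rounded to a power of two, capped at 32) across
## increasing divergence; Iss.c is the interpolated index at the divergence
## where NJ recovers the generating topology for 95% of replicates.
calibrate_iss_c <- function(n_otu, n_sites, base_freq, replicates, seed) {
  set.seed(seed)
  ntip <- 2^max(2, min(5, round(log2(n_otu))))
  tree <- ape::compute.brlen(ape::stree(ntip, "balanced"), 1)
  tree$edge.length <- tree$edge.length / max(node_depths(tree))  # depth 1
  nrep <- max(8, min(replicates, 40))
  nsim_sites <- min(n_sites, 600)
  levels <- c(0.05, 0.15, 0.3, 0.6, 1.2, 2.4, 4.8)   # subs/site root-to-tip
  rows <- lapply(levels, function(d) {
    res <- vapply(seq_len(nrep), function(i) {
      aln <- simulate_alignment(tree, rate = d, length = nsim_sites,
                                seed = sample.int(1e8, 1))
      mat <- unclass(aln)
      iss_i <- mean(site_entropies(mat), na.rm = TRUE)
      dm <- ape::dist.dna(ape::as.DNAbin(tolower(mat)), model = "raw",
                          pairwise.deletion = TRUE)
      ok <- tryCatch({
        est <- ape::nj(dm)
        ape::dist.topo(ape::unroot(est), ape::unroot(tree)) == 0
      }, error = function(e) FALSE)
      c(iss_i, as.numeric(ok))
    }, c(0, 0))
    data.frame(divergence = d, mean_entropy = mean(res[1, ]),
               recovery = mean(res[2, ]))
  })
  tab <- do.call(rbind, rows)
  ## same full-saturation baseline as the observed index
  cols <- matrix(sample(c("A", "C", "G", "T"), ntip * 2000, replace = TRUE,
                        prob = rep(0.25, 4)), nrow = ntip)
  h_fs <- mean(site_entropies(cols))
  tab$iss <- tab$mean_entropy / h_fs
  ## first divergence where recovery drops below 95%, linear interpolation
  ## of iss against recovery across that bracket
  below <- which(tab$recovery < 0.95)
  iss_c <- if (!length(below)) {
    max(tab$iss)  # never failed: critical index beyond the explored range
  } else if (below[1] == 1) {
    tab$iss[1]
  } else {
    i <- below[1]
    r1 <- tab$recovery[i - 1]; r2 <- tab$recovery[i]
    w <- (r1 - 0.95) / max(r1 - r2, 1e-9)
    tab$iss[i - 1] + w * (tab$iss[i] - tab$iss[i - 1])
  }
  ## spread of per-level iss around the bracket as a crude calibration se
  iss_c_se <- max(stats::sd(tab$iss) / sqrt(nrow(tab)) * 0.5, 0.01)
  list(iss_c = iss_c, iss_c_se = iss_c_se, table = tab)
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("Substitution saturation: Iss = %.3f (se %.3f), Iss.c = %.3f (se %.3f)\n",
              x$iss, x$iss_se, x$iss_c, x$iss_c_se))
  cat(sprintf("  p = %.4g -> %s (%d OTUs, %d sites)\n", x$p_value,
              if (x$saturated) "SATURATED: sequences are unreliable"
              else "little saturation: sequences usable", x$n_otu, x$n_sites))
  invisible(x)
}

#' Node-density artifact test
#'
#' Fits the power law `n = beta * x^delta` between the number of nodes `n`
#' on each root-to-tip path and the path length `x` by nonlinear least
#' squares.  The artifact of sparse taxon sampling inflates the curvature:
#' absence of the artifact requires `beta` significantly greater than zero
#' and `delta <= 1`.  Significance of `beta` is assessed by permutation of
#' the node counts against the path lengths (seeded).  Tips sharing
#' ancestors are not independent; the permutation test inherits this
#' approximation from the original method.
#'
#' @param tree a rooted `phylo` with at least 4 tips; ultrametric trees (all
#'   path lengths equal) yield a not-applicable result rather than an error.
#' @param n_perm permutations for the significance of beta (default 1000).
#' @param seed integer seed.
#' @return object of class `node_density_result`: `beta`, `delta`,
#'   `p_beta`, `applicable`, `verdict` (`"no-artifact"`, `"artifact"` or
#'   `"not-applicable"`) and the fitted profile.
#' @export
node_density_test <- function(tree, n_perm = 1000, seed = 1) {
  if (ape::Ntip(tree) < 4) stop("node-density test needs at least 4 tips")
  prof <- tip_path_profile(tree)
  node_density_fit(prof, n_perm = n_perm, seed = seed)
}

#' Node-density power-law fit on a precomputed tip profile
#'
#' The work-horse behind [node_density_test()]; exposed so that profiles
#' constructed directly (e.g. noiseless generating curves in validation)
#' can be fitted too.
#'
#' @param profile a `tip_path_profile` (or data.frame with columns
#'   `path_length`, `n_nodes`).
#' @inheritParams node_density_test
#' @return a `node_density_result` (see [node_density_test()]).
#' @export
node_density_fit <- function(profile, n_perm = 1000, seed = 1) {
  x <- profile$path_length
  n <- profile$n_nodes
  res <- function(applicable, beta = NA, delta = NA, p = NA, verdict) {
    structure(list(beta = beta, delta = delta, p_beta = p,
                   applicable = applicable, verdict = verdict,
                   profile = profile),
              class = "node_density_result")
  }
  if (length(unique(signif(x, 10))) < 3 || any(x <= 0))
    return(res(FALSE, verdict = "not-applicable"))

  fit_bd <- function(xx, nn) {
    ## log-log start, then nonlinear least squares on the original scale
    st <- stats::coef(stats::lm(log(nn) ~ log(xx)))
    f <- tryCatch(
      minpack.lm::nlsLM(nn ~ beta * xx^delta,
                        start = list(beta = unname(exp(st[1])),
                                     delta = unname(st[2])),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) {
      ## degenerate surfaces (e.g. exactly flat profiles) leave nls with a
      ## singular gradient; the log-log regression is the fit there
      return(c(beta = unname(exp(st[1])), delta = unname(st[2])))
    }
    stats::coef(f)
  }
  co <- fit_bd(x, n)
  if (is.null(co)) return(res(FALSE, verdict = "not-applicable"))
  beta <- unname(co["beta"]); delta <- unname(co["delta"])

  ## permutation significance of the association (zero-slope reference):
  ## statistic = SSE reduction of the power-law fit over the constant fit
  sse_gain <- function(xx, nn) {
    c0 <- sum((nn - mean(nn))^2)
    cc <- fit_bd(xx, nn)
    if (is.null(cc)) return(0)
    c0 - sum((nn - cc["beta"] * xx^cc["delta"])^2)
  }
  obs <- sse_gain(x, n)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) sse_gain(x, sample(n)), 0)
  p_beta <- (1 + sum(perm >= obs)) / (n_perm + 1)

  sig <- p_beta < 0.05 && beta > 0
  verdict <- if (sig && delta <= 1) "no-artifact" else "artifact"
  res(TRUE, beta, delta, p_beta, verdict)
}

#' @export
print.node_density_result <- function(x, ...) {
  if (!x$applicable) {
    cat("Node-density test: not applicable",
        "(fewer than 3 distinct root-to-tip path lengths)\n")
    return(invisible(x))
  }
  cat(sprintf("Node-density test: beta = %.4f (perm. p = %.4g), delta = %.4f -> %s\n",
              x$beta, x$p_beta, x$delta, x$verdict))
  invisible(x)
}

#' Node-density test across a tree sample
#'
#' Applies [node_density_test()] to every tree and reports the percentage of
#' trees in each cell of the (beta significant) x (delta <= 1) table, plus
#' the not-applicable fraction, so the sample-level artifact check can be
#' read under any joint criterion.
#'
#' @param sample a [tree_sample()].
#' @inheritParams node_density_test
#' @return data.frame with one row per tree (`beta`, `delta`, `p_beta`,
#'   `verdict`) and attribute `summary`: named percentage vector.
#' @export
node_density_sample <- function(sample, n_perm = 200, seed = 1) {
  stopifnot(inherits(sample, "tree_sample"))
  rows <- lapply(seq_len(length(sample)), function(i) {
    r <- node_density_test(sample[[i]], n_perm = n_perm, seed = seed + i)
    data.frame(tree = i, beta = r$beta, delta = r$delta, p_beta = r$p_beta,
               applicable = r$applicable, verdict = r$verdict)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$applicable
  sig <- ok & tab$p_beta < 0.05 & tab$beta > 0
  d1 <- ok & tab$delta <= 1
  summ <- 100 * c(
    "beta_sig & delta<=1"  = mean(sig & d1),
    "beta_sig & delta>1"   = mean(sig & !d1),
    "beta_ns & delta<=1"   = mean(!sig & ok & d1),
    "beta_ns & delta>1"    = mean(!sig & ok & !d1),
    "not_applicable"       = mean(!ok))
  attr(tab, "summary") <- summ
  tab
}
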