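## Tree and trait-table input/output, ultrametricity validation and
## root-to-tip path structure. Trees are ape "phylo" objects with branch
## lengths in Myr; a tree sample is a "tree_sample" wrapper around an
## ape "multiPhylo" whose members share one tip set.

#' Read a sample of trees from a Newick or Nexus file
#'
#' Reads one or more rooted, branch-length-annotated trees and validates that
#' every tree carries the same tip set.  Nexus TRANSLATE tables are resolved
#' (via ape).  The result is the container consumed by [fit_over_sample()] and
#' the sample-level diagnostics.
#'
#' @param path path to the tree file.
#' @param format `"newick"` or `"nexus"`.  Defaults to guessing from the file
#'   extension (`.nex`/`.nexus`/`.trees` read as Nexus).
#' @param provenance free-form tag recording where the sample came from,
#'   e.g. `"posterior sample"`, `"consensus"` or `"ML"`.
#' @return a `tree_sample`: list with elements `trees` (a `multiPhylo`) and
#'   `provenance`.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("(A:1,B:1);", f)
#' ts <- read_tree_sample(f, "newick")
#' length(ts)
#' @export
read_tree_sample <- function(path, format = c("guess", "newick", "nexus"),
                             provenance = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.(nex|nexus|trees|tre)$", tolower(path)))
      "nexus" else "newick"
  }
  trees <- tryCatch(
    switch(format,
           newick = ape::read.tree(path),
           nexus  = ape::read.nexus(path)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(trees)) stop("no trees parsed from ", path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  class(trees) <- "multiPhylo"
  tree_sample(trees, provenance = provenance)
}

#' Construct and validate a tree sample
#'
#' @param trees a `phylo`, `multiPhylo` or list of `phylo` objects.
#' @param provenance provenance tag (see [read_tree_sample()]).
#' @return a `tree_sample` object.
#' @export
tree_sample <- function(trees, provenance = "unknown") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo"))
      stop("element ", i, " is not a phylogeny")
    validate_phylogeny(tr, where = paste0("tree ", i))
    tr
  })
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("heterogeneous tip sets: tree ", i,
           " does not match the tip set of tree 1")
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, provenance = provenance),
            class = "tree_sample")
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
`[[.tree_sample` <- function(x, i) x$trees[[i]]

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample:", length(x$trees), "tree(s),",
      ape::Ntip(x$trees[[1]]), "tips; provenance:", x$provenance, "\n")
  invisible(x)
}

validate_phylogeny <- function(tree, where = "tree") {
  if (is.null(tree$edge.length))
    stop(where, ": branch lengths are required")
  if (any(!is.finite(tree$edge.length)))
    stop(where, ": non-finite branch lengths")
  if (any(tree$edge.length < 0))
    stop(where, ": negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop(where, ": duplicate tip labels")
  ## rooted = exactly one node without a parent edge (a basal polytomy is
  ## still a rooted tree for path-profile purposes)
  nnode <- ape::Ntip(tree) + tree$Nnode
  no_parent <- setdiff(seq_len(nnode), tree$edge[, 2])
  if (length(no_parent) != 1L)
    stop(where, ": tree must have exactly one root")
  invisible(tree)
}

#' Write a tree sample to file
#'
#' Round-trips through ape's Newick/Nexus writers with enough digits that
#' branch lengths survive to better than 1e-9 relative error.
#'
#' @param sample a `tree_sample` or `phylo`.
#' @param path output path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(sample, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- if (inherits(sample, "tree_sample")) sample$trees else sample
  if (format == "newick") {
    ape::write.tree(trees, file = path, digits = 12)
  } else {
    ape::write.nexus(trees, file = path, translate = TRUE)
  }
  invisible(path)
}

#' Check a tree is ultrametric and return its depth
#'
#' All root-to-tip path lengths must agree with their mean to within
#' `rel_tol * depth`; Bayesian posterior samples typically carry floating
#' point jitter, hence a relative rather than exact test.
#'
#' @param tree a `phylo`.
#' @param rel_tol allowed relative deviation of any tip depth from the mean
#'   depth (default `1e-3`).
#' @return the mean root-to-tip distance (tree depth, Myr).
#' @examples
#' assert_ultrametric(ape::stree(4, "balanced"), rel_tol = 1e-3)
#' @export
assert_ultrametric <- function(tree, rel_tol = 1e-3) {
  validate_phylogeny(tree)
  if (ape::Ntip(tree) < 2) stop("tree must have at least 2 tips")
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  depth <- mean(d)
  dev <- abs(d - depth)
  if (any(dev > rel_tol * depth)) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' has depth %.6g vs mean %.6g (rel dev %.3g > %.3g)",
      tree$tip.label[worst], d[worst], depth, dev[worst] / depth, rel_tol))
  }
  depth
}

## root-to-tip path length for every node (tips first, ape numbering)
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Root-to-tip path lengths and node counts
#'
#' For every tip, the sum of branch lengths from the root and the number of
#' internal nodes on that path.  The count includes the root and excludes the
#' tip, so a star tree gives 1 for every tip: it counts the speciation events
#' witnessed along the path.  This profile is the input of the node-density
#' artifact test.
#'
#' @param tree a rooted `phylo`.
#' @return a data.frame with columns `tip`, `path_length`, `n_nodes`, of class
#'   `tip_path_profile`.
#' @examples
#' tip_path_profile(ape::stree(5, "star"))
#' @export
tip_path_profile <- function(tree) {
  validate_phylogeny(tree)
  ntip <- ape::Ntip(tree)
  depths <- node_depths(tree)
  ## number of edges on the root-to-tip path == number of internal nodes on
  ## the path counting the root and excluding the tip (binary or not)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  counts <- integer(ntip)
  for (i in seq_len(ntip)) {
    k <- 0L
    node <- i
    while (node != root) {
      node <- parent[node]
      k <- k + 1L
    }
    counts[i] <- k
  }
  out <- data.frame(tip = tree$tip.label,
                    path_length = depths[seq_len(ntip)],
                    n_nodes = counts,
                    stringsAsFactors = FALSE)
  class(out) <- c("tip_path_profile", "data.frame")
  out
}

#' Read a trait table
#'
#' Two- or three-column tab-separated file: species label, trait value
#' (natural log of maximum head-body length in mm for the motivating
#' analysis), and optionally a per-species measurement standard deviation on
#' the same log scale.  Lines starting with `#` are comments.
#'
#' @param path path to the TSV file.
#' @return a named numeric vector of trait values with optional `sd`
#'   attribute, of class `trait_table`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("trait table needs at least 2 columns")
  trait_table(stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]])),
              sd = if (ncol(tab) >= 3) as.numeric(tab[[3]]) else NULL)
}

#' Construct a trait table
#'
#' @param x named numeric vector, species label -> trait value (ln mm).
#' @param sd optional numeric vector of measurement standard deviations.
#' @return object of class `trait_table` (a named numeric vector).
#' @export
trait_table <- function(x, sd = NULL) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("trait values must be named by species")
  if (anyDuplicated(names(x))) stop("duplicate species labels in trait table")
  if (any(!is.finite(x))) stop("trait values must be finite")
  if (!is.null(sd)) {
    if (length(sd) != length(x)) stop("sd must match trait length")
    if (any(!is.finite(sd) | sd < 0)) stop("sd must be finite and >= 0")
  }
  structure(as.numeric(x), names = names(x), sd = sd, class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table:", length(x), "species, range [",
      sprintf("%.3f", min(x)), ",", sprintf("%.3f", max(x)), "] (ln units)\n")
  invisible(x)
}

#' Write a trait table to TSV
#'
#' @param traits a `trait_table` or named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  sd <- attr(traits, "sd")
  df <- data.frame(species = names(traits), value = as.numeric(traits))
  if (!is.null(sd)) df$sd <- sd
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# species\tvalue (ln mm)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## traits aligned to a tree's tip order, with measurement sd filled in
align_traits <- function(tree, traits, sd_default = NULL) {
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing))
    stop("traits missing for tips: ", paste(missing, collapse = ", "))
  x <- as.numeric(traits[tree$tip.label])
  sd <- attr(traits, "sd")
  if (!is.null(sd)) {
    sd <- sd[match(tree$tip.label, names(traits))]
  } else if (!is.null(sd_default)) {
    sd <- rep(sd_default, length(x))
  }
  list(x = stats::setNames(x, tree$tip.label), sd = sd)
}
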