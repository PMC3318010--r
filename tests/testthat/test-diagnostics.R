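make_divergent_alignment <- function(rate, seed, ntip = 16, len = 400) {
  tr <- ape::compute.brlen(ape::stree(ntip, "balanced"), 1)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  simulate_alignment(tr, rate = rate, length = len, seed = seed)
}

test_that("identical sequences give a zero saturation index", {
  aln <- dna_alignment(stats::setNames(rep(strrep("ACGT", 50), 6),
                                       paste0("s", 1:6)))
  res <- saturation_test(aln, replicates = 10, seed = 1)
  expect_equal(res$iss, 0)
  expect_false(res$saturated)
})

test_that("fully randomized residues drive the index toward one", {
  set.seed(3)
  mat <- matrix(sample(c("A", "C", "G", "T"), 8 * 1500, replace = TRUE),
                nrow = 8)
  rownames(mat) <- paste0("s", 1:8)
  res <- saturation_test(dna_alignment(mat), replicates = 15, seed = 2)
  expect_gt(res$iss, 0.9)
  expect_lt(res$iss, 1.1)
  expect_true(res$saturated)
})

test_that("a low-divergence simulated alignment is confidently unsaturated", {
  aln <- make_divergent_alignment(rate = 0.05, seed = 7)
  res <- saturation_test(aln, replicates = 25, seed = 3)
  expect_lt(res$iss, res$iss_c)
  expect_lt(res$p_value, 0.05)
})

test_that("the saturation index grows with simulated divergence", {
  iss_at <- function(rate) {
    mean(vapply(1:5, function(i) {
      aln <- make_divergent_alignment(rate, seed = 100 * rate + i,
                                      ntip = 8, len = 300)
      saturation_test(aln, replicates = 10, seed = i)$iss
    }, 0))
  }
  v <- c(iss_at(0.05), iss_at(0.5), iss_at(5))
  expect_true(all(diff(v) > 0))
})

test_that("the index ignores sequence order and species labels", {
  aln <- make_divergent_alignment(rate = 0.3, seed = 11, ntip = 8, len = 300)
  r1 <- saturation_test(aln, replicates = 10, seed = 5)
  mat <- unclass(aln)
  perm <- sample(nrow(mat))
  mat2 <- mat[perm, ]
  rownames(mat2) <- paste0("x", seq_len(nrow(mat2)))
  r2 <- saturation_test(dna_alignment(mat2), replicates = 10, seed = 5)
  expect_equal(r2$iss, r1$iss)
  expect_equal(r2$iss_c, r1$iss_c)
})

test_that("node-density fit recovers noiseless generating curves", {
  x <- seq(0.5, 4, length.out = 30)
  prof <- data.frame(tip = paste0("t", 1:30), path_length = x,
                     n_nodes = 2 * x)
  fit <- node_density_fit(prof, n_perm = 200, seed = 1)
  expect_equal(fit$beta, 2, tolerance = 1e-6)
  expect_equal(fit$delta, 1, tolerance = 1e-6)
  expect_lt(fit$p_beta, 0.05)
  expect_equal(fit$verdict, "no-artifact")
  ## flat curve: no dependence on path length
  prof2 <- data.frame(tip = paste0("t", 1:30), path_length = x, n_nodes = 3)
  fit2 <- node_density_fit(prof2, n_perm = 200, seed = 1)
  expect_equal(fit2$delta, 0, tolerance = 1e-6)
})

test_that("degenerate path-length spreads yield a not-applicable verdict", {
  fit <- node_density_test(balanced4(), n_perm = 100, seed = 1)
  expect_false(fit$applicable)
  expect_equal(fit$verdict, "not-applicable")
})

test_that("node-density parameters transform correctly under time rescaling", {
  set.seed(8)
  tr <- ape::rtree(40)  # non-ultrametric: path lengths vary
  f1 <- node_density_test(tr, n_perm = 100, seed = 2)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3
  f2 <- node_density_test(tr2, n_perm = 100, seed = 2)
  expect_equal(f2$delta, f1$delta, tolerance = 0.02)
  expect_equal(f2$beta, f1$beta * 3^(-f1$delta), tolerance = 0.05)
  ## and the fit itself is invariant to tip order
  f3 <- node_density_test(ape::ladderize(tr), n_perm = 100, seed = 2)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-6)
})

test_that("the sample-level wrapper tabulates all four verdict cells", {
  set.seed(9)
  trees <- tree_sample(replicate(3, {
    tr <- ape::rtree(20)
    tr
  }, simplify = FALSE) |> (\(l) {
    for (i in seq_along(l)) l[[i]]$tip.label <- paste0("t", 1:20)
    l
  })())
  tab <- node_density_sample(trees, n_perm = 50, seed = 1)
  expect_equal(nrow(tab), 3L)
  s <- attr(tab, "summary")
  expect_equal(sum(s), 100)
  expect_named(s, c("beta_sig & delta<=1", "beta_sig & delta>1",
                    "beta_ns & delta<=1", "beta_ns & delta>1",
                    "not_applicable"))
})
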