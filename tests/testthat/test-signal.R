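test_that("phylogenetic covariance holds shared path lengths", {
  V <- phylo_covariance(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(unname(V), diag(2))
  V3 <- phylo_covariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(V3["A", "B"], 1)
  expect_equal(unname(diag(V3)), rep(2, 3))
  Vr <- phylo_covariance(unit_coal_tree(10, seed = 1))
  expect_true(isSymmetric(Vr))
  expect_true(all(Vr >= 0))
  expect_true(all(Vr <= outer(diag(Vr), diag(Vr), pmin) + 1e-12))
})

test_that("lambda transform scales only the off-diagonal", {
  V <- phylo_covariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(unname(lambda_transform(V, 0)), diag(diag(V)))
  expect_equal(lambda_transform(V, 0.5)["A", "B"], 0.5)
  expect_equal(diag(lambda_transform(V, 0.5)), diag(V))
  expect_error(lambda_transform(V, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(V, -0.1), "\\[0, 1\\]")
})

test_that("GLS estimators match the bivariate normal by hand", {
  fit <- gls_fit(c(A = 0, B = 2), diag(2))
  expect_equal(fit$alpha, 1)
  expect_equal(fit$sigma2, 1)
  expect_equal(fit$loglik, sum(stats::dnorm(c(0, 2), 1, 1, log = TRUE)))
})

test_that("GLS is location-equivariant and permutation-invariant", {
  tr <- unit_coal_tree(8, seed = 5)
  V <- phylo_covariance(tr)
  y <- simulate_traits(tr, sigma2 = 0.5, lam = 1, x0 = 2, seed = 2)
  f1 <- gls_fit(y, V)
  f2 <- gls_fit(y + 3.7, V)
  expect_equal(f2$alpha, f1$alpha + 3.7)
  expect_equal(f2$sigma2, f1$sigma2)
  expect_equal(f2$loglik, f1$loglik)
  perm <- sample(rownames(V))
  f3 <- gls_fit(y[perm], V[perm, perm])
  expect_equal(f3$loglik, f1$loglik)
  expect_equal(f3$alpha, f1$alpha)
})

test_that("GLS profile maximum matches a brute-force grid search", {
  tr <- unit_coal_tree(6, seed = 11)
  V <- phylo_covariance(tr)
  y <- simulate_traits(tr, sigma2 = 0.3, lam = 1, x0 = 1, seed = 4)
  fit <- gls_fit(y, V)
  yv <- as.numeric(y[rownames(V)])
  Vi <- solve(V)
  ld <- as.numeric(determinant(V)$modulus)
  grid_ll <- function(alpha, s2) {
    r <- yv - alpha
    -0.5 * (6 * log(2 * pi * s2) + ld + as.numeric(t(r) %*% Vi %*% r) / s2)
  }
  alphas <- seq(fit$alpha - 0.5, fit$alpha + 0.5, length.out = 201)
  s2s <- exp(seq(log(fit$sigma2) - 1, log(fit$sigma2) + 1, length.out = 201))
  best <- max(outer(alphas, s2s, Vectorize(grid_ll)))
  expect_lt(abs(best - fit$loglik), 1e-4)
  expect_gte(fit$loglik, best)  # the closed form dominates any grid point
})

test_that("lambda profile endpoints equal the untransformed and independent fits", {
  tr <- unit_coal_tree(12, seed = 6)
  V <- phylo_covariance(tr)
  y <- simulate_traits(tr, sigma2 = 0.4, lam = 0.6, x0 = 0, seed = 8)
  prof1 <- driftshift:::lambda_profile_loglik(1, y, V)
  expect_equal(prof1, gls_fit(y, V)$loglik)
  prof0 <- driftshift:::lambda_profile_loglik(0, y, V)
  expect_equal(prof0, gls_fit(y, diag(diag(V)))$loglik)
})

test_that("a proportional-to-identity covariance flags lambda as unidentifiable", {
  star <- ape::compute.brlen(ape::stree(8, "star"), 1)
  y <- simulate_traits(star, sigma2 = 1, lam = 1, x0 = 0, seed = 3)
  res <- fit_lambda(star, y, mode = "ml")
  expect_false(res$identifiable)
  expect_true(is.na(res$lambda))
})

test_that("lambda ML recovers high signal under Brownian motion and low when shuffled", {
  tr <- unit_coal_tree(50, seed = 20)
  hits_bm <- hits_sh <- 0L
  nrep <- 20
  for (i in seq_len(nrep)) {
    y <- simulate_traits(tr, sigma2 = 1, lam = 1, x0 = 0, seed = 300 + i)
    lam_bm <- fit_lambda(tr, y, mode = "ml")$lambda
    set.seed(600 + i)
    ysh <- trait_table(stats::setNames(sample(as.numeric(y)), names(y)))
    lam_sh <- fit_lambda(tr, ysh, mode = "ml")$lambda
    hits_bm <- hits_bm + (lam_bm >= 0.9)
    hits_sh <- hits_sh + (lam_sh <= 0.1)
  }
  expect_gte(hits_bm, 0.8 * nrep)
  expect_gte(hits_sh, 0.8 * nrep)
})

test_that("ML lambda agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- unit_coal_tree(40, seed = 21)
  y <- simulate_traits(tr, sigma2 = 0.5, lam = 0.7, x0 = 0, seed = 99)
  ours <- fit_lambda(tr, y, mode = "ml")
  ref <- phytools::phylosig(tr, as.numeric(y)[match(tr$tip.label, names(y))],
                            method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 0.02)
  expect_equal(ours$loglik, ref$logL, tolerance = 0.01)
})

test_that("bayes factors use the 2 delta-ln scale", {
  expect_equal(bayes_factor(7.4, -4.9), 24.6)
  expect_equal(bayes_factor(7.4, 9.3), -3.8)
  expect_equal(bayes_factor(-13.2, -13.2), 0)
  expect_error(bayes_factor(Inf, 0), "finite")
})

test_that("harmonic mean estimator approaches a conjugate analytic marginal", {
  ## y_i ~ N(m, 1), m ~ N(0, 1): analytic ln marginal available in closed form
  set.seed(77)
  n <- 10
  y <- rnorm(n, 0.4, 1)
  post_var <- 1 / (n + 1)
  post_mean <- sum(y) * post_var
  ## analytic: y ~ MVN(0, I + 11')
  S <- diag(n) + 1
  ln_true <- -0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                       t(y) %*% solve(S) %*% y)
  m_samp <- rnorm(1e5, post_mean, sqrt(post_var))
  ll <- vapply(m_samp, function(m) sum(dnorm(y, m, 1, log = TRUE)), 0)
  expect_lt(abs(ln_harmonic_mean(ll) - as.numeric(ln_true)), 1)
})

test_that("MCMC mode brackets the ML estimate and reports usable marginals", {
  tr <- unit_coal_tree(25, seed = 30)
  y <- simulate_traits(tr, sigma2 = 0.5, lam = 1, x0 = 0, seed = 31)
  ml <- fit_lambda(tr, y, mode = "ml")
  mc <- fit_lambda(tr, y, mode = "mcmc", iterations = 8000, seed = 42)
  expect_true(mc$lambda >= 0 && mc$lambda <= 1)
  expect_true(mc$interval[1] <= mc$lambda && mc$lambda <= mc$interval[2])
  expect_lt(abs(mc$lambda - ml$lambda), 0.35)
  expect_true(mc$acceptance > 0.05 && mc$acceptance < 0.8)
  ## strong Brownian signal: the lambda = 0 model should lose clearly
  expect_gt(mc$bf0, 3)
})

test_that("hpd_interval finds the shortest covering window", {
  x <- c(rep(1, 90), seq(100, 109))
  expect_equal(hpd_interval(x, 0.9), c(1, 1))
  set.seed(1)
  z <- rnorm(5000)
  h <- hpd_interval(z, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.12)
  expect_equal(h[2], 1.96, tolerance = 0.12)
})
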