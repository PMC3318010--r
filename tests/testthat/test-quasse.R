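test_that("speciation-rate families evaluate their formulas and clamp at zero", {
  expect_equal(speciation_rate(speciation_function("constant", c = 0.2),
                               c(-3, 0, 7)), rep(0.2, 3))
  lin <- speciation_function("linear", a = 0.1, b = 0.05)
  expect_equal(speciation_rate(lin, 2), 0.2)
  expect_equal(speciation_rate(lin, -10), 0)   # clamped
  hump <- speciation_function("hump", y0 = 0.1, y1 = 0.5, m = 5, w = 1)
  expect_equal(speciation_rate(hump, 5), 0.5)
  expect_equal(speciation_rate(hump, 50), 0.1, tolerance = 1e-12)
  sig <- speciation_function("sigmoidal", y0 = 0.1, y1 = 0.3, m = 5, r = 1)
  expect_equal(speciation_rate(sig, 5), 0.2)
  expect_lt(speciation_rate(sig, 0), 0.11)
  expect_gt(speciation_rate(sig, 10), 0.29)
})

test_that("tip state is a unit-mass density with zero extinction", {
  g <- character_grid(-4, 4, 256)
  st <- tip_initial_state(0.7, 0.2, g)
  expect_equal(sum(st$D) * g$dx, 1, tolerance = 1e-6)
  expect_true(all(st$E == 0))
  ## small sd concentrates the mass in the bin holding the trait
  st2 <- tip_initial_state(0.7, 0.02, g)
  expect_gt(max(st2$D) * g$dx, 0.5)
  expect_equal(g$x[which.max(st2$D)], 0.7, tolerance = g$dx)
  expect_error(tip_initial_state(9, 0.2, g), "outside")
})

test_that("character grid enforces its power-of-two contract", {
  expect_error(character_grid(0, 1, 100), "power of two")
  expect_error(character_grid(2, 1, 64), "exceed")
  g <- character_grid(-1, 1, 64)
  expect_equal(g$dx, 2 / 64)
  expect_equal(length(g$x), 64)
})

test_that("branch propagation matches closed forms", {
  g <- character_grid(-5, 5, 256)
  st <- tip_initial_state(0, 0.3, g)
  ## pure death of D under constant speciation, no diffusion
  p1 <- quasse_params(speciation_function("constant", c = 0.4), mu = 0,
                      sigma2 = 1e-10, theta = 0)
  out <- propagate_branch(st, 1.5, p1, g, nsteps = 40)
  expect_equal(sum(out$D) / sum(st$D), exp(-0.4 * 1.5), tolerance = 1e-9)
  expect_lt(max(out$E), 1e-12)
  ## extinction-only: E = 1 - exp(-mu t) uniformly in x
  p2 <- quasse_params(speciation_function("constant", c = 0), mu = 0.25,
                      sigma2 = 1e-10, theta = 0)
  out2 <- propagate_branch(st, 2, p2, g, nsteps = 40)
  expect_equal(range(out2$E), rep(1 - exp(-0.5), 2), tolerance = 1e-9)
  ## pure diffusion-advection: heat kernel moments (backward shift -theta t)
  p3 <- quasse_params(speciation_function("constant", c = 0), mu = 0,
                      sigma2 = 0.3, theta = 0.4)
  out3 <- propagate_branch(st, 2, p3, g, nsteps = 100)
  m <- sum(g$x * out3$D) / sum(out3$D)
  v <- sum((g$x - m)^2 * out3$D) / sum(out3$D)
  expect_equal(m, -0.4 * 2, tolerance = 1e-4)
  expect_equal(v, 0.3^2 + 0.3 * 2, tolerance = 1e-3)  # tip var + sigma2 t
  expect_equal(sum(out3$D) * g$dx, 1, tolerance = 1e-6)
})

test_that("extinction probability grows monotonically and stays in [0, 1]", {
  g <- character_grid(-3, 8, 128)
  st <- tip_initial_state(2, 0.3, g)
  p <- quasse_params(speciation_function("linear", a = 0.1, b = 0.05),
                     mu = 0.3, sigma2 = 0.05, theta = 0.1)
  prev <- st
  last_e <- 0
  for (t in c(0.5, 0.5, 0.5, 0.5)) {
    prev <- propagate_branch(prev, t, p, g, nsteps = 25)
    expect_true(all(prev$E >= 0 & prev$E <= 1))
    expect_gt(min(prev$E), last_e - 1e-10)
    last_e <- min(prev$E)
  }
  expect_gt(last_e, 0)
})

test_that("node combination multiplies daughters by the local speciation rate", {
  g <- character_grid(-2, 2, 64)
  fn <- speciation_function("constant", c = 0.37)
  left <- tip_initial_state(0, 0.2, g)
  ones <- structure(list(D = rep(1, g$n), E = numeric(g$n)),
                    class = "branch_state")
  comb <- node_combine(left, ones, fn, g)
  expect_equal(comb$D, 0.37 * left$D)
  ## commutativity
  right <- tip_initial_state(0.5, 0.2, g)
  expect_equal(node_combine(left, right, fn, g)$D,
               node_combine(right, left, fn, g)$D)
  ## annihilation
  zero <- structure(list(D = numeric(g$n), E = numeric(g$n)),
                    class = "branch_state")
  expect_true(all(node_combine(left, zero, fn, g)$D == 0))
  ## extinction-vector disagreement is an error
  badE <- structure(list(D = rep(1, g$n), E = rep(0.01, g$n)),
                    class = "branch_state")
  expect_error(node_combine(left, badE, fn, g), "inconsistency")
})

test_that("trait-independent likelihood factorizes into pure-birth x Brownian", {
  tree <- unit_coal_tree(10, seed = 42)
  traits <- simulate_traits(tree, sigma2 = 0.2, lam = 1, x0 = 0, seed = 7)
  lam <- 0.6; s2 <- 0.2; tip_sd <- 0.05
  p <- quasse_params(speciation_function("constant", c = lam), mu = 0,
                     sigma2 = s2)
  pad <- 5 * sqrt(s2) + 1
  g <- character_grid(min(traits) - pad, max(traits) + pad, 512)
  ll <- quasse_loglik(tree, traits, p, grid = g, root_mode = "flat",
                      condition = FALSE,
                      control = list(tip_sd = tip_sd, tstep = 0.01))
  oracle <- yule_loglik(tree, lam) +
    brownian_flat_root_loglik(tree, traits, s2, tip_sd) -
    log(g$upper - g$lower)
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-3)
})

test_that("2-tip likelihood matches the independent stiff-solver oracle", {
  skip_if_not_installed("deSolve")
  tree <- ape::read.tree(text = "(A:1,B:1);")
  traits <- c(A = 0.3, B = -0.2)
  fn <- speciation_function("linear", a = 0.3, b = 0.15)
  s2 <- 0.3; th <- -0.2
  p <- quasse_params(fn, mu = 0.05, sigma2 = s2, theta = th)
  pad <- 5 * sqrt(s2) + abs(th) + 0.5
  g <- character_grid(-0.2 - pad, 0.3 + pad, 256)
  ll <- quasse_loglik(tree, traits, p, grid = g,
                      control = list(tip_sd = 0.05, tstep = 0.01))
  oracle <- mol_2tip_loglik(1, 0.3, -0.2, fn, 0.05, s2, th, 0.05,
                            g$lower, g$upper, nx = 1280)
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-3)
})

test_that("likelihood is invariant to tip order and to grid reflection", {
  tree <- unit_coal_tree(8, seed = 14)
  traits <- simulate_traits(tree, sigma2 = 0.1, lam = 1, x0 = 0, seed = 15)
  fn <- speciation_function("sigmoidal", y0 = 0.2, y1 = 0.5, m = 0.1, r = 0.3)
  p <- quasse_params(fn, mu = 0.05, sigma2 = 0.1, theta = 0.15)
  g <- character_grid(min(traits) - 2.5, max(traits) + 2.5, 256)
  ctl <- list(tip_sd = 0.05, tstep = 0.01)
  l1 <- quasse_loglik(tree, traits, p, grid = g, control = ctl)
  perm <- sample(names(traits))
  l2 <- quasse_loglik(tree, traits[perm], p, grid = g, control = ctl)
  expect_equal(as.numeric(l2), as.numeric(l1), tolerance = 1e-10)
  ## reflect the trait axis: negate traits, midpoint and drift, swap y0/y1
  fn_r <- suppressWarnings(
    speciation_function("sigmoidal", y0 = 0.5, y1 = 0.2, m = -0.1, r = 0.3))
  p_r <- quasse_params(fn_r, mu = 0.05, sigma2 = 0.1, theta = -0.15)
  g_r <- character_grid(-g$upper, -g$lower, 256)
  tneg <- stats::setNames(-as.numeric(traits), names(traits))
  l3 <- suppressWarnings(
    quasse_loglik(tree, tneg, p_r, grid = g_r, control = ctl))
  expect_equal(as.numeric(l3), as.numeric(l1), tolerance = 1e-4)
})

test_that("likelihood reaches a refinement plateau in grid and time step", {
  tree <- unit_coal_tree(10, seed = 16)
  traits <- simulate_traits(tree, sigma2 = 0.2, lam = 1, x0 = 0, seed = 17)
  fn <- speciation_function("linear", a = 0.5, b = 0.1)
  p <- quasse_params(fn, mu = 0.1, sigma2 = 0.2, theta = 0.2)
  lo <- min(traits) - 3; up <- max(traits) + 3
  ll_a <- quasse_loglik(tree, traits, p, grid = character_grid(lo, up, 1024),
                        control = list(tip_sd = 0.1, tstep = 0.01))
  ll_b <- quasse_loglik(tree, traits, p, grid = character_grid(lo, up, 2048),
                        control = list(tip_sd = 0.1, tstep = 0.005))
  expect_lt(abs(as.numeric(ll_a) - as.numeric(ll_b)), 1e-3)
})

test_that("model df and AIC follow the published accounting", {
  expect_equal(model_df("constant"), 3L)
  expect_equal(model_df("linear"), 4L)
  expect_equal(model_df("sigmoidal"), 6L)
  expect_equal(model_df("hump"), 6L)
  expect_equal(model_df("linear", drift = TRUE), 5L)
  expect_equal(model_df("sigmoidal", drift = TRUE), 7L)
  expect_equal(model_df("hump", drift = TRUE), 7L)
  f <- quasse_fit("linear", drift = TRUE, loglik = -62.56)
  expect_equal(f$aic, 135.12)
  expect_equal(f$label, "Drift Linear")
})

test_that("model comparison computes AIC, chi-square and the AIC winner", {
  full <- quasse_fit("constant", loglik = -70.34)
  dl <- quasse_fit("linear", drift = TRUE, loglik = -62.56, theta = 0.48)
  dh <- quasse_fit("hump", drift = TRUE, loglik = -61.80, theta = 0.48)
  tab <- compare_models(list(full, dl, dh))
  expect_equal(tab$AIC[tab$model == "Drift Linear"], 135.12)
  expect_equal(tab$ChiSq[tab$model == "Drift Linear"], 15.56)
  expect_equal(tab$ChiSq[tab$model == "Drift Hump"], 17.08)
  expect_equal(attr(tab, "best"), "Drift Linear")
  expect_lt(tab$p_value[tab$model == "Drift Linear"], 0.001)
  ## degenerate twin fits: no difference, p = 1
  twin <- compare_models(list(full, quasse_fit("constant", loglik = -70.34)))
  expect_equal(twin$ChiSq[2], 0)
  expect_equal(twin$p_value[2], 1)
  expect_error(compare_models(list(dl, dh)), "Full")
})

test_that("fitting a constant model recovers plausible rates on a simulated tree", {
  gen <- quasse_params(speciation_function("constant", c = 0.5), mu = 0,
                       sigma2 = 0.3, theta = 0)
  sim <- simulate_quasse_forward(gen, simulation_config(seed = 33, dt = 0.02,
                                                        max_tips = 30,
                                                        x0 = 0))
  fit <- fit_quasse(sim$tree, sim$traits, kind = "constant",
                    control = list(nx = 256, tstep = 0.02, n_starts = 2,
                                   maxit = 200, seed = 1, tip_sd = 0.05))
  expect_equal(fit$df, 3L)
  expect_true(is.finite(fit$loglik))
  ## the optimizer must not be worse than the truth as a reference point
  g <- attr(fit, "settings")$grid_obj
  ll_true <- quasse_loglik(sim$tree, sim$traits, gen, grid = g,
                           control = list(nx = 256, tstep = 0.02,
                                          tip_sd = 0.05))
  expect_gte(fit$loglik + 1e-6, as.numeric(ll_true))
  ## generating rates recovered to the right order of magnitude on 30 tips
  expect_gt(fit$params$sigma2, 0.1)
  expect_lt(fit$params$sigma2, 0.9)
  expect_gt(fit$params$speciation$pars$c, 0.15)
  expect_lt(fit$params$speciation$pars$c, 1.5)
})
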