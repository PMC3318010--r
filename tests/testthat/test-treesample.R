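## small synthetic posterior sample shared by the tests below
make_sample <- function(ntrees = 3, ntip = 25, seed = 70) {
  p <- quasse_params(speciation_function("linear", a = -1, b = 0.35),
                     mu = 0, sigma2 = 0.1, theta = 0.25)
  sims <- lapply(seq_len(ntrees), function(i)
    simulate_quasse_forward(p, simulation_config(seed = seed + i, dt = 0.02,
                                                 max_tips = ntip, x0 = 4.7)))
  ## a posterior sample shares one tip set: relabel to a common set
  trees <- lapply(sims, function(s) s$tree)
  traits <- sims[[1]]$traits
  list(sample = tree_sample(trees, provenance = "posterior sample"),
       traits_per_tree = lapply(sims, function(s) s$traits))
}

fake_fit_table <- function(df) {
  structure(list(table = df, fits = NULL), class = "sample_fit_table")
}

test_that("drift aggregation reports means and shortest intervals", {
  tab <- data.frame(tree = 1:2, model = "Drift Linear",
                    theta = c(0.2, 0.4), lnLik = 0, AIC = 0)
  agg <- aggregate_drift(fake_fit_table(tab))
  expect_equal(agg$mean_theta, 0.3)
  set.seed(1)
  big <- data.frame(tree = 1:1000, model = "Drift Hump",
                    theta = rnorm(1000, 0.3, 0.05), lnLik = 0, AIC = 0)
  agg2 <- aggregate_drift(fake_fit_table(big))
  expect_equal(agg2$hpd_lower, 0.2, tolerance = 0.03)
  expect_equal(agg2$hpd_upper, 0.4, tolerance = 0.03)
  expect_false(agg2$skewed)
  expect_error(aggregate_drift(fake_fit_table(
    data.frame(tree = 1, model = "Full", theta = NA, lnLik = 0, AIC = 0))),
    "no drift")
})

test_that("sample-level bayes factors average per-tree likelihoods", {
  tab <- data.frame(tree = rep(1:3, 2),
                    model = rep(c("Drift Linear", "Full"), each = 3),
                    lnLik = c(-10, -12, -11, -15, -17, -16),
                    AIC = c(30, 34, 32, 36, 40, 38), theta = NA)
  ft <- fake_fit_table(tab)
  expect_equal(sample_bayes_factor(ft, "Drift Linear", "Full"), 10)
  expect_equal(sample_bayes_factor(ft, "Full", "Full"), 0)
  ## tree order is irrelevant
  tab2 <- tab[sample(nrow(tab)), ]
  expect_equal(sample_bayes_factor(fake_fit_table(tab2),
                                   "Drift Linear", "Full"), 10)
  bf <- sample_bf_matrix(ft)
  expect_equal(bf["Drift Linear", "Full"], 10)
  expect_equal(bf, -t(bf))
  expect_equal(unname(diag(bf)), c(0, 0))
  wins <- attr(bf, "aic_wins")
  expect_equal(unname(wins["Drift Linear"]), 1)
  expect_error(sample_bayes_factor(ft, "Hump", "Full"), "not present")
})

test_that("model label parsing covers the seven-model battery", {
  spec <- seven_models()
  expect_equal(nrow(spec), 7L)
  expect_equal(spec$label,
               c("Full", "Linear", "Sigmoidal", "Hump",
                 "Drift Linear", "Drift Sigmoidal", "Drift Hump"))
  expect_equal(parse_model_labels("drift-hump")$kind, "hump")
  expect_true(parse_model_labels("drift-hump")$drift)
  expect_error(parse_model_labels("cubic"), "unknown model")
})

test_that("a one-tree sample reproduces the single-tree battery exactly", {
  ms <- make_sample(ntrees = 1, ntip = 20)
  ctl <- list(nx = 128, tstep = 0.03, tip_sd = 0.1, n_starts = 1,
              maxit = 150, seed = 3)
  sft <- fit_over_sample(ms$sample, ms$traits_per_tree[[1]],
                         c("Full", "Drift Linear"), control = ctl)
  direct <- fit_battery(ms$sample[[1]], ms$traits_per_tree[[1]],
                        c("Full", "Drift Linear"), control = ctl)
  expect_equal(sort(sft$table$lnLik), sort(direct$lnLik), tolerance = 1e-9)
  expect_equal(sample_bayes_factor(sft, "Drift Linear", "Full"),
               2 * (direct$lnLik[direct$model == "Drift Linear"] -
                      direct$lnLik[direct$model == "Full"]),
               tolerance = 1e-9)
})

test_that("fit tables over a sample are complete and order-invariant in aggregation", {
  ms <- make_sample(ntrees = 2, ntip = 20)
  traits <- ms$traits_per_tree[[1]]
  ## the shared tip set means one trait table serves all trees
  ctl <- list(nx = 128, tstep = 0.03, tip_sd = 0.1, n_starts = 1,
              maxit = 120, seed = 4)
  sft <- fit_over_sample(ms$sample, traits, c("Full", "Drift Linear"),
                         control = ctl)
  expect_equal(nrow(sft$table), 4L)
  expect_setequal(sft$table$model, c("Full", "Drift Linear"))
  agg <- aggregate_drift(sft)
  expect_equal(agg$n, 2L)
  rev_tab <- fake_fit_table(sft$table[rev(seq_len(nrow(sft$table))), ])
  expect_equal(aggregate_drift(rev_tab)$mean_theta, agg$mean_theta)
})
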