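## Quantitative-trait state-dependent speciation/extinction likelihood with
## drift-diffusion character evolution, ML fitting of the seven speciation
## models (constant "Full", linear, sigmoidal, hump, each with or without a
## directional drift), and AIC / nested chi-square model comparison.
##
## Backward-time equations solved along each branch (x = ln body size):
##   dE/dt = mu - (lam(x)+mu) E + lam(x) E^2 + (s2/2) E_xx - theta E_x
##   dD/dt = -(lam(x)+mu) D + 2 lam(x) E D   + (s2/2) D_xx - theta D_x
## The advection sign is fixed so that theta > 0 means the trait increases in
## forward time (a positive, Cope's-rule trend); this convention is locked by
## a simulation-recovery test.

#' Speciation-rate function of the trait
#'
#' Four families: `constant` (rate `c`), `linear` (`max(0, a + b * x)`),
#' `sigmoidal` (`y0 + (y1 - y0) / (1 + exp(-(x - m) / r))`) and `hump`
#' (`y0 + (y1 - y0) * exp(-(x - m)^2 / (2 w^2))`).  Evaluated rates are
#' clamped at zero: rates are rates.
#'
#' @param kind one of `"constant"`, `"linear"`, `"sigmoidal"`, `"hump"`.
#' @param c constant rate (events/Myr).
#' @param a,b intercept and slope of the linear model.
#' @param y0,y1 low/high (or baseline/peak) rates.
#' @param m midpoint (sigmoidal) or mode (hump), in trait units (ln mm).
#' @param r,w smoothness (sigmoidal) and width (hump), both > 0.
#' @return object of class `speciation_function`.
#' @export
speciation_function <- function(kind = c("constant", "linear", "sigmoidal", "hump"),
                                c = NULL, a = NULL, b = NULL,
                                y0 = NULL, y1 = NULL, m = NULL,
                                r = NULL, w = NULL) {
  kind <- match.arg(kind)
  pars <- switch(kind,
    constant = {
      if (is.null(c) || c < 0) stop("constant model needs c >= 0")
      list(c = c)
    },
    linear = {
      if (is.null(a) || is.null(b)) stop("linear model needs a and b")
      list(a = a, b = b)
    },
    sigmoidal = {
      if (is.null(y0) || is.null(y1) || is.null(m) || is.null(r))
        stop("sigmoidal model needs y0, y1, m, r")
      if (r <= 0) stop("r must be > 0")
      if (y0 < 0 || y1 < 0) stop("rates must be >= 0")
      if (y1 < y0) warning("sigmoidal with y1 < y0: decreasing rate in x")
      list(y0 = y0, y1 = y1, m = m, r = r)
    },
    hump = {
      if (is.null(y0) || is.null(y1) || is.null(m) || is.null(w))
        stop("hump model needs y0, y1, m, w")
      if (w <= 0) stop("w must be > 0")
      if (y0 < 0 || y1 < 0) stop("rates must be >= 0")
      if (y1 < y0) warning("hump with y1 < y0: inverted (valley) shape")
      list(y0 = y0, y1 = y1, m = m, w = w)
    })
  structure(list(kind = kind, pars = pars), class = "speciation_function")
}

#' Evaluate a speciation-rate function
#'
#' @param fn a [speciation_function()].
#' @param x trait values (ln mm).
#' @return speciation rates (events/Myr), clamped at 0.
#' @export
speciation_rate <- function(fn, x) {
  stopifnot(inherits(fn, "speciation_function"))
  p <- fn$pars
  rate <- switch(fn$kind,
    constant  = rep(p$c, length(x)),
    linear    = p$a + p$b * x,
    sigmoidal = p$y0 + (p$y1 - p$y0) / (1 + exp(-(x - p$m) / p$r)),
    hump      = p$y0 + (p$y1 - p$y0) * exp(-(x - p$m)^2 / (2 * p$w^2)))
  pmax(rate, 0)
}

#' Parameters of one trait-dependent birth-death model
#'
#' @param speciation a [speciation_function()] (houses the speciation rate
#'   lambda_S as a function of the trait).
#' @param mu extinction rate (events/Myr, >= 0).
#' @param sigma2 diffusion parameter: expected squared rate of trait change
#'   (ln-mm^2/Myr, > 0).
#' @param theta drift parameter: expected (deterministic) rate of trait
#'   change (ln-mm/Myr); 0 for no-drift models, > 0 is a positive trend.
#' @return object of class `quasse_params`.
#' @export
quasse_params <- function(speciation, mu = 0, sigma2, theta = 0) {
  stopifnot(inherits(speciation, "speciation_function"))
  if (!is.finite(mu) || mu < 0) stop("mu must be finite and >= 0")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  if (!is.finite(theta)) stop("theta must be finite")
  structure(list(speciation = speciation, mu = mu, sigma2 = sigma2,
                 theta = theta),
            class = "quasse_params")
}

#' Uniform character grid for the likelihood discretization
#'
#' Points `x_k = lower + k * dx`, `k = 0, ..., n - 1`, `dx = (upper - lower) / n`
#' (the upper bound is the exclusive end of the periodic FFT domain).  `n`
#' must be a power of two.
#'
#' @param lower,upper trait bounds (ln mm).
#' @param n number of grid points (power of two).
#' @return object of class `character_grid` with fields `lower`, `upper`,
#'   `n`, `dx`, `x`.
#' @export
character_grid <- function(lower, upper, n = 1024) {
  if (upper <= lower) stop("upper must exceed lower")
  n <- as.integer(n)
  if (n < 8 || bitwAnd(n, n - 1L) != 0L)
    stop("n must be a power of two (>= 8)")
  dx <- (upper - lower) / n
  structure(list(lower = lower, upper = upper, n = n, dx = dx,
                 x = lower + (seq_len(n) - 1) * dx),
            class = "character_grid")
}

## grid wide enough for all parameter values explored during a fit:
## tip range + 5 sd of total diffusion + total backward advection + tip error
make_character_grid <- function(traits, depth, sigma2_max, theta_max,
                                tip_sd = 0, n = 1024) {
  pad <- 5 * sqrt(sigma2_max * depth) + abs(theta_max) * depth +
    10 * tip_sd + 1e-6
  character_grid(min(traits) - pad, max(traits) + pad, n)
}

#' Initial branch state at an extant tip
#'
#' `D` is a Gaussian density centred on the observed trait with standard
#' deviation `sd` (the measurement error), discretized on the grid and
#' normalized to unit mass; `E` is identically zero (extant tip, complete
#' sampling).
#'
#' @param trait observed trait value (ln mm), strictly inside the grid.
#' @param sd measurement standard deviation (ln mm, > 0).
#' @param grid a [character_grid()].
#' @return object of class `branch_state` with fields `D` and `E`.
#' @export
tip_initial_state <- function(trait, sd, grid) {
  stopifnot(inherits(grid, "character_grid"))
  if (!is.finite(trait) || trait <= grid$lower || trait >= grid$upper)
    stop("trait ", trait, " lies outside the character grid [",
         grid$lower, ", ", grid$upper, "]")
  if (!is.finite(sd) || sd <= 0) stop("tip sd must be > 0")
  D <- stats::dnorm(grid$x, trait, sd)
  s <- sum(D) * grid$dx
  if (s <= 0) stop("tip density vanished on the grid; refine the grid")
  structure(list(D = D / s, E = numeric(grid$n)), class = "branch_state")
}

#' Propagate a branch state backward in time
#'
#' Integrates the coupled (D, E) equations along a branch of length `t` by
#' operator splitting: the exact pointwise birth-death update alternated with
#' a spectral (FFT) diffusion-advection step per time slice.
#'
#' @param state a `branch_state`.
#' @param t branch length (Myr, >= 0).
#' @param params a [quasse_params()].
#' @param grid a [character_grid()].
#' @param nsteps number of splitting steps; defaults to `ceiling(t / dt_max)`.
#' @param dt_max maximum step length (Myr); ignored when `nsteps` is given.
#' @return the propagated `branch_state`.
#' @export
propagate_branch <- function(state, t, params, grid, nsteps = NULL,
                             dt_max = NULL) {
  stopifnot(inherits(state, "branch_state"), inherits(grid, "character_grid"),
            inherits(params, "quasse_params"))
  if (t < 0) stop("branch length must be >= 0")
  if (t == 0) return(state)
  if (is.null(nsteps)) {
    if (is.null(dt_max)) dt_max <- t / 25
    nsteps <- max(1L, ceiling(t / dt_max))
  }
  lam <- speciation_rate(params$speciation, grid$x)
  out <- propagate_branch_cpp(state$D, state$E, lam, params$mu,
                              params$sigma2, params$theta, t, grid$dx,
                              as.integer(nsteps))
  structure(list(D = out$D, E = out$E), class = "branch_state")
}

## fraction of D mass sitting in the outermost cell on either side; values
## below a noise floor (relative to the density peak) are ignored so that
## sub-resolution spectral ringing is not mistaken for truncated mass.  A
## genuinely truncated tail carries boundary values comparable to the peak,
## so the guard still converts silent mass loss into a hard error long
## before it can move the log-likelihood.
boundary_mass_fraction <- function(D) {
  tot <- sum(D)
  if (tot <= 0) return(1)
  floor_cut <- 1e-4 * max(D)
  edge <- c(D[1], D[length(D)])
  sum(edge[edge > floor_cut]) / tot
}

#' Combine two daughter states at a speciation node
#'
#' `D(x) = D_left(x) * D_right(x) * lambda_S(x)`; the extinction vector is
#' carried through (both daughters must agree, as they describe the same
#' process below the node).
#'
#' @param left,right `branch_state`s of the daughter branches.
#' @param fn the [speciation_function()].
#' @param grid a [character_grid()].
#' @param e_tol maximum pointwise disagreement tolerated between the two
#'   extinction vectors (default `1e-8` for direct use; [quasse_loglik()]
#'   relaxes this to absorb operator-splitting jitter between sibling
#'   branches discretized with different step counts).
#' @return the combined `branch_state`.
#' @export
node_combine <- function(left, right, fn, grid, e_tol = 1e-8) {
  stopifnot(inherits(left, "branch_state"), inherits(right, "branch_state"))
  dev <- max(abs(left$E - right$E))
  if (dev > e_tol)
    stop(sprintf(
      "internal inconsistency: sibling extinction vectors differ by %.3g (> %.3g)",
      dev, e_tol))
  structure(list(D = left$D * right$D * speciation_rate(fn, grid$x),
                 E = (left$E + right$E) / 2),
            class = "branch_state")
}

## default per-tip measurement sd: 1/100 of the observed trait range
default_tip_sd <- function(x) max(diff(range(x)) / 100, 1e-4)

quasse_control <- function(control = list()) {
  defaults <- list(
    tstep = 0.01,        # splitting step as a fraction of tree depth
    nx = 1024L,          # grid points (power of two)
    tip_sd = NULL,       # measurement sd; default range/100
    boundary_tol = 1e-6, # max fraction of D mass in the outermost cells
    e_tol = 2e-3,        # sibling-E agreement tolerance inside the traversal
    ultra_tol = 1e-3,    # ultrametricity tolerance
    sigma2_max = NULL,   # fit bounds (also size the fitting grid)
    theta_max = NULL,
    rate_max = NULL,
    n_starts = 5L,       # optimizer starting points
    maxit = 500L,
    reltol = 1e-8,
    optimizer = "auto",  # "sbplx" (subplex, via nloptr) | "nelder-mead"
    seed = 1L)
  unknown <- setdiff(names(control), names(defaults))
  if (length(unknown)) stop("unknown control option(s): ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(defaults, control)
}

#' Log-likelihood of a trait-dependent birth-death model
#'
#' Post-order pruning over the tree: Gaussian tip conditioning, backward
#' propagation along branches, multiplication by the speciation rate at
#' nodes, and integration of the root density against a weight function.
#'
#' @param tree ultrametric `phylo` (branch lengths in Myr).
#' @param traits `trait_table` or named numeric vector covering all tips.
#' @param params a [quasse_params()].
#' @param grid optional [character_grid()]; constructed automatically from
#'   the traits and parameters when omitted.
#' @param root_mode `"obs"` (root weights proportional to the root density
#'   itself) or `"flat"` (uniform weights over the grid extent).
#' @param condition condition the likelihood on survival of the two root
#'   lineages (divides by the weighted `lambda_S (1 - E_root)^2`).
#' @param control list of numerical settings, see Details; notable entries:
#'   `tstep` (splitting step as fraction of tree depth, default 0.01), `nx`
#'   (grid points, default 1024), `tip_sd` (measurement sd, default 1/100 of
#'   the trait range), `boundary_tol` (grid-coverage guard, default 1e-6).
#' @return the log-likelihood (scalar), with attribute `root_mode`.
#' @export
quasse_loglik <- function(tree, traits, params, grid = NULL,
                          root_mode = c("obs", "flat"), condition = TRUE,
                          control = list()) {
  root_mode <- match.arg(root_mode)
  ctrl <- quasse_control(control)
  stopifnot(inherits(params, "quasse_params"))
  depth <- assert_ultrametric(tree, rel_tol = ctrl$ultra_tol)
  al <- align_traits(tree, traits)
  x <- al$x
  tip_sd <- if (!is.null(al$sd)) al$sd else {
    rep(if (is.null(ctrl$tip_sd)) default_tip_sd(x) else ctrl$tip_sd,
        length(x))
  }
  if (is.null(grid)) {
    grid <- make_character_grid(x, depth, params$sigma2, params$theta,
                                tip_sd = max(tip_sd), n = ctrl$nx)
  }
  stopifnot(inherits(grid, "character_grid"))
  ## resolution floor: a tip density narrower than the grid resolution
  ## cannot be represented (its spectrum extends past the Nyquist frequency
  ## and rings); flooring the measurement sd at 1.5 dx keeps the discretized
  ## tip conditioning well-posed, and is identical across models sharing a
  ## grid, so likelihood differences are unaffected
  tip_sd <- pmax(tip_sd, 1.5 * grid$dx)
  dt_max <- ctrl$tstep * depth
  lam_grid <- speciation_rate(params$speciation, grid$x)

  ntip <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  tipD <- vapply(seq_len(ntip), function(i)
    tip_initial_state(x[tr$tip.label[i]], tip_sd[i], grid)$D,
    numeric(grid$n))
  res <- quasse_prune_cpp(tr$edge, tr$edge.length,
                          as.integer(pmax(1, ceiling(tr$edge.length / dt_max))),
                          tipD, lam_grid, params$mu, params$sigma2,
                          params$theta, grid$dx, ntip, tr$Nnode)
  if (!isTRUE(res$ok)) return(-Inf)
  if (res$boundary > ctrl$boundary_tol)
    stop("character grid too narrow: probability mass reached the boundary; ",
         "widen the grid or increase the pad")
  if (res$e_dev > ctrl$e_tol)
    stop(sprintf(
      "internal inconsistency: sibling extinction vectors differ by %.3g (> %.3g)",
      res$e_dev, ctrl$e_tol))
  rs <- list(D = res$D, E = res$E)
  logcomp <- res$logcomp
  D <- rs$D
  tot <- sum(D) * grid$dx
  if (!is.finite(tot) || tot <= 0) return(-Inf)
  w <- switch(root_mode,
              obs  = D / tot,
              flat = rep(1 / (grid$upper - grid$lower), grid$n))
  lik <- sum(D * w) * grid$dx
  if (condition) {
    cond <- sum(w * lam_grid * (1 - rs$E)^2) * grid$dx
    if (!is.finite(cond) || cond <= 0) return(-Inf)
    lik <- lik / cond
  }
  if (!is.finite(lik) || lik <= 0) return(-Inf)
  structure(log(lik) + logcomp, root_mode = root_mode, condition = condition)
}

combine_children <- function(children, fn, grid, e_tol) {
  if (is.null(children) || !length(children))
    stop("internal error: node without accumulated children")
  st <- children[[1]]
  for (k in seq_along(children)[-1])
    st <- node_combine(st, children[[k]], fn, grid, e_tol = e_tol)
  st
}

## ---------------------------------------------------------------------------
## ML fitting

model_df_table <- c(constant = 3L, linear = 4L, sigmoidal = 6L, hump = 6L)

#' Free-parameter count of a model
#'
#' Counts the speciation-function parameters plus `mu` and `sigma2`, plus
#' `theta` for drift models: Full 3, Linear 4, Sigmoidal 6, Hump 6, and one
#' more with drift.  (The root state is integrated out, not counted.)
#'
#' @param kind model kind (`"constant"`, `"linear"`, `"sigmoidal"`, `"hump"`).
#' @param drift logical: does the model include the drift parameter?
#' @return integer degrees of freedom.
#' @export
model_df <- function(kind, drift = FALSE) {
  kind <- match.arg(kind, names(model_df_table))
  model_df_table[[kind]] + as.integer(drift)
}

#' Human-readable model label
#'
#' `"Full"` for the constant (trait-independent) model, otherwise the
#' capitalized kind, prefixed with `"Drift "` for drift models.
#'
#' @inheritParams model_df
#' @return character label.
#' @export
model_label <- function(kind, drift = FALSE) {
  kind <- match.arg(kind, names(model_df_table))
  base <- c(constant = "Full", linear = "Linear",
            sigmoidal = "Sigmoidal", hump = "Hump")[[kind]]
  if (drift && kind == "constant")
    stop("the constant (Full) model has no drift variant")
  if (drift) paste("Drift", base) else base
}

#' Assemble a fitted-model record
#'
#' Container used both by [fit_quasse()] and to assemble published fit
#' tables (degrees of freedom and log-likelihoods) for re-computation of AIC
#' and chi-square statistics with [compare_models()].
#'
#' @param kind,drift model identity (see [model_df()]).
#' @param loglik natural log of the maximized likelihood.
#' @param params optional fitted [quasse_params()].
#' @param df degrees of freedom; defaults to the [model_df()] convention.
#' @param theta drift estimate (taken from `params` when available).
#' @param convergence optimizer convergence code (0 = converged).
#' @return object of class `quasse_fit` with `aic = 2 df - 2 loglik`.
#' @export
quasse_fit <- function(kind, drift = FALSE, loglik, params = NULL,
                       df = NULL, theta = NA_real_, convergence = NA_integer_) {
  kind <- match.arg(kind, names(model_df_table))
  if (is.null(df)) df <- model_df(kind, drift)
  if (!is.null(params)) theta <- params$theta
  structure(list(kind = kind, drift = drift, label = model_label(kind, drift),
                 params = params, loglik = loglik, df = as.integer(df),
                 aic = 2 * df - 2 * loglik, theta = theta,
                 convergence = convergence),
            class = "quasse_fit")
}

#' @export
print.quasse_fit <- function(x, ...) {
  cat(sprintf("%s model: lnL = %.4f, df = %d, AIC = %.4f", x$label,
              x$loglik, x$df, x$aic))
  if (x$drift) cat(sprintf(", theta = %.4f", x$theta))
  cat("\n")
  invisible(x)
}

## pack/unpack model parameters to the unconstrained optimizer scale;
## mu_fixed (when non-NULL) removes the extinction rate from the vector
par_pack <- function(kind, drift, fn_pars, mu, sigma2, theta,
                     mu_fixed = NULL) {
  p <- switch(kind,
    constant  = c(lc = log(fn_pars$c)),
    linear    = c(a = fn_pars$a, b = fn_pars$b),
    sigmoidal = c(ly0 = log(max(fn_pars$y0, 1e-8)),
                  ly1 = log(max(fn_pars$y1, 1e-8)),
                  m = fn_pars$m, lr = log(fn_pars$r)),
    hump      = c(ly0 = log(max(fn_pars$y0, 1e-8)),
                  ly1 = log(max(fn_pars$y1, 1e-8)),
                  m = fn_pars$m, lw = log(fn_pars$w)))
  if (is.null(mu_fixed)) p <- c(p, lmu = log(max(mu, 1e-7)))
  p <- c(p, ls2 = log(sigma2))
  if (drift) p <- c(p, theta = theta)
  p
}

par_unpack <- function(kind, drift, p, mu_fixed = NULL) {
  fn <- switch(kind,
    constant  = speciation_function("constant", c = exp(p[["lc"]])),
    linear    = speciation_function("linear", a = p[["a"]], b = p[["b"]]),
    sigmoidal = suppressWarnings(
      speciation_function("sigmoidal", y0 = exp(p[["ly0"]]),
                          y1 = exp(p[["ly1"]]), m = p[["m"]],
                          r = exp(p[["lr"]]))),
    hump      = suppressWarnings(
      speciation_function("hump", y0 = exp(p[["ly0"]]),
                          y1 = exp(p[["ly1"]]), m = p[["m"]],
                          w = exp(p[["lw"]]))))
  quasse_params(fn,
                mu = if (is.null(mu_fixed)) exp(p[["lmu"]]) else mu_fixed,
                sigma2 = exp(p[["ls2"]]),
                theta = if (drift) p[["theta"]] else 0)
}

#' Fit a trait-dependent birth-death model by maximum likelihood
#'
#' Maximizes [quasse_loglik()] over the model's free parameters
#' (Nelder-Mead on a log/identity-transformed scale, from several seeded
#' moment-based starting points).  The character grid is fixed once per fit,
#' sized from the search bounds on `sigma2` and `theta`, so that every
#' likelihood evaluation shares the same discretization.
#'
#' @inheritParams quasse_loglik
#' @param kind speciation model kind (`"constant"`, `"linear"`,
#'   `"sigmoidal"`, `"hump"`).
#' @param drift include the directional drift parameter?
#' @param init optional `quasse_params` used as an additional starting point
#'   (e.g. the fit of a nested model).
#' @param grid optional shared [character_grid()].  When several models are
#'   compared on one tree they must share a grid so that discretization
#'   bias cancels in likelihood differences; when omitted, the grid is
#'   built from the drift-inclusive search bounds for the same reason.
#' @param mu_fixed optional fixed extinction rate; when given, `mu` is
#'   removed from the free parameters (the reported df drops by one).
#'   Useful for fitting the generating model class in simulation studies.
#' @return a [quasse_fit()] with the fitted parameters and AIC.
#' @export
fit_quasse <- function(tree, traits, kind = "constant", drift = FALSE,
                       root_mode = "obs", condition = TRUE,
                       init = NULL, grid = NULL, mu_fixed = NULL,
                       control = list()) {
  kind <- match.arg(kind, names(model_df_table))
  if (drift && kind == "constant")
    stop("the constant (Full) model has no drift variant")
  ## during optimization, parameter exploration legitimately pushes 5-sigma
  ## diffusion tails to the pad edge; a 1e-5 mass truncation perturbs the
  ## log-likelihood by < 1e-4, so the exploration guard is laxer than the
  ## default evaluation guard unless the caller pinned it
  if (is.null(control$boundary_tol)) control$boundary_tol <- 1e-5
  ctrl <- quasse_control(control)
  depth <- assert_ultrametric(tree, rel_tol = ctrl$ultra_tol)
  al <- align_traits(tree, traits)
  x <- al$x
  tip_sd <- if (!is.null(al$sd)) max(al$sd) else
    if (is.null(ctrl$tip_sd)) default_tip_sd(x) else ctrl$tip_sd

  ## moment-based heuristics
  n <- length(x)
  lam0 <- (n - 1) / sum(tree$edge.length)        # Yule-style rate guess
  s2_0 <- tryCatch(max(gls_fit(x, phylo_covariance(tree))$sigma2, 1e-6),
                   error = function(e) max(stats::var(x) / depth, 1e-6))
  xm <- mean(x); xs <- max(stats::sd(x), 0.05)

  sigma2_max <- if (is.null(ctrl$sigma2_max)) 6 * s2_0 else ctrl$sigma2_max
  theta_max <- if (is.null(ctrl$theta_max))
    diff(range(x)) / depth + 3 * sqrt(s2_0 / depth) + 0.05 else ctrl$theta_max
  rate_max <- if (is.null(ctrl$rate_max)) 50 * lam0 else ctrl$rate_max
  ## the pad includes the drift allowance even for no-drift models, so that
  ## nested fits on the same tree share an identical discretization
  if (is.null(grid))
    grid <- make_character_grid(x, depth, sigma2_max, theta_max,
                                tip_sd = tip_sd, n = ctrl$nx)
  stopifnot(inherits(grid, "character_grid"))

  base_fn <- switch(kind,
    constant  = list(c = lam0),
    linear    = list(a = lam0, b = 0),
    sigmoidal = list(y0 = lam0, y1 = lam0 * 1.5, m = xm, r = xs),
    hump      = list(y0 = lam0, y1 = lam0 * 1.5, m = xm, w = xs))
  p0 <- par_pack(kind, drift, base_fn, mu = lam0 / 10, sigma2 = s2_0,
                 theta = 0, mu_fixed = mu_fixed)

  set.seed(ctrl$seed)
  starts <- list(p0)
  if (drift) {
    ## drift models get deterministic +/- theta starts first: the theta = 0
    ## axis is a saddle whenever the speciation slope is also near zero
    for (sgn in c(1, -1)) {
      if (length(starts) >= ctrl$n_starts) break
      pk <- p0
      pk[["theta"]] <- sgn * 0.4 * theta_max
      starts <- c(starts, list(pk))
    }
  }
  while (length(starts) < ctrl$n_starts) {
    pk <- p0 + stats::rnorm(length(p0), 0, 0.4)
    if (kind == "linear")
      pk[["b"]] <- stats::rnorm(1, 0, lam0 / (2 * xs))
    if (drift) pk[["theta"]] <- stats::rnorm(1, 0, 0.3 * theta_max)
    starts <- c(starts, list(pk))
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "quasse_params"))
    starts <- c(list(par_pack(kind, drift, init$speciation$pars,
                              init$mu, init$sigma2, init$theta,
                              mu_fixed = mu_fixed)),
                starts)
  }

  last_problem <- "none"
  penalized <- function(p) {
    if (any(!is.finite(p))) {
      last_problem <<- "non-finite parameter vector"
      return(1e10)
    }
    if (exp(p[["ls2"]]) > sigma2_max) {
      last_problem <<- "sigma2 above search bound"
      return(1e10)
    }
    if (drift && abs(p[["theta"]]) > theta_max) {
      last_problem <<- "theta outside search bound"
      return(1e10)
    }
    pars <- tryCatch(par_unpack(kind, drift, p, mu_fixed = mu_fixed),
                     error = function(e) {
      last_problem <<- conditionMessage(e)
      NULL
    })
    if (is.null(pars)) return(1e10)
    if (max(speciation_rate(pars$speciation, grid$x)) > rate_max) {
      last_problem <<- "speciation rate above search bound"
      return(1e10)
    }
    ll <- tryCatch(
      quasse_loglik(tree, x, pars, grid = grid, root_mode = root_mode,
                    condition = condition,
                    control = list(tstep = ctrl$tstep, nx = ctrl$nx,
                                   tip_sd = tip_sd, e_tol = ctrl$e_tol,
                                   boundary_tol = ctrl$boundary_tol,
                                   ultra_tol = ctrl$ultra_tol)),
      error = function(e) {
        last_problem <<- conditionMessage(e)
        -Inf
      })
    if (!is.finite(ll)) 1e10 else -ll
  }

  use_sbplx <- ctrl$optimizer %in% c("auto", "sbplx") &&
    requireNamespace("nloptr", quietly = TRUE)
  if (ctrl$optimizer == "sbplx" && !use_sbplx)
    stop("optimizer 'sbplx' requires the nloptr package")
  run_opt <- function(par0) {
    if (use_sbplx) {
      nm <- names(par0)
      named_obj <- function(p) penalized(stats::setNames(p, nm))
      r <- tryCatch(
        nloptr::sbplx(unname(par0), named_obj,
                      control = list(maxeval = 3 * ctrl$maxit,
                                     xtol_rel = 1e-6, ftol_rel = ctrl$reltol,
                                     ftol_abs = 1e-5)),
        error = function(e) NULL)
      if (is.null(r)) return(NULL)
      list(par = stats::setNames(r$par, names(par0)), value = r$value,
           convergence = if (r$convergence > 0) 0L else r$convergence)
    } else {
      tryCatch(
        stats::optim(par0, penalized, method = "Nelder-Mead",
                     control = list(maxit = ctrl$maxit,
                                    reltol = ctrl$reltol)),
        error = function(e) NULL)
    }
  }
  best <- NULL
  trace <- character(0)
  for (s in seq_along(starts)) {
    f0 <- penalized(starts[[s]])
    if (f0 >= 1e10) {
      trace <- c(trace, sprintf("start %d: infeasible starting point (%s)",
                                s, last_problem))
      next
    }
    opt <- run_opt(starts[[s]])
    if (is.null(opt)) {
      trace <- c(trace, sprintf("start %d: optimizer error", s))
      next
    }
    trace <- c(trace, sprintf("start %d: value %.4f (conv %d)", s,
                              -opt$value, opt$convergence))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("fit_quasse: no starting point led to a successful optimization\n",
         paste(trace, collapse = "\n"))
  ## one polish restart from the incumbent: a fresh simplex escapes
  ## degenerate collapsed simplexes
  polish <- run_opt(best$par)
  if (!is.null(polish) && polish$value < best$value) best <- polish
  pars <- par_unpack(kind, drift, best$par, mu_fixed = mu_fixed)
  fit <- quasse_fit(kind, drift, loglik = -best$value, params = pars,
                    df = model_df(kind, drift) - !is.null(mu_fixed),
                    convergence = best$convergence)
  attr(fit, "trace") <- trace
  attr(fit, "settings") <- list(root_mode = root_mode, condition = condition,
                                nx = ctrl$nx, tstep = ctrl$tstep,
                                tip_sd = tip_sd, grid = c(grid$lower, grid$upper),
                                grid_obj = grid,
                                seed = ctrl$seed, n_starts = ctrl$n_starts)
  fit
}

## re-express fitted speciation parameters as a starting point for another
## model kind (used for warm-start chaining along the model hierarchy)
promote_speciation <- function(fn, kind, m0, scale0) {
  if (fn$kind == kind) return(fn$pars)
  base_rate <- switch(fn$kind,
    constant = fn$pars$c,
    linear = max(fn$pars$a + fn$pars$b * m0, 1e-4),
    sigmoidal = (fn$pars$y0 + fn$pars$y1) / 2,
    hump = (fn$pars$y0 + fn$pars$y1) / 2)
  switch(kind,
    constant  = list(c = base_rate),
    linear    = list(a = base_rate, b = 0),
    sigmoidal = list(y0 = base_rate, y1 = base_rate, m = m0, r = scale0),
    hump      = list(y0 = base_rate, y1 = base_rate, m = m0, w = scale0))
}

#' Fit a battery of models on one tree with a shared discretization
#'
#' Fits the requested models with [fit_quasse()] on a single shared
#' character grid (so that discretization bias cancels exactly in the
#' likelihood differences used by AIC and chi-square tests), warm-starting
#' each model from its closest already-fitted relative: constant feeds the
#' trait-dependent models, and each no-drift fit feeds its drift variant at
#' `theta = 0`.
#'
#' @inheritParams fit_quasse
#' @param models model labels or specification (see [parse_model_labels()]);
#'   the constant model is added automatically when absent (it anchors both
#'   the warm starts and the comparison table).
#' @return a [compare_models()] table with the fits attached as
#'   `attr(, "fits")`.
#' @export
fit_battery <- function(tree, traits, models = c("Full", "Linear",
                                                 "Sigmoidal", "Hump",
                                                 "Drift Linear",
                                                 "Drift Sigmoidal",
                                                 "Drift Hump"),
                        root_mode = "obs", condition = TRUE,
                        control = list()) {
  spec <- as_model_spec(models)
  if (!any(spec$kind == "constant" & !spec$drift))
    spec <- rbind(data.frame(kind = "constant", drift = FALSE,
                             label = "Full"), spec)
  ## fit order: constant, then no-drift, then drift models
  ord <- order(spec$drift, spec$kind != "constant")
  spec <- spec[ord, ]
  al <- align_traits(tree, traits)
  m0 <- mean(al$x); scale0 <- max(stats::sd(al$x), 0.05)
  fits <- list()
  for (j in seq_len(nrow(spec))) {
    kind <- spec$kind[j]; drift <- spec$drift[j]
    parent <- if (drift) {
      fits[[model_label(kind, FALSE)]] %||% fits[["Full"]]
    } else if (kind != "constant") {
      fits[["Full"]]
    } else NULL
    init <- if (!is.null(parent)) {
      pp <- parent$params
      quasse_params(do.call(speciation_function,
                            c(list(kind = kind),
                              promote_speciation(pp$speciation, kind,
                                                 m0, scale0))),
                    mu = pp$mu, sigma2 = pp$sigma2, theta = pp$theta)
    } else NULL
    fit <- fit_quasse(tree, traits, kind = kind, drift = drift,
                      root_mode = root_mode, condition = condition,
                      init = init, grid = grid_of(fits) , control = control)
    fits[[fit$label]] <- fit
  }
  out <- compare_models(unname(fits))
  attr(out, "fits") <- fits
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## the shared grid is whatever the first fit constructed
grid_of <- function(fits) {
  if (!length(fits)) return(NULL)
  g <- attr(fits[[1]], "settings")$grid_obj
  g
}

#' Compare fitted models by AIC and nested chi-square tests
#'
#' Builds the model-comparison table: `AIC = 2 df - 2 lnL` per model, the
#' likelihood-ratio statistic `ChiSq = 2 (lnL_model - lnL_Full)` of each
#' model against the constant-rate ("Full") model with its upper-tail
#' chi-square p-value on the df difference, and the best model by AIC.
#'
#' @param fits list of [quasse_fit()] objects sharing one tree and trait
#'   set; must include the Full (constant, no-drift) model.
#' @return data.frame of class `model_comparison` with columns `model`,
#'   `df`, `lnLik`, `AIC`, `ChiSq`, `df_diff`, `p_value`, `theta`; the best
#'   model's label is in `attr(, "best")`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "quasse_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, TRUE, "quasse_fit")))
  labels <- vapply(fits, `[[`, "", "label")
  full_i <- which(labels == "Full")
  if (!length(full_i))
    stop("compare_models requires the Full (constant-rate) model")
  full <- fits[[full_i[1]]]
  df <- vapply(fits, `[[`, 0L, "df")
  lnl <- vapply(fits, `[[`, 0, "loglik")
  chisq <- 2 * (lnl - full$loglik)
  ddf <- df - full$df
  p <- ifelse(ddf > 0, stats::pchisq(chisq, ddf, lower.tail = FALSE),
              ifelse(abs(chisq) < 1e-12, 1, NA_real_))
  out <- data.frame(model = labels, df = df, lnLik = lnl, AIC = 2 * df - 2 * lnl,
                    ChiSq = ifelse(seq_along(fits) == full_i[1], NA, chisq),
                    df_diff = ifelse(seq_along(fits) == full_i[1], NA, ddf),
                    p_value = ifelse(seq_along(fits) == full_i[1], NA, p),
                    theta = vapply(fits, `[[`, 0, "theta"),
                    stringsAsFactors = FALSE)
  attr(out, "best") <- labels[which.min(out$AIC)]
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  print.data.frame(x, digits = 6, row.names = FALSE)
  cat("Best model by AIC:", attr(x, "best"), "\n")
  invisible(x)
}
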