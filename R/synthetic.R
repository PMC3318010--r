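## Forward simulators with the statistical structure the analysis assumes:
## trait-dependent birth-death trees with drift-diffusion traits (the
## generating process of the fitted models), lambda-structured traits on a
## fixed tree (the generating process of the signal stage), and Jukes-Cantor
## DNA alignments of tunable divergence (for the saturation diagnostic).

#' Configuration of a forward birth-death simulation
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param dt Euler time step (Myr); refined automatically whenever any
#'   per-step event probability would exceed `max_step_prob`.
#' @param max_tips stop once this many lineages are simultaneously extant
#'   (the returned tree then has exactly this many tips).
#' @param max_time stop at this time (Myr) if the tip target is not set or
#'   not reached.
#' @param x0 root trait value (ln mm).
#' @param max_step_prob cap on per-step event probabilities (default 0.1).
#' @param max_attempts retries after total extinction before giving up.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, dt = 0.01, max_tips = NULL,
                              max_time = NULL, x0 = 0,
                              max_step_prob = 0.1, max_attempts = 100) {
  if (is.null(max_tips) && is.null(max_time))
    stop("set at least one stop condition (max_tips or max_time)")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(seed = as.integer(seed), dt = dt, max_tips = max_tips,
                 max_time = max_time, x0 = x0,
                 max_step_prob = max_step_prob,
                 max_attempts = as.integer(max_attempts)),
            class = "simulation_config")
}

#' Forward simulation of a trait-dependent birth-death process
#'
#' Euler simulation in forward time: each lineage's trait follows
#' `x <- x + theta * dt + rnorm(1, 0, sqrt(sigma2 * dt))`; it speciates with
#' probability `lambda_S(x) * dt` and goes extinct with probability
#' `mu * dt` per step (step size refined so probabilities stay below the
#' configured cap).  Extinct lineages are pruned; the returned tree is the
#' reconstructed tree of extant tips, ultrametric by construction, together
#' with the tip traits.  Runs that go fully extinct are retried (fresh
#' substream) up to `max_attempts` times.
#'
#' @param params a [quasse_params()].
#' @param cfg a [simulation_config()].
#' @return list with `tree` (`phylo`), `traits` (`trait_table`), `time`
#'   (realized depth, Myr) and `attempts`.
#' @export
simulate_quasse_forward <- function(params, cfg) {
  stopifnot(inherits(params, "quasse_params"),
            inherits(cfg, "simulation_config"))
  for (attempt in seq_len(cfg$max_attempts)) {
    set.seed(cfg$seed + (attempt - 1L) * 10007L)
    sim <- simulate_bd_once(params, cfg)
    if (!is.null(sim)) {
      sim$attempts <- attempt
      return(sim)
    }
  }
  stop("total extinction in all ", cfg$max_attempts,
       " attempts; raise max_attempts or adjust the rates")
}

simulate_bd_once <- function(params, cfg) {
  fn <- params$speciation
  mu <- params$mu; s2 <- params$sigma2; theta <- params$theta
  ## lineage ledger; grown geometrically
  cap <- 256L
  parent <- integer(cap); t_start <- numeric(cap); t_end <- numeric(cap)
  trait <- numeric(cap); alive <- logical(cap); split <- logical(cap)
  nlin <- 1L
  parent[1] <- 0L; t_start[1] <- 0; trait[1] <- cfg$x0; alive[1] <- TRUE
  t <- 0
  target <- if (is.null(cfg$max_tips)) Inf else cfg$max_tips
  t_max <- if (is.null(cfg$max_time)) Inf else cfg$max_time
  repeat {
    idx <- which(alive)
    n_alive <- length(idx)
    if (n_alive == 0L) return(NULL)
    if (n_alive >= target || t >= t_max) break
    ## refine the step so no event probability exceeds the cap
    lam <- speciation_rate(fn, trait[idx])
    pmaxev <- max(lam, mu) * cfg$dt
    k <- max(1L, ceiling(pmaxev / cfg$max_step_prob))
    dt <- cfg$dt / k
    for (sub in seq_len(k)) {
      idx <- which(alive)
      n_alive <- length(idx)
      if (n_alive == 0L) return(NULL)
      if (n_alive >= target || t >= t_max) break
      xs <- trait[idx] + theta * dt + stats::rnorm(n_alive, 0, sqrt(s2 * dt))
      trait[idx] <- xs
      lam <- speciation_rate(fn, xs)
      u <- stats::runif(n_alive)
      sp <- u < lam * dt
      ex <- !sp & (u < lam * dt + mu * dt)
      t <- t + dt
      for (i in idx[ex]) {
        alive[i] <- FALSE; t_end[i] <- t
      }
      for (i in idx[sp]) {
        if (nlin + 2L > cap) {
          cap <- cap * 2L
          length(parent) <- cap; length(t_start) <- cap
          length(t_end) <- cap; length(trait) <- cap
          length(alive) <- cap; length(split) <- cap
          alive[is.na(alive)] <- FALSE
          split[is.na(split)] <- FALSE
        }
        alive[i] <- FALSE; split[i] <- TRUE; t_end[i] <- t
        for (d in 1:2) {
          nlin <- nlin + 1L
          parent[nlin] <- i; t_start[nlin] <- t; t_end[nlin] <- NA
          trait[nlin] <- trait[i]; alive[nlin] <- TRUE; split[nlin] <- FALSE
        }
        if (sum(alive[seq_len(nlin)]) >= target) break
      }
    }
  }
  total_time <- t
  live <- which(alive[seq_len(nlin)])
  t_end[live] <- total_time
  recs <- data.frame(parent = parent[seq_len(nlin)],
                     t_start = t_start[seq_len(nlin)],
                     t_end = t_end[seq_len(nlin)],
                     trait = trait[seq_len(nlin)],
                     extant = alive[seq_len(nlin)],
                     split = split[seq_len(nlin)])
  if (sum(recs$extant) < 2L) return(NULL)
  tree <- lineages_to_phylo(recs)
  keep <- paste0("t", which(recs$extant))
  if (length(keep) < 2L) return(NULL)
  pruned <- ape::keep.tip(tree, keep)
  tipids <- as.integer(sub("^t", "", pruned$tip.label))
  traits_out <- stats::setNames(recs$trait[tipids], pruned$tip.label)
  pruned$tip.label <- paste0("sp", seq_along(pruned$tip.label))
  names(traits_out) <- pruned$tip.label
  list(tree = pruned, traits = trait_table(traits_out), time = total_time)
}

## build an ape phylo from the lineage ledger (tips = non-splitting
## lineages, labelled "t<lineage id>"; includes extinct tips)
lineages_to_phylo <- function(recs) {
  n <- nrow(recs)
  children <- split(seq_len(n), recs$parent[seq_len(n)])
  is_tip <- !recs$split
  tip_ids <- which(is_tip)
  int_ids <- which(!is_tip)
  ntip <- length(tip_ids)
  tipno <- integer(n); tipno[tip_ids] <- seq_len(ntip)
  ## root lineage is id 1 and sorts first among internals, so it becomes
  ## ape's root number ntip + 1 automatically
  intno <- integer(n); intno[int_ids] <- ntip + seq_along(int_ids)
  nodeno <- ifelse(is_tip, tipno, intno)
  edge <- cbind(nodeno[recs$parent[-1]], nodeno[-1])
  len <- (recs$t_end - recs$t_start)[-1]
  tree <- list(edge = edge, edge.length = len,
               tip.label = paste0("t", tip_ids),
               Nnode = length(int_ids))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Drift simulation-and-recovery study
#'
#' The package's standing validation experiment for the drift machinery.
#' Each replicate simulates a 100-tip clade forward in time and fits the
#' constant-rate ("Full") and drift-linear models.  Under the drift
#' generator — `lambda(x) = max(0, -2 + 0.5 x)`, `mu = 0`,
#' `sigma2 = 0.15`, `theta = 0.3`, root state `x0 = 4.7` (about 110 mm) —
#' it reports whether a drift model wins AIC and the drift estimate from a
#' fit of the generating model class (extinction fixed at its generating
#' value: with extinction free, `theta` and `mu` lie on a likelihood ridge
#' and the point estimate is arbitrary along it; see the package vignette).
#' Under the null generator (constant rate 0.5, same diffusion, no drift)
#' it reports the drift-vs-Full chi-square test, whose rejection rate at
#' the 5% level measures the test's type-I behaviour.
#'
#' @param seed integer seed of the replicate (drives both the simulation
#'   and the fits).
#' @param null simulate under the constant-rate null instead of the drift
#'   generator?
#' @param control [fit_quasse()] control list; the defaults here
#'   (`nx = 256`, `tstep = 0.025`, `tip_sd = 0.05`, 3 starts, search bounds
#'   `sigma2_max = 0.45` and `theta_max = 0.5`) keep a replicate at desk
#'   scale.
#' @return one-row data.frame: `seed`, `null`, `theta_rec` (drift estimate,
#'   generating-class fit; `NA` for null replicates), `theta_free` (drift
#'   estimate with extinction free), `dAIC` (drift-linear minus Full),
#'   `chisq`, `p_value`, `n_tips`, `depth`.
#' @export
drift_recovery_replicate <- function(seed, null = FALSE, control = list()) {
  ## study-protocol numerics: 256-point grid with search bounds fixed at
  ## three times the generating diffusion rate and a drift bound of 0.5
  ## ln-mm/Myr, so that every replicate uses the same discretization scale
  ctl <- utils::modifyList(list(nx = 256, tstep = 0.025, tip_sd = 0.05,
                                n_starts = 3, maxit = 100, e_tol = 5e-2,
                                sigma2_max = 0.45, theta_max = 0.5,
                                seed = seed),
                           control)
  gen <- if (null) {
    quasse_params(speciation_function("constant", c = 0.5), mu = 0,
                  sigma2 = 0.15, theta = 0)
  } else {
    quasse_params(speciation_function("linear", a = -2, b = 0.5), mu = 0,
                  sigma2 = 0.15, theta = 0.3)
  }
  sim <- simulate_quasse_forward(
    gen, simulation_config(seed = seed, dt = 0.02, max_tips = 100,
                           x0 = 4.7))
  tab <- fit_battery(sim$tree, sim$traits, c("Full", "Drift Linear"),
                     control = ctl)
  fits <- attr(tab, "fits")
  grid <- attr(fits$Full, "settings")$grid_obj
  full <- fits$Full
  drift <- fits$`Drift Linear`
  ## recovery fit within the generating class (extinction fixed at zero);
  ## because the free-extinction drift model nests it, its solution also
  ## serves as one more start for the free fit whenever it wins
  ctl_rec <- ctl; ctl_rec$n_starts <- 2L
  rec <- fit_quasse(sim$tree, sim$traits, "linear", drift = TRUE,
                    grid = grid, mu_fixed = 0, init = drift$params,
                    control = ctl_rec)
  if (rec$loglik > drift$loglik) {
    ctl1 <- ctl; ctl1$n_starts <- 1L
    drift2 <- fit_quasse(sim$tree, sim$traits, "linear", drift = TRUE,
                         grid = grid, init = rec$params, control = ctl1)
    if (drift2$loglik > drift$loglik) drift <- drift2
  }
  chisq <- 2 * (drift$loglik - full$loglik)
  data.frame(seed = seed, null = null,
             theta_rec = if (null) NA_real_ else rec$theta,
             theta_free = drift$theta,
             dAIC = drift$aic - full$aic, chisq = chisq,
             p_value = stats::pchisq(max(chisq, 0), 2, lower.tail = FALSE),
             n_tips = ape::Ntip(sim$tree),
             depth = assert_ultrametric(sim$tree, 1e-5))
}

#' Simulate tip traits with lambda-structured covariance
#'
#' Draws one realization from the multivariate normal with mean `x0` and
#' covariance `sigma2 * lambda_transform(V, lam)` where `V` is the tree's
#' phylogenetic covariance: Brownian motion for `lam = 1`, independent tips
#' for `lam = 0`.
#'
#' @param tree ultrametric `phylo`.
#' @param sigma2 Brownian rate (ln-mm^2/Myr, >= 0).
#' @param lam Pagel's lambda in `[0, 1]`.
#' @param x0 root (mean) trait value, ln mm.
#' @param seed integer seed.
#' @return a [trait_table()].
#' @export
simulate_traits <- function(tree, sigma2, lam = 1, x0 = 0, seed = 1) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  V <- phylo_covariance(tree)
  W <- sigma2 * lambda_transform(V, lam)
  set.seed(seed)
  if (sigma2 == 0)
    return(trait_table(stats::setNames(rep(x0, nrow(V)), rownames(V))))
  ch <- tryCatch(chol(W + diag(1e-12 * mean(diag(W)), nrow(W))),
                 error = function(e)
                   stop("transformed covariance is not positive definite"))
  y <- x0 + as.numeric(t(ch) %*% stats::rnorm(nrow(W)))
  trait_table(stats::setNames(y, rownames(V)))
}

#' Simulate a DNA alignment under Jukes-Cantor
#'
#' Site-by-site simulation down the tree: the root base is uniform and each
#' branch substitutes with the JC69 transition probability
#' `3/4 (1 - exp(-4/3 rate t))`, choosing uniformly among the other bases.
#'
#' @param tree rooted `phylo` with branch lengths in Myr.
#' @param rate substitution rate (substitutions/site/Myr).
#' @param length number of sites.
#' @param seed integer seed.
#' @return a [dna_alignment()] with the tree's tip labels.
#' @export
simulate_alignment <- function(tree, rate, length, seed = 1) {
  if (length < 1) stop("length must be >= 1")
  if (rate < 0) stop("rate must be >= 0")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nnode, length)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, length, replace = TRUE)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    p_sub <- 0.75 * (1 - exp(-4 / 3 * rate * tr$edge.length[e]))
    s <- seqs[par, ]
    hit <- stats::runif(length) < p_sub
    if (any(hit)) {
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[child, ] <- s
  }
  mat <- matrix(bases[seqs[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(mat) <- tree$tip.label
  dna_alignment(mat)
}
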