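## Pagel's lambda phylogenetic signal under GLS.
##
## The trait vector y is modelled as multivariate normal with mean alpha * 1
## and covariance sigma2 * V_lambda, where V is the matrix of shared
## root-to-tip path lengths and lambda multiplies its off-diagonal elements.
## lambda = 1 is Brownian motion on the tree, lambda = 0 is phylogenetic
## independence.  No directional drift term is fitted here: on an ultrametric
## tree a drift shifts all tip means equally and is confounded with the root
## state; drift is estimated in the birth-death (quasse) stage instead.

#' Phylogenetic variance-covariance matrix
#'
#' `V[i, j]` is the branch length shared by the root-to-tip paths of tips
#' `i` and `j`; the diagonal holds root-to-tip distances.  Under Brownian
#' motion the trait covariance is proportional to this matrix.
#'
#' @param tree a rooted `phylo` with non-negative branch lengths.
#' @return tips x tips numeric matrix with tip labels as dimnames.
#' @examples
#' phylo_covariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal elements by `lam`, leaving the diagonal
#' unchanged.
#'
#' @param V square covariance matrix (see [phylo_covariance()]).
#' @param lam scaling parameter in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) ||
      lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]")
  W <- V * lam
  diag(W) <- diag(V)
  W
}

#' Generalized least squares fit of a single-mean Brownian model
#'
#' Maximum-likelihood estimates of the root state `alpha` and rate `sigma2`
#' for `y ~ MVN(alpha * 1, sigma2 * V)`, by the closed-form GLS estimators,
#' together with the profile maximum log-likelihood.
#'
#' @param traits named numeric vector (or `trait_table`) matching `V`'s tip
#'   labels; if unnamed, taken in `V`'s order.
#' @param V phylogenetic covariance matrix, positive definite.
#' @return list of class `gls_fit`: `alpha`, `sigma2`, `loglik`, `n`.
#' @export
gls_fit <- function(traits, V) {
  y <- if (!is.null(names(traits)) && !is.null(rownames(V))) {
    miss <- setdiff(rownames(V), names(traits))
    if (length(miss)) stop("traits missing for: ", paste(miss, collapse = ", "))
    as.numeric(traits[rownames(V)])
  } else as.numeric(traits)
  n <- length(y)
  if (n != nrow(V)) stop("trait length does not match V")
  ch <- tryCatch(chol(V), error = function(e)
    stop("V is singular or not positive definite; ",
         "increase lambda or the matrix jitter tolerance", call. = FALSE))
  logdetV <- 2 * sum(log(diag(ch)))
  ## solve via the Cholesky factor: z = L^-T y etc.
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  one_Vi_one <- sum(Vi_1)
  alpha <- sum(Vi_y) / one_Vi_one
  r <- y - alpha
  Vi_r <- Vi_y - alpha * Vi_1
  q <- sum(r * Vi_r)
  sigma2 <- max(q / n, .Machine$double.xmin)
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  structure(list(alpha = alpha, sigma2 = sigma2, loglik = loglik, n = n),
            class = "gls_fit")
}

## profile log-likelihood of lambda given tree-derived V (optionally with
## measurement variance added on the diagonal)
lambda_profile_loglik <- function(lam, traits, V, me_var = 0) {
  W <- lambda_transform(V, lam)
  if (any(me_var > 0)) diag(W) <- diag(W) + me_var / mean(diag(V))
  gls_fit(traits, W)$loglik
}

#' Estimate Pagel's lambda for a trait on a tree
#'
#' `mode = "ml"`: profiles the GLS likelihood over lambda in `[0, 1]`,
#' returning the maximizer and a 95% interval by likelihood-ratio inversion
#' (drop of `qchisq(0.95, 1)/2` log-units, truncated to `[0, 1]`).
#'
#' `mode = "mcmc"`: random-walk Metropolis sampling of
#' `(lambda, ln sigma2, alpha)` under a uniform prior on lambda in `[0, 1]`
#' and bounded uniform priors on `ln sigma2` and `alpha`; reports the
#' posterior mean, the 95% HPD interval, and log marginal likelihoods for the
#' observed model and for the models with lambda forced to 0 and 1, by the
#' harmonic-mean estimator (to mirror the "Ln Harmonic mean" reporting
#' convention) or by stepping-stone sampling (`marginal = "stepping-stone"`,
#' recommended when the number itself matters).
#'
#' @param tree ultrametric `phylo`.
#' @param traits `trait_table` or named numeric vector covering all tips.
#' @param mode `"ml"` or `"mcmc"`.
#' @param iterations MCMC iterations (default 1e5).
#' @param burnin fraction of iterations discarded (default 0.1).
#' @param seed integer seed for the MCMC.
#' @param marginal `"harmonic-mean"` or `"stepping-stone"`.
#' @return object of class `phylo_signal` with elements `lambda`, `interval`,
#'   `loglik` (at the estimate), `loglik0`/`loglik1` (lambda forced to 0/1 —
#'   ln marginal likelihoods in mcmc mode), `bf0`, `bf1`, `mode`,
#'   `identifiable`, and in mcmc mode `samples` and `acceptance`.
#' @export
fit_lambda <- function(tree, traits, mode = c("ml", "mcmc"),
                       iterations = 1e5, burnin = 0.1, seed = 1,
                       marginal = c("harmonic-mean", "stepping-stone")) {
  mode <- match.arg(mode)
  marginal <- match.arg(marginal)
  if (ape::Ntip(tree) < 3) stop("at least 3 tips are required")
  al <- align_traits(tree, traits)
  V <- phylo_covariance(tree)
  ## zero-length sister branches make V exactly singular; a relative ridge
  ## of 1e-8 restores positive definiteness without visibly moving lambda
  if (inherits(try(chol(V), silent = TRUE), "try-error"))
    V <- V + diag(1e-8 * mean(diag(V)), nrow(V))
  y <- al$x[rownames(V)]

  prof <- function(l) lambda_profile_loglik(l, y, V)
  ## flat-profile detection: for V proportional to I the likelihood carries no
  ## information about lambda and any maximizer would be spurious
  probe <- vapply(c(0, 0.25, 0.5, 0.75, 1), prof, 0)
  identifiable <- diff(range(probe)) > 1e-8

  if (mode == "ml") {
    if (!identifiable) {
      res <- list(lambda = NA_real_, interval = c(0, 1),
                  loglik = probe[1], loglik0 = probe[1], loglik1 = probe[5],
                  bf0 = 0, bf1 = 0, mode = "ml", identifiable = FALSE)
      class(res) <- "phylo_signal"
      return(res)
    }
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    ## the maximum can sit on a boundary; compare against the endpoints
    cand <- rbind(c(opt$maximum, opt$objective),
                  c(0, probe[1]), c(1, probe[5]))
    best <- cand[which.max(cand[, 2]), ]
    lam_hat <- best[1]; ll_hat <- best[2]
    drop <- stats::qchisq(0.95, 1) / 2
    lo <- if (prof(0) >= ll_hat - drop) 0 else
      stats::uniroot(function(l) prof(l) - (ll_hat - drop),
                     c(0, lam_hat), tol = 1e-6)$root
    hi <- if (prof(1) >= ll_hat - drop) 1 else
      stats::uniroot(function(l) prof(l) - (ll_hat - drop),
                     c(lam_hat, 1), tol = 1e-6)$root
    res <- list(lambda = lam_hat, interval = c(lo, hi), loglik = ll_hat,
                loglik0 = probe[1], loglik1 = probe[5],
                bf0 = bayes_factor(ll_hat, probe[1]),
                bf1 = bayes_factor(ll_hat, probe[5]),
                mode = "ml", identifiable = TRUE)
    class(res) <- "phylo_signal"
    return(res)
  }

  ## ---- MCMC mode -----------------------------------------------------------
  fit1 <- gls_fit(y, V)
  bounds <- list(lsig = log(fit1$sigma2) + c(-8, 8),
                 alpha = mean(y) + c(-1, 1) * 8 * max(stats::sd(y), 1e-3))
  loglik_fun <- function(lam) {
    W <- lambda_transform(V, lam)
    ch <- chol(W)
    logdetW <- 2 * sum(log(diag(ch)))
    Wi <- chol2inv(ch)
    function(par) {  # par = (lsig, alpha)
      s2 <- exp(par[1]); r <- y - par[2]
      -0.5 * (length(y) * log(2 * pi * s2) + logdetW +
                sum(r * (Wi %*% r)) / s2)
    }
  }
  run_chain <- function(lam_free, lam_fixed, seed_off) {
    set.seed(seed + seed_off)
    npar <- if (lam_free) 3L else 2L
    cur <- c(if (lam_free) 0.5, log(fit1$sigma2), fit1$alpha)
    step <- c(if (lam_free) 0.1, 0.4, 0.5 * stats::sd(y))
    llf <- if (lam_free) NULL else loglik_fun(lam_fixed)
    cur_ll <- if (lam_free) loglik_fun(cur[1])(cur[-1]) else llf(cur)
    nit <- as.integer(iterations)
    keep_from <- as.integer(burnin * nit)
    out_ll <- numeric(nit); out_par <- matrix(NA_real_, nit, npar)
    acc <- 0L
    for (it in seq_len(nit)) {
      prop <- cur + stats::rnorm(npar) * step
      lsig_i <- if (lam_free) 2L else 1L
      ok <- !(lam_free && (prop[1] < 0 || prop[1] > 1)) &&
        prop[lsig_i] >= bounds$lsig[1] && prop[lsig_i] <= bounds$lsig[2] &&
        prop[npar] >= bounds$alpha[1] && prop[npar] <= bounds$alpha[2]
      if (ok) {
        prop_ll <- if (lam_free) loglik_fun(prop[1])(prop[-1]) else llf(prop)
        if (is.finite(prop_ll) && log(stats::runif(1)) < prop_ll - cur_ll) {
          cur <- prop; cur_ll <- prop_ll; acc <- acc + 1L
        }
      }
      ## crude adaptation during burn-in toward 20-40% acceptance
      if (it < keep_from && it %% 500L == 0L) {
        rate <- acc / it
        if (rate < 0.2) step <- step * 0.8
        if (rate > 0.4) step <- step * 1.25
      }
      out_ll[it] <- cur_ll; out_par[it, ] <- cur
    }
    keep <- seq.int(keep_from + 1L, nit)
    list(loglik = out_ll[keep], par = out_par[keep, , drop = FALSE],
         acceptance = acc / nit)
  }
  ss_marginal <- function(lam_free, lam_fixed, seed_off, K = 16,
                          nit_per = max(2000, iterations %/% 20)) {
    ## stepping-stone over power posteriors with beta_k = (k/K)^3
    betas <- (0:K / K)^3
    set.seed(seed + seed_off + 1000)
    lnr <- 0
    for (k in seq_len(K)) {
      b0 <- betas[k]; b1 <- betas[k + 1]
      ## short chain targeting prior * lik^b0
      npar <- if (lam_free) 3L else 2L
      cur <- c(if (lam_free) stats::runif(1), log(fit1$sigma2), fit1$alpha)
      step <- c(if (lam_free) 0.2, 0.6, stats::sd(y))
      ll_of <- function(p) {
        if (lam_free) loglik_fun(p[1])(p[-1]) else loglik_fun(lam_fixed)(p)
      }
      cur_ll <- ll_of(cur)
      lls <- numeric(nit_per)
      lsig_i <- if (lam_free) 2L else 1L
      for (it in seq_len(nit_per)) {
        prop <- cur + stats::rnorm(npar) * step
        ok <- !(lam_free && (prop[1] < 0 || prop[1] > 1)) &&
          prop[lsig_i] >= bounds$lsig[1] && prop[lsig_i] <= bounds$lsig[2] &&
          prop[npar] >= bounds$alpha[1] && prop[npar] <= bounds$alpha[2]
        if (ok) {
          pll <- ll_of(prop)
          if (is.finite(pll) && log(stats::runif(1)) < b0 * (pll - cur_ll)) {
            cur <- prop; cur_ll <- pll
          }
        }
        lls[it] <- cur_ll
      }
      lls <- lls[-seq_len(nit_per %/% 5)]
      lnr <- lnr + (logsumexp((b1 - b0) * lls) - log(length(lls)))
    }
    lnr
  }

  chain <- run_chain(TRUE, NA, 0)
  lam_s <- chain$par[, 1]
  if (marginal == "harmonic-mean") {
    lnm_obs <- ln_harmonic_mean(chain$loglik)
    lnm_0 <- ln_harmonic_mean(run_chain(FALSE, 0, 1)$loglik)
    lnm_1 <- ln_harmonic_mean(run_chain(FALSE, 1, 2)$loglik)
  } else {
    lnm_obs <- ss_marginal(TRUE, NA, 0)
    lnm_0 <- ss_marginal(FALSE, 0, 1)
    lnm_1 <- ss_marginal(FALSE, 1, 2)
  }
  res <- list(lambda = mean(lam_s), interval = hpd_interval(lam_s, 0.95),
              loglik = lnm_obs, loglik0 = lnm_0, loglik1 = lnm_1,
              bf0 = bayes_factor(lnm_obs, lnm_0),
              bf1 = bayes_factor(lnm_obs, lnm_1),
              mode = paste0("mcmc-", marginal),
              identifiable = identifiable,
              samples = lam_s, acceptance = chain$acceptance,
              note = if (marginal == "harmonic-mean")
                "harmonic-mean marginal likelihoods are high-variance; see stepping-stone option")
  class(res) <- "phylo_signal"
  res
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Pagel's lambda (", x$mode, " mode)\n", sep = "")
  if (!x$identifiable)
    cat("  WARNING: flat lambda profile - lambda is unidentifiable on this tree\n")
  cat(sprintf("  lambda = %.3f  (95%%: %.3f, %.3f)\n",
              x$lambda, x$interval[1], x$interval[2]))
  cat(sprintf("  ln L(obs) = %.3f   ln L(lambda=0) = %.3f   ln L(lambda=1) = %.3f\n",
              x$loglik, x$loglik0, x$loglik1))
  cat(sprintf("  BF vs lambda=0: %.2f   BF vs lambda=1: %.2f\n", x$bf0, x$bf1))
  invisible(x)
}

#' Bayes factor on the 2 delta-ln scale
#'
#' `BF = 2 * (ln m1 - ln m2)`.  Values >= 3 are conventionally read as
#' positive support for model 1, <= -3 as support for model 2.
#'
#' @param ln_m1,ln_m2 log marginal likelihoods of the two models.
#' @return the Bayes factor (unitless).
#' @examples
#' bayes_factor(7.4, -4.9)  # 24.6
#' @export
bayes_factor <- function(ln_m1, ln_m2) {
  if (!is.finite(ln_m1) || !is.finite(ln_m2))
    stop("log marginal likelihoods must be finite")
  2 * (ln_m1 - ln_m2)
}
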