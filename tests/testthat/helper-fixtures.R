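## Shared fixtures and independent oracles, built in code at test time.

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

caterpillar5 <- function() ape::read.tree(
  text = "((((A:1,B:1):1,C:2):1,D:3):1,E:4);")

## random ultrametric tree rescaled to unit depth
unit_coal_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

## closed-form pure-birth contribution of the engine's traversal:
## lambda per combine event, exp(-lambda * branch) per unit branch length
yule_loglik <- function(tree, lambda) {
  n <- ape::Ntip(tree)
  (n - 1) * log(lambda) - lambda * sum(tree$edge.length)
}

## ln of the Brownian tip-trait density integrated over a flat root state:
## y ~ MVN(alpha 1, sigma2 V + tip_sd^2 I), alpha marginalized uniformly
brownian_flat_root_loglik <- function(tree, traits, sigma2, tip_sd) {
  V <- ape::vcv.phylo(tree)
  y <- as.numeric(traits[rownames(V)])
  n <- length(y)
  S <- sigma2 * V + diag(tip_sd^2, n)
  Si <- solve(S)
  alpha_hat <- sum(Si %*% y) / sum(Si)
  r <- y - alpha_hat
  -0.5 * (n - 1) * log(2 * pi) - 0.5 * as.numeric(determinant(S)$modulus) -
    0.5 * log(sum(Si)) - 0.5 * as.numeric(t(r) %*% Si %*% r)
}

## independent method-of-lines oracle for a 2-tip ultrametric tree:
## central finite differences in x, stiff lsoda integration in time,
## interleaved state (E_i, D_A_i, D_B_i) so the Jacobian is banded
mol_2tip_loglik <- function(t1, xa, xb, fn, mu, s2, theta, tip_sd,
                            lower, upper, nx,
                            root_mode = "obs", condition = TRUE) {
  dx <- (upper - lower) / nx
  x <- lower + (seq_len(nx) - 1) * dx
  lam <- speciation_rate(fn, x)
  iE <- seq(1, 3 * nx, 3); iA <- iE + 1; iB <- iE + 2
  rhs <- function(t, S, parms) {
    E <- S[iE]; DA <- S[iA]; DB <- S[iB]
    lapz <- function(u) (c(0, u[-nx]) - 2 * u + c(u[-1], 0)) / dx^2
    gradz <- function(u) (c(u[-1], 0) - c(0, u[-nx])) / (2 * dx)
    lapn <- function(u) (c(u[1], u[-nx]) - 2 * u + c(u[-1], u[nx])) / dx^2
    gradn <- function(u) (c(u[-1], u[nx]) - c(u[1], u[-nx])) / (2 * dx)
    dE <- mu - (lam + mu) * E + lam * E^2 +
      0.5 * s2 * lapn(E) + theta * gradn(E)
    dDA <- -(lam + mu) * DA + 2 * lam * E * DA +
      0.5 * s2 * lapz(DA) + theta * gradz(DA)
    dDB <- -(lam + mu) * DB + 2 * lam * E * DB +
      0.5 * s2 * lapz(DB) + theta * gradz(DB)
    out <- numeric(3 * nx)
    out[iE] <- dE; out[iA] <- dDA; out[iB] <- dDB
    list(out)
  }
  DA <- stats::dnorm(x, xa, tip_sd); DA <- DA / (sum(DA) * dx)
  DB <- stats::dnorm(x, xb, tip_sd); DB <- DB / (sum(DB) * dx)
  S0 <- numeric(3 * nx); S0[iA] <- DA; S0[iB] <- DB
  sol <- deSolve::ode(S0, c(0, t1), rhs, NULL, method = "lsoda",
                      jactype = "bandint", bandup = 3, banddown = 3,
                      rtol = 1e-9, atol = 1e-11)
  S <- sol[2, -1]
  E <- S[iE]; D <- S[iA] * S[iB] * lam
  tot <- sum(D) * dx
  w <- if (root_mode == "obs") D / tot else rep(1 / (upper - lower), nx)
  lik <- sum(D * w) * dx
  if (condition) lik <- lik / (sum(w * lam * (1 - E)^2) * dx)
  log(lik)
}
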