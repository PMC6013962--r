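# Independent oracles used to validate the fast implementations.

# ESF by explicit subset enumeration: gamma_r = sum over size-r subsets
oracle_esf <- function(eps, r) {
  I <- length(eps)
  if (r == 0) return(1)
  sum(utils::combn(I, r, function(ix) prod(eps[ix])))
}

# conditional probability of a response pattern given its raw score, by
# enumerating every pattern with the same score
oracle_pattern_loglik <- function(y, beta) {
  I <- length(y)
  r <- sum(y)
  pats <- utils::combn(I, r, function(ix) {
    z <- integer(I); z[ix] <- 1L; z
  })
  num <- exp(-sum(y * beta))
  den <- sum(apply(pats, 2L, function(z) exp(-sum(z * beta))))
  log(num / den)
}

# coarse-to-fine grid maximization of the conditional likelihood for
# I = 3 items under the sum-to-zero constraint (two free coordinates)
oracle_grid_rasch3 <- function(data, span = 3, fine_step = 1e-3) {
  eval_ll <- function(b1, b2) conditional_loglik(data, c(b1, b2, -b1 - b2))
  best <- c(0, 0); best_ll <- -Inf
  steps <- c(0.05, fine_step)
  spans <- c(span, 0.1)    # fine pass: small window around the coarse optimum
  for (pass in 1:2) {
    step <- steps[pass]; sp <- spans[pass]
    g1 <- seq(best[1] - sp, best[1] + sp, by = step)
    g2 <- seq(best[2] - sp, best[2] + sp, by = step)
    for (b1 in g1) for (b2 in g2) {
      ll <- eval_ll(b1, b2)
      if (ll > best_ll) { best_ll <- ll; best <- c(b1, b2) }
    }
  }
  c(best, -sum(best))
}

# same, for a two-parameter LLTM on an arbitrary design matrix
oracle_grid_lltm2 <- function(data, W, span = 3, fine_step = 1e-3) {
  eval_ll <- function(a) conditional_loglik(data, as.numeric(W %*% a))
  best <- c(0, 0); best_ll <- -Inf
  steps <- c(0.05, fine_step)
  spans <- c(span, 0.1)
  for (pass in 1:2) {
    step <- steps[pass]; sp <- spans[pass]
    g1 <- seq(best[1] - sp, best[1] + sp, by = step)
    g2 <- seq(best[2] - sp, best[2] + sp, by = step)
    for (a1 in g1) for (a2 in g2) {
      ll <- eval_ll(c(a1, a2))
      if (ll > best_ll) { best_ll <- ll; best <- c(a1, a2) }
    }
  }
  best
}

# brute-force well-conditioning check: every ordered bipartition (S1, S2)
# must contain a person with a 1 on S1 and a 0 on S2
oracle_well_conditioned <- function(Y) {
  keep <- rowSums(Y) > 0L & rowSums(Y) < ncol(Y)
  Y <- Y[keep, , drop = FALSE]
  I <- ncol(Y)
  for (mask in 1:(2^I - 2)) {
    s1 <- which(bitwAnd(mask, bitwShiftL(1L, 0:(I - 1L))) > 0)
    s2 <- setdiff(seq_len(I), s1)
    ok <- FALSE
    for (p in seq_len(nrow(Y))) {
      if (any(Y[p, s1] == 1L) && any(Y[p, s2] == 0L)) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# person-parameter root by bisection of R - sum_i plogis(theta - beta_i)
oracle_bisect_theta <- function(r, beta, lo = -10, hi = 10, tol = 1e-8) {
  f <- function(th) r - sum(plogis(th - beta))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# convenience: simulate a fixed-design response matrix from raw item values
sim_rm <- function(beta, P, seed, dist = list(family = "normal", mean = 0, sd = 1.5)) {
  sc <- simulation_scenario(system = NULL, beta = beta, n_persons = P,
                            person_dist = dist, seed = seed)
  simulate_responses(sc)
}
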