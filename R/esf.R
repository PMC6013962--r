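# Elementary symmetric functions (ESFs) are the normalizing constants of the
# conditional likelihood: gamma_r(eps) = sum over size-r subsets S of
# prod_{i in S} eps_i, with eps_i = exp(-beta_i).  Everything is computed in
# log space with the summation recursion
#   gamma_r^{(1..m)} = gamma_r^{(1..m-1)} + eps_m * gamma_{r-1}^{(1..m-1)},
# which is numerically stable (unlike the difference algorithm) and keeps
# the conditional machinery usable for a few hundred items.

# vectorized log(exp(a) + exp(b)), tolerant of -Inf
.logadd <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log ESFs of orders 0..rmax for log-weights le
.esf_log <- function(le, rmax = length(le)) {
  lg <- c(0, rep(-Inf, rmax))
  if (rmax == 0L) return(lg)
  idx <- seq_len(rmax)
  for (x in le) {
    lg[idx + 1L] <- .logadd(lg[idx + 1L], x + lg[idx])
  }
  lg
}

#' Elementary symmetric functions of the conditional likelihood
#'
#' Computes \eqn{\gamma_r(\epsilon) = \sum_{|S|=r} \prod_{i \in S}
#' \epsilon_i} for positive weights \eqn{\epsilon_i = e^{-\beta_i}}, via the
#' numerically stable summation recursion evaluated in log space, together
#' with the leave-one-out values \eqn{\gamma_{r-1}^{(i)}} (the ESFs of the
#' weights with item \eqn{i} removed) that enter the conditional item
#' probabilities \eqn{P(Y_i = 1 \mid R = r) = \epsilon_i
#' \gamma_{r-1}^{(i)} / \gamma_r}.
#'
#' @param eps Positive numeric vector of item weights.
#' @param r Optional single order, `0 <= r <= length(eps)`.
#' @param log Return log values?
#' @return A list with `gamma` (orders `0..I`, named by order), `loo`
#'   (matrix `I x I`: row `i` holds the ESFs of `eps[-i]` at orders
#'   `0..I-1`), and when `r` is supplied also `gamma_r` and `loo_rm1`
#'   (the \eqn{\gamma_{r-1}^{(i)}} vector; all-zero for `r = 0`).
#' @examples
#' esf_gamma(c(2, 3, 5), r = 2)$gamma_r  # 2*3 + 2*5 + 3*5 = 31
#' @export
esf_gamma <- function(eps, r = NULL, log = FALSE) {
  if (any(!is.finite(eps)) || any(eps <= 0)) {
    stop("all weights must be finite and positive")
  }
  I <- length(eps)
  le <- base::log(eps)
  lg <- .esf_log(le, I)
  lloo <- matrix(-Inf, I, I,
                 dimnames = list(item = seq_len(I), order = 0:(I - 1L)))
  for (i in seq_len(I)) lloo[i, ] <- .esf_log(le[-i], I - 1L)
  names(lg) <- 0:I
  out <- list(gamma = if (log) lg else exp(lg),
              loo = if (log) lloo else exp(lloo))
  if (!is.null(r)) {
    if (length(r) != 1L || is.na(r) || r < 0 || r > I || r != round(r)) {
      stop(sprintf("order r must be a single integer in 0..%d", I))
    }
    out$gamma_r <- if (log) lg[[r + 1L]] else exp(lg[[r + 1L]])
    out$loo_rm1 <- if (r == 0) {
      if (log) rep(-Inf, I) else numeric(I)
    } else {
      if (log) lloo[, r] else exp(lloo[, r])
    }
  }
  out
}

# Conditional-likelihood building blocks for a set of items with values
# `beta` and person raw scores summarized as a count table.
#
#  r_counts   : named integer vector, names = raw score r, values = #persons
#  item_sums  : per-item response totals over those persons (needed for the
#               score vector, not the log-likelihood)
# Returns log-likelihood, score vector (gradient of the conditional
# log-likelihood in beta), and the conditional information matrix
# sum_p Cov(Y_p | R_p) (negative Hessian).
.cml_eval <- function(beta, r_counts, item_sums = NULL,
                      need_score = TRUE, need_info = FALSE) {
  I <- length(beta)
  le <- -beta
  rs <- as.integer(names(r_counts))
  n_r <- as.numeric(r_counts)
  rmax <- max(rs, 1L)
  lg <- .esf_log(le, rmax)

  # loglik = sum_p [ -sum_i y_ip beta_i - log gamma_{r_p} ]
  loglik_tail <- -sum(n_r * lg[rs + 1L])
  out <- list()
  if (!is.null(item_sums)) {
    out$loglik <- -sum(item_sums * beta) + loglik_tail
  }
  if (!need_score && !need_info) return(out)

  lloo <- matrix(NA_real_, I, rmax)  # col r: log gamma^{(i)}_{r-1}... stored by order
  for (i in seq_len(I)) lloo[i, ] <- .esf_log(le[-i], rmax)[seq_len(rmax) + 1L][seq_len(rmax)]
  # lloo[i, q] = log ESF of eps[-i] at order q (q = 1..rmax); order 0 is 0
  loo_ord <- function(i, q) if (q == 0L) 0 else lloo[i, q]

  # conditional item probabilities pi[i, which r]
  pi_mat <- matrix(0, I, length(rs))
  for (ri in seq_along(rs)) {
    r <- rs[ri]
    if (r == 0L) next
    if (r == I) { pi_mat[, ri] <- 1; next }
    q <- r - 1L
    lpq <- if (q == 0L) numeric(I) else lloo[, q]
    pi_mat[, ri] <- exp(le + lpq - lg[r + 1L])
  }
  expected <- as.numeric(pi_mat %*% n_r)
  if (need_score) out$score <- expected - item_sums

  if (need_info) {
    info <- matrix(0, I, I)
    # pairwise P(Y_i = Y_j = 1 | r) = eps_i eps_j gamma^{(ij)}_{r-2} / gamma_r
    for (ri in seq_along(rs)) {
      r <- rs[ri]
      if (r == 0L || r == I) next
      pij <- matrix(0, I, I)
      if (r >= 2L) {
        for (i in seq_len(I - 1L)) {
          le2 <- le[-i]
          for (jj in seq_len(I - i)) {
            j <- i + jj
            lg2 <- .esf_log(le2[-(j - 1L)], r - 1L)
            pij[i, j] <- pij[j, i] <-
              exp(le[i] + le[j] + lg2[r - 1L] - lg[r + 1L])
          }
        }
      }
      p <- pi_mat[, ri]
      cov_r <- pij - tcrossprod(p)
      diag(cov_r) <- p * (1 - p)
      info <- info + n_r[ri] * cov_r
    }
    out$info <- info
  }
  out
}
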