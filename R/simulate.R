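#' Define a simulation scenario for MAPR validation
#'
#' A scenario fixes everything needed to generate preference data under
#' the model: the classification system, the comparator states (or raw
#' item values), the person health-status distribution, the sample size
#' and the seed.  The defaults emulate the kind of study the estimators
#' are built for: 163 patients judging the 17 fixed EQ-5D-3L comparator
#' states used in the package examples, with item values composed from
#' [eq5d3l_weights()] and a right-bounded skewed person distribution
#' (most patients in fair-to-good health near the top of the scale, a
#' long tail of severe states).
#'
#' The person distribution is either `list(family = "normal", mean, sd)`
#' or `list(family = "skewed", location, meanlog, sdlog)`, the latter a
#' negated log-normal: `theta = location - rlnorm(meanlog, sdlog)`.
#'
#' @param system A `mapr_system` (default EQ-5D-3L); `NULL` allowed when
#'   `beta` is supplied directly.
#' @param states Comparator state codes (default: the package's 17-state
#'   EQ-5D-3L example set).
#' @param beta Optional item values; default composed from `alpha`.
#' @param alpha Attribute weights used to compose `beta` from `states`
#'   (default [eq5d3l_weights()]).
#' @param n_persons Number of respondents (default 163).
#' @param person_dist Person distribution spec (default skewed; see
#'   Details).
#' @param seed Master seed; fully determines the output.
#' @param adaptive `NULL` for a fixed design, or
#'   `list(bank = codes, k = count)` to give each person the `k` bank
#'   states with values closest to their own (see
#'   [select_adaptive_comparators()]).
#' @return A list of class `mapr_scenario`.
#' @export
simulation_scenario <- function(system = eq5d3l(),
                                states = eq5d3l_study_states(),
                                beta = NULL,
                                alpha = eq5d3l_weights(),
                                n_persons = 163L,
                                person_dist = list(family = "skewed",
                                                   location = 0,
                                                   meanlog = 1,
                                                   sdlog = 1),
                                seed = 1L,
                                adaptive = NULL) {
  if (is.null(beta)) {
    if (is.null(system)) stop("supply either 'beta' or a system + alpha")
    beta <- beta_from_alpha(states, alpha, system)
  } else {
    nm <- names(beta)
    if (is.null(nm) && length(states) == length(beta)) nm <- states
    if (is.null(nm)) nm <- paste0("I", seq_along(beta))
    beta <- stats::setNames(as.numeric(beta), nm)
  }
  if (any(!is.finite(beta))) stop("item values must be finite")
  n_persons <- as.integer(n_persons)
  if (n_persons < 1L) stop("n_persons must be >= 1")
  if (!person_dist$family %in% c("normal", "skewed")) {
    stop("person_dist$family must be 'normal' or 'skewed'")
  }
  structure(list(system = system, states = states, beta = beta,
                 alpha = alpha, n_persons = n_persons,
                 person_dist = person_dist,
                 seed = as.integer(seed), adaptive = adaptive),
            class = "mapr_scenario")
}

#' The 17 fixed EQ-5D-3L comparator states of the package examples
#'
#' A fixed comparator set spanning the severity continuum from mild
#' (`"11211"`) to worst (`"33333"`), as used in a small empirical
#' valuation study; serves as the default item set of the simulator.
#'
#' @return Character vector of 17 state codes.
#' @export
eq5d3l_study_states <- function() {
  c("11211", "21111", "11121", "11112", "12111", "11311", "11131",
    "11113", "13311", "22222", "32211", "11133", "32313", "33323",
    "23232", "32223", "33333")
}

# per-person substream seed: changing n_persons must not reshuffle the
# draws of earlier persons (kept below 2^31)
.person_seed <- function(master, p) {
  as.integer((as.double(master) * 69091 + as.double(p) * 1013) %% 2147483647)
}

.draw_theta <- function(dist, n) {
  switch(dist$family,
    normal = stats::rnorm(n, dist$mean, dist$sd),
    skewed = dist$location - stats::rlnorm(n, dist$meanlog, dist$sdlog))
}

#' Simulate preference responses under the MAPR model
#'
#' Draws each person's health status from the scenario's distribution and
#' each response independently as
#' \eqn{Y_{ip} \sim Bernoulli(\pi_{ip})} with
#' \eqn{\pi_{ip} = logit^{-1}(\theta_p - \beta_i)} (local independence).
#' Each person uses a seed substream derived from the master seed, so the
#' same person index yields the same draws regardless of `n_persons`.
#' The generating truth is returned alongside the data for recovery
#' studies.  Under an adaptive design different persons see different
#' comparator sets, so the output is a list of per-person response
#' vectors instead of a single rectangular matrix.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list with `data` (a [response_matrix()]), `theta` (true
#'   person parameters), `beta` (true item values), and for adaptive
#'   designs `comparators` (per-person state codes).
#' @export
simulate_responses <- function(scenario) {
  stopifnot(inherits(scenario, "mapr_scenario"))
  beta <- scenario$beta
  P <- scenario$n_persons
  I <- length(beta)

  theta <- numeric(P)
  if (is.null(scenario$adaptive)) {
    Y <- matrix(0L, P, I, dimnames = list(paste0("P", seq_len(P)), names(beta)))
    for (p in seq_len(P)) {
      set.seed(.person_seed(scenario$seed, p))
      theta[p] <- .draw_theta(scenario$person_dist, 1L)
      Y[p, ] <- stats::rbinom(I, 1L, prob_prefer_own(theta[p], beta))
    }
    return(list(data = response_matrix(Y), theta = theta, beta = beta))
  }

  bank <- scenario$adaptive$bank
  k <- scenario$adaptive$k
  bank_values <- beta_from_alpha(bank, scenario$alpha %||% eq5d3l_weights(),
                                 scenario$system)
  comparators <- vector("list", P)
  responses <- vector("list", P)
  for (p in seq_len(P)) {
    set.seed(.person_seed(scenario$seed, p))
    theta[p] <- .draw_theta(scenario$person_dist, 1L)
    sel <- select_adaptive_comparators(theta[p], bank, bank_values, k)
    comparators[[p]] <- sel
    responses[[p]] <- stats::setNames(
      stats::rbinom(k, 1L, prob_prefer_own(theta[p], bank_values[sel])), sel)
  }
  list(responses = responses, comparators = comparators,
       theta = theta, bank_values = bank_values)
}

#' Select individualized comparator states close to a person's own value
#'
#' Implements the adaptive MAPR design: given the person's own latent
#' value (typically \eqn{f(\tilde x_p)} composed from their
#' self-classification), returns the `k` bank states whose values are
#' closest to it, balanced above and below where both sides have enough
#' candidates (comparators near one's own state maximize the Fisher
#' information of the person estimate).  Falls back one-sided when a side
#' runs out.  Ties in distance are broken by bank order.
#'
#' @param own Either a latent value, or a state code (valued through
#'   `values` if named, otherwise an error).
#' @param bank Character vector of candidate state codes; a person's own
#'   state code (if `own` is a code) is excluded from the candidates.
#' @param values Numeric values of the bank states, same length/order.
#' @param k Number of comparators to select, `k <=` usable bank size.
#' @param balance Balance selections above/below the own value where
#'   possible (default `TRUE`); `FALSE` selects purely by distance.
#' @return Character vector of `k` selected bank state codes.
#' @export
select_adaptive_comparators <- function(own, bank, values, k, balance = TRUE) {
  if (length(bank) == 0L) stop("comparator bank is empty")
  if (length(values) != length(bank)) stop("one value per bank state required")
  if (is.character(own)) {
    keep <- bank != own
    own_value <- values[match(own, bank)]
    if (is.na(own_value)) stop("own state code not found in the bank values")
    bank <- bank[keep]; values <- values[keep]
  } else {
    own_value <- as.numeric(own)
  }
  if (k > length(bank)) stop("k exceeds the usable bank size")
  d <- values - own_value
  ord <- order(abs(d))                     # ties: bank order (stable)
  if (!balance) return(bank[ord[seq_len(k)]])
  below <- ord[d[ord] < 0]
  above <- ord[d[ord] >= 0]
  n_below <- min(length(below), k %/% 2L)
  n_above <- min(length(above), k - n_below)
  n_below <- k - n_above                   # one-sided fallback
  sel <- c(below[seq_len(n_below)], above[seq_len(n_above)])
  bank[sel[order(abs(d[sel]))]]
}

#' Convert per-person rankings to a binary preference matrix
#'
#' In a ranking task each respondent orders a card deck of comparator
#' states, their own health-state description and possibly auxiliary cards
#' (e.g. "dead") from best to worst.  The binary response to comparator
#' `i` is 1 iff it is ranked below (worse than) the respondent's own
#' entry.  The own entry and any `drop` entries are excluded from the
#' output columns.
#'
#' @param rankings List of character vectors, one per person, each a
#'   best-to-worst ordering containing `own` exactly once; all persons
#'   must rank the same item set.
#' @param own Label of the own-health entry (default `"own"`).
#' @param drop Labels excluded from the output columns (default
#'   `"dead"`).
#' @return A [response_matrix()].
#' @export
rankings_to_binary <- function(rankings, own = "own", drop = "dead") {
  if (!length(rankings)) stop("no rankings supplied")
  ref <- setdiff(rankings[[1L]], c(own, drop))
  items <- sort(ref)
  P <- length(rankings)
  ids <- names(rankings) %||% paste0("P", seq_len(P))
  Y <- matrix(0L, P, length(items), dimnames = list(ids, items))
  for (p in seq_len(P)) {
    rk <- rankings[[p]]
    if (anyDuplicated(rk)) {
      stop(sprintf("person %s: ranking contains duplicated entries (%s); ties are not supported",
                   ids[p], paste(unique(rk[duplicated(rk)]), collapse = ", ")))
    }
    if (sum(rk == own) != 1L) {
      stop(sprintf("person %s: ranking must contain '%s' exactly once", ids[p], own))
    }
    if (!setequal(setdiff(rk, c(own, drop)), items)) {
      stop(sprintf("person %s: ranking item set differs from the first person's", ids[p]))
    }
    own_pos <- which(rk == own)
    worse <- rk[seq_along(rk) > own_pos]
    Y[p, ] <- as.integer(items %in% worse)
  }
  response_matrix(Y)
}
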