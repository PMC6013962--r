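#' Construct a binary preference response matrix
#'
#' Rows are persons, columns are comparator health states (items).  Entry
#' `Y[p, i] = 1` means person `p` judged their own health to be better than
#' comparator state `i`; `0` means worse.  The per-person raw score
#' `R_p = sum_i Y[p, i]` is the sufficient statistic for the person's own
#' health status, so it is computed and stored on construction.
#'
#' Missing entries are rejected: the conditional-likelihood machinery
#' assumes a complete matrix, and incomplete response designs can bias the
#' estimates unless the missingness mechanism is modelled.
#'
#' @param Y Numeric/integer matrix of 0/1 entries.
#' @param persons Optional person ids (default: rownames or `P1..`).
#' @param items Optional item ids / state codes (default: colnames or `I1..`).
#' @return An object of class `response_matrix` with elements `Y`,
#'   `persons`, `items`, `raw_scores`.
#' @export
response_matrix <- function(Y, persons = NULL, items = NULL) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) {
    stop("response matrix contains missing values; a complete matrix is required")
  }
  if (!all(Y %in% c(0, 1))) stop("response matrix entries must be 0 or 1")
  storage.mode(Y) <- "integer"
  persons <- persons %||% rownames(Y) %||% paste0("P", seq_len(nrow(Y)))
  items <- items %||% colnames(Y) %||% paste0("I", seq_len(ncol(Y)))
  if (length(persons) != nrow(Y)) stop("length(persons) != nrow(Y)")
  if (length(items) != ncol(Y)) stop("length(items) != ncol(Y)")
  if (anyDuplicated(items)) stop("item ids must be unique")
  dimnames(Y) <- list(persons, items)
  structure(
    list(Y = Y, persons = as.character(persons), items = as.character(items),
         raw_scores = stats::setNames(as.integer(rowSums(Y)), persons)),
    class = "response_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Preference response matrix: %d persons x %d comparator states\n",
              nrow(x$Y), ncol(x$Y)))
  ext <- sum(x$raw_scores == 0L | x$raw_scores == ncol(x$Y))
  cat(sprintf("  raw scores %d..%d; %d person(s) with extreme scores\n",
              min(x$raw_scores), max(x$raw_scores), ext))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$Y)

# subset a response matrix, recomputing raw scores
.rm_subset <- function(data, persons = NULL, items = NULL) {
  Y <- data$Y
  if (!is.null(persons)) Y <- Y[persons, , drop = FALSE]
  if (!is.null(items)) Y <- Y[, items, drop = FALSE]
  response_matrix(Y)
}

# short content fingerprint so nested tests can verify both models saw the
# same data (dims, margins, and an order-sensitive checksum)
.rm_fingerprint <- function(data) {
  Y <- data$Y
  w <- matrix(seq_len(length(Y)) %% 97L + 1L, nrow(Y), ncol(Y))
  sprintf("%dx%d/%d/%d", nrow(Y), ncol(Y), sum(Y), sum(Y * w))
}

#' Probability of preferring one's own health
#'
#' Under the Rasch (holistic MAPR) model a person with health status
#' `theta` prefers their own health over a comparator state of value `beta`
#' with probability \eqn{\pi = e^{\theta-\beta} / (1 + e^{\theta-\beta})}.
#' Computed overflow-safely; `+/-Inf` inputs map to the limits 1 and 0.
#'
#' @param theta Person health-status value(s) on the latent scale.
#' @param beta Comparator state value(s).
#' @return Probabilities, recycled to the common length.
#' @seealso [logit_prefer_own()] for the linear predictor
#'   \eqn{\eta = \theta - \beta}.
#' @examples
#' prob_prefer_own(0, 0)        # 0.5: no preference difference
#' prob_prefer_own(log(3), 0)   # 0.75
#' @export
prob_prefer_own <- function(theta, beta) {
  eta <- theta - beta
  p <- stats::plogis(eta)
  # theta = beta = +/-Inf gives eta = NaN; define by the theta limit
  p[is.nan(eta)] <- 0.5
  p
}

#' Logit of the preference probability
#'
#' @inheritParams prob_prefer_own
#' @return The linear predictor \eqn{\eta = \theta - \beta}.
#' @export
logit_prefer_own <- function(theta, beta) theta - beta

#' Conditional log-likelihood of a response matrix
#'
#' The per-person likelihood conditional on the raw score \eqn{R_p = r_p} is
#' \eqn{\exp(-\sum_i y_{ip}\beta_i) / \gamma_{r_p}(\epsilon)} with
#' \eqn{\epsilon_i = e^{-\beta_i}}; it no longer involves the person
#' parameters.  Persons with extreme raw scores (0 or all items) have
#' conditional likelihood 1 and contribute 0.
#'
#' @param data A [response_matrix()].
#' @param beta Item values, one per column of `data`.
#' @return The conditional log-likelihood (a single number, `<= 0`).
#' @export
conditional_loglik <- function(data, beta) {
  stopifnot(inherits(data, "response_matrix"))
  I <- ncol(data$Y)
  if (length(beta) != I) stop("length(beta) must equal the item count")
  keep <- data$raw_scores > 0L & data$raw_scores < I
  if (!any(keep)) return(0)
  Yk <- data$Y[keep, , drop = FALSE]
  r_counts <- table(rowSums(Yk))
  ev <- .cml_eval(beta, r_counts, item_sums = colSums(Yk),
                  need_score = FALSE)
  ev$loglik
}

#' Fit the holistic MAPR (Rasch) model by conditional maximum likelihood
#'
#' Solves the CML estimating equations
#' \eqn{\sum_p y_{ip} = \sum_p P(Y_{ip}=1 \mid R_p = r_p, \beta)} by a
#' damped Newton-Raphson iteration on the sum-to-zero parameterization.
#' Persons with extreme raw scores carry no information about `beta` and
#' are excluded; items every retained person answered identically (constant
#' columns) are dropped with a warning, and the remaining matrix must be
#' well conditioned (see [check_well_conditioned()]) for the estimates to
#' exist and be unique.
#'
#' @param data A [response_matrix()].
#' @param anchor `"sum"` (default): estimates centered to `sum(beta) = 0`;
#'   `"item"`: the item named by `anchor_item` is fixed at 0, which makes
#'   fits on the same data directly comparable to LLTM values anchored at
#'   the perfect-health state.
#' @param anchor_item Item id used when `anchor = "item"`.
#' @param tol Convergence tolerance on the maximum score-equation residual
#'   \eqn{|\sum_p y_{ip} - \sum_p \hat P(Y_{ip}=1|r_p)|}.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `rasch_fit`: `beta`, `se_beta`, `log_cl`,
#'   `items`, `n_persons_used`, `dropped_items`, `iterations`, `converged`,
#'   `anchor`, `vcov`, `data_fingerprint`.
#' @export
fit_rasch_cml <- function(data, anchor = c("sum", "item"), anchor_item = NULL,
                          tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "response_matrix"))
  anchor <- match.arg(anchor)
  fingerprint <- .rm_fingerprint(data)
  prep <- .cml_prepare(data)
  work <- prep$data
  I <- ncol(work$Y)
  if (I < 2L) stop("at least two informative items are required")

  wc <- check_well_conditioned(work)
  if (!wc$well_conditioned) {
    stop(paste0(
      "response matrix is ill-conditioned: no person separates item set {",
      paste(wc$witness$set1, collapse = ", "), "} from {",
      paste(wc$witness$set2, collapse = ", "),
      "}; CML estimates do not exist/are not unique. ",
      "Consider removing the offending items."))
  }

  r_counts <- table(rowSums(work$Y))
  item_sums <- colSums(work$Y)
  K <- rbind(diag(I - 1L), rep(-1, I - 1L))  # sum-to-zero contrasts

  beta <- rep(0, I)
  converged <- FALSE
  iter <- 0L
  ev <- .cml_eval(beta, r_counts, item_sums, need_score = TRUE, need_info = TRUE)
  repeat {
    iter <- iter + 1L
    g <- crossprod(K, ev$score)
    H <- crossprod(K, ev$info %*% K)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, I - 1L), g)
    })
    lam <- 1
    repeat {  # damp until the conditional log-likelihood does not decrease
      beta_new <- beta + as.numeric(K %*% (lam * step))
      beta_new <- beta_new - mean(beta_new)
      ev_new <- .cml_eval(beta_new, r_counts, item_sums,
                          need_score = TRUE, need_info = TRUE)
      if (ev_new$loglik >= ev$loglik - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    moved <- sqrt(sum((beta_new - beta)^2))
    beta <- beta_new
    ev <- ev_new
    if (max(abs(ev$score)) < tol && moved < 1e-10 * max(1, sqrt(sum(beta^2)))) {
      converged <- TRUE
      break
    }
    if (max(abs(ev$score)) < tol && iter > 1L) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop(sprintf(
      "CML Newton-Raphson did not converge in %d iterations (max residual %.3g); last beta: %s",
      max_iter, max(abs(ev$score)), paste(round(beta, 4), collapse = ", ")))
  }

  vc <- K %*% solve(crossprod(K, ev$info %*% K)) %*% t(K)
  if (anchor == "item") {
    if (is.null(anchor_item) || !anchor_item %in% work$items) {
      stop("anchor = \"item\" requires 'anchor_item' naming a retained item")
    }
    a <- match(anchor_item, work$items)
    # var(beta_i - beta_a) under the sum-zero covariance
    vc <- vc + vc[a, a] - outer(vc[, a], rep(1, I)) - outer(rep(1, I), vc[, a])
    beta <- beta - beta[a]
  }
  se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- names(se) <- work$items
  dimnames(vc) <- list(work$items, work$items)

  structure(list(
    beta = beta, se_beta = se, vcov = vc,
    log_cl = ev$loglik,
    items = work$items,
    n_persons_used = nrow(work$Y),
    dropped_items = prep$dropped_items,
    n_extreme_persons = prep$n_extreme,
    iterations = iter, converged = converged,
    anchor = if (anchor == "sum") "sum-to-zero" else paste0("item:", anchor_item),
    data_fingerprint = fingerprint,
    data_used = work
  ), class = "rasch_fit")
}

# Drop extreme-score persons and constant item columns, iterating until
# stable (dropping items can create new extreme scores).
.cml_prepare <- function(data) {
  work <- data
  dropped_items <- character(0)
  n_extreme <- 0L
  repeat {
    I <- ncol(work$Y)
    extreme <- work$raw_scores == 0L | work$raw_scores == I
    if (any(extreme)) {
      n_extreme <- n_extreme + sum(extreme)
      if (all(extreme)) stop("all persons have extreme raw scores; nothing to estimate")
      work <- .rm_subset(work, persons = which(!extreme))
      next
    }
    cs <- colSums(work$Y)
    const <- cs == 0L | cs == nrow(work$Y)
    if (any(const)) {
      dropped_items <- c(dropped_items, work$items[const])
      warning(sprintf(
        "dropping %d constant item column(s) (uninformative for CML): %s",
        sum(const), paste(work$items[const], collapse = ", ")), call. = FALSE)
      work <- .rm_subset(work, items = which(!const))
      next
    }
    break
  }
  list(data = work, dropped_items = dropped_items, n_extreme = n_extreme)
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("Holistic MAPR (Rasch) model, conditional ML\n")
  cat(sprintf("  %d items, %d persons used; conditional logLik = %.3f\n",
              length(x$beta), x$n_persons_used, x$log_cl))
  cat(sprintf("  anchoring: %s; converged in %d iteration(s)\n",
              x$anchor, x$iterations))
  print(round(data.frame(beta = x$beta, se = x$se_beta), 3))
  invisible(x)
}

#' @export
coef.rasch_fit <- function(object, ...) object$beta

#' @export
logLik.rasch_fit <- function(object, ...) {
  structure(object$log_cl, df = length(object$beta) - 1L, class = "logLik")
}

#' Maximum likelihood estimation of person health-status parameters
#'
#' Second estimation step: with the item values `beta` held fixed, the ML
#' estimate of a person's health status solves
#' \eqn{R_p = \sum_i \pi_i(\theta)} in \eqn{\theta}; its asymptotic
#' variance is the reciprocal Fisher information
#' \eqn{1 / \sum_i P_i(\hat\theta)(1-P_i(\hat\theta))}.  Because each
#' information summand \eqn{x(1-x)} is at most 0.25, the standard error can
#' never fall below \eqn{\sqrt{1/(0.25 I)}}: precision is bounded by the
#' number of comparators and is best when comparators sit close to the
#' person's own status.  Extreme raw scores (0 or `I`) have no finite ML
#' estimate and are flagged, with `+/-Inf` as the point value.
#'
#' @param scores Integer raw scores, or a [response_matrix()] (whose raw
#'   scores are used).
#' @param beta Fixed item values.
#' @return A data frame of class `person_fit` with columns `raw_score`,
#'   `theta`, `se_theta`, `extreme`.
#' @export
fit_persons_ml <- function(scores, beta) {
  if (inherits(scores, "response_matrix")) {
    if (!is.null(names(beta)) && all(names(beta) %in% scores$items) &&
        length(beta) < ncol(scores$Y)) {
      # beta from a fit that dropped items: score persons on the retained set
      scores <- .rm_subset(scores, items = match(names(beta), scores$items))
    }
    persons <- scores$persons
    scores <- scores$raw_scores
  } else {
    persons <- names(scores) %||% paste0("P", seq_along(scores))
  }
  I <- length(beta)
  scores <- as.integer(scores)
  if (any(scores < 0L | scores > I)) stop("raw scores must lie in 0..I")

  solve_theta <- function(r) {
    f <- function(th) sum(stats::plogis(th - beta)) - r
    lo <- min(beta) - 35; hi <- max(beta) + 35
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  uniq <- sort(unique(scores))
  th_map <- se_map <- stats::setNames(numeric(length(uniq)), uniq)
  for (r in uniq) {
    key <- as.character(r)
    if (r == 0L) {
      th_map[key] <- -Inf; se_map[key] <- Inf
    } else if (r == I) {
      th_map[key] <- Inf; se_map[key] <- Inf
    } else {
      th <- solve_theta(r)
      p <- stats::plogis(th - beta)
      th_map[key] <- th
      se_map[key] <- 1 / sqrt(sum(p * (1 - p)))
    }
  }
  key <- as.character(scores)
  out <- data.frame(
    person = persons, raw_score = scores,
    theta = unname(th_map[key]), se_theta = unname(se_map[key]),
    extreme = scores == 0L | scores == I,
    stringsAsFactors = FALSE
  )
  class(out) <- c("person_fit", "data.frame")
  out
}
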