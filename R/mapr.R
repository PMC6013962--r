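#' Compose a health-state value from attribute-level weights
#'
#' Under the attribute-parameterized MAPR model the value of a state
#' \eqn{x = (x_1, ..., x_J)} is the sum of the weights of its attribute
#' levels, \eqn{\beta = \sum_j \alpha_{j, x_j}}, with the level-1 weight of
#' every attribute fixed at 0.  The perfect-health state therefore has
#' value 0 exactly, and any state of the classification system can be
#' valued, including states never shown to respondents.
#'
#' @param codes Character vector of state codes.
#' @param alpha Named numeric vector of weights; names as produced by
#'   [build_design_matrix()] (`"attribute:level"`, plus optional
#'   interaction columns).
#' @param system A `mapr_system`.
#' @param interactions Optional interaction specification matching the one
#'   used to fit `alpha`.
#' @return Named numeric vector of state values.
#' @export
beta_from_alpha <- function(codes, alpha, system, interactions = NULL) {
  W <- build_design_matrix(codes, system, interactions = interactions)
  if (!all(colnames(W) %in% names(alpha))) {
    stop("alpha lacks weights for: ",
         paste(setdiff(colnames(W), names(alpha)), collapse = ", "))
  }
  stats::setNames(as.numeric(W %*% alpha[colnames(W)]), codes)
}

#' Illustrative EQ-5D-3L attribute-level weights
#'
#' A set of main-effects weights for the ten non-reference EQ-5D-3L
#' attribute levels on the latent preference scale (perfect health
#' anchored at 0, more negative = worse), estimated from a small empirical
#' patient study with the attribute-parameterized MAPR model.  Used as the
#' package's example weights and as the default truth of the simulator.
#'
#' @return Named numeric vector of 10 weights.
#' @examples
#' beta_from_alpha("21111", eq5d3l_weights(), eq5d3l())  # -0.274
#' @export
eq5d3l_weights <- function() {
  c("mobility:2" = -0.274, "mobility:3" = -2.909,
    "self_care:2" = -1.626, "self_care:3" = -3.554,
    "usual_activities:2" = -0.548, "usual_activities:3" = -1.479,
    "pain_discomfort:2" = -0.752, "pain_discomfort:3" = -3.548,
    "anxiety_depression:2" = -1.527, "anxiety_depression:3" = -3.352)
}

#' Fit the attribute-parameterized MAPR (LLTM) model by conditional ML
#'
#' Maximizes the same conditional likelihood as [fit_rasch_cml()] but with
#' the item values constrained to `beta = W alpha`, where `W` is the dummy
#' design matrix of the comparator states (see [build_design_matrix()]).
#' Gradient and information are chain-ruled through `W`; identification
#' comes from the reference-level constraint `alpha_j1 = 0`, which anchors
#' the scale at the perfect-health state instead of a sum-to-zero
#' constraint.  The number of free weights must be smaller than the number
#' of fitted states for the model to restrict anything; with one free
#' dummy per non-reference item the fit is a pure reparameterization of
#' the Rasch model.
#'
#' @param data A [response_matrix()] whose columns are the states in
#'   `states`.
#' @param states Character vector of state codes, one per item column
#'   (default: the item names of `data`).
#' @param system A `mapr_system`.
#' @param interactions Optional list of attribute-name pairs adding
#'   dummy-product columns.
#' @param design Optional pre-built design matrix overriding the
#'   state-based one (rows must match the items); used for saturated or
#'   custom parameterizations.
#' @param tol,max_iter Newton-Raphson controls as in [fit_rasch_cml()].
#' @return An object of class `lltm_fit`: `alpha`, `se_alpha`, `cov_alpha`,
#'   `log_cl`, `implied_beta`, `items`, `design`, `monotone`,
#'   `data_fingerprint` and convergence metadata.
#' @export
fit_mapr_cml <- function(data, states = NULL, system = NULL,
                         interactions = NULL, design = NULL,
                         tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "response_matrix"))
  fingerprint <- .rm_fingerprint(data)
  states <- states %||% data$items
  if (length(states) != ncol(data$Y)) {
    stop("need one state code per item column")
  }
  prep <- .cml_prepare(data)
  work <- prep$data
  keep_states <- states[match(work$items, data$items)]
  I <- ncol(work$Y)

  if (is.null(design)) {
    if (is.null(system)) stop("either 'system' or 'design' must be supplied")
    W <- build_design_matrix(keep_states, system, interactions = interactions)
  } else {
    W <- as.matrix(design)[match(work$items, data$items), , drop = FALSE]
    rownames(W) <- work$items
  }
  q <- ncol(W)
  qr_W <- qr(W)
  if (qr_W$rank < q) {
    dep <- colnames(W)[qr_W$pivot[(qr_W$rank + 1L):q]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }

  wc <- check_well_conditioned(work)
  if (!wc$well_conditioned) {
    stop(paste0(
      "response matrix is ill-conditioned: no person separates item set {",
      paste(wc$witness$set1, collapse = ", "), "} from {",
      paste(wc$witness$set2, collapse = ", "), "}"))
  }

  r_counts <- table(rowSums(work$Y))
  item_sums <- colSums(work$Y)

  alpha <- rep(0, q)
  ev <- .cml_eval(as.numeric(W %*% alpha), r_counts, item_sums,
                  need_score = TRUE, need_info = TRUE)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    g <- crossprod(W, ev$score)            # gradient in alpha: W' (E[Y|r] - y)
    H <- crossprod(W, ev$info %*% W)       # conditional information in alpha
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, q), g)
    })
    lam <- 1
    repeat {
      alpha_new <- alpha + lam * as.numeric(step)
      ev_new <- .cml_eval(as.numeric(W %*% alpha_new), r_counts, item_sums,
                          need_score = TRUE, need_info = TRUE)
      if (ev_new$loglik >= ev$loglik - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    alpha <- alpha_new
    ev <- ev_new
    if (max(abs(crossprod(W, ev$score))) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop(sprintf(
      "LLTM CML Newton-Raphson did not converge in %d iterations (max gradient %.3g); last alpha: %s",
      max_iter, max(abs(crossprod(W, ev$score))),
      paste(round(alpha, 4), collapse = ", ")))
  }

  cov_alpha <- solve(crossprod(W, ev$info %*% W))
  se_alpha <- sqrt(pmax(diag(cov_alpha), 0))
  names(alpha) <- names(se_alpha) <- colnames(W)
  dimnames(cov_alpha) <- list(colnames(W), colnames(W))
  implied <- stats::setNames(as.numeric(W %*% alpha), work$items)

  structure(list(
    alpha = alpha, se_alpha = se_alpha, cov_alpha = cov_alpha,
    log_cl = ev$loglik,
    implied_beta = implied,
    items = work$items, states = keep_states,
    system = system, interactions = interactions,
    design = W,
    n_persons_used = nrow(work$Y),
    dropped_items = prep$dropped_items,
    n_extreme_persons = prep$n_extreme,
    monotone = if (!is.null(system) && is.null(interactions))
      .check_alpha_monotone(alpha, system) else NA,
    iterations = iter, converged = converged,
    data_fingerprint = fingerprint,
    data_used = work
  ), class = "lltm_fit")
}

# Post-fit check (not a constraint): within each attribute the weights
# should become more negative with increasing severity level.
.check_alpha_monotone <- function(alpha, system) {
  ok <- TRUE
  for (j in seq_len(system$J)) {
    ks <- 2:system$n_levels[j]
    a <- alpha[paste0(system$attributes[j], ":", ks)]
    if (any(diff(c(0, a)) > 0)) ok <- FALSE
  }
  ok
}

#' @export
print.lltm_fit <- function(x, ...) {
  cat("Attribute-parameterized MAPR (LLTM) model, conditional ML\n")
  cat(sprintf("  %d items, %d free weights, %d persons used; conditional logLik = %.3f\n",
              length(x$items), length(x$alpha), x$n_persons_used, x$log_cl))
  if (!is.na(x$monotone)) {
    cat("  within-attribute level ordering of weights:",
        if (x$monotone) "monotone\n" else "NOT monotone (check the fit)\n")
  }
  print(round(data.frame(alpha = x$alpha, se = x$se_alpha), 3))
  invisible(x)
}

#' @export
coef.lltm_fit <- function(object, ...) object$alpha

#' @export
logLik.lltm_fit <- function(object, ...) {
  structure(object$log_cl, df = length(object$alpha), class = "logLik")
}

#' Predict latent values for arbitrary states from an LLTM fit
#'
#' @param object An `lltm_fit`.
#' @param codes State codes to value (default: every state of the system).
#' @param ... Unused.
#' @return Named numeric vector of implied state values.
#' @export
predict.lltm_fit <- function(object, codes = NULL, ...) {
  if (is.null(object$system)) {
    stop("fit was built from a custom design matrix; supply values via beta_from_alpha")
  }
  codes <- codes %||% enumerate_states(object$system)
  beta_from_alpha(codes, object$alpha, object$system,
                  interactions = object$interactions)
}

#' Predict binary preferences from latent values
#'
#' Predicts that a person prefers their own health (`1`) whenever their
#' own value is at least the comparator's value.  At exact equality the
#' model probability is 0.5; a deterministic tie rule is needed for
#' agreement statistics, and predicting "prefer own" is the documented
#' default (configurable).
#'
#' @param own_value The person's own latent value (scalar or one per
#'   comparator), either an estimated `theta` or a composed `f(x)` from
#'   their self-classification.
#' @param comparator_values Latent values of the comparator states on the
#'   same scale.
#' @param tie Prediction at exact equality, `1` (default) or `0`.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_preferences <- function(own_value, comparator_values, tie = 1L) {
  stopifnot(tie %in% c(0L, 1L))
  out <- ifelse(own_value > comparator_values, 1L,
                ifelse(own_value < comparator_values, 0L, as.integer(tie)))
  as.integer(out)
}

#' Cohen's kappa agreement between observed and predicted preferences
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} from the
#' 2x2 table of observed versus predicted binary preferences, with the
#' large-sample standard error and a 95% confidence interval.  Benchmarks:
#' kappa above 0.75 is considered excellent and 0.4-0.75 fair to good.
#'
#' @param observed,predicted Equal-length binary (0/1) vectors.
#' @return A list of class `kappa_agreement`: `kappa`, `se`, `ci` (95%),
#'   `agreement` (proportion observed agreement), `p_e` (chance
#'   agreement), `table`, `label`.
#' @examples
#' kappa_agreement(c(1, 1, 0, 0), c(1, 1, 0, 1))
#' @export
kappa_agreement <- function(observed, predicted) {
  observed <- as.integer(observed); predicted <- as.integer(predicted)
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    stop("observed and predicted must be equal-length, non-empty")
  }
  if (!all(c(observed, predicted) %in% 0:1)) stop("inputs must be binary 0/1")
  n <- length(observed)
  tab <- table(factor(observed, levels = 0:1),
               factor(predicted, levels = 0:1),
               dnn = c("observed", "predicted"))
  p_o <- sum(diag(tab)) / n
  rowm <- rowSums(tab) / n
  colm <- colSums(tab) / n
  p_e <- sum(rowm * colm)
  if (1 - p_e < .Machine$double.eps) {
    out <- list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                agreement = p_o, p_e = p_e, table = tab, n = n,
                label = "undefined (degenerate table, chance agreement = 1)")
    class(out) <- "kappa_agreement"
    return(out)
  }
  kap <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / n) / (1 - p_e)
  ci <- kap + c(-1, 1) * stats::qnorm(0.975) * se
  label <- if (is.na(kap)) "undefined"
    else if (kap > 0.75) "excellent"
    else if (kap >= 0.4) "fair to good"
    else "poor"
  out <- list(kappa = kap, se = se, ci = ci, agreement = p_o, p_e = p_e,
              table = tab, n = n, label = label)
  class(out) <- "kappa_agreement"
  out
}

#' @export
print.kappa_agreement <- function(x, ...) {
  cat(sprintf("Observed agreement: %.1f%% (chance %.1f%%)\n",
              100 * x$agreement, 100 * x$p_e))
  if (is.na(x$kappa)) {
    cat("kappa:", x$label, "\n")
  } else {
    cat(sprintf("Cohen's kappa: %.3f (95%% CI %.3f-%.3f) - %s\n",
                x$kappa, x$ci[1], x$ci[2], x$label))
  }
  invisible(x)
}
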