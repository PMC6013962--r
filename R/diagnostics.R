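#' Andersen's likelihood-ratio test of Rasch-model fit
#'
#' Splits the persons into score groups, fits the Rasch model by CML within
#' each group and on the pooled data, and compares
#' \eqn{2[\sum_g \ell_g(\hat\beta_g) - \ell(\hat\beta_{pooled})]} to a
#' chi-square with \eqn{(G-1)(I-1)} degrees of freedom.  Under a fitting
#' Rasch model the item values are invariant across score groups, so a
#' significant statistic signals misfit (e.g. multidimensionality or
#' item-by-group interaction).
#'
#' Items that are constant within any group are dropped from all groups
#' (with a message listing them), since group-wise CML estimates would not
#' exist for them; severe comparator states that nearly everyone judges
#' worse than their own health typically fall in this category.
#'
#' @param data A [response_matrix()].
#' @param split Grouping rule: `"median"` (default; persons at or below
#'   the median raw score versus above) or `"tertile"`, or supply `groups`.
#' @param groups Optional explicit group labels, one per person (overrides
#'   `split`).
#' @return A list of class `mapr_test`: `statistic`, `df`, `p_value`,
#'   `groups` (sizes), `items_used`, `dropped_items`, `method`.
#' @export
andersen_test <- function(data, split = c("median", "tertile"), groups = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  prep <- .cml_prepare(data)
  work <- prep$data
  dropped <- prep$dropped_items
  I <- ncol(work$Y)
  r <- rowSums(work$Y)

  if (is.null(groups)) {
    split <- match.arg(split)
    groups <- if (split == "median") {
      ifelse(r <= stats::median(r), "low", "high")
    } else {
      cut(r, breaks = stats::quantile(r, c(0, 1/3, 2/3, 1)),
          include.lowest = TRUE, labels = c("low", "mid", "high"))
    }
  } else {
    if (length(groups) != length(data$persons)) {
      stop("'groups' must give one label per person of the input matrix")
    }
    groups <- groups[match(work$persons, data$persons)]
  }
  groups <- as.character(groups)
  glev <- unique(groups)
  G <- length(glev)
  if (G < 2L) stop("grouping rule produced a single group; cannot test")

  # drop items constant within any group, from all groups, iterating since
  # removals change raw scores and can create new constant columns
  repeat {
    bad <- logical(ncol(work$Y))
    for (g in glev) {
      sub <- work$Y[groups == g, , drop = FALSE]
      cs <- colSums(sub)
      bad <- bad | cs == 0L | cs == nrow(sub)
    }
    if (!any(bad)) break
    dropped <- c(dropped, work$items[bad])
    message("Andersen test: dropping item(s) constant within a score group: ",
            paste(work$items[bad], collapse = ", "))
    keep_items <- which(!bad)
    work <- .rm_subset(work, items = keep_items)
    keep_p <- work$raw_scores > 0L & work$raw_scores < ncol(work$Y)
    groups <- groups[keep_p]
    work <- .rm_subset(work, persons = which(keep_p))
    if (ncol(work$Y) < 2L) stop("fewer than 2 items remain after group-wise exclusions")
  }
  I <- ncol(work$Y)

  pooled <- tryCatch(
    suppressWarnings(fit_rasch_cml(work)),
    error = function(e) stop("pooled fit failed: ", conditionMessage(e), call. = FALSE))
  ll_groups <- 0
  sizes <- integer(G); names(sizes) <- glev
  for (g in glev) {
    sub <- .rm_subset(work, persons = which(groups == g))
    sizes[g] <- nrow(sub$Y)
    fit_g <- tryCatch(
      suppressWarnings(fit_rasch_cml(sub)),
      error = function(e) stop(
        sprintf("group '%s' cannot be fitted (%s); consider removing more items",
                g, conditionMessage(e)), call. = FALSE))
    if (!identical(fit_g$items, pooled$items)) {
      stop(sprintf("group '%s' lost items during fitting; remove item(s) %s first",
                   g, paste(setdiff(pooled$items, fit_g$items), collapse = ", ")))
    }
    ll_groups <- ll_groups + fit_g$log_cl
  }

  stat <- max(0, 2 * (ll_groups - pooled$log_cl))
  df <- (G - 1L) * (I - 1L)
  out <- list(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    groups = sizes, items_used = work$items, dropped_items = dropped,
    method = sprintf("Andersen conditional likelihood-ratio test (%d score groups)", G)
  )
  class(out) <- "mapr_test"
  out
}

#' Likelihood-ratio test of the LLTM against the Rasch model
#'
#' The attribute-parameterized MAPR model is nested in the holistic one, so
#' \eqn{2[\ell_{CL}(Rasch) - \ell_{CL}(LLTM)]} is asymptotically chi-square
#' with df = (number of identified Rasch parameters) minus (number of free
#' attribute weights) = \eqn{(I-1) - q}.  A significant result means the
#' dummy-coded attribute levels do not fully capture the differences
#' between the comparator states; a non-significant one supports using the
#' parsimonious attribute model to value states.
#'
#' @param rasch A `rasch_fit`.
#' @param mapr An `lltm_fit` fitted to the identical response matrix and
#'   item set (checked via a data fingerprint).
#' @return A `mapr_test` list (`statistic`, `df`, `p_value`, `models`).
#' @export
lr_test_nested <- function(rasch, mapr) {
  stopifnot(inherits(rasch, "rasch_fit"), inherits(mapr, "lltm_fit"))
  if (!identical(rasch$data_fingerprint, mapr$data_fingerprint)) {
    stop("the two fits were not computed on the same response matrix")
  }
  if (!identical(rasch$items, mapr$items)) {
    stop("the two fits retain different item sets")
  }
  I <- length(rasch$items)
  q <- length(mapr$alpha)
  df <- (I - 1L) - q
  if (df < 0L) stop("LLTM has more free parameters than the Rasch model identifies")
  stat <- max(0, 2 * (rasch$log_cl - mapr$log_cl))
  out <- list(
    statistic = stat, df = df,
    p_value = if (df == 0L) NA_real_ else
      stats::pchisq(stat, df, lower.tail = FALSE),
    models = c(rasch = sprintf("Rasch (%d items, %d identified parameters)", I, I - 1L),
               mapr = sprintf("LLTM (%d attribute weights)", q)),
    method = "likelihood-ratio test of nested conditional likelihoods"
  )
  class(out) <- "mapr_test"
  out
}

#' @export
print.mapr_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  LR statistic = %.3f, df = %d, p = %s\n", x$statistic, x$df,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Check whether a response matrix is well conditioned
#'
#' CML estimates exist and are unique iff the response matrix (after
#' removing extreme-score persons) is well conditioned: in every partition
#' of the items into two non-empty subsets, some person responded 1 to an
#' item of the first subset and 0 to an item of the second.  This is
#' equivalent to strong connectivity of the directed item graph with an
#' edge \eqn{i \to j} whenever some person has \eqn{Y_i = 1, Y_j = 0},
#' which is what is tested.  When ill-conditioned, a violating bipartition
#' is returned as a witness (a sink component of the condensation: no
#' person separates it from the rest in the required direction).
#'
#' @param data A [response_matrix()].
#' @return A list with `well_conditioned` (logical) and `witness`
#'   (`NULL`, or a list with item-id vectors `set1`, `set2` such that no
#'   person has a 1 on `set1` and a 0 on `set2`).
#' @export
check_well_conditioned <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  Y <- data$Y
  keep <- rowSums(Y) > 0L & rowSums(Y) < ncol(Y)
  Y <- Y[keep, , drop = FALSE]
  I <- ncol(Y)
  if (I < 2L) return(list(well_conditioned = I == 1L, witness = NULL))
  # adjacency: edge i -> j iff some person has Y_i = 1 and Y_j = 0
  A <- crossprod(Y, 1L - Y) > 0
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no == 1L) {
    return(list(well_conditioned = TRUE, witness = NULL))
  }
  # find a sink component: no edges leaving it
  memb <- comp$membership
  sink <- NULL
  for (cid in seq_len(comp$no)) {
    inside <- memb == cid
    if (!any(A[inside, !inside, drop = FALSE])) { sink <- cid; break }
  }
  set1 <- data$items[memb == sink]
  list(well_conditioned = FALSE,
       witness = list(set1 = set1, set2 = setdiff(data$items, set1)))
}

#' Guttman scalogram summary of a response matrix
#'
#' Sorts persons by raw score (descending) and items by column total
#' (descending, i.e. the states most often judged worse than one's own
#' health come first) and compares each row against the ideal Guttman
#' staircase for its raw score: a person with score `r` should have 1s on
#' exactly the `r` most-endorsed items.  Cells deviating from that ideal
#' pattern are counted and located as misfits; the count is 0 iff the
#' sorted matrix is a perfect Guttman pattern, the deterministic limit of
#' the Rasch model.  Ties in raw score or column total keep the input
#' order (stable sort).
#'
#' @param data A [response_matrix()].
#' @return A list of class `scalogram`: `sorted` (the reordered matrix),
#'   `person_order`, `item_order`, `misfit_count`, `misfits` (data frame
#'   of row/column coordinates in the sorted matrix).
#' @export
guttman_scalogram <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  Y <- data$Y
  po <- order(-rowSums(Y))        # stable: ties keep input order
  io <- order(-colSums(Y))
  S <- Y[po, io, drop = FALSE]
  r <- rowSums(S)
  I <- ncol(S)
  ideal <- outer(r, seq_len(I), function(rr, ii) as.integer(ii <= rr))
  mis <- which(S != ideal, arr.ind = TRUE)
  out <- list(
    sorted = S,
    person_order = data$persons[po],
    item_order = data$items[io],
    misfit_count = nrow(mis),
    misfits = data.frame(person = data$persons[po][mis[, 1L]],
                         item = data$items[io][mis[, 2L]],
                         row = mis[, 1L], col = mis[, 2L])
  )
  class(out) <- "scalogram"
  out
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("Guttman scalogram: %d x %d sorted matrix, %d misfit cell(s)\n",
              nrow(x$sorted), ncol(x$sorted), x$misfit_count))
  invisible(x)
}

#' Person-item map data
#'
#' Joint display data for the person and item distributions on the common
#' latent scale: a histogram of the estimated person parameters next to
#' the item value locations, plus the fraction of (person, item) pairs
#' with \eqn{\hat\theta_p > \hat\beta_i} (the share of comparator states
#' judged, by the model, as worse than the person's own health).
#'
#' @param rasch A `rasch_fit` (or any named numeric `beta` vector).
#' @param persons A `person_fit` (or numeric `theta` vector); infinite
#'   estimates of extreme scorers are excluded from the histogram but kept
#'   in the pair fraction.
#' @param bins Number of histogram bins.
#' @return A list of class `person_item_map`: `breaks`, `counts`, `beta`,
#'   `theta`, `frac_theta_above_beta`.
#' @export
person_item_map <- function(rasch, persons, bins = 15L) {
  beta <- if (inherits(rasch, "rasch_fit")) rasch$beta else rasch
  theta <- if (inherits(persons, "person_fit")) persons$theta else persons
  finite_th <- theta[is.finite(theta)]
  rng <- range(c(finite_th, beta))
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h <- graphics::hist(pmin(pmax(finite_th, rng[1L]), rng[2L]),
                      breaks = breaks, plot = FALSE)
  frac <- mean(outer(theta, beta, ">"))
  out <- list(breaks = h$breaks, counts = h$counts, beta = beta,
              theta = theta, frac_theta_above_beta = frac)
  class(out) <- "person_item_map"
  out
}

#' @export
print.person_item_map <- function(x, ...) {
  cat(sprintf(
    "Person-item map: %d persons, %d items; %.1f%% of (person, item) pairs have theta > beta\n",
    length(x$theta), length(x$beta), 100 * x$frac_theta_above_beta))
  invisible(x)
}

#' Reduce a response matrix to a well-conditioned item subset
#'
#' Iteratively removes the witness item set returned by
#' [check_well_conditioned()] (re-removing persons whose scores become
#' extreme) until the remaining matrix is well conditioned, mirroring the
#' practical workflow of deleting comparator states that are too uniformly
#' judged for their values to be estimable.  The iteration always
#' terminates: every step removes at least one item.
#'
#' @param data A [response_matrix()].
#' @param prefer_drop `"smaller"` (default) drops the smaller side of the
#'   witness bipartition; `"set1"` always drops the witness `set1`.
#' @return A list with `data` (the reduced [response_matrix()]) and
#'   `dropped_items` (character, possibly empty).
#' @export
make_well_conditioned <- function(data, prefer_drop = c("smaller", "set1")) {
  stopifnot(inherits(data, "response_matrix"))
  prefer_drop <- match.arg(prefer_drop)
  dropped <- character(0)
  work <- data
  repeat {
    prep <- suppressWarnings(.cml_prepare(work))
    dropped <- c(dropped, prep$dropped_items)
    work <- prep$data
    wc <- check_well_conditioned(work)
    if (wc$well_conditioned) break
    drop_set <- if (prefer_drop == "set1" ||
                    length(wc$witness$set1) <= length(wc$witness$set2)) {
      wc$witness$set1
    } else wc$witness$set2
    if (length(drop_set) >= ncol(work$Y)) {
      stop("cannot reach a well-conditioned submatrix with >= 2 items")
    }
    dropped <- c(dropped, drop_set)
    work <- .rm_subset(work, items = which(!work$items %in% drop_set))
  }
  list(data = work, dropped_items = dropped)
}
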