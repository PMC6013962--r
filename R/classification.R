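#' Define a multi-attribute health-state classification system
#'
#' A classification system describes health states by `J` ordered attributes
#' (e.g. mobility, self-care), each with `n_j >= 2` severity levels.  Level 1
#' is always the best level; level `n_j` the worst.  The state with all
#' attributes at level 1 represents perfect health and anchors the latent
#' scale of the attribute-parameterized (LLTM) model at 0.
#'
#' @param attributes Either a named integer vector of level counts
#'   (names are attribute names), or a data frame with columns `name` and
#'   `levels`.
#' @return An object of class `mapr_system` with elements `attributes`
#'   (character), `n_levels` (integer), `J` and `n_states`.
#' @examples
#' sys <- classification_system(c(mobility = 3, pain = 3))
#' sys$n_states  # 9
#' @export
classification_system <- function(attributes) {
  if (is.data.frame(attributes)) {
    nm <- as.character(attributes$name)
    nl <- as.integer(attributes$levels)
  } else {
    nm <- names(attributes)
    nl <- as.integer(attributes)
  }
  if (length(nl) < 1L) stop("a classification system needs at least one attribute")
  if (is.null(nm) || any(!nzchar(nm))) stop("every attribute must be named")
  if (anyDuplicated(nm)) stop("attribute names must be unique")
  if (any(is.na(nl)) || any(nl < 2L)) stop("every attribute needs at least 2 levels")
  structure(
    list(attributes = nm, n_levels = nl, J = length(nl),
         n_states = prod(as.double(nl))),
    class = "mapr_system"
  )
}

#' @export
print.mapr_system <- function(x, ...) {
  cat("Multi-attribute classification system:", x$J, "attributes,",
      format(x$n_states, big.mark = ","), "states\n")
  for (j in seq_len(x$J)) {
    cat(sprintf("  %-20s %d levels\n", x$attributes[j], x$n_levels[j]))
  }
  invisible(x)
}

#' The EQ-5D-3L classification system
#'
#' Five attributes (mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression), three levels each; 3^5 = 243 describable states.
#' Digit strings such as `"33221"` are read in this attribute order.
#'
#' @return A `mapr_system` object.
#' @export
eq5d3l <- function() {
  classification_system(c(
    mobility = 3L, self_care = 3L, usual_activities = 3L,
    pain_discomfort = 3L, anxiety_depression = 3L
  ))
}

# A code uses one digit per attribute when all n_j <= 9, otherwise
# dash-delimited integers ("3-2-2-1-1").
.uses_digit_codes <- function(system) all(system$n_levels <= 9L)

#' Parse a health-state code
#'
#' @param code A state code: one digit per attribute (e.g. `"33221"`) when
#'   all attributes have at most 9 levels, otherwise dash-delimited
#'   (e.g. `"3-2-2-1-1"`).
#' @param system A `mapr_system`.
#' @return Integer vector of levels, one per attribute, named by attribute.
#' @examples
#' parse_state("33221", eq5d3l())
#' @export
parse_state <- function(code, system) {
  stopifnot(inherits(system, "mapr_system"))
  code <- as.character(code)
  if (length(code) != 1L || is.na(code)) stop("'code' must be a single string")
  if (.uses_digit_codes(system) && !grepl("-", code, fixed = TRUE)) {
    if (nchar(code) != system$J) {
      stop(sprintf("code '%s' has %d digits; system has %d attributes",
                   code, nchar(code), system$J))
    }
    parts <- strsplit(code, "", fixed = TRUE)[[1L]]
  } else {
    parts <- strsplit(code, "-", fixed = TRUE)[[1L]]
    if (length(parts) != system$J) {
      stop(sprintf("code '%s' has %d fields; system has %d attributes",
                   code, length(parts), system$J))
    }
  }
  if (!all(grepl("^[0-9]+$", parts))) {
    stop(sprintf("code '%s' contains non-numeric level fields", code))
  }
  lev <- as.integer(parts)
  bad <- which(lev < 1L | lev > system$n_levels)
  if (length(bad)) {
    stop(sprintf(
      "level %d is out of range 1..%d for attribute '%s' in code '%s'",
      lev[bad[1L]], system$n_levels[bad[1L]], system$attributes[bad[1L]], code))
  }
  stats::setNames(lev, system$attributes)
}

#' Encode attribute levels as a state code
#'
#' Inverse of [parse_state()]: `parse_state(state_code(x, sys), sys)`
#' returns `x`.
#'
#' @param levels Integer vector of levels, one per attribute.
#' @param system A `mapr_system`.
#' @return A single state code string.
#' @export
state_code <- function(levels, system) {
  stopifnot(inherits(system, "mapr_system"))
  levels <- as.integer(levels)
  if (length(levels) != system$J) {
    stop(sprintf("expected %d levels, got %d", system$J, length(levels)))
  }
  bad <- which(levels < 1L | levels > system$n_levels)
  if (length(bad)) {
    stop(sprintf("level %d out of range for attribute '%s'",
                 levels[bad[1L]], system$attributes[bad[1L]]))
  }
  sep <- if (.uses_digit_codes(system)) "" else "-"
  paste(levels, collapse = sep)
}

#' Level matrix for a vector of state codes
#'
#' @param codes Character vector of state codes.
#' @param system A `mapr_system`.
#' @return Integer matrix (states x attributes), rownames = codes.
#' @export
state_matrix <- function(codes, system) {
  m <- t(vapply(codes, parse_state, integer(system$J), system = system))
  dimnames(m) <- list(codes, system$attributes)
  m
}

#' Enumerate every state of a classification system
#'
#' States are returned in lexicographic order of their codes, perfect health
#' (`"11...1"`) first; the count equals the product of the level counts
#' (243 for EQ-5D-3L).
#'
#' @param system A `mapr_system`.
#' @return Character vector of state codes.
#' @export
enumerate_states <- function(system) {
  stopifnot(inherits(system, "mapr_system"))
  if (system$n_states > 1e6) {
    stop("system describes more than 1e6 states; enumeration refused")
  }
  grids <- lapply(system$n_levels, seq_len)
  # expand.grid varies the first factor fastest; reverse twice so the LAST
  # attribute varies fastest, giving lexicographic code order
  g <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[, rev(seq_len(system$J)), drop = FALSE])
  apply(g, 1L, state_code, system = system)
}

#' Dummy design matrix mapping states to attribute-level weights
#'
#' Builds the indicator matrix whose row for state `x` has a 1 in column
#' `(j, k)` iff attribute `j` of `x` is at level `k`, for the non-reference
#' levels `k = 2..n_j` only.  Level 1 of every attribute is the reference
#' and carries no column, implementing the identification constraint
#' `alpha_j1 = 0`; there is no intercept, so the perfect-health state maps
#' to the zero row and has implied value 0.
#'
#' @param codes Character vector of state codes (rows of the matrix).
#' @param system A `mapr_system`.
#' @param interactions Optional list of attribute-name pairs; each pair adds
#'   product columns of the two attributes' non-reference dummies.
#' @return Numeric matrix (states x free parameters) with columns named
#'   `"attribute:level"` (and `"a:k x b:l"` for interactions).
#' @export
build_design_matrix <- function(codes, system, interactions = NULL) {
  stopifnot(inherits(system, "mapr_system"))
  X <- state_matrix(codes, system)
  cols <- list()
  for (j in seq_len(system$J)) {
    for (k in 2:system$n_levels[j]) {
      cols[[paste0(system$attributes[j], ":", k)]] <- as.numeric(X[, j] == k)
    }
  }
  if (!is.null(interactions)) {
    for (pair in interactions) {
      if (length(pair) != 2L || !all(pair %in% system$attributes)) {
        stop("each interaction must name two attributes of the system")
      }
      ja <- match(pair[1L], system$attributes)
      jb <- match(pair[2L], system$attributes)
      for (ka in 2:system$n_levels[ja]) {
        for (kb in 2:system$n_levels[jb]) {
          nmcol <- paste0(pair[1L], ":", ka, " x ", pair[2L], ":", kb)
          cols[[nmcol]] <- as.numeric(X[, ja] == ka & X[, jb] == kb)
        }
      }
    }
  }
  W <- do.call(cbind, cols)
  rownames(W) <- codes
  W
}

#' Read a classification system from a YAML config file
#'
#' The file holds an ordered `attributes` list, each entry with `name`,
#' `levels` and optional `labels`.
#'
#' @param path Path to a YAML file.
#' @return A `mapr_system`.
#' @export
read_system_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$attributes)) stop("config lacks an 'attributes' list")
  nm <- vapply(cfg$attributes, function(a) as.character(a$name), character(1))
  nl <- vapply(cfg$attributes, function(a) as.integer(a$levels), integer(1))
  classification_system(stats::setNames(nl, nm))
}

#' Write a classification system to a YAML config file
#'
#' @param system A `mapr_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system_config <- function(system, path) {
  stopifnot(inherits(system, "mapr_system"))
  yaml::write_yaml(list(attributes = lapply(seq_len(system$J), function(j) {
    list(name = system$attributes[j], levels = system$n_levels[j])
  })), path)
  invisible(path)
}
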