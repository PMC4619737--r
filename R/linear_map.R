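#' Matrix-free linear operator
#'
#' A linear map is a pair of functions (forward and adjoint) together with its
#' dimensions; no matrix is ever stored. The adjoint must be the exact
#' transpose of the forward map, which [dot_product_test()] verifies on random
#' probes and [materialize()] verifies densely.
#'
#' @param n_rows Number of rows `m`.
#' @param n_cols Number of columns `n`.
#' @param forward Function mapping a length-`n` vector to a length-`m` vector.
#' @param adjoint Function mapping a length-`m` vector to a length-`n` vector.
#' @param label Short text label used in printing and error messages.
#' @return Object of class `linear_map`.
#' @export
linear_map <- function(n_rows, n_cols, forward, adjoint, label = "linear_map") {
  if (n_rows < 0 || n_cols < 0) abort_config("operator dimensions must be non-negative")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 forward = forward, adjoint = adjoint, label = label),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat("<linear_map> ", x$label, ": ", x$n_rows, " x ", x$n_cols, "\n", sep = "")
  invisible(x)
}

#' Apply a linear map (forward)
#' @param map A [linear_map()].
#' @param x Vector of length `map$n_cols`.
#' @return Vector of length `map$n_rows`.
#' @export
map_apply <- function(map, x) {
  if (length(x) != map$n_cols)
    abort_dim(map$label, ": forward input length ", length(x),
              " != n_cols ", map$n_cols)
  y <- map$forward(as.numeric(x))
  if (length(y) != map$n_rows)
    abort_dim(map$label, ": forward returned wrong length")
  y
}

#' Apply the adjoint of a linear map
#' @param map A [linear_map()].
#' @param y Vector of length `map$n_rows`.
#' @return Vector of length `map$n_cols`.
#' @export
map_adjoint <- function(map, y) {
  if (length(y) != map$n_rows)
    abort_dim(map$label, ": adjoint input length ", length(y),
              " != n_rows ", map$n_rows)
  x <- map$adjoint(as.numeric(y))
  if (length(x) != map$n_cols)
    abort_dim(map$label, ": adjoint returned wrong length")
  x
}

#' Compose two linear maps
#'
#' Returns the map `outer %*% inner` (apply `inner` first). The adjoint is the
#' reversed composition of the adjoints.
#'
#' @param outer,inner [linear_map()] objects with `outer$n_cols == inner$n_rows`.
#' @return A `linear_map`.
#' @export
compose_maps <- function(outer, inner) {
  if (outer$n_cols != inner$n_rows)
    abort_dim("cannot compose ", outer$label, " (", outer$n_cols, " cols) with ",
              inner$label, " (", inner$n_rows, " rows)")
  linear_map(outer$n_rows, inner$n_cols,
             forward = function(x) outer$forward(inner$forward(x)),
             adjoint = function(y) inner$adjoint(outer$adjoint(y)),
             label = paste0(outer$label, "%*%", inner$label))
}

#' Identity map
#' @param n Dimension.
#' @return A `linear_map` representing the n x n identity.
#' @export
identity_map <- function(n) {
  linear_map(n, n, forward = function(x) x, adjoint = function(y) y, label = "I")
}

#' Materialize a matrix-free operator as a dense matrix
#'
#' Applies the forward map to each standard basis vector (operating on the
#' identity), returning the operator in its finite dense form. Unless
#' `check_adjoint = FALSE`, the adjoint is materialized the same way and
#' verified to equal the transpose to `tol` (relative to the largest entry).
#'
#' @param map A [linear_map()].
#' @param max_entries Refuse to materialize operators with more than this many
#'   entries (guards against accidentally densifying scanner-scale problems).
#' @param check_adjoint Verify adjoint == transpose densely.
#' @param tol Tolerance for the adjoint check.
#' @return Dense `n_rows x n_cols` matrix.
#' @export
materialize <- function(map, max_entries = 5e7, check_adjoint = TRUE, tol = 1e-12) {
  ne <- as.numeric(map$n_rows) * as.numeric(map$n_cols)
  if (ne > max_entries)
    abort_size(map$label, ": ", format(ne), " entries exceeds dense guard ",
               format(max_entries))
  n <- map$n_cols
  m <- map$n_rows
  A <- matrix(0, m, n)
  e <- numeric(n)
  for (j in seq_len(n)) {
    e[j] <- 1
    A[, j] <- map$forward(e)
    e[j] <- 0
  }
  if (check_adjoint && m > 0L && n > 0L) {
    At <- matrix(0, n, m)
    f <- numeric(m)
    for (i in seq_len(m)) {
      f[i] <- 1
      At[, i] <- map$adjoint(f)
      f[i] <- 0
    }
    scale <- max(abs(A), 1e-300)
    if (max(abs(t(A) - At)) > tol * scale)
      abort_numeric(map$label, ": materialized adjoint does not equal transpose")
  }
  A
}

#' Dot-product (adjoint consistency) test
#'
#' Draws seeded standard-normal probes `x`, `y` and returns the maximum over
#' trials of `|<Ax, y> - <x, A'y>| / (||Ax|| ||y|| + tiny)`. A correct
#' forward/adjoint pair scores at numerical roundoff (<= 1e-10); a wrong
#' adjoint scores orders of magnitude higher.
#'
#' @param map A [linear_map()].
#' @param n_trials Number of random probe pairs.
#' @param seed Integer seed (deterministic result).
#' @return Maximum relative discrepancy over trials.
#' @export
dot_product_test <- function(map, n_trials = 100, seed = 1L) {
  if (n_trials < 1) abort_config("n_trials must be >= 1")
  set.seed(seed)
  worst <- 0
  for (k in seq_len(n_trials)) {
    x <- stats::rnorm(map$n_cols)
    y <- stats::rnorm(map$n_rows)
    Ax <- map$forward(x)
    Aty <- map$adjoint(y)
    num <- abs(sum(Ax * y) - sum(x * Aty))
    den <- sqrt(sum(Ax^2)) * sqrt(sum(y^2)) + .Machine$double.xmin
    worst <- max(worst, num / den)
  }
  worst
}
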