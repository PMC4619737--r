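#' Segmentation operator S
#'
#' Breaks an image into `N` overlapping pFOV blocks: pFOV `k` (0-based) copies
#' the drive-axis window `[k*shift, k*shift + p)` of every transverse line.
#' The adjoint sums block contributions back into the image, so `S'S` is
#' diagonal with the per-pixel coverage counts on its diagonal.
#'
#' @param geometry A [scan_geometry()].
#' @return A [linear_map()] of size `(N*p*n_transverse) x n_image`.
#' @export
make_segmentation <- function(geometry) {
  g <- geometry
  L <- g$image_shape[g$drive_axis]
  p <- g$pfov_width; d <- g$shift; N <- g$n_pfov; Tn <- g$n_transverse
  starts <- (seq_len(N) - 1L) * d          # 0-based window starts
  linear_map(
    n_rows = g$n_data, n_cols = g$n_image,
    forward = function(x) {
      M <- matrix(x, L, Tn)
      out <- array(0, c(p, Tn, N))
      for (k in seq_len(N)) out[, , k] <- M[starts[k] + seq_len(p), , drop = FALSE]
      as.numeric(out)
    },
    adjoint = function(y) {
      B <- array(y, c(p, Tn, N))
      M <- matrix(0, L, Tn)
      for (k in seq_len(N)) {
        idx <- starts[k] + seq_len(p)
        M[idx, ] <- M[idx, , drop = FALSE] + B[, , k]
      }
      as.numeric(M)
    },
    label = "S")
}

#' DC-removal operator D
#'
#' Subtracts from every drive-axis line of every pFOV block that line's mean
#' (equivalent to zeroing the zero-frequency bin in the spatial Fourier
#' domain). Block-diagonal in the per-line centering matrix
#' `R = I_p - (1/p) * ones(p, p)`, which is symmetric and idempotent, so the
#' adjoint equals the forward map.
#'
#' @param geometry A [scan_geometry()].
#' @return A self-adjoint [linear_map()] of size `m x m`.
#' @export
make_dc_removal <- function(geometry) {
  g <- geometry
  p <- g$pfov_width
  nlines <- g$n_transverse * g$n_pfov
  center <- function(y) {
    M <- matrix(y, p, nlines)
    as.numeric(M - rep(colMeans(M), each = p))
  }
  linear_map(g$n_data, g$n_data, forward = center, adjoint = center, label = "D")
}

#' Forward model A = D S
#'
#' Composition of segmentation and DC removal: maps an image vector to the
#' mean-free pFOV data the scanner delivers. Constant images are in the
#' nullspace (the global DC value is unobservable).
#'
#' @param geometry A [scan_geometry()].
#' @return A [linear_map()] of size `m x n_image`, labelled `"A"`.
#' @export
make_forward <- function(geometry) {
  A <- compose_maps(make_dc_removal(geometry), make_segmentation(geometry))
  A$label <- "A"
  A
}

# forward difference along `axis` with replicate (Neumann) boundary: the last
# difference along the axis is zero, so constants map to zero exactly.
axis_indices <- function(dd) lapply(dd, seq_len)

#' Spatial gradient operator along one axis
#'
#' Forward finite differences with a replicate (Neumann) boundary: entry `i`
#' is `x[i+1] - x[i]` and the last difference along the axis is 0. The adjoint
#' is the exact transpose (a negative divergence with matching boundary).
#' Used for the smoothness penalties `beta_i ||grad_i rho||^2`.
#'
#' @param axis Axis index into `image_shape`.
#' @param image_shape Integer image extents.
#' @param drive_axis Drive axis defining the vectorization order (default 1).
#' @return A square [linear_map()] on image vectors.
#' @export
make_gradient <- function(axis, image_shape, drive_axis = 1L) {
  image_shape <- as.integer(image_shape)
  nd <- length(image_shape)
  if (axis < 1L || axis > nd) abort_config("gradient axis ", axis, " out of range")
  n <- prod(image_shape)
  # dummy geometry just to reuse the vectorization helpers (single pFOV)
  geom <- scan_geometry(image_shape, pfov_width = image_shape[drive_axis],
                        n_pfov = 1L, shift = image_shape[drive_axis],
                        drive_axis = drive_axis)
  La <- image_shape[axis]
  fwd_arr <- function(arr) {
    if (nd == 1L) {
      g <- c(diff(arr), 0)
      return(g)
    }
    dd <- dim(arr)
    g <- array(0, dd)
    if (La > 1L) {
      ip <- axis_indices(dd); ip[[axis]] <- 2:La
      ic <- axis_indices(dd); ic[[axis]] <- 1:(La - 1L)
      part <- do.call(`[`, c(list(arr), ip, list(drop = FALSE))) -
              do.call(`[`, c(list(arr), ic, list(drop = FALSE)))
      g <- do.call(`[<-`, c(list(g), ic, list(value = part)))
    }
    g
  }
  adj_arr <- function(yarr) {
    if (nd == 1L) {
      z <- numeric(La)
      if (La > 1L) {
        yc <- yarr[1:(La - 1L)]
        z[1:(La - 1L)] <- z[1:(La - 1L)] - yc
        z[2:La] <- z[2:La] + yc
      }
      return(z)
    }
    dd <- dim(yarr)
    z <- array(0, dd)
    if (La > 1L) {
      ip <- axis_indices(dd); ip[[axis]] <- 2:La
      ic <- axis_indices(dd); ic[[axis]] <- 1:(La - 1L)
      yc <- do.call(`[`, c(list(yarr), ic, list(drop = FALSE)))
      zc <- do.call(`[`, c(list(z), ic, list(drop = FALSE))) - yc
      z <- do.call(`[<-`, c(list(z), ic, list(value = zc)))
      zp <- do.call(`[`, c(list(z), ip, list(drop = FALSE))) + yc
      z <- do.call(`[<-`, c(list(z), ip, list(value = zp)))
    }
    z
  }
  linear_map(n, n,
    forward = function(x) as_image_vector(fwd_arr(as_image_array(x, geom)), geom),
    adjoint = function(y) as_image_vector(adj_arr(as_image_array(y, geom)), geom),
    label = paste0("grad", axis))
}

#' Stack the data, Tikhonov and smoothness operators
#'
#' Builds the stacked least-squares system whose residual norm equals the
#' regularized objective exactly:
#' `||T rho - w||^2 = ||A rho - b||^2 + alpha ||rho||^2 + sum_i beta_i ||grad_i rho||^2`.
#' The Tikhonov and gradient rows are scaled by `sqrt(alpha)` and
#' `sqrt(beta_i)` so that `alpha`, `beta` are reported in objective units.
#' Rows with zero weight are omitted, so with `alpha = beta = 0` the stacked
#' operator is `A` itself and `w = b`.
#'
#' @param A The forward [linear_map()] (typically [make_forward()]).
#' @param alpha Tikhonov weight (>= 0).
#' @param beta Smoothness weight(s), a scalar or one value per image axis.
#' @param b Data vector of length `A$n_rows`.
#' @param geometry The [scan_geometry()] (defines image shape and layout for
#'   the gradient rows).
#' @return Object of class `stacked_system` with elements `T` (the stacked
#'   [linear_map()]), `w`, `alpha`, `beta`, `A`, `b`, `geometry`.
#' @export
stack_operators <- function(A, alpha, beta, b, geometry) {
  if (alpha < 0) abort_config("alpha must be >= 0")
  nd <- length(geometry$image_shape)
  beta <- rep_len(as.numeric(beta), nd)
  if (any(beta < 0)) abort_config("beta weights must be >= 0")
  if (length(b) != A$n_rows) abort_dim("b length does not match A n_rows")
  n <- A$n_cols
  blocks <- list(A)
  scales <- 1
  if (alpha > 0) {
    blocks <- c(blocks, list(identity_map(n)))
    scales <- c(scales, sqrt(alpha))
  }
  for (i in seq_len(nd)) {
    if (beta[i] > 0) {
      blocks <- c(blocks, list(make_gradient(i, geometry$image_shape,
                                             geometry$drive_axis)))
      scales <- c(scales, sqrt(beta[i]))
    }
  }
  m_each <- vapply(blocks, function(bk) bk$n_rows, integer(1))
  m_tot <- sum(m_each)
  ends <- cumsum(m_each)
  starts <- ends - m_each + 1L
  Tmap <- linear_map(m_tot, n,
    forward = function(x) {
      out <- numeric(m_tot)
      for (i in seq_along(blocks))
        out[starts[i]:ends[i]] <- scales[i] * blocks[[i]]$forward(x)
      out
    },
    adjoint = function(y) {
      acc <- numeric(n)
      for (i in seq_along(blocks))
        acc <- acc + scales[i] * blocks[[i]]$adjoint(y[starts[i]:ends[i]])
      acc
    },
    label = "T")
  w <- c(as.numeric(b), numeric(m_tot - A$n_rows))
  structure(list(T = Tmap, w = w, alpha = alpha, beta = beta,
                 A = A, b = as.numeric(b), geometry = geometry),
            class = "stacked_system")
}

#' @export
print.stacked_system <- function(x, ...) {
  cat("<stacked_system> T: ", x$T$n_rows, " x ", x$T$n_cols,
      ", alpha = ", x$alpha, ", beta = ", paste(x$beta, collapse = "/"),
      "\n", sep = "")
  invisible(x)
}
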