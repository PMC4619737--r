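#' Reconstruction configuration
#'
#' Bundles the optimization parameters. Defaults mirror a typical in-vivo
#' scale configuration: Tikhonov weight `alpha = 0.15`, smoothness
#' `beta = 0.04` on every axis, and a fixed budget of 10 FISTA iterations.
#' For noiseless synthetic data much weaker regularization and more
#' iterations give near-exact recovery (see the methods vignette).
#'
#' @param alpha Tikhonov weight (>= 0). Regularizes the DC singular direction
#'   and selects the feasible image with the lowest total DC value.
#' @param beta Smoothness weight(s) penalizing squared spatial gradients;
#'   scalar (recycled per axis) or one value per axis.
#' @param max_iters Iteration budget (>= 1).
#' @param rel_tol Stop early when the relative objective change drops below
#'   this (0 disables early stopping).
#' @param power_iters Power-iteration count for the Lipschitz/step estimate.
#' @param seed Seed for the power-iteration probe.
#' @param monotone If TRUE, use the monotone FISTA variant (never accept an
#'   iterate with a larger objective).
#' @param restart If TRUE, adaptively restart the momentum sequence.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(alpha = 0.15, beta = 0.04, max_iters = 10L,
                         rel_tol = 0, power_iters = 50L, seed = 1L,
                         monotone = FALSE, restart = FALSE) {
  if (alpha < 0 || any(beta < 0)) abort_config("weights must be >= 0")
  if (max_iters < 1) abort_config("max_iters must be >= 1")
  if (rel_tol < 0) abort_config("rel_tol must be >= 0")
  structure(list(alpha = alpha, beta = as.numeric(beta),
                 max_iters = as.integer(max_iters), rel_tol = rel_tol,
                 power_iters = as.integer(power_iters), seed = as.integer(seed),
                 monotone = isTRUE(monotone), restart = isTRUE(restart)),
            class = "recon_config")
}

#' Regularized data-consistency objective
#'
#' `||A rho - b||^2 + alpha ||rho||^2 + sum_i beta_i ||grad_i rho||^2`,
#' identical (to roundoff) to `||T rho - w||^2` for the stacked system built
#' by [stack_operators()].
#'
#' @param rho Image (array or operator-order vector).
#' @param A Forward [linear_map()].
#' @param b Data vector.
#' @param alpha,beta Regularization weights as in [recon_config()].
#' @param geometry A [scan_geometry()] (needed for the gradient terms and to
#'   vectorize array input).
#' @return Scalar objective value (>= 0).
#' @export
objective_value <- function(rho, A, b, alpha = 0, beta = 0, geometry) {
  v <- if (is.null(dim(rho))) as.numeric(rho) else as_image_vector(rho, geometry)
  if (length(v) != A$n_cols) abort_dim("rho length does not match A n_cols")
  if (length(b) != A$n_rows) abort_dim("b length does not match A n_rows")
  r <- map_apply(A, v) - b
  obj <- sum(r^2) + alpha * sum(v^2)
  nd <- length(geometry$image_shape)
  beta <- rep_len(as.numeric(beta), nd)
  for (i in seq_len(nd)) {
    if (beta[i] > 0) {
      G <- make_gradient(i, geometry$image_shape, geometry$drive_axis)
      obj <- obj + beta[i] * sum(map_apply(G, v)^2)
    }
  }
  obj
}

#' Projection onto the non-negative orthant
#'
#' The proximal operator of the non-negativity constraint: elementwise
#' `max(x, 0)`. Idempotent.
#'
#' @param rho Numeric vector or array.
#' @return Same shape, clipped at zero.
#' @export
project_nonnegative <- function(rho) pmax(rho, 0)

#' Largest eigenvalue of T'T by power iteration
#'
#' Seeded power iteration on the normal operator; used to set the FISTA step
#' size `1 / (1.05 * L)` (5 percent safety inflation).
#'
#' @param map A [linear_map()].
#' @param power_iters Number of iterations (>= 10).
#' @param seed Probe seed.
#' @return Estimate of `lambda_max(T'T)` (a tiny positive floor for the zero
#'   operator).
#' @export
lipschitz_estimate <- function(map, power_iters = 50L, seed = 1L) {
  if (power_iters < 10) abort_config("power_iters must be >= 10")
  set.seed(seed)
  v <- stats::rnorm(map$n_cols)
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(power_iters)) {
    z <- map$adjoint(map$forward(v))
    nz <- sqrt(sum(z^2))
    if (nz < 1e-300) return(.Machine$double.eps)
    lam <- sum(v * z)          # Rayleigh quotient (v is unit norm)
    v <- z / nz
  }
  max(lam, .Machine$double.eps)
}

fista_core <- function(Tmap, w, step, max_iters, rel_tol, monotone, restart,
                       objective = function(x, r) sum(r^2)) {
  n <- Tmap$n_cols
  x <- numeric(n)
  y <- x
  t_k <- 1
  r0 <- -w
  obj_prev <- objective(x, r0)
  objs <- numeric(max_iters)
  converged <- FALSE
  n_done <- 0L
  fx_prev <- obj_prev
  for (k in seq_len(max_iters)) {
    ry <- Tmap$forward(y) - w
    g <- Tmap$adjoint(ry)
    x_new <- pmax(y - step * g, 0)
    r_new <- Tmap$forward(x_new) - w
    f_new <- objective(x_new, r_new)
    if (monotone && f_new > fx_prev) {
      # monotone FISTA: keep the best iterate but let momentum use the candidate
      z <- x_new
      x_keep <- x
      f_keep <- fx_prev
    } else {
      z <- x_new
      x_keep <- x_new
      f_keep <- f_new
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    if (restart && sum((y - x_new) * (x_new - x)) > 0) {
      t_k <- 1
      t_next <- 1
    }
    y <- x_keep + ((t_k - 1) / t_next) * (x_keep - x) + (t_k / t_next) * (z - x_keep)
    x <- x_keep
    fx_prev <- f_keep
    t_k <- t_next
    objs[k] <- f_keep
    n_done <- k
    if (rel_tol > 0 && k > 1L) {
      denom <- max(objs[k - 1L], .Machine$double.xmin)
      if (abs(objs[k] - objs[k - 1L]) / denom < rel_tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(x = x, objs = objs[seq_len(n_done)], initial = obj_prev,
       converged = converged, n_iters = n_done)
}

#' Solve the non-negative regularized least-squares problem with FISTA
#'
#' Minimizes `||T rho - w||^2` subject to `rho >= 0` by the accelerated
#' proximal gradient method, starting from the zero image. The proximal step
#' is a projection onto the non-negative orthant; momentum follows the
#' standard sequence `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2`. If the
#' objective exceeds 10x its initial value the step is halved and the solve
#' restarted (an error after 5 halvings).
#'
#' @param system A `stacked_system` from [stack_operators()].
#' @param config A [recon_config()].
#' @return List with `image` (non-negative array in image shape) and `report`
#'   (class `solve_report`: per-iteration objective values, final objective,
#'   iteration count, step size, convergence flag).
#' @export
fista_solve <- function(system, config = recon_config()) {
  Tmap <- system$T
  w <- system$w
  L <- lipschitz_estimate(Tmap, config$power_iters, config$seed)
  step <- 1 / (1.05 * L)
  for (attempt in 0:5) {
    res <- fista_core(Tmap, w, step, config$max_iters, config$rel_tol,
                      config$monotone, config$restart)
    if (!length(res$objs) || max(res$objs) <= 10 * max(res$initial, .Machine$double.xmin))
      break
    step <- step / 2
    if (attempt == 5L)
      abort_numeric("FISTA diverged despite repeated step halving")
  }
  report <- structure(list(iterates = res$objs,
                           final_objective = if (length(res$objs)) res$objs[res$n_iters] else res$initial,
                           initial_objective = res$initial,
                           n_iters = res$n_iters,
                           step_size = step,
                           converged = res$converged),
                      class = "solve_report")
  list(image = as_image_array(res$x, system$geometry), report = report)
}

#' @export
print.solve_report <- function(x, ...) {
  cat("<solve_report> ", x$n_iters, " iterations, objective ",
      format(x$initial_objective), " -> ", format(x$final_objective),
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Dense projected-gradient reference solver
#'
#' Test oracle: materializes `T`, forms the normal equations densely, and runs
#' a long, conservatively stepped projected gradient descent. Refuses
#' problems with more than `max_n` unknowns. With `nonneg = FALSE` it solves
#' the unconstrained problem (useful for analytic cross-checks against
#' `solve(T'T, T'w)`).
#'
#' @param system A `stacked_system`.
#' @param n_steps Number of gradient steps.
#' @param max_n Size guard on the number of unknowns.
#' @param nonneg Apply the non-negativity projection (default TRUE).
#' @return Image array.
#' @export
reference_solve <- function(system, n_steps = 20000L, max_n = 200L, nonneg = TRUE) {
  n <- system$T$n_cols
  if (n > max_n) abort_size("reference_solve limited to n <= ", max_n)
  Tm <- materialize(system$T, check_adjoint = FALSE)
  TtT <- crossprod(Tm)
  Ttw <- as.numeric(crossprod(Tm, system$w))
  lam <- max(eigen(TtT, symmetric = TRUE, only.values = TRUE)$values)
  step <- 0.5 / max(lam, .Machine$double.eps)
  x <- numeric(n)
  for (k in seq_len(n_steps)) {
    x <- x - step * (as.numeric(TtT %*% x) - Ttw)
    if (nonneg) x <- pmax(x, 0)
  }
  as_image_array(x, system$geometry)
}
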