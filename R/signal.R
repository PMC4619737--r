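#' Drive-field trajectory for a 1D scan
#'
#' Field-free-region position model: a sinusoidal drive excursion over a
#' slowly advancing shift field, in (0-based) pixel units,
#' `x(t) = start_position + shift(t) + drive_amplitude * (1 - cos(2 pi f0 t))`.
#' Two shift models are supported. `"stepped"` (the package's idealization)
#' advances the shift by `shift_rate / f0` pixels at each drive-period
#' boundary, so every full drive cycle sweeps one fixed pFOV window up and
#' down; this makes the information destroyed by fundamental filtering
#' exactly one constant per pFOV. `"continuous"` uses the linear shift
#' `shift_rate * t` (closer to hardware, where the same loss is only
#' approximately constant per pFOV).
#'
#' @param drive_frequency Drive frequency `f0` in Hz.
#' @param drive_amplitude Drive excursion amplitude in pixels (half the
#'   peak-to-peak sweep).
#' @param shift_rate Mean shift-field speed in pixels per second.
#' @param sample_rate ADC sample rate in Hz (>= 20 * f0).
#' @param duration Scan duration in seconds.
#' @param start_position Position offset in pixels.
#' @param shift_mode `"stepped"` or `"continuous"`.
#' @return Object of class `drive_trajectory`.
#' @export
drive_trajectory <- function(drive_frequency, drive_amplitude, shift_rate,
                             sample_rate, duration, start_position = 0,
                             shift_mode = c("stepped", "continuous")) {
  if (duration <= 0) abort_config("duration must be > 0")
  if (sample_rate < 20 * drive_frequency)
    abort_config("sample_rate must be >= 20x the drive frequency")
  structure(list(drive_frequency = drive_frequency,
                 drive_amplitude = drive_amplitude,
                 shift_rate = shift_rate,
                 sample_rate = sample_rate,
                 duration = duration,
                 start_position = start_position,
                 shift_mode = match.arg(shift_mode)),
            class = "drive_trajectory")
}

#' Trajectory matched to a pFOV geometry
#'
#' Builds the stepped-shift trajectory whose drive cycles tile exactly the
#' windows of a 1D [scan_geometry()]: drive amplitude `(p - 1) / 2` (one
#' full sweep covers the `p` pixel centres of a window), the shift stepping
#' one pFOV shift `d` per drive period, and one period per pFOV.
#'
#' @param geometry 1D [scan_geometry()].
#' @param drive_frequency Drive frequency in Hz.
#' @param samples_per_period ADC samples per drive period (one pFOV).
#' @return A [drive_trajectory()] of duration `N / f0`.
#' @export
trajectory_for_geometry <- function(geometry, drive_frequency = 100,
                                    samples_per_period = 800L) {
  if (!is_1d_geometry(geometry))
    abort_config("signal-chain trajectories are 1D only")
  p <- geometry$pfov_width; d <- geometry$shift; N <- geometry$n_pfov
  f <- drive_frequency
  drive_trajectory(
    drive_frequency = f,
    drive_amplitude = (p - 1) / 2,
    shift_rate = d * f,
    sample_rate = samples_per_period * f,
    duration = N / f,
    start_position = 0,
    shift_mode = "stepped")
}

trajectory_samples <- function(traj) {
  n <- round(traj$sample_rate * traj$duration)
  t <- (seq_len(n) - 0.5) / traj$sample_rate  # half-sample offset: no exact turnarounds
  f0 <- traj$drive_frequency
  period <- floor(f0 * t)
  shift <- switch(traj$shift_mode,
                  stepped = (traj$shift_rate / f0) * period,
                  continuous = traj$shift_rate * t)
  pos <- traj$start_position + shift + traj$drive_amplitude * (1 - cos(2 * pi * f0 * t))
  vel <- traj$drive_amplitude * 2 * pi * f0 * sin(2 * pi * f0 * t)
  if (traj$shift_mode == "continuous") vel <- vel + traj$shift_rate
  list(times = t, positions = pos, velocities = vel,
       traversal = floor(2 * f0 * t), period = period)
}

#' Synthesize the raw 1D x-space signal
#'
#' The received voltage is the native image sampled at the instantaneous FFR
#' position, scaled by the instantaneous FFR velocity, plus an optional
#' direct-feedthrough tone at the fundamental frequency:
#' `s(t) = native(x(t)) * x'(t) + feedthrough_amp * cos(2 pi f0 t)`.
#' The native image is linearly interpolated between (0-based) pixel
#' centres. Errors if the trajectory exits the image extent.
#'
#' @param native 1D numeric native image.
#' @param traj A [drive_trajectory()].
#' @param feedthrough_amp Amplitude of the feedthrough tone.
#' @return Object of class `raw_signal` with `samples`, `times`, `positions`,
#'   `velocities`, `traversal`, `period`, `trajectory`.
#' @export
synthesize_signal_1d <- function(native, traj, feedthrough_amp = 0) {
  native <- as.numeric(native)
  L <- length(native)
  ts <- trajectory_samples(traj)
  if (min(ts$positions) < -0.5 || max(ts$positions) > L - 0.5)
    abort_config("FFR trajectory exits the image extent")
  rho <- stats::approx(x = 0:(L - 1), y = native, xout = ts$positions,
                       rule = 2)$y
  samples <- rho * ts$velocities +
    feedthrough_amp * cos(2 * pi * traj$drive_frequency * ts$times)
  structure(c(list(samples = samples), ts, list(trajectory = traj)),
            class = "raw_signal")
}

#' Remove DC, fundamental and out-of-band harmonic content
#'
#' Two stages. (1) Within each full drive period, the least-squares
#' projection of the signal onto the DC and fundamental components
#' `{1, cos(2 pi f0 t), sin(2 pi f0 t)}` is subtracted; this removes the
#' direct feedthrough exactly, and for a symmetric sweep the subtracted
#' signal component corresponds to exactly one constant in each pFOV image
#' (the DC loss the reconstruction must recover). Harmonics 2 and above are
#' orthogonal to the projection over full periods and pass untouched.
#' (2) A symmetric (zero-phase) Fourier mask removes content above harmonic
#' `n_harmonics + 1/2`.
#'
#' @param signal A `raw_signal`.
#' @param n_harmonics Highest retained harmonic (>= 2; default 15, a 300 kHz
#'   bandwidth at a 20 kHz drive).
#' @return The filtered `raw_signal`.
#' @export
remove_fundamental <- function(signal, n_harmonics = 15L) {
  if (n_harmonics < 2) abort_config("n_harmonics must be >= 2")
  traj <- signal$trajectory
  f0 <- traj$drive_frequency
  sr <- traj$sample_rate
  if ((n_harmonics + 0.5) * f0 > sr / 2)
    abort_config("n_harmonics band exceeds the Nyquist frequency")
  x <- signal$samples
  theta <- 2 * pi * f0 * signal$times
  for (k in unique(signal$period)) {
    i <- which(signal$period == k)
    B <- cbind(1, cos(theta[i]), sin(theta[i]))
    x[i] <- x[i] - B %*% qr.solve(B, x[i])
  }
  n <- length(x)
  bin <- seq_len(n) - 1L
  freq <- pmin(bin, n - bin) * sr / n     # symmetric frequency axis
  spec <- stats::fft(x)
  spec[freq > (n_harmonics + 0.5) * f0] <- 0
  signal$samples <- Re(stats::fft(spec, inverse = TRUE)) / n
  signal
}

#' Velocity compensation
#'
#' Normalizes the signal by the instantaneous FFR velocity; samples where
#' the speed falls below `velocity_floor` times the peak speed (the
#' turnaround points of the drive sweep) are marked invalid.
#'
#' @param signal A `raw_signal`.
#' @param velocity_floor Fraction of peak speed below which samples are
#'   masked (> 0).
#' @return Object of class `compensated_signal` with `values`, `valid`,
#'   `positions`, `pfov` (pFOV assignment per sample), `trajectory`.
#' @export
velocity_compensate <- function(signal, velocity_floor = 0.05) {
  if (velocity_floor <= 0) abort_config("velocity_floor must be > 0")
  speed <- abs(signal$velocities)
  valid <- speed >= velocity_floor * max(speed)
  if (!any(valid)) abort_config("degenerate trajectory: all samples below the velocity floor")
  values <- rep(NA_real_, length(signal$samples))
  values[valid] <- signal$samples[valid] / signal$velocities[valid]
  structure(list(values = values, valid = valid,
                 positions = signal$positions, pfov = signal$period,
                 trajectory = signal$trajectory),
            class = "compensated_signal")
}

#' Grid compensated samples to partial-FOV images
#'
#' Each drive traversal of a window becomes (part of) one pFOV image. Valid
#' samples are binned to the nearest pixel of their pFOV's window and
#' bin-averaged (duplicate samples average rather than sum, which is what
#' improves SNR with denser sampling); samples falling outside the window
#' are discarded. Pixels left empty (possible near turnarounds under an
#' aggressive velocity floor) are filled by linear interpolation along the
#' line and flagged FALSE in the stack mask; afterwards every line's mean is
#' removed (the unknown DC is filtered to zero).
#'
#' @param values Compensated sample values, or a `compensated_signal` (then
#'   `geometry` is the second argument and the rest are taken from it).
#' @param positions Sample positions in pixels (0-based).
#' @param geometry 1D [scan_geometry()].
#' @param pfov 0-based pFOV assignment per sample (defaults to all 0 for a
#'   single-pFOV geometry).
#' @param valid Logical validity mask per sample.
#' @return A [pfov_stack()] whose `mask` flags observed (TRUE) vs
#'   interpolated (FALSE) pixels.
#' @export
grid_to_partial_fovs <- function(values, positions = NULL, geometry = NULL,
                                 pfov = NULL, valid = NULL) {
  if (inherits(values, "compensated_signal")) {
    comp <- values
    geometry <- positions %||% geometry
    if (is.null(geometry)) abort_config("geometry required")
    positions <- comp$positions
    pfov <- comp$pfov
    valid <- comp$valid
    values <- comp$values
  }
  if (!is_1d_geometry(geometry)) abort_config("gridding is 1D only")
  p <- geometry$pfov_width; d <- geometry$shift; N <- geometry$n_pfov
  ns <- length(values)
  if (is.null(pfov)) {
    if (N != 1L) abort_config("pfov assignment required for N > 1")
    pfov <- rep(0L, ns)
  }
  pfov <- pmin(pfov, N - 1L)
  if (is.null(valid)) valid <- !is.na(values)
  local <- round(positions) - pfov * d    # 0-based pixel within the window
  ok <- valid & !is.na(values) & local >= 0 & local < p & pfov >= 0
  if (!any(ok)) abort_config("gridding failed: no valid samples")
  idx <- local[ok] + p * pfov[ok]         # 0-based (pixel, pfov) bin
  sums <- rowsum(values[ok], idx)
  counts <- rowsum(rep(1, sum(ok)), idx)
  img <- matrix(NA_real_, p, N)
  img[as.integer(rownames(sums)) + 1L] <- sums / counts
  mask <- !is.na(img)
  if (any(colSums(mask) == 0L))
    abort_config("gridding failed: pFOV ", which(colSums(mask) == 0L)[1],
                 " received no valid samples")
  for (k in seq_len(N)) {
    if (anyNA(img[, k])) {
      obs <- which(!is.na(img[, k]))
      img[, k] <- stats::approx(obs, img[obs, k], xout = seq_len(p), rule = 2)$y
    }
  }
  img <- img - rep(colMeans(img), each = p)   # DC filtered to zero per line
  pfov_stack(img, geometry, mask = array(mask, c(p, 1L, N)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full idealized 1D signal chain
#'
#' Synthesize the raw signal for a geometry-matched trajectory, remove the
#' DC/fundamental band and out-of-band harmonics, velocity compensate, and
#' grid to partial FOVs. On a smooth, well-resolved native image (PSF a few
#' pixels wide) the result agrees with [simulate_partial_fovs()]
#' (`dc_mode = "remove"`) to within a few percent; the residual is
#' interpolation and binning error, not DC bookkeeping.
#'
#' @param native 1D native image.
#' @param geometry 1D [scan_geometry()].
#' @param drive_frequency,samples_per_period Trajectory parameters
#'   (see [trajectory_for_geometry()]).
#' @param feedthrough_amp Direct-feedthrough tone amplitude.
#' @param n_harmonics Retained harmonic band (see [remove_fundamental()]).
#' @param velocity_floor Turnaround mask threshold.
#' @return A [pfov_stack()].
#' @export
process_signal_1d <- function(native, geometry, drive_frequency = 100,
                              samples_per_period = 800L, feedthrough_amp = 0,
                              n_harmonics = 15L, velocity_floor = 0.05) {
  traj <- trajectory_for_geometry(geometry, drive_frequency, samples_per_period)
  sig <- synthesize_signal_1d(native, traj, feedthrough_amp)
  sig <- remove_fundamental(sig, n_harmonics)
  comp <- velocity_compensate(sig, velocity_floor)
  grid_to_partial_fovs(comp, geometry)
}
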