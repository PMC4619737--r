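# File formats. Images travel as NIfTI (float64) or TIFF (float32);
# pFOV stacks as a NIfTI payload plus a JSON sidecar holding the scan
# geometry; configs as YAML or JSON; solve reports as CSV + JSON.

geometry_to_list <- function(g) {
  list(image_shape = as.integer(g$image_shape),
       drive_axis = g$drive_axis,
       pfov_width = g$pfov_width,
       overlap = g$overlap,
       shift = g$shift,
       n_pfov = g$n_pfov)
}

geometry_from_list <- function(l) {
  scan_geometry(unlist(l$image_shape), l$pfov_width, overlap = l$overlap,
                n_pfov = l$n_pfov, drive_axis = l$drive_axis %||% 1L)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read a partial-FOV stack
#'
#' The stack payload (`p x n_transverse x N`, float64) is stored as NIfTI and
#' the scan geometry (and observation mask, if any) in a JSON sidecar next to
#' it. Round-trips are exact to float64 precision.
#'
#' @param stack A [pfov_stack()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path` invisibly ([write_pfov_stack()]); a [pfov_stack()]
#'   ([read_pfov_stack()]).
#' @export
write_pfov_stack <- function(stack, path) {
  RNifti::writeNifti(stack$values, path, datatype = "double")
  meta <- list(geometry = geometry_to_list(stack$geometry))
  if (!is.null(stack$mask)) meta$mask <- as.integer(stack$mask)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pfov_stack
#' @export
read_pfov_stack <- function(path) {
  vals <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  g <- geometry_from_list(as.list(meta$geometry))
  mask <- if (!is.null(meta$mask)) array(as.logical(meta$mask),
                                         dim = dim(vals)) else NULL
  pfov_stack(vals, g, mask = mask)
}

#' Write / read an image volume
#'
#' Format chosen by extension: `.nii`/`.nii.gz` (float64 NIfTI), `.tif`/
#' `.tiff` (32-bit float TIFF; 3D volumes become multi-page), `.csv` (1D
#' vectors, one `value` column).
#'
#' @param image Numeric array (or 1D vector).
#' @param path Output path.
#' @return `path` invisibly ([write_image()]); a numeric array
#'   ([read_image()]).
#' @export
write_image <- function(image, path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  gz <- grepl("\\.gz$", path)
  if (ext == "nii") {
    RNifti::writeNifti(if (is.null(dim(image))) array(image, dim = length(image))
                       else image, path, datatype = "double")
  } else if (ext %in% c("tif", "tiff")) {
    rng <- range(image)
    arr <- if (is.null(dim(image))) array(image, dim = c(length(image), 1L)) else image
    if (length(dim(arr)) == 2L) {
      tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
    } else if (length(dim(arr)) == 3L) {
      pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
      tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    } else abort_config("TIFF supports 2D/3D images only")
    if (rng[1] < 0 || rng[2] > 1)
      warning("TIFF stores float samples; values outside [0,1] are kept but some viewers clip them")
  } else if (ext == "csv") {
    if (!is.null(dim(image)) && length(dim(image)) > 1L)
      abort_config("CSV image output is 1D only")
    utils::write.csv(data.frame(value = as.numeric(image)), path, row.names = FALSE)
  } else abort_config("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "nii") {
    out <- as.array(RNifti::readNifti(path))
    if (length(dim(out)) == 1L) out <- as.numeric(out)
    out
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (length(pages) == 1L) pages[[1]]
    else {
      arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
      for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
      arr
    }
  } else if (ext == "csv") {
    utils::read.csv(path)$value
  } else abort_config("unsupported image extension: ", ext)
}

#' Read a reconstruction config from YAML or JSON
#'
#' Recognized keys: `alpha`, `beta` (scalar or per-axis vector), `max_iters`,
#' `rel_tol`, `power_iters`, `seed`; missing keys fall back to the
#' [recon_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [recon_config()].
#' @export
read_recon_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  l <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else abort_config("config must be YAML or JSON")
  defaults <- recon_config()
  recon_config(alpha = l$alpha %||% defaults$alpha,
               beta = unlist(l$beta) %||% defaults$beta,
               max_iters = l$max_iters %||% defaults$max_iters,
               rel_tol = l$rel_tol %||% defaults$rel_tol,
               power_iters = l$power_iters %||% defaults$power_iters,
               seed = l$seed %||% defaults$seed)
}

#' Write a solve report
#'
#' Writes the per-iteration objective trace as CSV (`iteration`, `objective`)
#' and a JSON summary (final objective, iteration count, step size,
#' convergence flag).
#'
#' @param report A `solve_report` from [fista_solve()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list written to JSON.
#' @export
write_solve_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(data.frame(iteration = seq_along(report$iterates),
                                objective = report$iterates),
                     csv_path, row.names = FALSE)
  summary <- list(final_objective = report$final_objective,
                  initial_objective = report$initial_objective,
                  n_iters = report$n_iters,
                  step_size = report$step_size,
                  converged = report$converged)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
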