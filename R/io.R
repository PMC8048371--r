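#' Write / read a phantom specification as JSON
#'
#' @param spec A `phantom_spec`.
#' @param path File path.
#' @return `read_phantom_json` returns a `phantom_spec`.
#' @export
write_phantom_json <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- list(fov = spec$fov, field_strength = spec$field_strength,
              compartments = lapply(spec$compartments, function(cp)
                cp[c("name", "shape", "center", "semi_axes", "s0", "d_true",
                     "chem_shift", "priority")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  comps <- lapply(obj$compartments, function(cp)
    compartment(cp$name, cp$shape, unlist(cp$center), unlist(cp$semi_axes),
                s0 = cp$s0, d_true = cp$d_true, chem_shift = cp$chem_shift,
                priority = cp$priority))
  phantom_spec(comps, fov = as.numeric(obj$fov),
               field_strength = as.numeric(obj$field_strength))
}

#' Write rasterized parameter images as NIfTI volumes
#'
#' One volume per map (`s0`, `d`, `shift`, `label`), with pixel dimensions in
#' mm in the header.
#'
#' @param maps A `parameter_images`.
#' @param prefix Output path prefix; files `<prefix>_<map>.nii.gz` are written.
#' @return Invisibly, the written paths.
#' @export
write_parameter_images <- function(maps, prefix) {
  stopifnot(inherits(maps, "parameter_images"))
  paths <- character(0)
  for (nm in c("s0_map", "d_map", "shift_map", "label_map")) {
    p <- paste0(prefix, "_", sub("_map", "", nm), ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]],
                                       pixdim = rep(maps$pixel_mm, 2)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a reconstructed DWI stack as NIfTI plus a JSON sidecar
#'
#' The image array is written as a 4-D volume (y, x, slice, b x polarity) and
#' the b-value/polarity ordering plus acquisition parameters go to a JSON
#' sidecar next to it.
#'
#' @param stack A `dwi_stack`.
#' @param path Output `.nii.gz` path; the sidecar replaces the extension with
#'   `.json`.
#' @return Invisibly, `path`.
#' @export
write_dwi_stack <- function(stack, path) {
  stopifnot(inherits(stack, "dwi_stack"))
  d <- dim(stack$images)   # slice, b, pol, y, x
  vol <- aperm(stack$images, c(4, 5, 1, 2, 3))
  dim(vol) <- c(d[4], d[5], d[1], d[2] * d[3])
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(stack$pixel_mm, 2)), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(protocol = stack$protocol,
               b_values = stack$params$b_values,
               polarities = stack$params$polarities,
               volume_order = "b-major, polarity-minor",
               pixel_mm = stack$pixel_mm,
               provenance = stack$provenance)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI label mask from a NIfTI file
#'
#' @param path NIfTI path (integer label image).
#' @param label Label value to extract (default: all nonzero).
#' @return A logical matrix.
#' @export
read_roi_mask <- function(path, label = NULL) {
  img <- RNifti::readNifti(path)
  m <- as.array(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  if (is.null(label)) m != 0 else m == label
}

#' Persist / restore a simulated k-space set
#'
#' Stored with R's native serialization (samples, trajectory, times and the
#' full acquisition metadata travel together).
#'
#' @param kspace A `kspace_set`.
#' @param path File path (`.rds`).
#' @return `read_kspace` returns the `kspace_set`.
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "kspace_set"))
  saveRDS(kspace, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  ks <- readRDS(path)
  stopifnot(inherits(ks, "kspace_set"))
  ks
}

#' Read paired test-retest measurements from CSV
#'
#' Expects columns `subject`, `tissue`, `protocol`, `test`, `retest` (ADC in
#' 1e-3 mm^2/s).
#'
#' @param path CSV path.
#' @return A data frame; use with [sd_ws()], [cv_ws()], [bland_altman()].
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "tissue", "protocol", "test", "retest")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  df
}
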