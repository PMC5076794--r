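#' Per-voxel B1 map on a CSI grid
#'
#' Container for a per-voxel gamma*B1 map together with the quantities the
#' exclusion rules operate on: the fitted phase difference and its
#' Cramer-Rao lower bound. Voxels are never deleted; exclusions are recorded
#' as per-voxel reasons so the provenance of every masked value is kept.
#'
#' @param gamma_b1 Numeric array (any dimension) of gamma*B1 in Hz.
#' @param delta_phi Array of fitted phase differences, radians (same shape).
#' @param crlb_deg Array of phase-difference CRLBs in degrees (same shape).
#' @param method Estimation method label (e.g. `"A"`).
#' @param meta Named list of provenance (omega_rf, b_tilde, thresholds, ...).
#' @return An object of class `b1_map`.
#' @export
b1_map <- function(gamma_b1, delta_phi = NULL, crlb_deg = NULL,
                   method = "A", meta = list()) {
  dm <- dim(gamma_b1)
  if (is.null(dm)) dm <- length(gamma_b1)
  chk <- function(x, nm) {
    if (is.null(x)) return(array(NA_real_, dm))
    if (!identical(dim(x), dim(gamma_b1)) && length(x) != length(gamma_b1))
      stop(sprintf("'%s' must match the shape of gamma_b1", nm))
    array(as.numeric(x), dm)
  }
  structure(list(gamma_b1 = array(as.numeric(gamma_b1), dm),
                 delta_phi = chk(delta_phi, "delta_phi"),
                 crlb_deg = chk(crlb_deg, "crlb_deg"),
                 exclusion = array("none", dm),
                 method = method, meta = meta),
            class = "b1_map")
}

#' @export
print.b1_map <- function(x, ...) {
  n <- length(x$gamma_b1)
  nex <- sum(x$exclusion != "none")
  cat(sprintf("B1 map (method %s): %s voxels, %d excluded\n", x$method,
              paste(dim(x$gamma_b1), collapse = " x "), nex))
  ok <- x$exclusion == "none" & is.finite(x$gamma_b1)
  if (any(ok))
    cat(sprintf("  gamma*B1 range (included voxels): %.0f - %.0f Hz\n",
                min(x$gamma_b1[ok]), max(x$gamma_b1[ok])))
  invisible(x)
}

#' Apply voxel exclusion rules to a B1 map
#'
#' Flags voxels whose phase difference is negative (very low B1 or an
#' uncorrected wrap), whose phase CRLB exceeds the threshold (low SNR), or
#' which fall outside a supplied geometry mask. Values are retained; only
#' the exclusion reason is set. Typical CRLB thresholds: 20 degrees for
#' phantom work, 10 for skeletal muscle, 15 for cardiac maps.
#'
#' @param map A [b1_map()].
#' @param crlb_threshold CRLB threshold in degrees (> 0).
#' @param geometry_mask Optional logical array, `TRUE` where voxels are
#'   inside the object of interest.
#' @return The map with updated `exclusion` reasons (`"none"`,
#'   `"negative_phase_diff"`, `"crlb_exceeded"`, `"outside_mask"`).
#' @export
mask_voxels <- function(map, crlb_threshold, geometry_mask = NULL) {
  stopifnot(inherits(map, "b1_map"))
  if (!is.numeric(crlb_threshold) || crlb_threshold <= 0)
    stop("crlb_threshold must be > 0 (degrees)")
  excl <- array("none", dim(map$gamma_b1))
  if (!is.null(geometry_mask)) {
    if (length(geometry_mask) != length(map$gamma_b1))
      stop("geometry_mask must match the map shape")
    excl[!geometry_mask] <- "outside_mask"
  }
  bad_crlb <- is.finite(map$crlb_deg) & map$crlb_deg > crlb_threshold
  excl[excl == "none" & bad_crlb] <- "crlb_exceeded"
  neg <- is.finite(map$delta_phi) & map$delta_phi < 0
  excl[excl == "none" & neg] <- "negative_phase_diff"
  map$exclusion <- excl
  map$meta$crlb_threshold_deg <- crlb_threshold
  map
}

#' Write a B1 map as NIfTI with a JSON sidecar
#'
#' The gamma*B1 values (Hz, float32) go to a `.nii` volume; method,
#' model constants, thresholds and exclusion counts go to `<path>.json`.
#' Excluded voxels are written as `NA` in the volume.
#'
#' @param map A [b1_map()] with 3-dimensional data.
#' @param path Output path (`.nii` appended if missing).
#' @param pixdim Voxel size in mm, length 3 (default 1).
#' @return The NIfTI path, invisibly.
#' @export
write_b1map_nifti <- function(map, path, pixdim = c(1, 1, 1)) {
  stopifnot(inherits(map, "b1_map"))
  if (!grepl("\\.nii$", path)) path <- paste0(path, ".nii")
  vol <- map$gamma_b1
  vol[map$exclusion != "none"] <- NA_real_
  attr(vol, "pixdim") <- pixdim
  img <- RNifti::asNifti(vol, datatype = "float")
  RNifti::writeNifti(img, path, compression = 0)
  side <- list(method = map$method, meta = map$meta,
               exclusion_counts = as.list(table(map$exclusion)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
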