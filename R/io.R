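#' Write a CSI FID array to the plain-text container format
#'
#' The package's on-disk FID container is a pair of files: a JSON header
#' (`<path>.json`: grid dimensions, number of time points, dwell time in
#' seconds, arm carrier frequency, and free-form protocol metadata) and a
#' CSV table (`<path>.csv`) in long format with columns `i1, i2, i3, t, re,
#' im` -- one row per voxel per time point, voxel indices 1-based. The
#' layout is self-describing and diff-friendly.
#'
#' @param fids Complex array `[n1, n2, n3, nt]`.
#' @param dwell Dwell time in seconds.
#' @param path Base path (extensions appended).
#' @param carrier_hz Sensitizing-pulse carrier of this arm (or `NA`).
#' @param meta Named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_fid_array <- function(fids, dwell, path, carrier_hz = NA_real_,
                            meta = list()) {
  dm <- dim(fids)
  if (length(dm) != 4L) stop("fids must be a 4-d array [n1, n2, n3, nt]")
  hdr <- c(list(dims = dm[1:3], n_points = dm[4], dwell_s = dwell,
                carrier_hz = carrier_hz), meta)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  idx <- expand.grid(i1 = seq_len(dm[1]), i2 = seq_len(dm[2]),
                     i3 = seq_len(dm[3]), t = seq_len(dm[4]))
  utils::write.csv(data.frame(idx, re = Re(as.vector(fids)),
                              im = Im(as.vector(fids))),
                   paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Read a CSI FID array written by [write_fid_array()]
#'
#' @param path Base path (without extension).
#' @return List with `fids` (complex array), `dwell`, `carrier_hz`, `meta`.
#' @export
read_fid_array <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"))
  dm <- c(hdr$dims, hdr$n_points)
  fids <- array(0i, dm)
  fids[cbind(df$i1, df$i2, df$i3, df$t)] <- complex(real = df$re,
                                                    imaginary = df$im)
  extra <- hdr[setdiff(names(hdr), c("dims", "n_points", "dwell_s",
                                     "carrier_hz"))]
  list(fids = fids, dwell = hdr$dwell_s,
       carrier_hz = if (is.null(hdr$carrier_hz)) NA_real_ else hdr$carrier_hz,
       meta = extra)
}

#' Write a prior-knowledge table as CSV
#'
#' Columns: `name, offset_hz, amplitude, damping_hz, phase_rad, n_lines,
#' j_hz`.
#'
#' @param model A [spectrum_model()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_prior_csv <- function(model, path) {
  stopifnot(inherits(model, "spectrum_model"))
  utils::write.csv(model$peaks, path, row.names = FALSE)
  invisible(path)
}

#' Read a prior-knowledge table written by [write_prior_csv()]
#' @param path CSV path.
#' @return A [spectrum_model()].
#' @export
read_prior_csv <- function(path) spectrum_model(utils::read.csv(path))
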