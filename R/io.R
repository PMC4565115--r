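#' Controlled vocabulary of developmental stage labels
#'
#' Stage labels follow the conventional post-embryonic staging of
#' *Drosophila melanogaster*: second/third larval instar (L2, L3), pupa days
#' 1-4 sampled every 8 hours after puparium formation (APF), and adult day 1
#' (AD1). `"unknown"` is accepted wherever a stage has not been assigned.
#'
#' @return Character vector of valid `stage_label` values, in developmental
#'   order (with `"unknown"` last).
#' @export
stage_vocabulary <- function() {
  c("L2", "L3",
    "PD1 16h", "PD1 24h",
    "PD2 32h", "PD2 40h", "PD2 48h",
    "PD3 56h", "PD3 64h", "PD3 72h",
    "PD4 80h", "PD4 88h", "PD4 96h",
    "AD1", "unknown")
}

#' Stage lookup table
#'
#' Maps each stage label to its hours after puparium formation (APF; `NA` for
#' non-pupal stages) and whether the stage belongs to the pupal period, during
#' which recordings are taken every 8 h.
#'
#' @return A data.frame with columns `stage_label`, `hours_apf`, `is_pupal`.
#' @export
stage_info <- function() {
  data.frame(
    stage_label = c("L2", "L3",
                    "PD1 16h", "PD1 24h",
                    "PD2 32h", "PD2 40h", "PD2 48h",
                    "PD3 56h", "PD3 64h", "PD3 72h",
                    "PD4 80h", "PD4 88h", "PD4 96h",
                    "AD1"),
    hours_apf = c(NA, NA, 16, 24, 32, 40, 48, 56, 64, 72, 80, 88, 96, NA),
    is_pupal = c(FALSE, FALSE, rep(TRUE, 11), FALSE),
    stringsAsFactors = FALSE
  )
}

#' Acquisition metadata for an M-mode recording
#'
#' @param frame_rate_hz Frame rate in frames per second. The OCM system these
#'   tools target acquires M-mode images at 128 Hz.
#' @param pixel_size_x_um Transverse (within-frame horizontal) pixel pitch, um.
#' @param pixel_size_z_um Axial (depth, within-frame vertical) pixel pitch, um.
#' @param stage_label Developmental stage; must be in [stage_vocabulary()].
#' @param specimen_id Free-text specimen identifier.
#' @param genotype Free-text genotype label.
#'
#' @return An object of class `recording_metadata`.
#' @export
recording_metadata <- function(frame_rate_hz = 128,
                               pixel_size_x_um = 2.2,
                               pixel_size_z_um = 2.2,
                               stage_label = "unknown",
                               specimen_id = "",
                               genotype = "") {
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1 ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a single positive number")
  }
  if (!is.numeric(pixel_size_x_um) || pixel_size_x_um <= 0 ||
      !is.numeric(pixel_size_z_um) || pixel_size_z_um <= 0) {
    stop("pixel sizes must be positive")
  }
  if (!stage_label %in% stage_vocabulary()) {
    stop("unknown stage_label '", stage_label, "'; see stage_vocabulary()")
  }
  structure(
    list(frame_rate_hz = as.numeric(frame_rate_hz),
         pixel_size_x_um = as.numeric(pixel_size_x_um),
         pixel_size_z_um = as.numeric(pixel_size_z_um),
         stage_label = stage_label,
         specimen_id = as.character(specimen_id),
         genotype = as.character(genotype)),
    class = "recording_metadata"
  )
}

#' M-mode recording container
#'
#' Wraps a time-ordered stack of 2D cross-sectional intensity frames together
#' with its acquisition metadata. The frame axis comes first: `frames[k, , ]`
#' is the k-th frame, acquired at time `(k - 1) / frame_rate_hz` seconds
#' (timestamps at frame start). Rows are depth (axial, z), columns transverse
#' (x). Intensities are non-negative; files store them as 16-bit unsigned
#' integers, in memory they are numeric.
#'
#' @param frames Numeric 3D array ordered (time, depth rows, transverse cols).
#' @param metadata A [recording_metadata()] object.
#'
#' @return An object of class `ocm_recording` with elements `frames` and
#'   `metadata`.
#' @export
ocm_recording <- function(frames, metadata) {
  if (!inherits(metadata, "recording_metadata")) {
    stop("metadata must be a recording_metadata object")
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("frames must be a 3-dimensional array (time, rows, cols)")
  }
  if (dim(frames)[1] < 2) {
    stop("a recording must contain at least 2 frames")
  }
  if (any(!is.finite(frames)) || any(frames < 0)) {
    stop("frame intensities must be finite and non-negative")
  }
  structure(list(frames = frames, metadata = metadata),
            class = "ocm_recording")
}

#' Number of frames and duration of a recording
#'
#' @param rec An `ocm_recording`.
#' @return `n_frames()`: integer frame count. `duration_s()`: duration in
#'   seconds, `n_frames / frame_rate_hz`.
#' @export
n_frames <- function(rec) dim(rec$frames)[1]

#' @rdname n_frames
#' @export
duration_s <- function(rec) n_frames(rec) / rec$metadata$frame_rate_hz

#' Per-frame timestamps (seconds, at frame start)
#' @param rec An `ocm_recording`.
#' @return Numeric vector of length `n_frames(rec)`.
#' @export
frame_times <- function(rec) {
  (seq_len(n_frames(rec)) - 1) / rec$metadata$frame_rate_hz
}

#' @export
print.ocm_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("M-mode OCM recording: %d frames of %d x %d px, %.1f Hz (%.2f s)\n",
              d[1], d[2], d[3], x$metadata$frame_rate_hz, duration_s(x)))
  cat(sprintf("  stage: %s  specimen: %s  genotype: %s\n",
              x$metadata$stage_label,
              x$metadata$specimen_id, x$metadata$genotype))
  invisible(x)
}

.sidecar_fields <- c("frame_rate_hz", "pixel_size_x_um", "pixel_size_z_um",
                     "stage_label", "specimen_id", "genotype")

#' Read an M-mode recording from a multi-page TIFF plus JSON sidecar
#'
#' The TIFF holds one page per frame, page order = time order, 16-bit
#' unsigned intensities. The JSON sidecar carries acquisition metadata;
#' `frame_rate_hz` is mandatory (event timing depends on it, so there is no
#' silent default), the pixel sizes default to 1 um with a warning, and the
#' remaining fields default to `"unknown"` / empty.
#'
#' @param stack_path Path to the multi-page TIFF stack.
#' @param sidecar_path Path to the JSON metadata sidecar.
#'
#' @return An [ocm_recording()].
#' @export
read_recording <- function(stack_path, sidecar_path) {
  if (!file.exists(stack_path)) stop("stack file not found: ", stack_path)
  if (!file.exists(sidecar_path)) stop("sidecar file not found: ", sidecar_path)

  meta_raw <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta_raw$frame_rate_hz)) {
    stop("sidecar is missing mandatory field frame_rate_hz")
  }
  if (is.null(meta_raw$pixel_size_x_um) || is.null(meta_raw$pixel_size_z_um)) {
    warning("sidecar is missing pixel sizes; defaulting to 1 um")
  }
  meta <- recording_metadata(
    frame_rate_hz = meta_raw$frame_rate_hz,
    pixel_size_x_um = meta_raw$pixel_size_x_um %||% 1,
    pixel_size_z_um = meta_raw$pixel_size_z_um %||% 1,
    stage_label = meta_raw$stage_label %||% "unknown",
    specimen_id = meta_raw$specimen_id %||% "",
    genotype = meta_raw$genotype %||% ""
  )

  pages <- tiff::readTIFF(stack_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("recording must contain at least 2 frames")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent frame shapes in stack")
  }
  frames <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]]
  ocm_recording(frames, meta)
}

#' Write an M-mode recording to a multi-page TIFF plus JSON sidecar
#'
#' Intensities are clamped to \[0, 65535\], rounded, and stored as 16-bit
#' unsigned integers, so integer-valued input round-trips exactly.
#'
#' @param rec An [ocm_recording()].
#' @param stack_path Output TIFF path.
#' @param sidecar_path Output JSON path.
#' @param force Overwrite existing files? Defaults to `FALSE` (refusal error).
#'
#' @return Invisibly, `NULL`.
#' @export
write_recording <- function(rec, stack_path, sidecar_path, force = FALSE) {
  stopifnot(inherits(rec, "ocm_recording"))
  if (!force && (file.exists(stack_path) || file.exists(sidecar_path))) {
    stop("output file exists; use force = TRUE to overwrite")
  }
  vals <- round(pmin(pmax(rec$frames, 0), 65535))
  pages <- lapply(seq_len(dim(vals)[1]), function(k) vals[k, , ] / 65535)
  ok <- try(tiff::writeTIFF(pages, stack_path, bits.per.sample = 16,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("could not write stack: ", stack_path)
  jsonlite::write_json(rec$metadata[.sidecar_fields], sidecar_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Column set of a cardiac parameter table
#'
#' One row per (specimen, stage, recording). Units: HR in beats per minute;
#' CAP and FS in percent; diameters (EDD/ESD) in um along the transverse (x)
#' and axial (z) axes; areas (EDA/ESA) in um^2.
#'
#' @return Character vector of column names in canonical order.
#' @export
param_table_columns <- function() {
  c("specimen_id", "stage_label", "recording_index",
    "HR_bpm", "CAP_pct",
    "EDD_x_um", "EDD_z_um", "ESD_x_um", "ESD_z_um",
    "EDA_um2", "ESA_um2",
    "FS_x_pct", "FS_z_pct", "FS_area_pct", "flags")
}

.param_units_header <- paste0(
  "# units: HR_bpm=bpm; CAP_pct=%; EDD/ESD=um; EDA/ESA=um^2; FS=%; ",
  "recording_index=1-based")

#' Write a cardiac parameter table to CSV
#'
#' Writes the canonical column order (see [param_table_columns()]) preceded by
#' a `#`-prefixed units line. Numeric cells are rendered with 4 decimal
#' places; `NA`/`NaN` cells become empty fields.
#'
#' @param table Data.frame containing at least the canonical columns.
#' @param path Output CSV path.
#' @param force Overwrite existing file?
#' @return Invisibly, `NULL`.
#' @export
write_param_table <- function(table, path, force = FALSE) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("param table must be a nonempty data.frame")
  }
  missing_cols <- setdiff(param_table_columns(), names(table))
  if (length(missing_cols)) {
    stop("param table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!force && file.exists(path)) {
    stop("output file exists; use force = TRUE to overwrite")
  }
  out <- table[, param_table_columns()]
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% "recording_index"
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(out[[j]]), "", sprintf("%.4f", out[[j]]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.param_units_header, con)
  utils::write.csv(out, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(NULL)
}

#' Read a cardiac parameter table written by [write_param_table()]
#'
#' @param path CSV path.
#' @return Data.frame with the canonical columns; empty fields become `NA`.
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = "")
  missing_cols <- setdiff(param_table_columns(), names(tab))
  if (length(missing_cols)) {
    stop("not a param table; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
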