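# File I/O for cubes (ENVI .hdr/.raw and HDF5) and masks (8-bit PNG + JSON
# legend sidecar).
#
# The ENVI dialect is fixed: band-sequential (BSQ), float32 little-endian,
# wavelength units nm. One canonical dialect avoids silent unit or layout
# drift between writers and readers.

envi_paths <- function(path) {
  base <- sub("\\.hdr$", "", sub("\\.raw$", "", path))
  list(hdr = paste0(base, ".hdr"), raw = paste0(base, ".raw"))
}

is_hdf5_path <- function(path) grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)

#' Write a hyperspectral cube to disk
#'
#' Two container formats are supported: ENVI (a text header `.hdr` next to a
#' band-sequential float32 `.raw` binary) and HDF5 (datasets `/data` and
#' `/wavelengths`, attributes `subject_id` / `camera_id`). Both round-trip
#' through [read_cube()] at float32 precision for ENVI and exactly for HDF5.
#'
#' @param cube An [hsi_cube()].
#' @param path Output path. For ENVI, the base name (extensions are added);
#'   for HDF5 a `.h5`/`.hdf5` path.
#' @param format `"envi"` or `"hdf5"`; inferred from `path` when missing.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "hdf5")) {
  validate_hsi_cube(cube)
  if (length(format) > 1L) format <- if (is_hdf5_path(path)) "hdf5" else "envi"
  format <- match.arg(format, c("envi", "hdf5"))
  if (!dir.exists(dirname(path))) {
    abort_hsi(sprintf("directory does not exist: %s", dirname(path)),
              "hsisynth_io_error")
  }
  if (format == "envi") write_cube_envi(cube, path) else write_cube_hdf5(cube, path)
  invisible(path)
}

write_cube_envi <- function(cube, path) {
  p <- envi_paths(path)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {hsisynth hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = nm",
    sprintf("subject id = %s", cube$subject_id),
    if (!is.null(cube$camera_id)) sprintf("camera id = %s", cube$camera_id),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, digits = 15),
                  collapse = ", "))
  )
  writeLines(hdr, p$hdr)
  # BSQ: band-major, each band row-major (line by line). R arrays are
  # column-major, so permute to (W, H, C) before flattening.
  con <- file(p$raw, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(aperm(cube$data, c(2L, 1L, 3L))), con,
           size = 4L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(lines) {
  # collapse {...} continuation blocks onto single logical lines
  joined <- character()
  buf <- ""
  open <- FALSE
  for (ln in lines) {
    if (open) {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { joined <- c(joined, buf); open <- FALSE }
    } else if (grepl("\\{", ln) && !grepl("\\}", ln)) {
      buf <- ln; open <- TRUE
    } else {
      joined <- c(joined, ln)
    }
  }
  kv <- joined[grepl("=", joined)]
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  stats::setNames(as.list(vals), tolower(keys))
}

read_cube_envi <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr) || !file.exists(p$raw)) {
    abort_hsi(sprintf("ENVI pair not found at %s", path), "hsisynth_io_error")
  }
  h <- parse_envi_header(readLines(p$hdr, warn = FALSE))
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(h))) {
    abort_hsi("ENVI header is missing required fields", "hsisynth_format_error")
  }
  W <- as.integer(h$samples); H <- as.integer(h$lines); C <- as.integer(h$bands)
  if (h[["data type"]] != "4") {
    abort_hsi("only float32 (data type 4) ENVI files are supported",
              "hsisynth_format_error")
  }
  if (tolower(h$interleave) != "bsq") {
    abort_hsi("only BSQ interleave is supported", "hsisynth_format_error")
  }
  wl_raw <- h[["wavelength"]]
  if (is.null(wl_raw)) {
    abort_hsi("ENVI header lacks a wavelength block", "hsisynth_format_error")
  }
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (length(wl) != C) {
    abort_hsi(
      sprintf("header lists %d wavelengths for %d bands", length(wl), C),
      "hsisynth_format_error"
    )
  }
  n <- H * W * C
  raw <- readBin(p$raw, "numeric", n = n + 1L, size = 4L, endian = "little")
  if (length(raw) != n) {
    abort_hsi("ENVI binary size does not match header dims",
              "hsisynth_format_error")
  }
  data <- aperm(array(raw, c(W, H, C)), c(2L, 1L, 3L))
  hsi_cube(data, wl,
           subject_id = h[["subject id"]] %||% "unknown",
           camera_id = h[["camera id"]])
}

write_cube_hdf5 <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$data, path, "data")
  rhdf5::h5write(cube$wavelengths, path, "wavelengths")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(cube$subject_id, fid, "subject_id")
  if (!is.null(cube$camera_id)) {
    rhdf5::h5writeAttribute(cube$camera_id, fid, "camera_id")
  }
  invisible(path)
}

read_cube_hdf5 <- function(path) {
  if (!file.exists(path)) {
    abort_hsi(sprintf("file not found: %s", path), "hsisynth_io_error")
  }
  data <- rhdf5::h5read(path, "data")
  wl <- as.numeric(rhdf5::h5read(path, "wavelengths"))
  fid <- rhdf5::H5Fopen(path)
  att <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  if (length(wl) != dim(data)[3]) {
    abort_hsi("wavelength count does not match band count",
              "hsisynth_format_error")
  }
  hsi_cube(data, wl,
           subject_id = as.character(att$subject_id %||% "unknown"),
           camera_id = if (is.null(att$camera_id)) NULL else as.character(att$camera_id))
}

#' Read a hyperspectral cube
#'
#' Counterpart of [write_cube()]; the container format is inferred from the
#' path. All cube invariants are re-validated on read, so corrupt or
#' contradictory files raise classed errors rather than yielding an invalid
#' cube.
#'
#' @param path Path to an ENVI header/binary pair or an HDF5 container.
#' @return An [hsi_cube()].
#' @export
read_cube <- function(path) {
  if (is_hdf5_path(path)) read_cube_hdf5(path) else read_cube_envi(path)
}

#' Write a semantic mask
#'
#' Masks are stored as 8-bit grayscale PNG (label ids as pixel values, so
#' they stay viewable in ordinary image tools) with the legend and optional
#' fill label in a JSON sidecar at `<path>.json`.
#'
#' @param mask A [semantic_mask()]; all label ids must be < 256.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (max(mask$labels) > 255L) {
    abort_hsi("mask label ids must fit 8-bit PNG (< 256)", "hsisynth_validation_error")
  }
  png::writePNG(mask$labels / 255, path)
  side <- list(
    entries = data.frame(id = mask$legend$ids, name = mask$legend$names),
    background_id = mask$legend$background_id
  )
  if (!is.null(mask$fill_label)) side$fill_label <- mask$fill_label
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a semantic mask
#'
#' @param path Path to a `.png` written by [write_mask()]; the JSON legend
#'   sidecar must sit next to it.
#' @return A [semantic_mask()].
#' @export
read_mask <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side_path)) {
    abort_hsi(sprintf("mask or legend sidecar missing at %s", path),
              "hsisynth_io_error")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labels <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  legend <- label_legend(side$entries$id, side$entries$name, side$background_id)
  semantic_mask(labels, legend, fill_label = side$fill_label)
}
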