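# Core data model: hyperspectral cubes, semantic masks, label legends.

#' Construct a hyperspectral cube
#'
#' An `hsi_cube` is an H x W x C array of nonnegative reflectance
#' intensities with a strictly increasing wavelength axis (nm) and subject /
#' camera provenance. At the scale of intraoperative pushbroom cameras a cube
#' is 480 x 640 x 100 with bands from 500 to 1000 nm at 5 nm width, but any
#' (H, W, C) is accepted.
#'
#' @param data Numeric H x W x C array, finite and >= 0.
#' @param wavelengths Numeric vector of length C, strictly increasing, in nm.
#' @param subject_id Character scalar identifying the subject (animal).
#' @param camera_id Optional character scalar identifying the camera.
#' @return An object of class `hsi_cube`.
#' @examples
#' cube <- hsi_cube(array(0.5, c(4, 4, 3)), c(500, 505, 510), "pig01")
#' dim(cube$data)
#' @export
hsi_cube <- function(data, wavelengths, subject_id = "unknown", camera_id = NULL) {
  x <- structure(
    list(
      data = data,
      wavelengths = as.numeric(wavelengths),
      subject_id = as.character(subject_id),
      camera_id = if (is.null(camera_id)) NULL else as.character(camera_id)
    ),
    class = "hsi_cube"
  )
  validate_hsi_cube(x)
}

#' Validate an hsi_cube
#'
#' Checks the cube invariants (3-d array, finite nonnegative values,
#' wavelength axis of matching length and strictly increasing) and raises a
#' classed validation error on the first violation.
#'
#' @param x An `hsi_cube`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_hsi_cube <- function(x) {
  if (!is.array(x$data) || length(dim(x$data)) != 3L) {
    abort_hsi("cube data must be an H x W x C array", "hsisynth_validation_error")
  }
  if (anyNA(x$data) || any(!is.finite(x$data))) {
    abort_hsi("cube data must be finite", "hsisynth_validation_error")
  }
  if (any(x$data < 0)) {
    abort_hsi("cube data must be nonnegative reflectance", "hsisynth_validation_error")
  }
  C <- dim(x$data)[3L]
  if (length(x$wavelengths) != C) {
    abort_hsi(
      sprintf("wavelength axis has length %d but cube has %d bands",
              length(x$wavelengths), C),
      "hsisynth_validation_error"
    )
  }
  if (C > 1L && any(diff(x$wavelengths) <= 0)) {
    abort_hsi("wavelengths must be strictly increasing", "hsisynth_validation_error")
  }
  invisible(x)
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hsi_cube> %d x %d x %d, %g-%g nm, subject %s%s\n",
    d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$subject_id,
    if (is.null(x$camera_id)) "" else paste0(", camera ", x$camera_id)
  ))
  invisible(x)
}

#' Construct a label legend
#'
#' Ordered mapping from integer label ids to class names, with a designated
#' background id (the "blue cloth" class in surgical scenes, id 0 by
#' convention).
#'
#' @param ids Integer vector of unique nonnegative label ids.
#' @param names Character vector of class names, same length as `ids`.
#' @param background_id Integer id of the background class; must be in `ids`.
#' @return An object of class `label_legend`.
#' @examples
#' label_legend(c(0, 1, 2), c("blue cloth", "liver", "stomach"))
#' @export
label_legend <- function(ids, names, background_id = 0L) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) {
    abort_hsi("legend ids must be unique", "hsisynth_validation_error")
  }
  if (any(ids < 0L)) {
    abort_hsi("legend ids must be nonnegative", "hsisynth_validation_error")
  }
  if (length(names) != length(ids)) {
    abort_hsi("legend ids and names differ in length", "hsisynth_validation_error")
  }
  background_id <- as.integer(background_id)
  if (!background_id %in% ids) {
    abort_hsi("background_id must be present in the legend", "hsisynth_validation_error")
  }
  structure(
    list(ids = ids, names = as.character(names), background_id = background_id),
    class = "label_legend"
  )
}

#' @export
print.label_legend <- function(x, ...) {
  cat(sprintf("<label_legend> %d classes (background id %d)\n",
              length(x$ids), x$background_id))
  for (i in seq_along(x$ids)) {
    cat(sprintf("  %3d  %s\n", x$ids[i], x$names[i]))
  }
  invisible(x)
}

#' Construct a semantic segmentation mask
#'
#' An H x W integer label image plus its legend. Used both as the
#' conditioning signal of the diffusion model and as segmentation ground
#' truth. Every label occurring in the image must appear in the legend or
#' equal `fill_label` (the "unused" label assigned to augmentation voids).
#'
#' @param labels Integer H x W matrix of label ids.
#' @param legend A [label_legend()].
#' @param fill_label Optional integer id marking void pixels; must not
#'   collide with any legend id.
#' @return An object of class `semantic_mask`.
#' @examples
#' leg <- label_legend(c(0, 1), c("blue cloth", "liver"))
#' semantic_mask(matrix(c(0L, 1L, 1L, 0L), 2, 2), leg)
#' @export
semantic_mask <- function(labels, legend, fill_label = NULL) {
  if (!is.matrix(labels)) {
    abort_hsi("mask labels must be an H x W matrix", "hsisynth_validation_error")
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) {
    abort_hsi("mask labels must be nonnegative integers", "hsisynth_validation_error")
  }
  if (!inherits(legend, "label_legend")) {
    abort_hsi("legend must be a label_legend", "hsisynth_validation_error")
  }
  if (!is.null(fill_label)) {
    fill_label <- as.integer(fill_label)
    if (fill_label %in% legend$ids) {
      abort_hsi("fill_label must not collide with a legend id", "hsisynth_validation_error")
    }
  }
  present <- unique(as.vector(labels))
  allowed <- c(legend$ids, fill_label)
  bad <- setdiff(present, allowed)
  if (length(bad) > 0L) {
    abort_hsi(
      sprintf("mask contains label id(s) %s absent from the legend",
              paste(bad, collapse = ", ")),
      "hsisynth_validation_error"
    )
  }
  structure(
    list(labels = labels, legend = legend, fill_label = fill_label),
    class = "semantic_mask"
  )
}

#' @export
print.semantic_mask <- function(x, ...) {
  cat(sprintf("<semantic_mask> %d x %d, %d legend classes%s\n",
              nrow(x$labels), ncol(x$labels), length(x$legend$ids),
              if (is.null(x$fill_label)) "" else sprintf(", fill_label %d", x$fill_label)))
  invisible(x)
}

# Cube and mask must share the spatial grid exactly; checked wherever the two
# are paired.
check_paired <- function(cube, mask) {
  d <- dim(cube$data)
  if (d[1] != nrow(mask$labels) || d[2] != ncol(mask$labels)) {
    abort_hsi(
      sprintf("cube (%d x %d) and mask (%d x %d) spatial dims differ",
              d[1], d[2], nrow(mask$labels), ncol(mask$labels)),
      "hsisynth_shape_error"
    )
  }
  invisible(TRUE)
}

#' One-hot encode a semantic mask
#'
#' Expands an H x W label image into an H x W x K binary stack with exactly
#' one 1 per pixel; this is the representation fed to the diffusion model's
#' condition encoder. `argmax` over the K axis recovers the mask.
#'
#' @param mask A [semantic_mask()] or an integer label matrix.
#' @param n_classes Number of channels K; every label id must be < K.
#' @return An H x W x K array of 0/1 values.
#' @examples
#' leg <- label_legend(c(0, 2), c("blue cloth", "liver"))
#' m <- semantic_mask(matrix(c(0L, 2L), 1, 2), leg)
#' one_hot(m, 3)[1, , ]
#' @export
one_hot <- function(mask, n_classes) {
  labels <- if (inherits(mask, "semantic_mask")) mask$labels else mask
  if (!is_count(n_classes)) {
    abort_hsi("n_classes must be a positive integer", "hsisynth_validation_error")
  }
  if (any(labels >= n_classes)) {
    abort_hsi(
      sprintf("label id %d exceeds n_classes - 1 = %d",
              max(labels), n_classes - 1L),
      "hsisynth_validation_error"
    )
  }
  H <- nrow(labels); W <- ncol(labels); K <- as.integer(n_classes)
  oh <- array(0, c(H, W, K))
  # linear index of the single hot channel per pixel
  idx <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H),
               as.vector(labels) + 1L)
  oh[idx] <- 1
  oh
}

#' Recover a label matrix from a one-hot stack
#'
#' Inverse of [one_hot()]: per-pixel argmax over the channel axis. Ties break
#' toward the lowest label id.
#'
#' @param onehot H x W x K numeric array.
#' @return Integer H x W matrix of label ids (0-based).
#' @export
onehot_argmax <- function(onehot) {
  d <- dim(onehot)
  flat <- matrix(onehot, d[1] * d[2], d[3])
  matrix(max.col(flat, ties.method = "first") - 1L, d[1], d[2])
}
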