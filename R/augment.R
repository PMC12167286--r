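# Augmentation pipeline for diffusion training (rescaling, rotation, random
# crop, random flipping, label dropout) and the OoD-mask preprocessing used
# for cross-modality conditioning.
#
# Cube and mask always receive the identical geometric transform: linear
# interpolation for the cube, nearest-neighbor for the mask. Pixels with no
# source (rotation/rescale voids) are set to a new, unused fill label in the
# mask (max legend id + 1) and to 0 in the cube.

#' Augmentation configuration
#'
#' @param rescale_range Length-2 multiplicative rescale range.
#' @param rotation_range Length-2 rotation range in degrees.
#' @param crop_size Optional `c(h, w)` random-crop size; `NULL` keeps the
#'   full frame.
#' @param flip_prob Probability of a horizontal flip.
#' @param label_dropout_prob Per-class probability of label dropout.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rescale_range = c(0.9, 1.1),
                           rotation_range = c(-15, 15),
                           crop_size = NULL,
                           flip_prob = 0.5,
                           label_dropout_prob = 0) {
  if (flip_prob < 0 || flip_prob > 1 || label_dropout_prob < 0 ||
      label_dropout_prob > 1) {
    abort_hsi("probabilities must be in [0, 1]", "hsisynth_config_error")
  }
  if (rescale_range[1] > rescale_range[2] || rescale_range[1] <= 0) {
    abort_hsi("invalid rescale_range", "hsisynth_config_error")
  }
  structure(
    list(rescale_range = rescale_range, rotation_range = rotation_range,
         crop_size = crop_size, flip_prob = flip_prob,
         label_dropout_prob = label_dropout_prob),
    class = "augment_config"
  )
}

next_free_label <- function(legend) max(legend$ids) + 1L

# Inverse-mapped affine sampler shared by cube (bilinear) and mask
# (nearest). Transform: flip, then rescale + rotate about the frame center,
# then crop with offset. Returns source coordinates per target pixel and an
# in-support mask.
affine_grid <- function(H, W, out_hw, scale, angle_deg, flip_h, crop_off) {
  Ho <- out_hw[1]; Wo <- out_hw[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  coy <- (Ho + 1) / 2; cox <- (Wo + 1) / 2
  ty <- rep(seq_len(Ho), Wo) - coy + crop_off[1]
  tx <- rep(seq_len(Wo), each = Ho) - cox + crop_off[2]
  th <- angle_deg * pi / 180
  # inverse of (rotate by th, scale by s): rotate by -th, scale by 1/s
  sy <- (cos(th) * ty - sin(th) * tx) / scale + cy
  sx <- (sin(th) * ty + cos(th) * tx) / scale + cx
  if (flip_h) sx <- W + 1 - sx
  inside <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  list(sy = sy, sx = sx, inside = inside, Ho = Ho, Wo = Wo)
}

warp_mask <- function(labels, grid, fill_label) {
  out <- rep(as.integer(fill_label), grid$Ho * grid$Wo)
  ri <- pmin(pmax(round(grid$sy), 1L), nrow(labels))
  ci <- pmin(pmax(round(grid$sx), 1L), ncol(labels))
  idx <- (ci - 1L) * nrow(labels) + ri
  out[grid$inside] <- labels[idx[grid$inside]]
  matrix(out, grid$Ho, grid$Wo)
}

warp_cube <- function(data, grid) {
  H <- dim(data)[1]; W <- dim(data)[2]; C <- dim(data)[3]
  y0 <- pmin(pmax(floor(grid$sy), 1L), H)
  x0 <- pmin(pmax(floor(grid$sx), 1L), W)
  y1 <- pmin(y0 + 1L, H)
  x1 <- pmin(x0 + 1L, W)
  fy <- pmin(pmax(grid$sy - y0, 0), 1)
  fx <- pmin(pmax(grid$sx - x0, 0), 1)
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx); w11 <- fy * fx
  flat <- matrix(data, H * W, C)
  i00 <- (x0 - 1L) * H + y0; i01 <- (x1 - 1L) * H + y0
  i10 <- (x0 - 1L) * H + y1; i11 <- (x1 - 1L) * H + y1
  out <- w00 * flat[i00, , drop = FALSE] + w01 * flat[i01, , drop = FALSE] +
    w10 * flat[i10, , drop = FALSE] + w11 * flat[i11, , drop = FALSE]
  out[!grid$inside, ] <- 0
  array(out, c(grid$Ho, grid$Wo, C))
}

#' Jointly augment a cube/mask pair
#'
#' Samples one geometric transform (rescale, rotation, optional random crop,
#' horizontal flip) from `config` under `seed` and applies it identically to
#' both: bilinear interpolation for the cube, nearest-neighbor for the mask.
#' Void pixels get `fill_label` (a new id = max legend id + 1) in the mask
#' and 0 in the cube. Label dropout, if enabled, is applied afterwards.
#'
#' @param cube An [hsi_cube()].
#' @param mask The paired [semantic_mask()].
#' @param config An [augment_config()].
#' @param seed Integer seed; the pair transform is deterministic given it.
#' @return List with augmented `cube` and `mask` (the mask carries the fill
#'   label).
#' @export
augment_pair <- function(cube, mask, config = augment_config(), seed = 1L) {
  check_paired(cube, mask)
  H <- nrow(mask$labels); W <- ncol(mask$labels)
  fill <- mask$fill_label %||% next_free_label(mask$legend)
  with_seed(seed, {
    scale <- stats::runif(1, config$rescale_range[1], config$rescale_range[2])
    angle <- stats::runif(1, config$rotation_range[1], config$rotation_range[2])
    flip <- stats::runif(1) < config$flip_prob
    out_hw <- config$crop_size %||% c(H, W)
    if (any(out_hw > c(H, W))) {
      abort_hsi("crop_size exceeds image dims", "hsisynth_config_error")
    }
    max_off <- (c(H, W) - out_hw) / 2
    crop_off <- c(stats::runif(1, -max_off[1], max_off[1]),
                  stats::runif(1, -max_off[2], max_off[2]))
    grid <- affine_grid(H, W, out_hw, scale, angle, flip, crop_off)
    labels2 <- warp_mask(mask$labels, grid, fill)
    data2 <- warp_cube(cube$data, grid)
    mask2 <- semantic_mask(labels2, mask$legend, fill_label = fill)
    if (config$label_dropout_prob > 0) {
      mask2 <- label_dropout(mask2, config$label_dropout_prob,
                             seed = derive_seed(seed, 77))
    }
    list(
      cube = hsi_cube(pmax(data2, 0), cube$wavelengths,
                      subject_id = cube$subject_id, camera_id = cube$camera_id),
      mask = mask2
    )
  })
}

#' Label dropout
#'
#' Each non-background class present in the mask is independently, with
#' probability `p`, replaced by the fill label over its whole region.
#' Region-level (not per-pixel) dropout keeps the remaining mask plausible
#' as a scene annotation.
#'
#' @param mask A [semantic_mask()].
#' @param p Drop probability per class.
#' @param seed Integer seed.
#' @return The mask with dropped classes set to its fill label.
#' @export
label_dropout <- function(mask, p, seed = 1L) {
  if (p < 0 || p > 1) {
    abort_hsi("p must be in [0, 1]", "hsisynth_config_error")
  }
  fill <- mask$fill_label %||% next_free_label(mask$legend)
  bg <- mask$legend$background_id
  present <- setdiff(unique(as.vector(mask$labels)), c(bg, fill))
  labels <- mask$labels
  with_seed(seed, {
    for (k in sort(present)) {
      if (stats::runif(1) < p) labels[labels == k] <- as.integer(fill)
    }
  })
  semantic_mask(labels, mask$legend, fill_label = fill)
}

#' Reassign out-of-distribution labels to background
#'
#' Conditioning masks obtained from other modalities may carry labels the
#' generative model was never trained on; every label absent from
#' `known_legend` is reassigned to its background class (the "blue cloth"
#' label). Idempotent.
#'
#' @param mask A [semantic_mask()] (its own legend may be wider).
#' @param known_legend The [label_legend()] of the training distribution.
#' @return A [semantic_mask()] over `known_legend`.
#' @export
reassign_ood_labels <- function(mask, known_legend) {
  labels <- mask$labels
  unknown <- !(labels %in% known_legend$ids)
  labels[unknown] <- known_legend$background_id
  semantic_mask(labels, known_legend)
}
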