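# Validation suite: l1-normalized spectral agreement with hierarchical
# (subject-first) aggregation, Dice and normalized surface distance,
# subject-level bootstrap confidence intervals on model differences, and RGB
# reconstruction from hyperspectral cubes.
#
# Metric results are tidy tibbles with one record per (image, subject,
# class, metric); undefined records (class absent from both masks) carry NA
# and are excluded from aggregation, never zero-filled.

#' Evaluation configuration
#'
#' @param nsd_tolerance Boundary tolerance tau of the normalized surface
#'   distance, in pixels (default 2 at phantom scale).
#' @param n_bootstrap Bootstrap replicates (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed for resampling.
#' @return An `eval_config` list.
#' @export
eval_config <- function(nsd_tolerance = 2, n_bootstrap = 1000L,
                        ci_level = 0.95, seed = 1L) {
  if (nsd_tolerance < 0) {
    abort_hsi("nsd_tolerance must be >= 0", "hsisynth_config_error")
  }
  if (ci_level <= 0 || ci_level >= 1) {
    abort_hsi("ci_level must be in (0, 1)", "hsisynth_config_error")
  }
  structure(
    list(nsd_tolerance = nsd_tolerance, n_bootstrap = as.integer(n_bootstrap),
         ci_level = ci_level, seed = as.integer(seed)),
    class = "eval_config"
  )
}

#' l1-normalize a spectrum
#'
#' Divides by the sum of absolute band values so spectral shape can be
#' compared independently of intensity (gain, illumination).
#'
#' @param spectrum Numeric vector.
#' @return Normalized vector summing (in absolute value) to 1, or all-NA for
#'   an all-zero input.
#' @examples
#' l1_normalize(c(2, 2, 4))
#' @export
l1_normalize <- function(spectrum) {
  s <- sum(abs(spectrum))
  if (s == 0) return(rep(NA_real_, length(spectrum)))
  spectrum / s
}

scene_field <- function(scene, what) {
  if (what == "cube") {
    if (inherits(scene, "hsi_cube")) scene else scene$cube
  } else {
    if (inherits(scene, "semantic_mask")) scene else scene$mask
  }
}

# Median l1-normalized pixel spectrum of one class in one scene, or NULL.
image_class_spectrum <- function(scene, class_id, min_pixels = 1L) {
  cube <- scene_field(scene, "cube")
  mask <- scene_field(scene, "mask")
  px <- which(mask$labels == class_id)
  if (length(px) < min_pixels) return(NULL)
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])[px, , drop = FALSE]
  rs <- rowSums(abs(X))
  keep <- rs > 0
  if (!any(keep)) return(NULL)
  Xn <- X[keep, , drop = FALSE] / rs[keep]
  apply(Xn, 2, stats::median)
}

#' Hierarchically aggregated class spectrum
#'
#' Per image: the median l1-normalized pixel spectrum over the class pixels.
#' Per subject: the mean of its image spectra. Across subjects: mean and
#' standard deviation of the subject spectra (std is NA with a single
#' subject).
#'
#' @param dataset List of scenes `list(cube, mask, subject_id)`.
#' @param class_id Integer label id.
#' @return List with `median` (the across-subject mean spectrum),
#'   `subject_means` (matrix subjects x bands), `sd` (across-subject std per
#'   band), or `NULL` if the class is absent from every image.
#' @export
class_spectrum <- function(dataset, class_id) {
  subj <- vapply(dataset, function(s) s$subject_id %||% "s1", "")
  specs <- lapply(dataset, image_class_spectrum, class_id = class_id)
  keep <- !vapply(specs, is.null, TRUE)
  if (!any(keep)) return(NULL)
  m <- do.call(rbind, specs[keep])
  by_subj <- rowsum(m, subj[keep]) / as.vector(table(subj[keep])[sort(unique(subj[keep]))])
  list(
    median = colMeans(by_subj),
    subject_means = by_subj,
    sd = if (nrow(by_subj) > 1) apply(by_subj, 2, stats::sd) else
      rep(NA_real_, ncol(by_subj))
  )
}

#' Spectral agreement between two datasets
#'
#' l1 distance between the hierarchically aggregated median class spectra of
#' two datasets (typically real vs generated). Symmetric; 0 for a dataset
#' against itself.
#'
#' @param real_dataset,synth_dataset Scene lists.
#' @param class_id Integer label id.
#' @return Nonnegative scalar, or NA if the class is absent from either.
#' @export
spectral_agreement <- function(real_dataset, synth_dataset, class_id) {
  a <- class_spectrum(real_dataset, class_id)
  b <- class_spectrum(synth_dataset, class_id)
  if (is.null(a) || is.null(b)) return(NA_real_)
  sum(abs(a$median - b$median))
}

#' Dice similarity coefficient
#'
#' `2 |P intersect G| / (|P| + |G|)` for one class; NA (undefined, excluded
#' from aggregation) when the class is absent from both masks.
#'
#' @param pred_mask,gt_mask Integer label matrices or [semantic_mask()]s of
#'   equal shape.
#' @param class_id Integer label id.
#' @return Value in \[0, 1\] or NA.
#' @export
dsc <- function(pred_mask, gt_mask, class_id) {
  p <- if (inherits(pred_mask, "semantic_mask")) pred_mask$labels else pred_mask
  g <- if (inherits(gt_mask, "semantic_mask")) gt_mask$labels else gt_mask
  if (!all(dim(p) == dim(g))) {
    abort_hsi("mask shapes differ", "hsisynth_shape_error")
  }
  P <- p == class_id
  G <- g == class_id
  denom <- sum(P) + sum(G)
  if (denom == 0) return(NA_real_)
  2 * sum(P & G) / denom
}

# Boundary pixels of a binary region: 8-connectivity, and region pixels on
# the image border count as boundary.
region_boundary <- function(R) {
  H <- nrow(R); W <- ncol(R)
  if (!any(R)) return(matrix(numeric(0), 0, 2))
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- R
  sub <- function(dy, dx) pad[dy + seq_len(H), dx + seq_len(W), drop = FALSE]
  nb_all <- sub(0, 0) & sub(0, 1) & sub(0, 2) &
    sub(1, 0) & sub(1, 2) &
    sub(2, 0) & sub(2, 1) & sub(2, 2)
  b <- sub(1, 1) & !nb_all  # padding is FALSE, so border region pixels qualify
  which(b, arr.ind = TRUE)
}

min_dists <- function(A, B) {
  # per row of A, Euclidean distance to the nearest row of B
  if (nrow(B) == 0) return(rep(Inf, nrow(A)))
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Normalized surface distance
#'
#' Fraction of boundary pixels of prediction and ground truth lying within
#' tolerance `tau` (Euclidean pixel distance) of the other boundary.
#' Boundaries use 8-connectivity and image-border region pixels count as
#' boundary; NA when both boundaries are empty.
#'
#' @param pred_mask,gt_mask Label matrices or [semantic_mask()]s.
#' @param class_id Integer label id.
#' @param tau Tolerance in pixels (>= 0).
#' @return Value in \[0, 1\] or NA.
#' @export
nsd <- function(pred_mask, gt_mask, class_id, tau = 2) {
  p <- if (inherits(pred_mask, "semantic_mask")) pred_mask$labels else pred_mask
  g <- if (inherits(gt_mask, "semantic_mask")) gt_mask$labels else gt_mask
  if (!all(dim(p) == dim(g))) {
    abort_hsi("mask shapes differ", "hsisynth_shape_error")
  }
  if (tau < 0) abort_hsi("tau must be >= 0", "hsisynth_config_error")
  bp <- region_boundary(p == class_id)
  bg <- region_boundary(g == class_id)
  if (nrow(bp) == 0 && nrow(bg) == 0) return(NA_real_)
  hits <- sum(min_dists(bp, bg) <= tau) + sum(min_dists(bg, bp) <= tau)
  hits / (nrow(bp) + nrow(bg))
}

#' Build a tidy metric-record table for one test set
#'
#' Computes DSC and NSD per image and class and returns one row per
#' (image, subject, class, metric) — the long format every aggregation and
#' bootstrap function in the package consumes.
#'
#' @param preds List of predicted label matrices (or `semantic_mask`s).
#' @param dataset List of ground-truth scenes `list(cube, mask, subject_id)`.
#' @param class_ids Integer ids to score.
#' @param config An [eval_config()] (for the NSD tolerance).
#' @return A tibble with columns `image_id`, `subject_id`, `class_id`,
#'   `metric`, `value`.
#' @export
metric_records <- function(preds, dataset, class_ids, config = eval_config()) {
  rows <- purrr::imap(dataset, function(scene, i) {
    gt <- scene_field(scene, "mask")
    pr <- preds[[i]]
    purrr::map(class_ids, function(k) {
      tibble::tibble(
        image_id = sprintf("img%03d", i),
        subject_id = scene$subject_id %||% "s1",
        class_id = as.integer(k),
        metric = c("DSC", "NSD"),
        value = c(dsc(pr, gt, k), nsd(pr, gt, k, tau = config$nsd_tolerance))
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Hierarchical metric aggregation
#'
#' The subject-first average: per class and metric, first the mean metric
#' value within each subject, then the average of these subject means.
#' Undefined (NA) records are excluded before averaging, so subjects with
#' many images carry no extra weight and absent classes introduce no zeros.
#'
#' @param records A tibble as produced by [metric_records()].
#' @return A tibble with `class_id`, `metric`, `value`, `n_subjects`.
#' @export
hierarchical_aggregate <- function(records) {
  if (nrow(records) == 0L) {
    abort_hsi("records is empty", "hsisynth_validation_error")
  }
  records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$class_id, .data$metric, .data$subject_id) |>
    dplyr::summarise(subject_mean = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$class_id, .data$metric) |>
    dplyr::summarise(value = mean(.data$subject_mean),
                     n_subjects = dplyr::n(), .groups = "drop")
}

# Subject-mean matrix [subject x (class, metric)] used by the bootstrap.
subject_mean_matrix <- function(records, subjects, cells) {
  sm <- records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$class_id, .data$metric, .data$subject_id) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  M <- matrix(NA_real_, length(subjects), nrow(cells),
              dimnames = list(subjects, NULL))
  for (j in seq_len(nrow(cells))) {
    sj <- sm[sm$class_id == cells$class_id[j] & sm$metric == cells$metric[j], ]
    M[match(sj$subject_id, subjects), j] <- sj$m
  }
  M
}

#' Bootstrap CI on the metric difference between two models
#'
#' Resamples subjects with replacement (jointly for both record sets, since
#' both models are scored on the same test subjects), recomputes the
#' hierarchical aggregate of A minus B per replicate, and returns the
#' percentile interval per class and metric plus a pooled row (mean over
#' classes).
#'
#' @param records_a,records_b Metric tibbles from [metric_records()] for
#'   models A and B on the same test set.
#' @param config An [eval_config()].
#' @return A tibble with `class_id` (NA for the pooled row), `metric`,
#'   `estimate`, `low`, `high`.
#' @export
bootstrap_ci_difference <- function(records_a, records_b,
                                    config = eval_config()) {
  subjects <- sort(unique(c(records_a$subject_id, records_b$subject_id)))
  S <- length(subjects)
  if (S < 2L) {
    warning("fewer than 2 subjects: bootstrap CI undefined")
    return(tibble::tibble(class_id = NA_integer_, metric = NA_character_,
                          estimate = NA_real_, low = NA_real_, high = NA_real_))
  }
  cells <- dplyr::distinct(
    dplyr::bind_rows(records_a, records_b)[, c("class_id", "metric")]
  ) |> dplyr::arrange(.data$class_id, .data$metric)
  MA <- subject_mean_matrix(records_a, subjects, cells)
  MB <- subject_mean_matrix(records_b, subjects, cells)
  # cells with no defined record anywhere (class absent from the test set)
  # are dropped rather than reported as NaN
  keep <- colSums(!is.na(MA)) > 0 | colSums(!is.na(MB)) > 0
  cells <- cells[keep, , drop = FALSE]
  MA <- MA[, keep, drop = FALSE]
  MB <- MB[, keep, drop = FALSE]
  B <- config$n_bootstrap
  idx <- with_seed(config$seed,
                   matrix(sample.int(S, S * B, replace = TRUE), B, S))
  alpha <- (1 - config$ci_level) / 2
  out <- vector("list", nrow(cells) + 1L)
  diffs_all <- matrix(0, B, nrow(cells))
  est_all <- numeric(nrow(cells))
  for (j in seq_len(nrow(cells))) {
    a <- MA[, j]; b <- MB[, j]
    da <- matrix(a[idx], B, S)
    db <- matrix(b[idx], B, S)
    dj <- rowMeans(da, na.rm = TRUE) - rowMeans(db, na.rm = TRUE)
    diffs_all[, j] <- dj
    est_all[j] <- mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
    q <- stats::quantile(dj, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    out[[j]] <- tibble::tibble(class_id = cells$class_id[j],
                               metric = cells$metric[j],
                               estimate = est_all[j], low = q[1], high = q[2])
  }
  # pooled: per replicate, mean over classes within metric
  pooled <- lapply(unique(cells$metric), function(mt) {
    cols <- which(cells$metric == mt)
    dp <- rowMeans(diffs_all[, cols, drop = FALSE], na.rm = TRUE)
    q <- stats::quantile(dp, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    tibble::tibble(class_id = NA_integer_, metric = mt,
                   estimate = mean(est_all[cols], na.rm = TRUE),
                   low = q[1], high = q[2])
  })
  dplyr::bind_rows(c(out[seq_len(nrow(cells))], pooled))
}

#' Reconstruct an RGB preview from a hyperspectral cube
#'
#' Each channel averages reflectance over a wavelength window (defaults
#' R: 620-650 nm, G: 540-570 nm, B: 500-520 nm), the three channels are
#' jointly max-normalized and gamma-corrected (1/2.2). The windows are a
#' pragmatic band-integration stand-in — the sensor starts at 500 nm, so no
#' true colorimetric blue exists; previews are for visual inspection only.
#'
#' @param cube An [hsi_cube()].
#' @param windows Named list of `c(lo, hi)` nm windows for `r`, `g`, `b`.
#' @return H x W x 3 array in \[0, 1\].
#' @export
rgb_reconstruction <- function(cube,
                               windows = list(r = c(620, 650),
                                              g = c(540, 570),
                                              b = c(500, 520))) {
  wl <- cube$wavelengths
  chans <- lapply(windows, function(w) {
    sel <- wl >= w[1] & wl <= w[2]
    if (!any(sel)) {
      abort_hsi("RGB window lies outside the wavelength range",
                "hsisynth_config_error")
    }
    apply(cube$data[, , sel, drop = FALSE], c(1, 2), mean)
  })
  arr <- array(c(chans$r, chans$g, chans$b), c(dim(cube$data)[1:2], 3))
  mx <- max(arr)
  if (mx > 0) arr <- arr / mx
  arr^(1 / 2.2)
}
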