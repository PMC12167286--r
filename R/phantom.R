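# Synthetic hyperspectral phantoms: labeled scenes with the statistical
# structure of surgical HSI data (smooth per-class reflectance spectra with
# absorption dips, a background cloth class, several images per subject with
# a shared subject gain, smooth illumination, multiplicative + additive
# noise, and geometric out-of-distribution variants).

#' Phantom generator configuration
#'
#' Bundles every knob of the phantom scene generator. The defaults are the
#' package's reference study conditions: 5 subjects with 4 images each,
#' 64 x 64 scenes with 50 bands on 500-1000 nm, up to 3 organ blobs per
#' image, 5% multiplicative and 0.01 additive noise, a 10% illumination
#' gradient, and a log-normal subject gain with sigma 0.15.
#'
#' @param n_subjects Number of subjects (animals).
#' @param images_per_subject Images acquired per subject.
#' @param H,W,C Scene height, width and number of spectral bands.
#' @param n_organs Number of distinct organ classes in the library.
#' @param classes_per_image Length-2 integer range of organ blobs per scene.
#' @param sigma_m Multiplicative noise std (relative).
#' @param sigma_a Additive noise std (reflectance units).
#' @param illum_amp Amplitude of the linear illumination gradient.
#' @param gain_sigma Log-normal sigma of the per-subject gain.
#' @param blur_sigma Gaussian blur sigma (pixels) for `ood_mode = "blur"`.
#' @param ood_mode One of `"none"`, `"occlusion"`, `"isolation"`, `"blur"`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_subjects = 5, images_per_subject = 4,
                           H = 64, W = 64, C = 50,
                           n_organs = 4, classes_per_image = NULL,
                           sigma_m = 0.05, sigma_a = 0.01,
                           illum_amp = 0.10, gain_sigma = 0.15,
                           blur_sigma = 1.5,
                           ood_mode = c("none", "occlusion", "isolation", "blur"),
                           seed = 1L) {
  ood_mode <- match.arg(ood_mode)
  for (v in c(n_subjects, images_per_subject, H, W, C, n_organs)) {
    if (!is_count(v)) {
      abort_hsi("phantom counts must be positive integers", "hsisynth_config_error")
    }
  }
  if (sigma_m < 0 || sigma_a < 0) {
    abort_hsi("noise sigmas must be nonnegative", "hsisynth_config_error")
  }
  if (is.null(classes_per_image)) classes_per_image <- c(1, min(3, n_organs))
  if (length(classes_per_image) != 2L || classes_per_image[1] > classes_per_image[2] ||
      classes_per_image[1] < 1L || classes_per_image[2] > n_organs) {
    abort_hsi("classes_per_image must be a valid range within 1..n_organs",
              "hsisynth_config_error")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      images_per_subject = as.integer(images_per_subject),
      H = as.integer(H), W = as.integer(W), C = as.integer(C),
      n_organs = as.integer(n_organs),
      classes_per_image = as.integer(classes_per_image),
      sigma_m = sigma_m, sigma_a = sigma_a,
      illum_amp = illum_amp, gain_sigma = gain_sigma,
      blur_sigma = blur_sigma, ood_mode = ood_mode,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

l1_norm_rows <- function(m) m / rowSums(abs(m))

draw_spectrum <- function(u) {
  # smooth baseline (linear ramp) minus 1-3 Gaussian absorption dips
  a <- stats::runif(1, 0.45, 0.80)
  b <- stats::runif(1, -0.25, 0.35)
  s <- a + b * u
  for (j in seq_len(sample(1:3, 1))) {
    ctr <- stats::runif(1, 0.1, 0.9)
    wid <- stats::runif(1, 0.04, 0.12)
    dep <- stats::runif(1, 0.15, 0.45) * a
    s <- s - dep * exp(-(u - ctr)^2 / (2 * wid^2))
  }
  pmax(s, 0.02)
}

#' Generate a spectral reference library
#'
#' Draws one smooth reference reflectance spectrum per class (a linear
#' baseline minus 1-3 Gaussian absorption dips at class-specific centers).
#' Classes are redrawn until every pair of l1-normalized spectra is at least
#' `min_separation` apart, so rendered classes remain spectrally decodable.
#' Class 1 is the background cloth; the last class is an occluder
#' (hand/instrument material) used only by occlusion phantoms.
#'
#' @param n_classes Total number of classes (>= 2, including background).
#' @param n_bands Number of spectral bands (>= 8).
#' @param seed Integer seed; output is deterministic given it.
#' @param wavelengths Optional wavelength axis; default 500-1000 nm.
#' @param min_separation Pairwise normalized-l1 separation floor.
#' @param max_retries Redraw budget before a generation error.
#' @return A `spectral_library`: list with `spectra` (K x C), `wavelengths`,
#'   `class_names`.
#' @examples
#' lib <- make_spectral_library(3, 50, seed = 1)
#' matplot(lib$wavelengths, t(lib$spectra), type = "l")
#' @export
make_spectral_library <- function(n_classes, n_bands, seed,
                                  wavelengths = NULL,
                                  min_separation = 0.05,
                                  max_retries = 50L) {
  if (!is_count(n_classes) || n_classes < 2) {
    abort_hsi("n_classes must be >= 2", "hsisynth_config_error")
  }
  if (!is_count(n_bands) || n_bands < 8) {
    abort_hsi("n_bands must be >= 8", "hsisynth_config_error")
  }
  if (is.null(wavelengths)) wavelengths <- seq(500, 1000, length.out = n_bands)
  u <- (wavelengths - min(wavelengths)) / diff(range(wavelengths))
  spectra <- with_seed(seed, {
    s <- t(vapply(seq_len(n_classes), function(k) draw_spectrum(u),
                  numeric(n_bands)))
    tries <- 0L
    repeat {
      nrm <- l1_norm_rows(s)
      d <- as.matrix(stats::dist(nrm, method = "manhattan"))
      diag(d) <- Inf
      bad <- which(apply(d, 1, min) < min_separation)
      if (length(bad) == 0L) break
      tries <- tries + 1L
      if (tries > max_retries) {
        abort_hsi("could not reach spectral separation floor",
                  "hsisynth_generation_error")
      }
      # redraw only the most crowded class
      worst <- bad[which.min(apply(d, 1, min)[bad])]
      s[worst, ] <- draw_spectrum(u)
    }
    s
  })
  names_k <- c("blue cloth",
               paste0("organ_", seq_len(max(0, n_classes - 2))),
               if (n_classes >= 2) "occluder")
  structure(
    list(spectra = spectra, wavelengths = wavelengths,
         class_names = names_k[seq_len(n_classes)]),
    class = "spectral_library"
  )
}

library_legend <- function(library, include_occluder = TRUE) {
  K <- nrow(library$spectra)
  ids <- seq_len(K) - 1L
  if (!include_occluder) {
    keep <- seq_len(K - 1L)
    return(label_legend(ids[keep], library$class_names[keep], 0L))
  }
  label_legend(ids, library$class_names, 0L)
}

occluder_id <- function(library) nrow(library$spectra) - 1L

# Rasterize a Fourier-perturbed ellipse into a logical H x W matrix.
blob_region <- function(H, W, cx, cy, rx, ry, phi, eps, psi) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  dx <- xs - cx; dy <- ys - cy
  dxr <- cos(phi) * dx + sin(phi) * dy
  dyr <- -sin(phi) * dx + cos(phi) * dy
  r <- sqrt((dxr / rx)^2 + (dyr / ry)^2)
  th <- atan2(dyr, dxr)
  bound <- 1
  for (m in seq_along(eps)) bound <- bound + eps[m] * cos((m + 1) * th + psi[m])
  r <= pmax(bound, 0.2)
}

random_blob <- function(H, W, min_frac = 0.10, max_frac = 0.30) {
  cx <- stats::runif(1, 0.25 * W, 0.75 * W)
  cy <- stats::runif(1, 0.25 * H, 0.75 * H)
  rx <- stats::runif(1, min_frac, max_frac) * W
  ry <- stats::runif(1, min_frac, max_frac) * H
  phi <- stats::runif(1, 0, pi)
  eps <- stats::runif(3, 0, 0.15)
  psi <- stats::runif(3, 0, 2 * pi)
  blob_region(H, W, cx, cy, rx, ry, phi, eps, psi)
}

# Multi-lobed "hand" (palm + finger lobes) or elongated "instrument" shape.
occluder_region <- function(H, W) {
  if (stats::runif(1) < 0.5) {
    cx <- stats::runif(1, 0.3 * W, 0.7 * W)
    cy <- stats::runif(1, 0.3 * H, 0.7 * H)
    r0 <- stats::runif(1, 0.12, 0.2) * min(H, W)
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    th <- atan2(ys - cy, xs - cx)
    r <- sqrt((xs - cx)^2 + (ys - cy)^2)
    lobes <- stats::runif(1, 0.3, 0.5) * cos(5 * th + stats::runif(1, 0, 2 * pi))
    r <= r0 * (1.2 + pmax(lobes, 0))
  } else {
    # rotated elongated rectangle
    cx <- stats::runif(1, 0.3 * W, 0.7 * W)
    cy <- stats::runif(1, 0.3 * H, 0.7 * H)
    len <- stats::runif(1, 0.5, 0.9) * min(H, W)
    wid <- stats::runif(1, 0.06, 0.12) * min(H, W)
    phi <- stats::runif(1, 0, pi)
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    dxr <- cos(phi) * (xs - cx) + sin(phi) * (ys - cy)
    dyr <- -sin(phi) * (xs - cx) + cos(phi) * (ys - cy)
    abs(dxr) <= len / 2 & abs(dyr) <= wid / 2
  }
}

# Row-normalized truncated-Gaussian smoothing matrix (edges renormalized).
gauss_smoother <- function(n, sigma) {
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  Smat <- exp(-d^2 / (2 * sigma^2))
  Smat[abs(d) > ceiling(3 * sigma)] <- 0
  Smat / rowSums(Smat)
}

gauss_blur_cube <- function(data, sigma) {
  d <- dim(data)
  Sh <- gauss_smoother(d[1], sigma)
  Sw <- gauss_smoother(d[2], sigma)
  out <- data
  for (b in seq_len(d[3])) out[, , b] <- Sh %*% data[, , b] %*% t(Sw)
  out
}

#' Render one labeled phantom scene
#'
#' Composes a mask of background plus random smooth organ blobs (low-order
#' Fourier perturbations of ellipses) and renders each pixel's spectrum as
#' class reference x subject gain x smooth illumination x (1 + N(0, sigma_m^2))
#' + N(0, sigma_a^2), clipped at zero. OoD modes overlay a hand/instrument
#' occluder, isolate a single organ, or blur the cube spatially.
#'
#' @param library A [make_spectral_library()] output with C = `config$C` bands.
#' @param config A [phantom_config()].
#' @param subject_id Subject identifier stored in the cube.
#' @param seed Integer seed; the scene is deterministic given it.
#' @param gain Per-subject multiplicative gain; drawn log-normally when `NULL`.
#' @return A list with elements `cube` ([hsi_cube()]) and `mask`
#'   ([semantic_mask()]).
#' @export
render_scene <- function(library, config, subject_id = "S1", seed = 1L,
                         gain = NULL) {
  C <- ncol(library$spectra)
  if (C != config$C) {
    abort_hsi("library band count does not match config$C", "hsisynth_shape_error")
  }
  K <- nrow(library$spectra)
  organ_ids <- seq_len(K - 2L)  # ids 1..n_organs (0 background, K-1 occluder)
  if (config$n_organs != length(organ_ids)) {
    abort_hsi("library class count does not match config$n_organs + 2",
              "hsisynth_config_error")
  }
  H <- config$H; W <- config$W
  with_seed(seed, {
    if (is.null(gain)) gain <- stats::rlnorm(1, 0, config$gain_sigma)
    rng <- config$classes_per_image
    n_blobs <- if (rng[1] == rng[2]) rng[1] else {
      rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    }
    classes <- organ_ids[sample.int(length(organ_ids), n_blobs)]
    labels <- matrix(0L, H, W)
    for (k in classes) {
      placed <- FALSE
      for (try in 1:8) {
        reg <- random_blob(H, W)
        # keep earlier classes from being wiped out entirely
        prev <- labels[reg]
        cand <- labels
        cand[reg] <- k
        survivors <- setdiff(unique(prev), 0L)
        if (sum(reg) > 0 && all(vapply(survivors, function(s) any(cand == s), TRUE))) {
          labels <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort_hsi("failed to place a phantom organ blob", "hsisynth_generation_error")
      }
    }
    if (config$ood_mode == "isolation") {
      keep <- classes[1]
      labels[labels != 0L & labels != keep] <- 0L
    }
    if (config$ood_mode == "occlusion") {
      occ <- occluder_region(H, W)
      labels[occ] <- occluder_id(library)
    }
    # illumination: linear gradient of amplitude illum_amp, mean ~ 1
    dir <- stats::runif(1, 0, 2 * pi)
    xn <- matrix(rep(seq_len(W), each = H), H, W) / W - 0.5
    yn <- matrix(rep(seq_len(H), W), H, W) / H - 0.5
    illum <- 1 + config$illum_amp * 2 * (cos(dir) * xn + sin(dir) * yn)
    ref <- library$spectra[as.vector(labels) + 1L, , drop = FALSE]  # (H*W) x C
    scale <- gain * as.vector(illum)
    n <- length(scale)
    noise_m <- if (config$sigma_m > 0) {
      1 + matrix(stats::rnorm(n * C, 0, config$sigma_m), n, C)
    } else 1
    noise_a <- if (config$sigma_a > 0) {
      matrix(stats::rnorm(n * C, 0, config$sigma_a), n, C)
    } else 0
    px <- ref * scale * noise_m + noise_a
    data <- array(pmax(px, 0), c(H, W, C))
    if (config$ood_mode == "blur") data <- gauss_blur_cube(data, config$blur_sigma)
    legend <- library_legend(library)
    list(
      cube = hsi_cube(data, library$wavelengths, subject_id = subject_id),
      mask = semantic_mask(labels, legend)
    )
  })
}

#' Generate a hierarchical phantom dataset
#'
#' Renders `n_subjects x images_per_subject` scenes. Each subject carries a
#' single log-normal multiplicative gain shared by all of its images; this
#' induces the within-subject correlation that the hierarchical (subject
#' first) metric aggregation and subject-level bootstrap exist to respect.
#'
#' @param config A [phantom_config()].
#' @param library Optional [make_spectral_library()]; generated from
#'   `config` when `NULL`.
#' @return A list of scenes, each `list(cube, mask, subject_id)`, with the
#'   library attached as attribute `"library"`.
#' @examples
#' ds <- make_dataset(phantom_config(n_subjects = 2, images_per_subject = 2,
#'                                   H = 16, W = 16, C = 12))
#' length(ds)
#' @export
make_dataset <- function(config, library = NULL) {
  if (is.null(library)) {
    library <- make_spectral_library(config$n_organs + 2L, config$C,
                                     seed = derive_seed(config$seed, 101))
  }
  gains <- with_seed(derive_seed(config$seed, 202),
                     stats::rlnorm(config$n_subjects, 0, config$gain_sigma))
  out <- vector("list", config$n_subjects * config$images_per_subject)
  idx <- 1L
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("subj%02d", i)
    for (j in seq_len(config$images_per_subject)) {
      sc <- render_scene(library, config, subject_id = sid,
                         seed = derive_seed(config$seed, 303, i, j),
                         gain = gains[i])
      out[[idx]] <- list(cube = sc$cube, mask = sc$mask, subject_id = sid)
      idx <- idx + 1L
    }
  }
  attr(out, "library") <- library
  out
}
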