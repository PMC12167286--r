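test_that("l1_normalize scales to unit absolute sum and preserves direction", {
  expect_equal(l1_normalize(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  v <- c(0.1, 0.3, 0.6)
  expect_equal(l1_normalize(v), v)  # already normalized: identity
  set.seed(1)
  for (i in 1:10) {
    x <- runif(20)
    expect_equal(sum(abs(l1_normalize(x))), 1)
  }
  expect_true(all(is.na(l1_normalize(c(0, 0)))))
})

test_that("class spectra aggregate subject-first", {
  # two subjects with constant spectra a and b average to (a + b) / 2
  mk_scene <- function(spec, sid) {
    C <- length(spec)
    cube <- hsi_cube(array(rep(spec, each = 16), c(4, 4, C)),
                     seq(500, 600, length.out = C), subject_id = sid)
    list(cube = cube, mask = tiny_mask(matrix(1L, 4, 4)), subject_id = sid)
  }
  a <- c(1, 2, 3, 4); b <- c(4, 3, 2, 1)
  # duplicate subject 1's image: must not change the aggregate
  ds <- list(mk_scene(a, "s1"), mk_scene(a, "s1"), mk_scene(b, "s2"))
  cs <- class_spectrum(ds, 1L)
  expect_equal(cs$median, (l1_normalize(a) + l1_normalize(b)) / 2)
  expect_equal(nrow(cs$subject_means), 2)
  # single subject: std is NA by convention
  cs1 <- class_spectrum(list(mk_scene(a, "s1")), 1L)
  expect_true(all(is.na(cs1$sd)))
  # absent class
  expect_null(class_spectrum(ds, 5L))
})

test_that("noise-free phantom class spectra equal the normalized library", {
  cfg <- noise_free_config()
  lib <- make_spectral_library(4, cfg$C, seed = 5)
  sc <- render_scene(lib, cfg, seed = 2, gain = 1.7)
  ds <- list(list(cube = sc$cube, mask = sc$mask, subject_id = "s1"))
  for (k in unique(as.vector(sc$mask$labels))) {
    got <- class_spectrum(ds, k)$median
    expect_equal(got, l1_normalize(lib$spectra[k + 1, ]), tolerance = 1e-12)
  }
})

test_that("spectral agreement is zero on itself and symmetric", {
  cfg <- phantom_config(n_subjects = 2, images_per_subject = 2, H = 16,
                        W = 16, C = 10, n_organs = 2, seed = 9)
  ds <- make_dataset(cfg)
  a <- ds[1:2]; b <- ds[3:4]
  expect_equal(spectral_agreement(a, a, 0L), 0)
  expect_equal(spectral_agreement(a, b, 0L), spectral_agreement(b, a, 0L))
  expect_true(is.na(spectral_agreement(a, b, 42L)))
})

test_that("dsc matches hand values and its invariants", {
  g <- matrix(0L, 2, 2); g[1, 1] <- 1L; g[1, 2] <- 1L
  p <- matrix(0L, 2, 2); p[1, 2] <- 1L; p[2, 2] <- 1L
  expect_equal(dsc(p, g, 1L), 0.5)       # 2*1 / (2+2)
  expect_equal(dsc(g, g, 1L), 1)
  expect_equal(dsc(p, g, 1L), dsc(g, p, 1L))
  disj <- matrix(0L, 2, 2); disj[2, 1] <- 1L
  expect_equal(dsc(disj, g, 1L), 0)
  expect_true(is.na(dsc(matrix(0L, 2, 2), matrix(0L, 2, 2), 1L)))
  expect_error(dsc(matrix(0L, 2, 2), matrix(0L, 3, 3), 1L),
               class = "hsisynth_shape_error")
})

# Brute-force oracles, deliberately written without the package's vectorized
# helpers.
dsc_oracle <- function(p, g, k) {
  P <- sum(p == k); G <- sum(g == k); I <- sum(p == k & g == k)
  if (P + G == 0) NA_real_ else 2 * I / (P + G)
}

boundary_oracle <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  out <- NULL
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (m[y, x] != k) next
    edge <- FALSE
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > H || xx < 1 || xx > W) edge <- TRUE
      else if (m[yy, xx] != k) edge <- TRUE
    }
    if (edge) out <- rbind(out, c(y, x))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

nsd_oracle <- function(p, g, k, tau) {
  bp <- boundary_oracle(p, k); bg <- boundary_oracle(g, k)
  if (nrow(bp) == 0 && nrow(bg) == 0) return(NA_real_)
  near <- function(A, B) {
    if (nrow(A) == 0) return(0)
    if (nrow(B) == 0) return(0)
    cnt <- 0
    for (i in seq_len(nrow(A))) {
      dmin <- Inf
      for (j in seq_len(nrow(B))) {
        dmin <- min(dmin, sqrt(sum((A[i, ] - B[j, ])^2)))
      }
      if (dmin <= tau) cnt <- cnt + 1
    }
    cnt
  }
  (near(bp, bg) + near(bg, bp)) / (nrow(bp) + nrow(bg))
}

test_that("dsc and nsd equal exhaustive brute-force oracles on random masks", {
  set.seed(77)
  n_pairs <- 200
  blobmask <- function() {
    m <- matrix(0L, 16, 16)
    for (k in sample(1:2, sample(0:2, 1))) {
      cy <- runif(1, 3, 13); cx <- runif(1, 3, 13); r <- runif(1, 1, 5)
      for (y in 1:16) for (x in 1:16) {
        if ((y - cy)^2 + (x - cx)^2 < r^2) m[y, x] <- k
      }
    }
    m
  }
  for (i in seq_len(n_pairs)) {
    p <- blobmask(); g <- blobmask()
    k <- sample(1:2, 1)
    tau <- sample(c(0, 1, 2, 3), 1)
    expect_identical(dsc(p, g, k), dsc_oracle(p, g, k))
    expect_identical(nsd(p, g, k, tau), nsd_oracle(p, g, k, tau))
  }
})

test_that("nsd hand fixture: 1 x 6 row with adjacent segments", {
  g <- matrix(c(0L, 1L, 1L, 0L, 0L, 0L), 1, 6)
  p <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L), 1, 6)
  expect_identical(nsd(p, g, 1L, tau = 1), nsd_oracle(p, g, 1L, 1))
  expect_equal(nsd(g, g, 1L, tau = 0), 1)
  # all boundary distances beyond tau give 0
  far <- matrix(0L, 8, 8); far[1:2, 1:2] <- 1L
  farp <- matrix(0L, 8, 8); farp[7:8, 7:8] <- 1L
  expect_equal(nsd(farp, far, 1L, tau = 2), 0)
})

test_that("hierarchical aggregation averages subjects, not images", {
  rec <- tibble::tibble(
    image_id = c("i1", "i2", "i3"),
    subject_id = c("S1", "S1", "S2"),
    class_id = 1L,
    metric = "DSC",
    value = c(0.8, 0.6, 1.0)
  )
  agg <- hierarchical_aggregate(rec)
  expect_equal(agg$value, 0.85)  # subject means 0.7 and 1.0
  expect_equal(agg$n_subjects, 2L)
  # constant values: aggregate equals the constant whatever the counts
  rec2 <- rec; rec2$value <- 0.4
  expect_equal(hierarchical_aggregate(rec2)$value, 0.4)
  # duplicating an image of a constant-valued subject changes nothing
  rec3 <- dplyr::bind_rows(rec, rec[1, ])
  rec3$value[c(1, 2, 4)] <- 0.7
  expect_equal(hierarchical_aggregate(rec3)$value, 0.85)
  # undefined records are dropped, not zero-filled
  rec4 <- dplyr::bind_rows(rec, tibble::tibble(
    image_id = "i4", subject_id = "S2", class_id = 1L,
    metric = "DSC", value = NA_real_))
  expect_equal(hierarchical_aggregate(rec4)$value, 0.85)
})

test_that("bootstrap difference CI is seeded and centers on zero for A == B", {
  set.seed(5)
  rec <- tibble::tibble(
    image_id = sprintf("i%02d", 1:20),
    subject_id = rep(sprintf("S%d", 1:10), each = 2),
    class_id = 1L, metric = "DSC",
    value = runif(20, 0.5, 0.9)
  )
  cfg <- eval_config(n_bootstrap = 500, seed = 3)
  ci <- bootstrap_ci_difference(rec, rec, cfg)
  expect_true(all(ci$low <= 0 & ci$high >= 0))
  expect_equal(ci$estimate, rep(0, nrow(ci)))
  ci2 <- bootstrap_ci_difference(rec, rec, cfg)
  expect_identical(ci, ci2)
  # fewer subjects -> wider interval
  rec4 <- rec[rec$subject_id %in% c("S1", "S2", "S3", "S4"), ]
  rec4$value <- rec$value[1:8]
  ciw <- bootstrap_ci_difference(rec4, dplyr::mutate(rec4, value = value + 0.001),
                                 cfg)
  expect_gt(ciw$high[1] - ciw$low[1], ci$high[1] - ci$low[1])
  expect_warning(bootstrap_ci_difference(rec[1:2, ], rec[1:2, ], cfg),
                 "fewer than 2 subjects")
})

test_that("rgb reconstruction integrates the configured windows", {
  wl <- seq(500, 1000, length.out = 50)
  flat <- hsi_cube(array(0.6, c(4, 4, 50)), wl)
  rgb <- rgb_reconstruction(flat)
  expect_equal(rgb[, , 1], rgb[, , 2])
  expect_equal(rgb[, , 2], rgb[, , 3])
  # constant 1.0 cube: every channel is 1 after joint normalization
  ones <- hsi_cube(array(1, c(2, 2, 50)), wl)
  expect_true(all(rgb_reconstruction(ones) == 1))
  # energy only in the green window dominates the green channel
  g <- array(0, c(2, 2, 50))
  g[, , wl >= 540 & wl <= 570] <- 1
  green <- rgb_reconstruction(hsi_cube(g, wl))
  expect_true(all(green[, , 2] > green[, , 1]))
  expect_true(all(green[, , 2] > green[, , 3]))
  expect_error(
    rgb_reconstruction(flat, windows = list(r = c(200, 210), g = c(540, 570),
                                            b = c(500, 520))),
    class = "hsisynth_config_error"
  )
})
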