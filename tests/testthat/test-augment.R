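identity_config <- function() {
  augment_config(rescale_range = c(1, 1), rotation_range = c(0, 0),
                 flip_prob = 0, label_dropout_prob = 0)
}

test_that("the identity transform returns the pair unchanged", {
  cfg <- noise_free_config()
  lib <- make_spectral_library(4, cfg$C, seed = 2)
  sc <- render_scene(lib, cfg, seed = 4)
  out <- augment_pair(sc$cube, sc$mask, identity_config(), seed = 1)
  expect_equal(out$cube$data, sc$cube$data, tolerance = 1e-12)
  expect_identical(out$mask$labels, sc$mask$labels)
})

test_that("a 90-degree rotation matches the hand-rotated mask exactly", {
  leg <- tiny_legend(2)
  labels <- matrix(c(1L, 0L, 0L, 0L,
                     2L, 1L, 0L, 0L,
                     2L, 2L, 1L, 0L,
                     2L, 2L, 2L, 1L), 4, 4, byrow = TRUE)
  mask <- semantic_mask(labels, leg)
  cube <- hsi_cube(array(labels + 1, c(4, 4, 2)) / 4,
                   c(500, 600))
  cfg <- augment_config(rescale_range = c(1, 1), rotation_range = c(90, 90),
                        flip_prob = 0)
  out <- augment_pair(cube, mask, cfg, seed = 1)
  # hand rule for a 90-degree rotation about the center of a 4 x 4 frame:
  # target (y, x) draws from source (5 - x, y)
  ref <- matrix(0L, 4, 4)
  for (y in 1:4) for (x in 1:4) ref[y, x] <- labels[5L - x, y]
  expect_identical(out$mask$labels, ref)
  # the cube undergoes the identical transform (bands encode the label here)
  expect_equal(out$cube$data[, , 1], (ref + 1) / 4, tolerance = 1e-9)
})

test_that("rotation voids carry a fill label missing from the legend", {
  cfg45 <- augment_config(rescale_range = c(1, 1),
                          rotation_range = c(45, 45), flip_prob = 0)
  mask <- tiny_mask(matrix(1L, 8, 8), tiny_legend(1))
  cube <- tiny_cube(8, 8, 3, value = 0.7)
  out <- augment_pair(cube, mask, cfg45, seed = 2)
  fill <- out$mask$fill_label
  expect_false(fill %in% out$mask$legend$ids)
  expect_equal(fill, max(out$mask$legend$ids) + 1L)
  corners <- c(out$mask$labels[1, 1], out$mask$labels[1, 8],
               out$mask$labels[8, 1], out$mask$labels[8, 8])
  expect_true(all(corners == fill))
  # void pixels of the cube are black
  void <- out$mask$labels == fill
  for (b in 1:3) expect_true(all(out$cube$data[, , b][void] == 0))
})

test_that("cube and mask stay geometrically consistent under augmentation", {
  # on a noise-free phantom the class is decodable from the spectrum, so
  # every augmented non-void pixel must carry the spectrum of its mask label
  cfg <- noise_free_config(H = 32, W = 32, C = 12)
  lib <- make_spectral_library(4, 12, seed = 6)
  sc <- render_scene(lib, cfg, seed = 8, gain = 1)
  acfg <- augment_config(rescale_range = c(1, 1), rotation_range = c(90, 90),
                         flip_prob = 0)
  out <- augment_pair(sc$cube, sc$mask, acfg, seed = 3)
  fill <- out$mask$fill_label
  flat <- matrix(out$cube$data, 32 * 32, 12)
  lab <- as.vector(out$mask$labels)
  ok <- lab != fill
  for (k in unique(lab[ok])) {
    rows <- flat[lab == k, , drop = FALSE]
    ref <- matrix(rep(lib$spectra[k + 1, ], each = nrow(rows)), nrow(rows))
    expect_equal(rows, ref, tolerance = 1e-9)
  }
})

test_that("label dropout is region-level with the stated rate", {
  leg <- tiny_legend(3)
  labels <- matrix(0L, 10, 10)
  labels[2:4, 2:4] <- 1L
  labels[6:8, 2:4] <- 2L
  labels[2:4, 6:8] <- 3L
  mask <- semantic_mask(labels, leg)
  expect_identical(label_dropout(mask, 0, seed = 1)$labels, labels)
  all_dropped <- label_dropout(mask, 1, seed = 1)
  fill <- all_dropped$fill_label
  expect_true(all(all_dropped$labels %in% c(0L, fill)))
  # empirical per-class drop rate over many seeded runs
  p <- 0.3
  n <- 2000
  drops <- vapply(seq_len(n), function(s) {
    out <- label_dropout(mask, p, seed = s)
    vapply(1:3, function(k) !any(out$labels == k), TRUE)
  }, logical(3))
  rate <- rowMeans(drops)
  expect_true(all(abs(rate - p) < 3 * sqrt(p * (1 - p) / n)))
  # dropped classes vanish wholesale, never partially
  out <- label_dropout(mask, 0.5, seed = 11)
  for (k in 1:3) {
    n_k <- sum(out$labels == k)
    expect_true(n_k == 0 || n_k == 9)
  }
})

test_that("OoD labels are reassigned to background and idempotently so", {
  known <- tiny_legend(2)
  wide <- label_legend(c(0:2, 99L), c("blue cloth", "organ_1", "organ_2",
                                      "instrument"))
  labels <- matrix(c(0L, 1L, 2L, 99L), 2, 2)
  mask <- semantic_mask(labels, wide)
  out <- reassign_ood_labels(mask, known)
  expect_equal(out$labels[labels == 99L], known$background_id)
  expect_identical(out$labels[labels != 99L], labels[labels != 99L])
  out2 <- reassign_ood_labels(out, known)
  expect_identical(out2$labels, out$labels)
  # masks with only known labels pass through unchanged
  m2 <- semantic_mask(matrix(c(0L, 1L), 1, 2), known)
  expect_identical(reassign_ood_labels(m2, known)$labels, m2$labels)
})
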