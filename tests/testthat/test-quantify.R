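noiseless_nuclear <- function(field, render = render_params(noise = FALSE)) {
  ev <- data.frame(event_id = integer(0), x = numeric(0), y = numeric(0),
                   tags = character(0), class = character(0),
                   cell_id = integer(0), source = character(0),
                   mode = character(0))
  render_field(ev, field, render, seed = 1)$channels$nuclear
}

test_that("nucleus segmentation finds each nucleus once", {
  f <- make_field(3, width = 320, height = 320,
                  config = list(cell_radius = c(48, 52),
                                nucleus_radius = c(20, 24)), seed = 2)
  p <- quant_params(nucleus_diameter_range = c(20, 120))
  lab <- segment_nuclei(noiseless_nuclear(f), p)
  expect_equal(max(lab), 3)
  # each true nucleus is covered by exactly one label
  for (cid in 1:3) {
    covered <- lab[f$nuclei_lab == cid]
    covered <- covered[covered > 0]
    expect_length(unique(covered), 1)
  }
  expect_equal(max(segment_nuclei(matrix(0, 64, 64), p)), 0)
  # an object below the minimum diameter is excluded
  img <- matrix(0, 64, 64)
  img[30:31, 30:31] <- 100
  expect_equal(max(segment_nuclei(img, p)), 0)
})

test_that("cell delineation matches the brute-force nearest-nucleus rule", {
  nuc <- matrix(0L, 40, 40)
  nuc[8:12, 8:12] <- 1L
  nuc[8:12, 24:28] <- 2L
  for (N in c(6, 20)) {
    expect_identical(delineate_cells(nuc, N), bf_expand(nuc, N))
  }
  # equidistant pixels go to the lower label
  mid <- delineate_cells(nuc, 20)[10, 18]
  expect_equal(mid, 1L)
  expect_error(delineate_cells(nuc, 0), "positive")
  empty <- matrix(0L, 10, 10)
  expect_true(all(delineate_cells(empty, 5) == 0))
})

test_that("white top-hat matches brute-force morphology", {
  expect_true(all(enhance_speckles(matrix(7, 20, 20), 3) == 0))
  set.seed(1)
  img <- matrix(runif(24 * 24, 0, 50), 24, 24)
  img[12, 12] <- 400
  got <- enhance_speckles(img, 2)
  want <- pmax(img - bf_opening(img, 2), 0)
  expect_equal(got, want, tolerance = 1e-6)
  # an isolated bright spot smaller than the disk is preserved
  flat <- matrix(10, 32, 32)
  flat[16, 16] <- 200
  enh <- enhance_speckles(flat, 3)
  expect_gt(enh[16, 16], 150)
  expect_lt(max(enh[-16, ]), 1e-6)
  # a smooth gradient leaves no speckle residue
  grad <- outer(seq(0, 60, length.out = 48), rep(1, 48))
  expect_lt(max(enhance_speckles(grad, 3)), 10)
  expect_error(enhance_speckles(flat, 0), "feature_size")
})

test_that("spot detection counts isolated spots and gates by size", {
  img <- matrix(0, 128, 128)
  pts <- cbind(c(20, 20, 64, 100, 108), c(20, 90, 64, 30, 104))
  for (i in seq_len(nrow(pts))) {
    dx <- outer(rep(1, 128), seq_len(128)) - pts[i, 2]
    dy <- outer(seq_len(128), rep(1, 128)) - pts[i, 1]
    img <- img + 500 * exp(-(dx^2 + dy^2) / (2 * 1.5^2))
  }
  p <- quant_params(spot_threshold = "manual", spot_threshold_level = 50)
  lab <- detect_spots(img, p)
  expect_equal(max(lab), nrow(pts))
  expect_equal(max(detect_spots(matrix(0, 64, 64), p)), 0)
  # a blob above the diameter gate is excluded
  blob <- matrix(0, 64, 64)
  blob[10:50, 10:50] <- 100
  expect_equal(max(detect_spots(blob, p)), 0)
})

test_that("cross-channel consolidation merges by disk overlap", {
  a <- matrix(0L, 64, 64); b <- matrix(0L, 64, 64)
  a[30:32, 30:32] <- 1L
  b[30:32, 30:32] <- 1L
  one <- consolidate_spots(a, b, B = 2)
  expect_equal(nrow(one$objects), 1)
  expect_true(one$objects$from_A & one$objects$from_B)
  # centroids 2B + 2 apart stay separate
  b2 <- matrix(0L, 64, 64)
  b2[30:32, 36:38] <- 1L                 # 6 px apart with B = 2
  two <- consolidate_spots(a, b2, B = 2)
  expect_equal(nrow(two$objects), 2)
  # empty B channel: objects are the A spots only
  onlyA <- consolidate_spots(a, matrix(0L, 64, 64), B = 2)
  expect_equal(nrow(onlyA$objects), 1)
  expect_false(onlyA$objects$from_B)
  expect_error(consolidate_spots(a, b, B = 0), "B must be")
})

test_that("masking drops out-of-cell objects and assigns cell ids", {
  cells <- matrix(0L, 64, 64)
  cells[10:40, 10:40] <- 3L
  obj <- data.frame(object_id = 1:2, x = c(20, 60), y = c(20, 60),
                    from_A = TRUE, from_B = FALSE)
  got <- mask_and_assign(obj, cells)
  expect_equal(nrow(got), 1)
  expect_equal(got$cell_id, 3L)
  expect_equal(nrow(mask_and_assign(obj, matrix(0L, 64, 64))), 0)
})

test_that("angled thresholds classify the canonical axis and diagonal", {
  lab <- matrix(0L, 40, 40)
  lab[10:12, 10:12] <- 1L
  lab[25:27, 25:27] <- 2L
  chA <- matrix(0, 40, 40); chB <- matrix(0, 40, 40)
  chA[10:12, 10:12] <- 200                       # pure A object
  chA[25:27, 25:27] <- 150; chB[25:27, 25:27] <- 150   # diagonal object
  obj <- data.frame(object_id = 1:2, x = c(11, 26), y = c(11, 26),
                    from_A = TRUE, from_B = FALSE, cell_id = 1L)
  th <- classification_thresholds(t_A = 0, t_B = 0)
  sp <- measure_and_classify(obj, lab, chA, chB, th)
  expect_equal(sp$class, c("freeA", "complex"))
  expect_equal(sp$phi[1], 0)
  expect_equal(sp$phi[2], 45)
  # both-zero objects are discarded as background
  chA0 <- matrix(0, 40, 40)
  sp0 <- measure_and_classify(obj, lab, chA0, chA0, th)
  expect_equal(nrow(sp0), 0)
  expect_error(classification_thresholds(theta_low = 70, theta_high = 60))
})

test_that("per-cell summaries normalize and conserve counts", {
  spot <- data.frame(object_id = 1:10, x = 1, y = 1,
                     cell_id = c(rep(1, 10)),
                     I_A = 1, I_B = 1, phi = 0,
                     class = c(rep("freeA", 2), rep("freeB", 3),
                               rep("complex", 5)))
  cc <- per_cell_counts(spot)
  expect_equal(c(cc$f_freeA, cc$f_freeB, cc$f_complex), c(0.2, 0.3, 0.5))
  expect_equal(cc$n, cc$n_freeA + cc$n_freeB + cc$n_complex)
  # empty cells are reported with n = 0 and NA fractions
  cc2 <- per_cell_counts(spot, cell_ids = 1:3)
  expect_equal(cc2$n, c(10, 0, 0))
  expect_true(all(is.na(cc2$f_freeA[2:3])))
  ff <- frame_fractions(spot)
  expect_equal(sum(ff), 1)
})

test_that("full pipeline conserves detected products in one class each", {
  sim <- simulate_experiment(mode = "molboolean", n_cells = 2, width = 320,
                             height = 320,
                             population = list(freeA = 10, freeB = 10,
                                               complex = 10, cell_cv = 0),
                             field_config = list(cell_radius = c(52, 60),
                                                 nucleus_radius = c(22, 26)),
                             seed = 4)
  p <- quant_params(nucleus_diameter_range = c(20, 120),
                    cell_expand_N = 45)
  res <- quantify_field(sim$channels, p)
  expect_true(all(res$spots$class %in% c("freeA", "freeB", "complex")))
  expect_equal(res$cells$n,
               res$cells$n_freeA + res$cells$n_freeB + res$cells$n_complex)
  expect_equal(sum(res$cells$n), nrow(res$spots))
})

test_that("chance colocalization inflates the complex class with density", {
  # all-singleton ground truth: any measured complex is a colocalization
  # artifact, and the artifact rate grows with event density
  fracs <- vapply(c(4, 16, 48), function(dens) {
    sim <- simulate_experiment(
      mode = "molboolean", n_cells = 2, width = 320, height = 320,
      population = list(freeA = dens, freeB = dens, complex = 0,
                        cell_cv = 0,
                        compartments = list(freeA = "cytoplasm",
                                            freeB = "cytoplasm",
                                            complex = "membrane")),
      field_config = list(cell_radius = c(52, 60),
                          nucleus_radius = c(22, 26)),
      seed = 21)
    p <- quant_params(nucleus_diameter_range = c(20, 120),
                      cell_expand_N = 45)
    res <- quantify_field(sim$channels, p)
    unname(res$frame[["f_complex"]])
  }, 0)
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[3], fracs[1])
})

test_that("single-channel pipeline counts spots per cell", {
  sim <- simulate_experiment(
    mode = "pla", n_cells = 2, width = 320, height = 320,
    population = list(freeA = 0, freeB = 0, complex = 12, cell_cv = 0,
                      compartments = list(freeA = "cytoplasm",
                                          freeB = "cytoplasm",
                                          complex = "cytoplasm")),
    field_config = list(cell_radius = c(52, 60),
                        nucleus_radius = c(22, 26)),
    seed = 6)
  p <- quant_params(nucleus_diameter_range = c(20, 120),
                    cell_expand_N = 45)
  res <- quantify_pla(sim$channels$nuclear, sim$channels$detA, p)
  expect_equal(nrow(res$cells), 2)
  expect_gt(sum(res$cells$n), 0)
  expect_lt(abs(sum(res$cells$n) - nrow(sim$truth)) /
              max(nrow(sim$truth), 1), 0.15)
  # blank signal channel: every cell counts zero
  blank <- matrix(100, 320, 320)
  res0 <- quantify_pla(sim$channels$nuclear, blank, p)
  expect_true(all(res0$cells$n == 0))
})
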