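small_field <- function(seed = 1, n = 2)
  make_field(n, width = 256, height = 256,
             config = list(cell_radius = c(52, 60),
                           nucleus_radius = c(22, 26)), seed = seed)

test_that("field generation is deterministic, contained and bounded", {
  f0 <- make_field(0, width = 64, height = 64)
  expect_equal(f0$n_cells, 0)
  expect_true(all(f0$cell_lab == 0))
  f1 <- small_field(7)
  f2 <- small_field(7)
  expect_identical(f1$nuclei_lab, f2$nuclei_lab)
  expect_identical(f1$cell_lab, f2$cell_lab)
  for (cid in seq_len(f1$n_cells)) {
    nuc <- f1$nuclei_lab == cid
    cell <- f1$cell_lab == cid
    expect_true(all(cell[nuc]))            # nucleus inside its cell
    expect_lt(sum(nuc), sum(cell))         # strictly smaller
  }
  # disjoint cells
  expect_true(all(table(f1$cell_lab[f1$cell_lab > 0]) > 0))
  expect_error(make_field(50, width = 256, height = 256,
                          config = list(cell_radius = c(52, 60),
                                        nucleus_radius = c(22, 26),
                                        max_retries = 200)),
               "non-overlapping")
})

test_that("molecule placement honors counts and compartments", {
  f <- small_field(3)
  pop <- list(freeA = 0, freeB = 0, complex = 50, cell_cv = 0,
              compartments = list(freeA = "cytoplasm", freeB = "cytoplasm",
                                  complex = "membrane"))
  mol <- place_molecules(f, pop, seed = 1)
  expect_equal(nrow(mol), 50 * f$n_cells)
  expect_true(all(mol$class == "complex"))
  for (i in seq_len(nrow(mol))) {
    px <- floor(mol$x[i] / f$pixel_size) + 1
    py <- floor(mol$y[i] / f$pixel_size) + 1
    expect_equal(f$membrane_lab[py, px], mol$cell_id[i])
  }
  # partner-null scenario: only free B requested, nothing else appears
  molB <- place_molecules(f, list(freeA = 0, freeB = 20, complex = 0,
                                  cell_cv = 0), seed = 1)
  expect_true(all(molB$class == "freeB"))
  expect_identical(place_molecules(f, pop, seed = 9),
                   place_molecules(f, pop, seed = 9))
})

test_that("degenerate probabilities give the deterministic event sets", {
  f <- small_field(2)
  mol <- place_molecules(f, list(freeA = 10, freeB = 10, complex = 10,
                                 cell_cv = 0), seed = 2)
  p1 <- assay_params(occupancy_A = 1, occupancy_B = 1)
  ev <- simulate_molecular_events(mol, p1, seed = 5)
  expect_equal(sum(ev$tags == "AB"), sum(mol$class == "complex"))
  expect_equal(sum(ev$tags == "A"), sum(mol$class == "freeA"))
  expect_equal(sum(ev$tags == "B"), sum(mol$class == "freeB"))
  # each molecule contributes at most one event under default geometry
  expect_false(anyDuplicated(ev$source) > 0)
})

test_that("assay modes enforce their event-type contracts", {
  f <- small_field(4)
  mol <- place_molecules(f, list(freeA = 30, freeB = 30, complex = 30,
                                 cell_cv = 0), seed = 3)
  for (s in 1:5) {
    pad <- simulate_molecular_events(mol, assay_params(mode = "padlock"),
                                     seed = s)
    expect_equal(sum(pad$tags == "AB"), 0)
    pla <- simulate_molecular_events(mol, assay_params(mode = "pla"),
                                     seed = s)
    expect_true(all(pla$class == "complex"))
  }
  # padlock: a complex can emit one event per bound probe, never more
  pad <- simulate_molecular_events(mol, assay_params(mode = "padlock",
                                                     occupancy_A = 1,
                                                     occupancy_B = 1),
                                   seed = 1)
  cx_sources <- pad$source[pad$source %in%
                             mol$molecule_id[mol$class == "complex"]]
  expect_true(all(table(cx_sources) <= 2))
})

test_that("closed-form expectations match the worked example and limits", {
  ef <- expected_fractions(assay_params(), list(complex = 1))
  expect_equal(ef$expected[ef$class == "complex"], 0.64)
  ef0 <- expected_fractions(assay_params(occupancy_A = 0),
                            list(freeA = 100, complex = 100))
  expect_equal(ef0$expected[ef0$class == "freeA"], 0)
  expect_equal(ef0$expected[ef0$class == "complex"], 0)
  # monotonicity of the expected dual count in every probability knob
  base <- list(occupancy_A = 0.5, occupancy_B = 0.6, e_circle = 0.7,
               e_nick = 0.8, e_tag = 0.9, e_ligate = 0.85, e_rca = 0.75)
  dual_of <- function(args) {
    p <- do.call(assay_params, args)
    ef <- expected_fractions(p, list(complex = 1))
    ef$expected[ef$class == "complex"]
  }
  for (knob in names(base)) {
    lo <- base; hi <- base
    lo[[knob]] <- base[[knob]] - 0.2
    hi[[knob]] <- base[[knob]] + 0.1
    expect_lte(dual_of(lo), dual_of(base))
    expect_lte(dual_of(base), dual_of(hi))
  }
})

test_that("Monte-Carlo class frequencies match the closed form at 1e6", {
  n <- 1e6
  mol <- data.frame(molecule_id = seq_len(n),
                    class = rep(c("freeA", "freeB", "complex"),
                                length.out = n),
                    x = 0, y = 0, compartment = "cytoplasm", cell_id = 1L)
  p <- assay_params(occupancy_A = 0.7, occupancy_B = 0.85,
                    e_circle = 0.95, e_nick = 0.9, e_tag = 0.92,
                    e_ligate = 0.97, e_rca = 0.93, s_max = 50)
  ev <- simulate_molecular_events(mol, p, seed = 5)
  ef <- expected_fractions(p, list(freeA = sum(mol$class == "freeA"),
                                   freeB = sum(mol$class == "freeB"),
                                   complex = sum(mol$class == "complex")))
  obs <- table(factor(ev$class, levels = c("freeA", "freeB", "complex")))
  for (cl in c("freeA", "freeB", "complex")) {
    e <- ef$expected[ef$class == cl]
    # conservative binomial SE on the relevant molecule count
    n_src <- if (cl == "complex") sum(mol$class == "complex") else n
    se <- sqrt(e * (1 - e / n_src))
    expect_lt(abs(obs[[cl]] - e), 3 * se)
  }
})

test_that("rendering places spots at event positions with shared duals", {
  f <- make_field(1, width = 96, height = 96,
                  config = list(cell_radius = c(30, 32),
                                nucleus_radius = c(12, 13)), seed = 1)
  quiet <- render_params(noise = FALSE)
  ev0 <- simulate_molecular_events(
    place_molecules(f, list(freeA = 0, freeB = 0, complex = 0,
                            cell_cv = 0), seed = 1),
    assay_params(), seed = 1)
  r0 <- render_field(ev0, f, render_params(noise = TRUE), seed = 2)
  # no events: detection channels are background within noise bounds
  expect_lt(abs(mean(r0$channels$detA) - 100), 1)
  expect_lt(abs(mean(r0$channels$detB) - 100), 1)
  # one singleton at a known position: noiseless argmax within 1 px
  ev1 <- data.frame(event_id = 1L, x = 4000, y = 5000, tags = "A",
                    class = "freeA", cell_id = 1L, source = "1",
                    mode = "molboolean")
  p_nj <- assay_params(rcp_displacement = 0)
  r1 <- render_field(ev1, f, quiet, seed = 3)
  am <- which(r1$channels$detA == max(r1$channels$detA), arr.ind = TRUE)
  expect_lt(abs(am[1, "col"] - (4000 / f$pixel_size + 0.5)), 1)
  expect_lt(abs(am[1, "row"] - (5000 / f$pixel_size + 0.5)), 1)
  expect_equal(max(r1$channels$detB), 100)   # flat background
  # dual event: per-channel noiseless maxima coincide
  ev2 <- ev1; ev2$tags <- "AB"; ev2$class <- "complex"
  r2 <- render_field(ev2, f, quiet, seed = 4)
  amA <- which(r2$channels$detA == max(r2$channels$detA), arr.ind = TRUE)
  amB <- which(r2$channels$detB == max(r2$channels$detB), arr.ind = TRUE)
  expect_lte(sqrt(sum((amA[1, ] - amB[1, ])^2)), 0.5)
})

test_that("simulation runs are reproducible from seed and sidecar", {
  dir1 <- file.path(tempdir(), "simrep1")
  dir2 <- file.path(tempdir(), "simrep2")
  s1 <- simulate_experiment(mode = "molboolean", n_cells = 2, width = 256,
                            height = 256,
                            population = list(freeA = 5, freeB = 5,
                                              complex = 5, cell_cv = 0),
                            field_config = list(cell_radius = c(52, 60),
                                                nucleus_radius = c(22, 26)),
                            seed = 11, outdir = dir1)
  s2 <- simulate_experiment(mode = "molboolean", n_cells = 2, width = 256,
                            height = 256,
                            population = list(freeA = 5, freeB = 5,
                                              complex = 5, cell_cv = 0),
                            field_config = list(cell_radius = c(52, 60),
                                                nucleus_radius = c(22, 26)),
                            seed = 11, outdir = dir2)
  expect_identical(s1$channels, s2$channels)
  expect_identical(unname(tools::md5sum(s1$files[["tiff"]])),
                   unname(tools::md5sum(s2$files[["tiff"]])))
  side <- jsonlite::read_json(s1$files[["sidecar"]])
  expect_equal(side$seed, 11)
  expect_equal(side$counts$events, nrow(s1$events))
})
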