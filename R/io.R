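# ---- FASTA -----------------------------------------------------------------

#' Read an oligo set from FASTA
#'
#' Headers may carry whitespace-separated `mod=`, `role=` and `tail=` fields
#' after the record name; missing fields default to `mod=none`,
#' `role=detection`.
#'
#' @param path FASTA file.
#' @return named list of [oligo] objects.
#' @export
read_oligo_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(set)) {
    hdr <- names(set)[i]
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    nm <- toks[1]
    kv <- toks[-1]
    field <- function(key, default) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default
    }
    mod <- field("mod", "none")
    if (mod == "aldehyde or oYo-link") mod <- "aldehyde"
    out[[nm]] <- oligo(nm, as.character(set[[i]]),
                       end5_mod = mod,
                       role = field("role", "detection"),
                       tail = field("tail", ""))
  }
  out
}

#' Write an oligo set to FASTA
#'
#' @param oligos named list of [oligo] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(oligos, path) {
  seqs <- Biostrings::DNAStringSet(vapply(oligos, `[[`, "", "sequence"))
  names(seqs) <- vapply(oligos, function(o) {
    paste0(o$name, " mod=", o$end5_mod, " role=", o$role,
           if (nzchar(o$tail)) paste0(" tail=", o$tail) else "")
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# ---- images ----------------------------------------------------------------

#' Read a multi-channel TIFF stack
#'
#' Channels are resolved by name through `channel_map`, a named integer
#' vector mapping channel names to 1-based slice indices. The simulator
#' writes (nuclear, detA, detB) in that order.
#'
#' @param path TIFF file.
#' @param channel_map named integer vector, e.g.
#'   `c(nuclear = 1, detA = 2, detB = 3)`.
#' @return named list of numeric matrices (row = y, col = x).
#' @export
read_image_stack <- function(path,
                             channel_map = c(nuclear = 1, detA = 2,
                                             detB = 3)) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  out <- list()
  for (nm in names(channel_map)) {
    idx <- channel_map[[nm]]
    if (idx > length(raw))
      stop("channel '", nm, "' (slice ", idx, ") missing: file has ",
           length(raw), " slice(s)")
    out[[nm]] <- raw[[idx]]
  }
  out
}

#' Write a multi-channel image stack as TIFF
#'
#' Integer counts are stored as 16-bit; the channel order is the order of
#' the input list and is echoed into the JSON sidecar written by
#' [simulate_experiment].
#'
#' @param channels named list of numeric matrices.
#' @param path output TIFF.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(channels, path) {
  imgs <- lapply(channels, function(m) {
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

# ---- tables ----------------------------------------------------------------

#' Write the per-object and per-cell result tables
#'
#' Mirrors a spreadsheet export: one CSV of detected objects (spot table)
#' and one per-cell summary CSV with stable column order. Re-reading with
#' [read_tables] reproduces the tables.
#'
#' @param spot_table data frame from [measure_and_classify].
#' @param cell_summaries data frame from [per_cell_counts].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the two paths, invisibly.
#' @export
write_tables <- function(spot_table, cell_summaries, dir, prefix = "result") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, paste0(prefix, "_objects.csv"))
  cp <- file.path(dir, paste0(prefix, "_cells.csv"))
  utils::write.csv(spot_table, sp, row.names = FALSE)
  utils::write.csv(cell_summaries, cp, row.names = FALSE)
  invisible(c(objects = sp, cells = cp))
}

#' Re-read tables written by [write_tables]
#' @param dir directory containing the CSVs.
#' @param prefix file-name prefix used at write time.
#' @return list with `objects` and `cells` data frames.
#' @export
read_tables <- function(dir, prefix = "result") {
  list(objects = utils::read.csv(file.path(dir,
                                           paste0(prefix, "_objects.csv"))),
       cells = utils::read.csv(file.path(dir, paste0(prefix, "_cells.csv"))))
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All simulator, segmentation, classification and statistics defaults in
#' one nested list; [write_run_config] / [read_run_config] round-trip it
#' losslessly through YAML, and every pipeline run echoes its resolved
#' configuration plus seed into a JSON sidecar.
#'
#' @return nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    mode = "molboolean",
    seed = 1L,
    simulator = list(
      n_cells = 4L, width = 640L, height = 640L, pixel_size = 100,
      population = list(freeA = 19, freeB = 19, complex = 21,
                        cell_cv = 0.35),
      params = unclass(assay_params()),
      render = local({
        rp <- unclass(render_params())
        rp$background <- as.list(rp$background)  # YAML-native map
        rp
      })),
    segmentation = unclass(quant_params()),
    stats = list(exact_threshold = 20L, continuity_correction = TRUE))
}

#' Write a run configuration to YAML
#' @param config nested list (see [default_run_config]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return nested list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yaml::read_yaml(path)
}

#' Write the reproducibility sidecar of a run
#'
#' Records the resolved configuration, master seed, package version and
#' per-stage object counts so that a run is reproducible from the sidecar
#' alone.
#'
#' @param config resolved configuration list.
#' @param seed master seed used.
#' @param counts named list/vector of per-stage object counts.
#' @param path output JSON.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(config, seed, counts, path) {
  jsonlite::write_json(
    list(package = "molbool",
         version = as.character(utils::packageVersion("molbool")),
         seed = seed, counts = as.list(counts), config = config),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# ---- fixtures --------------------------------------------------------------

.FIXTURES <- c("table1-oligos", "two-cell-demo", "padlock-control",
               "occupancy-sweep")

#' Generate a bundled demonstration dataset
#'
#' Deterministic tiny inputs used by the tests and documentation:
#' \describe{
#'   \item{table1-oligos}{the packaged design-table FASTA, copied verbatim.}
#'   \item{two-cell-demo}{a 256 px two-cell field simulated, rendered and
#'     written as TIFF + ground-truth CSV + sidecar.}
#'   \item{padlock-control}{paired fields rendered from one
#'     molecule table in dual-tag mode and in padlock mode.}
#'   \item{occupancy-sweep}{closed-form expected event fractions over a grid
#'     of epitope occupancies, as CSV.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory.
#' @param seed master seed.
#' @return named character vector of created files, invisibly.
#' @export
make_fixture <- function(name, dir = tempdir(), seed = 1L) {
  if (!name %in% .FIXTURES)
    stop("unknown fixture '", name, "'; available: ",
         paste(.FIXTURES, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
    "table1-oligos" = {
      dst <- file.path(dir, "molboolean_oligos.fasta")
      file.copy(system.file("extdata", "molboolean_oligos.fasta",
                            package = "molbool", mustWork = TRUE),
                dst, overwrite = TRUE)
      invisible(c(fasta = dst))
    },
    "two-cell-demo" = {
      sim <- simulate_experiment(
        mode = "molboolean", n_cells = 2L, width = 256L, height = 256L,
        population = list(freeA = 8, freeB = 8, complex = 9, cell_cv = 0),
        field_config = list(cell_radius = c(55, 62), nucleus_radius = c(24, 28)),
        seed = seed, outdir = dir, prefix = "two_cell_demo")
      invisible(sim$files)
    },
    "padlock-control" = {
      pair <- simulate_mode_pair(
        n_cells = 2L, width = 256L, height = 256L,
        population = list(freeA = 8, freeB = 8, complex = 12, cell_cv = 0),
        field_config = list(cell_radius = c(55, 62), nucleus_radius = c(24, 28)),
        seed = seed, outdir = dir)
      invisible(pair$files)
    },
    "occupancy-sweep" = {
      occ <- seq(0.1, 1, by = 0.1)
      grid <- expand.grid(p_A = occ, p_B = occ)
      grid$p_dual <- mapply(function(a, b) {
        ef <- expected_fractions(assay_params(occupancy_A = a, occupancy_B = b),
                                 list(freeA = 0, freeB = 0, complex = 1))
        ef$expected[ef$class == "complex"]
      }, grid$p_A, grid$p_B)
      dst <- file.path(dir, "occupancy_sweep.csv")
      utils::write.csv(grid, dst, row.names = FALSE)
      invisible(c(csv = dst))
    })
}
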