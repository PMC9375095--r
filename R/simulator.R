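# Derive a reproducible sub-seed for a named stage, so placement, binding,
# efficiency draws and noise have independent, individually replayable
# streams under one master seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}

# ---- parameters ------------------------------------------------------------

#' Assay parameters
#'
#' Epitope occupancies are the probabilities that a given epitope is bound
#' by its (probe-carrying) antibody; the proximity threshold is the maximal
#' epitope separation at which one circle can engage both arms (about 40 nm
#' for secondary proximity probes, 30 nm for primary conjugates). The
#' per-step enzymatic efficiencies default to 1 and are explicit knobs.
#' Epitope separation within a complex is drawn uniformly on
#' `[0, s_max]` nm. `rcp_displacement` is the radius (nm) of the uniform
#' disk over which a rolling-circle product's centroid is displaced from
#' its generating epitope (the product is a ~0.5-1 um DNA ball anchored
#' near, not on, the epitope).
#'
#' @param occupancy_A,occupancy_B epitope occupancy probabilities.
#' @param proximity_threshold nm.
#' @param s_max nm, upper bound of the within-complex epitope separation.
#' @param e_circle,e_nick,e_tag,e_ligate,e_rca per-step success
#'   probabilities.
#' @param mode `"molboolean"`, `"pla"` or `"padlock"`.
#' @param rcp_displacement nm.
#' @param spurious_rate expected off-target singleton events per channel per
#'   field (Poisson), default 0.
#' @return an `assay_params` object.
#' @export
assay_params <- function(occupancy_A = 0.8, occupancy_B = 0.8,
                         proximity_threshold = 40, s_max = 20,
                         e_circle = 1, e_nick = 1, e_tag = 1,
                         e_ligate = 1, e_rca = 1,
                         mode = c("molboolean", "pla", "padlock"),
                         rcp_displacement = 500, spurious_rate = 0) {
  mode <- match.arg(mode)
  p <- list(occupancy_A = occupancy_A, occupancy_B = occupancy_B,
            proximity_threshold = proximity_threshold, s_max = s_max,
            e_circle = e_circle, e_nick = e_nick, e_tag = e_tag,
            e_ligate = e_ligate, e_rca = e_rca, mode = mode,
            rcp_displacement = rcp_displacement,
            spurious_rate = spurious_rate)
  probs <- c(p$occupancy_A, p$occupancy_B, p$e_circle, p$e_nick, p$e_tag,
             p$e_ligate, p$e_rca)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all occupancies and efficiencies must lie in [0, 1]")
  if (!is.finite(p$proximity_threshold) || p$proximity_threshold <= 0)
    stop("proximity_threshold must be > 0")
  if (p$s_max < 0) stop("s_max must be >= 0")
  structure(p, class = "assay_params")
}

#' Rendering parameters
#'
#' Spots are isotropic Gaussians of width `psf_sigma` (nm); peak amplitudes
#' are lognormal with a per-event size component (`amp_sdlog`, shared
#' between channels of a dual event) and an independent per-channel factor
#' (`channel_sdlog`). Photon shot noise is Poisson on the noiseless image;
#' read noise is additive Gaussian.
#'
#' @param psf_sigma nm.
#' @param amp_meanlog,amp_sdlog lognormal parameters of the per-event peak
#'   amplitude (counts).
#' @param channel_sdlog lognormal sd of the independent per-channel factor.
#' @param background per-channel background counts
#'   (named: nuclear, detA, detB).
#' @param nucleus_intensity added counts inside nuclei in the nuclear
#'   channel.
#' @param read_noise Gaussian read noise sd (counts).
#' @param noise logical; `FALSE` renders noiseless images (for oracles).
#' @return a `render_params` object.
#' @export
render_params <- function(psf_sigma = 200, amp_meanlog = log(600),
                          amp_sdlog = 0.4, channel_sdlog = 0.1,
                          background = c(nuclear = 20, detA = 100,
                                         detB = 100),
                          nucleus_intensity = 150, read_noise = 3,
                          noise = TRUE) {
  stopifnot(psf_sigma > 0, all(background >= 0), read_noise >= 0)
  structure(list(psf_sigma = psf_sigma, amp_meanlog = amp_meanlog,
                 amp_sdlog = amp_sdlog, channel_sdlog = channel_sdlog,
                 background = background,
                 nucleus_intensity = nucleus_intensity,
                 read_noise = read_noise, noise = noise),
            class = "render_params")
}

# ---- cell fields -----------------------------------------------------------

#' Generate a synthetic field of fixed cells
#'
#' Places `n_cells` non-overlapping elliptical cells (each with a concentric
#' elliptical nucleus and a membrane band along the cell boundary) inside
#' the frame, emulating a PFA-fixed adherent monolayer imaged in a single
#' focal plane. Deterministic under a fixed seed.
#'
#' @param n_cells number of cells (>= 0).
#' @param width,height frame size in px.
#' @param pixel_size nm per px.
#' @param config list overriding geometry defaults: `cell_radius` (px,
#'   range), `nucleus_radius` (px, range), `membrane_width` (px),
#'   `max_retries`.
#' @param seed master seed.
#' @return a `cell_field` object: label matrices `nuclei_lab`, `cell_lab`,
#'   `membrane_lab` (row = y, col = x), a `cells` data frame and the
#'   geometry metadata.
#' @export
make_field <- function(n_cells, width = 640L, height = 640L,
                       pixel_size = 100, config = list(), seed = 1L) {
  stopifnot(n_cells >= 0)
  cfg <- utils::modifyList(
    list(cell_radius = c(95, 115), nucleus_radius = c(38, 48),
         membrane_width = 4, max_retries = 2000L), config)
  set.seed(substream_seed(seed, "field"))
  empty_cells <- data.frame(cell_id = integer(0), cx = numeric(0),
                            cy = numeric(0), a = numeric(0), b = numeric(0),
                            theta = numeric(0), na = numeric(0),
                            nb = numeric(0))
  cells <- empty_cells
  tries <- 0L
  since_restart <- 0L
  while (nrow(cells) < n_cells) {
    if (tries >= cfg$max_retries)
      stop("could not place ", n_cells, " non-overlapping cells in a ",
           width, "x", height, " frame after ", tries, " retries")
    if (since_restart >= 100L) {          # dead-end packing: start over
      cells <- empty_cells
      since_restart <- 0L
    }
    tries <- tries + 1L
    since_restart <- since_restart + 1L
    a <- stats::runif(1, cfg$cell_radius[1], cfg$cell_radius[2])
    b <- stats::runif(1, cfg$cell_radius[1], cfg$cell_radius[2])
    th <- stats::runif(1, 0, pi)
    r <- max(a, b)
    cx <- stats::runif(1, r + 2, width - r - 2)
    cy <- stats::runif(1, r + 2, height - r - 2)
    if (nrow(cells) > 0) {
      d <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
      if (any(d < r + pmax(cells$a, cells$b) + 3)) next
    }
    scale_n <- stats::runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2]) /
      mean(c(a, b))
    cells <- rbind(cells, data.frame(
      cell_id = nrow(cells) + 1L, cx = cx, cy = cy, a = a, b = b,
      theta = th, na = a * scale_n, nb = b * scale_n))
    since_restart <- 0L
  }
  lab <- matrix(0L, nrow = height, ncol = width)
  nuc <- matrix(0L, nrow = height, ncol = width)
  mem <- matrix(0L, nrow = height, ncol = width)
  if (n_cells > 0) {
    xs <- matrix(rep(seq_len(width), each = height), nrow = height)
    ys <- matrix(rep(seq_len(height), times = width), nrow = height)
    for (i in seq_len(nrow(cells))) {
      cc <- cells[i, ]
      dx <- xs - cc$cx; dy <- ys - cc$cy
      u <- dx * cos(cc$theta) + dy * sin(cc$theta)
      v <- -dx * sin(cc$theta) + dy * cos(cc$theta)
      q <- (u / cc$a)^2 + (v / cc$b)^2
      qn <- (u / cc$na)^2 + (v / cc$nb)^2
      inner <- (1 - cfg$membrane_width / mean(c(cc$a, cc$b)))^2
      lab[q <= 1] <- cc$cell_id
      nuc[qn <= 1] <- cc$cell_id
      mem[q <= 1 & q > inner] <- cc$cell_id
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, n_cells = as.integer(n_cells),
                 cells = cells, nuclei_lab = nuc, cell_lab = lab,
                 membrane_lab = mem, config = cfg, seed = seed),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> %d cells, %dx%d px @ %g nm/px\n",
              x$n_cells, x$width, x$height, x$pixel_size))
  invisible(x)
}

.compartment_mask <- function(field, cell_id, compartment) {
  switch(compartment,
    nucleus = field$nuclei_lab == cell_id,
    membrane = field$membrane_lab == cell_id,
    cytoplasm = field$cell_lab == cell_id & field$nuclei_lab != cell_id &
      field$membrane_lab != cell_id,
    stop("unknown compartment '", compartment, "'"))
}

#' Place ground-truth molecules in a cell field
#'
#' Molecules of the three classes (free A, free B, AB complex) are placed
#' uniformly within their assigned compartment of each cell. Per-cell
#' counts are either exactly the requested per-cell numbers
#' (`cell_cv = 0`) or Poisson draws around the per-cell mean modulated by a
#' shared lognormal cell-abundance factor (`cell_cv` = its sdlog),
#' emulating cell-to-cell expression variability.
#'
#' @param field a `cell_field`.
#' @param population list with per-cell `freeA`, `freeB`, `complex` counts
#'   (or means), `cell_cv` (lognormal sdlog, 0 = exact counts) and
#'   optionally `compartments`, a named list mapping each class to
#'   `"nucleus"`, `"cytoplasm"` or `"membrane"` (default: free proteins in
#'   the cytoplasm, complexes in the membrane band).
#' @param seed master seed.
#' @return a molecule table: `molecule_id`, `class`, `x`, `y` (nm),
#'   `compartment`, `cell_id`.
#' @export
place_molecules <- function(field, population, seed = 1L) {
  stopifnot(inherits(field, "cell_field"))
  pop <- utils::modifyList(
    list(freeA = 0, freeB = 0, complex = 0, cell_cv = 0.35,
         compartments = list(freeA = "cytoplasm", freeB = "cytoplasm",
                             complex = "membrane")), population)
  set.seed(substream_seed(seed, "placement"))
  rows <- list()
  for (cid in seq_len(field$n_cells)) {
    fac <- if (pop$cell_cv > 0)
      stats::rlnorm(1, -pop$cell_cv^2 / 2, pop$cell_cv) else 1
    for (cls in c("freeA", "freeB", "complex")) {
      mu <- pop[[cls]]
      n <- if (pop$cell_cv > 0) stats::rpois(1, mu * fac) else as.integer(mu)
      if (n == 0) next
      comp <- pop$compartments[[cls]]
      mask <- .compartment_mask(field, cid, comp)
      idx <- which(mask)
      if (!length(idx))
        stop("empty '", comp, "' compartment in cell ", cid)
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      row_i <- (pick - 1L) %% field$height + 1L
      col_i <- (pick - 1L) %/% field$height + 1L
      x <- (col_i - 0.5 + stats::runif(n, -0.5, 0.5)) * field$pixel_size
      y <- (row_i - 0.5 + stats::runif(n, -0.5, 0.5)) * field$pixel_size
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, x = x, y = y, compartment = comp, cell_id = cid)
    }
  }
  mol <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), x = numeric(0), y = numeric(0),
               compartment = character(0), cell_id = integer(0))
  mol <- cbind(molecule_id = seq_len(nrow(mol)), mol)
  rownames(mol) <- NULL
  mol
}

# ---- molecular event sampling ----------------------------------------------

.disk_jitter <- function(n, radius) {
  if (n == 0 || radius <= 0)
    return(cbind(dx = numeric(n), dy = numeric(n)))
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(dx = r * cos(a), dy = r * sin(a))
}

.event_rows <- function(mol_rows, tags, params, source_extra = NULL) {
  n <- nrow(mol_rows)
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), tags = character(0),
                      class = character(0), cell_id = integer(0),
                      source = character(0)))
  j <- .disk_jitter(n, params$rcp_displacement)
  data.frame(
    x = as.numeric(mol_rows$x + j[, "dx"]),
    y = as.numeric(mol_rows$y + j[, "dy"]),
    tags = tags,
    class = unname(c(A = "freeA", B = "freeB", AB = "complex")[tags]),
    cell_id = mol_rows$cell_id,
    source = as.character(mol_rows$molecule_id),
    row.names = NULL)
}

#' Sample molecular-level amplification events from a molecule table
#'
#' Implements the assay's generative chain. Antibody binding of each
#' epitope is Bernoulli in its occupancy. A complex is dual-eligible when
#' both epitopes are bound and their separation (uniform on `[0, s_max]`)
#' is within the proximity threshold; one circle then engages both arms:
#' each arm independently survives circle hybridization x nicking
#' (`e_circle * e_nick`), each surviving nick needs its cognate tag
#' (`e_tag`), sealing requires every nick resolved (a dual-eligible complex
#' whose one tag fails yields no event at all -- the circle stays nicked and
#' cannot amplify), and sealed circles amplify with `e_ligate * e_rca`.
#' Bound free molecules -- and each bound partner of a non-proximal
#' complex -- run the same single-arm chain. In `pla` mode only
#' dual-eligible pairs can emit (probability
#' `e_circle * e_ligate * e_rca`), always as one single-channel event; in
#' `padlock` mode every bound probe independently emits its own singleton
#' (probability `e_circle * e_ligate * e_rca`) and a dual event is
#' impossible.
#'
#' @param molecules molecule table from [place_molecules].
#' @param params [assay_params].
#' @param seed master seed.
#' @return event table: `event_id`, `x`, `y` (nm, displaced by
#'   `rcp_displacement` from the epitope), `tags` (`"A"`, `"B"` or `"AB"`),
#'   `class`, `cell_id`, `source` (molecule ids), `mode`.
#' @export
simulate_molecular_events <- function(molecules, params = assay_params(),
                                      seed = 1L) {
  stopifnot(inherits(params, "assay_params"))
  set.seed(substream_seed(seed, "binding"))
  q <- params$e_circle * params$e_nick
  tt <- params$e_tag
  L <- params$e_ligate * params$e_rca
  pl <- params$e_circle * params$e_ligate * params$e_rca
  fa <- molecules[molecules$class == "freeA", , drop = FALSE]
  fb <- molecules[molecules$class == "freeB", , drop = FALSE]
  cx <- molecules[molecules$class == "complex", , drop = FALSE]
  bern <- function(n, p) stats::runif(n) < p
  ev <- list()

  boundA <- bern(nrow(fa), params$occupancy_A)
  boundB <- bern(nrow(fb), params$occupancy_B)
  gA <- bern(nrow(cx), params$occupancy_A)
  gB <- bern(nrow(cx), params$occupancy_B)
  sep <- stats::runif(nrow(cx), 0, params$s_max)
  proximal <- sep <= params$proximity_threshold

  if (params$mode == "molboolean") {
    ev$fa <- .event_rows(fa[boundA & bern(nrow(fa), q * tt * L), ,
                            drop = FALSE], "A", params)
    ev$fb <- .event_rows(fb[boundB & bern(nrow(fb), q * tt * L), ,
                            drop = FALSE], "B", params)
    elig <- gA & gB & proximal
    # shared circle: per-arm nick survival, per-nick cognate tag, global seal
    nickA <- elig & bern(nrow(cx), q)
    nickB <- elig & bern(nrow(cx), q)
    tagA <- nickA & bern(nrow(cx), tt)
    tagB <- nickB & bern(nrow(cx), tt)
    sealed <- elig & (!nickA | tagA) & (!nickB | tagB) & (nickA | nickB)
    emit <- sealed & bern(nrow(cx), L)
    dual <- emit & nickA & nickB
    sglA <- emit & nickA & !nickB
    sglB <- emit & !nickA & nickB
    ev$dual <- .event_rows(cx[dual, , drop = FALSE], "AB", params)
    ev$cxA <- .event_rows(cx[sglA, , drop = FALSE], "A", params)
    ev$cxB <- .event_rows(cx[sglB, , drop = FALSE], "B", params)
    # bound partners outside a dual-eligible pair run independent
    # single-arm chains (single bound, or bound but out of proximity)
    sideA <- gA & !elig
    sideB <- gB & !elig
    ev$farA <- .event_rows(cx[sideA & bern(nrow(cx), q * tt * L), ,
                              drop = FALSE], "A", params)
    ev$farB <- .event_rows(cx[sideB & bern(nrow(cx), q * tt * L), ,
                              drop = FALSE], "B", params)
  } else if (params$mode == "pla") {
    elig <- gA & gB & proximal
    emit <- elig & bern(nrow(cx), pl)
    ev$dual <- .event_rows(cx[emit, , drop = FALSE], "A", params)
    ev$dual$class <- rep("complex", nrow(ev$dual))
  } else {                                   # padlock
    ev$fa <- .event_rows(fa[boundA & bern(nrow(fa), pl), , drop = FALSE],
                         "A", params)
    ev$fb <- .event_rows(fb[boundB & bern(nrow(fb), pl), , drop = FALSE],
                         "B", params)
    ev$cxA <- .event_rows(cx[gA & bern(nrow(cx), pl), , drop = FALSE],
                          "A", params)
    ev$cxB <- .event_rows(cx[gB & bern(nrow(cx), pl), , drop = FALSE],
                          "B", params)
  }
  out <- do.call(rbind, ev)
  if (is.null(out) || !nrow(out))
    out <- data.frame(x = numeric(0), y = numeric(0), tags = character(0),
                      class = character(0), cell_id = integer(0),
                      source = character(0))
  rownames(out) <- NULL
  cbind(event_id = seq_len(nrow(out)), out,
        mode = rep(params$mode, nrow(out)))
}

# ---- closed-form expectations ----------------------------------------------

#' Closed-form expected event counts per class
#'
#' Analytic twin of [simulate_molecular_events] under the same generative
#' rules. Writing `pA`, `pB` for the occupancies,
#' `q = e_circle * e_nick`, `t = e_tag`, `L = e_ligate * e_rca`,
#' `g = min(1, proximity_threshold / s_max)` (the chance a complex is
#' proximal) and `E = e_circle * e_ligate * e_rca`:
#' \describe{
#'   \item{dual (per complex)}{`pA * pB * g * q^2 * t^2 * L` -- at unit
#'     efficiencies this is the textbook dual-occupancy product, e.g.
#'     0.8 x 0.8 = 0.64.}
#'   \item{A-singleton (per complex)}{`(pA*(1-pB) + pA*pB*(1-g)) * q*t*L +
#'     pA*pB*g * q*(1-q) * t*L` (single bound, bound-but-distal, or dual
#'     circle whose B-arm dropped out); symmetric for B.}
#'   \item{A-singleton (per free A)}{`pA * q*t*L`.}
#'   \item{pla}{per complex `pA*pB*g*E`; free molecules emit nothing.}
#'   \item{padlock}{per bound probe `E`; duals impossible.}
#' }
#'
#' @param params [assay_params].
#' @param population_spec list/vector with total molecule counts `freeA`,
#'   `freeB`, `complex`.
#' @return data frame with event `class`, per-molecule probability `prob`
#'   and `expected` counts.
#' @export
expected_fractions <- function(params = assay_params(), population_spec) {
  stopifnot(inherits(params, "assay_params"))
  ps <- as.list(population_spec)
  nA <- ps$freeA %||% 0; nB <- ps$freeB %||% 0; nC <- ps$complex %||% 0
  pA <- params$occupancy_A; pB <- params$occupancy_B
  q <- params$e_circle * params$e_nick
  t <- params$e_tag
  L <- params$e_ligate * params$e_rca
  E <- params$e_circle * params$e_ligate * params$e_rca
  g <- if (params$s_max == 0) 1 else
    min(1, params$proximity_threshold / params$s_max)
  if (params$mode == "molboolean") {
    p_dual <- pA * pB * g * q^2 * t^2 * L
    pA_cx <- (pA * (1 - pB) + pA * pB * (1 - g)) * q * t * L +
      pA * pB * g * q * (1 - q) * t * L
    pB_cx <- (pB * (1 - pA) + pA * pB * (1 - g)) * q * t * L +
      pA * pB * g * q * (1 - q) * t * L
    eA <- nA * pA * q * t * L + nC * pA_cx
    eB <- nB * pB * q * t * L + nC * pB_cx
    eD <- nC * p_dual
    prob <- c(pA * q * t * L, pB * q * t * L, p_dual)
  } else if (params$mode == "pla") {
    eA <- 0; eB <- 0; eD <- nC * pA * pB * g * E
    prob <- c(0, 0, pA * pB * g * E)
  } else {
    eA <- nA * pA * E + nC * pA * E
    eB <- nB * pB * E + nC * pB * E
    eD <- 0
    prob <- c(pA * E, pB * E, 0)
  }
  data.frame(class = c("freeA", "freeB", "complex"),
             prob = prob, expected = c(eA, eB, eD))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- rendering -------------------------------------------------------------

.add_spots <- function(img, x_px, y_px, amp, sigma_px) {
  if (!length(x_px)) return(img)
  h <- nrow(img); w <- ncol(img)
  rad <- ceiling(4 * sigma_px)
  off <- seq(-rad, rad)
  for (i in seq_along(x_px)) {
    cx <- x_px[i]; cy <- y_px[i]
    cols <- round(cx) + off; rows <- round(cy) + off
    okc <- cols >= 1 & cols <= w; okr <- rows >= 1 & rows <= h
    if (!any(okc) || !any(okr)) next
    gx <- exp(-((cols[okc] - cx)^2) / (2 * sigma_px^2))
    gy <- exp(-((rows[okr] - cy)^2) / (2 * sigma_px^2))
    img[rows[okr], cols[okc]] <-
      img[rows[okr], cols[okc]] + amp[i] * outer(gy, gx)
  }
  img
}

#' Render molecular events to a multi-channel image stack
#'
#' Produces the three channels (nuclear, detA, detB) as count images. Each
#' event is drawn as an isotropic Gaussian spot in detA and/or detB
#' according to its tag set; a dual event shares one centroid in both
#' channels. Nuclei are drawn in the nuclear channel. Poisson shot noise
#' plus Gaussian read noise is applied unless `render$noise` is `FALSE`.
#'
#' @param events event table from [simulate_molecular_events].
#' @param field the `cell_field` the events live in.
#' @param render [render_params].
#' @param seed master seed.
#' @return list with `channels` (named list of matrices) and `truth` (the
#'   event table with pixel coordinates `x_px`, `y_px` appended).
#' @export
render_field <- function(events, field, render = render_params(),
                         seed = 1L) {
  stopifnot(inherits(field, "cell_field"), inherits(render, "render_params"))
  set.seed(substream_seed(seed, "render"))
  h <- field$height; w <- field$width
  sigma_px <- render$psf_sigma / field$pixel_size
  bg <- render$background
  nuclear <- matrix(bg[["nuclear"]], h, w)
  nuclear[field$nuclei_lab > 0] <-
    nuclear[field$nuclei_lab > 0] + render$nucleus_intensity
  nuclear <- .ebi_to_mat(EBImage::gblur(.mat_to_ebi(nuclear), sigma = 2))
  detA <- matrix(bg[["detA"]], h, w)
  detB <- matrix(bg[["detB"]], h, w)
  n <- nrow(events)
  truth <- events
  if (n) {
    x_px <- events$x / field$pixel_size + 0.5
    y_px <- events$y / field$pixel_size + 0.5
    size_amp <- stats::rlnorm(n, render$amp_meanlog, render$amp_sdlog)
    fA <- stats::rlnorm(n, 0, render$channel_sdlog)
    fB <- stats::rlnorm(n, 0, render$channel_sdlog)
    inA <- events$tags %in% c("A", "AB")
    inB <- events$tags %in% c("B", "AB")
    detA <- .add_spots(detA, x_px[inA], y_px[inA],
                       (size_amp * fA)[inA], sigma_px)
    detB <- .add_spots(detB, x_px[inB], y_px[inB],
                       (size_amp * fB)[inB], sigma_px)
    truth$x_px <- x_px
    truth$y_px <- y_px
  } else {
    truth$x_px <- numeric(0)
    truth$y_px <- numeric(0)
  }
  channels <- list(nuclear = nuclear, detA = detA, detB = detB)
  if (render$noise) {
    set.seed(substream_seed(seed, "noise"))
    channels <- lapply(channels, function(m) {
      m2 <- stats::rpois(length(m), pmax(m, 0)) +
        stats::rnorm(length(m), 0, render$read_noise)
      matrix(pmin(pmax(round(m2), 0), 65535), nrow(m), ncol(m))
    })
  }
  list(channels = channels, truth = truth)
}

# EBImage stores images [x, y]; this package uses [row = y, col = x].
.mat_to_ebi <- function(m) EBImage::Image(t(m))
.ebi_to_mat <- function(img) t(EBImage::imageData(img))

# ---- experiment orchestration ----------------------------------------------

#' Simulate a complete ground-truthed experiment
#'
#' Builds a cell field, places molecules, samples molecular events under
#' the chosen assay mode, renders the image stack and (optionally) writes
#' TIFF + ground-truth CSV + a JSON sidecar echoing the resolved
#' configuration and seed.
#'
#' @param mode `"molboolean"`, `"pla"` or `"padlock"`.
#' @param n_cells,width,height,pixel_size field geometry.
#' @param population see [place_molecules].
#' @param params [assay_params] (its `mode` is overridden by `mode`).
#' @param render [render_params].
#' @param field_config geometry overrides for [make_field].
#' @param seed master seed.
#' @param outdir optional output directory.
#' @param prefix file-name prefix when writing.
#' @return list: `field`, `molecules`, `events`, `channels`, `truth`,
#'   `files` (when written).
#' @export
simulate_experiment <- function(mode = "molboolean", n_cells = 4L,
                                width = 640L, height = 640L,
                                pixel_size = 100,
                                population = list(freeA = 19, freeB = 19,
                                                  complex = 21),
                                params = assay_params(),
                                render = render_params(),
                                field_config = list(), seed = 1L,
                                outdir = NULL, prefix = "sim") {
  params$mode <- match.arg(mode, c("molboolean", "pla", "padlock"))
  field <- make_field(n_cells, width, height, pixel_size,
                      config = field_config, seed = seed)
  mol <- place_molecules(field, population, seed = seed)
  ev <- simulate_molecular_events(mol, params, seed = seed)
  ev <- .add_spurious(ev, field, params, seed)
  rn <- render_field(ev, field, render, seed = seed)
  out <- list(field = field, molecules = mol, events = ev,
              channels = rn$channels, truth = rn$truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tif <- file.path(outdir, paste0(prefix, ".tif"))
    csv <- file.path(outdir, paste0(prefix, "_truth.csv"))
    side <- file.path(outdir, paste0(prefix, "_run.json"))
    write_image_stack(rn$channels, tif)
    utils::write.csv(rn$truth, csv, row.names = FALSE)
    write_sidecar(list(mode = params$mode, n_cells = n_cells, width = width,
                       height = height, pixel_size = pixel_size,
                       population = population, params = unclass(params),
                       render = unclass(render)),
                  seed,
                  list(molecules = nrow(mol), events = nrow(ev)), side)
    out$files <- c(tiff = tif, truth = csv, sidecar = side)
  }
  out
}

.add_spurious <- function(ev, field, params, seed) {
  if (params$spurious_rate <= 0) return(ev)
  set.seed(substream_seed(seed, "spurious"))
  ns <- stats::rpois(2, params$spurious_rate)
  if (sum(ns) == 0) return(ev)
  extra <- data.frame(
    x = stats::runif(sum(ns), 0, field$width * field$pixel_size),
    y = stats::runif(sum(ns), 0, field$height * field$pixel_size),
    tags = rep(c("A", "B"), ns))
  extra$class <- c(A = "freeA", B = "freeB")[extra$tags]
  extra$cell_id <- NA_integer_
  extra$source <- "spurious"
  extra$mode <- if (nrow(ev)) ev$mode[1] else params$mode
  extra <- cbind(event_id = nrow(ev) + seq_len(nrow(extra)), extra)
  rbind(ev, extra[, names(ev)])
}

#' Paired dual-tag / padlock simulation from one molecule table
#'
#' The padlock control replaces the nickable circle with per-probe padlocks
#' that can never report duality; comparing the two modes on identical
#' ground truth isolates what the dual readout adds. One field and one
#' molecule table are generated; events are sampled and rendered under both
#' modes.
#'
#' @inheritParams simulate_experiment
#' @return list with `field`, `molecules` and per-mode `molboolean` /
#'   `padlock` sub-lists (`events`, `channels`, `truth`), plus `files` when
#'   `outdir` is given.
#' @export
simulate_mode_pair <- function(n_cells = 4L, width = 640L, height = 640L,
                               pixel_size = 100,
                               population = list(freeA = 19, freeB = 19,
                                                 complex = 21),
                               params = assay_params(),
                               render = render_params(),
                               field_config = list(), seed = 1L,
                               outdir = NULL) {
  field <- make_field(n_cells, width, height, pixel_size,
                      config = field_config, seed = seed)
  mol <- place_molecules(field, population, seed = seed)
  out <- list(field = field, molecules = mol)
  files <- character(0)
  for (mode in c("molboolean", "padlock")) {
    p <- params; p$mode <- mode
    ev <- simulate_molecular_events(mol, p, seed = substream_seed(seed, mode))
    rn <- render_field(ev, field, render, seed = substream_seed(seed, mode))
    out[[mode]] <- list(events = ev, channels = rn$channels,
                        truth = rn$truth)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      tif <- file.path(outdir, paste0("pair_", mode, ".tif"))
      csv <- file.path(outdir, paste0("pair_", mode, "_truth.csv"))
      write_image_stack(rn$channels, tif)
      utils::write.csv(rn$truth, csv, row.names = FALSE)
      files <- c(files, stats::setNames(c(tif, csv),
                                        paste0(mode, c("_tiff", "_truth"))))
    }
  }
  if (length(files)) out$files <- files
  out
}
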