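# ---- parameters ------------------------------------------------------------

#' Quantification-pipeline parameters
#'
#' Mirrors the module chain of a CellProfiler-style spot pipeline: identify
#' nuclei by diameter with Otsu thresholding, expand to cells by distance N,
#' enhance speckles with a white top-hat, identify spots by diameter,
#' shrink-to-point and regrow by distance B, merge across channels, mask to
#' cells, measure and classify.
#'
#' @param nucleus_diameter_range accepted nucleus diameter (px).
#' @param nucleus_threshold `"otsu2"` or `"otsu3"` (three-class Otsu with
#'   middle + high classes as foreground, used for faint nuclear stains).
#' @param cell_expand_N px the nuclei are expanded by to delineate cells.
#' @param spot_diameter_range accepted spot diameter (px).
#' @param speckle_feature_size radius (px) of the top-hat structuring disk;
#'   features larger than the disk are suppressed.
#' @param spot_threshold `"otsu2"`, `"manual"` or `"robust_background"`.
#' @param spot_threshold_level manual global threshold (counts) when
#'   `spot_threshold = "manual"`.
#' @param robust_k sd multiplier of the robust-background threshold.
#' @param spot_expand_B px: spots are shrunk to their centroid and regrown
#'   to a disk of this radius before cross-channel merging.
#' @param spot_declump_tolerance intensity-watershed tolerance used to
#'   split touching spots, as a multiple of the spot threshold.
#' @param declump_tolerance watershed tolerance (px) used when splitting
#'   touching nuclei.
#' @return a `quant_params` object.
#' @export
quant_params <- function(nucleus_diameter_range = c(40, 220),
                         nucleus_threshold = c("otsu2", "otsu3"),
                         cell_expand_N = 75,
                         spot_diameter_range = c(2, 18),
                         speckle_feature_size = 7,
                         spot_threshold = c("robust_background", "otsu2",
                                            "manual"),
                         spot_threshold_level = NULL,
                         robust_k = 3,
                         spot_expand_B = 2,
                         spot_declump_tolerance = 0.25,
                         declump_tolerance = 10) {
  nucleus_threshold <- match.arg(nucleus_threshold)
  spot_threshold <- match.arg(spot_threshold)
  stopifnot(all(nucleus_diameter_range > 0),
            diff(nucleus_diameter_range) >= 0,
            all(spot_diameter_range > 0), diff(spot_diameter_range) >= 0,
            cell_expand_N > 0, speckle_feature_size > 0, spot_expand_B > 0)
  if (spot_threshold == "manual" && is.null(spot_threshold_level))
    stop("spot_threshold = 'manual' needs spot_threshold_level")
  structure(list(nucleus_diameter_range = nucleus_diameter_range,
                 nucleus_threshold = nucleus_threshold,
                 cell_expand_N = cell_expand_N,
                 spot_diameter_range = spot_diameter_range,
                 speckle_feature_size = speckle_feature_size,
                 spot_threshold = spot_threshold,
                 spot_threshold_level = spot_threshold_level,
                 robust_k = robust_k,
                 spot_expand_B = spot_expand_B,
                 spot_declump_tolerance = spot_declump_tolerance,
                 declump_tolerance = declump_tolerance),
            class = "quant_params")
}

#' Dual-channel classification thresholds
#'
#' Objects are classified in the background-subtracted intensity plane
#' (I_A - t_A, I_B - t_B), clipped at 0. The angle from the I_A axis,
#' `phi = atan2(I_B', I_A')`, is binned by two half-lines through the
#' origin: `phi < theta_low` is free A, `phi > theta_high` is free B, and
#' the wedge between is the complex class.
#'
#' Three background modes are exposed. `"local"` (default) subtracts, per
#' object, the median intensity of the non-object pixels in an annulus
#' around the object -- this tracks the local offset contributed by the
#' tails of neighbouring products and keeps crowded dual signals inside
#' the wedge. `"global_otsu"` subtracts one per-channel Otsu level
#' computed on non-spot pixels; `"manual"` uses the supplied `t_A`, `t_B`
#' (the density-plot workflow).
#'
#' @param background `"local"`, `"global_otsu"` or `"manual"`.
#' @param t_A,t_B manual background cutoffs (counts); supplying them
#'   implies `background = "manual"`.
#' @param theta_low,theta_high angle bounds in degrees,
#'   `0 <= theta_low < theta_high <= 90`.
#' @param bg_annulus inner/outer radius (px) of the local background
#'   annulus.
#' @return a `classification_thresholds` object.
#' @export
classification_thresholds <- function(background = c("local", "global_otsu",
                                                     "manual"),
                                      t_A = NULL, t_B = NULL,
                                      theta_low = 30, theta_high = 60,
                                      bg_annulus = c(4, 8)) {
  if (!is.null(t_A) || !is.null(t_B)) background <- "manual"
  else background <- match.arg(background)
  if (background == "manual" && (is.null(t_A) || is.null(t_B)))
    stop("manual background needs both t_A and t_B")
  if (!(theta_low >= 0 && theta_low < theta_high && theta_high <= 90))
    stop("need 0 <= theta_low < theta_high <= 90")
  if (!is.null(t_A) && t_A < 0) stop("t_A must be >= 0")
  if (!is.null(t_B) && t_B < 0) stop("t_B must be >= 0")
  stopifnot(length(bg_annulus) == 2, bg_annulus[1] < bg_annulus[2])
  structure(list(background = background, t_A = t_A, t_B = t_B,
                 theta_low = theta_low, theta_high = theta_high,
                 bg_annulus = bg_annulus),
            class = "classification_thresholds")
}

# ---- thresholds ------------------------------------------------------------

.otsu2 <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v) || diff(range(v)) == 0) return(max(v, 0))
  mx <- max(v)
  as.numeric(EBImage::otsu(EBImage::Image(v / mx), range = c(0, 1),
                           levels = 256)) * mx
}

# Three-class Otsu (exhaustive over a binned histogram); returns the two
# cut levels.
.otsu3 <- function(v, levels = 128L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), levels)
  mid <- (br[-1] + br[-length(br)]) / 2
  w <- h / sum(h)
  cw <- cumsum(w); cm <- cumsum(w * mid)
  best <- -Inf; cut <- c(1L, 2L)
  for (i in 1:(levels - 2L)) {
    for (j in (i + 1L):(levels - 1L)) {
      w0 <- cw[i]; w1 <- cw[j] - cw[i]; w2 <- 1 - cw[j]
      if (w0 <= 0 || w1 <= 0 || w2 <= 0) next
      m0 <- cm[i] / w0
      m1 <- (cm[j] - cm[i]) / w1
      m2 <- (cm[levels] - cm[j]) / w2
      mt <- cm[levels]
      s <- w0 * (m0 - mt)^2 + w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2
      if (s > best) { best <- s; cut <- c(i, j) }
    }
  }
  c(br[cut[1] + 1L], br[cut[2] + 1L])
}

.robust_background <- function(v, k = 3, trim = 0.05) {
  qs <- stats::quantile(v, c(trim, 1 - trim), names = FALSE)
  core <- v[v >= qs[1] & v <= qs[2]]
  mean(core) + k * stats::sd(core)
}

# ---- segmentation ----------------------------------------------------------

.equiv_diameter <- function(area) 2 * sqrt(area / pi)

.filter_labels_by_diameter <- function(lab, drange) {
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  d <- .equiv_diameter(areas)
  keep <- which(d >= drange[1] & d <= drange[2])
  out <- matrix(0L, nrow(lab), ncol(lab))
  newid <- integer(max(lab))
  newid[keep] <- seq_along(keep)
  sel <- lab > 0
  out[sel] <- newid[lab[sel]]
  out
}

#' Segment nuclei from the nuclear channel
#'
#' Otsu thresholding (two- or three-class), hole filling, distance-map
#' watershed declumping of touching nuclei, and a diameter gate. An empty
#' image yields zero labels, not an error.
#'
#' @param img nuclear-channel matrix (row = y, col = x).
#' @param params [quant_params].
#' @return integer label matrix with sequential labels.
#' @export
segment_nuclei <- function(img, params = quant_params()) {
  stopifnot(is.matrix(img))
  v <- as.numeric(img)
  th <- if (params$nucleus_threshold == "otsu2") .otsu2(v)
        else {
    # three-class Otsu: the middle class joins the foreground when its
    # mean sits closer to the high class than to the background class
    cuts <- .otsu3(v)
    m0 <- mean(v[v <= cuts[1]])
    m1 <- mean(v[v > cuts[1] & v <= cuts[2]])
    m2 <- mean(v[v > cuts[2]])
    if (is.finite(m1) && (m1 - m0) >= (m2 - m1)) cuts[1] else cuts[2]
  }
  mask <- img > th
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  ebi <- .mat_to_ebi(mask * 1)
  ebi <- EBImage::fillHull(ebi)
  ebi <- EBImage::opening(ebi, EBImage::makeBrush(5, "disc"))
  dm <- EBImage::distmap(ebi)
  ws <- EBImage::watershed(dm, tolerance = params$declump_tolerance, ext = 1)
  lab <- .ebi_to_mat(ws)
  storage.mode(lab) <- "integer"
  lab <- .filter_labels_by_diameter(lab, params$nucleus_diameter_range)
  lab
}

#' Delineate cells by expanding nuclei
#'
#' Every pixel within `N` px (Euclidean) of a nucleus is assigned to its
#' nearest nucleus; equidistant pixels go to the lower label id. Each cell
#' therefore contains its nucleus.
#'
#' @param nuclei_lab label matrix from [segment_nuclei].
#' @param N expansion distance in px (> 0).
#' @return integer cell label matrix (same label ids as the nuclei).
#' @export
delineate_cells <- function(nuclei_lab, N) {
  if (!is.numeric(N) || length(N) != 1 || N <= 0)
    stop("N must be a positive distance in px")
  k <- max(nuclei_lab)
  out <- matrix(0L, nrow(nuclei_lab), ncol(nuclei_lab))
  if (k == 0) return(out)
  best_d <- matrix(Inf, nrow(nuclei_lab), ncol(nuclei_lab))
  for (l in seq_len(k)) {
    m <- nuclei_lab == l
    if (!any(m)) next
    # distance of every pixel to this nucleus: distmap of the complement
    d <- .ebi_to_mat(EBImage::distmap(.mat_to_ebi((!m) * 1)))
    upd <- d < best_d                 # strict: ties keep the lower label
    best_d[upd] <- d[upd]
    out[upd] <- l
  }
  out[best_d > N] <- 0L
  out
}

#' White top-hat speckle enhancement
#'
#' Subtracts the morphological opening with a disk of radius
#' `feature_size`, removing slowly varying background while preserving
#' bright features smaller than the disk. Output is non-negative; a
#' constant image maps to all zeros.
#'
#' @param img single-channel matrix.
#' @param feature_size disk radius in px (> 0).
#' @return enhanced matrix.
#' @export
enhance_speckles <- function(img, feature_size) {
  if (!is.numeric(feature_size) || feature_size <= 0)
    stop("feature_size must be > 0")
  stopifnot(is.matrix(img))
  brush <- EBImage::makeBrush(2 * round(feature_size) + 1, "disc")
  # grayscale morphology in EBImage operates on [0, 1]; rescale count images
  mx <- max(img, 1)
  opened <- .ebi_to_mat(EBImage::opening(.mat_to_ebi(img / mx), brush)) * mx
  pmax(img - opened, 0)
}

#' Detect spots in a speckle-enhanced image
#'
#' Global thresholding (two-class Otsu, manual level, or robust background
#' = trimmed mean + k sd) followed by connected-component labelling and an
#' equivalent-diameter gate.
#'
#' @param enhanced matrix from [enhance_speckles].
#' @param params [quant_params].
#' @return integer spot label matrix.
#' @export
detect_spots <- function(enhanced, params = quant_params()) {
  stopifnot(is.matrix(enhanced))
  v <- as.numeric(enhanced)
  th <- switch(params$spot_threshold,
               otsu2 = .otsu2(v),
               manual = params$spot_threshold_level,
               robust_background = .robust_background(v, params$robust_k))
  mask <- enhanced > th
  if (!any(mask)) return(matrix(0L, nrow(enhanced), ncol(enhanced)))
  # intensity watershed splits touching spots at their saddle
  ws <- EBImage::watershed(.mat_to_ebi(enhanced * mask),
                           tolerance = params$spot_declump_tolerance * th,
                           ext = 1)
  lab <- .ebi_to_mat(ws)
  storage.mode(lab) <- "integer"
  .filter_labels_by_diameter(lab, params$spot_diameter_range)
}

.centroids <- function(lab, weights = NULL) {
  if (max(lab) == 0)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  idx <- which(lab > 0)
  l <- lab[idx]
  row_i <- (idx - 1L) %% nrow(lab) + 1L
  col_i <- (idx - 1L) %/% nrow(lab) + 1L
  if (is.null(weights)) {
    data.frame(label = sort(unique(l)),
               x = as.numeric(tapply(col_i, l, mean)),
               y = as.numeric(tapply(row_i, l, mean)))
  } else {
    w <- weights[idx]
    sw <- tapply(w, l, sum)
    data.frame(label = sort(unique(l)),
               x = as.numeric(tapply(col_i * w, l, sum) / sw),
               y = as.numeric(tapply(row_i * w, l, sum) / sw))
  }
}

#' Consolidate per-channel spots into unified RCP objects
#'
#' Each detected spot is shrunk to its centroid and regrown to a disk of
#' radius `B`; disks overlapping across channels (centroids closer than
#' `2B`) are merged into one object, so a product stained in both channels
#' becomes a single object with dual provenance.
#'
#' @param spotsA,spotsB spot label matrices on the same grid.
#' @param B disk radius in px (> 0).
#' @return list: `objects` (data frame `object_id`, `x`, `y`, `from_A`,
#'   `from_B`) and `label` (object label matrix of painted disks).
#' @export
consolidate_spots <- function(spotsA, spotsB, B, intensityA = NULL,
                              intensityB = NULL) {
  if (!is.numeric(B) || B <= 0) stop("B must be > 0")
  stopifnot(identical(dim(spotsA), dim(spotsB)))
  ca <- .centroids(spotsA, intensityA); cb <- .centroids(spotsB, intensityB)
  pts <- rbind(
    if (nrow(ca)) cbind(ca, chan = "A") else NULL,
    if (nrow(cb)) cbind(cb, chan = "B") else NULL)
  h <- nrow(spotsA); w <- ncol(spotsA)
  if (is.null(pts) || !nrow(pts))
    return(list(objects = data.frame(object_id = integer(0), x = numeric(0),
                                     y = numeric(0), from_A = logical(0),
                                     from_B = logical(0)),
                label = matrix(0L, h, w)))
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ia <- which(pts$chan == "A"); ib <- which(pts$chan == "B")
  if (length(ia) && length(ib)) {
    d2 <- outer(pts$x[ia], pts$x[ib], "-")^2 +
      outer(pts$y[ia], pts$y[ib], "-")^2
    hits <- which(d2 < (2 * B)^2, arr.ind = TRUE)
    for (p in seq_len(nrow(hits))) {
      ri <- find(ia[hits[p, 1]]); rj <- find(ib[hits[p, 2]])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ids <- match(roots, sort(unique(roots)))
  objects <- do.call(rbind, lapply(sort(unique(ids)), function(k) {
    sel <- ids == k
    data.frame(object_id = k, x = mean(pts$x[sel]), y = mean(pts$y[sel]),
               from_A = any(pts$chan[sel] == "A"),
               from_B = any(pts$chan[sel] == "B"))
  }))
  # paint member disks with the merged object id; pixels contested by
  # different objects go to the nearest member centroid
  lab <- matrix(0L, h, w)
  dist <- matrix(Inf, h, w)
  r <- ceiling(B)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= B^2, ]
  for (i in seq_len(n)) {
    rows <- round(pts$y[i]) + off$dy
    cols <- round(pts$x[i]) + off$dx
    ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
    pix <- cbind(rows[ok], cols[ok])
    d2 <- (rows[ok] - pts$y[i])^2 + (cols[ok] - pts$x[i])^2
    upd <- d2 < dist[pix]
    lab[pix[upd, , drop = FALSE]] <- ids[i]
    dist[pix[upd, , drop = FALSE]] <- d2[upd]
  }
  list(objects = objects, label = lab)
}

#' Mask objects to cells and assign cell ids
#'
#' Objects whose centroid falls on background are removed (off-cell specks
#' and products of excluded cells); the rest inherit the cell label under
#' their centroid.
#'
#' @param objects object data frame from [consolidate_spots].
#' @param cell_lab cell label matrix from [delineate_cells].
#' @return the objects that lie inside cells, with `cell_id` appended.
#' @export
mask_and_assign <- function(objects, cell_lab) {
  if (!nrow(objects)) return(cbind(objects, cell_id = integer(0)))
  rows <- pmin(pmax(round(objects$y), 1), nrow(cell_lab))
  cols <- pmin(pmax(round(objects$x), 1), ncol(cell_lab))
  cid <- cell_lab[cbind(rows, cols)]
  out <- objects[cid > 0, , drop = FALSE]
  out$cell_id <- cid[cid > 0]
  rownames(out) <- NULL
  out
}

#' Measure dual-channel intensities and classify objects
#'
#' Mean raw intensities over each object mask are measured in both
#' detection channels, background cutoffs are subtracted (clipped at 0),
#' and each object is binned by its angle in the intensity plane (see
#' [classification_thresholds]). Objects at the origin of the subtracted
#' plane are discarded as background.
#'
#' @param objects assigned objects from [mask_and_assign].
#' @param label object label matrix from [consolidate_spots].
#' @param chanA,chanB raw detection-channel matrices.
#' @param thresholds [classification_thresholds].
#' @return a spot table: `object_id`, `x`, `y`, `cell_id`, `I_A`, `I_B`,
#'   `phi` (degrees) and `class` in `freeA` / `freeB` / `complex`.
#' @export
measure_and_classify <- function(objects, label, chanA, chanB,
                                 thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (!nrow(objects))
    return(data.frame(object_id = integer(0), x = numeric(0),
                      y = numeric(0), cell_id = integer(0),
                      I_A = numeric(0), I_B = numeric(0), phi = numeric(0),
                      class = character(0)))
  sel <- label > 0
  mA <- tapply(chanA[sel], label[sel], mean)
  mB <- tapply(chanB[sel], label[sel], mean)
  I_A <- as.numeric(mA[as.character(objects$object_id)])
  I_B <- as.numeric(mB[as.character(objects$object_id)])
  if (thresholds$background == "local") {
    bg <- .local_background(objects, label, chanA, chanB,
                            thresholds$bg_annulus)
    t_A <- bg$t_A
    t_B <- bg$t_B
  } else if (thresholds$background == "global_otsu") {
    t_A <- .otsu2(chanA[!sel])
    t_B <- .otsu2(chanB[!sel])
  } else {
    t_A <- thresholds$t_A
    t_B <- thresholds$t_B
  }
  Ap <- pmax(I_A - t_A, 0)
  Bp <- pmax(I_B - t_B, 0)
  phi <- atan2(Bp, Ap) * 180 / pi
  keep <- !(Ap == 0 & Bp == 0)
  cls <- ifelse(phi < thresholds$theta_low, "freeA",
                ifelse(phi > thresholds$theta_high, "freeB", "complex"))
  out <- data.frame(object_id = objects$object_id, x = objects$x,
                    y = objects$y, cell_id = objects$cell_id,
                    I_A = I_A, I_B = I_B, phi = phi, class = cls)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}


# Per-object local background: median of non-object pixels in an annulus
# around the object centroid (falls back to the whole-image non-object
# median when the annulus is fully covered by objects).
.local_background <- function(objects, label, chanA, chanB, annulus) {
  h <- nrow(label); w <- ncol(label)
  off <- expand.grid(dy = -annulus[2]:annulus[2],
                     dx = -annulus[2]:annulus[2])
  d2 <- off$dx^2 + off$dy^2
  off <- off[d2 > annulus[1]^2 & d2 <= annulus[2]^2, ]
  freeA <- stats::median(chanA[label == 0])
  freeB <- stats::median(chanB[label == 0])
  t_A <- numeric(nrow(objects)); t_B <- numeric(nrow(objects))
  for (i in seq_len(nrow(objects))) {
    rows <- round(objects$y[i]) + off$dy
    cols <- round(objects$x[i]) + off$dx
    ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
    pix <- cbind(rows[ok], cols[ok])
    pix <- pix[label[pix] == 0, , drop = FALSE]
    if (nrow(pix) >= 8) {
      t_A[i] <- stats::median(chanA[pix])
      t_B[i] <- stats::median(chanB[pix])
    } else {
      t_A[i] <- freeA
      t_B[i] <- freeB
    }
  }
  list(t_A = t_A, t_B = t_B)
}

#' Per-cell counts and normalized fractions
#'
#' Counts of the three signal categories per cell, normalized against the
#' total number of signals in that cell. Cells with zero spots are
#' reported with `n = 0` and `NA` fractions.
#'
#' @param spot_table classified spot table.
#' @param cell_ids optional vector of all cell ids present in the field
#'   (so empty cells are reported too).
#' @return data frame: `cell_id`, `n_freeA`, `n_freeB`, `n_complex`, `n`,
#'   `f_freeA`, `f_freeB`, `f_complex`.
#' @export
per_cell_counts <- function(spot_table, cell_ids = NULL) {
  ids <- sort(unique(c(cell_ids, spot_table$cell_id)))
  out <- do.call(rbind, lapply(ids, function(cid) {
    sub <- spot_table[spot_table$cell_id == cid, , drop = FALSE]
    n <- c(freeA = sum(sub$class == "freeA"),
           freeB = sum(sub$class == "freeB"),
           complex = sum(sub$class == "complex"))
    tot <- sum(n)
    data.frame(cell_id = cid, n_freeA = n[["freeA"]],
               n_freeB = n[["freeB"]], n_complex = n[["complex"]], n = tot,
               f_freeA = if (tot > 0) n[["freeA"]] / tot else NA_real_,
               f_freeB = if (tot > 0) n[["freeB"]] / tot else NA_real_,
               f_complex = if (tot > 0) n[["complex"]] / tot else NA_real_)
  }))
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), n_freeA = integer(0),
                      n_freeB = integer(0), n_complex = integer(0),
                      n = integer(0), f_freeA = numeric(0),
                      f_freeB = numeric(0), f_complex = numeric(0))
  rownames(out) <- NULL
  out
}

#' Pooled frame-level fractions
#'
#' Share of all in-cell products per category in the whole frame (the
#' tissue-style readout, where per-cell assignment is unreliable).
#'
#' @param spot_table classified spot table.
#' @return named numeric vector of the three fractions.
#' @export
frame_fractions <- function(spot_table) {
  n <- nrow(spot_table)
  c(f_freeA = sum(spot_table$class == "freeA") / n,
    f_freeB = sum(spot_table$class == "freeB") / n,
    f_complex = sum(spot_table$class == "complex") / n)
}

# ---- full pipelines --------------------------------------------------------

#' Quantify a dual-channel field
#'
#' Runs the full chain on a (nuclear, detA, detB) stack: nucleus
#' segmentation, cell delineation, per-channel speckle enhancement and
#' spot detection, cross-channel consolidation, masking to cells,
#' intensity classification and per-cell summaries.
#'
#' @param channels named list of matrices (`nuclear`, `detA`, `detB`).
#' @param params [quant_params].
#' @param thresholds [classification_thresholds].
#' @return list: `nuclei_lab`, `cell_lab`, `spots` (classified spot
#'   table), `cells` (per-cell summary), `frame` (pooled fractions).
#' @export
quantify_field <- function(channels, params = quant_params(),
                           thresholds = classification_thresholds()) {
  stopifnot(all(c("nuclear", "detA", "detB") %in% names(channels)))
  nuc <- segment_nuclei(channels$nuclear, params)
  cells <- delineate_cells(nuc, params$cell_expand_N)
  enhA <- enhance_speckles(channels$detA, params$speckle_feature_size)
  enhB <- enhance_speckles(channels$detB, params$speckle_feature_size)
  spotsA <- detect_spots(enhA, params)
  spotsB <- detect_spots(enhB, params)
  cons <- consolidate_spots(spotsA, spotsB, params$spot_expand_B,
                            intensityA = enhA, intensityB = enhB)
  assigned <- mask_and_assign(cons$objects, cells)
  spots <- measure_and_classify(assigned, cons$label, channels$detA,
                                channels$detB, thresholds)
  ids <- setdiff(sort(unique(cells[cells > 0])), 0)
  list(nuclei_lab = nuc, cell_lab = cells, spots = spots,
       cells = per_cell_counts(spots, cell_ids = ids),
       frame = frame_fractions(spots))
}

#' Quantify a single-channel proximity-ligation field
#'
#' The one-category variant: nuclei by three-class Otsu (middle + high
#' classes foreground), cells by N-expansion, speckle enhancement, spot
#' detection, masking to cells and per-cell spot counts.
#'
#' @param nuclear,signal channel matrices.
#' @param params [quant_params] (its `nucleus_threshold` is forced to
#'   `"otsu3"`).
#' @return list: `cell_lab`, `spots` (assigned objects), `cells`
#'   (data frame `cell_id`, `n`).
#' @export
quantify_pla <- function(nuclear, signal, params = quant_params()) {
  params$nucleus_threshold <- "otsu3"
  nuc <- segment_nuclei(nuclear, params)
  cells <- delineate_cells(nuc, params$cell_expand_N)
  enh <- enhance_speckles(signal, params$speckle_feature_size)
  spots <- detect_spots(enh, params)
  cen <- .centroids(spots)
  objects <- data.frame(object_id = seq_len(nrow(cen)), x = cen$x,
                        y = cen$y)
  assigned <- mask_and_assign(objects, cells)
  ids <- setdiff(sort(unique(cells[cells > 0])), 0)
  counts <- data.frame(cell_id = ids,
                       n = vapply(ids, function(cid)
                         sum(assigned$cell_id == cid), 0L))
  list(cell_lab = cells, spots = assigned, cells = counts)
}

#' Write a quality-control overlay image
#'
#' Writes a PNG of the two detection channels (A in magenta, B in green)
#' with classified object positions marked: free A magenta, free B green,
#' complex white.
#'
#' @param channels named channel list.
#' @param spot_table classified spot table.
#' @param path output PNG.
#' @return `path`, invisibly.
#' @export
qc_overlay <- function(channels, spot_table, path) {
  sc <- function(m) {
    m <- m - min(m)
    if (max(m) > 0) m / max(m) else m
  }
  r <- sc(channels$detA); g <- sc(channels$detB); b <- sc(channels$detA)
  mark <- function(ch, cls_on, val) {
    for (i in seq_len(nrow(spot_table))) {
      if (!spot_table$class[i] %in% cls_on) next
      rr <- round(spot_table$y[i]); cc <- round(spot_table$x[i])
      rs <- max(1, rr - 3):min(nrow(ch), rr + 3)
      ch[rs, max(1, cc - 3)] <- val; ch[rs, min(ncol(ch), cc + 3)] <- val
      cs <- max(1, cc - 3):min(ncol(ch), cc + 3)
      ch[max(1, rr - 3), cs] <- val; ch[min(nrow(ch), rr + 3), cs] <- val
    }
    ch
  }
  r <- mark(r, c("freeA", "complex"), 1)
  g <- mark(g, c("freeB", "complex"), 1)
  b <- mark(b, c("freeA", "complex"), 1)
  img <- EBImage::rgbImage(red = t(r), green = t(g), blue = t(b))
  EBImage::writeImage(img, path)
  invisible(path)
}
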