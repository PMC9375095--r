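# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# character-table reverse complement
bf_rc <- function(s) {
  if (!nzchar(s)) return("")
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# longest terminal-anchored exact rc match by greedy substring search
bf_terminal_match <- function(query, target, from5 = TRUE) {
  n <- nchar(query)
  best <- 0L
  for (k in seq_len(n)) {
    sub <- if (from5) substr(query, 1, k) else substr(query, n - k + 1, n)
    if (!grepl(bf_rc(sub), target, fixed = TRUE)) break
    best <- k
  }
  best
}

# brute-force grayscale opening (erosion then dilation) with a disk
bf_opening <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  # same disc membership rule as EBImage::makeBrush(2*radius + 1, "disc")
  off <- off[off$dx^2 + off$dy^2 <= (radius + 0.5)^2, ]
  stat_filter <- function(m, f) {
    out <- matrix(0, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      rr <- r + off$dy; cc <- c + off$dx
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      out[r, c] <- f(m[cbind(rr[ok], cc[ok])])
    }
    out
  }
  stat_filter(stat_filter(img, min), max)
}

# nearest-nucleus expansion by exhaustive per-pixel search
bf_expand <- function(nuclei_lab, N) {
  h <- nrow(nuclei_lab); w <- ncol(nuclei_lab)
  pts <- which(nuclei_lab > 0, arr.ind = TRUE)
  lab_of <- nuclei_lab[pts]
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    d2 <- (pts[, 1] - r)^2 + (pts[, 2] - c)^2
    j <- which(d2 == min(d2))
    if (sqrt(min(d2)) <= N) out[r, c] <- min(lab_of[j])
  }
  out
}

# exact two-sided rank-sum p by full enumeration of group assignments
bf_ranksum_exact <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pool), n)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(n)])
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (length(pool) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# match recovered cell labels to simulated field cells via nucleus centroids
match_cells <- function(res, field) {
  labs <- sort(unique(res$cell_lab[res$cell_lab > 0]))
  if (!length(labs)) return(integer(0))
  h <- nrow(res$nuclei_lab)
  cen <- vapply(labs, function(l) {
    idx <- which(res$nuclei_lab == l)
    c(x = mean((idx - 1) %/% h + 1), y = mean((idx - 1) %% h + 1))
  }, c(x = 0, y = 0))
  map <- vapply(seq_along(labs), function(i) {
    which.min((field$cells$cx - cen["x", i])^2 +
                (field$cells$cy - cen["y", i])^2)
  }, 0L)
  stats::setNames(map, labs)
}

# per-cell truth/recovered class-count matrices for a quantified simulation
recovery_counts <- function(sim, res) {
  tt <- table(factor(sim$truth$cell_id, levels = seq_len(sim$field$n_cells)),
              factor(sim$truth$class,
                     levels = c("freeA", "freeB", "complex")))
  map <- match_cells(res, sim$field)
  cl <- res$cells
  tc <- map[as.character(cl$cell_id)]
  list(truth = tt[tc, , drop = FALSE],
       recovered = cbind(cl$n_freeA, cl$n_freeB, cl$n_complex))
}
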