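# ---- two-group rank-sum ----------------------------------------------------

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison of two per-cell samples with mid-ranks
#' for ties. Small samples (both below `exact_threshold`, no ties) use the
#' exact permutation null; larger samples use the normal approximation
#' with tie correction and (optionally) continuity correction. The
#' statistic is the Mann-Whitney U for `x`.
#'
#' @param x,y numeric samples (non-empty, finite).
#' @param exact force exact (`TRUE`) or approximate (`FALSE`); default
#'   decides by `exact_threshold` and the presence of ties.
#' @param correct continuity correction for the normal approximation.
#' @param exact_threshold per-group size below which the exact null is
#'   used.
#' @return list with `statistic` (U), `p.value`, `exact`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL, correct = TRUE,
                          exact_threshold = 20L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (!all(is.finite(c(x, y)))) stop("samples must be finite")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact))
    exact <- length(x) < exact_threshold && length(y) < exact_threshold &&
      !ties
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = correct))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = exact,
       method = if (exact) "exact rank-sum" else
         paste0("normal approximation",
                if (correct) " with continuity correction"))
}

# ---- k-group: Kruskal-Wallis + Dunn ----------------------------------------

#' Kruskal-Wallis test with Dunn's pairwise post hoc
#'
#' Tie-corrected Kruskal-Wallis H against the chi-square reference for
#' three or more groups, followed by two-sided Dunn's pairwise z tests on
#' the pooled mid-ranks with Bonferroni adjustment
#' (`p_adj = min(1, m * p)` over the m pairwise comparisons).
#'
#' @param groups named list of numeric vectors (>= 3 non-empty groups).
#' @return list with `H`, `df`, `p.value` and a `pairwise` data frame
#'   (`group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
kw_dunn <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("need >= 3 groups; use rank_sum_test() for two groups")
  if (any(vapply(groups, length, 0L) == 0L))
    stop("all groups must be non-empty")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(values))) stop("group values must be finite")
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  kw <- stats::kruskal.test(values, g)

  N <- length(values)
  r <- rank(values)                       # mid-ranks
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  tie_tab <- table(values)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  var_base <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  combs <- utils::combn(seq_along(groups), 2)
  m <- ncol(combs)
  pw <- do.call(rbind, lapply(seq_len(m), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               z = z, p = p)
  }))
  pw$p_adj <- stats::p.adjust(pw$p, method = "bonferroni")
  rownames(pw) <- NULL
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, pairwise = pw)
}

# ---- box-plot summary ------------------------------------------------------

#' Five-number box-plot summary with 1.5 IQR whiskers
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile` type 7). Whiskers sit at the most extreme observations
#' within 1.5 IQR of the quartiles; observations beyond are listed as
#' outliers.
#'
#' @param sample non-empty finite numeric vector.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_summary <- function(sample) {
  if (!length(sample)) stop("sample must be non-empty")
  if (!all(is.finite(sample))) stop("sample must be finite")
  qs <- stats::quantile(sample, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- sample[sample >= lo_fence & sample <= hi_fence]
  list(median = qs[2], q1 = qs[1], q3 = qs[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(sample[sample < lo_fence | sample > hi_fence]))
}

#' Compare grouped per-cell quantities
#'
#' Dispatcher used by the command line: two groups go to
#' [rank_sum_test], three or more to [kw_dunn]; box summaries are
#' computed per group.
#'
#' @param values numeric vector of per-cell values.
#' @param group grouping vector (coerced to factor).
#' @return list with `test` and `boxes` (per-group box summaries).
#' @export
compare_groups <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  split_vals <- split(values, group)
  test <- if (nlevels(group) == 2)
    rank_sum_test(split_vals[[1]], split_vals[[2]])
  else kw_dunn(split_vals)
  boxes <- lapply(split_vals, box_summary)
  list(test = test, boxes = boxes)
}
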