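# Immune-contexture statistics: batch mean-centering, Mann-Whitney group
# comparisons with Benjamini-Hochberg control, log2 ratio annotation,
# Spearman/Ward hierarchical clustering and the marker correlation vector.

#' Mean-center features within stain batches
#'
#' Removes additive batch effects by subtracting, within each batch, every
#' feature's batch mean (computed over non-missing values). Missing values
#' are untouched; a feature that is entirely missing within a batch is left
#' missing with a warning.
#'
#' @param x numeric matrix or data.frame of features (rows = patients).
#' @param batch batch label per row.
#' @return centered matrix of `x`'s shape.
#' @export
mean_center_batches <- function(x, batch) {
  m <- as.matrix(x)
  if (length(batch) != nrow(m)) stop("every row needs a batch label")
  for (b in unique(batch)) {
    idx <- batch == b
    for (j in seq_len(ncol(m))) {
      v <- m[idx, j]
      if (all(is.na(v))) {
        warning("feature '", colnames(m)[j], "' is all-missing in batch '",
                b, "'; left unchanged")
        next
      }
      m[idx, j] <- v - mean(v, na.rm = TRUE)
    }
  }
  m
}

#' Mann-Whitney U test for two samples
#'
#' Exact p-value (full enumeration of the rank distribution) when the
#' combined sample size is at most 16 and there are no ties. Beyond the
#' cutover, tie-free samples of moderate size still use the exact null
#' distribution (the plain normal approximation can deviate from it by more
#' than 0.01 at m = n = 8); tied or very large samples use the normal
#' approximation with tie and continuity corrections. U is reported for the
#' first sample.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max combined-size cutover for the enumeration branch
#'   (default 16).
#' @return list with `U` and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 16L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && ((length(x) + length(y)) <= exact_max ||
                       length(x) * length(y) <= 1e4)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1; order-preserving and
#' invariant to the input order.
#'
#' @param p vector of p-values in [0, 1] (NAs passed through).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Compare every feature between two patient groups
#'
#' Per-feature two-sided Mann-Whitney U test on non-missing values,
#' Benjamini-Hochberg correction across all tested features, significance at
#' q < `alpha`, and the log2 ratio of group medians (with pseudo-count
#' handling for zero medians; see [log2_ratio_table()]).
#'
#' @param x feature matrix/data.frame (rows = patients); typically
#'   batch-centered before testing.
#' @param group two-level label per row (e.g. "ALL" vs "control"); the first
#'   level of `levels` is the numerator of the ratio.
#' @param levels character length 2: numerator and denominator groups.
#' @param alpha significance level on the q scale (default 0.05).
#' @param ratio_data optional matrix of `x`'s shape on the raw proportion
#'   scale, used for the group medians and log2 ratios (mean-centered values
#'   can be negative, where a ratio is meaningless). Defaults to `x`.
#' @return data.frame of class `comparison_result`: feature, group medians
#'   (from `ratio_data`), U, p, q, `significant`, `log2_ratio`.
#' @export
compare_groups <- function(x, group, levels = NULL, alpha = 0.05,
                           ratio_data = NULL) {
  m <- as.matrix(x)
  rm_ <- if (is.null(ratio_data)) m else as.matrix(ratio_data)
  if (!all(dim(rm_) == dim(m)))
    stop("ratio_data must match the feature matrix shape")
  if (is.null(levels)) levels <- unique(group)
  if (length(levels) != 2) stop("exactly two groups are required")
  g1 <- group == levels[1]; g2 <- group == levels[2]
  if (sum(g1) < 2 || sum(g2) < 2) stop("both groups need >= 2 patients")
  rows <- list()
  for (j in seq_len(ncol(m))) {
    a <- m[g1, j]; a <- a[!is.na(a)]
    b <- m[g2, j]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("feature '", colnames(m)[j],
              "' has < 2 values in a group; skipped")
      next
    }
    wt <- mann_whitney_u(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = colnames(m)[j],
      median_1 = stats::median(rm_[g1, j], na.rm = TRUE),
      median_2 = stats::median(rm_[g2, j], na.rm = TRUE),
      U = wt$U, p = wt$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable features")
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < alpha
  names(res)[names(res) == "median_1"] <- paste0("median_", levels[1])
  names(res)[names(res) == "median_2"] <- paste0("median_", levels[2])
  res$log2_ratio <- log2_median_ratio(res[[2]], res[[3]])
  class(res) <- c("comparison_result", "data.frame")
  res
}

# log2(mA / mB) with the zero-median pseudo-fraction rule: zeros are replaced
# by half the smallest nonzero median across all features and both groups.
# Negative medians (possible on a centered scale) yield NA.
log2_median_ratio <- function(ma, mb) {
  nz <- c(ma, mb); nz <- nz[!is.na(nz) & nz > 0]
  pseudo <- if (length(nz)) min(nz) / 2 else NA_real_
  a <- ifelse(!is.na(ma) & ma == 0, pseudo, ma)
  b <- ifelse(!is.na(mb) & mb == 0, pseudo, mb)
  out <- suppressWarnings(log2(a / b))
  out[is.nan(out)] <- NA_real_
  out[(!is.na(ma) & ma < 0) | (!is.na(mb) & mb < 0)] <- NA_real_
  out[!is.na(ma) & !is.na(mb) & ma == 0 & mb == 0] <- NA_real_
  out
}

#' Filter a comparison table to the significant log2 ratio annotation
#'
#' Keeps only features significant at q < `alpha` and reports their log2
#' group-median ratios; features where both medians are zero are omitted
#' with a message.
#'
#' @param comparison a [compare_groups()] result.
#' @param alpha q-value cutoff (default 0.05).
#' @return data.frame: feature, medians, q, log2_ratio.
#' @export
log2_ratio_table <- function(comparison, alpha = 0.05) {
  keep <- comparison$significant & comparison$q < alpha
  res <- comparison[keep, , drop = FALSE]
  both0 <- is.na(res$log2_ratio)
  if (any(both0)) {
    message("omitting ", sum(both0),
            " feature(s) with zero medians in both groups")
    res <- res[!both0, , drop = FALSE]
  }
  res[, c("feature", names(res)[2:3], "q", "log2_ratio")]
}

#' Hierarchical clustering with Spearman correlation distance and ward.D2
#'
#' Distance between rows (and between columns) is `1 - Spearman rho` on
#' pairwise-complete observations; agglomeration uses the squared-distance
#' Ward variant (`ward.D2`).
#'
#' @param x numeric matrix (e.g. features x patients).
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`.
#' @export
hierarchical_cluster <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2x2 matrix")
  spearman_dist <- function(mm, what) {
    sds <- apply(mm, 1, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sds) | sds == 0))
      stop("constant ", what, " (Spearman rho undefined): ",
           paste(rownames(mm)[!is.finite(sds) | sds == 0], collapse = ", "))
    rho <- stats::cor(t(mm), method = "spearman",
                      use = "pairwise.complete.obs")
    stats::as.dist(1 - rho)
  }
  hr <- stats::hclust(spearman_dist(m, "row"), method = "ward.D2")
  hc <- stats::hclust(spearman_dist(t(m), "column"), method = "ward.D2")
  list(row_hclust = hr, col_hclust = hc,
       row_order = hr$order, col_order = hc$order)
}

#' Spearman correlation of every feature against an anchor feature
#'
#' rho per feature versus the anchor on pairwise-complete observations;
#' p-values from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`,
#' Benjamini-Hochberg correction across features, significance at q < alpha.
#'
#' @param x feature matrix/data.frame (columns = features).
#' @param anchor name of the anchor feature column.
#' @param alpha significance level (default 0.05).
#' @return data.frame: feature, rho, n, p, q, significant. Constant features
#'   get NA rho.
#' @export
correlate_markers <- function(x, anchor, alpha = 0.05) {
  m <- as.matrix(x)
  if (!anchor %in% colnames(m)) stop("anchor feature '", anchor, "' absent")
  a <- m[, anchor]
  feats <- colnames(m)
  rho <- p <- rep(NA_real_, length(feats))
  nn <- integer(length(feats))
  for (j in seq_along(feats)) {
    v <- m[, j]
    ok <- !is.na(a) & !is.na(v)
    nn[j] <- sum(ok)
    if (nn[j] < 3) next
    if (stats::sd(v[ok]) == 0 || stats::sd(a[ok]) == 0) next
    r <- stats::cor(a[ok], v[ok], method = "spearman")
    rho[j] <- r
    if (abs(r) >= 1) { p[j] <- 0; next }
    tval <- r * sqrt((nn[j] - 2) / (1 - r^2))
    p[j] <- 2 * stats::pt(-abs(tval), nn[j] - 2)
  }
  q <- rep(NA_real_, length(feats))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  data.frame(feature = feats, rho = rho, n = nn, p = p, q = q,
             significant = !is.na(q) & q < alpha,
             stringsAsFactors = FALSE)
}
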