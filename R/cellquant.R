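# Cell segmentation, intensity measurement, hierarchical phenotype gating,
# spot-level QC and duplicate averaging.

#' Otsu threshold of an intensity histogram
#'
#' Maximizes the between-class variance `w0 * w1 * (mu0 - mu1)^2` over all
#' cut points between occupied bins; ties are broken toward the lower
#' threshold. Foreground is `value > threshold`.
#'
#' @param values numeric vector of bin values (ascending).
#' @param counts non-negative counts per bin.
#' @return the threshold (a bin value); pixels strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(values, counts) {
  if (length(values) != length(counts)) stop("values/counts length mismatch")
  keep <- counts > 0
  v <- values[keep]; n <- counts[keep]
  if (length(v) < 2)
    stop("histogram must occupy at least 2 distinct bins")
  o <- order(v); v <- v[o]; n <- n[o]
  w0 <- cumsum(n)
  total <- w0[length(w0)]
  s0 <- cumsum(n * v)
  stot <- s0[length(s0)]
  k <- seq_len(length(v) - 1)       # cut after bin k
  mu0 <- s0[k] / w0[k]
  w1 <- total - w0[k]
  mu1 <- (stot - s0[k]) / w1
  bcv <- (w0[k] / total) * (w1 / total) * (mu0 - mu1)^2
  v[k[which.max(bcv)]]              # which.max returns the first (lowest) tie
}

#' Otsu threshold of an image
#'
#' Histograms the image into `nbins` equal-width bins (bin midpoints as
#' values) and applies [otsu_threshold()].
#'
#' @param img numeric matrix.
#' @param nbins number of histogram bins (default 256).
#' @return threshold value.
#' @export
otsu_image <- function(img, nbins = 256L) {
  r <- range(img)
  if (diff(r) == 0) stop("constant image: Otsu threshold undefined")
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(img, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  otsu_threshold(mids, counts)
}

#' Segment cells on a lineage marker channel
#'
#' Foreground is the Otsu threshold of the Gaussian-smoothed marker channel.
#' Connected components larger than `max_size` are split by a watershed on
#' the nuclear channel seeded at its regional intensity maxima (the
#' "intracellular intensity pattern" of each nucleus); components smaller
#' than `min_size` are discarded. A blank (constant) channel yields an empty
#' mask.
#'
#' @param marker,nuclear registered single-channel matrices of equal shape.
#' @param sigma Gaussian pre-smoothing sd in pixels (default 1; 0 disables).
#' @param mean_radius mean nucleus radius in pixels, used for default size
#'   bounds and the minimum seed separation.
#' @param min_size,max_size component size bounds in pixels; defaults are
#'   25% and 100% of the mean nucleus area (every component that could hold
#'   more than one nucleus is handed to the watershed, which leaves
#'   single-peak components intact).
#' @param tolerance watershed peak tolerance on the nuclear intensity scale.
#' @return integer label matrix (0 = background, labels 1..K).
#' @export
segment_cells <- function(marker, nuclear, sigma = 1, mean_radius = 4,
                          min_size = NULL, max_size = NULL,
                          tolerance = 0.1) {
  if (!all(dim(marker) == dim(nuclear)))
    stop("marker and nuclear channels must be registered to the same shape")
  mean_area <- pi * mean_radius^2
  if (is.null(min_size)) min_size <- 0.25 * mean_area
  if (is.null(max_size)) max_size <- mean_area

  if (diff(range(marker)) == 0)
    return(matrix(0L, nrow(marker), ncol(marker)))
  sm <- if (sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(marker), sigma = sigma))
  else marker
  thr <- otsu_image(sm)
  fg <- sm > thr
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  nlab <- max(labels)
  if (nlab == 0) return(matrix(0L, nrow(marker), ncol(marker)))

  areas <- tabulate(labels[labels > 0], nlab)
  big <- which(areas > max_size)
  if (length(big)) {
    big_mask <- matrix(labels %in% big, nrow(labels), ncol(labels))
    nuc_sm <- if (sigma > 0)
      EBImage::imageData(EBImage::gblur(EBImage::Image(nuclear),
                                        sigma = sigma))
    else nuclear
    relief <- nuc_sm * big_mask
    ws <- EBImage::imageData(EBImage::watershed(
      EBImage::Image(relief), tolerance = tolerance,
      ext = max(1L, as.integer(round(mean_radius / 2)))))
    labels[big_mask] <- ifelse(ws[big_mask] > 0, ws[big_mask] + nlab, 0L)
  }

  # min-size filter and sequential relabeling
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(matrix(0L, nrow(marker), ncol(marker)))
  sz <- vapply(ids, function(i) sum(labels == i), 0)
  keep <- ids[sz >= min_size]
  lut <- integer(max(ids) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  out <- matrix(lut[labels + 1L], nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  out
}

#' Estimate the total cell count of a spot from the nuclear channel
#'
#' Binarizes the nuclear channel by Otsu and divides the foreground area by
#' the mean nucleus area (the standard binary-DAPI-area count).
#'
#' @param nuclear nuclear channel matrix.
#' @param mean_nucleus_area mean nucleus area in pixels (> 0).
#' @return integer cell count estimate.
#' @export
count_total_cells <- function(nuclear, mean_nucleus_area) {
  if (!is_num1(mean_nucleus_area) || mean_nucleus_area <= 0)
    stop("mean nucleus area must be a positive number")
  if (diff(range(nuclear)) == 0) return(0L)
  thr <- otsu_image(nuclear)
  as.integer(round(sum(nuclear > thr) / mean_nucleus_area))
}

#' Measure per-cell integrated intensities over a label mask
#'
#' @param labels integer label matrix (0 = background).
#' @param stack named list of channel matrices sharing the mask's shape.
#' @return data.frame with one row per label: `cell`, centroid `x` (column)
#'   and `y` (row), `area` (pixels), and one integrated-intensity column per
#'   channel (sum of pixel values over the cell mask).
#' @export
measure_intensities <- function(labels, stack) {
  stopifnot(is.list(stack), length(stack) > 0)
  if (!all(vapply(stack, function(m) all(dim(m) == dim(labels)), TRUE)))
    stop("mask and channels must share shape")
  nlab <- max(labels)
  if (nlab == 0) {
    out <- data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0))
    for (nm in names(stack)) out[[nm]] <- numeric(0)
    return(out)
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- as.vector(rowsum(rep(1, length(lab)), lab))
  ids <- as.integer(rownames(rowsum(rep(1, length(lab)), lab)))
  out <- data.frame(cell = ids,
                    x = as.vector(rowsum(cols, lab)) / area,
                    y = as.vector(rowsum(rows, lab)) / area,
                    area = area)
  for (nm in names(stack))
    out[[nm]] <- as.vector(rowsum(stack[[nm]][idx], lab))
  out
}

# ---------------------------------------------------------------------------
# Gating tree
# ---------------------------------------------------------------------------

#' Build a hierarchical phenotype gating tree
#'
#' Each node defines a phenotype by required-positive and required-negative
#' markers, restricted to a parent population (or all cells), and declares
#' its reporting denominator: "all" (proportion of all cells in the spot) or
#' "parent" (proportion of the parent phenotype).
#'
#' @param nodes list of nodes; each a list with `name`, `parent` (NA for a
#'   root), `positive` (character), `negative` (character, may be empty) and
#'   `denominator` ("all" or "parent").
#' @param markers character vector of panel markers the tree may reference.
#' @return object of class `gating_tree` (nodes in topological order).
#' @export
gating_tree <- function(nodes, markers) {
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  for (nd in nodes) {
    bad <- setdiff(c(nd$positive, nd$negative), markers)
    if (length(bad))
      stop("gating node '", nd$name, "' references unknown marker(s): ",
           paste(bad, collapse = ", "))
    if (!nd$denominator %in% c("all", "parent"))
      stop("denominator must be 'all' or 'parent'")
    if (is.na(nd$parent) && nd$denominator == "parent")
      stop("root node '", nd$name, "' cannot use a parent denominator")
    if (!is.na(nd$parent) && !nd$parent %in% names(nodes))
      stop("node '", nd$name, "' has unknown parent '", nd$parent, "'")
  }
  # topological order; a cycle leaves nodes unplaceable
  placed <- character(0)
  remaining <- nodes
  ordered <- list()
  while (length(remaining)) {
    ready <- vapply(remaining, function(nd)
      is.na(nd$parent) || nd$parent %in% placed, TRUE)
    if (!any(ready)) stop("gating tree contains a cycle")
    ordered <- c(ordered, remaining[ready])
    placed <- c(placed, names(remaining)[ready])
    remaining <- remaining[!ready]
  }
  structure(list(nodes = ordered, markers = markers), class = "gating_tree")
}

#' Default gating tree for the synthetic lymphoid/myeloid panel
#'
#' Roots: CD3 T cells, CD20 B cells, CD56 NK cells, CD68 macrophages.
#' CD4/CD8 T subsets are reported as proportions of all cells; the
#' PD1+TIM3+ exhausted subset is reported as a proportion of its CD3+CD4+
#' parent.
#'
#' @return a [gating_tree()].
#' @export
default_gating_tree <- function() {
  markers <- c("CD3", "CD4", "CD8", "CD20", "CD56", "CD68", "PD1", "TIM3")
  gating_tree(list(
    list(name = "CD3_T", parent = NA, positive = "CD3",
         negative = character(0), denominator = "all"),
    list(name = "CD4_T", parent = "CD3_T", positive = "CD4",
         negative = "CD8", denominator = "all"),
    list(name = "CD8_T", parent = "CD3_T", positive = "CD8",
         negative = "CD4", denominator = "all"),
    list(name = "CD4_PD1_TIM3", parent = "CD4_T",
         positive = c("PD1", "TIM3"), negative = character(0),
         denominator = "parent"),
    list(name = "B", parent = NA, positive = "CD20",
         negative = character(0), denominator = "all"),
    list(name = "NK", parent = NA, positive = "CD56",
         negative = character(0), denominator = "all"),
    list(name = "MAC", parent = NA, positive = "CD68",
         negative = character(0), denominator = "all")
  ), markers)
}

#' Roots of a gating tree with their segmentation markers
#' @keywords internal
tree_roots <- function(tree) {
  roots <- Filter(function(nd) is.na(nd$parent), tree$nodes)
  stats::setNames(vapply(roots, function(nd) nd$positive[1], ""),
                  vapply(roots, `[[`, "", "name"))
}

#' Classify cells into phenotypes by thresholded integrated intensity
#'
#' Marker positivity is defined on the area-normalized integrated intensity
#' (integrated intensity / area, so large cells are not spuriously positive);
#' phenotype membership is the conjunction of the required-positive and
#' required-negative markers restricted to the parent population.
#'
#' @param cells cell table from [measure_intensities()].
#' @param thresholds named numeric: positivity threshold per marker on the
#'   area-normalized intensity scale.
#' @param tree a [gating_tree()].
#' @return `cells` with one logical membership column per phenotype and a
#'   `lineage` column (name of the first root phenotype the cell belongs to).
#' @export
classify_cells <- function(cells, thresholds, tree) {
  need <- unique(unlist(lapply(tree$nodes, function(nd)
    c(nd$positive, nd$negative))))
  miss <- setdiff(need, names(thresholds))
  if (length(miss))
    stop("no positivity threshold for marker(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("gating tree references marker(s) missing from the cell table: ",
         paste(miss, collapse = ", "))
  n <- nrow(cells)
  pos <- lapply(need, function(m)
    (cells[[m]] / cells$area) > thresholds[[m]])
  names(pos) <- need
  member <- list()
  for (nd in tree$nodes) {
    ok <- rep(TRUE, n)
    for (m in nd$positive) ok <- ok & pos[[m]]
    for (m in nd$negative) ok <- ok & !pos[[m]]
    if (!is.na(nd$parent)) ok <- ok & member[[nd$parent]]
    member[[nd$name]] <- ok
  }
  for (nm in names(member)) cells[[nm]] <- member[[nm]]
  roots <- names(tree_roots(tree))
  lin <- rep(NA_character_, n)
  for (r in rev(roots)) lin[member[[r]]] <- r
  cells$lineage <- lin
  cells
}

#' Data-driven default positivity gates
#'
#' Otsu threshold on the pooled per-cell area-normalized integrated-intensity
#' distribution of each marker. Markers with a degenerate (near-constant)
#' distribution get an infinite threshold (no positive cells) with a warning.
#'
#' @param cells pooled cell table from [measure_intensities()].
#' @param markers character vector of markers to gate.
#' @param nbins histogram bins (default 64).
#' @return named numeric vector of thresholds.
#' @export
default_gates <- function(cells, markers, nbins = 64L) {
  vapply(markers, function(m) {
    v <- cells[[m]] / cells$area
    if (length(v) < 2 || diff(range(v)) < 1e-12) {
      warning("marker ", m, ": degenerate intensity distribution; ",
              "no cells gated positive")
      return(Inf)
    }
    otsu_image(matrix(v, 1), nbins = nbins)
  }, 0)
}

#' Quantify one TMA spot into proportion features with QC
#'
#' Proportion-of-all-cells features divide each phenotype count by the total
#' cell count; parent-denominated features divide by the parent phenotype
#' count. A feature whose denominator population is empty is missing (NA),
#' not zero. The QC flag fails iff the total cell count is below the
#' threshold (default 1000 cells).
#'
#' @param cells classified cell table ([classify_cells()]); may combine the
#'   per-lineage segmentations of one spot.
#' @param total_cells total cell count of the spot ([count_total_cells()]).
#' @param tree the [gating_tree()].
#' @param qc_threshold minimum total cell count (default 1000).
#' @param spot_id,patient_id,batch identifiers carried into the result.
#' @return one-row data.frame: identifiers, `total_cells`, `qc_pass`, then
#'   one proportion column per phenotype.
#' @export
quantify_spot <- function(cells, total_cells, tree, qc_threshold = 1000,
                          spot_id = "spot1", patient_id = "patient1",
                          batch = "batch1") {
  if (total_cells < 0) stop("total cell count must be >= 0")
  counts <- vapply(tree$nodes, function(nd)
    if (nrow(cells)) sum(cells[[nd$name]]) else 0L, 0L)
  names(counts) <- vapply(tree$nodes, `[[`, "", "name")
  out <- data.frame(spot_id = spot_id, patient_id = patient_id, batch = batch,
                    total_cells = as.integer(total_cells),
                    qc_pass = total_cells >= qc_threshold,
                    stringsAsFactors = FALSE)
  for (nd in tree$nodes) {
    den <- if (nd$denominator == "all") total_cells else counts[[nd$parent]]
    out[[nd$name]] <- if (is.na(den) || den == 0) NA_real_
                      else counts[[nd$name]] / den
  }
  out
}

#' Quantify a synthetic or loaded spot image end to end
#'
#' Segments each gating-tree root on its lineage marker channel, pools the
#' per-lineage cell tables, gates phenotypes and returns the spot's
#' [quantify_spot()] row.
#'
#' @param fluor named list of registered channel matrices including
#'   `nuclear`.
#' @param tree a [gating_tree()].
#' @param mean_radius mean nucleus radius (pixels).
#' @param gates optional named positivity thresholds; computed by
#'   [default_gates()] on the pooled cells when NULL.
#' @param qc_threshold,spot_id,patient_id,batch passed to [quantify_spot()].
#' @param sigma pre-smoothing sd passed to [segment_cells()].
#' @return list with `quantification` (one-row data.frame), `cells` (pooled
#'   classified table) and `total_cells`.
#' @export
quantify_spot_image <- function(fluor, tree = default_gating_tree(),
                                mean_radius = 4, gates = NULL,
                                qc_threshold = 1000, spot_id = "spot1",
                                patient_id = "patient1", batch = "batch1",
                                sigma = 1) {
  stopifnot("nuclear" %in% names(fluor))
  total <- count_total_cells(fluor$nuclear, pi * mean_radius^2)
  roots <- tree_roots(tree)
  tabs <- list()
  for (r in names(roots)) {
    chan <- roots[[r]]
    if (!chan %in% names(fluor))
      stop("panel lacks channel '", chan, "' needed to segment ", r)
    labels <- segment_cells(fluor[[chan]], fluor$nuclear, sigma = sigma,
                            mean_radius = mean_radius)
    cells <- measure_intensities(labels, fluor[names(fluor) != "nuclear"])
    cells$segmented_on <- rep(r, nrow(cells))
    tabs[[r]] <- cells
  }
  pooled <- do.call(rbind, tabs)
  rownames(pooled) <- NULL
  if (is.null(gates))
    gates <- default_gates(pooled, tree$markers)
  pooled <- classify_cells(pooled, gates, tree)
  # a cell counts only towards phenotypes under the root it was segmented on
  for (nd in tree$nodes) {
    root <- nd$name
    p <- nd$parent
    while (!is.na(p)) { root <- p
      p <- tree$nodes[[root]]$parent }
    pooled[[nd$name]] <- pooled[[nd$name]] & pooled$segmented_on == root
  }
  q <- quantify_spot(pooled, total, tree, qc_threshold = qc_threshold,
                     spot_id = spot_id, patient_id = patient_id, batch = batch)
  list(quantification = q, cells = pooled, total_cells = total)
}

#' Average duplicate spots into per-patient profiles
#'
#' For each patient and feature, the arithmetic mean over QC-passing spots
#' with a non-missing value; missing if no spot qualifies. Patients with no
#' QC-passing spot are dropped.
#'
#' @param spots data.frame of [quantify_spot()] rows (one per spot).
#' @return per-patient data.frame: `patient_id`, `batch`, `n_spots`, feature
#'   means.
#' @export
aggregate_duplicates <- function(spots) {
  meta <- c("spot_id", "patient_id", "batch", "total_cells", "qc_pass")
  feats <- setdiff(names(spots), meta)
  ok <- spots[spots$qc_pass, , drop = FALSE]
  if (!nrow(ok))
    return(cbind(data.frame(patient_id = character(0), batch = character(0),
                            n_spots = integer(0)),
                 stats::setNames(as.data.frame(
                   matrix(numeric(0), 0, length(feats))), feats)))
  pts <- unique(ok$patient_id)
  res <- lapply(pts, function(p) {
    sub <- ok[ok$patient_id == p, , drop = FALSE]
    row <- data.frame(patient_id = p, batch = sub$batch[1],
                      n_spots = nrow(sub), stringsAsFactors = FALSE)
    for (f in feats) {
      v <- sub[[f]][!is.na(sub[[f]])]
      row[[f]] <- if (length(v)) mean(v) else NA_real_
    }
    row
  })
  do.call(rbind, res)
}

#' Gate a flow-cytometry event table to the CD4+PD1+TIM3+ proportion
#'
#' Sequential gates CD45+ -> CD3+ -> CD4+ -> PD1+TIM3+; returns the
#' double-positive count divided by the CD3+CD4+ count. The returned feature
#' carries the same name as the mIHC feature (`CD4_PD1_TIM3`) so the survival
#' layer treats both cohorts identically.
#'
#' @param events data.frame with CD45, CD3, CD4, CD8, PD1, TIM3 columns.
#' @param threshold positivity gate on the intensity scale (default 2, the
#'   midpoint of the synthetic mixture components).
#' @return named length-1 numeric (`CD4_PD1_TIM3`), NA when there are no
#'   CD3+CD4+ events; attributes `n_parent` and `n_positive` carry the gate
#'   counts.
#' @export
gate_fc_events <- function(events, threshold = 2) {
  need <- c("CD45", "CD3", "CD4", "CD8", "PD1", "TIM3")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table lacks column(s): ",
                         paste(miss, collapse = ", "))
  cd45 <- events$CD45 > threshold
  cd3 <- cd45 & events$CD3 > threshold
  cd4 <- cd3 & events$CD4 > threshold
  dp <- cd4 & events$PD1 > threshold & events$TIM3 > threshold
  np <- sum(cd4)
  val <- if (np == 0) NA_real_ else sum(dp) / np
  structure(stats::setNames(val, "CD4_PD1_TIM3"),
            n_parent = np, n_positive = sum(dp))
}
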