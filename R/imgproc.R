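# Image preprocessing: chromogen color deconvolution of brightfield images
# and phase-correlation registration of the fluorescent and brightfield
# staining rounds.

#' Color-deconvolve a brightfield RGB image into chromogen concentrations
#'
#' Per-pixel optical density `OD = -log10(max(I, eps) / I0)` is unmixed with
#' the inverse of the stain matrix; negative concentrations (noise leakage
#' outside the stain simplex) are clipped at 0. The OD floor `eps` guards
#' against log(0) on fully absorbed pixels.
#'
#' @param rgb h x w x 3 array of transmitted intensities in (0, I0].
#' @param stain_matrix 3x3 unit-OD stain matrix (rows = chromogens).
#' @param I0 incident intensity (default 255).
#' @param eps intensity floor before the log (default 1/255).
#' @param clip clip negative concentrations at zero (default TRUE).
#' @return h x w x 3 array of per-chromogen concentration maps, dimnames on
#'   the third axis taken from the stain-matrix row names.
#' @export
deconvolve_brightfield <- function(rgb, stain_matrix, I0 = 255,
                                   eps = 1 / 255, clip = TRUE) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be an h x w x 3 array")
  k <- cond_number(stain_matrix)
  if (!is.finite(k) || k > 1e12)
    stop("stain matrix is singular; condition number = ", signif(k, 4))
  d <- dim(rgb)
  I <- pmax(matrix(rgb, prod(d[1:2]), 3), eps)
  od <- -log10(I / I0)
  conc <- od %*% solve(stain_matrix)   # solve(M) since OD = c %*% M
  if (clip) conc[conc < 0] <- 0
  out <- array(conc, d)
  dimnames(out) <- list(NULL, NULL, rownames(stain_matrix))
  out
}

#' Adapt one image's histogram to a reference image's histogram
#'
#' Monotone quantile mapping: each source pixel is replaced by the reference
#' quantile at its own empirical CDF position, so the output's empirical
#' distribution matches the reference's and its range is contained in the
#' reference range.
#'
#' @param source,reference single-channel numeric matrices.
#' @return matrix of `source`'s shape with the adapted intensities.
#' @export
match_histograms <- function(source, reference) {
  if (!is.matrix(source) || !is.matrix(reference))
    stop("source and reference must be single-channel matrices")
  rng <- range(reference)
  if (diff(rng) == 0)
    stop("reference image is constant; quantile mapping is undefined")
  src <- as.vector(source)
  ref_sorted <- sort(as.vector(reference))
  nref <- length(ref_sorted)
  # CDF position of each source pixel (average rank, ties share a position)
  pos <- rank(src, ties.method = "average") / length(src)
  # tolerance guards the exact-integer case against floating-point round-up
  idx <- pmin(pmax(ceiling(pos * nref - 1e-9), 1L), nref)
  matrix(ref_sorted[idx], nrow(source), ncol(source))
}

#' Estimate a translation between two images by phase correlation
#'
#' Computes the normalized cross-power spectrum of the Hann-windowed images
#' and takes the argmax of its inverse transform. Returns the translation of
#' `moving` relative to `fixed` (i.e. `moving` ~ `fixed` shifted by
#' `c(dx, dy)`), with wrap-around resolved to the signed shift of smallest
#' magnitude. The peak value is normalized to [0, 1].
#'
#' @param fixed,moving numeric matrices of identical shape.
#' @param window apply a Hann window before the transform (default TRUE).
#' @param subpixel refine the peak by a quadratic fit to its 3x3
#'   neighbourhood (default FALSE).
#' @return list with `dx`, `dy` (pixels) and `peak`.
#' @export
phase_correlation <- function(fixed, moving, window = TRUE, subpixel = FALSE) {
  if (!all(dim(fixed) == dim(moving)))
    stop("images must share dimensions")
  nr <- nrow(fixed); nc <- ncol(fixed)
  if (window) {
    w <- hann2d(nr, nc)
    fixed <- fixed * w; moving <- moving * w
  }
  F1 <- stats::fft(fixed)
  F2 <- stats::fft(moving)
  R <- F1 * Conj(F2)
  mod <- Mod(R)
  R <- R / pmax(mod, .Machine$double.eps)
  corr <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- unname(which(corr == max(corr), arr.ind = TRUE)[1, ])
  peak <- max(corr)

  wrap <- function(i, n) { s <- i - 1L; if (s > n / 2) s - n else s }
  dy <- wrap(pk[1], nr)
  dx <- wrap(pk[2], nc)

  if (subpixel) {
    refine <- function(idx, n, along_rows) {
      at <- function(off) {
        i <- ((pk[1] - 1L + if (along_rows) off else 0L) %% nr) + 1L
        j <- ((pk[2] - 1L + if (along_rows) 0L else off) %% nc) + 1L
        corr[i, j]
      }
      c0 <- at(0L); cm <- at(-1L); cp <- at(1L)
      den <- cm - 2 * c0 + cp
      if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm - cp) / den
    }
    dy <- dy - refine(pk[1], nr, TRUE)
    dx <- dx - refine(pk[2], nc, FALSE)
  }
  # corr peak at +s means moving = fixed shifted by -s under this convention;
  # flip so the return value is the displacement of `moving`.
  list(dx = -dx, dy = -dy, peak = peak)
}

#' Register the fluorescent and brightfield rounds of one TMA spot
#'
#' Follows the standard two-round protocol: the mean image of each round is
#' formed, the brightfield-derived mean is histogram-adapted to the
#' fluorescent mean, both are downsized by block averaging (default factor
#' 8), and the translation is estimated by 2D phase correlation and scaled
#' back to full resolution. The brightfield stack is then shifted into the
#' fluorescent frame.
#'
#' @param fluor_stack named list of single-channel matrices (round 1).
#' @param bf_stack list of single-channel matrices derived from the
#'   brightfield round (e.g. deconvolved chromogen maps), same full-resolution
#'   shape.
#' @param factor integer downsizing factor (default 8).
#' @param subpixel use quadratic subpixel refinement of the correlation peak.
#' @return list with `registration` (class `registration_result`: `dx`, `dy`
#'   at full resolution, `peak`, `factor`) and `aligned` (the brightfield
#'   stack shifted by the negated estimate).
#' @export
register_rounds <- function(fluor_stack, bf_stack, factor = 8L,
                            subpixel = FALSE) {
  factor <- as.integer(factor)
  if (factor < 1) stop("downsizing factor must be >= 1")
  dims <- dim(fluor_stack[[1]])
  ok <- function(st) all(vapply(st, function(m) all(dim(m) == dims), TRUE))
  if (!ok(fluor_stack) || !ok(bf_stack))
    stop("all channels of both rounds must share full-resolution dimensions")
  if (any(dims < 4L * factor))
    stop("image dimensions (", paste(dims, collapse = "x"),
         ") must be at least 4x the downsizing factor (", factor, ")")

  mean_img <- function(st) Reduce(`+`, st) / length(st)
  m1 <- mean_img(fluor_stack)
  m2 <- mean_img(bf_stack)
  m2 <- match_histograms(m2, m1)

  d1 <- block_mean(m1, factor)
  d2 <- block_mean(m2, factor)
  pc <- phase_correlation(d1, d2, window = TRUE, subpixel = subpixel)

  reg <- structure(list(dx = pc$dx * factor, dy = pc$dy * factor,
                        peak = pc$peak, factor = factor),
                   class = "registration_result")
  aligned <- lapply(bf_stack, function(m)
    shift_matrix(m, -round(reg$dx), -round(reg$dy)))
  list(registration = reg, aligned = aligned)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "Phase-correlation registration: dx = %.2f px, dy = %.2f px (peak %.3f, factor %d)\n",
    x$dx, x$dy, x$peak, x$factor))
  invisible(x)
}
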