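# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' All randomness in the package flows from one master seed; each component
#' draws from its own sub-stream so that adding a stage never perturbs the
#' draws of another.
#'
#' @param seed master seed (integer).
#' @param label character label of the component.
#' @return an integer seed in [0, 2^31 - 1).
#' @keywords internal
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 1000003 + h) %% 2147483647)
}

#' Translate a matrix by an integer offset, zero-filling exposed borders
#'
#' Content moves by `dx` columns (positive = towards higher column index)
#' and `dy` rows (positive = towards higher row index).
#'
#' @param m numeric matrix.
#' @param dx,dy integer offsets (columns, rows).
#' @param fill value for exposed borders.
#' @return translated matrix of identical dimensions.
#' @keywords internal
shift_matrix <- function(m, dx, dy, fill = 0) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Downsize a matrix by block averaging
#'
#' Averages non-overlapping `factor` x `factor` blocks; trailing rows/columns
#' that do not fill a block are dropped. Averaging (rather than decimation)
#' suppresses aliasing before spectral operations.
#'
#' @param m numeric matrix.
#' @param factor integer >= 1.
#' @return downsized matrix.
#' @keywords internal
block_mean <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(m)
  nr <- (nrow(m) %/% factor) * factor
  nc <- (ncol(m) %/% factor) * factor
  if (nr < factor || nc < factor)
    stop("matrix too small to downsize by factor ", factor)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # average rows within blocks, then columns
  g1 <- rep(seq_len(nr %/% factor), each = factor)
  m2 <- rowsum(m, g1) / factor
  g2 <- rep(seq_len(nc %/% factor), each = factor)
  t(rowsum(t(m2), g2) / factor)
}

#' 2D Hann window
#' @keywords internal
hann2d <- function(nr, nc) {
  wr <- if (nr > 1) 0.5 - 0.5 * cos(2 * pi * (0:(nr - 1)) / (nr - 1)) else 1
  wc <- if (nc > 1) 0.5 - 0.5 * cos(2 * pi * (0:(nc - 1)) / (nc - 1)) else 1
  outer(wr, wc)
}

# is x a single finite number?
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# 2-norm condition number from the full singular spectrum (Inf when exactly
# singular; base kappa(exact = TRUE) ignores zero singular values)
cond_number <- function(m) {
  d <- svd(m, nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}
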