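# Independent oracles used to validate the package's implementations.
# These deliberately use brute force / enumeration, never the code they check.

# Exact two-sided Mann-Whitney p by full enumeration of all C(m+n, m)
# assignments of the pooled sample to group x.
enum_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_of(seq_len(m))
  us <- apply(utils::combn(m + n, m), 2, u_of)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# Brute-force Otsu: exhaustive between-class-variance maximization over all
# cut points, ties to the lowest threshold.
brute_otsu <- function(values, counts) {
  keep <- counts > 0
  v <- values[keep]; n <- counts[keep]
  o <- order(v); v <- v[o]; n <- n[o]
  total <- sum(n)
  best <- -Inf; thr <- NA
  for (k in seq_len(length(v) - 1)) {
    w0 <- sum(n[1:k]) / total
    w1 <- 1 - w0
    mu0 <- sum(n[1:k] * v[1:k]) / sum(n[1:k])
    mu1 <- sum(n[(k + 1):length(v)] * v[(k + 1):length(v)]) /
      sum(n[(k + 1):length(v)])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-15) { best <- bcv; thr <- v[k] }
  }
  thr
}

# Newton-Raphson maximization of the Breslow Cox partial likelihood.
newton_cox <- function(time, event, X, iter = 100, tol = 1e-12) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(iter)) {
    eta <- drop(X %*% beta); w <- exp(eta)
    U <- numeric(p); H <- matrix(0, p, p)
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      ws <- w[rs]; sw <- sum(ws)
      Xr <- X[rs, , drop = FALSE]
      xbar <- colSums(Xr * ws) / sw
      U <- U + X[i, ] - xbar
      H <- H + crossprod(Xr * sqrt(ws)) / sw - tcrossprod(xbar)
    }
    step <- solve(H, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Exhaustive integer-shift search maximizing zero-fill cross-correlation.
exhaustive_shift <- function(fixed, moving, max_shift) {
  best <- -Inf; arg <- c(0, 0)
  for (dx in -max_shift:max_shift) {
    for (dy in -max_shift:max_shift) {
      back <- immunotma:::shift_matrix(moving, -dx, -dy)
      s <- sum(fixed * back)
      if (s > best) { best <- s; arg <- c(dx, dy) }
    }
  }
  arg
}

# Quantile-mapping oracle for histogram adaptation
quantile_map_oracle <- function(source, reference) {
  pos <- rank(as.vector(source), ties.method = "average") / length(source)
  matrix(stats::quantile(as.vector(reference), probs = pos, type = 1),
         nrow(source), ncol(source))
}
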