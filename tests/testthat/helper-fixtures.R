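# Shared in-code fixtures for the test suite.

# A small spot spec sized so hard-core placement is comfortable.
small_spot_spec <- function(n_cells = 80, canvas = 256, seed = 1, ...) {
  spot_spec(canvas = canvas, n_cells = n_cells, seed = seed, ...)
}

# single-type spec (all cells CD3+CD4+ T cells); handy for segmentation tests
t_only_spec <- function(n_cells, canvas, seed = 1, ...) {
  spot_spec(canvas = canvas, n_cells = n_cells,
            proportions = c(T_CD4 = 1),
            chromogen_sources = c("nuclear", "CD3", "CD4"),
            seed = seed, ...)
}

# Exponential two-group survival data with a planted hazard ratio.
planted_hr_data <- function(n, hr, censor_rate = 0, seed = 1) {
  set.seed(seed)
  g <- rep(0:1, length.out = n)
  rate <- 0.1 * hr^g
  t_ev <- rexp(n, rate)
  cens <- runif(n) < censor_rate
  time <- ifelse(cens, runif(n, 0, t_ev), t_ev)
  list(time = time, event = as.integer(!cens), group = g)
}
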