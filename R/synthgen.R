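# Synthetic-data generators: ground-truthed TMA spot images, patient cohorts
# with planted proportional-hazards structure, and flow-cytometry-like event
# tables. These define the study conditions under which every downstream
# stage is validated.

#' Default chromogen stain matrix
#'
#' Unit optical-density RGB vectors (rows) for a 3-plex chromogenic panel:
#' hematoxylin, DAB and eosin-like chromogens (classic RGB absorption
#' profiles, row-normalized to unit Euclidean length).
#'
#' @return a 3x3 numeric matrix; rows are chromogens, columns R, G, B.
#' @export
default_stain_matrix <- function() {
  m <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.268, 0.570, 0.776),
    eosin       = c(0.072, 0.990, 0.105)
  )
  m / sqrt(rowSums(m^2))
}

#' Validate a stain matrix
#'
#' Rows must be unit-normalized OD vectors and the matrix invertible.
#'
#' @param m 3x3 numeric matrix.
#' @return `m`, invisibly, or an error.
#' @export
validate_stain_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != 3 || ncol(m) != 3 || !all(is.finite(m)))
    stop("stain matrix must be a finite 3x3 matrix")
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("stain matrix rows must have unit Euclidean norm (got ",
         paste(signif(norms, 6), collapse = ", "), ")")
  k <- cond_number(m)
  if (!is.finite(k) || k > 1e12)
    stop("stain matrix is singular or ill-conditioned (condition number ",
         signif(k, 4), ")")
  invisible(m)
}

#' Default marker expression profiles per synthetic cell type
#'
#' Mean fluorescence (arbitrary units in [0, 1]) of each panel marker for
#' each simulated cell type; a zero entry means the type is truly negative
#' for that marker. The panel mirrors a lymphoid/myeloid mIHC design:
#' CD3/CD4/CD8 T-cell lineages with a PD1+TIM3+ exhausted CD4 subset,
#' CD20 B cells, CD56 NK cells, CD68 macrophages, plus marker-null
#' (leukemic blast-like) cells.
#'
#' @return named list: type -> named numeric vector of marker means.
#' @export
default_cell_profiles <- function() {
  list(
    T_CD4        = c(CD3 = 0.80, CD4 = 0.80),
    T_CD4_PD1TIM3 = c(CD3 = 0.80, CD4 = 0.80, PD1 = 0.70, TIM3 = 0.70),
    T_CD8        = c(CD3 = 0.80, CD8 = 0.80),
    B            = c(CD20 = 0.85),
    NK           = c(CD56 = 0.75),
    MAC          = c(CD68 = 0.80),
    OTHER        = numeric(0)
  )
}

#' Specification of one synthetic TMA spot
#'
#' @param canvas canvas size in pixels (single integer, square canvas).
#' @param n_cells expected cell count (integer >= 0).
#' @param proportions named numeric vector of cell-type fractions; must sum
#'   to 1 and name a subset of `names(profiles)`.
#' @param profiles per-type marker expression profiles, as
#'   [default_cell_profiles()].
#' @param nucleus_radius length-2 numeric, min/max nucleus radius (pixels).
#' @param shift planted inter-round translation `c(dx, dy)` in pixels of the
#'   brightfield round relative to the fluorescent round.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units; fluorescent channels are on a [0, 1] scale).
#' @param stain_matrix chromogen stain matrix ([default_stain_matrix()]).
#' @param chromogen_sources length-3 character: which rendered maps drive the
#'   three chromogen concentration planes ("nuclear" or a marker name).
#' @param aggregate_frac fraction of cells generated as touching pairs
#'   (sub-diameter spacing) to exercise aggregate splitting.
#' @param min_sep_factor hard-core separation between nucleus centers, as a
#'   multiple of the maximal nucleus diameter.
#' @param nuclear_intensity peak intensity of the nuclear channel.
#' @param seed integer seed; all spot randomness derives from it.
#' @return an object of class `spot_spec`.
#' @export
spot_spec <- function(canvas = 512L,
                      n_cells = 500L,
                      proportions = c(T_CD4 = 0.10, T_CD4_PD1TIM3 = 0.02,
                                      T_CD8 = 0.08, B = 0.10, NK = 0.02,
                                      MAC = 0.08, OTHER = 0.60),
                      profiles = default_cell_profiles(),
                      nucleus_radius = c(3, 5),
                      shift = c(0, 0),
                      noise_sd = 0,
                      stain_matrix = default_stain_matrix(),
                      chromogen_sources = c("nuclear", "CD68", "CD20"),
                      aggregate_frac = 0,
                      min_sep_factor = 1.5,
                      nuclear_intensity = 0.9,
                      seed = 1L) {
  spec <- list(canvas = as.integer(canvas), n_cells = as.integer(n_cells),
               proportions = proportions, profiles = profiles,
               nucleus_radius = as.numeric(nucleus_radius), shift = as.numeric(shift),
               noise_sd = noise_sd, stain_matrix = stain_matrix,
               chromogen_sources = chromogen_sources,
               aggregate_frac = aggregate_frac,
               min_sep_factor = min_sep_factor,
               nuclear_intensity = nuclear_intensity,
               seed = as.integer(seed))
  class(spec) <- "spot_spec"
  validate_spot_spec(spec)
  spec
}

#' @rdname spot_spec
#' @param spec a `spot_spec`.
#' @export
validate_spot_spec <- function(spec) {
  stopifnot(inherits(spec, "spot_spec"))
  if (spec$canvas < 16) stop("canvas must be at least 16 pixels")
  if (spec$n_cells < 0) stop("expected cell count must be >= 0")
  if (abs(sum(spec$proportions) - 1) > 1e-9)
    stop("cell-type proportions must sum to 1 (got ", sum(spec$proportions), ")")
  if (any(spec$proportions < 0)) stop("proportions must be non-negative")
  unknown <- setdiff(names(spec$proportions), names(spec$profiles))
  if (length(unknown))
    stop("proportions name types without profiles: ", paste(unknown, collapse = ", "))
  if (length(spec$nucleus_radius) != 2 || any(spec$nucleus_radius <= 0) ||
      diff(spec$nucleus_radius) < 0)
    stop("nucleus_radius must be an increasing positive pair")
  if (max(abs(spec$shift)) >= 0.25 * spec$canvas)
    stop("planted shift magnitude must be below 25% of the canvas")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  validate_stain_matrix(spec$stain_matrix)
  if (spec$aggregate_frac < 0 || spec$aggregate_frac > 1)
    stop("aggregate_frac must be in [0, 1]")
  invisible(spec)
}

#' Panel markers implied by a spot spec
#' @keywords internal
spec_markers <- function(spec) {
  unique(unlist(lapply(spec$profiles, names), use.names = FALSE))
}

# Hard-core sampling of n centers in [margin, canvas - margin]^2 with minimum
# pairwise separation min_sep, via a uniform grid occupancy structure.
hardcore_centers <- function(n, canvas, margin, min_sep, max_tries = 300L) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  lo <- margin; hi <- canvas - margin
  if (hi <= lo) stop("canvas too small for the requested nucleus radius")
  cell <- max(min_sep, 1)
  ng <- max(1L, as.integer(ceiling((hi - lo) / cell)))
  grid <- vector("list", ng * ng)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  budget <- max_tries * n
  while (placed < n && tries < budget) {
    tries <- tries + 1L
    x <- runif(1, lo, hi); y <- runif(1, lo, hi)
    gx <- min(ng, 1L + as.integer((x - lo) / cell))
    gy <- min(ng, 1L + as.integer((y - lo) / cell))
    ok <- TRUE
    for (ix in max(1L, gx - 1L):min(ng, gx + 1L)) {
      for (iy in max(1L, gy - 1L):min(ng, gy + 1L)) {
        for (k in grid[[(iy - 1L) * ng + ix]]) {
          if ((xs[k] - x)^2 + (ys[k] - y)^2 < min_sep^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      idx <- (gy - 1L) * ng + gx
      grid[[idx]] <- c(grid[[idx]], placed)
    }
  }
  if (placed < n)
    stop("requested density too high for hard-core placement: only ", placed,
         " of ", n, " cells fit (canvas ", canvas, ", min separation ",
         signif(min_sep, 4), " px)")
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# Render one radially-peaked nucleus blob into matrix `img` (in place value
# return). Peak `peak` at the center falling to 0.3*peak at the rim so every
# nucleus carries exactly one regional intensity maximum with a saddle deep
# enough to survive pre-watershed smoothing.
render_blob <- function(img, cx, cy, r, peak, flat = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  c0 <- max(1L, as.integer(floor(cx - r))); c1 <- min(nc, as.integer(ceiling(cx + r)))
  r0 <- max(1L, as.integer(floor(cy - r))); r1 <- min(nr, as.integer(ceiling(cy + r)))
  if (c0 > c1 || r0 > r1) return(img)
  cols <- c0:c1; rows <- r0:r1
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  inside <- d2 <= r^2
  if (!any(inside)) return(img)
  val <- if (flat) peak * inside else peak * (1 - 0.7 * sqrt(d2) / r) * inside
  img[rows, cols] <- pmax(img[rows, cols], val)
  img
}

#' Generate one synthetic TMA spot with ground truth
#'
#' Renders a fluorescent channel stack (nuclear channel plus one channel per
#' panel marker), a brightfield RGB image synthesized from chromogen
#' concentration maps through the Beer-Lambert forward model
#' (I = I0 * 10^(-t(M) c), I0 = 255), and the ground-truth cell table.
#' Nucleus centers are placed by hard-core sampling so single cells are
#' unambiguous; the brightfield round is translated by the planted shift
#' relative to the fluorescent round. Deterministic given `spec$seed`.
#'
#' @param spec a [spot_spec()].
#' @return list with elements `fluor` (named list of matrices on a [0,1]
#'   intensity scale; first element `nuclear`), `brightfield` (h x w x 3
#'   array, intensities in (0, 255]), `concentrations` (h x w x 3 array of
#'   true chromogen concentrations, pre-shift), `truth` (data.frame: cell id,
#'   x, y, radius, type, logical positivity per marker), and `meta`
#'   (planted shift, seed, channel names).
#' @export
generate_tma_spot <- function(spec) {
  validate_spot_spec(spec)
  set.seed(substream_seed(spec$seed, "spot"))
  markers <- spec_markers(spec)
  n <- spec$n_cells
  cv <- spec$canvas
  rmin <- spec$nucleus_radius[1]; rmax <- spec$nucleus_radius[2]
  min_sep <- spec$min_sep_factor * 2 * rmax

  n_pair <- if (n > 0) as.integer(round(spec$aggregate_frac * n / 2)) else 0L
  n_single <- n - 2L * n_pair
  # primaries of aggregate pairs get extra clearance so companions of
  # different pairs never approach each other
  sep_pad <- if (n_pair > 0) 3 * rmax else 0
  centers <- hardcore_centers(n_single + n_pair, cv,
                              margin = rmax + 1 + (sep_pad > 0) * rmax,
                              min_sep = min_sep + sep_pad)

  radii <- if (n > 0) runif(n, rmin, rmax) else numeric(0)
  if (n_pair > 0) {
    # aggregate pairs: companion nucleus at sub-diameter spacing, scaled to
    # the pair's larger nucleus so the inter-peak saddle stays resolvable
    prim <- centers[seq.int(n_single + 1L, n_single + n_pair), , drop = FALSE]
    ang <- runif(n_pair, 0, 2 * pi)
    r_prim <- radii[seq.int(n_single + 1L, n_single + n_pair)]
    r_comp <- radii[seq.int(n_single + n_pair + 1L, n)]
    d <- 1.8 * pmax(r_prim, r_comp)
    comp <- cbind(pmin(pmax(prim[, 1] + d * cos(ang), rmax + 1), cv - rmax - 1),
                  pmin(pmax(prim[, 2] + d * sin(ang), rmax + 1), cv - rmax - 1))
    centers <- rbind(centers, comp)
  }

  types <- if (n > 0)
    sample(names(spec$proportions), n, replace = TRUE, prob = spec$proportions)
  else character(0)

  pos <- matrix(FALSE, n, length(markers), dimnames = list(NULL, markers))
  for (m in markers) {
    mu <- vapply(spec$profiles[types], function(p) if (m %in% names(p)) p[[m]] else 0, 0)
    pos[, m] <- mu > 0
  }

  blank <- matrix(0, cv, cv)
  nuclear <- blank
  chans <- stats::setNames(rep(list(blank), length(markers)), markers)
  if (n > 0) {
    for (i in seq_len(n)) {
      nuclear <- render_blob(nuclear, centers[i, 1], centers[i, 2], radii[i],
                             spec$nuclear_intensity)
      prof <- spec$profiles[[types[i]]]
      for (m in names(prof)) {
        chans[[m]] <- render_blob(chans[[m]], centers[i, 1], centers[i, 2],
                                  radii[i], prof[[m]], flat = TRUE)
      }
    }
  }

  # chromogen concentration maps feeding the Beer-Lambert brightfield model
  pick_map <- function(src) if (identical(src, "nuclear")) nuclear else
    if (src %in% names(chans)) chans[[src]] else
      stop("unknown chromogen source '", src, "'")
  conc <- array(0, c(cv, cv, 3))
  for (k in 1:3) conc[, , k] <- pick_map(spec$chromogen_sources[k])

  conc_shifted <- conc
  if (any(spec$shift != 0)) {
    for (k in 1:3)
      conc_shifted[, , k] <- shift_matrix(conc[, , k], spec$shift[1], spec$shift[2])
  }
  brightfield <- beer_lambert_forward(conc_shifted, spec$stain_matrix, I0 = 255)

  if (spec$noise_sd > 0) {
    nuclear <- pmax(nuclear + stats::rnorm(length(nuclear), 0, spec$noise_sd), 0)
    chans <- lapply(chans, function(ch)
      pmax(ch + stats::rnorm(length(ch), 0, spec$noise_sd), 0))
    bn <- stats::rnorm(length(brightfield), 0, spec$noise_sd * 255)
    brightfield <- pmin(pmax(brightfield + bn, 1e-3), 255)
  }

  truth <- data.frame(cell = seq_len(n),
                      x = if (n > 0) centers[, 1] else numeric(0),
                      y = if (n > 0) centers[, 2] else numeric(0),
                      radius = radii,
                      type = types,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(pos))

  list(fluor = c(list(nuclear = nuclear), chans),
       brightfield = brightfield,
       concentrations = conc,
       truth = truth,
       meta = list(shift = spec$shift, seed = spec$seed,
                   markers = markers, canvas = cv,
                   noise_sd = spec$noise_sd,
                   stain_matrix = spec$stain_matrix))
}

#' Beer-Lambert forward model for brightfield synthesis
#'
#' Transmitted intensity per pixel and RGB channel:
#' `I = I0 * 10^(-sum_s M[s, ] * c_s)`, with `M` the row-normalized stain
#' matrix and `c_s` the concentration of chromogen `s`.
#'
#' @param conc h x w x S array of chromogen concentrations (S = nrow(M)).
#' @param stain_matrix S x 3 unit-OD stain matrix.
#' @param I0 incident intensity (default 255).
#' @return h x w x 3 array of transmitted RGB intensities in (0, I0].
#' @export
beer_lambert_forward <- function(conc, stain_matrix, I0 = 255) {
  stopifnot(length(dim(conc)) == 3, dim(conc)[3] == nrow(stain_matrix))
  d <- dim(conc)
  cmat <- matrix(conc, prod(d[1:2]), d[3])
  od <- cmat %*% stain_matrix          # pixels x 3 optical densities
  array(I0 * 10^(-od), c(d[1], d[2], 3))
}

# ---------------------------------------------------------------------------
# Cohort generator
# ---------------------------------------------------------------------------

#' Specification of a synthetic patient cohort
#'
#' Survival follows a cause-specific exponential proportional-hazards model:
#' each patient gets latent relapse and death times with hazards
#' `rate_cause * exp(x' beta_cause)` over standardized covariates; the
#' observed first event competes with an independent Bernoulli censoring
#' indicator. The planted signal covariates mirror the clinical risk profile
#' of adult B-ALL: higher age, lower platelet count and a higher
#' CD4+PD1+TIM3+ exhausted T-cell fraction all increase hazard.
#'
#' @param n number of patients (>= 2).
#' @param beta_relapse,beta_death named numeric log-hazard coefficients on
#'   standardized covariates for the two causes. Names must be covariate
#'   names; covariates not named get coefficient 0.
#' @param rate_relapse,rate_death baseline cause-specific hazards (events per
#'   day).
#' @param censor_rate probability in [0, 1) that a patient is censored
#'   (uniformly before their first event).
#' @param n_null_features number of additional immune features carrying no
#'   survival signal.
#' @param mrd_slope,mrd_intercept logistic dependence of MRD positivity on
#'   the standardized true relapse risk score.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100L,
                        beta_relapse = c(age = 0.5, platelet = -0.5,
                                         cd4_pd1_tim3 = 0.6),
                        beta_death = c(age = 0.6, platelet = -0.4,
                                       cd4_pd1_tim3 = 0.5),
                        rate_relapse = 0.15 / 365.25,
                        rate_death = 0.08 / 365.25,
                        censor_rate = 0.2,
                        n_null_features = 7L,
                        mrd_slope = 1.0,
                        mrd_intercept = -0.5,
                        seed = 1L) {
  spec <- list(n = as.integer(n), beta_relapse = beta_relapse,
               beta_death = beta_death, rate_relapse = rate_relapse,
               rate_death = rate_death, censor_rate = censor_rate,
               n_null_features = as.integer(n_null_features),
               mrd_slope = mrd_slope, mrd_intercept = mrd_intercept,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n < 2) stop("cohort must have n >= 2 patients")
  if (!all(is.finite(c(spec$beta_relapse, spec$beta_death))))
    stop("non-finite log-hazard coefficient")
  if (spec$rate_relapse <= 0 || spec$rate_death <= 0)
    stop("baseline hazards must be positive")
  if (spec$censor_rate < 0 || spec$censor_rate >= 1)
    stop("censoring rate must be in [0, 1)")
  invisible(spec)
}

#' Generate a synthetic patient cohort with planted hazard structure
#'
#' @param spec a [cohort_spec()].
#' @return list with `covariates` (patient_id, age, platelet, cd4_pd1_tim3 in
#'   percent, and null immune features), `survival` (patient_id, time in
#'   days, event in {censored, relapse, death}; plus wide columns
#'   relapse_time, death_time, followup_time for endpoint derivation),
#'   `mrd` (patient_id, blast_fraction, mrd_positive) and `truth`
#'   (standardized design matrix, true linear predictors, coefficients).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(substream_seed(spec$seed, "cohort"))
  n <- spec$n

  age <- pmax(18, pmin(85, stats::rnorm(n, 45, 13)))
  platelet <- stats::rlnorm(n, log(120), 0.55)               # 10^9/L
  # CD4+PD1+TIM3+ fraction of CD4 T cells, percent: small, right-skewed
  cd4_pd1_tim3 <- stats::rgamma(n, shape = 0.35, scale = 0.35)
  covs <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                     age = age, platelet = platelet,
                     cd4_pd1_tim3 = cd4_pd1_tim3,
                     stringsAsFactors = FALSE)
  if (spec$n_null_features > 0) {
    for (j in seq_len(spec$n_null_features)) {
      covs[[paste0("null_feature_", j)]] <-
        stats::rbeta(n, 2, 20) * 100     # null immune proportions, percent
    }
  }

  xnames <- setdiff(names(covs), "patient_id")
  X <- scale(as.matrix(covs[xnames]))
  beta_vec <- function(beta) {
    b <- stats::setNames(numeric(length(xnames)), xnames)
    unknown <- setdiff(names(beta), xnames)
    if (length(unknown)) stop("coefficient names unknown: ",
                              paste(unknown, collapse = ", "))
    b[names(beta)] <- beta
    b
  }
  b_rel <- beta_vec(spec$beta_relapse)
  b_dea <- beta_vec(spec$beta_death)
  lp_rel <- drop(X %*% b_rel)
  lp_dea <- drop(X %*% b_dea)

  t_rel <- stats::rexp(n, spec$rate_relapse * exp(lp_rel))
  t_dea <- stats::rexp(n, spec$rate_death * exp(lp_dea))
  first <- pmin(t_rel, t_dea)
  cause <- ifelse(t_rel <= t_dea, "relapse", "death")

  censored <- stats::runif(n) < spec$censor_rate
  ctime <- stats::runif(n, 0, first)

  time <- ifelse(censored, ctime, first)
  event <- ifelse(censored, "censored", cause)

  # wide follow-up view: relapsed patients later die of a post-relapse hazard
  t_post <- stats::rexp(n, spec$rate_death * 3 * exp(lp_dea))
  relapse_time <- ifelse(!censored & cause == "relapse", t_rel, NA_real_)
  death_time <- ifelse(censored, NA_real_,
                       ifelse(cause == "death", t_dea, t_rel + t_post))
  followup_time <- ifelse(censored, ctime, death_time)

  survival <- data.frame(patient_id = covs$patient_id,
                         time = time, event = event,
                         relapse_time = relapse_time,
                         death_time = death_time,
                         followup_time = followup_time,
                         stringsAsFactors = FALSE)

  z <- as.numeric(scale(lp_rel))
  if (stats::sd(lp_rel) == 0) z <- rep(0, n)
  p_mrd <- stats::plogis(spec$mrd_intercept + spec$mrd_slope * z)
  mrd_positive <- stats::runif(n) < p_mrd
  blast_fraction <- ifelse(mrd_positive,
                           10^stats::runif(n, -3.8, -1.5),
                           10^stats::runif(n, -6.5, -4.2))
  mrd <- data.frame(patient_id = covs$patient_id,
                    blast_fraction = blast_fraction,
                    mrd_positive = mrd_positive,
                    stringsAsFactors = FALSE)

  list(covariates = covs, survival = survival, mrd = mrd,
       truth = list(X = X, lp_relapse = lp_rel, lp_death = lp_dea,
                    beta_relapse = b_rel, beta_death = b_dea,
                    seed = spec$seed))
}

# ---------------------------------------------------------------------------
# Flow-cytometry-like event tables
# ---------------------------------------------------------------------------

#' Generate a flow-cytometry-like event table
#'
#' Per-event intensities for CD45, CD3, CD4, CD8, PD1 and TIM3 are drawn from
#' well-separated negative/positive Gaussian mixture components
#' (negative mean 1, positive mean 3, sd 0.15) so that gating at the midpoint
#' (2.0) recovers the specified population fractions. Fractions are
#' conditional on the parent gate (CD45+ of all, CD3+ of CD45+, CD4+ of CD3+,
#' PD1+TIM3+ of CD4+), which keeps the hierarchy consistent by construction;
#' a fraction outside [0, 1] (a child exceeding its parent) is an error.
#'
#' @param n number of events.
#' @param fractions named list/vector with elements `CD45`, `CD3`, `CD4`,
#'   `PD1TIM3` (conditional positive fractions) and optionally `CD8`
#'   (fraction of CD3+CD4- events that are CD8+, default 0.9).
#' @param seed integer seed.
#' @param neg_mean,pos_mean,sd mixture component parameters.
#' @return data.frame with one row per event and columns CD45, CD3, CD4, CD8,
#'   PD1, TIM3.
#' @export
generate_fc_events <- function(n,
                               fractions = list(CD45 = 0.9, CD3 = 0.4,
                                                CD4 = 0.5, PD1TIM3 = 0.1),
                               seed = 1L,
                               neg_mean = 1, pos_mean = 3, sd = 0.15) {
  fr <- as.list(fractions)
  for (nm in c("CD45", "CD3", "CD4", "PD1TIM3")) {
    if (is.null(fr[[nm]])) stop("fractions must include '", nm, "'")
    if (!is_num1(fr[[nm]]) || fr[[nm]] < 0 || fr[[nm]] > 1)
      stop("gate fraction '", nm, "' must lie in [0, 1]: a child population ",
           "cannot exceed its parent")
  }
  if (is.null(fr$CD8)) fr$CD8 <- 0.9
  set.seed(substream_seed(seed, "fc"))
  n <- as.integer(n)

  cd45p <- stats::runif(n) < fr$CD45
  cd3p <- cd45p & (stats::runif(n) < fr$CD3)
  cd4p <- cd3p & (stats::runif(n) < fr$CD4)
  cd8p <- cd3p & !cd4p & (stats::runif(n) < fr$CD8)
  dp <- cd4p & (stats::runif(n) < fr$PD1TIM3)

  draw <- function(positive)
    stats::rnorm(n, ifelse(positive, pos_mean, neg_mean), sd)
  data.frame(CD45 = draw(cd45p), CD3 = draw(cd3p), CD4 = draw(cd4p),
             CD8 = draw(cd8p), PD1 = draw(dp), TIM3 = draw(dp))
}
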