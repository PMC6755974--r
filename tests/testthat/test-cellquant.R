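test_that("Otsu threshold equals exhaustive search and handles edge cases", {
  # bimodal two-level histogram
  thr <- otsu_threshold(c(10, 200), c(100, 100))
  expect_gt(thr, 9); expect_lt(thr, 200)
  expect_equal(thr, brute_otsu(c(10, 200), c(100, 100)))

  # two-Gaussian mixture quantized to 256 levels
  set.seed(3)
  px <- c(rnorm(5e4, 50, 10), rnorm(5e4, 180, 10))
  px <- pmin(pmax(round(px), 0), 255)
  counts <- tabulate(px + 1, 256)
  vals <- 0:255
  expect_equal(otsu_threshold(vals, counts), brute_otsu(vals, counts))
  expect_gt(otsu_threshold(vals, counts), 50)
  expect_lt(otsu_threshold(vals, counts), 180)

  expect_error(otsu_threshold(5, 100), "2 distinct")
  expect_error(otsu_image(matrix(1, 4, 4)), "constant")

  # random histograms agree with brute force (incl. tie-breaking)
  set.seed(11)
  for (i in 1:50) {
    v <- sort(sample(0:40, sample(3:12, 1)))
    n <- sample(1:30, length(v), replace = TRUE)
    expect_equal(otsu_threshold(v, n), brute_otsu(v, n))
  }
})

test_that("segmentation recovers isolated cells and their centroids", {
  sp <- t_only_spec(n_cells = 300, canvas = 480, seed = 13)
  spot <- generate_tma_spot(sp)
  expect_equal(segment_cells(matrix(0, 32, 32), matrix(0, 32, 32)),
               matrix(0L, 32, 32))
  expect_error(segment_cells(matrix(1, 8, 8), matrix(1, 4, 4)), "registered")

  labels <- segment_cells(spot$fluor$CD3, spot$fluor$nuclear)
  expect_equal(max(labels), 300)
  cells <- measure_intensities(labels, spot$fluor["CD3"])
  d <- vapply(seq_len(nrow(cells)), function(i)
    min(sqrt((spot$truth$x - cells$x[i])^2 + (spot$truth$y - cells$y[i])^2)),
    0)
  expect_lt(max(d), 2)
})

test_that("touching aggregate pairs are split into two cells", {
  sp <- t_only_spec(n_cells = 200, canvas = 820, seed = 19, aggregate_frac = 1)
  spot <- generate_tma_spot(sp)
  expect_equal(nrow(spot$truth), 200)
  labels <- segment_cells(spot$fluor$CD3, spot$fluor$nuclear)
  # >= 95% of the 100 pairs resolved into 2 labels
  expect_gte(max(labels), 0.95 * 200)
  expect_lte(max(labels), 1.05 * 200)
})

test_that("total-cell counting follows the binary-area rule", {
  expect_equal(count_total_cells(matrix(0, 16, 16), 25), 0L)
  expect_error(count_total_cells(matrix(1, 4, 4), 0), "positive")

  # 50 non-overlapping disks; radius 6 rasterizes to 113 px, matching its
  # continuous area 36*pi to 0.1%
  img <- matrix(0, 300, 300)
  centers <- expand.grid(x = seq(20, 285, by = 36), y = seq(20, 285, by = 36))
  centers <- centers[1:50, ]
  for (i in 1:50)
    img <- immunotma:::render_blob(img, centers$x[i], centers$y[i], 6, 1,
                                   flat = TRUE)
  cnt <- count_total_cells(img, 36 * pi)
  expect_lte(abs(cnt - 50), 1)

  sp <- spot_spec(canvas = 1024, n_cells = 2000, seed = 23)
  spot <- generate_tma_spot(sp)
  mean_area <- pi * mean(spot$truth$radius^2)
  cnt <- count_total_cells(spot$fluor$nuclear, mean_area)
  expect_lt(abs(cnt - 2000) / 2000, 0.05)
})

test_that("integrated intensities sum pixel values and scale linearly", {
  labels <- matrix(0L, 4, 4)
  labels[1, 1:4] <- 1L
  ch <- matrix(0, 4, 4); ch[1, 1:4] <- c(1, 2, 3, 4)
  out <- measure_intensities(labels, list(m = ch))
  expect_equal(out$m, 10)
  expect_equal(out$area, 4)
  out2 <- measure_intensities(labels, list(m = 2 * ch))
  expect_equal(out2$m, 2 * out$m)
})

test_that("gating trees validate structure and classify by thresholds", {
  expect_error(gating_tree(list(
    list(name = "a", parent = NA, positive = "NOPE",
         negative = character(0), denominator = "all")), c("CD3")),
    "unknown marker")
  expect_error(gating_tree(list(
    list(name = "a", parent = "b", positive = "CD3",
         negative = character(0), denominator = "all"),
    list(name = "b", parent = "a", positive = "CD3",
         negative = character(0), denominator = "all")), "CD3"),
    "cycle")

  tree <- default_gating_tree()
  cells <- data.frame(cell = 1:3, x = 0, y = 0, area = c(10, 10, 10),
                      CD3 = c(8, 0, 8), CD4 = c(8, 0, 0), CD8 = c(0, 0, 8),
                      CD20 = 0, CD56 = 0, CD68 = 0,
                      PD1 = c(8, 0, 0), TIM3 = c(8, 0, 0))
  thr <- setNames(rep(0.3, 8), tree$markers)
  cl <- classify_cells(cells, thr, tree)
  expect_equal(cl$CD4_PD1_TIM3, c(TRUE, FALSE, FALSE))
  expect_equal(cl$CD8_T, c(FALSE, FALSE, TRUE))
  expect_equal(cl$lineage, c("CD3_T", NA, "CD3_T"))
  # all-zero cell is negative everywhere
  expect_false(any(unlist(cl[2, c("CD3_T", "CD4_T", "CD8_T", "B", "NK",
                                  "MAC", "CD4_PD1_TIM3")])))
})

test_that("phenotype labels match ground truth on a clean synthetic spot", {
  sp <- spot_spec(canvas = 560, n_cells = 400, seed = 31)
  spot <- generate_tma_spot(sp)
  res <- quantify_spot_image(spot$fluor, qc_threshold = 100)
  truth_counts <- table(spot$truth$type)
  cells <- res$cells
  expect_equal(sum(cells$CD4_T),
               sum(truth_counts[c("T_CD4", "T_CD4_PD1TIM3")], na.rm = TRUE),
               tolerance = 0.02)
  expect_equal(sum(cells$CD4_PD1_TIM3),
               unname(truth_counts["T_CD4_PD1TIM3"]), tolerance = 0.02)
})

test_that("spot quantification applies QC and missing-denominator rules", {
  tree <- default_gating_tree()
  cells <- data.frame(cell = 1:2, x = 0, y = 0, area = 10,
                      CD3 = 0, CD4 = 0, CD8 = 0, CD20 = 0,
                      CD56 = c(8, 8), CD68 = 0, PD1 = 0, TIM3 = 0)
  thr <- setNames(rep(0.3, 8), tree$markers)
  cells <- classify_cells(cells, thr, tree)

  q1 <- quantify_spot(cells, total_cells = 999, tree)
  expect_false(q1$qc_pass)
  q2 <- quantify_spot(cells[rep(1:2, 5), ], total_cells = 1000, tree)
  expect_true(q2$qc_pass)
  expect_equal(q2$NK, 10 / 1000)
  # no CD3+CD4+ cells -> parent-denominated feature missing, not zero
  expect_true(is.na(q2$CD4_PD1_TIM3))
  expect_equal(q2$CD4_T, 0)
  expect_error(quantify_spot(cells, total_cells = -1, tree), ">= 0")
})

test_that("QC monotonicity: lowering the threshold never excludes a spot", {
  tree <- default_gating_tree()
  cells <- data.frame(cell = 1, x = 0, y = 0, area = 10, CD3 = 8, CD4 = 8,
                      CD8 = 0, CD20 = 0, CD56 = 0, CD68 = 0, PD1 = 0,
                      TIM3 = 0)
  cells <- classify_cells(cells, setNames(rep(0.3, 8), tree$markers), tree)
  totals <- c(200, 800, 1500, 5000)
  pass_hi <- vapply(totals, function(tc)
    quantify_spot(cells, tc, tree, qc_threshold = 1000)$qc_pass, TRUE)
  pass_lo <- vapply(totals, function(tc)
    quantify_spot(cells, tc, tree, qc_threshold = 500)$qc_pass, TRUE)
  expect_true(all(pass_lo >= pass_hi))
})

test_that("proportions are count-consistent and lineages do not exceed 1", {
  sp <- spot_spec(canvas = 480, n_cells = 300, seed = 37, noise_sd = 0.02)
  spot <- generate_tma_spot(sp)
  res <- quantify_spot_image(spot$fluor, qc_threshold = 100)
  q <- res$quantification
  tree <- default_gating_tree()
  lin <- vapply(tree$nodes, function(nd) nd$denominator == "all" &&
                  is.na(nd$parent), TRUE)
  lin_names <- names(lin)[lin]
  expect_lte(sum(unlist(q[lin_names]), na.rm = TRUE), 1)
  for (nd in tree$nodes) {
    v <- q[[nd$name]]
    if (is.na(v)) next
    den <- if (nd$denominator == "all") res$total_cells
           else sum(res$cells[[nd$parent]])
    expect_lt(abs(v * den - round(v * den)), 1e-9)
  }
})

test_that("duplicate spots are averaged with QC and missing handling", {
  base <- data.frame(spot_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
                     patient_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
                     batch = "b1",
                     total_cells = c(2000, 2000, 2000, 500, 400, 300),
                     qc_pass = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     NK = c(0.10, 0.20, 0.05, 0.50, 0.1, 0.2))
  prof <- aggregate_duplicates(base)
  expect_equal(prof$NK[prof$patient_id == "p1"], 0.15)
  # one duplicate QC-failed -> surviving spot's value
  expect_equal(prof$NK[prof$patient_id == "p2"], 0.05)
  # both failed -> patient dropped
  expect_false("p3" %in% prof$patient_id)
})

test_that("FC gating recovers the planted double-positive fraction", {
  ev <- data.frame(CD45 = 0, CD3 = 0, CD4 = 0, CD8 = 0, PD1 = 0, TIM3 = 0)
  expect_true(is.na(gate_fc_events(ev)))

  tab <- generate_fc_events(50000, fractions = list(CD45 = 0.95, CD3 = 0.4,
                                                    CD4 = 0.5, PD1TIM3 = 0.1),
                            seed = 41)
  got <- gate_fc_events(tab)
  expect_named(got, "CD4_PD1_TIM3")
  np <- attr(got, "n_parent")
  expect_lt(abs(unname(got) - 0.1), 3 * sqrt(0.1 * 0.9 / np))
})
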