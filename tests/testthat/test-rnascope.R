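make_control <- function(values, channel = "Gal") {
  data.frame(cell_id = sprintf("ctrl%03d", seq_along(values)),
             channel = channel, max_intensity = values,
             stringsAsFactors = FALSE)
}

test_that("threshold is control mean max intensity plus three sample SDs", {
  thr <- derive_threshold(make_control(c(1, 2, 3)), "Gal")
  expect_equal(thr$mean_max, 2)
  expect_equal(thr$sd_max, 1)      # sample SD, n - 1 denominator
  expect_equal(thr$threshold, 5)

  # zero spread: threshold equals the constant
  expect_equal(derive_threshold(make_control(rep(7, 5)), "Gal")$threshold, 7)

  expect_error(derive_threshold(make_control(3), "Gal"), ">= 2 control cells")
  expect_error(derive_threshold(make_control(c(1, 2), "Gal"), "Fos"),
               ">= 2 control cells")
})

test_that("cluster resolution divides out the single-signal intensity", {
  expect_equal(resolve_cluster(1500, 300, 0), 5L)
  expect_equal(resolve_cluster(1000, 300, 100), 3L)
  expect_equal(resolve_cluster(950, 300, 100), 3L)    # round(2.83) half-up
  expect_equal(resolve_cluster(440, 300, 0), 1L)      # round(1.47)
  expect_equal(resolve_cluster(460, 300, 0), 2L)      # half-up at 1.53
  expect_equal(resolve_cluster(150, 300, 0), 1L)      # clamp to >= 1
  expect_warning(n <- resolve_cluster(50, 300, 100), "below background")
  expect_equal(n, 1L)
  expect_error(resolve_cluster(100, 0), "must be > 0")
})

test_that("per-cell counts sum supra-threshold objects and zero-fill", {
  signals <- data.frame(
    cell_id = c("c1", "c1", "c2"),
    animal_id = "a1", section_id = "s1", condition = "ctrl",
    channel = "Gal",
    integral_intensity = c(350, 290, 900),
    stringsAsFactors = FALSE)
  thr <- list(Gal = list(threshold = 300))
  cal <- list(Gal = list(single_signal_mean_intensity = 300, background = 0))
  cells <- data.frame(cell_id = c("c1", "c2", "c3"), animal_id = "a1",
                      section_id = "s1", condition = "ctrl",
                      stringsAsFactors = FALSE)
  out <- cell_molecule_counts(signals, thr, cal, cells)
  expect_equal(out$Gal[match(c("c1", "c2", "c3"), out$cell_id)], c(1L, 3L, 0L))

  expect_error(cell_molecule_counts(signals, list(), cal, cells),
               "no threshold")
  expect_error(cell_molecule_counts(signals, thr, list(), cells),
               "no calibration")
})

test_that("positivity rules and composite classes", {
  counts <- data.frame(cell_id = c("c1", "c2", "c3"),
                       animal_id = "a1", section_id = "s1", condition = "x",
                       Gal = c(2L, 3L, 1L), Calcr = c(0L, 2L, 2L),
                       Fos = c(4L, 5L, 9L), stringsAsFactors = FALSE)
  cls <- classify_cells(counts, c(Gal = 2, Calcr = 2, Fos = 5))
  expect_equal(cls$Gal_pos, c(TRUE, TRUE, FALSE))    # Gal 2+ molecules
  expect_equal(cls$Fos_pos, c(FALSE, TRUE, TRUE))    # Fos 5+: 4 is negative
  expect_equal(composite_positive(cls, c("Gal", "Calcr")),
               c(FALSE, TRUE, FALSE))
  expect_error(classify_cells(counts, c(Nope = 2)), "unknown channel")
  expect_error(classify_cells(counts, c(Gal = 0)), ">= 1")
})

test_that("per-1000 normalization and its bounds", {
  expect_equal(positives_per_1000(50, 2000), 25)
  expect_equal(positives_per_1000(0, 10), 0)
  expect_equal(positives_per_1000(10, 10), 1000)
  expect_error(positives_per_1000(5, 0), "n_total_cells")
  expect_error(positives_per_1000(11, 10), "<=")
})

test_that("H-score bins, bounds and mixture linearity", {
  expect_equal(h_score(rep(0L, 10)), 0)
  expect_equal(h_score(rep(16L, 4)), 400)
  expect_equal(h_score(c(rep(2L, 5), rep(5L, 5))), 150)
  # bin edges: 1-3 -> 1, 4-9 -> 2, 10-15 -> 3, 16+ -> 4
  expect_equal(h_score(c(0L, 1L, 3L, 4L, 9L, 10L, 15L, 16L)),
               (0 + 1 + 1 + 2 + 2 + 3 + 3 + 4) / 8 * 100)
  expect_error(h_score(integer(0)), "empty")
  expect_error(h_score(c(1, -1)), "non-negative")

  set.seed(31)
  for (i in 1:20) {
    c1 <- rpois(sample(5:50, 1), sample(1:12, 1))
    c2 <- rpois(sample(5:50, 1), sample(1:12, 1))
    h1 <- h_score(c1); h2 <- h_score(c2)
    expect_gte(h1, 0); expect_lte(h1, 400)
    # order invariance and exact mixture weighting
    expect_equal(h_score(sample(c1)), h1)
    n1 <- length(c1); n2 <- length(c2)
    expect_equal(h_score(c(c1, c2)),
                 (n1 * h1 + n2 * h2) / (n1 + n2), tolerance = 1e-12)
  }
})

test_that("class fold changes divide mean molecule counts", {
  counts <- data.frame(cell_id = sprintf("c%d", 1:6),
                       animal_id = "a1", section_id = "s1", condition = "x",
                       Magel2 = c(6L, 5L, 5L, 2L, 2L, 2L),
                       stringsAsFactors = FALSE)
  gal_th <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  fc <- fold_change_classes(counts, "Magel2", gal_th, !gal_th)
  expect_equal(fc, (16 / 3) / 2)
  # reciprocal identity
  expect_equal(fc * fold_change_classes(counts, "Magel2", !gal_th, gal_th), 1)
  # identical classes
  expect_equal(fold_change_classes(counts, "Magel2", gal_th, gal_th), 1)
  # predicate form
  fc2 <- fold_change_classes(counts, "Magel2",
                             function(df) df$Magel2 >= 5,
                             function(df) df$Magel2 < 5)
  expect_equal(fc2, (16 / 3) / 2)
  expect_error(fold_change_classes(counts, "Magel2", gal_th, rep(FALSE, 6)),
               "non-empty")
  counts$Zero <- 0L
  expect_error(fold_change_classes(counts, "Zero", gal_th, !gal_th),
               "zero mean")
})

test_that("noise-free synthetic spots are recovered exactly", {
  sp <- simulate_spots(n_cells = 300, single_intensity_sd = 0,
                       cluster_prob = 0.5, background = 50,
                       control_noise_sd = 10, seed = 12)
  thr <- derive_thresholds(sp$control)
  counts <- cell_molecule_counts(sp$signals, thr, default_calibration(),
                                 cells = sp$cells)
  gt <- sp$ground_truth[match(counts$cell_id, sp$ground_truth$cell_id), ]
  for (ch in c("Gal", "Calcr", "Fos")) {
    expect_identical(counts[[ch]], gt[[ch]])
  }
})

test_that("10% intensity noise perturbs per-cell counts by at most 1 in >= 99% of cells", {
  sp <- simulate_spots(n_cells = 1500, single_intensity_sd = 30,
                       cluster_prob = 0.3, background = 50,
                       control_noise_sd = 10, seed = 8)
  thr <- derive_thresholds(sp$control)
  counts <- cell_molecule_counts(sp$signals, thr, default_calibration(),
                                 cells = sp$cells)
  gt <- sp$ground_truth[match(counts$cell_id, sp$ground_truth$cell_id), ]
  err <- abs(c(counts$Gal - gt$Gal, counts$Calcr - gt$Calcr,
               counts$Fos - gt$Fos))
  expect_gte(mean(err <= 1), 0.99)
})

test_that("single-intensity estimator targets the dim half of the objects", {
  set.seed(4)
  singles <- rnorm(400, 300, 20)
  clusters <- rnorm(100, 900, 50)
  sig <- data.frame(cell_id = "c", animal_id = "a", section_id = "s",
                    condition = "x", channel = "Gal",
                    integral_intensity = c(singles, clusters),
                    stringsAsFactors = FALSE)
  est <- estimate_single_intensity(sig, "Gal")
  expect_lt(abs(est - 300), 30)
  expect_error(estimate_single_intensity(sig, "Missing"), "no objects")
})

test_that("per-animal summary aggregates pooled counts per channel", {
  counts <- data.frame(cell_id = sprintf("c%d", 1:8),
                       animal_id = rep(c("a1", "a2"), each = 4),
                       section_id = rep(c("s1", "s2"), 4),
                       condition = rep(c("exposed", "control"), each = 4),
                       Gal = c(2L, 0L, 3L, 0L, 5L, 5L, 0L, 0L),
                       stringsAsFactors = FALSE)
  s <- summarize_by_animal(counts, c(Gal = 2))
  a1 <- s[s$animal_id == "a1", ]
  expect_equal(a1$n_cells, 4)
  expect_equal(a1$n_positive, 2)
  expect_equal(a1$per_1000, 500)
  expect_equal(a1$h_score, h_score(c(2L, 0L, 3L, 0L)))
  expect_equal(s$condition[s$animal_id == "a2"], "control")
})
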