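# Breadth-threshold model: curve evaluation, calibration fitting,
# model selection, subsampling and the detection rule.

test_that("the reference threshold curve evaluates to its documented values", {
  m <- default_threshold_model()
  expect_equal(breadth_threshold(m, 0), -180.31, tolerance = 1e-9)
  expect_equal(breadth_threshold(m, 5), 73.76706, tolerance = 1e-4)
  expect_equal(round(breadth_threshold(m, 50), 2), 75.27)
  # strictly increasing with supremum c (grid kept below the depth where
  # b^d underflows past double precision)
  d <- seq(0, 15, by = 0.25)
  thr <- breadth_threshold(m, d)
  expect_true(all(diff(thr) > 0))
  expect_true(all(thr < m$c))
  expect_error(breadth_threshold(m, -1), "non-negative")
  expect_error(threshold_model(a = 10, b = 0.5, c = 50), "a")
  expect_error(threshold_model(a = -10, b = 1.5, c = 50), "b")
  expect_error(threshold_model(a = -10, b = 0.5, c = 150), "c")
})

test_that("saturation fitting recovers known parameters", {
  d <- c(0.5, 1, 2, 3, 5, 8)
  truth <- c(a = -255.58, b = 0.358, c = 75.27)
  y <- truth["a"] * truth["b"]^d + truth["c"]
  fit <- fit_saturation(data.frame(mean_depth = d, breadth_pct = y))
  expect_lt(abs(fit$a - truth["a"]) / abs(truth["a"]), 1e-6)
  expect_lt(abs(fit$b - truth["b"]) / truth["b"], 1e-6)
  expect_lt(abs(fit$c - truth["c"]) / truth["c"], 1e-6)
  expect_lt(fit$rmse, 1e-6)
  expect_identical(fit$source, "fitted")

  # noisy recovery of the asymptote (quick check; the full-size study
  # lives in the acceptance suite)
  set.seed(1)
  d20 <- seq(0.25, 10, length.out = 20)
  errs <- replicate(20, {
    y <- truth["a"] * truth["b"]^d20 + truth["c"] + rnorm(20, 0, 1)
    abs(fit_saturation(data.frame(mean_depth = d20, breadth_pct = y))$c -
          truth["c"])
  })
  expect_lt(median(errs), 2)

  expect_error(fit_saturation(data.frame(mean_depth = d,
                                         breadth_pct = rep(100, 6))),
               "degenerate")
  expect_error(fit_saturation(data.frame(mean_depth = 1:3,
                                         breadth_pct = c(1, 2, 3))),
               "at least 5")
})

test_that("the smallest asymptote is selected with lexicographic tie-breaking", {
  mk <- function(c, id) threshold_model(-50, 0.4, c, genome_id = id)
  ms <- list(mk(92.1, "x"), mk(75.27, "y"), mk(88.0, "z"))
  expect_equal(select_min_asymptote(ms)$c, 75.27)
  expect_identical(select_min_asymptote(list(mk(80, "only")))$genome_id, "only")
  tied <- list(mk(80, "zeta"), mk(80, "alpha"))
  expect_identical(select_min_asymptote(tied)$genome_id, "alpha")
  expect_error(select_min_asymptote(list()), "non-empty")
})

test_that("the detection rule fires the documented branches", {
  m <- default_threshold_model()
  prof <- function(b, d) list(genome_id = "g", breadth_pct = b, mean_depth = d)

  call <- classify_detection(prof(51, 0.3), m)
  expect_true(call$detected)
  expect_identical(call$rule, "breadth_above_cutoff")

  call <- classify_detection(prof(40, 5), m)   # 40 < 73.77
  expect_false(call$detected)
  expect_identical(call$rule, "curve_fail")

  # below the cutoff but above the curve: threshold(2) = 42.51
  call <- classify_detection(prof(45, 2), m)
  expect_true(call$detected)
  expect_identical(call$rule, "curve_pass")

  call <- classify_detection(prof(5, 5), m)
  expect_false(call$detected)
  expect_identical(call$rule, "floor_fail")

  # "more than 50%" is strict
  expect_false(classify_detection(prof(50, 50), m)$detected)

  # alternative reading: minimum mean depth instead of breadth floor only
  call <- classify_detection(prof(40, 5), m, min_depth = 10)
  expect_identical(call$rule, "depth_floor_fail")

  # monotone in breadth at fixed depth
  det <- vapply(seq(0, 100, by = 0.5), function(b)
    classify_detection(prof(b, 3), m)$detected, logical(1))
  expect_true(all(diff(det) >= 0))
})

test_that("subsampling is nested, monotone and exact at fraction 1", {
  g <- generate_genome(50000, 0.5, genome_id = "g", seed = 31)
  ref <- build_reference(list(g))
  rs <- simulate_metagenome(
    community_design(c(g = 1), n_reads = 3000, read_length = 150, seed = 32),
    list(g))
  al <- map_reads(rs, ref)
  full <- compute_coverage(al, ref, total_reads = nrow(rs))
  ser <- subsample_series(al, ref, fractions = c(0.05, 0.2, 0.5, 1),
                          total_reads = nrow(rs), seed = 33)
  pts <- ser$g$points
  expect_equal(pts$mean_depth[4], full$g$mean_depth)
  expect_equal(pts$breadth_pct[4], full$g$breadth_pct)
  expect_true(all(diff(pts$mean_depth) > 0))
  expect_true(all(diff(pts$breadth_pct) >= 0))
  # determinism
  ser2 <- subsample_series(al, ref, fractions = c(0.05, 0.2, 0.5, 1),
                           total_reads = nrow(rs), seed = 33)
  expect_identical(ser, ser2)
  expect_error(subsample_series(al, ref, fractions = numeric()), "non-empty")
  expect_error(subsample_series(al, ref, fractions = c(0.5, 0.2)),
               "strictly increasing")
})

test_that("a deep mapping subsampled to depth ~1 matches the coverage law", {
  g <- generate_genome(50000, 0.5, genome_id = "g", seed = 34)
  ref <- build_reference(list(g))
  n <- round(10 * 50000 / 150)  # depth ~10
  rs <- simulate_metagenome(
    community_design(c(g = 1), n_reads = n, read_length = 150, seed = 35),
    list(g))
  al <- map_reads(rs, ref)
  ser <- subsample_series(al, ref, fractions = c(0.1, 1), total_reads = n,
                          seed = 36)
  expect_lt(abs(ser$g$points$breadth_pct[1] -
                  expected_breadth(ser$g$points$mean_depth[1])), 3)
})

test_that("detection reports cover every reference genome with stable columns", {
  spiked <- generate_genome(40000, 0.45, genome_id = "spiked", seed = 41)
  absent <- generate_genome(40000, 0.45, genome_id = "absent", seed = 42)
  ref <- build_reference(list(spiked, absent))
  rs <- simulate_metagenome(
    community_design(c(spiked = 1), n_reads = round(3 * 40000 / 150),
                     seed = 43),
    list(spiked, absent))
  al <- map_reads(rs, ref)
  rep <- detection_report(compute_coverage(al, ref, total_reads = nrow(rs)),
                          default_threshold_model(),
                          metagenome_id = "mg1")
  expect_identical(rep$genome_id, c("spiked", "absent"))
  expect_identical(names(rep),
                   c("metagenome_id", "genome_id", "unmasked_length",
                     "mapped_reads", "mapped_read_pct", "mean_depth",
                     "breadth_pct", "threshold_pct", "detected", "rule"))
  expect_true(rep$detected[rep$genome_id == "spiked"])
  expect_false(rep$detected[rep$genome_id == "absent"])

  # zero mapped reads: everything undetected at zero breadth
  rep0 <- detection_report(
    compute_coverage(aquadetect:::.empty_alignments(), ref, total_reads = 10),
    default_threshold_model())
  expect_true(all(!rep0$detected))
  expect_true(all(rep0$breadth_pct == 0))
})
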