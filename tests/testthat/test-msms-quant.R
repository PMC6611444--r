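test_that("precursor matching honors the retention cutoff and inclusive window", {
  target <- lithiated_mz(1556.7935, 2)  # ~785.4
  scans <- toy_scans(rt = c(15, 25, 30, 40, 50),
                     pmz = c(target, 785.6, target + 3.0, target + 3.01,
                             target - 2.9),
                     pint = rep(1000, 5))
  m <- match_precursors(scans, target, tol_da = 3, rt_min = 20)
  # rt 15 excluded despite exact m/z; 3.00 Da inside, 3.01 Da outside
  expect_equal(m$scan_id, c("s2", "s3", "s5"))

  # matching against any charge state, scan reported once per candidate
  targets <- lithiated_mz(1556.7935, 1:3)
  m2 <- match_precursors(scans, targets, tol_da = 3, rt_min = 20)
  expect_equal(nrow(m2), 3)
  expect_equal(anyDuplicated(m2$scan_id), 0)

  expect_equal(nrow(match_precursors(scans[0, ], target)), 0)
})

test_that("background intensity reproduces the binned 15th-percentile definition", {
  # degenerate distributions
  expect_equal(background_intensity(rep(250, 8)), 250)
  expect_equal(background_intensity(1234), 1234)

  # seeded exponential sample vs independent brute-force histogram oracle
  set.seed(7)
  x <- rexp(1000, rate = 1 / 5e4)
  expect_equal(background_intensity(x), brute_bg(x))
  set.seed(8)
  for (i in 1:10) {
    y <- rlnorm(sample(5:400, 1), meanlog = 8, sdlog = 1.2)
    expect_equal(background_intensity(y), brute_bg(y))
  }
  expect_error(background_intensity(numeric(0)), "no matched precursors")

  # unbinned variant is the plain empirical percentile
  expect_equal(background_intensity(x, binned = FALSE),
               unname(quantile(x, 0.15)))
})

test_that("scan filtering discards strictly below 1.5 x background", {
  scans <- toy_scans(rt = rep(30, 3), pmz = rep(500, 3),
                     pint = c(150, 149, 151))
  kept <- filter_scans(scans, bg_int = 100, factor = 1.5)
  expect_equal(kept$precursor_intensity, c(150, 151))  # 1.5x exactly retained

  set.seed(21)
  mixed <- toy_scans(rt = rep(30, 10), pmz = rep(500, 10),
                     pint = runif(10, 0, 400))
  expect_equal(filter_scans(mixed, 100)$scan_id,
               mixed$scan_id[mixed$precursor_intensity >= 150])
})

test_that("glycanTIC sums fragment intensities over retained scans", {
  expect_equal(glycan_tic(toy_scans(30, 500, 10)[0, ]), 0)
  one <- toy_scans(30, 500, 10, frags = list(c(100, 50, 25)))
  expect_equal(glycan_tic(one), 175)

  set.seed(5)
  frags <- replicate(12, runif(sample(1:8, 1), 0, 1000), simplify = FALSE)
  run <- toy_scans(rt = rep(30, 12), pmz = rep(500, 12), pint = rep(1, 12),
                   frags = frags)
  oracle <- 0
  for (f in frags) for (v in f) oracle <- oracle + v
  expect_equal(glycan_tic(run), oracle)

  # monotonicity: adding a fragment peak never decreases the TIC
  run2 <- run
  run2$fragments[[3]] <- dplyr::bind_rows(
    run2$fragments[[3]], tibble::tibble(mz = 900, intensity = 123))
  expect_gt(glycan_tic(run2), glycan_tic(run))
})

test_that("quantify_run computes background before filtering and is deterministic", {
  target <- 700
  scans <- toy_scans(rt = rep(30, 8), pmz = rep(target, 8),
                     pint = c(10, 10, 10, 1000, 1100, 1200, 1300, 1400),
                     frags = replicate(8, c(10, 20), simplify = FALSE))
  cands <- tibble::tibble(label = "G1", mz = list(target))
  rec <- quantify_run(scans, cands)
  # bg computed over ALL 8 matched scans (15th pct in the low cluster)
  expect_equal(rec$n_matched, 8L)
  expect_equal(rec$bg_int, brute_bg(scans$precursor_intensity))
  expect_equal(rec$n_retained, 5L)
  expect_equal(rec$glycan_tic, 5 * 30)
  expect_identical(rec, quantify_run(scans, cands))

  # unmatched candidate yields a zero record, not an error
  rec2 <- quantify_run(scans, tibble::tibble(label = "G2", mz = list(2000)))
  expect_equal(rec2$n_matched, 0L)
  expect_equal(rec2$glycan_tic, 0)
})

test_that("two-fold normalization follows the replicate and standard rules", {
  # toy time point: two runs, repSumTIC 100 and 50, standard TICs 40 and 20
  records <- tibble::tibble(
    label = rep(c("G1", "G2", "DP5"), 2),
    run_id = rep(c("r1", "r2"), each = 3),
    n_matched = 5L, max_pre_int = 1, bg_int = 0, n_retained = 5L,
    glycan_tic = c(60, 40, 40, 30, 20, 20))
  runs <- tibble::tibble(run_id = c("r1", "r2"),
                         sample_id = c("s1", "s2"), time_point = "T1")
  out <- normalize_quant(records, runs)
  r1 <- out[out$run_id == "r1" & out$label != "DP5", ]
  r2 <- out[out$run_id == "r2" & out$label != "DP5", ]
  expect_equal(unique(r1$rep_norm_factor), 1.0)  # max run in its time point
  expect_equal(unique(r2$rep_norm_factor), 0.5)
  # standard replaced by the time-point max (40) in both replicates
  expect_equal(unique(out$std_norm_tic), 40)
  # hand-computed final values: TIC * rnf / stdNormTIC
  expect_equal(r1$glycan_norm_tic_final[r1$label == "G1"], 60 * 1 / 40)
  expect_equal(r2$glycan_norm_tic_final[r2$label == "G2"], 20 * 0.5 / 40)

  # identical runs give identical final vectors
  dup <- records
  dup$glycan_tic <- rep(c(60, 40, 40), 2)
  out2 <- normalize_quant(dup, runs)
  expect_equal(out2$glycan_norm_tic_final[out2$run_id == "r1"],
               out2$glycan_norm_tic_final[out2$run_id == "r2"])

  # global intensity scaling leaves the final values unchanged
  scaled <- records
  scaled$glycan_tic <- scaled$glycan_tic * 37.5
  out3 <- normalize_quant(scaled, runs)
  expect_equal(out3$glycan_norm_tic_final, out$glycan_norm_tic_final)

  # standard missing from a time point is an error naming it
  no_std <- records[records$label != "DP5", ]
  expect_error(normalize_quant(no_std, runs), "DP5")
  zero_std <- records
  zero_std$glycan_tic[zero_std$label == "DP5"] <- 0
  expect_error(normalize_quant(zero_std, runs), "T1")

  # zero-signal run excluded with a warning
  with_zero <- records
  with_zero$glycan_tic[with_zero$run_id == "r2" &
                         with_zero$label != "DP5"] <- 0
  expect_warning(out4 <- normalize_quant(with_zero, runs), "r2")
  expect_false("r2" %in% out4$run_id)

  # per-replicate standard variant cancels the replicate factor
  out5 <- normalize_quant(records, runs, standard_per_replicate = TRUE)
  g1 <- out5[out5$label == "G1", ]
  expect_equal(g1$glycan_norm_tic_final, c(60 / 40, 30 / 20))
})

test_that("scan TSV round trip preserves scans", {
  scans <- toy_scans(rt = c(25, 30), pmz = c(500.1234, 600.5),
                     pint = c(1000, 2000),
                     frags = list(c(10.5, 20.25), c(5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scans(scans, path)
  back <- read_scans(path)
  expect_equal(back$precursor_mz, scans$precursor_mz, tolerance = 1e-8)
  expect_equal(nrow(back$fragments[[1]]), 2)
  expect_equal(back$fragments[[2]]$intensity, 5, tolerance = 1e-4)
})
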