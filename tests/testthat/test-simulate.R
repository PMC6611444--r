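test_that("Biosorter simulation is seeded, stage-faithful, and validated", {
  w <- c(L1 = 1)
  ev <- simulate_biosorter(w, 2000, seed = 5)
  # a single tight stage lands almost entirely inside its own region
  roi <- default_ws_rois()[1, ]
  inside <- ev$tof >= roi$tof_min & ev$tof <= roi$tof_max &
    ev$ext >= roi$ext_min & ev$ext <= roi$ext_max
  expect_gte(mean(inside), 0.99)

  # bit-identical on re-run with the same seed, different with another
  expect_identical(ev, simulate_biosorter(w, 2000, seed = 5))
  expect_false(identical(ev, simulate_biosorter(w, 2000, seed = 6)))

  expect_error(simulate_biosorter(w, 0), "positive")
  expect_error(simulate_biosorter(c(L1 = 0.4, adult = 0.4), 10), "sum to 1")
  expect_error(simulate_biosorter(c(dauer = 1), 10), "unknown stage")
})

test_that("MS run simulation feeds quantification faithfully", {
  cands <- default_study_candidates()
  # one nonzero glycan + the standard: exactly those two quantify > 0
  ab <- setNames(rep(0, 8), setdiff(cands$label, "DP5"))
  ab["NG_40"] <- 5
  ab <- c(ab, DP5 = 5)
  run <- simulate_msrun(cands, ab, run_id = "r1", seed = 11)
  rec <- quantify_run(run, cands)
  expect_gt(rec$glycan_tic[rec$label == "NG_40"], 0)
  expect_gt(rec$glycan_tic[rec$label == "DP5"], 0)
  others <- rec$label[!rec$label %in% c("NG_40", "DP5")]
  # absent glycans see only window background, well below the real signal
  expect_lt(max(rec$glycan_tic[rec$label %in% others]),
            0.01 * rec$glycan_tic[rec$label == "NG_40"])

  # all scans respect the retention window
  expect_true(all(run$rt_min > 20))

  # doubling all abundances and the standard leaves the final values unchanged
  runs <- tibble::tibble(run_id = c("rA", "rB"), sample_id = c("rA", "rB"),
                         time_point = "T1")
  two_runs <- function(mult) {
    dplyr::bind_rows(
      quantify_run(simulate_msrun(cands, mult * c(setNames(c(5, 2, 1, 3, 4, 2, 1, 3),
                                                           setdiff(cands$label, "DP5")),
                                                  DP5 = 5),
                                  run_id = "rA", seed = 21), cands),
      quantify_run(simulate_msrun(cands, mult * c(setNames(c(4, 3, 2, 2, 3, 1, 2, 4),
                                                           setdiff(cands$label, "DP5")),
                                                  DP5 = 5),
                                  run_id = "rB", seed = 22), cands))
  }
  # Exact at the records level (pure normalization algebra); through the
  # simulator the fixed-level background chemistry and the integer bin
  # count of the background estimator perturb the retained set slightly,
  # so the invariance holds to the background's share of the signal.
  n1 <- normalize_quant(two_runs(1), runs)
  n2 <- normalize_quant(two_runs(2), runs)
  ok <- !is.na(n1$glycan_norm_tic_final)
  expect_equal(n2$glycan_norm_tic_final[ok], n1$glycan_norm_tic_final[ok],
               tolerance = 2e-3)
})

test_that("replicate normalization factors follow constructed sum ratios", {
  # two noise-free runs whose repSumTICs are forced to a 2:1 ratio
  mk <- function(tic_scale, run_id) {
    tibble::tibble(label = c("G1", "G2", "DP5"), run_id = run_id,
                   n_matched = 1L, max_pre_int = 1, bg_int = 0,
                   n_retained = 1L,
                   glycan_tic = tic_scale * c(60, 40, 50))
  }
  runs <- tibble::tibble(run_id = c("a", "b"), sample_id = c("a", "b"),
                         time_point = "T1")
  out <- normalize_quant(dplyr::bind_rows(mk(1, "a"), mk(0.5, "b")), runs)
  expect_equal(unique(out$rep_norm_factor[out$run_id == "a"]), 1.0)
  expect_equal(unique(out$rep_norm_factor[out$run_id == "b"]), 0.5)
})

test_that("NMR simulation is linear in concentration and seeded", {
  peaks <- default_nmr_peaks()
  conc <- matrix(0, nrow = 6, ncol = nrow(peaks),
                 dimnames = list(paste0("s", 1:6), peaks$metabolite))
  conc[, "4.17"] <- c(1, 2, 4, 6, 8, 10)
  spec <- simulate_nmr(peaks, conc, noise_sd = 0, seed = 9)
  feats <- integrate_features(spec, default_nmr_rois())
  expect_gt(cor(feats[["4.17"]], conc[, "4.17"]), 0.999)

  # zero concentrations: only DSS and noise; metabolite regions are ~0
  zero <- simulate_nmr(peaks, 0 * conc, noise_sd = 0, seed = 9)
  fz <- integrate_features(zero, default_nmr_rois())
  expect_lt(max(abs(as.matrix(fz[, -1]))), 1e-4)

  expect_identical(simulate_nmr(peaks, conc, seed = 4)$intensities,
                   simulate_nmr(peaks, conc, seed = 4)$intensities)
  expect_error(simulate_nmr(peaks, conc - 5), "non-negative")
})

test_that("a full synthetic study is reproducible and correctly wired", {
  st <- make_study(n_replicates = 2, n_events = 100, seed = 17)
  st2 <- make_study(n_replicates = 2, n_events = 100, seed = 17)
  expect_identical(st$scans, st2$scans)
  expect_identical(st$events, st2$events)
  expect_identical(st$nmr$intensities, st2$nmr$intensities)

  expect_equal(nrow(st$samples), 10)
  expect_setequal(names(st$events), st$samples$sample_id)
  expect_setequal(unique(st$scans$run_id), st$samples$sample_id)
  expect_setequal(st$nmr$sample_ids, st$samples$sample_id)
  # mixture weights are a valid simplex per sample
  expect_equal(unname(rowSums(st$truth$weights)), rep(1, 10),
               tolerance = 1e-9)

  # stage -> analyte coupling dimension check
  bad <- default_coupling()[, 1:3]
  expect_error(make_study(coupling = bad), "stage count")
})

test_that("planted couplings survive the full pipeline in one seeded study", {
  st <- make_study(seed = 23)
  res <- analyze_study(st)
  net <- build_network(res$features, res$types, threshold = 0.5)
  pl <- st$truth$planted
  e <- net$edges
  for (i in seq_len(nrow(pl))) {
    hit <- e[(e$source == pl$a[i] & e$target == pl$b[i]) |
               (e$source == pl$b[i] & e$target == pl$a[i]), ]
    expect_equal(nrow(hit), 1)
    expect_equal(sign(hit$r), pl$sign[i])
  }

  # worm-size sums: the pure-L1 time point is dominated by WS1
  f <- res$features
  t1 <- f$sample_id %in% st$samples$sample_id[st$samples$time_point == "T1"]
  expect_gt(min(f$WS1[t1]), 0.5)
  expect_gt(mean(f$WS4[!t1]) , mean(f$WS4[t1]))

  # clustergram columns: the final time point's offspring make it resemble
  # the first, so they group before any other time point joins them
  prof <- profile_means(f[, !names(f) %in% c("WS1", "WS2", "WS3", "WS4")],
                        st$samples)
  cg <- clustergram(prof)
  coph <- as.matrix(stats::cophenetic(cg$col_hclust))
  expect_lte(coph["T1", "T5"], min(coph["T1", c("T2", "T3", "T4")]))
})
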