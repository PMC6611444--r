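# Seeded synthetic data with known ground truth: Biosorter event clouds from
# a mixture of developmental-stage distributions, targeted MS2 scan sets for
# candidate glycans plus an internal standard, and Lorentzian-peak NMR
# spectra, all tied together by a linear stage -> analyte coupling so that
# planted correlations can be recovered end to end.

#' Default developmental-stage models
#'
#' Bivariate (TOF, log10 EXT) Gaussian clouds for five stages from L1 to
#' adult. TOF tracks worm length, EXT optical density; the two are
#' positively correlated within a stage. `mass` is the relative mass per
#' worm implied by the cloud center (TOF x EXT), for reference.
#'
#' @return Tibble with columns `stage`, `tof_mean`, `tof_sd`, `lext_mean`,
#'   `lext_sd`, `rho`.
#' @export
default_stages <- function() {
  tibble(stage = c("L1", "L2", "L3", "L4", "adult"),
         tof_mean = c(60, 130, 230, 360, 560),
         tof_sd = c(10, 18, 28, 40, 60),
         lext_mean = c(0.8, 1.3, 1.7, 2.05, 2.45),
         lext_sd = c(0.12, 0.12, 0.12, 0.12, 0.12),
         rho = 0.6)
}

#' Default time-point stage mixtures
#'
#' Five collection time points drifting from a pure synchronized L1 culture
#' (T1) through larval stages to a bimodal adult-plus-offspring population
#' (T5), whose resemblance to T1 drives the characteristic clustergram
#' adjacency of the first and last time points.
#'
#' @return A 5 x 5 matrix (time points x stages) of mixture weights, rows
#'   summing to 1.
#' @export
default_timepoints <- function() {
  w <- rbind(
    T1 = c(L1 = 1.00, L2 = 0.00, L3 = 0.00, L4 = 0.00, adult = 0.00),
    T2 = c(L1 = 0.10, L2 = 0.75, L3 = 0.15, L4 = 0.00, adult = 0.00),
    T3 = c(L1 = 0.00, L2 = 0.10, L3 = 0.70, L4 = 0.20, adult = 0.00),
    T4 = c(L1 = 0.00, L2 = 0.00, L3 = 0.10, L4 = 0.55, adult = 0.35),
    T5 = c(L1 = 0.35, L2 = 0.10, L3 = 0.00, L4 = 0.10, adult = 0.45))
  w / rowSums(w)
}

#' Default worm-size regions for the default stage models
#'
#' Four non-overlapping TOF x EXT rectangles placed over the L1, L2, L3/L4,
#' and adult clouds of [default_stages()] — the scripted counterpart of
#' hand-selecting regions from overlaid Biosorter plots.
#'
#' @return ROI tibble (`label`, `tof_min`, `tof_max`, `ext_min`, `ext_max`).
#' @export
default_ws_rois <- function() {
  tibble(label = c("WS1", "WS2", "WS3", "WS4"),
         tof_min = c(25, 96, 176, 441),
         tof_max = c(95, 175, 440, 1000),
         ext_min = c(1, 1, 1, 1),
         ext_max = c(30, 80, 400, 1500))
}

#' Simulate a Biosorter sample from a stage mixture
#'
#' Draws each event's stage from the mixture weights, then (TOF, log10 EXT)
#' from the stage's correlated bivariate normal; EXT is exponentiated back
#' to instrument units.
#'
#' @param weights Named mixture weights over the rows of `stages`
#'   (non-negative, summing to 1).
#' @param n_events Number of events (> 0).
#' @param stages Stage model tibble, see [default_stages()].
#' @param seed Integer seed (the generator is a pure function of its
#'   arguments and this seed).
#' @return Event tibble with `tof`, `ext`, and the true `stage` per event.
#' @export
simulate_biosorter <- function(weights, n_events, stages = default_stages(),
                               seed = 1) {
  if (n_events <= 0) abort("n_events must be positive")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("mixture weights must be non-negative and sum to 1")
  }
  missing <- setdiff(names(weights), stages$stage)
  if (length(missing) > 0) {
    abort(paste0("unknown stage(s): ", paste(missing, collapse = ", ")))
  }
  with_seed(seed, {
    picks <- sample(names(weights), n_events, replace = TRUE, prob = weights)
    idx <- match(picks, stages$stage)
    z1 <- rnorm(n_events)
    z2 <- rnorm(n_events)
    rho <- stages$rho[idx]
    tof <- stages$tof_mean[idx] + stages$tof_sd[idx] * z1
    lext <- stages$lext_mean[idx] +
      stages$lext_sd[idx] * (rho * z1 + sqrt(1 - rho^2) * z2)
    tibble(tof = pmax(tof, 1), ext = 10^lext, stage = picks)
  })
}

#' Simulate a targeted MS2 run
#'
#' Emits, for every candidate with positive abundance, a fixed number of MS2
#' scans past the 20-minute mark with precursor m/z jittered around the
#' candidate's theoretical value (Gaussian, default sd 0.2 Da — far inside
#' the 3 Da matching window), precursor intensity proportional to abundance
#' with log-normal noise, and fragment peaks whose summed intensity is
#' proportional to the precursor intensity. Each candidate window also
#' receives a few near-isobaric low-intensity background scans (Top-10
#' acquisition fragments co-eluting junk within the matching window; this
#' background population is what the binned 15th-percentile estimator
#' measures), plus decoy scans at random non-candidate m/z. The internal
#' standard is a candidate like any other with its own configured m/z.
#'
#' @param candidates Tibble with `label` and `mz` list-column (candidate m/z
#'   values actually ionized).
#' @param abundances Named numeric vector of true abundances (>= 0) per
#'   candidate label.
#' @param run_id Run identifier.
#' @param n_scans Scans emitted per detectable candidate.
#' @param mz_sd Precursor m/z noise sd in Da.
#' @param intensity_scale Intensity units per abundance unit.
#' @param intensity_sdlog Log-normal noise sdlog on precursor intensities.
#' @param efficiency Per-run multiplicative injection/ionization efficiency
#'   applied to every intensity (the quantity the replicate normalization
#'   must contend with).
#' @param n_background Near-isobaric background scans per candidate window.
#' @param background_level Background intensity as a fraction of
#'   `intensity_scale`.
#' @param n_decoys Number of decoy scans at random m/z.
#' @param rt_range Retention-time range (minutes) of emitted scans.
#' @param seed Integer seed.
#' @return A scan tibble (see [read_scans()]).
#' @export
simulate_msrun <- function(candidates, abundances, run_id = "run1",
                           n_scans = 5, mz_sd = 0.2, intensity_scale = 1e5,
                           intensity_sdlog = 0.2, efficiency = 1,
                           n_background = 4, background_level = 0.002,
                           n_decoys = 15, rt_range = c(25, 140), seed = 1) {
  if (any(abundances < 0)) abort("abundances must be non-negative")
  with_seed(seed, {
    scans <- list()
    for (k in seq_len(nrow(candidates))) {
      lab <- candidates$label[k]
      ab <- if (lab %in% names(abundances)) abundances[[lab]] else 0
      if (is.na(ab) || ab <= 0) next
      mzs <- candidates$mz[[k]]
      for (b in seq_len(n_background)) {
        target <- if (length(mzs) == 1) mzs else sample(mzs, 1)
        bg_int <- background_level * intensity_scale * efficiency *
          rlnorm(1, 0, 0.5)
        scans[[length(scans) + 1]] <- tibble(
          run_id = run_id,
          scan_id = paste0(run_id, "_", lab, "_bg", b),
          rt_min = runif(1, rt_range[1], rt_range[2]),
          precursor_mz = target + runif(1, -2.5, 2.5),
          precursor_intensity = bg_int,
          fragments = list(tibble(mz = runif(4, 150, target),
                                  intensity = rep(bg_int / 8, 4))))
      }
      for (s in seq_len(n_scans)) {
        target <- if (length(mzs) == 1) mzs else sample(mzs, 1)
        pre_int <- ab * intensity_scale * efficiency * rlnorm(1, 0, intensity_sdlog)
        nfrag <- 6
        props <- runif(nfrag)
        frag_int <- 0.8 * pre_int * props / sum(props)
        scans[[length(scans) + 1]] <- tibble(
          run_id = run_id,
          scan_id = paste0(run_id, "_", lab, "_", s),
          rt_min = runif(1, rt_range[1], rt_range[2]),
          precursor_mz = target + rnorm(1, 0, mz_sd),
          precursor_intensity = pre_int,
          fragments = list(tibble(mz = runif(nfrag, 150, target),
                                  intensity = frag_int)))
      }
    }
    for (d in seq_len(n_decoys)) {
      pre_int <- 0.002 * intensity_scale * efficiency * rlnorm(1, 0, 0.5)
      scans[[length(scans) + 1]] <- tibble(
        run_id = run_id, scan_id = paste0(run_id, "_decoy_", d),
        rt_min = runif(1, rt_range[1], rt_range[2]),
        precursor_mz = runif(1, 400, 1500),
        precursor_intensity = pre_int,
        fragments = list(tibble(mz = runif(4, 150, 800),
                                intensity = rep(pre_int / 8, 4))))
    }
    dplyr::bind_rows(scans) |> dplyr::arrange(.data$rt_min)
  })
}

#' Simulate a 1D NMR spectral matrix
#'
#' Each metabolite contributes a Lorentzian line at its chemical shift with
#' area proportional to its concentration; a DSS reference singlet sits at
#' 0.0 ppm and Gaussian baseline noise is added. A per-sample dilution
#' factor (correctable by PQN) can be supplied.
#'
#' @param peaks Tibble with `metabolite` and `ppm` (one row per resonance;
#'   a metabolite may have several).
#' @param concentrations Matrix (samples x metabolites, dimnames required)
#'   of true concentrations (>= 0).
#' @param ppm_range Axis limits, default `c(9.5, -0.5)`.
#' @param n_points Axis resolution.
#' @param linewidth Full width at half maximum, ppm.
#' @param noise_sd Baseline noise sd (intensity units).
#' @param dilution Optional per-sample multiplicative factors.
#' @param seed Integer seed.
#' @return An `nmr_matrix`.
#' @export
simulate_nmr <- function(peaks, concentrations, ppm_range = c(9.5, -0.5),
                         n_points = 1500, linewidth = 0.01, noise_sd = 0.02,
                         dilution = NULL, seed = 1) {
  if (any(concentrations < 0)) abort("concentrations must be non-negative")
  ppm <- seq(max(ppm_range), min(ppm_range), length.out = n_points)
  samples <- rownames(concentrations)
  dilution <- dilution %||% rep(1, nrow(concentrations))
  g <- linewidth / 2
  with_seed(seed, {
    mat <- matrix(0, nrow = nrow(concentrations), ncol = n_points)
    for (s in seq_len(nrow(concentrations))) {
      spectrum <- rep(0, n_points)
      for (k in seq_len(nrow(peaks))) {
        conc <- concentrations[s, peaks$metabolite[k]]
        if (conc <= 0) next
        spectrum <- spectrum + conc * g^2 / ((ppm - peaks$ppm[k])^2 + g^2)
      }
      spectrum <- spectrum + 2 * g^2 / (ppm^2 + g^2)  # DSS at 0.0 ppm
      mat[s, ] <- dilution[s] * spectrum + rnorm(n_points, 0, noise_sd)
    }
    nmr_matrix(ppm, mat, sample_ids = samples)
  })
}

#' Default candidate set for the synthetic study
#'
#' Eight glycans from the packaged candidate table (four tied to small
#' worms, three to adults, one broadly abundant) plus the internal standard
#' DP5 at a user-supplied m/z. Simulated precursors ionize at z = 1 or 2.
#'
#' @param standard_mz m/z of the 13C-permethylated isomaltopentaose
#'   internal standard.
#' @return Tibble with `label` and `mz` list-column.
#' @export
default_study_candidates <- function(standard_mz = 1083.6) {
  all <- glycan_candidates(z = 1:2)
  keep <- all[all$label %in% c("NG_30", "NG_39", "NG_40", "NG_62",
                               "OG_1", "OG_10", "OG_15", "OG_17"), ]
  dplyr::bind_rows(
    tibble(label = keep$label,
           mz = purrr::map2(keep$mz_1, keep$mz_2, c)),
    tibble(label = "DP5", mz = list(standard_mz)))
}

#' Default stage -> analyte coupling
#'
#' Linear loadings tying each analyte's true abundance to the stage mixture:
#' small-worm glycans and phosphorylcholine load on L1, charged O-glycans
#' and UDP-GlcNAc on adults, with flat or broad profiles as negative
#' controls. The planted, guaranteed-positive associations are attached as
#' attribute `"planted"`.
#'
#' @return Matrix (analytes x stages) with a `planted` attribute
#'   (tibble `a`, `b`, `sign`).
#' @export
default_coupling <- function() {
  stages <- c("L1", "L2", "L3", "L4", "adult")
  rows <- rbind(
    NG_30 = c(10, 1, 0.5, 0.5, 0.5),
    NG_39 = c(8, 6, 5, 4, 4),
    NG_40 = c(12, 1, 0.5, 0.5, 0.5),
    NG_62 = c(0.3, 0.3, 0.5, 2, 6),
    OG_1 = c(0.5, 0.5, 1, 4, 10),
    OG_10 = c(6, 0.8, 0.5, 0.5, 0.5),
    OG_15 = c(5, 0.6, 0.5, 0.5, 0.5),
    OG_17 = c(0.3, 0.3, 0.8, 3, 8),
    `5.51` = c(0.5, 0.5, 1, 4, 10),   # UDP-GlcNAc
    `4.17` = c(10, 1, 0.8, 0.8, 0.8), # phosphorylcholine
    `3.26` = c(0.5, 0.5, 1, 3, 8),    # betaine
    `4.11` = c(1, 5, 6, 3, 1),        # lactate
    `2.89` = c(2, 2, 2, 2, 2),        # asparagine (flat control)
    `5.23` = c(3, 3, 3, 3, 3))        # glucose-6-phosphate (flat control)
  colnames(rows) <- stages
  planted <- tibble(
    a = c("NG_30", "NG_40", "OG_10", "OG_15", "NG_62", "OG_1", "OG_17",
          "4.17", "5.51", "3.26", "4.17", "5.51", "5.51"),
    b = c("WS1", "WS1", "WS1", "WS1", "WS4", "WS4", "WS4",
          "WS1", "WS4", "WS4", "NG_40", "OG_1", "OG_17"),
    sign = 1)
  attr(rows, "planted") <- planted
  rows
}

#' Default NMR peak table and feature regions for the synthetic study
#'
#' Chemical shifts of the simulated metabolites (UDP-GlcNAc 5.51,
#' glucose-6-phosphate 5.23, phosphorylcholine 4.17, lactate 4.11,
#' betaine 3.26, asparagine 2.89 ppm).
#'
#' @return Tibble with `metabolite` (ppm label) and `ppm`.
#' @export
default_nmr_peaks <- function() {
  tibble(metabolite = c("5.51", "5.23", "4.17", "4.11", "3.26", "2.89"),
         ppm = c(5.51, 5.23, 4.17, 4.11, 3.26, 2.89))
}

#' @rdname default_nmr_peaks
#' @param half_width Half-width of each integration region in ppm.
#' @return For `default_nmr_rois()`, an ROI tibble (`label`, `left_ppm`,
#'   `right_ppm`).
#' @export
default_nmr_rois <- function(half_width = 0.02) {
  peaks <- default_nmr_peaks()
  tibble(label = peaks$metabolite,
         left_ppm = peaks$ppm + half_width,
         right_ppm = peaks$ppm - half_width)
}

#' Generate a complete synthetic study
#'
#' Mirrors a five-time-point by seven-replicate developmental design: per
#' sample, a jittered stage mixture generates (1) a Biosorter event cloud,
#' (2) true analyte abundances through the linear stage coupling with
#' log-normal noise, realized as a targeted MS2 run (glycans plus a
#' constant-amount internal standard) and (3) a 1D NMR spectrum (metabolite
#' rows of the coupling) with a per-sample dilution factor. All three data
#' types share sample ids and run order.
#'
#' @param coupling Stage coupling matrix, see [default_coupling()];
#'   glycan rows are those whose names appear in `candidates$label`.
#' @param n_replicates Replicates per time point.
#' @param n_events Biosorter events per sample.
#' @param timepoints Time-point mixture matrix, see [default_timepoints()].
#' @param stages Stage models, see [default_stages()].
#' @param candidates MS candidate set, see [default_study_candidates()].
#' @param nmr_peaks NMR peak table, see [default_nmr_peaks()].
#' @param analyte_sdlog Log-normal noise on true analyte abundances.
#' @param mixture_sdlog Log-normal jitter on per-sample stage weights.
#' @param efficiency_sdlog Per-run MS efficiency noise.
#' @param baseline Abundance added to every analyte regardless of stage.
#' @param standard_amount True amount of the internal standard per run.
#' @param seed Integer seed; every sample's sub-seed derives from it.
#' @return A `glyco_study`: list with `samples` (tibble `sample_id`,
#'   `time_point`, `replicate`), `events` (named list of event tibbles),
#'   `scans` (one bound scan tibble, `run_id` = sample id), `nmr`
#'   (`nmr_matrix`), `candidates`, and `truth` (stage weights, analyte
#'   abundances, coupling, planted associations).
#' @export
make_study <- function(coupling = default_coupling(), n_replicates = 7,
                       n_events = 600, timepoints = default_timepoints(),
                       stages = default_stages(),
                       candidates = default_study_candidates(),
                       nmr_peaks = default_nmr_peaks(),
                       analyte_sdlog = 0.15, mixture_sdlog = 0.08,
                       efficiency_sdlog = 0.1, baseline = 0.5,
                       standard_amount = 5, seed = 1) {
  if (ncol(coupling) != ncol(timepoints)) {
    abort("coupling columns must match the stage count of `timepoints`")
  }
  if (!all(colnames(coupling) == colnames(timepoints))) {
    abort("coupling and timepoint stage names disagree")
  }
  samples <- tidyr::expand_grid(time_point = rownames(timepoints),
                                replicate = seq_len(n_replicates)) |>
    dplyr::mutate(sample_id = paste0(.data$time_point, "_r", .data$replicate))
  n <- nrow(samples)
  analytes <- rownames(coupling)
  glycan_ids <- intersect(analytes, candidates$label)
  metab_ids <- setdiff(analytes, glycan_ids)

  weights <- matrix(0, nrow = n, ncol = ncol(coupling),
                    dimnames = list(samples$sample_id, colnames(coupling)))
  truth <- matrix(0, nrow = n, ncol = length(analytes),
                  dimnames = list(samples$sample_id, analytes))
  events <- list()
  scan_list <- list()

  base_seed <- as.integer(seed %% 100000L)
  with_seed(base_seed, {
    sub_seeds <- sample.int(1e6, 3 * n)
    dilution <- rlnorm(n, 0, 0.15)
    efficiency <- rlnorm(n, 0, efficiency_sdlog)
  })

  for (i in seq_len(n)) {
    sid <- samples$sample_id[i]
    base_w <- timepoints[samples$time_point[i], ]
    w <- with_seed(sub_seeds[3 * i - 2], {
      jit <- base_w * rlnorm(length(base_w), 0, mixture_sdlog)
      jit / sum(jit)
    })
    weights[i, ] <- w
    a <- with_seed(sub_seeds[3 * i - 2] + 1L, {
      (drop(coupling %*% w) + baseline) *
        rlnorm(length(analytes), 0, analyte_sdlog)
    })
    truth[i, ] <- a
    events[[sid]] <- simulate_biosorter(w, n_events, stages = stages,
                                        seed = sub_seeds[3 * i - 1])
    ab <- c(a[glycan_ids], DP5 = standard_amount)
    scan_list[[sid]] <- simulate_msrun(candidates, ab, run_id = sid,
                                       efficiency = efficiency[i],
                                       seed = sub_seeds[3 * i])
  }

  conc <- truth[, metab_ids, drop = FALSE]
  nmr <- simulate_nmr(nmr_peaks, conc, dilution = dilution,
                      seed = base_seed + 7L)

  structure(list(samples = samples[, c("sample_id", "time_point", "replicate")],
                 events = events,
                 scans = dplyr::bind_rows(scan_list),
                 nmr = nmr, candidates = candidates,
                 truth = list(weights = weights, analytes = truth,
                              coupling = coupling,
                              planted = attr(coupling, "planted"))),
            class = "glyco_study")
}

#' @export
print.glyco_study <- function(x, ...) {
  cat("<glyco_study> ", nrow(x$samples), " samples (",
      length(unique(x$samples$time_point)), " time points), ",
      length(x$events), " Biosorter clouds, ", nrow(x$scans),
      " MS2 scans, ", length(x$nmr$sample_ids), " NMR spectra\n", sep = "")
  invisible(x)
}

# localized RNG: restores the caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
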