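# Targeted MS2 quantification: precursor matching, binned-percentile
# background estimation, scan filtering, fragment TIC summation, and the
# two-fold (replicate + internal standard) normalization.

#' Read MS2 scans from the package's delimited scan format
#'
#' The scan table is TSV with columns `run_id`, `scan_id`, `rt_min`,
#' `precursor_mz`, `precursor_intensity`, and `fragments` holding
#' semicolon-separated `mz:intensity` pairs. One row per MS2 scan.
#'
#' @param path Path to a scan TSV (several runs may share one file).
#' @return A scan tibble with a `fragments` list-column of
#'   `tibble(mz, intensity)`.
#' @seealso [write_scans()], [read_scans_mzml()]
#' @export
read_scans <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           run_id = readr::col_character(),
                           scan_id = readr::col_character(),
                           rt_min = readr::col_double(),
                           precursor_mz = readr::col_double(),
                           precursor_intensity = readr::col_double(),
                           fragments = readr::col_character()
                         ))
  raw$fragments <- purrr::map(raw$fragments, parse_fragment_string)
  dplyr::arrange(raw, .data$run_id, .data$rt_min)
}

parse_fragment_string <- function(s) {
  if (is.na(s) || s == "") return(tibble(mz = numeric(), intensity = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble(mz = as.numeric(purrr::map_chr(parts, 1)),
         intensity = as.numeric(purrr::map_chr(parts, 2)))
}

#' Write MS2 scans to the package scan format
#'
#' @param scans Scan tibble as produced by [read_scans()] or the simulator.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path) {
  out <- scans
  out$fragments <- purrr::map_chr(scans$fragments, function(f) {
    paste(sprintf("%.4f:%.4f", f$mz, f$intensity), collapse = ";")
  })
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read MS2 scans from an mzML file
#'
#' Thin adapter over Bioconductor's mzR returning the same scan tibble as
#' [read_scans()]. Only MS2 spectra with precursor metadata are kept.
#' Untested plumbing for convenience; the delimited scan format is the
#' primary input path.
#'
#' @param path Path to an mzML file.
#' @param run_id Run identifier to assign; defaults to the file name.
#' @return A scan tibble.
#' @export
read_scans_mzml <- function(path, run_id = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package")
  }
  run_id <- run_id %||% sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  handle <- mzR::openMSfile(path)
  on.exit(try(close(handle), silent = TRUE))
  hdr <- mzR::header(handle)
  ms2 <- which(hdr$msLevel == 2)
  frag <- purrr::map(ms2, function(i) {
    pk <- mzR::peaks(handle, i)
    tibble(mz = pk[, 1], intensity = pk[, 2])
  })
  tibble(run_id = run_id,
         scan_id = as.character(hdr$acquisitionNum[ms2]),
         rt_min = hdr$retentionTime[ms2] / 60,
         precursor_mz = hdr$precursorMZ[ms2],
         precursor_intensity = hdr$precursorIntensity[ms2],
         fragments = frag)
}

#' Match MS2 scans to a candidate's lithiated m/z values
#'
#' A scan matches when its retention time is past `rt_min` (column
#' equilibration and sample loading) and its precursor m/z lies within
#' `tol_da` (inclusive) of the candidate m/z for any of the considered charge
#' states. Each scan is returned at most once per candidate.
#'
#' @param scans Scan tibble (one run).
#' @param mz_targets Numeric vector of candidate m/z values (e.g. the
#'   lithiated m/z at z = 1, 2, 3).
#' @param tol_da m/z tolerance in Da (inclusive window), default 3.
#' @param rt_min Scans at or before this retention time (minutes) are
#'   excluded; default 20.
#' @return The matching subset of `scans`.
#' @export
match_precursors <- function(scans, mz_targets, tol_da = 3, rt_min = 20) {
  stopifnot(tol_da > 0, length(mz_targets) >= 1)
  if (nrow(scans) == 0) return(scans)
  hit <- purrr::map_lgl(scans$precursor_mz, function(pmz) {
    any(abs(pmz - mz_targets) <= tol_da)
  })
  scans[scans$rt_min > rt_min & hit, ]
}

#' Background precursor intensity (binned 15th percentile)
#'
#' Builds an equal-width histogram of the matched precursor intensities over
#' `[0, maxPreInt]` with `max(1, round(maxPreInt / numPrecursors))` bins and
#' returns the upper edge of the first bin at which the cumulative precursor
#' fraction reaches `quantile` (default 0.15). With
#' `binned = FALSE` a plain empirical percentile is returned instead, for
#' sensitivity analysis.
#'
#' @param intensities Non-empty numeric vector of matched precursor
#'   intensities.
#' @param quantile Cumulative fraction defining the background, default 0.15.
#' @param binned Use the binned-histogram definition (default) or a plain
#'   percentile.
#' @return Background intensity (scalar).
#' @export
background_intensity <- function(intensities, quantile = 0.15, binned = TRUE) {
  if (length(intensities) == 0) abort("no matched precursors")
  if (!binned) return(stats::quantile(intensities, quantile, names = FALSE))
  max_pre <- max(intensities)
  if (max_pre <= 0) return(0)
  nbins <- max(1, round(max_pre / length(intensities)))
  width <- max_pre / nbins
  idx <- pmin(nbins, floor(intensities / width) + 1)  # [k*w, (k+1)*w), top closed
  counts <- tabulate(idx, nbins = nbins)
  cum <- cumsum(counts) / length(intensities)
  first <- which(cum >= quantile)[1]
  first * width
}

#' Filter scans against the background
#'
#' The discard rule is strict: scans with precursor intensity `<
#' factor * bg_int` are dropped, so a scan at exactly `factor * bg_int` is
#' retained.
#'
#' @param scans Scan tibble.
#' @param bg_int Background intensity from [background_intensity()].
#' @param factor Multiple of the background required to retain a scan,
#'   default 1.5.
#' @return The retained subset of `scans`.
#' @export
filter_scans <- function(scans, bg_int, factor = 1.5) {
  stopifnot(bg_int >= 0)
  scans[scans$precursor_intensity >= factor * bg_int, ]
}

#' Summed fragment intensity (glycanTIC)
#'
#' @param scans Retained scan tibble.
#' @return Sum over scans of the summed fragment-peak intensities; 0 for an
#'   empty input.
#' @export
glycan_tic <- function(scans) {
  if (nrow(scans) == 0) return(0)
  sum(purrr::map_dbl(scans$fragments, function(f) sum(f$intensity)))
}

#' Quantify candidate glycans in one MS run
#'
#' For each candidate: match precursors (within `tol_da` of any charge
#' state's m/z, past the `rt_min` mark), estimate the background from all
#' matched precursors, discard scans below `factor * bgInt`, and sum fragment
#' intensities into glycanTIC. Background estimation always precedes
#' filtering and never feeds back into it. Isomer abundances of one
#' composition are summed as a single species by construction (matching is by
#' composition m/z only).
#'
#' @param scans Scan tibble for a single run.
#' @param candidates Tibble with `label` and either `mz` (list-column of m/z
#'   values per candidate) or `mz_1`/`mz_2`/... columns, e.g. from
#'   [glycan_candidates()].
#' @param tol_da,rt_min,factor See [match_precursors()] and [filter_scans()].
#' @param quantile Background percentile, see [background_intensity()].
#' @return A tibble with one row per candidate: `label`, `run_id`,
#'   `n_matched`, `max_pre_int`, `bg_int`, `n_retained`, `glycan_tic`.
#' @export
quantify_run <- function(scans, candidates, tol_da = 3, rt_min = 20,
                         factor = 1.5, quantile = 0.15) {
  run_id <- if (nrow(scans) > 0) scans$run_id[1] else NA_character_
  targets <- candidate_mz_list(candidates)
  purrr::map2(candidates$label, targets, function(lab, mzs) {
    matched <- match_precursors(scans, mzs, tol_da = tol_da, rt_min = rt_min)
    if (nrow(matched) == 0) {
      return(tibble(label = lab, run_id = run_id, n_matched = 0L,
                    max_pre_int = NA_real_, bg_int = NA_real_,
                    n_retained = 0L, glycan_tic = 0))
    }
    bg <- background_intensity(matched$precursor_intensity, quantile = quantile)
    kept <- filter_scans(matched, bg, factor = factor)
    tibble(label = lab, run_id = run_id, n_matched = nrow(matched),
           max_pre_int = max(matched$precursor_intensity), bg_int = bg,
           n_retained = nrow(kept), glycan_tic = glycan_tic(kept))
  }) |> dplyr::bind_rows()
}

candidate_mz_list <- function(candidates) {
  if ("mz" %in% names(candidates)) return(candidates$mz)
  mz_cols <- grep("^mz_[0-9]+$", names(candidates), value = TRUE)
  if (length(mz_cols) == 0) {
    abort("candidates need an `mz` list-column or mz_<z> columns")
  }
  purrr::map(seq_len(nrow(candidates)),
             function(i) as.numeric(candidates[i, mz_cols]))
}

#' Two-fold normalization of glycan quantification records
#'
#' First normalization: per run, `repSumTIC` is the summed glycanTIC over all
#' experimental glycans (the internal standard excluded); within each time
#' point the run with the maximal `repSumTIC` defines `maxRepSumTIC`, and each
#' run is scaled by `repNormFactor = repSumTIC / maxRepSumTIC` (so the largest
#' run has factor 1). Second normalization: the internal standard's intensity
#' in every replicate is replaced by the maximum standard glycanTIC over the
#' replicates of that time point (`stdNormTIC`; an equal amount of standard is
#' spiked into every replicate), and each experimental glycan's normalized TIC
#' is divided by it.
#'
#' @param records Quantification records from [quantify_run()], all runs
#'   bound together.
#' @param runs Tibble mapping `run_id` to `sample_id` and `time_point`.
#' @param standard_id `label` of the internal standard (e.g. `"DP5"`).
#' @param standard_per_replicate If `TRUE`, divide by each replicate's own
#'   repNormFactor-scaled standard instead of the time-point maximum (this
#'   variant cancels the first normalization algebraically; off by default).
#' @return `records` joined with `sample_id`, `time_point`, `rep_sum_tic`,
#'   `rep_norm_factor`, `std_norm_tic`, `glycan_norm_tic`, and
#'   `glycan_norm_tic_final`. Standard rows are retained but carry `NA`
#'   final values.
#' @export
normalize_quant <- function(records, runs, standard_id = "DP5",
                            standard_per_replicate = FALSE) {
  rec <- dplyr::left_join(records, runs, by = "run_id")
  if (anyNA(rec$time_point)) abort("every run_id needs a time_point in `runs`")
  std <- rec[rec$label == standard_id, ]
  if (nrow(std) == 0) abort(paste0("standard '", standard_id, "' absent from records"))
  missing_tp <- setdiff(unique(rec$time_point), unique(std$time_point[std$glycan_tic > 0]))
  if (length(missing_tp) > 0) {
    abort(paste0("internal standard '", standard_id,
                 "' has no positive glycanTIC in time point(s): ",
                 paste(missing_tp, collapse = ", ")))
  }

  exp_rec <- rec[rec$label != standard_id, ]
  sums <- exp_rec |>
    dplyr::group_by(.data$run_id, .data$time_point) |>
    dplyr::summarise(rep_sum_tic = sum(.data$glycan_tic), .groups = "drop")
  zero_runs <- sums$run_id[sums$rep_sum_tic <= 0]
  if (length(zero_runs) > 0) {
    warn(paste0("excluding run(s) with zero repSumTIC: ",
                paste(zero_runs, collapse = ", ")))
    sums <- sums[!sums$run_id %in% zero_runs, ]
    rec <- rec[!rec$run_id %in% zero_runs, ]
  }
  sums <- sums |>
    dplyr::group_by(.data$time_point) |>
    dplyr::mutate(rep_norm_factor = .data$rep_sum_tic / max(.data$rep_sum_tic)) |>
    dplyr::ungroup()

  std_tp <- rec[rec$label == standard_id, ] |>
    dplyr::group_by(.data$time_point) |>
    dplyr::summarise(std_norm_tic = max(.data$glycan_tic), .groups = "drop")

  out <- rec |>
    dplyr::left_join(sums[, c("run_id", "rep_sum_tic", "rep_norm_factor")],
                     by = "run_id") |>
    dplyr::left_join(std_tp, by = "time_point")

  if (standard_per_replicate) {
    std_run <- rec[rec$label == standard_id, c("run_id", "glycan_tic")]
    names(std_run)[2] <- "std_run_tic"
    out <- dplyr::left_join(out, std_run, by = "run_id")
    out$std_norm_tic <- out$std_run_tic * out$rep_norm_factor
    out$std_run_tic <- NULL
  }

  out$glycan_norm_tic <- ifelse(out$label == standard_id, NA_real_,
                                out$glycan_tic * out$rep_norm_factor)
  out$glycan_norm_tic_final <- out$glycan_norm_tic / out$std_norm_tic
  out
}

#' Wide feature table of final normalized glycan intensities
#'
#' @param normalized Output of [normalize_quant()].
#' @param standard_id Standard label to drop.
#' @return A tibble with one row per sample (`sample_id` first) and one
#'   column per glycan label holding `glycan_norm_tic_final`.
#' @export
quant_feature_table <- function(normalized, standard_id = "DP5") {
  normalized[normalized$label != standard_id,
             c("sample_id", "label", "glycan_norm_tic_final")] |>
    tidyr::pivot_wider(names_from = "label",
                       values_from = "glycan_norm_tic_final")
}
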