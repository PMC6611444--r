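# 1D NMR spectral-matrix preparation (referencing, masking, PQN, a simple
# segment-shift aligner) and declarative region-of-interest integration into
# named features. The interactive point-and-click binner of the original
# MATLAB workflow is replaced by ROI files so the analysis is scriptable.

#' Construct an NMR spectral matrix
#'
#' @param ppm Strictly monotonic chemical-shift axis; stored descending
#'   (conventional NMR display order).
#' @param intensities Numeric matrix, one row per sample, `length(ppm)`
#'   columns.
#' @param sample_ids Character vector of row identifiers.
#' @return An `nmr_matrix` object.
#' @export
nmr_matrix <- function(ppm, intensities, sample_ids = NULL) {
  if (is.vector(intensities)) intensities <- matrix(intensities, nrow = 1)
  if (length(ppm) != ncol(intensities)) {
    abort("matrix width must equal ppm length")
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) abort("ppm axis must be strictly monotonic")
  if (all(d > 0)) {  # store descending
    ppm <- rev(ppm)
    intensities <- intensities[, ncol(intensities):1, drop = FALSE]
  }
  sample_ids <- sample_ids %||% rownames(intensities) %||%
    paste0("S", seq_len(nrow(intensities)))
  rownames(intensities) <- sample_ids
  structure(list(ppm = as.numeric(ppm), intensities = intensities,
                 sample_ids = sample_ids),
            class = "nmr_matrix")
}

#' @export
print.nmr_matrix <- function(x, ...) {
  cat("<nmr_matrix> ", length(x$sample_ids), " samples x ", length(x$ppm),
      " points, ", round(max(x$ppm), 2), " to ", round(min(x$ppm), 2),
      " ppm\n", sep = "")
  invisible(x)
}

#' Read an NMR spectral matrix from delimited text
#'
#' Expects the first column to hold sample identifiers and the header row the
#' ppm axis values.
#'
#' @param path TSV/CSV file.
#' @param delim Field delimiter.
#' @return An `nmr_matrix`.
#' @export
read_nmr_matrix <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1])
  ppm <- as.numeric(names(raw)[-1])
  nmr_matrix(ppm, mat, sample_ids = ids)
}

#' Reference spectra to the DSS resonance at 0.0 ppm
#'
#' Per sample, locates the maximum within a search window around 0 ppm and
#' shifts the spectrum by a whole number of points so that maximum lands on
#' the axis point closest to 0.0 ppm (edge points are filled with the edge
#' value). Errors if no peak in the window rises above the noise floor.
#'
#' @param spec An `nmr_matrix`.
#' @param window Two-element ppm window to search, default `c(-0.2, 0.2)`.
#' @param min_snr Required ratio of the window maximum to the spectrum's
#'   median absolute intensity, default 5.
#' @return A referenced `nmr_matrix`.
#' @export
reference_to_dss <- function(spec, window = c(-0.2, 0.2), min_snr = 5) {
  stopifnot(inherits(spec, "nmr_matrix"))
  in_win <- which(spec$ppm >= min(window) & spec$ppm <= max(window))
  if (length(in_win) == 0) abort("search window outside ppm axis")
  target <- in_win[which.min(abs(spec$ppm[in_win]))]
  out <- spec
  for (s in seq_len(nrow(spec$intensities))) {
    row <- spec$intensities[s, ]
    floor_level <- median(abs(row))
    peak_at <- in_win[which.max(row[in_win])]
    if (row[peak_at] < min_snr * floor_level) {
      abort(paste0("no reference peak above noise floor in sample '",
                   spec$sample_ids[s], "'"))
    }
    out$intensities[s, ] <- shift_vector(row, target - peak_at)
  }
  out
}

# integer-point shift with edge-value fill; positive k moves content right
shift_vector <- function(v, k) {
  n <- length(v)
  if (k == 0) return(v)
  if (abs(k) >= n) abort("shift exceeds vector length")
  if (k > 0) c(rep(v[1], k), v[seq_len(n - k)])
  else c(v[(1 - k):n], rep(v[n], -k))
}

#' Remove solvent regions from a spectral matrix
#'
#' Drops the points inside each ppm interval (water, methanol, ...) from both
#' the axis and the intensity matrix. Regions that do not intersect the axis
#' produce a warning and are skipped.
#'
#' @param spec An `nmr_matrix`.
#' @param regions List of two-element ppm intervals, e.g.
#'   `list(c(4.7, 4.9), c(3.33, 3.37))`.
#' @return An `nmr_matrix` with fewer points.
#' @export
mask_regions <- function(spec, regions) {
  stopifnot(inherits(spec, "nmr_matrix"))
  if (length(regions) == 0) return(spec)
  drop <- rep(FALSE, length(spec$ppm))
  for (r in regions) {
    inside <- spec$ppm >= min(r) & spec$ppm <= max(r)
    if (!any(inside)) {
      warn(paste0("mask region [", min(r), ", ", max(r),
                  "] ppm is outside the axis; skipped"))
      next
    }
    drop <- drop | inside
  }
  if (all(drop)) abort("masking removed every point (empty spectrum)")
  nmr_matrix(spec$ppm[!drop], spec$intensities[, !drop, drop = FALSE],
             sample_ids = spec$sample_ids)
}

#' Probabilistic quotient normalization
#'
#' Divides each spectrum by the median of its point-wise quotients to a
#' reference spectrum (the point-wise median spectrum across samples by
#' default), correcting overall dilution differences between samples.
#'
#' @param spec An `nmr_matrix` with at least two samples (unless an explicit
#'   `reference` is supplied).
#' @param reference Optional reference spectrum (numeric vector matching the
#'   axis); default is the median spectrum.
#' @return An `nmr_matrix`; the per-sample dilution quotients are attached as
#'   attribute `"quotients"` (named numeric).
#' @export
pqn_normalize <- function(spec, reference = NULL) {
  stopifnot(inherits(spec, "nmr_matrix"))
  if (is.null(reference) && nrow(spec$intensities) < 2) {
    abort("PQN needs at least 2 samples (or an explicit reference)")
  }
  reference <- reference %||% apply(spec$intensities, 2, median)
  support <- reference > 0
  if (!any(support)) abort("reference spectrum has no positive support")
  quot <- purrr::map_dbl(seq_len(nrow(spec$intensities)), function(s) {
    row <- spec$intensities[s, ]
    if (all(row == 0)) {
      abort(paste0("sample '", spec$sample_ids[s], "' is all zero"))
    }
    median(row[support] / reference[support])
  })
  out <- spec
  out$intensities <- spec$intensities / quot
  attr(out, "quotients") <- setNames(quot, spec$sample_ids)
  out
}

#' Simple cross-correlation segment alignment
#'
#' A deliberately simple stand-in for full spectral alignment: the axis is
#' partitioned at the given ppm boundaries, and each segment of each sample
#' is shifted by a whole number of points (at most `max_shift`) to maximize
#' its cross-correlation with the corresponding segment of a reference
#' (median) spectrum. Ties are broken toward zero shift; vacated points are
#' filled with the segment's edge value.
#'
#' @param spec An `nmr_matrix`.
#' @param boundaries ppm values cutting the axis into segments (the default
#'   mimics a three-region scheme at 3.3566 and 4.7651 ppm).
#' @param max_shift Maximum shift in points.
#' @param reference Optional reference spectrum; default median spectrum.
#' @return An aligned `nmr_matrix`; per-sample, per-segment shifts attached
#'   as attribute `"shifts"` (samples x segments matrix).
#' @export
segment_align <- function(spec, boundaries = c(3.3566, 4.7651),
                          max_shift = 10, reference = NULL) {
  stopifnot(inherits(spec, "nmr_matrix"), max_shift >= 0)
  reference <- reference %||% apply(spec$intensities, 2, median)
  cuts <- sort(unique(c(-Inf, boundaries, Inf)))
  seg_id <- cut(spec$ppm, breaks = cuts, labels = FALSE)
  segments <- split(seq_along(spec$ppm), seg_id)
  shifts <- matrix(0L, nrow = nrow(spec$intensities), ncol = length(segments))
  out <- spec
  for (g in seq_along(segments)) {
    idx <- segments[[g]]
    if (max_shift >= length(idx)) {
      abort("max_shift must be smaller than the segment length")
    }
    ref_seg <- reference[idx]
    for (s in seq_len(nrow(spec$intensities))) {
      seg <- spec$intensities[s, idx]
      best <- best_segment_shift(seg, ref_seg, max_shift)
      shifts[s, g] <- best
      out$intensities[s, idx] <- shift_vector(seg, best)
    }
  }
  attr(out, "shifts") <- shifts
  out
}

best_segment_shift <- function(seg, ref_seg, max_shift) {
  if (max_shift == 0) return(0L)
  cand <- seq(-max_shift, max_shift)
  cand <- cand[order(abs(cand), cand)]  # tie-break toward 0
  scores <- purrr::map_dbl(cand, function(k) {
    sum(shift_vector(seg, k) * ref_seg)
  })
  cand[which.max(scores)]
}

#' Integrate spectral regions of interest into named features
#'
#' Each feature is the per-sample sum of intensities between its left and
#' right ppm boundaries (`left >= ppm >= right`; boundaries of different
#' features may overlap). Unlabeled features are auto-named with the ppm of
#' the across-sample mean-spectrum maximum inside the region, printed to two
#' decimals; on a name collision the closest unused two-decimal ppm value is
#' taken.
#'
#' @param spec An `nmr_matrix`.
#' @param rois Tibble with `left_ppm`, `right_ppm`, and optional `label`
#'   (NA labels are auto-named).
#' @return A feature tibble, one row per sample (`sample_id` first, then one
#'   column per feature).
#' @export
integrate_features <- function(spec, rois) {
  stopifnot(inherits(spec, "nmr_matrix"))
  mean_spec <- colMeans(spec$intensities)
  used <- character()
  values <- list()
  for (k in seq_len(nrow(rois))) {
    r <- rois[k, ]
    lo <- max(r$left_ppm, r$right_ppm)
    hi <- min(r$left_ppm, r$right_ppm)
    idx <- which(spec$ppm <= lo & spec$ppm >= hi)
    if (length(idx) == 0) {
      abort(paste0("region ", lo, " to ", hi, " ppm contains no points"))
    }
    label <- if (!is.null(r$label) && !is.na(r$label)) as.character(r$label) else {
      peak_ppm <- spec$ppm[idx[which.max(mean_spec[idx])]]
      unused_ppm_name(peak_ppm, used)
    }
    if (label %in% names(values)) label <- unused_ppm_name(as.numeric(label), used)
    used <- c(used, label)
    values[[label]] <- unname(rowSums(spec$intensities[, idx, drop = FALSE]))
  }
  dplyr::bind_cols(tibble(sample_id = spec$sample_ids), as_tibble(values))
}

# nearest unused two-decimal ppm value to `target`
unused_ppm_name <- function(target, used) {
  base <- round(target, 2)
  cand <- base + seq(-1000, 1000) * 0.01
  cand <- cand[order(abs(cand - target))]
  for (value in cand) {
    nm <- sprintf("%.2f", value)
    if (!nm %in% used) return(nm)
  }
  abort("could not find an unused feature name")  # nocov
}

#' @export
tidy.nmr_matrix <- function(x, ...) {
  tidyr::expand_grid(sample_id = x$sample_ids, ppm = x$ppm) |>
    dplyr::mutate(intensity = as.vector(t(x$intensities)))
}

#' @export
autoplot.nmr_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$ppm, y = .data$intensity,
                               group = .data$sample_id,
                               colour = .data$sample_id)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}
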