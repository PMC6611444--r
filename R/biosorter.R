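# Biosorter (large-particle flow cytometry) event handling: 2D binning of
# time-of-flight x extinction event clouds, worm-mass normalization,
# row-major linearization, and worm-size region sums.

#' Read a Biosorter event table
#'
#' One event (worm) per row. Extra columns (fluorescence channels and so on)
#' are ignored; TOF and EXT column names are configurable to accommodate
#' instrument export variants.
#'
#' @param path Delimited text file (TSV by default).
#' @param tof_col,ext_col Column names for time of flight and extinction.
#' @param delim Field delimiter.
#' @return A tibble with numeric `tof` and `ext` columns.
#' @export
read_biosorter <- function(path, tof_col = "TOF", ext_col = "EXT",
                           delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    warn("Biosorter file has no events")
    return(tibble(tof = numeric(), ext = numeric()))
  }
  for (col in c(tof_col, ext_col)) {
    if (!col %in% names(raw)) abort(paste0("missing column '", col, "'"))
  }
  as_events(tibble(tof = raw[[tof_col]], ext = raw[[ext_col]]))
}

as_events <- function(events) {
  for (col in c("tof", "ext")) {
    val <- suppressWarnings(as.numeric(events[[col]]))
    bad <- which(is.na(val) & !is.na(events[[col]]))
    if (length(bad) > 0) {
      abort(paste0("non-numeric ", toupper(col), " value at row ", bad[1]))
    }
    events[[col]] <- val
  }
  events
}

#' Bin Biosorter events into a 2D count map
#'
#' Events are counted on raw TOF and raw EXT axes with half-open bins
#' `[k*bin_size, (k+1)*bin_size)`; events with either coordinate beyond
#' `bound` (exclusive test on values > bound; the bound itself is kept) are
#' excluded as clump/multi-worm artifacts. `log10(EXT)` is a display
#' transform only and plays no role in binning.
#'
#' @param events Event tibble with `tof` and `ext` columns.
#' @param bin_size Bin width in instrument units for both axes, default 1.
#' @param bound Upper bound in instrument units (inclusive), default 1600.
#' @param exclude `"either"` (default: drop an event if either axis exceeds
#'   the bound) or `"both"` (drop only if both do; a surviving event whose
#'   single overrunning coordinate lies past the bound is clamped into the
#'   edge bin).
#' @return A `binned_map` object: a TOF-by-EXT matrix of counts with
#'   binning metadata.
#' @export
bin_events <- function(events, bin_size = 1, bound = 1600,
                       exclude = c("either", "both")) {
  exclude <- match.arg(exclude)
  stopifnot(bin_size > 0, bound > 0)
  events <- as_events(events)
  over_tof <- events$tof > bound
  over_ext <- events$ext > bound
  drop <- if (exclude == "either") over_tof | over_ext else over_tof & over_ext
  keep <- events[!drop & events$tof > 0 & events$ext > 0, ]
  nbins <- ceiling(bound / bin_size)
  grid <- matrix(0, nrow = nbins, ncol = nbins)
  if (nrow(keep) > 0) {
    i <- pmin(nbins, floor(keep$tof / bin_size) + 1)
    j <- pmin(nbins, floor(keep$ext / bin_size) + 1)
    tab <- table(factor(i, levels = seq_len(nbins)),
                 factor(j, levels = seq_len(nbins)))
    grid <- matrix(as.numeric(tab), nrow = nbins)
  }
  new_binned_map(grid, bin_size = bin_size, bound = bound, normalized = FALSE)
}

new_binned_map <- function(grid, bin_size, bound, normalized) {
  structure(list(grid = grid, bin_size = bin_size, bound = bound,
                 normalized = normalized),
            class = "binned_map")
}

#' @export
print.binned_map <- function(x, ...) {
  cat("<binned_map> ", nrow(x$grid), " x ", ncol(x$grid),
      " bins of ", x$bin_size, " unit(s), ",
      if (x$normalized) "mass-normalized" else
        paste0(sum(x$grid), " events"), "\n", sep = "")
  invisible(x)
}

#' Bin centers of a binned map
#'
#' @param map A `binned_map`.
#' @return List with numeric vectors `tof` and `ext` of bin-center
#'   coordinates.
#' @export
bin_centers <- function(map) {
  ctr <- (seq_len(nrow(map$grid)) - 0.5) * map$bin_size
  list(tof = ctr, ext = (seq_len(ncol(map$grid)) - 0.5) * map$bin_size)
}

#' Worm-mass normalization of a binned count map
#'
#' Each bin's count is weighted by the product of its TOF and EXT bin centers
#' (TOF is proportional to worm length and EXT to optical thickness, so their
#' product is taken as proportional to worm mass), then the whole map is
#' divided by the total estimated mass so it sums to 1. This corrects both
#' for the much larger per-worm mass of adults and for differences in total
#' worm numbers between replicates.
#'
#' @param map A raw count `binned_map` from [bin_events()].
#' @return A normalized `binned_map` summing to 1.
#' @export
mass_normalize <- function(map) {
  stopifnot(inherits(map, "binned_map"))
  if (map$normalized) abort("map is already normalized")
  if (sum(map$grid) == 0) abort("no in-bound events")
  ctr <- bin_centers(map)
  weighted <- map$grid * outer(ctr$tof, ctr$ext)
  new_binned_map(weighted / sum(weighted), bin_size = map$bin_size,
                 bound = map$bound, normalized = TRUE)
}

#' Linearize a binned map to a vector (and back)
#'
#' Rows (TOF bins) of the 2D matrix are extracted and concatenated into a
#' single vector (row-major order), the form in which Biosorter maps are
#' fused with analytical feature vectors. `delinearize()` inverts the
#' operation exactly.
#'
#' @param map A `binned_map` (or plain matrix).
#' @return For `linearize()`, a numeric vector with a `dim` attribute-free
#'   layout of length `m * n`; names encode the bin indices as
#'   `bin_<tof>_<ext>`.
#' @export
linearize <- function(map) {
  grid <- if (inherits(map, "binned_map")) map$grid else map
  v <- as.vector(t(grid))
  names(v) <- paste0("bin_", rep(seq_len(nrow(grid)), each = ncol(grid)), "_",
                     rep(seq_len(ncol(grid)), times = nrow(grid)))
  v
}

#' @rdname linearize
#' @param v Numeric vector from [linearize()].
#' @param shape Integer vector `c(m, n)` (TOF bins, EXT bins).
#' @return For `delinearize()`, an `m x n` matrix.
#' @export
delinearize <- function(v, shape) {
  if (length(v) != prod(shape)) {
    abort(paste0("vector length ", length(v), " does not match shape ",
                 shape[1], " x ", shape[2]))
  }
  matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

#' Worm-size region sums on a normalized Biosorter map
#'
#' Sums the normalized worm weights in hand-selected, non-overlapping
#' rectangles of the TOF x EXT plane (worm-size regions WS1-WS4). A bin
#' contributes to a region when its bin center falls inside the rectangle
#' (`tof_min <= center <= tof_max`, likewise for EXT).
#'
#' @param map A normalized `binned_map`.
#' @param rois Tibble with columns `label`, `tof_min`, `tof_max`, `ext_min`,
#'   `ext_max`; rectangles must not overlap.
#' @return A tibble with `label` and `total`.
#' @export
roi_sum <- function(map, rois) {
  stopifnot(inherits(map, "binned_map"))
  check_roi_overlap(rois)
  ctr <- bin_centers(map)
  totals <- purrr::map_dbl(seq_len(nrow(rois)), function(k) {
    r <- rois[k, ]
    ti <- ctr$tof >= r$tof_min & ctr$tof <= r$tof_max
    ei <- ctr$ext >= r$ext_min & ctr$ext <= r$ext_max
    sum(map$grid[ti, ei])
  })
  tibble(label = rois$label, total = totals)
}

check_roi_overlap <- function(rois) {
  n <- nrow(rois)
  if (n < 2) return(invisible(rois))
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      tof_olap <- rois$tof_min[a] <= rois$tof_max[b] &&
        rois$tof_min[b] <= rois$tof_max[a]
      ext_olap <- rois$ext_min[a] <= rois$ext_max[b] &&
        rois$ext_min[b] <= rois$ext_max[a]
      if (tof_olap && ext_olap) {
        abort(paste0("worm-size regions '", rois$label[a], "' and '",
                     rois$label[b], "' overlap"))
      }
    }
  }
  invisible(rois)
}

#' Read worm-size regions from a YAML or TSV file
#'
#' YAML files hold a list of records with `label`, `tof_min`, `tof_max`,
#' `ext_min`, `ext_max`; TSV files the same columns. Regions are validated
#' for non-overlap.
#'
#' @param path ROI file.
#' @return ROI tibble.
#' @export
read_rois <- function(path) {
  rois <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    dplyr::bind_rows(purrr::map(yaml::read_yaml(path), as_tibble))
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  check_roi_overlap(rois)
  rois
}

#' @export
tidy.binned_map <- function(x, drop_zero = TRUE, ...) {
  ctr <- bin_centers(x)
  long <- tidyr::expand_grid(tof = ctr$tof, ext = ctr$ext)
  long$value <- as.vector(t(x$grid))
  if (drop_zero) long <- long[long$value != 0, ]
  long
}

#' @export
autoplot.binned_map <- function(object, trans_ext = TRUE, ...) {
  d <- tidy(object)
  d$ext_axis <- if (trans_ext) log10(d$ext) else d$ext
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tof, y = .data$ext_axis,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "TOF", y = if (trans_ext) "log10 EXT" else "EXT",
                  fill = if (object$normalized) "weight" else "count") +
    ggplot2::theme_minimal()
}
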