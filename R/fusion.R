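# Data fusion and driver-peak correlation. Linearized Biosorter population
# vectors are joined with analytical feature vectors from the same samples;
# STOCSY correlates every column against a chosen driver (a feature column or
# a 2D Biosorter region), and SHY cross-correlates two feature tables from
# different analytical platforms. Correlation vectors over the Biosorter
# block can be reprojected onto the 2D map for display.

#' Fuse Biosorter population vectors with an analytical feature table
#'
#' Each sample's normalized Biosorter map is linearized (row-major) and
#' concatenated with its analytical features into one long vector; samples
#' are aligned by identifier. Bins that are zero across every sample carry
#' no correlation information (zero variance), so only bins occupied in at
#' least one sample are stored; the column catalog keeps their 2D indices so
#' maps can be reconstructed.
#'
#' @param maps Named list of normalized `binned_map` objects, one per sample
#'   (names are sample ids).
#' @param features Feature tibble with a `sample_id` column and numeric
#'   feature columns.
#' @return A `fused_dataset`: list with `data` (samples x columns matrix),
#'   `catalog` (tibble: `column`, `block` = `"biosorter"`/`"feature"`,
#'   `tof_idx`, `ext_idx`), `sample_ids`, and the map geometry (`shape`,
#'   `bin_size`).
#' @export
fuse <- function(maps, features) {
  if (is.null(names(maps)) || any(names(maps) == "")) {
    abort("`maps` must be a named list (names = sample ids)")
  }
  if (anyDuplicated(names(maps))) abort("duplicate sample id in `maps`")
  if (anyDuplicated(features$sample_id)) {
    abort("duplicate sample id in `features`")
  }
  common <- intersect(names(maps), features$sample_id)
  if (length(common) == 0) abort("no samples in common between the datasets")
  dropped <- setdiff(union(names(maps), features$sample_id), common)
  if (length(dropped) > 0) {
    warn(paste0("dropping sample(s) present in only one dataset: ",
                paste(dropped, collapse = ", ")))
  }
  maps <- maps[common]
  features <- features[match(common, features$sample_id), ]

  shape <- dim(maps[[1]]$grid)
  bin_block <- do.call(rbind, purrr::map(maps, linearize))
  occupied <- which(colSums(bin_block != 0) > 0)
  bin_block <- bin_block[, occupied, drop = FALSE]
  # row-major linearization: column k of the full vector is bin (i, j)
  tof_idx <- ((occupied - 1) %/% shape[2]) + 1
  ext_idx <- ((occupied - 1) %% shape[2]) + 1

  feat_mat <- as.matrix(features[, setdiff(names(features), "sample_id")])
  rownames(feat_mat) <- common
  data <- cbind(bin_block, feat_mat)

  catalog <- dplyr::bind_rows(
    tibble(column = colnames(bin_block), block = "biosorter",
           tof_idx = tof_idx, ext_idx = ext_idx),
    tibble(column = colnames(feat_mat), block = "feature",
           tof_idx = NA_integer_, ext_idx = NA_integer_)
  )
  structure(list(data = data, catalog = catalog, sample_ids = common,
                 shape = shape, bin_size = maps[[1]]$bin_size),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  cat("<fused_dataset> ", length(x$sample_ids), " samples, ",
      sum(x$catalog$block == "biosorter"), " occupied Biosorter bins + ",
      sum(x$catalog$block == "feature"), " features\n", sep = "")
  invisible(x)
}

# Pearson r of each column of `mat` against `driver`, with two-sided
# t-distribution p-values; zero-variance columns are masked (NA).
pearson_against <- function(mat, driver) {
  n <- length(driver)
  if (n < 3) abort("need at least 3 samples")
  if (sd(driver) == 0) abort("driver has zero variance")
  sds <- apply(mat, 2, sd)
  r <- rep(NA_real_, ncol(mat))
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- as.vector(cor(driver, mat[, ok, drop = FALSE]))
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p)
}

#' STOCSY: correlate every fused column against a driver
#'
#' Computes the Pearson correlation of each column of the fused dataset with
#' the driver series across samples, with two-sided t-distribution p-values.
#' The driver is either a named column (a glycan, an NMR feature, or a
#' specific Biosorter bin) or, in inverse mode, a 2D Biosorter region of
#' interest whose per-sample normalized count sum is used as the driver
#' series.
#'
#' @param fused A `fused_dataset` from [fuse()].
#' @param driver A column name present in the fused catalog, or a one-row
#'   ROI tibble (`tof_min`, `tof_max`, `ext_min`, `ext_max`).
#' @param method `"pearson"` (the default and the method of record) or
#'   `"spearman"` for a robustness check.
#' @return A `stocsy` object: the correlation tibble (`column`, `block`,
#'   `tof_idx`, `ext_idx`, `r`, `p`) plus driver metadata.
#' @export
stocsy <- function(fused, driver, method = c("pearson", "spearman")) {
  stopifnot(inherits(fused, "fused_dataset"))
  method <- match.arg(method)
  if (is.character(driver)) {
    if (!driver %in% colnames(fused$data)) {
      abort(paste0("driver column '", driver, "' not found"))
    }
    series <- fused$data[, driver]
    driver_id <- driver
  } else {
    series <- roi_driver_series(fused, driver)
    driver_id <- if ("label" %in% names(driver)) driver$label else "roi"
  }
  mat <- fused$data
  if (method == "spearman") {
    mat <- apply(mat, 2, rank)
    series <- rank(series)
  }
  res <- pearson_against(mat, series)
  out <- fused$catalog
  out$r <- res$r
  out$p <- res$p
  structure(list(correlations = out, driver = driver_id,
                 n = length(fused$sample_ids), shape = fused$shape,
                 bin_size = fused$bin_size, method = method),
            class = "stocsy")
}

#' Per-sample driver series from a Biosorter region of interest
#'
#' Sums, for every sample, the fused Biosorter bins whose bin centers fall
#' inside the rectangle — the inverse-mode driver of [stocsy()].
#'
#' @param fused A `fused_dataset`.
#' @param roi One-row tibble with `tof_min`, `tof_max`, `ext_min`, `ext_max`.
#' @return Named numeric vector over samples.
#' @export
roi_driver_series <- function(fused, roi) {
  cat_bins <- fused$catalog[fused$catalog$block == "biosorter", ]
  ctr_tof <- (cat_bins$tof_idx - 0.5) * fused$bin_size
  ctr_ext <- (cat_bins$ext_idx - 0.5) * fused$bin_size
  inside <- ctr_tof >= roi$tof_min & ctr_tof <= roi$tof_max &
    ctr_ext >= roi$ext_min & ctr_ext <= roi$ext_max
  cols <- cat_bins$column[inside]
  rowSums(fused$data[, cols, drop = FALSE])
}

#' @export
tidy.stocsy <- function(x, ...) x$correlations

#' @export
glance.stocsy <- function(x, ...) {
  r <- x$correlations$r
  tibble(driver = x$driver, n_samples = x$n,
         n_columns = nrow(x$correlations), n_masked = sum(is.na(r)),
         max_abs_r = max(abs(r), na.rm = TRUE))
}

#' Reproject a STOCSY correlation vector onto the 2D Biosorter map
#'
#' Reverses the linearization: Biosorter-block correlation values are placed
#' back on the TOF x EXT grid (bins never occupied, or with zero variance,
#' stay masked as `NA`); feature-block correlations are carried alongside as
#' a tibble.
#'
#' @param st A `stocsy` object.
#' @param threshold Optional absolute-r display threshold; cells with
#'   `|r| < threshold` are masked.
#' @return A `correlation_map`: list with `grid` (matrix of r), `features`
#'   (tibble of feature correlations), `driver`, `threshold`, `bin_size`.
#' @export
project_map <- function(st, threshold = NULL) {
  stopifnot(inherits(st, "stocsy"))
  bins <- st$correlations[st$correlations$block == "biosorter", ]
  if (nrow(bins) > 0 &&
      (max(bins$tof_idx) > st$shape[1] || max(bins$ext_idx) > st$shape[2])) {
    abort("catalog indices exceed the map shape")
  }
  grid <- matrix(NA_real_, nrow = st$shape[1], ncol = st$shape[2])
  grid[cbind(bins$tof_idx, bins$ext_idx)] <- bins$r
  if (!is.null(threshold)) grid[abs(grid) < threshold] <- NA_real_
  feats <- st$correlations[st$correlations$block == "feature",
                           c("column", "r", "p")]
  structure(list(grid = grid, features = feats, driver = st$driver,
                 threshold = threshold, bin_size = st$bin_size),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map> driver '", x$driver, "', ", nrow(x$grid), " x ",
      ncol(x$grid), " bins, ", sum(!is.na(x$grid)), " unmasked\n", sep = "")
  invisible(x)
}

#' @export
autoplot.correlation_map <- function(object, trans_ext = TRUE, ...) {
  idx <- which(!is.na(object$grid), arr.ind = TRUE)
  d <- tibble(tof = (idx[, 1] - 0.5) * object$bin_size,
              ext = (idx[, 2] - 0.5) * object$bin_size,
              r = object$grid[idx])
  d$ext_axis <- if (trans_ext) log10(d$ext) else d$ext
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tof, y = .data$ext_axis,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(title = paste("driver:", object$driver),
                  x = "TOF", y = if (trans_ext) "log10 EXT" else "EXT") +
    ggplot2::theme_minimal()
}

#' SHY: cross-correlation between two platforms' feature tables
#'
#' Statistical heterospectroscopy: every feature of table A is used as a
#' driver against every feature of table B across the common samples,
#' yielding Pearson r and p-value matrices.
#'
#' @param features_a,features_b Feature tibbles with `sample_id` columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `shy` object with matrices `r` and `p` (rows = A features,
#'   columns = B features) and `n` common samples. Zero-variance features
#'   yield masked (`NA`) rows/columns.
#' @export
shy <- function(features_a, features_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(features_a$sample_id, features_b$sample_id)
  if (length(common) < 3) abort("need at least 3 common samples")
  a <- as.matrix(features_a[match(common, features_a$sample_id),
                            setdiff(names(features_a), "sample_id")])
  b <- as.matrix(features_b[match(common, features_b$sample_id),
                            setdiff(names(features_b), "sample_id")])
  if (method == "spearman") {
    a <- apply(a, 2, rank)
    b <- apply(b, 2, rank)
  }
  n <- length(common)
  r <- suppressWarnings(cor(a, b))
  r[is.nan(r)] <- NA_real_
  ok_a <- apply(a, 2, sd) > 0
  ok_b <- apply(b, 2, sd) > 0
  r[!ok_a, ] <- NA_real_
  r[, !ok_b] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(r = r, p = p, n = n, method = method), class = "shy")
}

#' @export
print.shy <- function(x, ...) {
  cat("<shy> ", nrow(x$r), " x ", ncol(x$r), " feature correlations over ",
      x$n, " samples\n", sep = "")
  invisible(x)
}

#' @export
tidy.shy <- function(x, ...) {
  tidyr::expand_grid(driver = rownames(x$r), target = colnames(x$r)) |>
    dplyr::mutate(r = as.vector(t(x$r)), p = as.vector(t(x$p)))
}

#' @export
glance.shy <- function(x, ...) {
  tibble(n_samples = x$n, n_pairs = length(x$r),
         n_masked = sum(is.na(x$r)),
         max_abs_r = max(abs(x$r), na.rm = TRUE))
}
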