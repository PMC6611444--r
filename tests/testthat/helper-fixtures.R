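# In-code fixtures shared across tests.

# A minimal scan tibble; fragment list-column built from a list of numeric
# vectors of fragment intensities (m/z values are arbitrary).
toy_scans <- function(rt, pmz, pint, frags = NULL, run_id = "runA") {
  n <- length(rt)
  frags <- frags %||% replicate(n, c(100, 50, 25), simplify = FALSE)
  tibble::tibble(
    run_id = run_id,
    scan_id = paste0("s", seq_len(n)),
    rt_min = rt,
    precursor_mz = pmz,
    precursor_intensity = pint,
    fragments = lapply(frags, function(f) {
      tibble::tibble(mz = seq(100, by = 10, length.out = length(f)),
                     intensity = f)
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force implementation of the binned-percentile background
brute_bg <- function(x, q = 0.15) {
  mx <- max(x)
  nb <- max(1, round(mx / length(x)))
  w <- mx / nb
  edges <- seq_len(nb) * w
  counts <- vapply(seq_len(nb), function(k) {
    lo <- (k - 1) * w
    sum(if (k == nb) x >= lo & x <= mx else x >= lo & x < edges[k])
  }, numeric(1))
  cum <- cumsum(counts) / length(x)
  edges[which(cum >= q)[1]]
}

# brute-force Pearson from the sum formula (no stats::cor)
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# small normalized biosorter maps keyed by sample, built from fixed events
toy_maps <- function(sample_ids, n_events = 50, bin_size = 4, bound = 40,
                     seed = 99) {
  set.seed(seed)
  out <- lapply(sample_ids, function(s) {
    ev <- tibble::tibble(tof = runif(n_events, 1, bound - 1),
                         ext = runif(n_events, 1, bound - 1))
    mass_normalize(bin_events(ev, bin_size = bin_size, bound = bound))
  })
  names(out) <- sample_ids
  out
}

# brute-force average-linkage agglomeration returning merge heights and the
# sequence of merged cluster memberships (O(n^3))
brute_average_linkage <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in seq(a + 1, length(clusters))) {
        avg <- mean(d[clusters[[a]], clusters[[b]]])
        if (avg < best_d - 1e-12) {
          best_d <- avg; best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    members <- c(members, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, members = members)
}
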