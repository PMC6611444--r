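# construct feature columns with an exact sample correlation to x:
# y = r * x + sqrt(1 - r^2) * z with x, z orthonormal standardized vectors
exact_r_column <- function(x, z, r) {
  xs <- (x - mean(x)) / sd(x)
  zr <- z - mean(z)
  zr <- zr - sum(zr * xs) / sum(xs * xs) * xs   # orthogonalize to x
  zs <- zr / sd(zr)
  r * xs + sqrt(1 - r^2) * zs
}

test_that("edges use the inclusive |r| >= threshold rule", {
  # x = (1, 0, -1), y = (4, -4, 0): r = 4 / sqrt(2 * 32) = 0.5 exactly,
  # including in floating point (all intermediates are exact)
  exact <- tibble::tibble(sample_id = paste0("s", 1:3),
                          a = c(1, 0, -1), b = c(4, -4, 0))
  types_ab <- tibble::tibble(label = c("a", "b"),
                             type = c("n_glycan", "nmr_feature"))
  net_exact <- build_network(exact, types_ab, threshold = 0.5)
  expect_equal(nrow(net_exact$edges), 1)   # r = 0.50 kept (inclusive)
  expect_identical(net_exact$edges$r, 0.5)
  expect_equal(net_exact$edges$sign, "positive")

  # a pair just below the threshold never forms an edge
  set.seed(71)
  x <- rnorm(20)
  feats <- tibble::tibble(sample_id = paste0("s", 1:20),
                          a = x,
                          c = exact_r_column(x, rnorm(20), 0.49))
  types <- tibble::tibble(label = c("a", "c"),
                          type = c("n_glycan", "nmr_feature"))
  net <- build_network(feats, types, threshold = 0.5)
  expect_equal(nrow(net$edges), 0)

  expect_error(build_network(feats, types[1, , drop = FALSE]), "node type")
  bad_types <- types
  bad_types$type[1] <- "mystery"
  expect_error(build_network(feats, bad_types), "unknown node type")
})

test_that("a planted correlated block is recovered as a clique", {
  set.seed(72)
  n <- 30
  latent <- rnorm(n)
  feats <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    p1 = latent + rnorm(n, 0, 0.3),
    p2 = latent + rnorm(n, 0, 0.3),
    p3 = -latent + rnorm(n, 0, 0.3),
    q1 = rnorm(n), q2 = rnorm(n))
  types <- tibble::tibble(label = c("p1", "p2", "p3", "q1", "q2"),
                          type = "nmr_feature")
  net <- build_network(feats, types, threshold = 0.5)
  labs <- c("p1", "p2", "p3")
  # all three planted pairs present, with signs from brute-force Pearson
  for (i in 1:2) {
    for (j in seq(i + 1, 3)) {
      e <- net$edges[(net$edges$source == labs[i] & net$edges$target == labs[j]) |
                       (net$edges$source == labs[j] & net$edges$target == labs[i]), ]
      expect_equal(nrow(e), 1)
      r0 <- brute_pearson(feats[[labs[i]]], feats[[labs[j]]])
      expect_equal(e$r, r0, tolerance = 1e-12)
      expect_equal(e$sign, if (r0 > 0) "positive" else "negative")
    }
  }

  # edge count is non-increasing in the threshold
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(th) nrow(build_network(feats, types, th)$edges),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("network export round-trips through GraphML and TSV", {
  set.seed(73)
  n <- 15
  feats <- tibble::tibble(sample_id = paste0("s", 1:n),
                          NG_40 = rnorm(n))
  feats$OG_1 <- feats$NG_40 + rnorm(n, 0, 0.2)
  feats$`4.17` <- -feats$NG_40 + rnorm(n, 0, 0.2)
  feats$WS1 <- rnorm(n)
  net <- build_network(feats, feature_types(feats), threshold = 0.5)
  expect_gt(nrow(net$edges), 0)

  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(net, prefix)
  back <- read_network(paste0(prefix, ".graphml"))
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$type[match(net$nodes$id, back$nodes$id)],
               net$nodes$type)
  key <- function(e) paste(pmin(e$source, e$target), pmax(e$source, e$target))
  expect_setequal(key(back$edges), key(net$edges))
  ord <- match(key(net$edges), key(back$edges))
  expect_equal(back$edges$r[ord], net$edges$r, tolerance = 1e-9)
  expect_equal(back$edges$sign[ord], net$edges$sign)

  # sign attribute convention
  expect_true(all(net$edges$sign[net$edges$r > 0] == "positive"))
  expect_true(all(net$edges$sign[net$edges$r < 0] == "negative"))

  # empty edge set still exports a valid node-only graph
  lonely <- build_network(tibble::tibble(sample_id = paste0("s", 1:5),
                                         a = rnorm(5), b = rnorm(5)),
                          tibble::tibble(label = c("a", "b"),
                                         type = "nmr_feature"),
                          threshold = 0.9999)
  prefix2 <- file.path(withr::local_tempdir(), "empty")
  export_network(lonely, prefix2)
  back2 <- read_network(paste0(prefix2, ".graphml"))
  expect_equal(nrow(back2$edges), 0)
  expect_setequal(back2$nodes$id, c("a", "b"))
})

test_that("clustergram standardizes rows and matches brute-force average linkage", {
  profiles <- tibble::tibble(
    analyte = c("g1", "g2", "g3", "g4"),
    T1 = c(10, 1, 5, 9.5),
    T2 = c(2, 8, 5.5, 2.5),
    T3 = c(1, 9, 7, 1.5))
  cg <- clustergram(profiles)
  expect_equal(unname(rowMeans(cg$matrix)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(cg$matrix, 1, sd)), rep(1, 4), tolerance = 1e-12)

  oracle <- brute_average_linkage(cg$matrix)
  expect_equal(cg$row_hclust$height, oracle$heights, tolerance = 1e-12)
  # the sequence of merged clusters matches the O(n^3) agglomeration
  merged_sets <- list()
  for (step in seq_len(nrow(cg$row_hclust$merge))) {
    m <- cg$row_hclust$merge[step, ]
    expand <- function(v) {
      if (v < 0) -v else merged_sets[[v]]
    }
    merged_sets[[step]] <- sort(c(expand(m[1]), expand(m[2])))
  }
  expect_equal(merged_sets, oracle$members)

  # column clustering runs on the standardized matrix
  col_oracle <- brute_average_linkage(t(cg$matrix))
  expect_equal(cg$col_hclust$height, col_oracle$heights, tolerance = 1e-12)

  # identical rows merge first at height 0
  twin <- tibble::tibble(analyte = c("a", "b", "c"),
                         T1 = c(1, 1, 9), T2 = c(5, 5, 2), T3 = c(2, 2, 7))
  cg2 <- clustergram(twin)
  expect_equal(cg2$row_hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(-cg2$row_hclust$merge[1, ], c(1, 2))

  flat <- tibble::tibble(analyte = c("a", "flatliner"),
                         T1 = c(1, 3), T2 = c(2, 3), T3 = c(3, 3))
  expect_error(clustergram(flat), "flatliner")
})
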