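# Thresholded correlation network over worm-size sums, glycans, and NMR
# features, with Cytoscape-compatible export, plus the developmental-profile
# clustergram (row-standardized, average-linkage Euclidean clustering).

NODE_TYPES <- c("worm_size", "n_glycan", "o_glycan", "nmr_feature")

#' Build a correlation network across worm sizes, glycans, and NMR features
#'
#' Computes all pairwise Pearson correlations (with two-sided t p-values)
#' between the columns of a combined feature table and keeps an undirected
#' edge wherever `|r| >= threshold` (inclusive). Node types come from a
#' label map and drive downstream styling (worm-size regions, N-glycans,
#' O-glycans, NMR features).
#'
#' @param features Tibble with `sample_id` plus one numeric column per node.
#' @param types Tibble mapping `label` to `type` (one of `worm_size`,
#'   `n_glycan`, `o_glycan`, `nmr_feature`).
#' @param threshold Inclusive absolute-r edge threshold in (0, 1], default
#'   0.5.
#' @return A `glyco_network`: list with `nodes` (`id`, `type`), `edges`
#'   (`source`, `target`, `r`, `p`, `sign`), and `threshold`. Masked
#'   (zero-variance) pairs never form edges.
#' @export
build_network <- function(features, types, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  labels <- setdiff(names(features), "sample_id")
  if (nrow(features) < 3) abort("need at least 3 samples")
  unknown <- setdiff(labels, types$label)
  if (length(unknown) > 0) {
    abort(paste0("no node type for feature(s): ",
                 paste(unknown, collapse = ", ")))
  }
  bad <- setdiff(types$type, NODE_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown node type(s): ", paste(bad, collapse = ", ")))
  }
  cross <- shy(features, features)
  edges <- tidy(cross) |>
    dplyr::filter(match(.data$driver, labels) < match(.data$target, labels),
                  !is.na(.data$r), abs(.data$r) >= threshold) |>
    dplyr::transmute(source = .data$driver, target = .data$target,
                     r = .data$r, p = .data$p,
                     sign = ifelse(.data$r > 0, "positive", "negative"))
  nodes <- tibble(id = labels,
                  type = types$type[match(labels, types$label)])
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "glyco_network")
}

#' @export
print.glyco_network <- function(x, ...) {
  cat("<glyco_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges at |r| >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.glyco_network <- function(x, ...) x$edges

#' @export
glance.glyco_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         threshold = x$threshold,
         p_min = if (nrow(x$edges)) min(x$edges$p) else NA_real_,
         p_max = if (nrow(x$edges)) max(x$edges$p) else NA_real_)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a correlation network for graph tools
#'
#' Writes a GraphML file (Cytoscape-compatible; node `type` and edge `r`,
#' `p`, `sign` attributes included) and/or TSV node and edge tables.
#'
#' @param net A `glyco_network`.
#' @param prefix Output path prefix; files `<prefix>.graphml`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` are written.
#' @param format Any of `"graphml"`, `"tsv"`.
#' @return The written file paths, invisibly.
#' @export
export_network <- function(net, prefix, format = c("graphml", "tsv")) {
  format <- match.arg(format, several.ok = TRUE)
  written <- character()
  if ("graphml" %in% format) {
    path <- paste0(prefix, ".graphml")
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    written <- c(written, path)
  }
  if ("tsv" %in% format) {
    nodes_path <- paste0(prefix, "_nodes.tsv")
    edges_path <- paste0(prefix, "_edges.tsv")
    readr::write_tsv(net$nodes, nodes_path)
    readr::write_tsv(net$edges, edges_path)
    written <- c(written, nodes_path, edges_path)
  }
  invisible(written)
}

#' Read a network back from a GraphML export
#'
#' @param path A `.graphml` file written by [export_network()].
#' @return A `glyco_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(id = igraph::vertex_attr(g, "name"),
                  type = igraph::vertex_attr(g, "type"))
  if (igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g)
    edges <- tibble(source = ends[, 1], target = ends[, 2],
                    r = igraph::edge_attr(g, "r"),
                    p = igraph::edge_attr(g, "p"),
                    sign = igraph::edge_attr(g, "sign"))
  } else {
    edges <- tibble(source = character(), target = character(),
                    r = numeric(), p = numeric(), sign = character())
  }
  structure(list(nodes = nodes, edges = edges, threshold = NA_real_),
            class = "glyco_network")
}

#' @export
autoplot.glyco_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  layout <- igraph::layout_with_fr(g)
  nd <- object$nodes
  nd$x <- layout[, 1]
  nd$y <- layout[, 2]
  ed <- object$edges
  ed$x <- nd$x[match(ed$source, nd$id)]
  ed$y <- nd$y[match(ed$source, nd$id)]
  ed$xend <- nd$x[match(ed$target, nd$id)]
  ed$yend <- nd$y[match(ed$target, nd$id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$sign),
                          alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(positive = "red",
                                            negative = "blue")) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type), size = 3) +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$id),
                       vjust = -1, size = 2.5) +
    ggplot2::theme_void()
}

#' Developmental-profile clustergram
#'
#' Standardizes each analyte's profile (row) to mean 0 and standard
#' deviation 1, then clusters both dimensions of the standardized matrix
#' hierarchically with Euclidean distance and average linkage. Replicate
#' means per time point are expected as input.
#'
#' @param profiles Tibble whose first column identifies the analyte (row)
#'   and whose remaining numeric columns are time-point means; or a plain
#'   matrix with rownames.
#' @return A `clustergram`: list with the standardized `matrix`,
#'   `row_hclust`, `col_hclust`, and leaf orders `row_order`/`col_order`.
#' @export
clustergram <- function(profiles) {
  if (inherits(profiles, "data.frame")) {
    ids <- as.character(profiles[[1]])
    mat <- as.matrix(profiles[, -1])
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(profiles)
    ids <- rownames(mat) %||% paste0("row", seq_len(nrow(mat)))
    rownames(mat) <- ids
  }
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    abort("clustergram needs at least 2 rows and 2 columns")
  }
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant profile cannot be standardized: ",
                 paste(ids[sds == 0], collapse = ", ")))
  }
  z <- (mat - rowMeans(mat)) / sds
  row_hc <- hclust(dist(z), method = "average")
  col_hc <- hclust(dist(t(z)), method = "average")
  structure(list(matrix = z, row_hclust = row_hc, col_hclust = col_hc,
                 row_order = row_hc$order, col_order = col_hc$order),
            class = "clustergram")
}

#' @export
print.clustergram <- function(x, ...) {
  cat("<clustergram> ", nrow(x$matrix), " analytes x ", ncol(x$matrix),
      " conditions (row-standardized, average-linkage Euclidean)\n", sep = "")
  invisible(x)
}

#' @export
tidy.clustergram <- function(x, ...) {
  tidyr::expand_grid(analyte = rownames(x$matrix),
                     condition = colnames(x$matrix)) |>
    dplyr::mutate(z = as.vector(t(x$matrix)))
}

#' @export
autoplot.clustergram <- function(object, ...) {
  d <- tidy(object)
  d$analyte <- factor(d$analyte,
                      levels = rownames(object$matrix)[object$row_order])
  d$condition <- factor(d$condition,
                        levels = colnames(object$matrix)[object$col_order])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$analyte,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal()
}
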