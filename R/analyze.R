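# Convenience pipeline: run every stage of the workflow over a study (real
# or synthetic) and assemble the combined worm-size / glycan / NMR feature
# table that feeds the correlation network.

#' Run the full cross-platform workflow over a study
#'
#' Bins and mass-normalizes each sample's Biosorter events, sums the
#' worm-size regions, quantifies the candidate glycans in each MS run with
#' the two-fold normalization, PQN-normalizes the NMR matrix and integrates
#' the feature regions, and joins everything into one samples x features
#' table with a node-type map ready for [build_network()].
#'
#' @param study A `glyco_study` from [make_study()] (or a list with the same
#'   elements assembled from real data).
#' @param bin_size Biosorter bin width in instrument units. The instrument
#'   workflow default is 1 unit; coarser bins trade map resolution for
#'   speed and are appropriate when only region sums are needed.
#' @param bound Biosorter exclusion bound (units, inclusive).
#' @param ws_rois Worm-size region tibble, see [default_ws_rois()].
#' @param nmr_rois NMR feature regions, see [default_nmr_rois()].
#' @param standard_id Internal-standard label.
#' @param tol_da,rt_min Precursor matching parameters, see
#'   [match_precursors()].
#' @return List with `features` (tibble: `sample_id`, WS sums, glycan and
#'   NMR feature columns), `types` (node-type map), `maps` (normalized
#'   `binned_map`s), `quant` (normalized quantification records), and
#'   `nmr_features`.
#' @export
analyze_study <- function(study, bin_size = 10, bound = 1600,
                          ws_rois = default_ws_rois(),
                          nmr_rois = default_nmr_rois(),
                          standard_id = "DP5", tol_da = 3, rt_min = 20) {
  maps <- purrr::map(study$events, function(ev) {
    mass_normalize(bin_events(ev, bin_size = bin_size, bound = bound))
  })
  ws <- purrr::imap(maps, function(m, sid) {
    out <- roi_sum(m, ws_rois)
    out$sample_id <- sid
    out
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "label", values_from = "total")

  runs <- tibble(run_id = study$samples$sample_id,
                 sample_id = study$samples$sample_id,
                 time_point = study$samples$time_point)
  records <- study$scans |>
    dplyr::group_split(.data$run_id) |>
    purrr::map(quantify_run, candidates = study$candidates,
               tol_da = tol_da, rt_min = rt_min) |>
    dplyr::bind_rows()
  quant <- normalize_quant(records, runs, standard_id = standard_id)
  glycans <- quant_feature_table(quant, standard_id = standard_id)

  nmr_feat <- integrate_features(pqn_normalize(study$nmr), nmr_rois)

  features <- ws |>
    dplyr::inner_join(glycans, by = "sample_id") |>
    dplyr::inner_join(nmr_feat, by = "sample_id")

  types <- feature_types(features, ws_labels = ws_rois$label)
  list(features = features, types = types, maps = maps, quant = quant,
       nmr_features = nmr_feat)
}

#' Infer node types for a combined feature table
#'
#' Labels beginning `NG_` are N-glycans, `OG_` O-glycans, worm-size labels
#' come from the supplied set, and everything else is an NMR feature.
#'
#' @param features Combined feature tibble (with `sample_id`).
#' @param ws_labels Labels of the worm-size columns.
#' @return Tibble with `label` and `type`.
#' @export
feature_types <- function(features, ws_labels = c("WS1", "WS2", "WS3", "WS4")) {
  labels <- setdiff(names(features), "sample_id")
  tibble(label = labels,
         type = dplyr::case_when(
           labels %in% ws_labels ~ "worm_size",
           grepl("^NG_", labels) ~ "n_glycan",
           grepl("^OG_", labels) ~ "o_glycan",
           TRUE ~ "nmr_feature"))
}

#' Mean developmental profiles from a feature table
#'
#' Averages each feature over the replicates of each time point — the input
#' expected by [clustergram()].
#'
#' @param features Feature tibble with `sample_id`.
#' @param samples Tibble mapping `sample_id` to `time_point`.
#' @return Tibble: one row per feature, one column per time point.
#' @export
profile_means <- function(features, samples) {
  features |>
    dplyr::left_join(samples[, c("sample_id", "time_point")],
                     by = "sample_id") |>
    dplyr::select(-"sample_id") |>
    dplyr::group_by(.data$time_point) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"time_point", names_to = "feature") |>
    tidyr::pivot_wider(names_from = "time_point") |>
    dplyr::rename(analyte = "feature")
}
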