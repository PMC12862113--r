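#' Pipeline configuration
#'
#' One object holds every tunable of the analysis so the empirical run and
#' all null replicates are guaranteed to share it; its canonical hash is
#' attached to every artifact written by [run_gap_analysis()].
#'
#' @param k retained principal components (paper default 4).
#' @param var_threshold optional cumulative variance fraction overriding `k`.
#' @param log_exempt trait names kept on the raw scale before
#'   standardisation.
#' @param slice_interval slice spacing in My.
#' @param max_age oldest slice in My.
#' @param cap Vietoris-Rips cap rule: `"enclosing"` (enclosing radius, the
#'   default) or a positive number.
#' @param notable_threshold persistence threshold for notable gaps
#'   (strict `>`, PC units).
#' @param link_radius centroid distance for linking gap series (PC units).
#' @param n_null number of Brownian-motion null replicates.
#' @param master_seed master seed; all randomness derives from it.
#' @param max_points guard: refuse Vietoris-Rips on slices with more
#'   points than this unless `force`.
#' @param force override the point-count guard.
#' @return a classed list (`gap_config`).
#' @export
gap_config <- function(k = 4L, var_threshold = NULL,
                       log_exempt = "hand_wing_index",
                       slice_interval = 1, max_age = 10,
                       cap = "enclosing", notable_threshold = 0.4,
                       link_radius = 1, n_null = 10L, master_seed = 1L,
                       max_points = 600L, force = FALSE) {
  stopifnot(slice_interval > 0, max_age > 0, notable_threshold > 0,
            link_radius > 0, n_null >= 1L, max_points > 0L)
  structure(list(k = k, var_threshold = var_threshold,
                 log_exempt = log_exempt,
                 slice_interval = slice_interval, max_age = max_age,
                 cap = cap, notable_threshold = notable_threshold,
                 link_radius = link_radius, n_null = as.integer(n_null),
                 master_seed = as.integer(master_seed),
                 max_points = as.integer(max_points), force = force),
            class = "gap_config")
}

#' Canonical hash of a configuration
#'
#' FNV-1a hash of the canonical deparse of the config, used to stamp
#' outputs and to assert that empirical and null runs share byte-identical
#' settings.
#'
#' @param config a [gap_config()].
#' @return an 8-hex-digit string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config), control = "all"), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full analysis end to end
#'
#' Chains the stages preprocess -> pca -> (project) -> asr -> slice ->
#' homology -> gaps -> series -> null -> compare. Deterministic given the
#' same inputs and config; when `out_dir` is given, per-stage CSV/JSON
#' artifacts are written, each stamped with the config hash.
#'
#' @param tree a `phylo` tree, or a path/Newick string accepted by
#'   [read_newick()].
#' @param traits species trait table (data frame) with a species column,
#'   or an already-computed score matrix named by tip label (in which case
#'   the morphospace stages are skipped).
#' @param config a [gap_config()].
#' @param project_table optional second trait table projected into the
#'   fitted morphospace (e.g. extinct species); never used for fitting.
#' @param out_dir optional output directory.
#' @param species_col species-id column name.
#' @return list with `morphospace` (model + scores or `NULL`),
#'   `projected`, `empirical` (the [run_gap_pipeline()] result) and
#'   `comparison` (the [compare_to_null()] result).
#' @export
run_gap_analysis <- function(tree, traits, config = gap_config(),
                             project_table = NULL, out_dir = NULL,
                             species_col = "species") {
  phy <- if (inherits(tree, "phylo")) tree else read_newick(tree)
  morpho <- NULL
  projected <- NULL
  if (is.matrix(traits)) {
    scores <- traits
  } else {
    morpho <- fit_morphospace(traits, log_exempt = config$log_exempt,
                              species_col = species_col, k = config$k,
                              var_threshold = config$var_threshold)
    scores <- morpho$scores
    if (!is.null(project_table)) {
      projected <- project_scores(morpho$model, project_table, species_col)
    }
  }
  keep <- intersect(phy$tip.label, rownames(scores))
  if (length(keep) < ape::Ntip(phy)) {
    phy <- ape::keep.tip(phy, keep)
  }
  scores <- scores[phy$tip.label, , drop = FALSE]
  empirical <- run_gap_pipeline(phy, scores, config)
  comparison <- compare_to_null(empirical, phy, config)
  result <- list(morphospace = morpho, projected = projected,
                 empirical = empirical, comparison = comparison,
                 config = config, config_hash = config_hash(config))
  if (!is.null(out_dir)) write_analysis_outputs(result, out_dir)
  result
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# morphogap ",
                    as.character(utils::packageVersion("morphogap")),
                    " config_hash=", hash), con)
  write.csv(df, con, row.names = FALSE)
}

write_analysis_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- result$config_hash
  emp <- result$empirical
  write_stamped_csv(as.data.frame(emp$states),
                    file.path(out_dir, "node_states.csv"), hash)
  write_stamped_csv(sliced_clouds_df(emp$slices),
                    file.path(out_dir, "sliced_clouds.csv"), hash)
  write_stamped_csv(emp$series$gaps,
                    file.path(out_dir, "gap_table.csv"), hash)
  write_stamped_csv(emp$series$series,
                    file.path(out_dir, "gap_series.csv"), hash)
  cmp <- result$comparison
  if (!is.null(cmp$null_gaps) && nrow(cmp$null_gaps) > 0L) {
    write_stamped_csv(cmp$null_gaps,
                      file.path(out_dir, "null_gaps.csv"), hash)
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("morphogap")),
    config_hash = hash,
    config = unclass(result$config),
    focal = if (!is.null(cmp$focal)) {
      list(slice_age = cmp$focal$slice_age,
           persistence = cmp$focal$persistence, size = cmp$focal$size,
           sparsity = cmp$focal$sparsity,
           centroid = as.numeric(cmp$focal$centroid))
    },
    quantile = if (!is.null(cmp$quantile)) {
      cmp$quantile[c("quantile", "method", "flagged")]
    },
    exceedance = cmp$exceedance[c("count", "rate")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
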