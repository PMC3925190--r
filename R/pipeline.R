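#' Derive a stage seed from a master seed
#'
#' Stable string hash (31-polynomial over the stage label, folded with the
#' master seed modulo 2^31 - 1) so every pipeline stage, probe and
#' (pocket, ligand) pair gets its own reproducible RNG stream from one
#' master seed.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(as.character(label))) h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}

#' Default pipeline configuration
#'
#' Every tunable of every stage with its default; amend entries and pass to
#' [run_pipeline()].  All values are echoed into `run_summary.json` for
#' provenance.
#'
#' @param ensemble path to a multi-model PDB (NULL: generate a fixture).
#' @param library path to a SMILES/SDF library (NULL: generate a toy one).
#' @param outdir output directory.
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(ensemble = NULL, library = NULL,
                           outdir = "idpscreen_run", seed = 1) {
  list(
    ensemble = ensemble,
    library = library,
    probes = NULL,                       # NULL: bundled 15-probe set
    outdir = outdir,
    seed = seed,
    characterize = list(subsample = NULL, probe_radius = 1.4,
                        sasa_points = 960, contact_cutoff = 5.4,
                        min_seq_sep = 3),
    select = list(k = 5, bias_strength = 1),
    map = list(grid_spacing = 2.0, n_orientations = 24, top_k = 30,
               cluster_radius = 3.5),
    pockets = list(rank_fraction = 0.25, proximity_cutoff = 8,
                   lining_dist = 4.5, long_range_min = 12),
    screen = list(mw_max = 325, grid_spacing = 1.5, n_orientations = 24,
                  top_k = 5, box_margin = 4, e_total_max = -4,
                  l_re_max = -0.25, per_pocket_cap = 20),
    fixture = list(n_residues = 60, n_models = 10, plant_pocket = TRUE,
                   cavity_radius = 4, compactness_spread = 1,
                   library_n = 20, charged_fraction = 0.2)
  )
}

write_tsv_atomic <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!file.rename(tmp, path)) { file.copy(tmp, path, overwrite = TRUE); unlink(tmp) }
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!file.rename(tmp, path)) { file.copy(tmp, path, overwrite = TRUE); unlink(tmp) }
  invisible(path)
}

#' Run the five-stage discovery pipeline
#'
#' characterize -> select -> map -> pockets -> screen, writing
#' `conformer_summary.tsv`, `selection.json`, `hotspots.tsv`,
#' `pockets.json`, `hits.tsv` and `run_summary.json` into the output
#' directory.  Every file is written atomically (temp + rename); a stage
#' failure halts the run with the stage name in the error, leaving earlier
#' intermediates in place.  Reruns with an identical configuration produce
#' byte-identical outputs.
#'
#' @param config configuration list from [default_config()].
#' @return the output directory, invisibly; the run summary as attribute
#'   `summary`.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  fixture_used <- is.null(config$ensemble)
  ens <- stage("input", {
    if (fixture_used) {
      fx <- config$fixture
      generate_disordered_ensemble(
        n_residues = fx$n_residues, n_models = fx$n_models,
        seed = derive_seed(config$seed, "fixture_ensemble"),
        plant_pocket = fx$plant_pocket, cavity_radius = fx$cavity_radius,
        compactness_spread = fx$compactness_spread)
    } else read_ensemble_pdb(config$ensemble)
  })
  libpath <- stage("input", {
    if (is.null(config$library)) {
      fx <- config$fixture
      generate_toy_library(fx$library_n,
                           seed = derive_seed(config$seed, "fixture_library"),
                           charged_fraction = fx$charged_fraction,
                           path = file.path(config$outdir, "toy_library.smi"))
    } else config$library
  })

  # --- characterize -------------------------------------------------------
  ch <- config$characterize
  summaries <- stage("characterize", {
    if (!is.null(ch$subsample))
      ens <- subsample_ensemble(ens, ch$subsample,
                                seed = derive_seed(config$seed, "subsample"))
    ens <- assign_parameters_ensemble(ens)
    summarize_ensemble(ens, probe_radius = ch$probe_radius,
                       n_points = ch$sasa_points, cutoff = ch$contact_cutoff,
                       min_seq_sep = ch$min_seq_sep)
  })
  write_tsv_atomic(summaries, file.path(config$outdir, "conformer_summary.tsv"))

  # --- select -------------------------------------------------------------
  selres <- stage("select", {
    dmat <- conformer_distance_matrix(ens)
    select_diverse_compact(summaries, dmat, k = config$select$k,
                           bias_strength = config$select$bias_strength,
                           seed = derive_seed(config$seed, "select"))
  })
  write_json_atomic(unclass(selres), file.path(config$outdir, "selection.json"))

  # --- map ----------------------------------------------------------------
  probes <- stage("map", {
    if (is.null(config$probes)) load_probe_set(seed = derive_seed(config$seed, "probes"))
    else read_library(config$probes, seed = derive_seed(config$seed, "probes"),
                      protonate = FALSE)
  })
  mp <- config$map
  ids <- vapply(ens$conformers, function(cf) cf$model_id, 1L)
  selected <- ens$conformers[match(selres$selected_ids, ids)]
  mapped <- stage("map", lapply(selected, function(cf)
    map_conformer(cf, probes, cluster_radius = mp$cluster_radius,
                  seed = derive_seed(config$seed, paste0("map_m", cf$model_id)),
                  grid_spacing = mp$grid_spacing,
                  n_orientations = mp$n_orientations, top_k = mp$top_k)))
  hs_rows <- do.call(rbind, lapply(seq_along(selected), function(i) {
    hs <- mapped[[i]]$hotspots
    if (length(hs) == 0) return(NULL)
    data.frame(model_id = selected[[i]]$model_id,
               rank = vapply(hs, function(h) h$rank, 1L),
               le_score = vapply(hs, function(h) h$le_score, 1.0),
               n_probes = vapply(hs, function(h) length(h$distinct_probe_ids), 1L),
               n_poses = vapply(hs, function(h) h$n_members, 1L),
               x = vapply(hs, function(h) h$centroid[1], 1.0),
               y = vapply(hs, function(h) h$centroid[2], 1.0),
               z = vapply(hs, function(h) h$centroid[3], 1.0))
  }))
  if (is.null(hs_rows))
    hs_rows <- data.frame(model_id = integer(0), rank = integer(0),
                          le_score = numeric(0), n_probes = integer(0),
                          n_poses = integer(0), x = numeric(0),
                          y = numeric(0), z = numeric(0))
  write_tsv_atomic(hs_rows, file.path(config$outdir, "hotspots.tsv"))

  # --- pockets ------------------------------------------------------------
  pk <- config$pockets
  pockets <- stage("pockets", {
    unlist(lapply(seq_along(selected), function(i)
      identify_pockets(selected[[i]], mapped[[i]]$hotspots,
                       rank_fraction = pk$rank_fraction,
                       proximity_cutoff = pk$proximity_cutoff,
                       lining_dist = pk$lining_dist,
                       long_range_min = pk$long_range_min)),
      recursive = FALSE)
  })
  write_json_atomic(lapply(pockets, function(p) {
    p <- unclass(p)
    p$centroid <- round(unname(p$centroid), 4)
    p$bbox <- lapply(p$bbox, function(v) round(unname(v), 4))
    p
  }), file.path(config$outdir, "pockets.json"))

  # --- screen -------------------------------------------------------------
  sc <- config$screen
  hits <- stage("screen", {
    ligands <- read_library(libpath, seed = derive_seed(config$seed, "library"))
    ligands <- filter_library(ligands, mw_max = sc$mw_max)
    confs <- setNames(selected, vapply(selected, function(cf)
      as.character(cf$model_id), ""))
    all_hits <- screen_pockets(confs, pockets, ligands, seed = config$seed,
                               grid_spacing = sc$grid_spacing,
                               n_orientations = sc$n_orientations,
                               top_k = sc$top_k, box_margin = sc$box_margin)
    select_hits(all_hits, e_total_max = sc$e_total_max,
                l_re_max = sc$l_re_max, per_pocket_cap = sc$per_pocket_cap)
  })
  write_tsv_atomic(hits, file.path(config$outdir, "hits.tsv"))

  summary <- list(
    package_version = as.character(utils::packageVersion("idpscreen")),
    config = config[order(names(config))],
    fixture_ensemble_used = fixture_used,
    library_path = as.character(libpath),
    n_conformers = length(ens$conformers),
    selected_models = selres$selected_ids,
    n_hotspots = nrow(hs_rows),
    n_pockets = length(pockets),
    n_hits = nrow(hits)
  )
  write_json_atomic(summary, file.path(config$outdir, "run_summary.json"))
  structure(invisible(config$outdir), summary = summary)
}
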