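#' Dock a library compound into a binding pocket
#'
#' Same exhaustive rigid search as [dock_probe()], restricted to the pocket
#' bounding box expanded by `box_margin`, followed by rigid-body plus
#' rotatable-torsion minimization of the short-listed candidates (the
#' protein stays rigid, every ligand degree of freedom in the reduced
#' representation is free).  Returns poses sorted by ascending `e_total`.
#'
#' @param conf the parameterized [Conformer] the pocket lives on.
#' @param pocket a `Pocket` from [identify_pockets()].
#' @param ligand a `Ligand`.
#' @param box_margin Angstrom added around the pocket bounding box.
#' @param grid_spacing,n_orientations,top_k,seed,shell,... passed to
#'   [dock_probe()].
#' @return list of pose lists; empty (with a warning) when the ligand
#'   cannot fit or no non-clashing pose exists.
#' @export
dock_ligand <- function(conf, pocket, ligand, box_margin = 4,
                        grid_spacing = 1.5, n_orientations = 24, top_k = 5,
                        seed = 1, shell = c(1, 4), ...) {
  stopifnot(inherits(pocket, "Pocket"), inherits(ligand, "Ligand"))
  if (pocket$model_id != conf$model_id)
    stop("pocket ", pocket$pocket_id, " belongs to model ", pocket$model_id,
         ", not model ", conf$model_id)
  box <- list(lo = pocket$bbox$lo - box_margin,
              hi = pocket$bbox$hi + box_margin)
  diam <- max(vapply(ligand$conformers, function(m)
    max(stats::dist(m)), 1.0))
  if (diam > sqrt(sum((box$hi - box$lo)^2))) {
    warning("ligand ", ligand$ligand_id, " larger than the search box")
    return(list())
  }
  dock_probe(conf, ligand, grid_spacing = grid_spacing,
             n_orientations = n_orientations, top_k = top_k, shell = shell,
             seed = seed, box = box, ...)
}

#' Rank docked ligands within a pocket
#'
#' `e_rank` is the 1-based position in ascending minimized `e_total` order
#' within the pocket (ties broken by ligand id); `l_re` is the ligand
#' efficiency of the screened compound, `e_total / heavy_atom_count`.
#'
#' @param results list of `list(ligand = <Ligand>, pose = <pose>)`, one per
#'   ligand, each pose carrying an `energy` component.
#' @param pocket_id identifier copied into every row.
#' @return data frame of `ScreenHit` rows: `ligand_id`, `pocket_id`,
#'   `e_vdw`, `e_elec`, `e_solv`, `e_total`, `e_rank`, `l_re`,
#'   `charge_class`, `heavy_atom_count`.
#' @export
rank_hits <- function(results, pocket_id) {
  if (length(results) == 0) {
    return(data.frame(ligand_id = character(0), pocket_id = character(0),
                      e_vdw = numeric(0), e_elec = numeric(0),
                      e_solv = numeric(0), e_total = numeric(0),
                      e_rank = integer(0), l_re = numeric(0),
                      charge_class = character(0),
                      heavy_atom_count = integer(0)))
  }
  df <- do.call(rbind, lapply(results, function(r) {
    en <- r$pose$energy
    data.frame(ligand_id = r$ligand$ligand_id, pocket_id = pocket_id,
               e_vdw = en$e_vdw, e_elec = en$e_elec, e_solv = en$e_solv,
               e_total = en$e_total, e_rank = NA_integer_,
               l_re = en$e_total / r$ligand$heavy_atom_count,
               charge_class = r$ligand$charge_class,
               heavy_atom_count = r$ligand$heavy_atom_count)
  }))
  df <- df[order(df$e_total, df$ligand_id), , drop = FALSE]
  df$e_rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Select in-silico hits from ranked screen results
#'
#' Keeps hits with `e_total <= e_total_max` and `l_re <= l_re_max`,
#' truncates each pocket to its `per_pocket_cap` best by `e_rank`, then
#' deduplicates across pockets by ligand id, keeping the pocket where the
#' ligand binds with the lowest energy.
#'
#' @param hits data frame from [rank_hits()] (possibly several pockets
#'   row-bound).
#' @param e_total_max energy ceiling, kcal/mol.
#' @param l_re_max ligand-efficiency ceiling, kcal/mol per heavy atom.
#' @param per_pocket_cap maximum hits retained per pocket.
#' @return the filtered hit data frame, sorted by pocket then `e_rank`.
#' @export
select_hits <- function(hits, e_total_max = -4, l_re_max = -0.25,
                        per_pocket_cap = 20) {
  keep <- hits[hits$e_total <= e_total_max & hits$l_re <= l_re_max, ,
               drop = FALSE]
  if (nrow(keep) > 0) {
    keep <- do.call(rbind, lapply(split(keep, keep$pocket_id), function(d) {
      d[order(d$e_rank), , drop = FALSE][seq_len(min(nrow(d), per_pocket_cap)), ,
                                         drop = FALSE]
    }))
    # dedupe: best (lowest-energy) pocket wins for each ligand
    keep <- keep[order(keep$e_total, keep$pocket_id), , drop = FALSE]
    keep <- keep[!duplicated(keep$ligand_id), , drop = FALSE]
    keep <- keep[order(keep$pocket_id, keep$e_rank), , drop = FALSE]
  }
  rownames(keep) <- NULL
  keep
}

#' Screen a ligand library against a set of pockets
#'
#' Docks every library compound into every pocket ([dock_ligand()]), keeps
#' each compound's best minimized pose per pocket, and ranks within pockets
#' ([rank_hits()]).  Screening against zero pockets yields an empty,
#' schema-valid table.
#'
#' @param conformers named list of parameterized [Conformer]s keyed by
#'   `model_id` (as character), covering every pocket's model.
#' @param pockets list of `Pocket` objects.
#' @param ligands list of `Ligand` objects.
#' @param seed master seed; per (pocket, ligand) seeds are derived.
#' @param ... passed to [dock_ligand()].
#' @return ranked hit data frame (all pockets row-bound).
#' @export
screen_pockets <- function(conformers, pockets, ligands, seed = 1, ...) {
  out <- list()
  for (pk in pockets) {
    conf <- conformers[[as.character(pk$model_id)]]
    if (is.null(conf))
      stop("no conformer supplied for model ", pk$model_id)
    results <- list()
    for (lig in ligands) {
      poses <- dock_ligand(conf, pk, lig,
                           seed = derive_seed(seed, paste0(pk$pocket_id, ":",
                                                           lig$ligand_id)),
                           ...)
      if (length(poses) == 0) next
      results[[length(results) + 1]] <- list(ligand = lig, pose = poses[[1]])
    }
    out[[length(out) + 1]] <- rank_hits(results, pk$pocket_id)
  }
  if (length(out) == 0) return(rank_hits(list(), ""))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
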