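#' Locate the Python chemistry backend
#'
#' SMILES/SDF parsing, pH-7.4 protonation, Gasteiger partial charges and
#' seeded 3D conformer embedding are delegated to RDKit through a bundled
#' Python script (`python` must be on the PATH with RDKit importable).
#'
#' @return path to the backend script.
#' @keywords internal
chem_backend_path <- function() {
  p <- system.file("python", "chem_backend.py", package = "idpscreen")
  if (p == "") stop("chem_backend.py not found in installed package")
  p
}

run_chem_backend <- function(input, seed = 1, n_confs = 1, protonate = TRUE) {
  out <- tempfile(fileext = ".json")
  on.exit(unlink(out))
  args <- c(chem_backend_path(), input, out, "--seed", as.integer(seed),
            "--nconfs", as.integer(n_confs), if (protonate) "--protonate")
  status <- suppressWarnings(
    system2("python", shQuote(args), stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("chemistry backend failed (is RDKit installed for 'python'?):\n",
         paste(status, collapse = "\n"))
  jsonlite::read_json(out, simplifyVector = FALSE)
}

#' Read a small-molecule library
#'
#' Accepts a SMILES file (one molecule per line, optional identifier after
#' whitespace) or an SDF V2000 file.  Each record is protonated with simple
#' pH 7.4 rules (carboxylic acids deprotonated, aliphatic amines
#' protonated), assigned aggregated-hydrogen Gasteiger partial charges, and
#' embedded into `n_confs` seeded 3D conformers; hydrogens are then
#' stripped so all downstream scoring is heavy-atom-only.  Unparseable
#' records are skipped and counted.
#'
#' @param path SMILES (.smi/.txt) or SDF (.sdf) file.
#' @param seed integer seed for conformer embedding.
#' @param n_confs conformers to generate per molecule.
#' @param protonate logical; apply the pH 7.4 rules.
#' @param param_table nonbonded parameter table for van der Waals radii
#'   (charges come from the Gasteiger model, not this table).
#' @return list of `Ligand` objects; the number of skipped records is
#'   attached as attribute `n_skipped`.
#' @export
read_library <- function(path, seed = 1, n_confs = 1, protonate = TRUE,
                         param_table = default_parameter_table()) {
  if (!file.exists(path)) stop("library file not found: ", path)
  res <- run_chem_backend(path, seed = seed, n_confs = n_confs,
                          protonate = protonate)
  mols <- res$molecules
  if (length(mols) == 0)
    stop("no valid molecules in ", path, " (", res$n_skipped, " skipped)")
  ligs <- lapply(mols, ligand_from_backend, param_table = param_table)
  ids <- vapply(ligs, function(l) l$ligand_id, "")
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  for (i in seq_along(ligs)) ligs[[i]]$ligand_id <- ids[i]
  attr(ligs, "n_skipped") <- res$n_skipped
  ligs
}

ligand_from_backend <- function(m, param_table) {
  el <- toupper(unlist(m$elements))
  if (!all(el %in% names(param_table$elements)))
    stop("no vdW parameters for element(s): ",
         paste(setdiff(el, names(param_table$elements)), collapse = ", "))
  rmin <- vapply(param_table$elements[el], function(p) as.numeric(p$rmin), 1.0)
  eps <- vapply(param_table$elements[el], function(p) as.numeric(p$eps), 1.0)
  params <- data.frame(element = el,
                       charge = as.numeric(unlist(m$charges)),
                       rmin = unname(rmin), eps = unname(eps))
  confs <- lapply(m$conformers, function(cc) {
    do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p))))
  })
  torsions <- lapply(m$torsions, function(t)
    list(axis = as.integer(unlist(t$axis)),
         moving = as.integer(unlist(t$moving))))
  structure(list(
    ligand_id = as.character(m$id),
    smiles = m$smiles,
    mol_weight = as.numeric(m$mw),
    formal_charge = as.integer(m$formal_charge),
    n_hydrogens = as.integer(m$n_hydrogens),
    heavy_atom_count = as.integer(m$heavy_atom_count),
    charge_class = if (m$formal_charge == 0) "neutral" else "charged",
    params = params,
    bonds = do.call(rbind, lapply(m$bonds, function(b) as.integer(unlist(b)))),
    torsions = torsions,
    conformers = confs
  ), class = "Ligand")
}

#' @export
print.Ligand <- function(x, ...) {
  cat(sprintf("Ligand %s: %s  MW %.2f  charge %+d (%s), %d heavy atoms, %d conformer(s)\n",
              x$ligand_id, x$smiles, x$mol_weight, x$formal_charge,
              x$charge_class, x$heavy_atom_count, length(x$conformers)))
  invisible(x)
}

#' Filter a library by molecular weight
#'
#' Keeps molecules with `mol_weight` strictly below `mw_max` (the
#' fragment-like regime is conventionally < 325 Da), preserving order.
#'
#' @param ligands list of `Ligand` objects.
#' @param mw_max molecular weight ceiling in Da.
#' @return the surviving subset (same class of list).
#' @export
filter_library <- function(ligands, mw_max = 325) {
  keep <- vapply(ligands, function(l) l$mol_weight < mw_max, TRUE)
  ligands[keep]
}
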