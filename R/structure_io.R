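#' @useDynLib idpscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim runif rnorm setNames
#' @importFrom utils read.delim write.table head
NULL

#' Construct a conformer
#'
#' A `Conformer` is one all-atom (or heavy-atom) model from a multi-model
#' ensemble: a data frame of atom records plus the residue sequence.  Atoms
#' are ordered by (chain, residue index); atom order must be identical across
#' all members of an [EnsembleSet].
#'
#' @param model_id integer model number (from the PDB MODEL record).
#' @param atoms data frame with columns `atom_name`, `element`,
#'   `residue_index` (author numbering, 1-based), `residue_name`, `chain_id`,
#'   `x`, `y`, `z` and, once parameterized, `charge`, `rmin`, `eps`,
#'   `is_heavy`.
#' @return object of class `Conformer`.
#' @export
new_conformer <- function(model_id, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  needed <- c("atom_name", "element", "residue_index", "residue_name",
              "chain_id", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in model ", model_id)
  ord <- order(atoms$chain_id, atoms$residue_index)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  if (!("is_heavy" %in% names(atoms)))
    atoms$is_heavy <- toupper(atoms$element) != "H"
  seqdf <- unique(atoms[, c("chain_id", "residue_index", "residue_name")])
  rownames(seqdf) <- NULL
  structure(list(model_id = as.integer(model_id), atoms = atoms,
                 sequence = seqdf),
            class = "Conformer")
}

#' @export
print.Conformer <- function(x, ...) {
  cat(sprintf("Conformer model %d: %d atoms, %d residues\n",
              x$model_id, nrow(x$atoms), nrow(x$sequence)))
  invisible(x)
}

coords_of <- function(conf) as.matrix(conf$atoms[, c("x", "y", "z")])

#' Construct an ensemble set
#'
#' Validates that all conformers share the same atom count and atom ordering
#' (atom names and residue indices), the contract every downstream
#' computation relies on.
#'
#' @param conformers list of [Conformer] objects.
#' @return object of class `EnsembleSet`.
#' @export
new_ensemble_set <- function(conformers) {
  stopifnot(length(conformers) >= 1)
  ref <- conformers[[1]]$atoms
  for (cf in conformers) {
    if (nrow(cf$atoms) != nrow(ref))
      stop(sprintf("model %d has %d atoms; model %d has %d (ensemble must be homogeneous)",
                   cf$model_id, nrow(cf$atoms),
                   conformers[[1]]$model_id, nrow(ref)))
    if (!identical(cf$atoms$atom_name, ref$atom_name) ||
        !identical(cf$atoms$residue_index, ref$residue_index))
      stop(sprintf("model %d atom ordering differs from model %d",
                   cf$model_id, conformers[[1]]$model_id))
  }
  structure(list(conformers = conformers,
                 sequence = conformers[[1]]$sequence),
            class = "EnsembleSet")
}

#' @export
print.EnsembleSet <- function(x, ...) {
  cat(sprintf("EnsembleSet: %d conformers x %d atoms (%d residues)\n",
              length(x$conformers), nrow(x$conformers[[1]]$atoms),
              nrow(x$sequence)))
  invisible(x)
}

#' @export
length.EnsembleSet <- function(x) length(x$conformers)

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  if (nchar(nm) == 0) return("X")
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE")) return(two)
  toupper(substr(nm, 1, 1))
}

#' Read a multi-model PDB ensemble
#'
#' Parses ATOM/HETATM records of a MODEL/ENDMDL multi-model PDB file (a
#' single-model file yields an ensemble of size one).  Alternate locations
#' other than blank or 'A' are dropped with a warning; the element is taken
#' from columns 77-78 when present, otherwise inferred from the atom name.
#'
#' @param path PDB file path.
#' @return an [EnsembleSet].
#' @export
read_ensemble_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  model_no <- 0L
  current <- 1L
  model_of <- integer(length(lines))
  for (i in seq_along(lines)) {
    if (rec[i] == "MODEL ") {
      model_no <- model_no + 1L
      current <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      if (is.na(current)) current <- model_no
    }
    model_of[i] <- current
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  al <- lines[is_atom]
  mdl <- model_of[is_atom]
  altloc <- substr(al, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  if (any(!keep)) {
    warning(sum(!keep), " alternate-location records dropped (kept altloc ' '/'A')")
    al <- al[keep]; mdl <- mdl[keep]
  }
  element <- trimws(substr(al, 77, 78))
  name <- trimws(substr(al, 13, 16))
  no_el <- element == ""
  if (any(no_el)) element[no_el] <- vapply(name[no_el], guess_element, "")
  atoms <- data.frame(
    atom_name = name,
    element = toupper(element),
    residue_index = as.integer(substr(al, 23, 26)),
    residue_name = trimws(substr(al, 18, 20)),
    chain_id = substr(al, 22, 22),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    stringsAsFactors = FALSE
  )
  confs <- lapply(split(seq_len(nrow(atoms)), mdl), function(idx) {
    new_conformer(mdl[idx[1]], atoms[idx, , drop = FALSE])
  })
  confs <- confs[order(vapply(confs, function(cf) cf$model_id, 1L))]
  new_ensemble_set(unname(confs))
}

#' Write an ensemble (or single conformer) as a multi-model PDB file
#'
#' @param ens an [EnsembleSet] or a single [Conformer].
#' @param path output path; written atomically (temp file + rename).
#' @param hetatm logical; write HETATM instead of ATOM records.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, hetatm = FALSE) {
  if (inherits(ens, "Conformer")) ens <- new_ensemble_set(list(ens))
  stopifnot(inherits(ens, "EnsembleSet"))
  rectype <- if (hetatm) "HETATM" else "ATOM  "
  out <- character(0)
  multi <- length(ens$conformers) > 1
  for (cf in ens$conformers) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", cf$model_id))
    a <- cf$atoms
    nm <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name)
    out <- c(out, sprintf(
      "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, seq_len(nrow(a)) %% 100000, substr(nm, 1, 4), " ",
      substr(a$residue_name, 1, 3), a$chain_id, a$residue_index, " ",
      a$x, a$y, a$z, 1, 0, substr(a$element, 1, 2)))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  atomic_write_lines(out, path)
  invisible(path)
}

# write-to-temp-then-rename so no output file is ever partially written
atomic_write_lines <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Built-in element-level nonbonded parameter table
#'
#' A deliberately small Lennard-Jones / partial-charge table keyed by
#' element, standing in for full force-field atom typing (which this package
#' does not reproduce).  `rmin` is the per-atom Rmin/2-style radius in
#' Angstrom (pairwise minimum-energy distance is `rmin_i + rmin_j`), `eps`
#' the well depth in kcal/mol, `charge` a default partial charge in units of
#' the elementary charge.  Entries under `atom_names` override element
#' entries for specific atom names.  The table can be replaced wholesale by
#' an edited JSON file via [read_parameter_table()].
#'
#' @return nested list with components `elements` and `atom_names`.
#' @export
default_parameter_table <- function() {
  list(
    elements = list(
      C = list(rmin = 1.908, eps = 0.086, charge = 0.00),
      N = list(rmin = 1.824, eps = 0.170, charge = 0.20),
      O = list(rmin = 1.661, eps = 0.210, charge = -0.20),
      S = list(rmin = 2.000, eps = 0.250, charge = 0.00),
      P = list(rmin = 2.100, eps = 0.200, charge = 0.00),
      H = list(rmin = 1.387, eps = 0.016, charge = 0.10),
      F = list(rmin = 1.750, eps = 0.061, charge = -0.15),
      CL = list(rmin = 1.948, eps = 0.265, charge = -0.10),
      BR = list(rmin = 2.220, eps = 0.320, charge = -0.10)
    ),
    atom_names = list()
  )
}

#' Read a parameter table from JSON
#' @param path JSON file with `elements` (and optionally `atom_names`) maps.
#' @return parameter table list as in [default_parameter_table()].
#' @export
read_parameter_table <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(tab$elements)) stop("parameter table lacks 'elements' map")
  if (is.null(tab$atom_names)) tab$atom_names <- list()
  tab
}

#' Attach nonbonded parameters to a conformer
#'
#' Assigns `charge`, `rmin` and `eps` to every atom by element lookup, with
#' optional atom-name overrides.  Idempotent: re-assigning with the same
#' table reproduces identical parameters.
#'
#' @param conf a [Conformer].
#' @param table parameter table (see [default_parameter_table()]).
#' @return the conformer with parameter columns filled; the summed partial
#'   charge is attached as attribute `total_charge`.
#' @export
assign_parameters <- function(conf, table = default_parameter_table()) {
  stopifnot(inherits(conf, "Conformer"))
  a <- conf$atoms
  el <- toupper(a$element)
  unknown <- !(el %in% names(table$elements))
  if (any(unknown)) {
    bad <- unique(paste0(a$atom_name[unknown], " (element ", el[unknown], ")"))
    stop("no parameters for atom(s): ", paste(bad, collapse = ", "))
  }
  get3 <- function(field) vapply(table$elements[el],
                                 function(p) as.numeric(p[[field]]), 1.0)
  a$rmin <- get3("rmin")
  a$eps <- get3("eps")
  a$charge <- get3("charge")
  if (length(table$atom_names)) {
    hit <- a$atom_name %in% names(table$atom_names)
    for (i in which(hit)) {
      p <- table$atom_names[[a$atom_name[i]]]
      for (f in c("rmin", "eps", "charge"))
        if (!is.null(p[[f]])) a[[f]][i] <- as.numeric(p[[f]])
    }
  }
  a$is_heavy <- el != "H"
  conf$atoms <- a
  attr(conf, "total_charge") <- sum(a$charge)
  conf
}

#' Apply [assign_parameters()] to every member of an ensemble
#' @inheritParams assign_parameters
#' @param ens an [EnsembleSet].
#' @return the ensemble with all conformers parameterized.
#' @export
assign_parameters_ensemble <- function(ens, table = default_parameter_table()) {
  stopifnot(inherits(ens, "EnsembleSet"))
  ens$conformers <- lapply(ens$conformers, assign_parameters, table = table)
  ens
}
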