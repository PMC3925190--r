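#' Generate a synthetic disordered-chain ensemble
#'
#' Builds `n_models` self-avoiding C-alpha random walks (3.8 Angstrom
#' steps) decorated with one pseudo side-chain heavy atom per residue, as a
#' desk-scale stand-in for an NMR-derived ensemble of a disordered protein.
#' Each model is confined to a sphere whose radius is drawn from a
#' `compactness_spread`-controlled distribution, so the radius of gyration
#' varies across models the way compact and extended members coexist in a
#' real disordered ensemble.  With `plant_pocket = TRUE`, model 1 threads
#' a 34-residue stretch over a deep spherical cap (polar angle up to ~137
#' degrees) of radius `cavity_radius + 2.6`, producing a concave,
#' oxygen-lined (negatively charged under the default parameter table)
#' bowl whose interior no atom invades, on an otherwise aliphatic,
#' extended chain -- the chain's one genuinely druggable surface cleft,
#' closed by residues far apart in sequence (a long-range tertiary
#' contact).  The cavity centre and radius are recorded in attribute
#' `cavity` (`model_id`, `center`, `radius`).
#'
#' No two atoms come closer than 2.6 Angstrom; the whole construction is
#' bitwise reproducible for a given seed.
#'
#' @param n_residues chain length (>= 10).
#' @param n_models ensemble size (>= 1).
#' @param seed integer seed.
#' @param plant_pocket logical; carve the concave cleft into model 1.
#' @param cavity_radius cavity radius in Angstrom (3-8 when planted).
#' @param compactness_spread non-negative width of the confinement-radius
#'   distribution; 0 makes all models equally compact.
#' @param confine_radius optional base confinement radius override
#'   (Angstrom); the default scales as `2.4 * n_residues^(1/3)`.
#' @param max_restarts model rebuild budget before erroring out on
#'   impossible geometry.
#' @return an [EnsembleSet] (unparameterized; run
#'   [assign_parameters_ensemble()] before energy work).
#' @export
generate_disordered_ensemble <- function(n_residues = 60, n_models = 10,
                                         seed = 1, plant_pocket = FALSE,
                                         cavity_radius = 4,
                                         compactness_spread = 1,
                                         confine_radius = NULL,
                                         max_restarts = 100) {
  stopifnot(n_residues >= 10, n_models >= 1, compactness_spread >= 0)
  if (plant_pocket && (cavity_radius < 3 || cavity_radius > 8))
    stop("cavity_radius must be in [3, 8] Angstrom")
  base_r <- if (is.null(confine_radius)) 2.4 * n_residues^(1 / 3) else confine_radius
  with_local_seed(seed, {
    seqnames <- sample(c("ALA", "VAL", "SER", "THR", "ASN", "GLN", "GLU",
                         "LYS"), n_residues, replace = TRUE)
    shell_idx <- integer(0)
    if (plant_pocket) {
      if (n_residues < 50)
        stop("plant_pocket needs n_residues >= 50 (34-residue wall plus tails)")
      # one contiguous 34-residue wall threaded over a deep spherical cap.
      # The wall is oxygen-lined (polar, deep vdW wells, net negative)
      # while the rest of the chain is aliphatic, so the planted cleft is
      # the chain's one genuinely druggable site.
      seqnames <- sample(c("ALA", "VAL"), n_residues, replace = TRUE)
      shell_idx <- seq(16L, 49L)
      seqnames[shell_idx] <- rep(c("GLU", "SER"), length.out = length(shell_idx))
    }
    # stratified confinement radii: every run covers the full
    # compact-to-extended continuum, with per-model jitter
    u <- if (n_models == 1) 0.5 else seq(0, 1, length.out = n_models)
    u <- pmin(1, pmax(0, u + runif(n_models, -0.4, 0.4) / max(1, n_models - 1)))
    confs <- vector("list", n_models)
    for (m in seq_len(n_models)) {
      planted <- plant_pocket && m == 1
      # the planted model gets a roomy confinement: its free segments stay
      # extended, so the engineered trough is the dominant concave site
      # rather than competing with crevices of a densely packed ball
      r_conf <- if (planted) max(1.8 * base_r, cavity_radius + 20)
                else base_r * (1 + 1.5 * compactness_spread * u[m])
      confs[[m]] <- build_chain_model(m, n_residues, seqnames, r_conf,
                                      planted, cavity_radius, shell_idx,
                                      max_restarts)
    }
    ens <- new_ensemble_set(confs)
    if (plant_pocket)
      attr(ens, "cavity") <- list(model_id = 1L, center = c(0, 0, 0),
                                  radius = cavity_radius)
    ens
  })
}

SC_ELEMENT <- c(ALA = "C", VAL = "C", SER = "O", THR = "O", ASN = "N",
                GLN = "N", GLU = "O", LYS = "N")

build_chain_model <- function(model_id, n_res, seqnames, r_conf, planted,
                              cavity_radius, shell_idx, max_restarts) {
  for (attempt in seq_len(max_restarts)) {
    ca <- try_chain_walk(n_res, r_conf, planted, cavity_radius, shell_idx)
    if (is.null(ca)) next
    cb <- try_side_chains(ca, r_conf, planted, cavity_radius, shell_idx)
    if (is.null(cb)) next
    atoms <- data.frame(
      atom_name = rep(c("CA", "CB"), n_res),
      element = as.vector(rbind("C", unname(SC_ELEMENT[seqnames]))),
      residue_index = rep(seq_len(n_res), each = 2),
      residue_name = rep(seqnames, each = 2),
      chain_id = "A",
      x = round(as.vector(rbind(ca[, 1], cb[, 1])), 3),
      y = round(as.vector(rbind(ca[, 2], cb[, 2])), 3),
      z = round(as.vector(rbind(ca[, 3], cb[, 3])), 3),
      stringsAsFactors = FALSE
    )
    return(new_conformer(model_id, atoms))
  }
  stop("could not build a self-avoiding chain (n_residues = ", n_res,
       ", confinement radius = ", round(r_conf, 2),
       " A) within ", max_restarts, " restarts")
}

# TRUE when p keeps clear of the planted bowl (centred at the origin) and
# out of its mouth chimney (the -z approach column, so probes can always
# reach the interior).  margin: minimum distance from the bowl centre --
# lenient (rs - 1, just outside the airspace) for side chains, strict
# (rs + 10) for the free tails so they can neither invade the bowl nor
# come near enough to its outer wall to form probe-sized slot sites.
trough_clear <- function(p, rs, cavity_radius, margin = rs - 1) {
  if (sqrt(sum(p^2)) < margin) return(FALSE)
  if (p[3] < 0 && p[3] > -(rs + 4)) {
    if (sqrt(p[1]^2 + p[2]^2) < cavity_radius + 0.5) return(FALSE)
  }
  TRUE
}

# self-avoiding CA walk; returns n x 3 matrix or NULL on failure
try_chain_walk <- function(n_res, r_conf, planted, cavity_radius, shell_idx) {
  step <- 3.8
  min_sep <- 2.65            # clash floor before coordinate rounding
  rs <- cavity_radius + 2.6
  ok_point <- function(p, placed, skip_last = TRUE, margin = rs + 10) {
    if (sqrt(sum(p^2)) > r_conf) return(FALSE)
    if (planted && !trough_clear(p, rs, cavity_radius, margin)) return(FALSE)
    if (nrow(placed) > 0) {
      prior <- if (skip_last) placed[-nrow(placed), , drop = FALSE] else placed
      if (nrow(prior) > 0) {
        d2 <- (prior[, 1] - p[1])^2 + (prior[, 2] - p[2])^2 +
              (prior[, 3] - p[3])^2
        if (min(d2) < min_sep^2) return(FALSE)
      }
    }
    TRUE
  }
  # grow a segment with bounded backtracking out of dead ends
  grow <- function(from, n_steps, placed) {
    seg <- matrix(NA_real_, n_steps, 3)
    n0 <- nrow(placed)
    i <- 1
    fails <- 0
    while (i <= n_steps) {
      cur <- if (i == 1) from else seg[i - 1, ]
      # margin ramps up over the first residues leaving the wall anchor
      mar <- min(rs + 10, rs + 2 + 4 * (i - 1))
      done <- FALSE
      for (try in 1:100) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- cur + step * dir
        if (ok_point(cand, placed, margin = mar)) {
          seg[i, ] <- cand
          placed <- rbind(placed, cand)
          i <- i + 1
          done <- TRUE
          break
        }
      }
      if (!done) {
        fails <- fails + 1
        nback <- min(3L, i - 1L)
        if (fails > 200 || nback == 0) return(NULL)
        placed <- placed[seq_len(nrow(placed) - nback), , drop = FALSE]
        i <- i - nback
      }
    }
    list(seg = seg, placed = placed)
  }

  if (!planted) {
    start <- random_point_in_ball(0.5 * r_conf)
    placed <- matrix(start, 1, 3)
    g <- grow(start, n_res - 1, placed)
    if (is.null(g)) return(NULL)
    return(rbind(start, g$seg))
  }

  # planted: thread the wall residues over one deep spherical cap
  n_shell <- length(shell_idx)
  shell <- cap_walk(n_shell, rs, step, 2.65)
  if (is.null(shell)) return(NULL)
  placed <- shell
  ca <- matrix(NA_real_, n_res, 3)
  ca[shell_idx, ] <- shell
  n_pre <- shell_idx[1] - 1L
  if (n_pre > 0) {
    g <- grow(shell[1, ], n_pre, placed)
    if (is.null(g)) return(NULL)
    ca[rev(seq_len(n_pre)), ] <- g$seg   # grown backwards from residue 16
    placed <- g$placed
  }
  n_post <- n_res - shell_idx[n_shell]
  if (n_post > 0) {
    g <- grow(shell[n_shell, ], n_post, placed)
    if (is.null(g)) return(NULL)
    ca[shell_idx[n_shell] + seq_len(n_post), ] <- g$seg
  }
  ca
}


# chain walk on a spherical cap (polar angle <= ~120 deg) of radius rs
# around `center`, starting at the +z pole; `avoid` holds previously placed
# atoms the new wall must clear
cap_walk <- function(n, rs, step, min_sep, center = c(0, 0, 0),
                     avoid = NULL) {
  theta_max <- 2.4
  alpha <- 2 * asin(step / (2 * rs))
  u <- c(0, 0, 1)
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- center + rs * u
  clear <- function(cand, prior) {
    if (!is.null(avoid) && nrow(avoid) > 0) {
      d2 <- (avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2 +
            (avoid[, 3] - cand[3])^2
      if (min(d2) < min_sep^2) return(FALSE)
    }
    if (nrow(prior) > 0) {
      d2 <- (prior[, 1] - cand[1])^2 + (prior[, 2] - cand[2])^2 +
            (prior[, 3] - cand[3])^2
      if (min(d2) < min_sep^2) return(FALSE)
    }
    TRUE
  }
  if (!is.null(avoid) && !clear(pts[1, ], pts[0, , drop = FALSE]))
    return(NULL)
  for (i in seq_len(n)[-1]) {
    done <- FALSE
    for (try in 1:200) {
      t <- rnorm(3)
      t <- t - sum(t * u) * u
      nt <- sqrt(sum(t^2))
      if (nt < 1e-8) next
      t <- t / nt
      v <- cos(alpha) * u + sin(alpha) * t
      if (acos(max(-1, min(1, v[3]))) > theta_max) next
      cand <- center + rs * v
      if (!clear(cand, pts[seq_len(i - 2), , drop = FALSE])) next
      pts[i, ] <- cand
      u <- v
      done <- TRUE
      break
    }
    if (!done) return(NULL)
  }
  pts
}

random_point_in_ball <- function(r) {
  repeat {
    p <- runif(3, -r, r)
    if (sum(p^2) <= r^2) return(p)
  }
}

# place one pseudo side-chain atom per residue, 2.8 A from its CA
try_side_chains <- function(ca, r_conf, planted, cavity_radius, shell_idx) {
  n <- nrow(ca)
  bond <- 2.8
  min_sep <- 2.65
  cb <- matrix(NA_real_, n, 3)
  placed <- ca
  for (i in seq_len(n)) {
    if (i %in% shell_idx) {
      # wall side chains tilt into the bowl: the oxygens line the concave
      # face (deep vdW wells for poses inside) while the convex back of
      # the wall exposes only the sparse carbon backbone
      radial <- ca[i, ]
      radial <- radial / sqrt(sum(radial^2))
      tang <- rnorm(3)
      tang <- tang - sum(tang * radial) * radial
      tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
      base_dir <- "wall"                 # graded tilts handled below
    } else {
      nb <- ca[pmax(1, i - 1), ] + ca[pmin(n, i + 1), ]
      base_dir <- ca[i, ] - nb / 2
      nbd <- sqrt(sum(base_dir^2))
      base_dir <- if (nbd > 1e-6) base_dir / nbd else c(0, 0, 1)
    }
    done <- FALSE
    for (try in 1:60) {
      dir <- if (identical(base_dir, "wall")) {
        # graded tilts: strongly inward first, backing off towards (and
        # past) the tangent plane as retries accumulate
        tilt <- c(-0.45, -0.25, 0, 0.3, 0.6)[min(ceiling(try / 12), 5)]
        tg <- if (try %% 12 == 1) tang else {
          t2 <- rnorm(3); t2 <- t2 - sum(t2 * radial) * radial
          t2 / max(sqrt(sum(t2^2)), 1e-9)
        }
        d <- tg + tilt * radial
        d / sqrt(sum(d^2))
      } else if (try == 1) base_dir else {
        d <- base_dir + 0.9 * rnorm(3); d / sqrt(sum(d^2))
      }
      cand <- ca[i, ] + bond * dir
      if (planted && !(i %in% shell_idx) &&
          !trough_clear(cand, cavity_radius + 2.6, cavity_radius)) next
      if (planted && (i %in% shell_idx) &&
          sqrt(sum(cand^2)) < cavity_radius + 1.1) next
      if (sqrt(sum(cand^2)) > r_conf + 3) next
      d2 <- (placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2 +
            (placed[, 3] - cand[3])^2
      d2[i] <- Inf                       # own CA is bonded, exempt
      if (min(d2) < min_sep^2) next
      if (sqrt(sum((cand - ca[i, ])^2)) < 2.6) next  # keep bond >= clash floor
      cb[i, ] <- cand
      placed <- rbind(placed, cand)
      done <- TRUE
      break
    }
    if (!done) return(NULL)
  }
  cb
}

# curated fragment SMILES with molecular weights of the pH-7.4 species
# (verified against RDKit at build time)
TOY_FRAGMENTS <- data.frame(
  rbind(
    c("benzene", "c1ccccc1", 78.114, 0),
    c("toluene", "Cc1ccccc1", 92.141, 0),
    c("phenol", "Oc1ccccc1", 94.113, 0),
    c("anisole", "COc1ccccc1", 108.140, 0),
    c("pyridine", "c1ccncc1", 79.102, 0),
    c("pyrrole", "c1cc[nH]c1", 67.091, 0),
    c("furan", "c1ccoc1", 68.075, 0),
    c("thiophene", "c1ccsc1", 84.143, 0),
    c("indole", "c1cc2ccccc2[nH]1", 117.151, 0),
    c("naphthalene", "c1ccc2ccccc2c1", 128.174, 0),
    c("quinoline", "c1ccc2ncccc2c1", 129.162, 0),
    c("aniline", "Nc1ccccc1", 93.129, 0),
    c("benzamide", "NC(=O)c1ccccc1", 121.139, 0),
    c("acetophenone", "CC(=O)c1ccccc1", 120.151, 0),
    c("methyl_benzoate", "COC(=O)c1ccccc1", 136.150, 0),
    c("benzonitrile", "N#Cc1ccccc1", 103.124, 0),
    c("cyclohexanol", "OC1CCCCC1", 100.161, 0),
    c("cyclohexanone", "O=C1CCCCC1", 98.145, 0),
    c("tetrahydrofuran", "C1CCOC1", 72.107, 0),
    c("styrene", "C=Cc1ccccc1", 104.152, 0),
    c("biphenyl", "c1ccc(cc1)-c1ccccc1", 154.212, 0),
    c("benzaldehyde", "O=Cc1ccccc1", 106.124, 0),
    c("p_cresol", "Cc1ccc(O)cc1", 108.140, 0),
    c("resorcinol", "Oc1cccc(O)c1", 110.112, 0),
    c("veratrole", "COc1ccccc1OC", 138.166, 0),
    c("acetanilide", "CC(=O)Nc1ccccc1", 135.166, 0),
    c("n_methylbenzamide", "CNC(=O)c1ccccc1", 135.166, 0),
    c("imidazole", "c1c[nH]cn1", 68.079, 0),
    c("pyrimidine", "c1cncnc1", 80.090, 0),
    c("indane", "C1Cc2ccccc2C1", 118.179, 0),
    c("tetralin", "C1CCc2ccccc2C1", 132.206, 0),
    c("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", 194.194, 0),
    c("adamantane", "C1C2CC3CC1CC(C2)C3", 136.238, 0),
    c("isobutylbenzene", "CC(C)Cc1ccccc1", 134.222, 0),
    c("ethyl_benzoate", "CCOC(=O)c1ccccc1", 150.177, 0),
    c("morpholine", "C1COCCN1", 88.130, 1),
    c("piperidine", "C1CCNCC1", 86.158, 1),
    c("pyrrolidine", "C1CCNC1", 72.131, 1),
    c("benzylamine", "NCc1ccccc1", 108.164, 1),
    c("phenethylamine", "NCCc1ccccc1", 122.191, 1),
    c("cyclohexylamine", "NC1CCCCC1", 100.185, 1),
    c("benzoic_acid", "OC(=O)c1ccccc1", 121.115, -1),
    c("phenylacetic_acid", "OC(=O)Cc1ccccc1", 135.142, -1),
    c("cyclohexanecarboxylic_acid", "OC(=O)C1CCCCC1", 127.163, -1),
    c("p_toluic_acid", "Cc1ccc(C(=O)O)cc1", 135.142, -1)
  ), stringsAsFactors = FALSE)
names(TOY_FRAGMENTS) <- c("name", "smiles", "mw", "formal_charge")
TOY_FRAGMENTS$mw <- as.numeric(TOY_FRAGMENTS$mw)
TOY_FRAGMENTS$formal_charge <- as.integer(TOY_FRAGMENTS$formal_charge)

#' Generate a toy fragment-like SMILES library
#'
#' Samples (with replacement) from a curated list of valid fragment SMILES,
#' honouring a requested charged fraction (within one molecule) and a
#' molecular-weight window; a desk-scale stand-in for a commercial
#' fragment-like vendor catalogue.  Identifiers are `lig001`, `lig002`, ...
#' in file order.
#'
#' @param n number of records (>= 1).
#' @param seed integer seed; the same seed reproduces the file byte for
#'   byte.
#' @param charged_fraction target fraction of charged (pH 7.4) molecules.
#' @param mw_range length-2 Da window; entries outside it are never drawn.
#' @param path output SMILES file (one `SMILES id` line per record).
#' @return `path` invisibly, with the sampled table as attribute `table`.
#' @export
generate_toy_library <- function(n, seed = 1, charged_fraction = 0.2,
                                 mw_range = c(60, 325),
                                 path = tempfile(fileext = ".smi")) {
  stopifnot(n >= 1, charged_fraction >= 0, charged_fraction <= 1)
  pool <- TOY_FRAGMENTS[TOY_FRAGMENTS$mw >= mw_range[1] &
                        TOY_FRAGMENTS$mw <= mw_range[2], , drop = FALSE]
  ch <- pool[pool$formal_charge != 0, , drop = FALSE]
  ne <- pool[pool$formal_charge == 0, , drop = FALSE]
  n_ch <- round(n * charged_fraction)
  if (n_ch > 0 && nrow(ch) == 0)
    stop("no charged fragments available in the requested MW range")
  if (n - n_ch > 0 && nrow(ne) == 0)
    stop("no neutral fragments available in the requested MW range")
  with_local_seed(seed, {
    rows <- rbind(
      if (n_ch > 0) ch[sample.int(nrow(ch), n_ch, replace = TRUE), ],
      if (n - n_ch > 0) ne[sample.int(nrow(ne), n - n_ch, replace = TRUE), ])
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    rows$id <- sprintf("lig%03d", seq_len(nrow(rows)))
    atomic_write_lines(paste(rows$smiles, rows$id), path)
    rownames(rows) <- NULL
    invisible(structure(path, table = rows))
  })
}

#' SMILES of the planted complementary binder
#'
#' Benzylpiperazine: at pH 7.4 both aliphatic ring nitrogens protonate, so
#' the molecule carries +2 and pairs an aromatic anchor with a doubly
#' charged head -- shape- and charge-complementary to the oxygen-lined
#' concave cleft planted by [generate_disordered_ensemble()].
#'
#' @return a SMILES string.
#' @export
planted_binder_smiles <- function() "C(c1ccccc1)N1CCNCC1"
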