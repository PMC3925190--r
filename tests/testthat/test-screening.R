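test_that("library reading computes MW, charge and conformers via the chemistry backend", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene",
               "Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine",
               "CC(C)CCCC(C)C1CCC2C1(CCC3C2CC=C4C3(CCC(C4)O)C)C sterol"),
             path)
  ligs <- read_library(path, seed = 1)
  expect_length(ligs, 3)
  ids <- vapply(ligs, `[[`, "", "ligand_id")
  expect_identical(ids, c("benzene", "caffeine", "sterol"))
  for (lig in ligs) {
    # MW agrees with independent atomic-mass summation to 0.01 Da
    expect_equal(lig$mol_weight, mw_oracle(lig), tolerance = 0.01)
    expect_equal(nrow(lig$conformers[[1]]), lig$heavy_atom_count)
    expect_false(any(lig$params$element == "H"))
  }
  expect_equal(ligs[[1]]$mol_weight, 78.11, tolerance = 0.01)
  expect_equal(ligs[[2]]$mol_weight, 194.19, tolerance = 0.01)
  expect_gt(ligs[[3]]$mol_weight, 325)
  # neutral molecules are classed neutral
  expect_identical(ligs[[1]]$charge_class, "neutral")
})

test_that("malformed and empty libraries are handled as contracts say", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 ok1", "not_a_smiles bad", "CCO ok2"), path)
  ligs <- read_library(path, seed = 1)
  expect_length(ligs, 2)
  expect_equal(attr(ligs, "n_skipped"), 1)
  writeLines(character(0), path)
  expect_error(read_library(path, seed = 1), "no valid molecules")
})

test_that("pH 7.4 protonation drives the charge classes", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("NCc1ccccc1 amine", "OC(=O)c1ccccc1 acid",
               "Nc1ccccc1 aniline"), path)
  ligs <- read_library(path, seed = 1)
  cls <- setNames(vapply(ligs, `[[`, "", "charge_class"),
                  vapply(ligs, `[[`, "", "ligand_id"))
  fc <- setNames(vapply(ligs, `[[`, 1L, "formal_charge"),
                 vapply(ligs, `[[`, "", "ligand_id"))
  expect_equal(fc[["amine"]], 1L)     # aliphatic amine protonated
  expect_equal(fc[["acid"]], -1L)     # carboxylic acid deprotonated
  expect_equal(fc[["aniline"]], 0L)   # aromatic amine untouched
  expect_identical(unname(cls), c("charged", "charged", "neutral"))
})

test_that("molecular-weight filtering keeps strictly-below survivors in order", {
  mk <- function(id, mw) structure(list(ligand_id = id, mol_weight = mw),
                                   class = "Ligand")
  ligs <- list(mk("a", 78.11), mk("b", 194.19), mk("c", 386.65))
  kept <- filter_library(ligs, mw_max = 325)
  expect_length(kept, 2)
  expect_identical(vapply(kept, `[[`, "", "ligand_id"), c("a", "b"))
  expect_length(filter_library(ligs, mw_max = 0), 0)
  expect_length(filter_library(ligs, mw_max = Inf), 3)
  # boundary is strict
  expect_length(filter_library(list(mk("x", 325)), 325), 0)
})

test_that("within-pocket ranking orders by energy and computes L_Re exactly", {
  mk <- function(id, e_total, heavy, cls = "neutral") {
    list(ligand = structure(list(ligand_id = id, heavy_atom_count = heavy,
                                 charge_class = cls), class = "Ligand"),
         pose = list(energy = list(e_vdw = e_total, e_elec = 0, e_solv = 0,
                                   e_total = e_total)))
  }
  res <- list(mk("lig1", -5, 5), mk("lig2", -9, 9), mk("lig3", -7, 7))
  hits <- rank_hits(res, "p1")
  expect_identical(hits$ligand_id, c("lig2", "lig3", "lig1"))
  expect_identical(hits$e_rank, 1:3)
  # l_re invariant holds exactly for every hit
  expect_identical(hits$l_re, hits$e_total / hits$heavy_atom_count)
  expect_equal(rank_hits(list(mk("x", -8, 8)), "p")$l_re, -1)
  # e_rank is 1..n with no gaps on random tables; ties break by ligand id
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    res <- lapply(seq_len(n), function(i)
      mk(sprintf("m%02d", i), sample(c(-8, -6, -4), 1), sample(4:9, 1)))
    h <- rank_hits(res, "p")
    expect_identical(h$e_rank, seq_len(n))
    expect_identical(order(h$e_total, h$ligand_id), seq_len(n))
  }
  # empty input yields a schema-valid empty table
  empty <- rank_hits(list(), "p")
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("ligand_id", "pocket_id", "e_total", "e_rank", "l_re",
                    "charge_class") %in% names(empty)))
})

test_that("hit selection applies thresholds, caps and cross-pocket dedup", {
  mk_table <- function(n, pocket) {
    data.frame(ligand_id = sprintf("m%02d", seq_len(n)), pocket_id = pocket,
               e_vdw = 0, e_elec = 0, e_solv = 0,
               e_total = -runif(n, 1, 12), e_rank = NA_integer_,
               l_re = NA_real_, charge_class = "neutral",
               heavy_atom_count = sample(4:10, n, replace = TRUE))
  }
  set.seed(72)
  tab <- mk_table(15, "p1")
  tab <- tab[order(tab$e_total), ]; tab$e_rank <- 1:15
  tab$l_re <- tab$e_total / tab$heavy_atom_count
  # impossible thresholds -> empty
  expect_identical(nrow(select_hits(tab, e_total_max = -Inf)), 0L)
  # loosening e_total_max never decreases the hit count
  cuts <- seq(-12, 0, by = 1)
  counts <- vapply(cuts, function(ct)
    nrow(select_hits(tab, e_total_max = ct, l_re_max = 0,
                     per_pocket_cap = 100)), 1L)
  expect_true(all(diff(counts) >= 0))
  # per-pocket cap truncates to the best
  capped <- select_hits(tab, e_total_max = 0, l_re_max = 0, per_pocket_cap = 4)
  expect_lte(nrow(capped), 4)
  expect_true(all(capped$e_rank <= 4))
  # a ligand passing in two pockets keeps its lower-energy pocket only
  two <- rbind(
    data.frame(ligand_id = "dup", pocket_id = "p1", e_vdw = 0, e_elec = 0,
               e_solv = 0, e_total = -6, e_rank = 1L, l_re = -1,
               charge_class = "neutral", heavy_atom_count = 6),
    data.frame(ligand_id = "dup", pocket_id = "p2", e_vdw = 0, e_elec = 0,
               e_solv = 0, e_total = -9, e_rank = 1L, l_re = -1.5,
               charge_class = "neutral", heavy_atom_count = 6))
  sel <- select_hits(two, e_total_max = 0, l_re_max = 0)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$pocket_id, "p2")
})

test_that("geometrically impossible ligands and empty pocket sets behave gracefully", {
  set.seed(73)
  conf <- random_conformer(20, spread = 8)
  pocket <- structure(list(pocket_id = "p1", model_id = 1L,
                           hotspot_ranks = 1:2, centroid = c(0, 0, 0),
                           lining_residues = 1:3, max_seq_separation = 2L,
                           long_range_flag = FALSE,
                           bbox = list(lo = c(-1, -1, -1), hi = c(1, 1, 1))),
                      class = "Pocket")
  # a ligand wider than the search box yields an empty pose list
  big <- structure(list(ligand_id = "big", heavy_atom_count = 2,
                        charge_class = "neutral",
                        params = lig_params(2),
                        torsions = list(),
                        conformers = list(rbind(c(0, 0, 0), c(40, 0, 0)))),
                   class = "Ligand")
  expect_warning(poses <- dock_ligand(conf, pocket, big, box_margin = 1),
                 "larger than the search box")
  expect_length(poses, 0)
  # pocket/conformer model mismatch is an error
  pocket2 <- pocket; pocket2$model_id <- 99L
  expect_error(dock_ligand(conf, pocket2, big), "belongs to model")
  # screening a library against zero pockets -> empty, schema-valid report
  out <- screen_pockets(list("1" = conf), list(), list(big))
  expect_identical(nrow(out), 0L)
  expect_true(all(c("ligand_id", "e_total", "e_rank", "l_re") %in% names(out)))
})

test_that("docking the same ligand twice is deterministic", {
  set.seed(74)
  conf <- random_conformer(25, spread = 6)
  probes <- cached_probes()
  eth <- probes[[which(vapply(probes, `[[`, "", "ligand_id") == "ethanol")]]
  p1 <- dock_probe(conf, eth, grid_spacing = 3, n_orientations = 6, top_k = 3,
                   seed = 5)
  p2 <- dock_probe(conf, eth, grid_spacing = 3, n_orientations = 6, top_k = 3,
                   seed = 5)
  expect_equal(p1[[1]]$energy$e_total, p2[[1]]$energy$e_total, tolerance = 1e-12)
  expect_equal(p1[[1]]$coords, p2[[1]]$coords, tolerance = 1e-12)
})
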