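test_that("signal-peptide removal preserves 1-based bookkeeping", {
  full <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")  # 100 aa
  expect_equal(mature_sequence(full)$residues, full)
  m <- mature_sequence(full, c(1, 20))
  expect_equal(nchar(m$residues), 80L)
  expect_equal(m$offset, 20L)
  expect_equal(paste0(m$signal, m$residues), full)
  # an 84-residue precursor with a 1-20 signal leaves 64 residues
  pre84 <- substr(full, 1, 84)
  expect_equal(nchar(mature_sequence(pre84, c(1, 20))$residues), 64L)
  expect_error(mature_sequence("ACDEF", c(1, 5)), "whole sequence")
  expect_error(mature_sequence("ACDEF", c(2, 3)), "start at 1")
  expect_error(mature_sequence("ACDEF", c(1, 9)), "within the sequence")
  # residue counts are conserved across the split
  cm <- composition(m$residues) * nchar(m$residues) / 100
  cs <- composition(m$signal) * nchar(m$signal) / 100
  cf <- composition(full) * nchar(full) / 100
  expect_equal(cm + cs, cf, tolerance = 1e-9)
})

test_that("net charge follows Henderson-Hasselbalch group by group", {
  # one basic group with pKa 9.0 at pH 7.4: 1/(1 + 10^-1.6)
  z <- net_charge("GKG", pH = 7.4, pka = pka_set(K = 9.0),
                  include_termini = FALSE)
  expect_equal(z, 1 / (1 + 10^(-1.6)), tolerance = 1e-12)
  # low-pH limit: + (n_H + n_K + n_R + 1)
  expect_equal(net_charge("HKRDE", pH = 1e-3), 4, tolerance = 0.01)
  # strictly decreasing in pH, for arbitrary sequences
  withr::with_seed(11, {
    for (i in 1:5) {
      seqs <- paste(sample(c("A", "R", "N", "D", "C", "E", "H", "K",
                             "Y", "G"), 30, replace = TRUE),
                    collapse = "")
      z <- net_charge(seqs, pH = seq(0.5, 13.5, by = 0.25))
      expect_true(all(diff(z) < 0))
    }
  })
  expect_error(net_charge("AXA"), "unknown residue")
  expect_equal(net_charge("AXA", strict = FALSE),
               net_charge("AA"), tolerance = 1e-12)
  expect_error(net_charge("AA", pH = 15), "pH")
})

test_that("the isoelectric point is the unique zero of the charge curve", {
  withr::with_seed(7, {
    for (i in 1:5) {
      s <- paste(sample(AA <- c("A", "R", "D", "C", "E", "H", "K", "Y",
                                "G", "S"), 40, replace = TRUE),
                 collapse = "")
      pi_b <- isoelectric_point(s)
      expect_lt(abs(net_charge(s, pi_b)), 0.01)
      # dense-grid oracle
      grid <- seq(0.01, 13.99, by = 0.002)
      zg <- net_charge(s, grid)
      expect_lt(abs(pi_b - grid[which.min(abs(zg))]), 0.01)
    }
  })
  # basic-only sequence without termini has no zero crossing
  expect_error(isoelectric_point("GKGKG", include_termini = FALSE),
               "undefined")
})

test_that("composition is a shuffle-invariant percentage", {
  co <- composition("AAAA")
  expect_equal(unname(co[["A"]]), 100)
  expect_equal(sum(co), 100, tolerance = 1e-9)
  all20 <- composition("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(all20 - 5) < 1e-9))
  s <- "MKWVTFISLLLLFSSAYS"
  sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(composition(s), composition(sh))
  expect_error(composition(""), "non-empty")
})

test_that("extinction coefficient and Beer-Lambert concentration compose", {
  expect_equal(unname(extinction_coefficient("WYYCC",
                                             cystines_paired = TRUE)),
               5500 + 2 * 1490 + 125)
  expect_equal(unname(extinction_coefficient("WYYCC")), 5500 + 2 * 1490)
  expect_equal(peptide_concentration(0, 8605)$molar, 0)
  c1 <- peptide_concentration(0.4, 8605, molar_mass = 9000)
  c2 <- peptide_concentration(0.8, 8605, molar_mass = 9000)
  expect_equal(c2$molar, 2 * c1$molar)
  expect_equal(c1$molar, 0.4 / 8605, tolerance = 1e-12)
  expect_equal(c1$mg_per_ml, 0.4 / 8605 * 9000, tolerance = 1e-12)
  expect_error(peptide_concentration(0.4, 0), "chromophore")
})

test_that("disulfide detection applies the distance window and greedy pairing", {
  mk <- function(res, x, y = 0, z = 0)
    data.frame(residue_name = "CYS", residue_index = res,
               atom_name = "SG", x = x, y = y, z = z)
  expect_equal(nrow(detect_disulfides(rbind(mk(13, 0), mk(87, 2.05)))), 1L)
  expect_equal(nrow(detect_disulfides(rbind(mk(13, 0), mk(87, 3.5)))), 0L)
  # three mutually in-range cysteines: greedy keeps only the closest pair,
  # which the brute-force matching oracle confirms is optimal here
  tri <- rbind(mk(1, 0), mk(2, 2.1), mk(3, x = 1.05, y = 2.0))
  got <- detect_disulfides(tri)
  d <- as.matrix(stats::dist(tri[, c("x", "y", "z")]))
  cand <- data.frame(residue_a = c(1, 1, 2), residue_b = c(2, 3, 3),
                     distance = c(d[1, 2], d[1, 3], d[2, 3]))
  cand <- cand[cand$distance >= 2 & cand$distance <= 3, ]
  want <- oracle_disulfide_matching(cand)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$residue_a, want$residue_a)
  expect_equal(got$residue_b, want$residue_b)
  # rigid-body invariance: rotate + translate all coordinates
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(tri[, c("x", "y", "z")]) %*% R +
    matrix(rep(c(5, -3, 2), each = 3), 3, 3)
  tri2 <- tri
  tri2[, c("x", "y", "z")] <- xyz
  got2 <- detect_disulfides(tri2)
  expect_equal(got2[, c("residue_a", "residue_b")],
               got[, c("residue_a", "residue_b")])
  expect_equal(got2$distance, got$distance, tolerance = 1e-9)
  # cysteine without SG atom is skipped with a warning
  noSG <- rbind(mk(13, 0), mk(87, 2.05),
                data.frame(residue_name = "CYS", residue_index = 99,
                           atom_name = "CB", x = 9, y = 9, z = 9))
  expect_warning(res <- detect_disulfides(noSG), "99")
  expect_equal(nrow(res), 1L)
})

test_that("candidate screening reproduces the published shortlist", {
  path <- system.file("extdata", "candidate_scores.csv",
                      package = "helmamp")
  rows <- utils::read.csv(path)
  scr <- screen_candidates(rows)
  expect_equal(sum(scr$retained), 5L)
  hmet <- scr[scr$id == "Hmet", ]
  expect_true(hmet$ampir_flag && hmet$multipep_flag)
  expect_false(hmet$camp_flag)   # no significant similarity to known AMPs
  tscp <- scr[scr$id == "Tscp", ]
  expect_true(tscp$ampir_flag)
  expect_false(tscp$multipep_flag || tscp$camp_flag)  # ampir-only
  # an all-zero row is not retained
  zero <- data.frame(id = "none", length = 50, ampir_precursor = 0,
                     ampir_mature = 0, multipep_antimicrobial = 0,
                     multipep_antibacterial = 0, camp_evalue = NA)
  expect_false(screen_candidates(zero)$retained)
  # long sequences must not carry MultiPep scores
  bad <- data.frame(id = "x", length = 250, ampir_precursor = 0.9,
                    multipep_antimicrobial = 0.8)
  expect_error(screen_candidates(bad), "cannot carry")
})

test_that("raising any screening threshold never grows the retained set", {
  withr::with_seed(3, {
    tbl <- data.frame(
      id = paste0("s", 1:40),
      length = sample(c(60, 120, 250), 40, replace = TRUE),
      ampir_precursor = round(stats::runif(40), 3),
      ampir_mature = round(stats::runif(40), 3),
      multipep_antimicrobial = NA_real_,
      multipep_antibacterial = NA_real_,
      camp_evalue = 10^-stats::runif(40, 0, 10)
    )
    short <- tbl$length < 200
    tbl$multipep_antimicrobial[short] <- round(stats::runif(sum(short)), 3)
    tbl$multipep_antibacterial[short] <- round(stats::runif(sum(short)), 3)
    prev <- NULL
    for (th in c(0.3, 0.5, 0.7, 0.9)) {
      kept <- tbl$id[screen_candidates(tbl, ampir_threshold = th,
                                       multipep_threshold = th,
                                       camp_evalue_max = 1e-5)$retained]
      if (!is.null(prev)) expect_true(all(kept %in% prev))
      prev <- kept
    }
    for (ce in c(1e-2, 1e-5, 1e-8)) {
      kept <- tbl$id[screen_candidates(tbl,
                                       camp_evalue_max = ce)$retained]
      if (exists("prev_ce")) expect_true(all(kept %in% prev_ce))
      prev_ce <- kept
    }
  })
})

test_that("FASTA and PDB readers feed the characterisation functions", {
  fa <- system.file("extdata", "synthetic_peptides.fasta",
                    package = "helmamp")
  peps <- read_peptides(fa)
  expect_equal(nrow(peps), 2L)
  expect_equal(peps$id, c("synthetic_cationic", "synthetic_anionic"))
  expect_gt(net_charge(peps$residues[1], 7.4), 0)
  expect_lt(net_charge(peps$residues[2], 7.4), 0)
  expect_gt(isoelectric_point(peps$residues[1]), 7)
  expect_lt(isoelectric_point(peps$residues[2]), 7)
  # minimal PDB with two bonded cysteines
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  SG  CYS A%4d    %8.3f%8.3f%8.3f  1.00  0.00           S",
            1L, 13L, 0, 0, 0),
    sprintf("ATOM  %5d  SG  CYS A%4d    %8.3f%8.3f%8.3f  1.00  0.00           S",
            2L, 87L, 2.05, 0, 0),
    "END"), pdb)
  atoms <- read_structure_atoms(pdb)
  expect_equal(nrow(atoms), 2L)
  bonds <- detect_disulfides(atoms)
  expect_equal(bonds$residue_a, 13)
  expect_equal(bonds$residue_b, 87)
  expect_equal(bonds$distance, 2.05, tolerance = 1e-6)
})

test_that("pKa presets validate their groups", {
  pk <- pka_set("bjellqvist")
  expect_equal(unname(pk[["C"]]), 8.3)
  pk2 <- pka_set("bjellqvist", C = 9.0)
  expect_equal(unname(pk2[["C"]]), 9.0)
  expect_error(pka_set(Z = 3), "unknown pKa group")
  expect_error(pka_set(C = 15), "pKa values")
  expect_lt(isoelectric_point("ACDC", pka = pka_set("emboss")) -
              isoelectric_point("ACDC", pka = pka_set("emboss")), 1e-12)
})
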