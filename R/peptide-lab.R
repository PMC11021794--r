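AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "K", "L", "M",
         "F", "P", "S", "T", "W", "Y", "V")

.check_residues <- function(residues, strict = TRUE) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("`residues` must be a non-empty one-letter amino-acid string.",
         call. = FALSE)
  aa <- strsplit(toupper(residues), "")[[1L]]
  allowed <- if (strict) AA1 else c(AA1, "X")
  bad <- setdiff(unique(aa), allowed)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         if (strict) " (set strict = FALSE to tolerate X)", call. = FALSE)
  aa
}

#' Ionizable-group pKa tables
#'
#' Named pKa presets for the groups driving peptide charge: the free
#' N- and C-termini and the side chains of Asp, Glu, Cys, Tyr, His, Lys
#' and Arg. `"bjellqvist"` (default) is the table used by most pI
#' calculators; `"emboss"` is the EMBOSS iep set. Individual values can be
#' overridden.
#'
#' @param preset `"bjellqvist"` or `"emboss"`.
#' @param ... Named overrides, e.g. `C = 9.0`.
#' @return Named numeric vector of class `pka_set` with elements `Nterm`,
#'   `Cterm`, `D`, `E`, `C`, `Y`, `H`, `K`, `R`.
#' @export
pka_set <- function(preset = c("bjellqvist", "emboss"), ...) {
  preset <- match.arg(preset)
  pk <- switch(preset,
    bjellqvist = c(Nterm = 9.69, Cterm = 2.34, D = 3.65, E = 4.25,
                   C = 8.3, Y = 10.07, H = 6.0, K = 10.53, R = 12.48),
    emboss = c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5,
               Y = 10.1, H = 6.5, K = 10.8, R = 12.5)
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(pk))
    if (length(bad)) stop("unknown pKa group(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    pk[names(over)] <- over
  }
  if (any(pk <= 0 | pk >= 14))
    stop("pKa values must lie in (0, 14).", call. = FALSE)
  class(pk) <- c("pka_set", "numeric")
  pk
}

#' Remove a signal peptide from a precursor sequence
#'
#' Secreted peptides carry an N-terminal signal peptide that is cleaved
#' before the mature peptide acts; physicochemical properties are usually
#' reported for the mature form. `signal_range` is 1-based inclusive.
#'
#' @param residues One-letter amino-acid string.
#' @param signal_range `c(start, end)`, 1-based inclusive; `NULL` returns
#'   the sequence unchanged.
#' @return A list with `residues` (mature sequence), `offset` (original
#'   position of the first mature residue minus one, preserving 1-based
#'   bookkeeping) and `signal` (the removed segment, `""` if none).
#' @examples
#' mature_sequence(strrep("M", 10), c(1, 4))
#' @export
mature_sequence <- function(residues, signal_range = NULL) {
  aa <- .check_residues(residues, strict = FALSE)
  n <- length(aa)
  if (is.null(signal_range))
    return(list(residues = residues, offset = 0L, signal = ""))
  s <- as.integer(signal_range[1L]); e <- as.integer(signal_range[2L])
  if (s < 1L || e > n || s > e)
    stop("`signal_range` must lie within the sequence.", call. = FALSE)
  if (s == 1L && e == n)
    stop("`signal_range` covers the whole sequence; no mature peptide ",
         "remains.", call. = FALSE)
  if (s != 1L)
    stop("signal peptides are N-terminal; `signal_range` must start at 1.",
         call. = FALSE)
  list(residues = paste(aa[(e + 1L):n], collapse = ""), offset = e,
       signal = paste(aa[s:e], collapse = ""))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch partial charges summed over ionizable groups:
#' basic groups (N-terminus, His, Lys, Arg) contribute
#' `+n / (1 + 10^(pH - pKa))`, acidic groups (C-terminus, Asp, Glu, Cys,
#' Tyr) contribute `-n / (1 + 10^(pKa - pH))`.
#'
#' @param residues One-letter amino-acid string.
#' @param pH pH value(s) in (0, 14); vectorised.
#' @param pka A [pka_set()].
#' @param include_termini Include the free terminal groups (disable for
#'   blocked/cyclic peptides).
#' @param strict Error on letters outside the 20-residue alphabet
#'   (`FALSE` additionally tolerates `X`, treated as non-ionizable).
#' @return Net charge in elementary charges (same length as `pH`).
#' @examples
#' net_charge("KRK", pH = 7.4)
#' @export
net_charge <- function(residues, pH = 7.4, pka = pka_set(),
                       include_termini = TRUE, strict = TRUE) {
  aa <- .check_residues(residues, strict = strict)
  if (any(pH <= 0 | pH >= 14)) stop("`pH` must be in (0, 14).",
                                    call. = FALSE)
  cnt <- table(factor(aa, levels = AA1))
  n_basic <- c(H = cnt[["H"]], K = cnt[["K"]], R = cnt[["R"]])
  n_acid <- c(D = cnt[["D"]], E = cnt[["E"]], C = cnt[["C"]],
              Y = cnt[["Y"]])
  if (include_termini) {
    n_basic <- c(Nterm = 1, n_basic)
    n_acid <- c(Cterm = 1, n_acid)
  }
  vapply(pH, function(ph) {
    pos <- sum(n_basic / (1 + 10^(ph - pka[names(n_basic)])))
    neg <- sum(n_acid / (1 + 10^(pka[names(n_acid)] - ph)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point of a peptide
#'
#' The pH at which [net_charge()] is zero. Net charge is strictly
#' decreasing in pH, so the root is unique; it is found by bisection
#' ([stats::uniroot()]) on (0, 14) to a tolerance of 0.01 pH units.
#'
#' @inheritParams net_charge
#' @param tol Absolute tolerance on the returned pH.
#' @return The pI.
#' @examples
#' isoelectric_point("ACDEFGHIKLMNPQRSTVWY")
#' @export
isoelectric_point <- function(residues, pka = pka_set(),
                              include_termini = TRUE, strict = TRUE,
                              tol = 0.01) {
  f <- function(ph) net_charge(residues, ph, pka, include_termini, strict)
  lo <- 1e-4; hi <- 14 - 1e-4
  if (f(lo) <= 0 || f(hi) >= 0)
    stop("pI undefined: the sequence has no ionizable group of one sign ",
         "(net charge does not change sign on (0, 14)).", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = tol / 10)$root
}

#' Amino-acid composition of a peptide
#'
#' Percent of each of the 20 standard residues (zeros included); sums to
#' 100.
#'
#' @inheritParams net_charge
#' @return Named numeric vector of percentages over the 20 residues.
#' @examples
#' composition("AAAA")
#' @export
composition <- function(residues, strict = TRUE) {
  aa <- .check_residues(residues, strict = strict)
  aa <- aa[aa %in% AA1]
  if (!length(aa)) stop("no standard residues in sequence.", call. = FALSE)
  100 * table(factor(aa, levels = AA1)) / length(aa)
}

#' Theoretical molar extinction coefficient at 280 nm
#'
#' `epsilon = 5500 * n_Trp + 1490 * n_Tyr + 125 * n_cystine`
#' (M^-1 cm^-1); the cystine term counts disulfide pairs and applies only
#' when the cysteines are oxidised (`cystines_paired = TRUE`, contributing
#' `floor(n_Cys / 2)` pairs).
#'
#' @inheritParams net_charge
#' @param cystines_paired Are cysteines disulfide-bonded?
#' @return Extinction coefficient (M^-1 cm^-1).
#' @examples
#' extinction_coefficient("WYYCC", cystines_paired = TRUE)  # 8605
#' @export
extinction_coefficient <- function(residues, cystines_paired = FALSE,
                                   strict = TRUE) {
  aa <- .check_residues(residues, strict = strict)
  cnt <- table(factor(aa, levels = AA1))
  5500 * cnt[["W"]] + 1490 * cnt[["Y"]] +
    if (cystines_paired) 125 * (cnt[["C"]] %/% 2) else 0
}

#' Peptide concentration from A280 via the Beer-Lambert law
#'
#' `c_molar = A280 / (epsilon * path_cm)`; the mass concentration is
#' `c_molar * molar_mass` when a molar mass is supplied.
#'
#' @param a280 Absorbance at 280 nm (>= 0).
#' @param epsilon Molar extinction coefficient (M^-1 cm^-1, > 0).
#' @param path_cm Optical path length (cm).
#' @param molar_mass Optional molar mass (g/mol) for the mass
#'   concentration.
#' @return A list with `molar` (mol/L) and `mg_per_ml` (`NA` without
#'   `molar_mass`).
#' @examples
#' peptide_concentration(0.5, epsilon = 8605, molar_mass = 9000)
#' @export
peptide_concentration <- function(a280, epsilon, path_cm = 1,
                                  molar_mass = NULL) {
  if (any(a280 < 0)) stop("`a280` must be >= 0.", call. = FALSE)
  if (path_cm <= 0) stop("`path_cm` must be > 0.", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("concentration undefined: the peptide has no chromophore ",
         "(epsilon must be > 0).", call. = FALSE)
  molar <- a280 / (epsilon * path_cm)
  list(molar = molar,
       mg_per_ml = if (is.null(molar_mass)) NA_real_ else
         molar * molar_mass)
}

#' Read ATOM records from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning a tidy atom table
#' (first model, first alternate location) in the schema consumed by
#' [detect_disulfides()].
#'
#' @param path Path to a PDB file.
#' @return data.frame with `residue_name`, `residue_index` (1-based author
#'   numbering), `atom_name`, `chain`, `x`, `y`, `z` (Å).
#' @export
read_structure_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A")), ,
           drop = FALSE]
  data.frame(residue_name = at$resid, residue_index = at$resno,
             atom_name = at$elety, chain = at$chain,
             x = at$x, y = at$y, z = at$z)
}

#' Detect disulfide bonds from cysteine sulfur geometry
#'
#' Pairs of cysteine SG atoms whose Euclidean distance lies in
#' `range` (default 2.0-3.0 Å) are considered likely disulfide bonds.
#' Conflicts are resolved greedily by ascending distance so that each
#' cysteine joins at most one bond. Cysteines lacking an SG atom are
#' skipped with a warning. The result is invariant under rigid-body
#' transformation of the coordinates.
#'
#' @param atoms Atom table ([read_structure_atoms()] schema).
#' @param range `c(min, max)` SG-SG distance window (Å).
#' @return data.frame with `residue_a`, `residue_b` (1-based cysteine
#'   residue indices, `a < b`) and `distance` (Å); zero rows when no pair
#'   qualifies.
#' @examples
#' atoms <- data.frame(residue_name = "CYS", residue_index = c(13, 87),
#'                     atom_name = "SG", x = c(0, 2.05), y = 0, z = 0)
#' detect_disulfides(atoms)
#' @export
detect_disulfides <- function(atoms, range = c(2, 3)) {
  stopifnot(is.data.frame(atoms),
            all(c("residue_name", "residue_index", "atom_name",
                  "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite.", call. = FALSE)
  cys <- atoms[atoms$residue_name == "CYS", , drop = FALSE]
  sg <- cys[cys$atom_name == "SG", , drop = FALSE]
  no_sg <- setdiff(unique(cys$residue_index), unique(sg$residue_index))
  if (length(no_sg))
    warning("cysteine(s) without an SG atom skipped: ",
            paste(no_sg, collapse = ", "), call. = FALSE)
  empty <- data.frame(residue_a = integer(0), residue_b = integer(0),
                      distance = numeric(0))
  if (nrow(sg) < 2L) return(empty)
  sg <- sg[!duplicated(sg$residue_index), , drop = FALSE]
  d <- as.matrix(stats::dist(sg[, c("x", "y", "z")]))
  idx <- which(upper.tri(d) & d >= range[1L] & d <= range[2L],
               arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  cand <- data.frame(residue_a = sg$residue_index[idx[, 1L]],
                     residue_b = sg$residue_index[idx[, 2L]],
                     distance = d[idx])
  swap <- cand$residue_a > cand$residue_b
  tmp <- cand$residue_a[swap]
  cand$residue_a[swap] <- cand$residue_b[swap]
  cand$residue_b[swap] <- tmp
  cand <- cand[order(cand$distance), , drop = FALSE]
  used <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$residue_a[i] %in% used || cand$residue_b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, cand$residue_a[i], cand$residue_b[i])
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$residue_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus screening of AMP-candidate score tables
#'
#' Applies the study's triage rules to a table of per-sequence predictor
#' outputs: an ampir flag when either classification model (precursor or
#' mature) scores above `ampir_threshold`; a MultiPep flag when the
#' sequence is shorter than `multipep_max_len` residues and either the
#' antimicrobial or antibacterial class scores above
#' `multipep_threshold`; a CAMP flag when the single top BLAST hit has
#' E-value at most `camp_evalue_max`. A sequence is retained when any
#' flag is set. Raising any threshold can only shrink the retained set.
#'
#' @param rows data.frame with columns `id`, `length`, and any of
#'   `ampir_precursor`, `ampir_mature`, `multipep_antimicrobial`,
#'   `multipep_antibacterial`, `camp_evalue` (missing values allowed;
#'   MultiPep columns must be `NA` for sequences of `multipep_max_len`
#'   residues or more, since the predictor does not accept them).
#' @param ampir_threshold,multipep_threshold Probability-score cutoffs.
#' @param camp_evalue_max BLAST E-value cutoff.
#' @param multipep_max_len Length limit of the MultiPep predictor.
#' @return `rows` with logical columns `ampir_flag`, `multipep_flag`,
#'   `camp_flag`, `retained` appended.
#' @examples
#' path <- system.file("extdata", "candidate_scores.csv",
#'                     package = "helmamp")
#' scr <- screen_candidates(read.csv(path))
#' scr[, c("id", "ampir_flag", "multipep_flag", "camp_flag", "retained")]
#' @export
screen_candidates <- function(rows, ampir_threshold = 0.7,
                              multipep_threshold = 0.7,
                              camp_evalue_max = 1e-5,
                              multipep_max_len = 200) {
  stopifnot(is.data.frame(rows), all(c("id", "length") %in% names(rows)))
  get <- function(col) if (col %in% names(rows)) rows[[col]] else
    rep(NA_real_, nrow(rows))
  ap <- get("ampir_precursor"); am <- get("ampir_mature")
  ma <- get("multipep_antimicrobial"); mb <- get("multipep_antibacterial")
  ce <- get("camp_evalue")
  for (v in list(ap, am, ma, mb))
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("prediction scores must lie in [0, 1].", call. = FALSE)
  long <- rows$length >= multipep_max_len
  if (any(long & (!is.na(ma) | !is.na(mb))))
    stop("sequences of length >= ", multipep_max_len, " cannot carry ",
         "MultiPep scores; found: ",
         paste(rows$id[long & (!is.na(ma) | !is.na(mb))], collapse = ", "),
         call. = FALSE)
  na_false <- function(x) !is.na(x) & x
  rows$ampir_flag <- na_false(ap > ampir_threshold) |
    na_false(am > ampir_threshold)
  rows$multipep_flag <- !long & (na_false(ma > multipep_threshold) |
                                   na_false(mb > multipep_threshold))
  rows$camp_flag <- na_false(ce <= camp_evalue_max)
  rows$retained <- rows$ampir_flag | rows$multipep_flag | rows$camp_flag
  rows
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return data.frame with `id` (first word of the header) and `residues`.
#' @export
read_peptides <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*", "", names(seqs)),
             residues = as.character(seqs), row.names = NULL)
}

#' Fetch peptide sequences from UniProt (requires network access)
#'
#' Convenience helper that downloads `<accession>.fasta` files from the
#' UniProt REST API and returns them via [read_peptides()]. All core
#' operations accept local FASTA, so the package works fully offline;
#' this helper only saves the manual download step.
#'
#' @param accessions Character vector of UniProt accessions.
#' @param destfile Path for the combined FASTA download.
#' @return data.frame as from [read_peptides()].
#' @export
fetch_uniprot_fasta <- function(accessions,
                                destfile = tempfile(fileext = ".fasta")) {
  urls <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta",
                  accessions)
  con <- file(destfile, "w")
  on.exit(close(con))
  for (u in urls) writeLines(readLines(u, warn = FALSE), con)
  flush(con)
  read_peptides(destfile)
}
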