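# Residue mass tables (Da). Monoisotopic values from the standard elemental
# composition of each residue with IUPAC atomic masses; average values from
# standard atomic weights. Cysteine is tabulated in its reduced (free thiol)
# form; disulfide oxidation is accounted for explicitly via `n_disulfides`.
.AA_MONO <- c(
  A = 71.03711, C = 103.00918, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04048, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

.AA_AVG <- c(
  A = 71.0780, C = 103.1428, D = 115.0876, E = 129.1142, F = 147.1742,
  G = 57.0514, H = 137.1395, I = 113.1579, K = 128.1725, L = 113.1579,
  M = 131.1960, N = 114.1028, P = 97.1154, Q = 128.1294, R = 156.1859,
  S = 87.0774, T = 101.1040, V = 99.1313, W = 186.2103, Y = 163.1736
)

.MASS <- list(
  water_mono  = 18.010565,
  water_avg   = 18.015286,
  hydrogen_mono = 1.00782503,
  hydrogen_avg  = 1.00794,
  proton      = 1.00727646,
  nh3_mono    = 17.026549,
  nh3_avg     = 17.030525
)

.mode_arg <- function(mode) match.arg(mode, c("mono", "average"))

.water <- function(mode) {
  if (mode == "mono") .MASS$water_mono else .MASS$water_avg
}

.hydrogen <- function(mode) {
  if (mode == "mono") .MASS$hydrogen_mono else .MASS$hydrogen_avg
}

.aa_table <- function(mode) if (mode == "mono") .AA_MONO else .AA_AVG

#' Mass constants used throughout the package
#'
#' Returns the fixed physical constants (in Da) behind all mass arithmetic:
#' water, hydrogen, proton and ammonia masses in monoisotopic and average
#' flavours.
#'
#' @return Named list of masses in Da.
#' @export
mass_constants <- function() .MASS

#' Residue mass of a standard amino acid
#'
#' @param letter Single one-letter code of a standard amino acid.
#' @param mode `"mono"` (monoisotopic) or `"average"`.
#' @return Residue (dehydrated) mass in Da.
#' @examples
#' residue_mass("G")                  # 57.02146
#' residue_mass("H") - residue_mass("L")  # 23.97485, the His/Leu shift
#' @export
residue_mass <- function(letter, mode = c("mono", "average")) {
  mode <- .mode_arg(mode)
  if (!is.character(letter) || length(letter) != 1L || nchar(letter) != 1L)
    stop("'letter' must be a single one-letter amino-acid code")
  tab <- .aa_table(mode)
  if (!letter %in% names(tab))
    stop(sprintf("unknown amino-acid code '%s'", letter))
  unname(tab[[letter]])
}

#' Construct a peptide with a disulfide count
#'
#' A peptide is its primary sequence plus the number of disulfide bonds it
#' carries in the oxidized state. Each disulfide removes two hydrogens from
#' the reduced-form mass; the pairing pattern does not affect mass and is not
#' modelled.
#'
#' @param sequence Character string over the 20 standard one-letter codes.
#' @param n_disulfides Number of disulfide bonds (default 0). Requires at
#'   least `2 * n_disulfides` cysteines in the sequence.
#' @param name Optional label.
#' @return Object of class `peptide`.
#' @examples
#' p <- peptide("YKRCHKKGGH", n_disulfides = 0)
#' peptide_mass(p)
#' @export
peptide <- function(sequence, n_disulfides = 0L, name = "") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("'sequence' must be a non-empty character string")
  sequence <- toupper(sequence)
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(letters), names(.AA_MONO))
  if (length(bad))
    stop(sprintf("unknown amino-acid code(s): %s", paste(bad, collapse = ", ")))
  n_disulfides <- as.integer(n_disulfides)
  if (is.na(n_disulfides) || n_disulfides < 0L)
    stop("'n_disulfides' must be a non-negative integer")
  n_cys <- sum(letters == "C")
  if (2L * n_disulfides > n_cys)
    stop(sprintf("%d disulfide(s) need %d cysteines; sequence has %d",
                 n_disulfides, 2L * n_disulfides, n_cys))
  structure(
    list(sequence = sequence, n_disulfides = n_disulfides, name = name),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide%s> %d residues, %d disulfide bond(s)\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              nchar(x$sequence), x$n_disulfides))
  cat(" ", x$sequence, "\n", sep = "")
  cat(sprintf("  mass: %.4f Da (mono), %.3f Da (average)\n",
              peptide_mass(x, "mono"), peptide_mass(x, "average")))
  invisible(x)
}

.as_peptide <- function(x) {
  if (inherits(x, "peptide")) x else peptide(x)
}

.residues <- function(pep) strsplit(pep$sequence, "", fixed = TRUE)[[1L]]

#' Neutral peptide mass with disulfide accounting
#'
#' Sum of residue masses plus one water, minus two hydrogens per disulfide
#' bond (oxidation removes 2 H per bond).
#'
#' @param pep A [peptide()] object or plain sequence string.
#' @param mode `"mono"` or `"average"`.
#' @return Neutral mass in Da.
#' @examples
#' mtx3 <- myotoxin3_peptide("45H")    # oxidized, 3 disulfides
#' peptide_mass(mtx3, "average")        # ~5168.1 Da; MALDI gave 5168.3
#' @export
peptide_mass <- function(pep, mode = c("mono", "average")) {
  mode <- .mode_arg(mode)
  pep <- .as_peptide(pep)
  tab <- .aa_table(mode)
  sum(tab[.residues(pep)]) + .water(mode) -
    pep$n_disulfides * 2 * .hydrogen(mode)
}

#' Signed mass difference between two peptides
#'
#' @param pep_a,pep_b [peptide()] objects or sequence strings.
#' @param mode `"mono"` or `"average"`.
#' @return `peptide_mass(pep_a) - peptide_mass(pep_b)` in Da.
#' @export
mass_difference <- function(pep_a, pep_b, mode = c("mono", "average")) {
  mode <- .mode_arg(mode)
  peptide_mass(pep_a, mode) - peptide_mass(pep_b, mode)
}

#' Candidate residue substitutions explaining a mass shift
#'
#' Brute-forces all 380 ordered pairs of distinct standard residues and
#' returns those whose residue-mass difference matches `|delta|` within
#' `tolerance`, sorted by mismatch. A 24 Da shift, for example, is explained
#' by His in place of Leu (or Ile) — the signature that separates the His5
#' and Leu5 isoforms of myotoxin-3.
#'
#' @param delta Observed mass shift in Da (sign ignored).
#' @param tolerance Matching tolerance in Da (> 0).
#' @param mode `"mono"` or `"average"`.
#' @return data.frame with columns `heavier`, `lighter`, `delta_da`,
#'   `mismatch_da`, sorted by `mismatch_da`.
#' @examples
#' infer_substitution(24, tolerance = 0.1)  # includes His/Leu
#' @export
infer_substitution <- function(delta, tolerance, mode = c("mono", "average")) {
  mode <- .mode_arg(mode)
  if (!is.numeric(tolerance) || tolerance <= 0) stop("'tolerance' must be > 0")
  tab <- .aa_table(mode)
  aa <- names(tab)
  grid <- expand.grid(heavier = aa, lighter = aa,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$heavier != grid$lighter, ]
  grid$delta_da <- tab[grid$heavier] - tab[grid$lighter]
  grid$mismatch_da <- abs(grid$delta_da - abs(delta))
  out <- grid[grid$mismatch_da <= tolerance, ]
  out <- out[order(out$mismatch_da, out$heavier, out$lighter), ]
  rownames(out) <- NULL
  out
}

#' Myotoxin-3 isoform peptides
#'
#' The four isoforms of myotoxin-3 from *Crotalus oreganus oreganus* venom
#' (UniProt P63176 for the canonical 45-mer): the full 45-residue chain with
#' His or Leu at position 5, and the 43-residue forms lacking the two
#' C-terminal residues. All carry three disulfide bonds in the oxidized state.
#'
#' @param isoform One of `"45H"`, `"45L"`, `"43H"`, `"43L"`.
#' @param oxidized If `TRUE` (default) three disulfide bonds, else none.
#' @return A [peptide()] object.
#' @examples
#' peptide_mass(myotoxin3_peptide("43H"), "average")  # ~4982.9 Da
#' @export
myotoxin3_peptide <- function(isoform = c("45H", "45L", "43H", "43L"),
                              oxidized = TRUE) {
  isoform <- match.arg(isoform)
  base <- "YKRCHKKGGHCFPKTVICLPPSSDFGKMDCRWKWKCCKKGSVNNA"
  seq <- base
  if (grepl("L", isoform, fixed = TRUE))
    substr(seq, 5L, 5L) <- "L"
  if (startsWith(isoform, "43"))
    seq <- substr(seq, 1L, 43L)
  peptide(seq, n_disulfides = if (oxidized) 3L else 0L,
          name = paste0("myotoxin-3 ", isoform))
}
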