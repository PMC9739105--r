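# MALDI in-source decay produces N-Calpha backbone cleavages: an N-terminal
# c-ion series and a C-terminal z-ion series. Conventions used here
# (monoisotopic, neutral):
#   c_i  = sum(residues 1..i)      + NH3
#   z_j  = sum(residues n-j+1..n)  + H2O - NH3 + 2 H   (z+1 radical species)
# so c_i + z_(n-i) = M + 2 H for the neutral peptide mass M (reduced form).
# Singly protonated m/z adds one proton mass.

#' c/z fragment-ion ladder of a peptide
#'
#' Computes the complete in-source-decay ladder: c-ions for the first
#' `n - 1` prefixes and z-ions (z+1 radical convention) for the first
#' `n - 1` suffixes, with monoisotopic neutral masses and singly-protonated
#' m/z.
#'
#' @param pep A [peptide()] object or sequence string (length >= 2).
#'   Disulfides are ignored for fragment masses: in-source decay of the
#'   reduced backbone is modelled.
#' @return data.frame with columns `series` ("c"/"z"), `index`,
#'   `neutral_mass`, `mz_1plus`, `bond` (the inter-residue bond the ion
#'   supports, counted from the N-terminus).
#' @examples
#' isd_ladder("GG")  # c1 neutral 74.04801
#' @export
isd_ladder <- function(pep) {
  pep <- .as_peptide(pep)
  res <- .residues(pep)
  n <- length(res)
  if (n < 2L) stop("fragment ladder needs a peptide of length >= 2")
  m <- .AA_MONO[res]
  idx <- seq_len(n - 1L)
  c_neutral <- cumsum(m)[idx] + .MASS$nh3_mono
  z_neutral <- cumsum(rev(m))[idx] + .MASS$water_mono - .MASS$nh3_mono +
    2 * .MASS$hydrogen_mono
  out <- data.frame(
    series = rep(c("c", "z"), each = n - 1L),
    index = c(idx, idx),
    neutral_mass = unname(c(c_neutral, z_neutral)),
    stringsAsFactors = FALSE
  )
  out$mz_1plus <- out$neutral_mass + .MASS$proton
  # bond k joins residues k and k+1; c_i supports bond i, z_j bond n-j
  out$bond <- ifelse(out$series == "c", out$index, n - out$index)
  out
}

#' Annotate an observed peak list against a candidate peptide
#'
#' Matches observed singly-protonated peaks to the candidate's c/z ladder by
#' greedy nearest-mass assignment: candidate (peak, ion) pairs within
#' `tolerance` are ranked by absolute mass error (ties broken by lower ion
#' index), and each peak and each ion is used at most once. Sequence coverage
#' is the fraction of the `n - 1` inter-residue bonds supported by at least
#' one matched ion; `terminal_span` is the longest contiguous run of
#' supported bonds anchored at either terminus (in residues), the quantity
#' behind "a 35-residue C-terminal fragment" style statements.
#'
#' @param peaks data.frame with columns `mz` and (optionally) `intensity`.
#' @param candidate A [peptide()] object or sequence string.
#' @param tolerance Matching tolerance in Da (> 0).
#' @return Object of class `isd_annotation`: list with `matches` (data.frame
#'   `mz`, `series`, `index`, `bond`, `delta_da`), `coverage`,
#'   `terminal_span`, `n_bonds`, `candidate`.
#' @export
annotate_peaks <- function(peaks, candidate, tolerance = 0.3) {
  if (!is.numeric(tolerance) || tolerance <= 0) stop("'tolerance' must be > 0")
  if (!is.data.frame(peaks) || !"mz" %in% names(peaks))
    stop("'peaks' must be a data.frame with an 'mz' column")
  candidate <- .as_peptide(candidate)
  ladder <- isd_ladder(candidate)
  n_bonds <- nchar(candidate$sequence) - 1L

  matches <- data.frame(mz = numeric(0), series = character(0),
                        index = integer(0), bond = integer(0),
                        delta_da = numeric(0), stringsAsFactors = FALSE)
  if (nrow(peaks)) {
    # all candidate pairs within tolerance
    dm <- outer(peaks$mz, ladder$mz_1plus, "-")
    ok <- which(abs(dm) <= tolerance, arr.ind = TRUE)
    if (nrow(ok)) {
      cand <- data.frame(peak = ok[, 1L], ion = ok[, 2L],
                         delta = dm[ok])
      cand <- cand[order(abs(cand$delta), ladder$index[cand$ion]), ]
      used_peak <- logical(nrow(peaks))
      used_ion <- logical(nrow(ladder))
      keep <- integer(0)
      for (r in seq_len(nrow(cand))) {
        p <- cand$peak[r]; i <- cand$ion[r]
        if (!used_peak[p] && !used_ion[i]) {
          used_peak[p] <- TRUE
          used_ion[i] <- TRUE
          keep <- c(keep, r)
        }
      }
      cand <- cand[keep, , drop = FALSE]
      matches <- data.frame(
        mz = peaks$mz[cand$peak],
        series = ladder$series[cand$ion],
        index = ladder$index[cand$ion],
        bond = ladder$bond[cand$ion],
        delta_da = cand$delta,
        stringsAsFactors = FALSE
      )
      matches <- matches[order(matches$series, matches$index), ]
      rownames(matches) <- NULL
    }
  }

  supported <- sort(unique(matches$bond))
  cov <- length(supported) / n_bonds
  span <- .terminal_span(supported, n_bonds)

  structure(
    list(matches = matches, coverage = cov, terminal_span = span,
         n_bonds = n_bonds, candidate = candidate, tolerance = tolerance),
    class = "isd_annotation"
  )
}

# longest contiguous run of supported bonds anchored at bond 1 (N-terminus)
# or bond n_bonds (C-terminus)
.terminal_span <- function(supported, n_bonds) {
  is_sup <- seq_len(n_bonds) %in% supported
  n_span <- 0L
  while (n_span < n_bonds && is_sup[n_span + 1L]) n_span <- n_span + 1L
  c_span <- 0L
  while (c_span < n_bonds && is_sup[n_bonds - c_span]) c_span <- c_span + 1L
  max(n_span, c_span)
}

#' @export
print.isd_annotation <- function(x, ...) {
  cat(sprintf("<isd_annotation> %d matched ion(s), coverage %.1f%% of %d bonds, terminal span %d\n",
              nrow(x$matches), 100 * x$coverage, x$n_bonds, x$terminal_span))
  invisible(x)
}
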