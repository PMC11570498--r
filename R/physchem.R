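# Physicochemical profiling: the features behind the first filter stage of
# the linker screen (length, pI, hydropathy, hydrophobic phi and
# electrostatic zeta residue-class fractions).

#' Residue scales used by the physicochemical profiler
#'
#' Returns the scale set: per-group acid dissociation constants (EMBOSS
#' values), Kyte--Doolittle hydropathy, and the hydrophobic (phi) and
#' electrostatic (zeta) residue classes.  Histidine is weakly charged at
#' neutral pH and belongs to neither class by default; Cys and Tyr titrate
#' for the pI computation but do not count as zeta residues.
#'
#' @param includeH if `TRUE`, add histidine to the zeta set.
#' @return A list with components `pKa` (named vector including `Nterm` and
#'   `Cterm`), `hydropathy` (named vector over the 20 canonical residues),
#'   `phiSet` and `zetaSet` (character vectors).
#' @examples
#' residueScales()$pKa[["K"]]
#' @export
residueScales <- function(includeH = FALSE) {
  scales <- list(
    pKa = c(
      Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
      H = 6.5, Nterm = 8.6, K = 10.8, R = 12.5
    ),
    hydropathy = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
      L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
    ),
    phiSet = c("A", "V", "L", "I", "M", "F", "W", "Y"),
    zetaSet = c("D", "E", "K", "R")
  )
  if (includeH) scales$zetaSet <- c(scales$zetaSet, "H")
  stopifnot(!any(scales$phiSet %in% scales$zetaSet))
  scales
}

.seq_chars <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  strsplit(seq, "")[[1]]
}

#' Net charge of a peptide at a given pH
#'
#' Henderson--Hasselbalch charge model: each basic group (N-terminus, K, R,
#' H) contributes `+1 / (1 + 10^(pH - pKa))` and each acidic group
#' (C-terminus, D, E, C, Y) contributes `-1 / (1 + 10^(pKa - pH))`.  `X`
#' residues contribute nothing.
#'
#' @param seq amino-acid sequence.
#' @param pH pH in \[0, 14\].
#' @param scales scale set from [residueScales()].
#' @return Net charge in elementary charge units.
#' @examples
#' netCharge("K", 7)  # ~ +0.976
#' @export
netCharge <- function(seq, pH, scales = residueScales()) {
  if (pH < 0 || pH > 14) stop("pH outside [0, 14]")
  ch <- .seq_chars(seq)
  pKa <- scales$pKa
  counts <- table(factor(ch, levels = names(pKa)))
  counts[["Nterm"]] <- 1L
  counts[["Cterm"]] <- 1L
  basic <- c("Nterm", "K", "R", "H")
  acidic <- c("Cterm", "D", "E", "C", "Y")
  pos <- sum(counts[basic] / (1 + 10^(pH - pKa[basic])))
  neg <- sum(counts[acidic] / (1 + 10^(pKa[acidic] - pH)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' The pH at which [netCharge()] is zero.  The charge is strictly decreasing
#' in pH and both termini always titrate, so the root is unique and always
#' bracketed by \[0, 14\]; bisection is iterated until the net charge at the
#' returned pH is below `tol` in magnitude.
#'
#' @inheritParams netCharge
#' @param tol convergence tolerance on |net charge| (and pH resolution).
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("G")  # (8.6 + 3.6)/2 = 6.1: only the termini titrate
#' @export
isoelectricPoint <- function(seq, scales = residueScales(), tol = 1e-3) {
  lo <- 0; hi <- 14
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    q <- netCharge(seq, mid, scales)
    if (abs(q) < tol && (hi - lo) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte--Doolittle hydropathy over the sequence.  `X` residues are
#' excluded from both numerator and denominator.
#'
#' @inheritParams netCharge
#' @return Mean hydropathy.
#' @examples
#' gravy("AIV")  # (1.8 + 4.5 + 4.2)/3 = 3.5
#' @export
gravy <- function(seq, scales = residueScales()) {
  ch <- .seq_chars(seq)
  h <- scales$hydropathy[ch]
  h <- h[!is.na(h)]
  if (length(h) == 0L) stop("no scored residues (all-X sequence?)")
  mean(h)
}

#' Physicochemical profile of one protein
#'
#' Computes all order-free per-protein features used by the first screen
#' stage: length, pI, GRAVY, net charge at pH 7, the hydrophobic (phi) and
#' electrostatic (zeta) residue-class fractions, and the residue
#' composition.
#'
#' @inheritParams netCharge
#' @return A list with components `length`, `pI`, `gravy`, `netChargePH7`,
#'   `fracPhi`, `fracZeta` and `composition` (named fractions summing to 1).
#' @examples
#' physchemProfile("KAKA")$fracZeta  # 0.5
#' @export
physchemProfile <- function(seq, scales = residueScales()) {
  ch <- .seq_chars(seq)
  n <- length(ch)
  comp <- table(ch) / n
  list(
    length = n,
    pI = isoelectricPoint(seq, scales),
    gravy = if (all(ch == "X")) NA_real_ else gravy(seq, scales),
    netChargePH7 = netCharge(seq, 7, scales),
    fracPhi = sum(ch %in% scales$phiSet) / n,
    fracZeta = sum(ch %in% scales$zetaSet) / n,
    composition = stats::setNames(as.numeric(comp), names(comp))
  )
}
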