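# Seeded synthetic proteome generator.  Emulates the linker architecture
# the screen is designed to find -- an optional N-terminal leader followed
# by 3-8 near-identical repeat units, each a short amphipathic sticker
# motif (~10 residues mixing hydrophobic and charged residues, the length
# of the single stable helix seen in real linker repeats) plus a disordered
# low-hydropathy spacer -- together with three labelled decoy classes and
# DIA-style co-IP enrichment tables with planted true positives.  All
# draws are governed by one integer seed; identical specs give
# byte-identical output.

# biased to S,P,G,E,K,T with K over E so linkers are net basic, like the
# known pyrenoid linkers (EPYC1 and CsLinker are lysine/arginine-rich)
.SPACER_RESIDUES <- c("S", "P", "G", "E", "K", "T", "A", "Q")
.SPACER_PROBS    <- c(0.20, 0.14, 0.16, 0.10, 0.18, 0.14, 0.04, 0.04)
.PHI_STICKER <- c("L", "I", "F", "V", "M")
.ZETA_STICKER <- c("E", "K", "R", "D")
.GLOBULAR_RESIDUES <- c("A", "V", "L", "I", "M", "F", "W", "Y", "G", "S",
                        "T", "C", "N", "Q", "D", "E", "K", "R", "H", "P")
.GLOBULAR_PROBS <- c(0.10, 0.09, 0.11, 0.08, 0.03, 0.06, 0.02, 0.05, 0.07,
                     0.05, 0.05, 0.02, 0.04, 0.03, 0.04, 0.04, 0.04, 0.04,
                     0.02, 0.02)

.sample_spacer <- function(n) {
  paste(sample(.SPACER_RESIDUES, n, replace = TRUE, prob = .SPACER_PROBS),
        collapse = "")
}

# amphipathic 10-mer: 3 hydrophobic + 3 charged residues at fixed register,
# spacer-like residues elsewhere (an invented template, not a real motif)
.sample_sticker <- function() {
  phi <- sample(.PHI_STICKER, 3L, replace = TRUE)
  zeta <- c(sample(c("K", "R"), 2L, replace = TRUE), sample(c("E", "D"), 1L))
  oth <- sample(c("S", "T", "A", "G"), 4L, replace = TRUE)
  paste(c(oth[1L], phi[1L], zeta[1L], oth[2L], phi[2L], zeta[2L],
          oth[3L], phi[3L], zeta[3L], oth[4L]), collapse = "")
}

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit))
    ch[hit] <- sample(.AA_ALPHABET, length(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Specification for a synthetic proteome
#'
#' Generation parameters for [generateProteome()].  Defaults emulate the
#' study architecture: 3--8 repeat units per linker, unit lengths of 35--85
#' residues (the known pyrenoid linkers repeat at ~60-residue units, well
#' inside the 20--120 residue cross-linking feasibility band the detector
#' accepts), a 10-residue amphipathic sticker motif per unit, and a 5%
#' per-unit substitution rate.
#'
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @param nLinkers number of planted linker proteins.
#' @param nDecoys named counts per decoy class (`globular`, `disordered`,
#'   `lowcomplexity`).
#' @param nRepeatsRange,periodRange integer ranges the per-linker repeat
#'   count and unit length are drawn from.
#' @param leaderRange leader (N-terminal non-repetitive segment) length
#'   range.
#' @param substitutionRate per-residue substitution probability applied to
#'   each repeat unit copy.
#' @return A list with class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(seed = 1L, nLinkers = 10L,
                          nDecoys = c(globular = 200L, disordered = 200L,
                                      lowcomplexity = 200L),
                          nRepeatsRange = c(3L, 8L),
                          periodRange = c(35L, 85L),
                          leaderRange = c(20L, 40L),
                          substitutionRate = 0.05) {
  stopifnot(all(c("globular", "disordered", "lowcomplexity")
                %in% names(nDecoys)))
  structure(
    list(
      seed = as.integer(seed), nLinkers = as.integer(nLinkers),
      nDecoys = nDecoys, nRepeatsRange = as.integer(nRepeatsRange),
      periodRange = as.integer(periodRange),
      leaderRange = as.integer(leaderRange),
      substitutionRate = substitutionRate
    ),
    class = "syntheticSpec"
  )
}

#' Generate one synthetic linker protein
#'
#' Leader + `nRepeats` mutated copies of a (sticker + spacer) unit.  The
#' construct is verified post-generation to be majority-disordered under
#' [foldIndex()] and is resampled (up to 10 times) if not; failure after 10
#' resamples signals incompatible parameters and raises an error.
#'
#' @param spec a [syntheticSpec()].  The caller is responsible for seeding
#'   the RNG; [generateProteome()] does this once per proteome.
#' @param index index used only for the returned truth row.
#' @return A list: `sequence`, and truth fields `class`, `period`,
#'   `copies`, `start`, `end` (1-based repeat span).
#' @export
makeLinker <- function(spec, index = 1L) {
  for (attempt in seq_len(10L)) {
    nrep <- sample(seq(spec$nRepeatsRange[1L], spec$nRepeatsRange[2L]), 1L)
    period <- sample(seq(spec$periodRange[1L], spec$periodRange[2L]), 1L)
    leader_n <- sample(seq(spec$leaderRange[1L], spec$leaderRange[2L]), 1L)
    unit <- paste0(.sample_sticker(), .sample_spacer(period - 10L))
    leader <- paste0("M", .sample_spacer(leader_n - 1L))
    units <- vapply(seq_len(nrep), function(i)
      .mutate(unit, spec$substitutionRate), "")
    seq <- paste0(leader, paste(units, collapse = ""))
    # verified post-generation: majority-disordered, and net basic at pH 7
    # (tandem copying amplifies any acidic bias of the single drawn unit,
    # so basicity is enforced on the assembled protein, as in the real
    # lysine-rich linker class)
    if (fractionDisordered(foldIndex(seq)) >= 0.5 &&
        netCharge(seq, 7) >= 0.02 * nchar(seq)) {
      return(list(
        sequence = seq, class = "linker", period = period,
        copies = nrep, start = leader_n + 1L,
        end = leader_n + nrep * period
      ))
    }
  }
  stop("could not generate a disordered linker in 10 attempts; ",
       "incompatible parameters")
}

#' Generate one synthetic decoy protein
#'
#' Three classes, each designed (and verified post-generation, with up to
#' 10 resamples) to fail a specific screen stage: `"globular"` decoys have
#' folded-protein-like hydrophobic-rich composition and fail the disorder
#' call; `"disordered"` decoys are non-repetitive disordered sequence and
#' carry no tandem repeat; `"lowcomplexity"` decoys are short-period
#' (< 20 residues) repeats whose long-period harmonics are rejected by the
#' consensus low-complexity guard.
#'
#' @param spec a [syntheticSpec()] (caller seeds the RNG).
#' @param class decoy class name.
#' @param index index used only for the truth row.
#' @return A list as in [makeLinker()] (`period`/`copies`/span are `NA`).
#' @export
makeDecoy <- function(spec,
                      class = c("globular", "disordered", "lowcomplexity"),
                      index = 1L) {
  class <- match.arg(class)
  rc <- RepeatConfig()
  for (attempt in seq_len(10L)) {
    if (class == "globular") {
      n <- sample(150:500, 1L)
      seq <- paste(sample(.GLOBULAR_RESIDUES, n, replace = TRUE,
                          prob = .GLOBULAR_PROBS), collapse = "")
      ok <- fractionDisordered(foldIndex(seq)) < 0.5
    } else if (class == "disordered") {
      n <- sample(150:500, 1L)
      seq <- .sample_spacer(n)
      ok <- length(findTandemRepeats(seq, rc)) == 0L
    } else {
      unit <- paste(sample(c("G", "P", "S", "A"), sample(2:6, 1L),
                           replace = TRUE), collapse = "")
      reps <- ceiling(sample(150:400, 1L) / nchar(unit))
      seq <- .mutate(strrep(unit, reps), 0.03)
      ok <- length(findTandemRepeats(seq, rc)) == 0L
    }
    if (ok) {
      return(list(sequence = seq, class = class, period = NA_integer_,
                  copies = NA_integer_, start = NA_integer_,
                  end = NA_integer_))
    }
  }
  stop("could not generate a valid '", class, "' decoy in 10 attempts")
}

#' Generate a synthetic proteome with ground truth
#'
#' Generates `nLinkers` planted linkers plus the configured decoys, shuffles
#' the record order and assigns position-based ids that encode nothing
#' about class; the class labels and true repeat coordinates live only in
#' the truth table.  Fully deterministic under `spec$seed`.
#'
#' @param spec a [syntheticSpec()].
#' @param outDir optional directory; when given, writes `proteome.fasta`,
#'   `truth.tsv` and returns the paths in the result.
#' @return A list with `proteome` (an `AAStringSet`), `truth` (a
#'   `data.frame` with columns id, class, period, copies, start, end) and,
#'   when `outDir` is given, `paths`.
#' @examples
#' ps <- generateProteome(syntheticSpec(seed = 7, nLinkers = 2,
#'   nDecoys = c(globular = 2, disordered = 2, lowcomplexity = 2)))
#' table(ps$truth$class)
#' @export
generateProteome <- function(spec = syntheticSpec(), outDir = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  recs <- list()
  for (i in seq_len(spec$nLinkers))
    recs[[length(recs) + 1L]] <- makeLinker(spec, i)
  for (cls in c("globular", "disordered", "lowcomplexity")) {
    for (i in seq_len(spec$nDecoys[[cls]]))
      recs[[length(recs) + 1L]] <- makeDecoy(spec, cls, i)
  }
  perm <- sample(length(recs))
  recs <- recs[perm]
  ids <- sprintf("prot%04d", seq_along(recs))
  proteome <- Biostrings::AAStringSet(vapply(recs, `[[`, "", "sequence"))
  names(proteome) <- ids
  mcols(proteome)$description <- rep("", length(proteome))
  truth <- data.frame(
    id = ids,
    class = vapply(recs, `[[`, "", "class"),
    period = vapply(recs, function(r) as.integer(r$period), 0L),
    copies = vapply(recs, function(r) as.integer(r$copies), 0L),
    start = vapply(recs, function(r) as.integer(r$start), 0L),
    end = vapply(recs, function(r) as.integer(r$end), 0L),
    stringsAsFactors = FALSE
  )
  out <- list(proteome = proteome, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(outDir, "proteome.fasta")
    tt <- file.path(outDir, "truth.tsv")
    writeProteome(proteome, fa)
    writeTable(truth, tt, format = "tsv")
    out$paths <- c(fasta = fa, truth = tt)
  }
  out
}

#' Generate a synthetic co-IP enrichment table
#'
#' DIA-style differential-abundance rows: planted true positives are drawn
#' above the (strict) significance thresholds, background proteins below at
#' least one of them, and summed intensities are lognormal.
#'
#' @param ids all protein ids.
#' @param truePositiveIds subset of `ids` to plant as enriched.
#' @param lfcMean,lfcSd log2 fold-change distribution of true positives.
#' @param logpMean,logpSd -log10(adjusted P) distribution of true
#'   positives.
#' @param lfcThreshold,logpThreshold the strict thresholds the plants must
#'   clear (draws are truncated just above them).
#' @param seed integer RNG seed.
#' @return A `data.frame` with columns `id`, `log2FC`, `negLog10AdjP`,
#'   `summedIntensity`.
#' @export
generateEnrichmentTable <- function(ids, truePositiveIds,
                                    lfcMean = 6, lfcSd = 0.5,
                                    logpMean = 6, logpSd = 0.5,
                                    lfcThreshold = 4, logpThreshold = 4,
                                    seed = 1L) {
  stopifnot(all(truePositiveIds %in% ids))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(ids)
  tp <- ids %in% truePositiveIds
  lfc <- stats::rnorm(n, 0, 1.5)
  logp <- stats::runif(n, 0, logpThreshold * 0.75)
  # background rows must not clear both strict thresholds
  both <- lfc > lfcThreshold & logp > logpThreshold
  lfc[both] <- lfcThreshold - abs(lfc[both] - lfcThreshold)
  lfc[tp] <- pmax(lfcThreshold + 0.25,
                  stats::rnorm(sum(tp), lfcMean, lfcSd))
  logp[tp] <- pmax(logpThreshold + 0.25,
                   stats::rnorm(sum(tp), logpMean, logpSd))
  data.frame(
    id = ids, log2FC = lfc, negLog10AdjP = logp,
    summedIntensity = stats::rlnorm(n, meanlog = 14, sdlog = 1.5),
    stringsAsFactors = FALSE
  )
}

#' Synthetic reference linker sequences
#'
#' Deterministic, clearly synthetic stand-ins for the two known pyrenoid
#' linkers, built from the generator's architecture: a `"cslinker"`-style
#' protein with six ~65-residue repeat units and an `"epyc1"`-style protein
#' with four ~60-residue units.  These are NOT the real CsLinker or EPYC1
#' sequences (which are not redistributed here); they reproduce the
#' architecture -- repeat count, unit length, amphipathic sticker,
#' disordered spacer -- for calibration, demonstration and testing.
#'
#' @param style `"cslinker"` (six repeats) or `"epyc1"` (four repeats).
#' @param matureTrim if `TRUE` (default) return the mature protein without
#'   a leader; if `FALSE`, prepend a synthetic 45-residue transit-peptide
#'   surrogate.
#' @return A single sequence as a character string.
#' @examples
#' nchar(syntheticLinkerReference("epyc1"))
#' @export
syntheticLinkerReference <- function(style = c("cslinker", "epyc1"),
                                     matureTrim = TRUE) {
  style <- match.arg(style)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(if (style == "cslinker") 20001L else 20002L)
  nrep <- if (style == "cslinker") 6L else 4L
  period <- if (style == "cslinker") 65L else 60L
  unit <- paste0(.sample_sticker(), .sample_spacer(period - 10L))
  units <- vapply(seq_len(nrep), function(i) .mutate(unit, 0.04), "")
  seq <- paste(units, collapse = "")
  if (!matureTrim)
    seq <- paste0("M", .sample_spacer(44L), seq)
  seq
}
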