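# The screen orchestrator: calibrate thresholds from a reference linker,
# apply the filter stages in order (physicochemistry -> tandem repeats ->
# sticker content -> disorder), record per-stage survivor counts, rank the
# survivors and intersect with co-IP enrichment results.

#' Calibrate a filter configuration from a reference linker
#'
#' Derives screen thresholds from a known linker protein (EPYC1 is the
#' canonical choice): pI band = reference pI +/- `piMargin`; length band =
#' `lengthFactor` times the reference length; minimum residue-class
#' fractions = `fracFactor` times the reference's; repeat period band fixed
#' at the 20--120 residue cross-linking scale; sticker requirement of at
#' least 1 hydrophobic and 2 electrostatic residues in the repeat consensus.
#' The reference must pass its own calibrated configuration (checked, so a
#' miscalibration fails loudly).
#'
#' @param reference reference sequence (character or `AAString`), or an
#'   `AAStringSet` of length 1.
#' @param piMargin half-width of the pI band (pH units, default 2).
#' @param lengthFactor numeric length band multipliers, default `c(0.3, 3)`.
#' @param fracFactor multiplier on the reference residue-class fractions,
#'   default 0.5.
#' @param matureTrim N-terminal residues to drop from the reference (and
#'   recorded in the config) before computation; transit-peptide surrogate.
#' @param repeatConfig repeat detector settings; band defaults to 20--120.
#' @param minDisorder disorder-fraction threshold recorded in the config.
#' @param disorderSource `"builtin"` or `"external"`.
#' @return A [FilterConfig-class].
#' @examples
#' ref <- syntheticLinkerReference("epyc1")
#' calibrateConfig(ref)
#' @export
calibrateConfig <- function(reference, piMargin = 2,
                            lengthFactor = c(0.3, 3), fracFactor = 0.5,
                            matureTrim = 0L, repeatConfig = RepeatConfig(),
                            minDisorder = 0.5, disorderSource = "builtin") {
  if (is(reference, "XStringSet")) {
    stopifnot(length(reference) == 1L)
    reference <- as.character(reference[[1L]])
  }
  reference <- as.character(reference)
  if (matureTrim > 0L) reference <- substring(reference, matureTrim + 1L)
  if (nchar(reference) < 2L * repeatConfig@periodMin)
    stop("reference shorter than twice the minimum repeat period")
  prof <- physchemProfile(reference)
  cfg <- FilterConfig(
    lengthMin = max(1L, floor(lengthFactor[1L] * prof$length)),
    lengthMax = ceiling(lengthFactor[2L] * prof$length),
    piMin = prof$pI - piMargin, piMax = prof$pI + piMargin,
    minFracZeta = fracFactor * prof$fracZeta,
    minFracPhi = fracFactor * prof$fracPhi,
    repeatConfig = repeatConfig,
    minPhiSticker = 1L, minZetaSticker = 2L,
    minDisorder = minDisorder, disorderSource = disorderSource,
    matureTrim = as.integer(matureTrim)
  )
  refset <- Biostrings::AAStringSet(reference)
  names(refset) <- "reference"
  # the config's matureTrim was already applied to `reference` above
  check_cfg <- cfg
  check_cfg@matureTrim <- 0L
  check_cfg@disorderSource <- "builtin"  # self-check needs no score table
  check <- runFlipper(refset, check_cfg, verbose = FALSE)
  if (sum(candidates(check)$passAll, na.rm = TRUE) != 1L)
    stop("reference fails its own calibrated configuration")
  cfg
}

.sticker_counts <- function(consensus, scales = residueScales()) {
  ch <- strsplit(consensus, "")[[1]]
  c(phi = sum(ch %in% scales$phiSet), zeta = sum(ch %in% scales$zetaSet))
}

#' Run the linker screen
#'
#' Applies the filter stages to every protein in the order: (1)
#' physicochemical bands (length, pI, minimum phi and zeta fractions), (2)
#' tandem-repeat presence with period in the configured band, (3)
#' interacting-residue (sticker) content of the best repeat hit's consensus,
#' (4) disorder fraction.  Stage flags are evaluated up to a protein's first
#' failure (later flags are `NA`), and per-stage survivor counts are
#' recorded.
#'
#' @param proteome an [Biostrings::AAStringSet] (see [readProteome()]).
#' @param cfg a [FilterConfig-class].
#' @param disorderScores named list of [DisorderProfile-class] objects,
#'   required when `cfg@disorderSource == "external"` (see
#'   [loadDisorderScores()]); profiles must cover every protein reaching the
#'   disorder stage or an error is raised.
#' @param scales residue scale set.
#' @param verbose log one line per stage with its survivor count.
#' @return A [FlipperScreen-class].  Repeat coordinates in the candidate
#'   table are 1-based inclusive on the mature (post-`matureTrim`)
#'   sequence.
#' @export
runFlipper <- function(proteome, cfg = FilterConfig(), disorderScores = NULL,
                       scales = residueScales(), verbose = FALSE) {
  stopifnot(is(proteome, "XStringSet"), length(proteome) > 0L)
  if (cfg@disorderSource == "external" && is.null(disorderScores))
    stop("disorderSource is 'external' but no disorderScores given")
  ids <- names(proteome)
  seqs <- as.character(proteome)
  if (cfg@matureTrim > 0L) {
    seqs <- ifelse(nchar(seqs) > cfg@matureTrim,
                   substring(seqs, cfg@matureTrim + 1L), seqs)
  }
  n <- length(seqs)
  len <- pI <- grv <- fphi <- fzeta <- rep(NA_real_, n)
  period <- rstart <- rend <- rep(NA_integer_, n)
  copies <- ident <- fdis <- rank_score <- rep(NA_real_, n)
  cons <- rep(NA_character_, n)
  p1 <- p2 <- p3 <- p4 <- rep(NA, n)

  for (i in seq_len(n)) {
    prof <- physchemProfile(seqs[i], scales)
    len[i] <- prof$length; pI[i] <- prof$pI; grv[i] <- prof$gravy
    fphi[i] <- prof$fracPhi; fzeta[i] <- prof$fracZeta
    p1[i] <- prof$length >= cfg@lengthMin && prof$length <= cfg@lengthMax &&
      prof$pI >= cfg@piMin && prof$pI <= cfg@piMax &&
      prof$fracZeta >= cfg@minFracZeta && prof$fracPhi >= cfg@minFracPhi
    if (!p1[i]) next
    hit <- if (len[i] >= 2L * cfg@repeatConfig@periodMin)
      bestHit(findTandemRepeats(seqs[i], cfg@repeatConfig)) else NULL
    p2[i] <- !is.null(hit)
    if (!p2[i]) next
    period[i] <- repeatPeriod(hit); copies[i] <- repeatCopies(hit)
    ident[i] <- repeatIdentity(hit); cons[i] <- repeatConsensus(hit)
    sp <- repeatSpan(hit); rstart[i] <- sp[["start"]]; rend[i] <- sp[["end"]]
    sk <- .sticker_counts(cons[i], scales)
    p3[i] <- sk[["phi"]] >= cfg@minPhiSticker &&
      sk[["zeta"]] >= cfg@minZetaSticker
    if (!p3[i]) next
    if (cfg@disorderSource == "builtin") {
      fdis[i] <- fractionDisordered(foldIndex(seqs[i]))
    } else {
      prof_d <- disorderScores[[ids[i]]]
      if (is.null(prof_d))
        stop("no external disorder scores for survivor ", ids[i])
      fdis[i] <- fractionDisordered(prof_d)
    }
    p4[i] <- fdis[i] >= cfg@minDisorder
    if (p4[i]) rank_score[i] <- copies[i] * ident[i] * fdis[i]
  }
  passAll <- !is.na(p4) & p4
  counts <- c(
    input = n,
    physchem = sum(p1, na.rm = TRUE),
    repeats = sum(p2, na.rm = TRUE),
    sticker = sum(p3, na.rm = TRUE),
    disorder = sum(passAll)
  )
  if (verbose) {
    for (nm in names(counts))
      message(sprintf("stage %-9s: %d surviving", nm, counts[[nm]]))
  }
  cand <- DataFrame(
    id = ids, length = as.integer(len), pI = pI, gravy = grv,
    fracPhi = fphi, fracZeta = fzeta,
    repeatPeriod = period, repeatCopies = copies, repeatIdentity = ident,
    repeatStart = rstart, repeatEnd = rend,
    consensus = cons, fractionDisordered = fdis,
    passPhyschem = p1, passRepeat = p2, passSticker = p3, passDisorder = p4,
    passAll = passAll, rankScore = rank_score
  )
  new("FlipperScreen", candidates = cand, stageCounts = counts, config = cfg)
}

#' Rank screen candidates
#'
#' Candidates passing all stages, sorted by
#' `rankScore = copies * identity * fractionDisordered` (descending; ties by
#' id ascending).  The rank score is a multivalency-times-disorder
#' surrogate for the manual structure-based triage used downstream of the
#' original screen, not an equivalent of it.
#'
#' @param screen a [FlipperScreen-class] (or its `candidates` DataFrame).
#' @return A `DataFrame` of passing candidates in rank order.
#' @export
rankCandidates <- function(screen) {
  df <- if (is(screen, "FlipperScreen")) candidates(screen) else screen
  df <- df[df$passAll %in% TRUE, , drop = FALSE]
  df[order(-df$rankScore, df$id), , drop = FALSE]
}

#' Filter a co-IP enrichment table
#'
#' Ids passing both thresholds strictly: `log2FC > lfcMin` and
#' `-log10(adjusted P) > logpMin` (defaults 4 and 4).
#'
#' @param rows data frame with columns `id`, `log2FC`, `negLog10AdjP` (a
#'   `summedIntensity` column, if present, is carried along but not used for
#'   filtering).
#' @param lfcMin,logpMin strict lower thresholds.
#' @return Character vector of passing ids.
#' @export
enrichmentFilter <- function(rows, lfcMin = 4, logpMin = 4) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) return(character())
  stopifnot(all(c("id", "log2FC", "negLog10AdjP") %in% names(rows)),
            all(is.finite(rows$log2FC)), all(is.finite(rows$negLog10AdjP)))
  rows$id[rows$log2FC > lfcMin & rows$negLog10AdjP > logpMin]
}

#' Intersect screen candidates with enriched proteins
#'
#' The triage step that pinpoints the linker: proteins found both by the
#' sequence screen and by co-IP enrichment.
#'
#' @param flipperIds,enrichedIds character vectors of ids.
#' @return A list with `ids` (the intersection, sorted) and `sizes` (named
#'   counts of the two input sets and the overlap).
#' @export
intersectCandidates <- function(flipperIds, enrichedIds) {
  ov <- sort(intersect(flipperIds, enrichedIds))
  list(
    ids = ov,
    sizes = c(screen = length(unique(flipperIds)),
              enriched = length(unique(enrichedIds)),
              overlap = length(ov))
  )
}

#' Export a candidate table
#'
#' Flattens a [FlipperScreen-class] into a plain data frame (one row per
#' protein) suitable for [writeTable()].
#'
#' @param screen a `FlipperScreen`.
#' @return A `data.frame`.
#' @export
candidateTable <- function(screen) {
  as.data.frame(candidates(screen))
}

# -- config serialization -----------------------------------------------------

#' Read / write filter configurations
#'
#' Filter configurations serialize to YAML with field names mirroring the
#' [FilterConfig-class] slots (the repeat settings nest under
#' `repeatConfig`).
#'
#' @param cfg a [FilterConfig-class].
#' @param path YAML file path.
#' @return `writeFilterConfig` returns `path` invisibly; `readFilterConfig`
#'   returns a `FilterConfig`.
#' @export
writeFilterConfig <- function(cfg, path) {
  rc <- cfg@repeatConfig
  x <- list(
    lengthMin = cfg@lengthMin, lengthMax = cfg@lengthMax,
    piMin = cfg@piMin, piMax = cfg@piMax,
    minFracZeta = cfg@minFracZeta, minFracPhi = cfg@minFracPhi,
    minPhiSticker = cfg@minPhiSticker, minZetaSticker = cfg@minZetaSticker,
    minDisorder = cfg@minDisorder, disorderSource = cfg@disorderSource,
    matureTrim = cfg@matureTrim,
    repeatConfig = list(
      periodMin = rc@periodMin, periodMax = rc@periodMax,
      minCopies = rc@minCopies, minIdentity = rc@minIdentity,
      minDistinct = rc@minDistinct, jitter = rc@jitter
    )
  )
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname writeFilterConfig
#' @export
readFilterConfig <- function(path) {
  x <- yaml::read_yaml(path)
  rc <- do.call(RepeatConfig, x$repeatConfig)
  x$repeatConfig <- NULL
  do.call(FilterConfig, c(x, list(repeatConfig = rc)))
}
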