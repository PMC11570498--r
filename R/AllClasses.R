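#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
NULL

#' Configuration for tandem repeat detection
#'
#' Holds the parameters of the tandem repeat detector.  The default period
#' band of 20--120 residues corresponds to the spacing feasible for
#' cross-linking adjacent Rubisco holoenzymes (roughly 2--8 nm of disordered
#' chain between sticker motifs).
#'
#' @slot periodMin,periodMax integer bounds (residues) on the repeat unit
#'   length considered.
#' @slot minCopies minimum number of repeat copies required for a hit.  Three
#'   is the minimum valence able to cross-link Rubiscos into a network.
#' @slot minIdentity minimum mean per-copy fraction of matches to the unit
#'   consensus, in \[0,1\].
#' @slot minDistinct minimum number of distinct residues in the consensus;
#'   guards against low-complexity sequence masquerading as long-period
#'   repeats through its harmonics.
#' @slot jitter allowed period drift (residues) when comparing a detected
#'   period against an expected one; the detection model itself is
#'   fixed-period and substitution-only.
#'
#' @seealso [findTandemRepeats()]
#' @export
setClass("RepeatConfig",
  representation(
    periodMin = "integer", periodMax = "integer",
    minCopies = "integer", minIdentity = "numeric",
    minDistinct = "integer", jitter = "integer"
  ),
  prototype(
    periodMin = 20L, periodMax = 120L, minCopies = 3L,
    minIdentity = 0.7, minDistinct = 5L, jitter = 2L
  )
)

setValidity("RepeatConfig", function(object) {
  msg <- character()
  if (object@periodMin < 2L) msg <- c(msg, "periodMin must be >= 2")
  if (object@periodMax < object@periodMin)
    msg <- c(msg, "periodMax must be >= periodMin")
  if (object@minCopies < 2L) msg <- c(msg, "minCopies must be >= 2")
  if (object@minIdentity <= 0 || object@minIdentity > 1)
    msg <- c(msg, "minIdentity must be in (0, 1]")
  if (object@minDistinct < 1L) msg <- c(msg, "minDistinct must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname RepeatConfig-class
#' @param periodMin,periodMax,minCopies,minIdentity,minDistinct,jitter see
#'   the corresponding slots.
#' @return A `RepeatConfig` object.
#' @examples
#' RepeatConfig()
#' RepeatConfig(periodMin = 3, periodMax = 10, minDistinct = 2)
#' @export
RepeatConfig <- function(periodMin = 20L, periodMax = 120L, minCopies = 3L,
                         minIdentity = 0.7, minDistinct = 5L, jitter = 2L) {
  new("RepeatConfig",
    periodMin = as.integer(periodMin), periodMax = as.integer(periodMax),
    minCopies = as.integer(minCopies), minIdentity = as.numeric(minIdentity),
    minDistinct = as.integer(minDistinct), jitter = as.integer(jitter)
  )
}

#' A detected tandem repeat region
#'
#' One tandem repeat detected in a protein sequence.  Coordinates are
#' 1-based inclusive residue positions.
#'
#' @slot start,end residue span of the repeat region (1-based inclusive).
#' @slot period repeat unit length in residues.
#' @slot copies number of unit copies; a trailing partial copy of at least
#'   half a period contributes fractionally, so `copies` may be non-integer.
#' @slot consensus majority-vote consensus of the unit (length = `period`).
#' @slot identity mean per-copy fraction of matches to the consensus.
#' @slot score `copies * period * identity`, the quantity maximised when
#'   resolving overlapping hits.
#'
#' @seealso [findTandemRepeats()], [bestHit()]
#' @export
setClass("RepeatHit",
  representation(
    start = "integer", end = "integer", period = "integer",
    copies = "numeric", consensus = "character", identity = "numeric",
    score = "numeric"
  )
)

setValidity("RepeatHit", function(object) {
  msg <- character()
  if (object@start < 1L || object@end < object@start)
    msg <- c(msg, "invalid span")
  if (nchar(object@consensus) != object@period)
    msg <- c(msg, "consensus length must equal period")
  if (object@copies < 2) msg <- c(msg, "copies must be >= 2")
  if (object@identity < 0 || object@identity > 1)
    msg <- c(msg, "identity must be in [0,1]")
  if (object@end - object@start + 1L <
      floor(object@copies * object@period) - object@period / 2)
    msg <- c(msg, "span shorter than implied by copies x period")
  if (length(msg)) msg else TRUE
})

#' Per-residue disorder profile
#'
#' Per-residue disorder scores and binary calls for one protein.  For the
#' built-in charge--hydropathy index the scores are unfoldability values
#' (disordered where the score is negative); for external predictor tables
#' they are probabilities in \[0,1\] (disordered where >= 0.5).
#'
#' @slot scores numeric per-residue scores, one per residue.
#' @slot calls logical per-residue disorder calls.
#' @slot source `"builtin"` or `"external"`.
#'
#' @seealso [foldIndex()], [loadDisorderScores()], [fractionDisordered()]
#' @export
setClass("DisorderProfile",
  representation(scores = "numeric", calls = "logical", source = "character")
)

setValidity("DisorderProfile", function(object) {
  msg <- character()
  if (length(object@scores) != length(object@calls))
    msg <- c(msg, "scores and calls must have equal length")
  if (length(object@scores) == 0L) msg <- c(msg, "empty profile")
  if (!object@source %in% c("builtin", "external"))
    msg <- c(msg, "source must be 'builtin' or 'external'")
  if (length(msg)) msg else TRUE
})

#' Filter configuration for the linker screen
#'
#' All thresholds applied by [runFlipper()], normally derived from a
#' reference linker with [calibrateConfig()].  Stages are applied in order:
#' physicochemical band filter, tandem repeat presence, sticker content of
#' the repeat consensus, then disorder fraction.
#'
#' @slot lengthMin,lengthMax accepted mature protein length band (residues).
#' @slot piMin,piMax accepted isoelectric point band (pH units).
#' @slot minFracZeta minimum fraction of electrostatic (zeta) residues.
#' @slot minFracPhi minimum fraction of hydrophobic (phi) residues.
#' @slot repeatConfig a [RepeatConfig-class] for the repeat stage.
#' @slot minPhiSticker,minZetaSticker minimum counts of phi and zeta residues
#'   required in the best repeat hit's consensus ("interacting residues").
#' @slot minDisorder minimum fraction of residues called disordered.
#' @slot disorderSource `"builtin"` (charge--hydropathy index) or
#'   `"external"` (per-residue score table).
#' @slot matureTrim number of N-terminal residues removed before any
#'   computation; a manual surrogate for chloroplast transit peptide removal.
#'
#' @export
setClass("FilterConfig",
  representation(
    lengthMin = "integer", lengthMax = "integer",
    piMin = "numeric", piMax = "numeric",
    minFracZeta = "numeric", minFracPhi = "numeric",
    repeatConfig = "RepeatConfig",
    minPhiSticker = "integer", minZetaSticker = "integer",
    minDisorder = "numeric", disorderSource = "character",
    matureTrim = "integer"
  ),
  prototype(
    lengthMin = 100L, lengthMax = 1000L, piMin = 7, piMax = 12,
    minFracZeta = 0.1, minFracPhi = 0.03,
    minPhiSticker = 1L, minZetaSticker = 2L,
    minDisorder = 0.5, disorderSource = "builtin", matureTrim = 0L
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@lengthMin < 1L || object@lengthMax < object@lengthMin)
    msg <- c(msg, "empty length band")
  if (object@piMin > object@piMax) msg <- c(msg, "empty pI band")
  if (object@minFracZeta < 0 || object@minFracZeta > 1 ||
      object@minFracPhi < 0 || object@minFracPhi > 1)
    msg <- c(msg, "residue-class fractions must be in [0,1]")
  if (object@minDisorder < 0 || object@minDisorder > 1)
    msg <- c(msg, "minDisorder must be in [0,1]")
  if (!object@disorderSource %in% c("builtin", "external"))
    msg <- c(msg, "disorderSource must be 'builtin' or 'external'")
  if (object@matureTrim < 0L) msg <- c(msg, "matureTrim must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterConfig-class
#' @param lengthMin,lengthMax,piMin,piMax,minFracZeta,minFracPhi,repeatConfig,minPhiSticker,minZetaSticker,minDisorder,disorderSource,matureTrim
#'   see the corresponding slots.
#' @return A `FilterConfig` object.
#' @export
FilterConfig <- function(lengthMin = 100L, lengthMax = 1000L,
                         piMin = 7, piMax = 12,
                         minFracZeta = 0.1, minFracPhi = 0.03,
                         repeatConfig = RepeatConfig(),
                         minPhiSticker = 1L, minZetaSticker = 2L,
                         minDisorder = 0.5, disorderSource = "builtin",
                         matureTrim = 0L) {
  new("FilterConfig",
    lengthMin = as.integer(lengthMin), lengthMax = as.integer(lengthMax),
    piMin = as.numeric(piMin), piMax = as.numeric(piMax),
    minFracZeta = as.numeric(minFracZeta), minFracPhi = as.numeric(minFracPhi),
    repeatConfig = repeatConfig,
    minPhiSticker = as.integer(minPhiSticker),
    minZetaSticker = as.integer(minZetaSticker),
    minDisorder = as.numeric(minDisorder),
    disorderSource = disorderSource, matureTrim = as.integer(matureTrim)
  )
}

#' Result container for a linker screen
#'
#' Returned by [runFlipper()].  `candidates` holds one row per input protein
#' with its physicochemical profile, best repeat hit summary, disorder
#' fraction, per-stage pass flags and a rank score; `stageCounts` records the
#' number of proteins surviving after each successive filter stage (first
#' entry = input proteome size).
#'
#' @slot candidates a [S4Vectors::DataFrame] with one row per protein.
#' @slot stageCounts named integer vector of survivors per stage.
#' @slot config the [FilterConfig-class] used.
#'
#' @export
setClass("FlipperScreen",
  representation(
    candidates = "DataFrame", stageCounts = "integer", config = "FilterConfig"
  )
)

setValidity("FlipperScreen", function(object) {
  sc <- object@stageCounts
  if (length(sc) && any(diff(sc) > 0L))
    return("stageCounts must be nonincreasing")
  TRUE
})

#' Fitted curve model
#'
#' Result of one of the nonlinear curve fits: Hill binding occupancy,
#' exponential FRAP recovery, or a linear calibration.  Derived quantities
#' include the half-maximal recovery time `T0.5 = ln(2)/k` for FRAP fits and
#' the half-occupancy concentration `K0.5` (identical to `KD` for the
#' hyperbolic Hill form used here) for binding fits.
#'
#' @slot model `"hill"`, `"frap"` or `"calibration"`.
#' @slot params named numeric fitted parameters.
#' @slot derived named numeric derived quantities.
#' @slot se named numeric bootstrap standard errors (empty when `nBoot = 0`).
#' @slot ci matrix of percentile confidence bounds (rows = parameters).
#' @slot nBoot,seed bootstrap replicate count and RNG seed.
#' @slot rss residual sum of squares at the fitted parameters.
#'
#' @seealso [fitHill()], [fitFrap()], [calibrationQuantify()]
#' @export
setClass("FitResult",
  representation(
    model = "character", params = "numeric", derived = "numeric",
    se = "numeric", ci = "matrix", nBoot = "integer", seed = "integer",
    rss = "numeric"
  )
)

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@model %in% c("hill", "frap", "calibration"))
    msg <- c(msg, "unknown model")
  if (object@model == "hill" && isTRUE(object@params[["KD"]] <= 0))
    msg <- c(msg, "KD must be > 0")
  if (object@model == "frap" && isTRUE(object@params[["k"]] <= 0))
    msg <- c(msg, "k must be > 0")
  if (length(msg)) msg else TRUE
})
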