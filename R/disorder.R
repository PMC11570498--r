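# Intrinsic disorder scoring.  The screen needs only a per-residue
# disordered/ordered call and the resulting disordered fraction; the
# built-in predictor is the classic charge-hydropathy unfoldability index
# (FoldIndex form), and per-residue probability tables from any external
# predictor (IUPred-family, metapredict, ...) can be loaded instead.

#' Built-in charge--hydropathy disorder profile
#'
#' Sliding-window unfoldability index
#' `I = 2.785 * <H> - |<R>| - 1.151`, where `<H>` is the window mean
#' Kyte--Doolittle hydropathy rescaled to \[0,1\] via `(h + 4.5)/9` and
#' `<R>` is the window mean integer charge (K, R = +1; D, E = -1; others 0).
#' Residues with `I < 0` are called disordered.  Windows are centred on each
#' residue and truncated at the termini; `X` contributes 0 to both means but
#' counts toward the window size.
#'
#' @param seq amino-acid sequence.
#' @param window odd window width in residues (default 51).
#' @param hCharge charge assigned to histidine (default 0).
#' @param scales scale set from [residueScales()].
#' @return A [DisorderProfile-class] with `source = "builtin"`.
#' @examples
#' mean(foldIndex(strrep("E", 100))@calls)  # 1: poly-E is fully disordered
#' @export
foldIndex <- function(seq, window = 51L, hCharge = 0,
                      scales = residueScales()) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  ch <- .seq_chars(seq)
  n <- length(ch)
  h <- scales$hydropathy[ch]
  h[is.na(h)] <- 0                 # X: neutral contribution
  h <- (h + 4.5) / 9
  h[ch == "X"] <- 0
  r <- numeric(n)
  r[ch %in% c("K", "R")] <- 1
  r[ch %in% c("D", "E")] <- -1
  r[ch == "H"] <- hCharge
  half <- window %/% 2L
  csh <- cumsum(c(0, h))
  csr <- cumsum(c(0, r))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  w <- hi - lo + 1L
  mh <- (csh[hi + 1L] - csh[lo]) / w
  mr <- (csr[hi + 1L] - csr[lo]) / w
  I <- 2.785 * mh - abs(mr) - 1.151
  new("DisorderProfile", scores = I, calls = I < 0, source = "builtin")
}

#' Load external per-residue disorder scores
#'
#' Reads a TSV of external predictor output with columns
#' `(id, pos, score)` -- 1-based contiguous positions, scores in \[0,1\] --
#' and returns one [DisorderProfile-class] per protein, calling residues
#' with score >= 0.5 disordered.  Proteome ids absent from the file are
#' reported in the `missing` attribute rather than silently passed; ids in
#' the file but not in the proteome are skipped with a warning.
#'
#' @param path TSV path with a header line `id<TAB>pos<TAB>score`.
#' @param ids character vector of proteome ids the profiles are for.
#' @return Named list of `DisorderProfile` objects (source `"external"`),
#'   with attribute `missing` listing proteome ids lacking score data.
#' @export
loadDisorderScores <- function(path, ids) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "pos", "score") %in% names(df)))
    stop("expected columns id, pos, score")
  if (any(df$score < 0 | df$score > 1))
    stop("score outside [0, 1]")
  unknown <- setdiff(unique(df$id), ids)
  if (length(unknown)) {
    warning("skipping score rows for unknown id(s): ",
            paste(unknown, collapse = ", "))
    df <- df[df$id %in% ids, , drop = FALSE]
  }
  profiles <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (!identical(as.integer(d$pos), seq_len(nrow(d))))
      stop("positions not contiguous from 1 for id ", d$id[1L])
    new("DisorderProfile",
      scores = as.numeric(d$score), calls = d$score >= 0.5,
      source = "external"
    )
  })
  missing <- setdiff(ids, names(profiles))
  attr(profiles, "missing") <- missing
  profiles
}

#' Fraction of residues called disordered
#'
#' @param profile a [DisorderProfile-class].
#' @return Mean of the per-residue calls, in \[0, 1\].
#' @export
fractionDisordered <- function(profile) {
  stopifnot(is(profile, "DisorderProfile"))
  mean(profile@calls)
}
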