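# Tandem repeat detection on the Rubisco cross-linking length scale.
#
# The detector is a self-match / seed-extension scheme: for each candidate
# period p the sequence is compared against itself at lag p; runs of high
# local match density seed candidate regions, which are then refined by a
# bounded enumeration of (start, copy-count) decompositions scored against a
# majority-vote consensus.  The model is substitution-only with fixed period
# (no indels inside units), which matches the near-equal-length repeat units
# of the known pyrenoid linkers.

#' Self-match periodicity profile
#'
#' Binary indicator of self-matches at lag `p`: element `i` is 1 when
#' residue `i` equals residue `i + p`, for `i` in `1 .. length - p`.  This is
#' the seeding signal of the tandem repeat detector.
#'
#' @param seq amino-acid sequence.
#' @param p lag in residues, `1 <= p < nchar(seq)`.
#' @return Integer vector of 0/1 of length `nchar(seq) - p`.
#' @examples
#' periodicityProfile(strrep("ABC", 4), 3)  # all ones
#' @export
periodicityProfile <- function(seq, p) {
  ch <- .seq_chars(seq)
  n <- length(ch)
  p <- as.integer(p)
  if (p < 1L || p >= n) stop("lag p must satisfy 1 <= p < sequence length")
  as.integer(ch[seq_len(n - p)] == ch[seq_len(n - p) + p])
}

# Score one fixed (start, period, k full copies) decomposition.
# `code` is the sequence as integer codes into the alphabetically sorted
# `levels`, so "first max" in the majority vote is the alphabetical
# tie-break.  Returns NULL when invalid under cfg.
.score_decomposition <- function(code, levels, start, p, k, cfg) {
  n <- length(code)
  end_full <- start + k * p - 1L
  if (start < 1L || end_full > n) return(NULL)
  units <- matrix(code[start:end_full], nrow = p)   # columns = copies
  nlev <- length(levels)
  counts <- matrix(
    tabulate(seq_len(p) + (units - 1L) * p, nbins = p * nlev), p, nlev
  )
  cons_code <- max.col(counts, ties.method = "first")
  per_copy <- colMeans(units == cons_code)
  if (per_copy[1L] < cfg@minIdentity || per_copy[k] < cfg@minIdentity)
    return(NULL)
  copies <- as.numeric(k)
  end <- end_full
  ids <- per_copy
  # trailing partial copy: counts iff >= half a period and identity passes
  t_len <- min(p - 1L, n - end_full)
  if (t_len * 2L >= p) {
    tid <- mean(code[(end_full + 1L):(end_full + t_len)] ==
                  cons_code[seq_len(t_len)])
    if (tid >= cfg@minIdentity) {
      copies <- copies + t_len / p
      end <- end_full + t_len
      ids <- c(ids, tid)
    }
  }
  identity <- mean(ids)
  if (identity < cfg@minIdentity) return(NULL)
  if (length(unique(cons_code)) < cfg@minDistinct) return(NULL)
  list(
    start = start, end = end, period = p, copies = copies,
    consensus = paste(levels[cons_code], collapse = ""), identity = identity,
    score = copies * p * identity
  )
}

# deterministic ordering: score desc, then period asc, then start asc
.hit_order <- function(hits) {
  order(-vapply(hits, `[[`, 0, "score"),
        vapply(hits, `[[`, 0L, "period"),
        vapply(hits, `[[`, 0L, "start"))
}

.span_overlap <- function(a, b) {
  max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)
}

#' Detect tandem repeats
#'
#' Finds tandem repeats with unit length inside the configured period band.
#' For each period, runs of high self-match density (from
#' [periodicityProfile()]) seed candidate regions; each region is refined by
#' enumerating nearby start phases and copy counts, building a majority-vote
#' consensus (ties broken alphabetically), re-scoring every copy against it
#' and trimming to the first and last copy meeting the identity threshold.
#' A trailing partial copy of at least half a period contributes
#' fractionally.  Overlapping hits are resolved by score
#' (`copies * period * identity`; ties prefer the smaller period, then the
#' smaller start), and a hit whose period is a multiple of a kept hit's
#' period is suppressed as a harmonic when the base-period hit scores at
#' least as high, covers at least 80% of its span and has identity within
#' 0.05 (the score guard keeps the reported optimum independent of the
#' suppression).  For short sequences (work bound
#' `(length - 2 periodMin) * band width <= 2000`) every start phase is
#' enumerated and detection is exact with respect to this score; longer
#' sequences are seeded from the self-match profile first.
#'
#' @param seq amino-acid sequence, length at least `2 * periodMin`.
#' @param cfg a [RepeatConfig-class].
#' @return A list of [RepeatHit-class] objects (empty when nothing passes),
#'   ordered by score under the tie rules above.
#' @examples
#' unit <- "MKRAEDSLVNPQGTSWHKYEAIDCF"
#' hits <- findTandemRepeats(paste0("GSGSGS", strrep(unit, 4), "TPTPTP"))
#' hits[[1]]
#' @export
findTandemRepeats <- function(seq, cfg = RepeatConfig()) {
  ch <- .seq_chars(seq)
  n <- length(ch)
  if (n < 2L * cfg@periodMin)
    stop("sequence shorter than twice the minimum period")
  levels <- sort(unique(ch))
  code <- match(ch, levels)
  p_hi <- min(cfg@periodMax, n %/% 2L)
  # below this work bound every start phase is enumerated (exact detection);
  # above it, seeding prunes the start space (proteome-scale heuristic)
  exhaustive <- (n - 2L * cfg@periodMin) * (p_hi - cfg@periodMin + 1L) <= 2000L
  seed_thresh <- max(0, cfg@minIdentity - 0.25)
  raw <- list()
  for (p in seq.int(cfg@periodMin, p_hi)) {
    if (n < (cfg@minCopies - 0.5) * p) next
    if (exhaustive) {
      regions <- list(c(1L, n - cfg@minCopies * p + 1L, n))
    } else {
      m <- as.integer(ch[seq_len(n - p)] == ch[seq_len(n - p) + p])
      if (length(m) < p) next
      # moving mean of width p over the lag profile
      cs <- cumsum(c(0L, m))
      mm <- (cs[(p + 1L):(length(m) + 1L)] -
               cs[seq_len(length(m) - p + 1L)]) / p
      hot <- mm >= seed_thresh
      if (!any(hot)) next
      r <- rle(hot)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      min_run <- max(1L, floor((cfg@minCopies - 1L) * p * 0.5))
      runs <- which(r$values & r$lengths >= min_run)
      if (!length(runs)) next
      # merge runs separated by less than one period
      iv <- cbind(starts[runs], ends[runs])
      merged <- list(iv[1L, ])
      if (nrow(iv) > 1L) for (j in 2L:nrow(iv)) {
        last <- merged[[length(merged)]]
        if (iv[j, 1L] - last[2L] <= p) {
          merged[[length(merged)]] <- c(last[1L], iv[j, 2L])
        } else merged[[length(merged) + 1L]] <- iv[j, ]
      }
      regions <- lapply(merged, function(reg) {
        a <- reg[1L]; b <- reg[2L] + 2L * p - 1L  # seq coords of region
        c(max(1L, a - p), min(a + p, n - cfg@minCopies * p + 1L), min(n, b + p))
      })
    }
    for (reg in regions) {
      s_lo <- reg[1L]; s_hi <- reg[2L]; b <- reg[3L]
      if (s_hi < s_lo) next
      best <- NULL
      for (s in s_lo:s_hi) {
        k_max <- min((n - s + 1L) %/% p, ((b - s + 1L) %/% p) + 1L)
        if (k_max < cfg@minCopies) next
        for (k in cfg@minCopies:k_max) {
          cand <- .score_decomposition(code, levels, s, p, k, cfg)
          if (is.null(cand)) next
          if (is.null(best) || cand$score > best$score ||
              (cand$score == best$score && cand$start < best$start))
            best <- cand
        }
      }
      if (!is.null(best)) raw[[length(raw) + 1L]] <- best
    }
  }
  if (!length(raw)) return(list())
  raw <- raw[.hit_order(raw)]
  # drop duplicate (start, period, end) coming from merged seed regions
  key <- vapply(raw, function(h) paste(h$start, h$period, h$end), "")
  raw <- raw[!duplicated(key)]
  # harmonic suppression: period k*p dropped when a hit at p covers >= 80%
  # of its span with identity within 0.05
  keep_h <- rep(TRUE, length(raw))
  for (i in seq_along(raw)) {
    hi <- raw[[i]]
    for (j in seq_along(raw)) {
      if (i == j || !keep_h[j]) next
      hj <- raw[[j]]
      if (hj$period < hi$period && hi$period %% hj$period == 0L &&
          hj$score >= hi$score &&
          .span_overlap(hi, hj) >= 0.8 * (hi$end - hi$start + 1L) &&
          abs(hi$identity - hj$identity) <= 0.05) {
        keep_h[i] <- FALSE
        break
      }
    }
  }
  raw <- raw[keep_h]
  # overlap resolution: greedy by score/tie order, discard hits majorly
  # overlapping an already-kept hit
  kept <- list()
  for (h in raw) {
    clash <- FALSE
    for (k in kept) {
      ov <- .span_overlap(h, k)
      if (ov > 0.5 * min(h$end - h$start + 1L, k$end - k$start + 1L)) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept[[length(kept) + 1L]] <- h
  }
  lapply(kept, function(h) {
    new("RepeatHit",
      start = as.integer(h$start), end = as.integer(h$end),
      period = as.integer(h$period), copies = h$copies,
      consensus = h$consensus, identity = h$identity, score = h$score
    )
  })
}

#' Best repeat hit
#'
#' The maximum-score hit under the detector's ordering (score descending,
#' ties to the smaller period, then the smaller start), or `NULL` for empty
#' input.
#'
#' @param hits list of [RepeatHit-class] objects.
#' @return A single `RepeatHit` or `NULL`.
#' @export
bestHit <- function(hits) {
  if (!length(hits)) return(NULL)
  o <- order(-vapply(hits, hitScore, 0),
             vapply(hits, repeatPeriod, 0L),
             vapply(hits, function(h) h@start, 0L))
  hits[[o[1L]]]
}
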