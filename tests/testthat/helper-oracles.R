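# Independent oracles used by the test suite.  These deliberately share no
# code with the package: alignment scores come from explicit enumeration of
# every gapped pairing, repeat hits from exhaustive enumeration of every
# (start, period, copies) decomposition, and pI from a dense grid scan of
# the sign change.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.substitution_matrix_for_tests <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# score of one explicit alignment (op string over M/A/B; A = gap in b,
# B = gap in a) under matrix `mat` and affine cost open + len * ext per run
score_ops <- function(ops, a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  i <- 0L; j <- 0L; sc <- 0
  for (op in ops) {
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      sc <- sc + mat[ca[i], cb[j]]
    } else if (op == "A") i <- i + 1L else j <- j + 1L
  }
  r <- rle(ops)
  gaps <- r$lengths[r$values != "M"]
  sc - sum(open + gaps * ext)
}

# brute-force optimal global alignment score by enumerating all monotone
# paths (no gap-vs-gap columns by construction)
bruteForceAlignScore <- function(a, b, mat, open = 10, ext = 1) {
  na <- nchar(a); nb <- nchar(b)
  best <- -Inf
  recurse <- function(i, j, ops) {
    if (i == na && j == nb) {
      best <<- max(best, score_ops(ops, a, b, mat, open, ext))
      return(invisible())
    }
    if (i < na && j < nb) recurse(i + 1L, j + 1L, c(ops, "M"))
    if (i < na) recurse(i + 1L, j, c(ops, "A"))
    if (j < nb) recurse(i, j + 1L, c(ops, "B"))
  }
  recurse(0L, 0L, character())
  best
}

# exhaustive top tandem-repeat hit maximizing copies * period * identity,
# ties to smaller period then smaller start; same validity rules as the
# detector contract (end-copy identity, mean identity, fractional tail,
# low-complexity guard) but enumerated rather than searched
oracleTopRepeat <- function(seq, pmin, pmax, min_copies, min_id,
                            min_distinct) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- NULL
  for (p in pmin:pmax) {
    if (n < min_copies * p) next
    for (s in 1:(n - min_copies * p + 1)) {
      kmax <- (n - s + 1) %/% p
      for (k in min_copies:kmax) {
        cons <- character(p)
        for (jj in 1:p) {
          col <- ch[s + jj - 1 + (0:(k - 1)) * p]
          tb <- table(col)
          cons[jj] <- sort(names(tb)[tb == max(tb)])[1]
        }
        per <- vapply(1:k, function(ci)
          mean(ch[s + (ci - 1) * p + 0:(p - 1)] == cons), 0)
        if (per[1] < min_id || per[k] < min_id) next
        copies <- k; end <- s + k * p - 1; ids <- per
        tlen <- min(p - 1, n - end)
        if (2 * tlen >= p) {
          tid <- mean(ch[(end + 1):(end + tlen)] == cons[1:tlen])
          if (tid >= min_id) {
            copies <- k + tlen / p; end <- end + tlen; ids <- c(ids, tid)
          }
        }
        idm <- mean(ids)
        if (idm < min_id) next
        if (length(unique(cons)) < min_distinct) next
        sc <- copies * p * idm
        if (is.null(best) || sc > best$score ||
            (sc == best$score && (p < best$period ||
              (p == best$period && s < best$start))))
          best <- list(score = sc, period = p, start = s, end = end,
                       copies = copies, k = k)
      }
    }
  }
  best
}

# random 4-letter test string, a third of them with a planted mutated tandem
randomRepeatCase <- function(i) {
  alph <- c("A", "C", "G", "T")
  n <- sample(20:60, 1)
  if (i %% 3 == 0) {
    p <- sample(3:10, 1); k <- sample(3:5, 1)
    unit <- paste(sample(alph, p, replace = TRUE), collapse = "")
    bc <- strsplit(strrep(unit, k), "")[[1]]
    nmut <- stats::rbinom(1, length(bc), 0.05)
    if (nmut > 0) {
      pos <- sample(length(bc), nmut)
      bc[pos] <- sample(alph, nmut, replace = TRUE)
    }
    paste0(
      paste(sample(alph, sample(0:8, 1), replace = TRUE), collapse = ""),
      paste(bc, collapse = ""),
      paste(sample(alph, sample(0:8, 1), replace = TRUE), collapse = "")
    )
  } else {
    paste(sample(alph, n, replace = TRUE), collapse = "")
  }
}

# vectorized net charge over a pH grid (independent of netCharge), for the
# grid-scan pI oracle
gridScanPI <- function(seq, step = 1e-4) {
  pKa <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
           H = 6.5, Nterm = 8.6, K = 10.8, R = 12.5)
  ch <- strsplit(seq, "")[[1]]
  cnt <- table(factor(ch, levels = names(pKa)))
  cnt[["Nterm"]] <- 1L; cnt[["Cterm"]] <- 1L
  pH <- seq(0, 14, by = step)
  q <- numeric(length(pH))
  for (g in c("Nterm", "K", "R", "H"))
    q <- q + cnt[[g]] / (1 + 10^(pH - pKa[[g]]))
  for (g in c("Cterm", "D", "E", "C", "Y"))
    q <- q - cnt[[g]] / (1 + 10^(pKa[[g]] - pH))
  i <- which(q <= 0)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  # linear interpolation across the sign change
  pH[i - 1L] + step * q[i - 1L] / (q[i - 1L] - q[i])
}

randomPeptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# exact planted tandem with distinct-rich unit, for detector fixtures
plantedTandem <- function(unit, k, flank1 = "", flank2 = "") {
  paste0(flank1, strrep(unit, k), flank2)
}
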