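test_that("the periodicity profile flags self-matches at the given lag", {
  s <- strrep("MKRAEDSLVN", 4)
  expect_true(all(periodicityProfile(s, 10) == 1L))
  expect_length(periodicityProfile(s, 10), nchar(s) - 10)
  expect_error(periodicityProfile("MKV", 3), "lag")

  # i.i.d. uniform 20-letter background: mean match rate ~ 1/20
  set.seed(101)
  s <- randomPeptide(10000)
  m <- periodicityProfile(s, 37)
  se <- sqrt(0.05 * 0.95 / length(m))
  expect_lt(abs(mean(m) - 0.05), 3 * se)

  # reversal symmetry: profile of reversed sequence is the reversed profile
  s <- randomPeptide(200)
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_identical(periodicityProfile(s, 13), rev(periodicityProfile(r, 13)))
})

test_that("an exact planted tandem is recovered with its exact span", {
  set.seed(55)
  unit <- "MKRAEDSLVNPQGTSWHKYEA"           # 21 distinct-rich residues
  unit <- paste0(unit, "IDCF")               # 25-mer, 11+ distinct
  fl1 <- randomPeptide(30); fl2 <- randomPeptide(30)
  seq <- plantedTandem(unit, 4, fl1, fl2)
  hits <- findTandemRepeats(seq)
  expect_length(hits, 1)
  h <- hits[[1]]
  expect_equal(repeatPeriod(h), 25L)
  expect_equal(repeatCopies(h), 4)
  expect_equal(repeatIdentity(h), 1)
  expect_equal(unname(repeatSpan(h)), c(31L, 130L))
  expect_equal(repeatConsensus(h), unit)
})

test_that("detection survives 10% substitution noise in >= 95/100 replicates", {
  set.seed(7)
  unit <- paste(sample(AA20, 25, replace = TRUE), collapse = "")
  detected <- 0L
  for (r in 1:100) {
    body <- strsplit(strrep(unit, 4), "")[[1]]
    mut <- which(stats::runif(length(body)) < 0.10)
    body[mut] <- sample(AA20, length(mut), replace = TRUE)
    seq <- paste0(randomPeptide(30), paste(body, collapse = ""),
                  randomPeptide(30))
    h <- bestHit(findTandemRepeats(seq))
    if (!is.null(h) && abs(repeatPeriod(h) - 25L) <= 2L &&
        repeatCopies(h) >= 3 && repeatIdentity(h) >= 0.85)
      detected <- detected + 1L
  }
  expect_gte(detected, 95L)
})

test_that("low-complexity and random sequence produce no hits", {
  # homopolymer: consensus fails the distinct-residue guard
  expect_length(findTandemRepeats(strrep("A", 300)), 0)
  # (GPP)n-style short-period repeat: harmonics rejected the same way
  expect_length(findTandemRepeats(strrep("GPP", 60)), 0)
  # random 500-mers: no false hit in >= 99/100 seeds
  fp <- 0L
  for (r in 1:100) {
    set.seed(1000 + r)
    if (length(findTandemRepeats(randomPeptide(500))) > 0L) fp <- fp + 1L
  }
  expect_lte(fp, 1L)
})

test_that("hits are invariant to flank content and fully deterministic", {
  set.seed(77)
  unit <- paste(sample(AA20, 30, replace = TRUE), collapse = "")
  # even copy counts: a period-doubling harmonic can only tie the true
  # period and loses the tie-break, so the result is flank-independent
  for (r in 1:5) {
    seq <- plantedTandem(unit, 4, randomPeptide(40), randomPeptide(40))
    h <- bestHit(findTandemRepeats(seq))
    expect_equal(repeatPeriod(h), 30L)
    expect_equal(repeatCopies(h), 4)
  }
  # identical input + config -> identical hit list
  seq <- plantedTandem(unit, 4, randomPeptide(40), randomPeptide(40))
  h1 <- findTandemRepeats(seq)
  h2 <- findTandemRepeats(seq)
  expect_identical(lapply(h1, repeatSpan), lapply(h2, repeatSpan))
  expect_identical(vapply(h1, hitScore, 0), vapply(h2, hitScore, 0))
})

test_that("reported spans respect the copy-count arithmetic", {
  set.seed(88)
  for (r in 1:5) {
    unit <- paste(sample(AA20, sample(20:40, 1), replace = TRUE),
                  collapse = "")
    seq <- plantedTandem(unit, sample(3:6, 1), randomPeptide(20),
                         randomPeptide(20))
    for (h in findTandemRepeats(seq)) {
      sp <- repeatSpan(h)
      expect_gte(sp[["start"]], 1L)
      expect_lte(sp[["end"]], nchar(seq))
      expect_lte(repeatCopies(h) * repeatPeriod(h),
                 sp[["end"]] - sp[["start"]] + 1 + repeatPeriod(h))
    }
  }
})

test_that("bestHit applies the score ordering with its tie rules", {
  mk <- function(start, period, copies, identity) {
    new("RepeatHit", start = as.integer(start),
        end = as.integer(start + ceiling(copies * period) - 1L),
        period = as.integer(period), copies = copies,
        consensus = paste(rep(AA20[1:10], length.out = period),
                          collapse = ""),
        identity = identity, score = copies * period * identity)
  }
  a <- mk(1, 30, 3, 1)        # score 90
  b <- mk(200, 25, 3, 1)      # score 75
  expect_identical(bestHit(list(b, a)), a)
  expect_identical(bestHit(list(a)), a)
  expect_null(bestHit(list()))
  # equal scores: prefer period 24 over 30, then smaller start
  c24 <- mk(100, 24, 5, 1)    # score 120
  c30 <- mk(1, 30, 4, 1)      # score 120
  expect_equal(repeatPeriod(bestHit(list(c30, c24))), 24L)
  d <- mk(50, 24, 5, 1)
  expect_equal(repeatSpan(bestHit(list(c24, d)))[["start"]], 50L)
})

test_that("the top hit matches exhaustive enumeration on small strings", {
  # spot sample here; the full 200-case sweep lives in the acceptance suite
  cfg <- RepeatConfig(periodMin = 3, periodMax = 10, minCopies = 3,
                      minIdentity = 0.7, minDistinct = 2)
  set.seed(202)
  for (i in 1:40) {
    seq <- randomRepeatCase(i)
    orc <- oracleTopRepeat(seq, 3, 10, 3, 0.7, 2)
    det <- bestHit(findTandemRepeats(seq, cfg))
    if (is.null(orc)) {
      expect_null(det, info = seq)
    } else {
      expect_false(is.null(det), info = seq)
      expect_equal(repeatPeriod(det), orc$period, info = seq)
      expect_equal(floor(repeatCopies(det)), orc$k, info = seq)
      expect_equal(unname(repeatSpan(det)), c(orc$start, orc$end),
                   info = seq)
    }
  }
})
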