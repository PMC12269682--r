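test_that("scanPositions applies softmax to logits and validates scorers", {
  # logits (1, 0, ..., 0): closed-form softmax puts e/(e+19) on the first letter
  one <- function(residues, position) c(1, rep(0, 19))
  attr(one, "emits") <- "logits"
  g <- scanPositions(chainSequence("AC"), one)
  expect_equal(max(scores(g)), exp(1) / (exp(1) + 19), tolerance = 1e-12)
  expect_equal(scores(g)[1, 1], exp(1) / (exp(1) + 19), tolerance = 1e-12)

  unif <- function(residues, position) rep(1 / 20, 20)
  attr(unif, "emits") <- "probabilities"
  g2 <- scanPositions(chainSequence("ACDEF"), unif)
  expect_true(all(abs(scores(g2) - 0.05) < 1e-12))

  # exactly L invocations; rows normalized
  calls <- 0
  counting <- function(residues, position) { calls <<- calls + 1; rnorm(20) }
  attr(counting, "emits") <- "logits"
  g3 <- scanPositions(chainSequence("ACDEF"), counting)
  expect_equal(calls, 5)
  expect_true(all(abs(rowSums(scores(g3)) - 1) <= 1e-6))

  short <- function(residues, position) rep(1, 19)
  attr(short, "emits") <- "logits"
  expect_error(scanPositions(chainSequence("AC"), short), "expected 20")
  inf <- function(residues, position) c(Inf, rep(0, 19))
  attr(inf, "emits") <- "logits"
  expect_error(scanPositions(chainSequence("AC"), inf), "non-finite")
  expect_error(scanPositions(chainSequence("AC"), function(r, p) rnorm(20)),
               "emits")
})

test_that("wild-type rank follows the strictly-greater convention", {
  mkGrid <- function(rows, seqStr) {
    new("MutationGrid", sequence = chainSequence(seqStr),
        scores = rows, aaOrder = fwdyn:::.AA1)
  }
  # unique maximum at WT -> rank 1
  row <- rep(0.02, 20); row[1] <- 1 - 0.02 * 19
  prof <- wtRankProfile(mkGrid(matrix(row, 1), "A"))
  expect_equal(prof$wt_rank, 1L)
  # uniform row -> rank 1 (ties share the best rank)
  prof2 <- wtRankProfile(mkGrid(matrix(rep(0.05, 20), 1), "C"))
  expect_equal(prof2$wt_rank, 1L)
  # X wild type -> flagged missing
  prof3 <- wtRankProfile(mkGrid(matrix(rep(0.05, 20), 1), "X"))
  expect_true(is.na(prof3$wt_rank))

  # 1,000 random rows agree with the counting oracle
  set.seed(11)
  for (k in 1:5) {
    rows <- matrix(rexp(200 * 20), 200)
    rows <- rows / rowSums(rows)
    seqStr <- paste(sample(fwdyn:::.AA1, 200, replace = TRUE), collapse = "")
    prof <- wtRankProfile(mkGrid(rows, seqStr))
    wtIdx <- match(strsplit(seqStr, "")[[1]], fwdyn:::.AA1)
    expected <- vapply(1:200, function(p) bruteRank(rows[p, ], wtIdx[p]), 0L)
    expect_identical(prof$wt_rank, expected)
  }
})

test_that("region summaries equal brute-force per-column medians and IQRs", {
  map <- regionMapVH()
  # degenerate: every antibody rank 1 -> FW median 1, IQR 0
  mkProf <- function(ranks) data.frame(
    position = seq_along(ranks), wt = "A", wt_probability = 0.5,
    wt_rank = ranks, region = regionLookup(map, "H", seq_along(ranks)))
  rs <- regionSummary(lapply(1:4, function(i) mkProf(rep(1L, 120))))
  expect_true(all(rs$perRegion$median_rank == 1))
  expect_true(all(rs$perRegion$iqr_rank == 0))
  # ranks {1,2,3} at a position -> median 2
  rs2 <- regionSummary(lapply(1:3, function(i) mkProf(rep(i, 120))))
  expect_true(all(rs2$perPosition$median_rank == 2))

  # 10 synthetic profiles match brute-force column medians
  set.seed(21)
  profs <- lapply(1:10, function(i) mkProf(sample(20, 120, replace = TRUE)))
  rs3 <- regionSummary(profs)
  mat <- sapply(profs, function(p) p$wt_rank)
  expect_equal(rs3$perPosition$median_rank, apply(mat, 1, median))
  expect_equal(rs3$perPosition$iqr_rank,
               apply(mat, 1, function(v) unname(quantile(v, .75) - quantile(v, .25))))
})

test_that("germline correlation is Spearman with degenerate inputs flagged", {
  x <- 1:10 / 10
  expect_equal(germlineIdentityCorrelation(x, x * 2)$rho, 1)
  expect_equal(germlineIdentityCorrelation(x, rev(x))$rho, -1)
  set.seed(5)
  a <- sort(runif(20)) + rnorm(20, sd = 0.05)
  b <- sort(runif(20))
  got <- germlineIdentityCorrelation(a, b)$rho
  # brute-force rank formula
  d <- rank(a) - rank(b)
  expect_equal(got, 1 - 6 * sum(d^2) / (20 * (20^2 - 1)), tolerance = 1e-12)
  expect_warning(res <- germlineIdentityCorrelation(rep(0.5, 5), 1:5 / 5),
                 "constant")
  expect_false(res$defined)
  expect_error(germlineIdentityCorrelation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("ddG classification uses the sign rule with zero destabilizing", {
  tab <- data.frame(pos1 = 1:3, wt1 = "A", mut1 = "V",
                    pos2 = NA, wt2 = NA, mut2 = NA,
                    ddg = c(-1.2, 0, 0.7), scan_kind = "single")
  cl <- classifyStability(tab)
  expect_equal(cl$records$stability, c("stabilizing", "destabilizing",
                                       "destabilizing"))
  expect_equal(cl$destabilizingFraction + cl$stabilizingFraction, 1)

  set.seed(8)
  big <- data.frame(pos1 = 1:100, wt1 = "A", mut1 = "V", pos2 = NA,
                    wt2 = NA, mut2 = NA,
                    ddg = c(abs(rnorm(94)) + 1e-3, -abs(rnorm(6)) - 1e-3),
                    scan_kind = "single")
  expect_equal(classifyStability(big)$destabilizingFraction, 0.94)
})

test_that("repertoire occurrence returns empirical fractions with absent = 0", {
  set.seed(3)
  seqs <- vapply(1:200, function(i)
    paste(sample(c("A", "G"), 100, replace = TRUE), collapse = ""), "")
  # plant N at position 85 in exactly 10 sequences
  for (i in 1:10) substr(seqs[i], 85, 85) <- "N"
  prof <- buildRepertoireProfile(seqs)
  expect_equal(repertoireOccurrence(prof, 85, "N"), 0.05)
  expect_equal(repertoireOccurrence(prof, 1, "W"), 0)
  sums <- tapply(prof$fraction, prof$position, sum)
  expect_true(all(sums <= 1 + 1e-12))
  expect_error(repertoireOccurrence(prof, 500, "A"), "out of")
})

test_that("double-mutant filtering enforces ddG and occurrence but only reports consistency", {
  singles <- data.frame(
    pos1 = c(40, 43, 50, 59), wt1 = c("A", "K", "R", "R"),
    mut1 = c("R", "D", "S", "N"), pos2 = NA, wt2 = NA, mut2 = NA,
    ddg = c(0.4, 0.3, -0.3, -0.2), scan_kind = "single")
  doubles <- data.frame(
    pos1 = c(50, 10, 40), wt1 = c("R", "A", "A"), mut1 = c("S", "V", "R"),
    pos2 = c(59, 20, 43), wt2 = c("R", "A", "K"), mut2 = c("N", "V", "D"),
    ddg = c(-0.8, 0.5, -0.6), scan_kind = "double")
  prof <- data.frame(position = c(50, 59, 40, 43),
                     aa = c("S", "N", "R", "D"),
                     fraction = c(0.04, 0.06, 0.02, 0.02))
  attr(prof, "L") <- 120
  cand <- filterDoubleMutants(singles, doubles, prof)
  # consistent stabilizing double with common mutants: passes
  expect_true(cand$pass[1]); expect_true(cand$consistent[1])
  # destabilizing double fails regardless; also incomplete (no singles)
  expect_false(cand$pass[2]); expect_true(cand$incomplete[2])
  # stabilizing double whose singles are both destabilizing still passes,
  # with the consistency flag reported false
  expect_true(cand$pass[3]); expect_false(cand$consistent[3])
})

test_that("candidate sets shrink monotonically as the occurrence threshold rises", {
  set.seed(17)
  n <- 40
  singles <- data.frame(pos1 = rep(1:20, each = 2), wt1 = "A",
                        mut1 = rep(c("V", "L"), 20), pos2 = NA, wt2 = NA,
                        mut2 = NA, ddg = rnorm(40), scan_kind = "single")
  doubles <- data.frame(pos1 = sample(1:10, n, TRUE), wt1 = "A",
                        mut1 = sample(c("V", "L"), n, TRUE),
                        pos2 = sample(11:20, n, TRUE), wt2 = "A",
                        mut2 = sample(c("V", "L"), n, TRUE),
                        ddg = rnorm(n), scan_kind = "double")
  prof <- expand.grid(position = 1:20, aa = c("V", "L"),
                      stringsAsFactors = FALSE)
  prof$fraction <- runif(nrow(prof), 0, 0.2)
  attr(prof, "L") <- 20
  sizes <- sapply(seq(0, 0.19, length.out = 20), function(th)
    sum(filterDoubleMutants(singles, doubles, prof, occThreshold = th)$pass))
  expect_true(all(diff(sizes) <= 0))
})
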