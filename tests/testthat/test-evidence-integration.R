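gr <- function(start, end, strand = "*", contig = "c1") {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                         strand = strand)
}

test_that("overlapping evidence from several sources merges into one region", {
  tracks <- list(augustus = gr(101, 250), tobacco_est = gr(121, 260),
                 conservation = gr(111, 240))
  regs <- buildConsensusRegions(tracks)
  expect_length(regs, 1)
  expect_equal(GenomicRanges::start(regs), 101)
  expect_equal(GenomicRanges::end(regs), 260)
  expect_setequal(regs$supportingSources[[1]],
                  c("augustus", "tobacco_est", "conservation"))
  expect_equal(regs$score, 3L)
  expect_false(regs$shortPenalized)
})

test_that("minimum length and short-region penalty apply", {
  expect_length(buildConsensusRegions(list(augustus = gr(100, 158))), 0)
  regs <- buildConsensusRegions(list(augustus = gr(100, 179)))  # 80 bp
  expect_length(regs, 1)
  expect_true(regs$shortPenalized)
  expect_equal(regs$score, 0L)   # 1 source - 1 penalty
  # same interval with two sources scores 1
  regs2 <- buildConsensusRegions(list(augustus = gr(100, 179),
                                      conservation = gr(100, 179)))
  expect_equal(regs2$score, 1L)
})

test_that("duplicate and unnamed tracks are rejected", {
  expect_error(buildConsensusRegions(list(gr(1, 100))), "named")
  expect_error(
    buildConsensusRegions(setNames(list(gr(1, 100), gr(1, 100)),
                                   c("augustus", "augustus"))),
    "duplicate")
})

test_that("filter rules remove EST-only, fgenesh-on-repeat and repeat overlap", {
  repeats <- gr(1000, 1100)
  tracks <- list(
    tobacco_est = gr(101, 300),                       # rule a: EST only
    fgenesh = c(gr(401, 600), gr(1050, 1250)),        # 2nd overlaps repeat
    conservation = gr(401, 600))
  regs <- buildConsensusRegions(tracks, repeats)
  out <- filterRegions(regs)
  log <- S4Vectors::metadata(out)$filterLog
  expect_equal(sort(log$rule), c("est_only", "fgenesh_repeat"))
  # {fgenesh, conservation} with repeat overlap survives rule b
  expect_equal(GenomicRanges::start(out), 401)

  # strict 25% boundary: exactly 25% kept, 25.5% removed
  regs200 <- buildConsensusRegions(
    list(augustus = gr(101, 300), conservation = gr(101, 300)),
    repeats = gr(101, 150))                      # 50/200 = 0.25
  expect_length(filterRegions(regs200), 1)
  regs200b <- buildConsensusRegions(
    list(augustus = gr(101, 300), conservation = gr(101, 300)),
    repeats = gr(101, 151))                      # 51/200 = 0.255
  out2 <- filterRegions(regs200b)
  expect_length(out2, 0)
  expect_equal(S4Vectors::metadata(out2)$filterLog$rule, "repeat_overlap")

  # rule c: TE-protein label track
  te <- filterRegions(regs200, teLabels = gr(150, 160))
  expect_length(te, 0)
  expect_equal(S4Vectors::metadata(te)$filterLog$rule, "te_match")
})

test_that("strand assignment votes by source priority", {
  tracks <- list(augustus = gr(101, 300, "+"),
                 conservation = gr(101, 300, "-"))
  regs <- buildConsensusRegions(tracks)
  # augustus outranks conservation
  expect_equal(as.character(GenomicRanges::strand(
    assignStrand(regs, tracks))), "+")
  # unanimous minus
  tr2 <- list(augustus = gr(101, 300, "-"), tobacco_est = gr(101, 300, "-"))
  expect_equal(as.character(GenomicRanges::strand(
    assignStrand(buildConsensusRegions(tr2), tr2))), "-")
  # only unstranded evidence -> '*'
  tr3 <- list(conservation = gr(101, 300, "*"))
  expect_equal(as.character(GenomicRanges::strand(
    assignStrand(buildConsensusRegions(tr3), tr3))), "*")
  # transcript evidence outvotes two ab initio predictions combined
  tr4 <- list(tobacco_est = gr(101, 300, "-"),
              augustus = gr(101, 300, "+"), fgenesh = gr(101, 300, "+"))
  expect_equal(as.character(GenomicRanges::strand(
    assignStrand(buildConsensusRegions(tr4), tr4))), "-")
})

test_that("ranking sorts by score, then length, then position", {
  tracks <- list(
    augustus = c(gr(101, 400), gr(1001, 1400), gr(2001, 2200)),
    conservation = c(gr(1001, 1400), gr(2001, 2200)),
    tobacco_est = c(gr(1001, 1400)))
  regs <- buildConsensusRegions(tracks)
  rk <- rankRegions(regs)
  expect_equal(rk$score, c(3L, 2L, 1L))
  # tie on score broken by longer region
  t2 <- list(augustus = c(gr(101, 200), gr(1001, 1300)))
  rk2 <- rankRegions(buildConsensusRegions(t2))
  expect_equal(GenomicRanges::width(rk2), c(300, 100))
  expect_length(rankRegions(regs, targetCount = 0), 0)
  expect_length(rankRegions(regs, targetCount = 2), 2)
  expect_error(rankRegions(regs, targetCount = -1), ">= 0")
})

test_that("exon-level evaluation counts exact boundary matches", {
  truth <- c(gr(1, 100), gr(201, 300), gr(401, 500))
  expect_equal(exonEval(truth, truth)[c("sensitivity", "specificity")],
               list(sensitivity = 1, specificity = 1))
  pred <- c(gr(1, 100), gr(201, 300), gr(601, 700))
  ev <- exonEval(pred, truth)
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$specificity, 2 / 3)
  empty <- exonEval(GenomicRanges::GRanges(), truth)
  expect_equal(empty$sensitivity, 0)
  expect_false(empty$specificityDefined)
  expect_error(exonEval(pred, GenomicRanges::GRanges()), "truth")
})

test_that("consensus building equals the positionwise oracle on random data", {
  set.seed(606)
  for (rep in 1:8) {
    contigLen <- sample(5000:20000, 1)
    tracks <- list()
    for (src in sample(DEFAULT_SOURCES, sample(2:5, 1))) {
      n <- sample(3:10, 1)
      st <- sample(contigLen - 500, n)
      tracks[[src]] <- GenomicRanges::GRanges(
        "c1", IRanges::IRanges(st, st + sample(60:400, n, replace = TRUE)))
    }
    regs <- buildConsensusRegions(tracks)
    want <- oracleConsensusRuns(tracks, "c1", contigLen, 60L)
    expect_equal(GenomicRanges::ranges(regs), want, info = paste("rep", rep))
    # pairwise non-overlap and sortedness
    if (length(regs) > 1) {
      expect_true(all(GenomicRanges::start(regs)[-1] >
                        GenomicRanges::end(regs)[-length(regs)]))
    }
    expect_true(all(regs$score >= 0 & regs$score <= 7))
  }
})

test_that("adding a supporting source never decreases a region's score", {
  set.seed(33)
  base <- list(augustus = gr(101, 400), conservation = gr(101, 400))
  s1 <- buildConsensusRegions(base)$score
  more <- c(base, list(tobacco_est = gr(101, 400)))
  s2 <- buildConsensusRegions(more)$score
  expect_gte(s2, s1)
  # saturates at 7
  all7 <- lapply(DEFAULT_SOURCES, function(s) gr(101, 400))
  names(all7) <- DEFAULT_SOURCES
  expect_equal(buildConsensusRegions(all7)$score, 7L)
})

test_that("pipeline recovery improves under jitter-tolerant matching", {
  ac <- generateAnnotatedContigs(contigPlan(sensitivity = 0.8, fdr = 0.1,
                                            jitterSd = 10), seed = 9)
  regs <- buildConsensusRegions(ac$tracks, ac$repeats)
  exact <- exonEval(GenomicRanges::granges(regs), ac$truthExons)
  tol <- exonEval(GenomicRanges::granges(regs), ac$truthExons,
                  tolerance = 25L)
  expect_gte(tol$sensitivity, exact$sensitivity)
  expect_gte(tol$specificity, exact$specificity)
  expect_gt(tol$sensitivity, 0.5)
})
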