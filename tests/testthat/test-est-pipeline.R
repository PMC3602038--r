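test_that("longest ORF matches hand-built cases at the length boundary", {
  s150 <- paste0("ATG", strrep("GCT", 48), "TAA")   # exactly 150 nt
  orf <- longestOrf(s150, 150L)
  expect_equal(orf[c("start", "end", "strand")],
               list(start = 1L, end = 150L, strand = "+"))
  rc <- longestOrf(revComp(s150), 150L)
  expect_equal(rc$end - rc$start + 1L, 150L)
  expect_equal(rc$strand, "-")
  # 147 nt is below the floor
  expect_null(longestOrf(paste0("ATG", strrep("GCT", 47), "TAA"), 150L))
})

test_that("longest ORF agrees with the brute-force oracle on random seqs", {
  set.seed(2718)
  nDisagree <- 0
  for (i in 1:150) {
    s <- randSeq(sample(200:500, 1))
    got <- longestOrf(s, 60L)       # lower floor exercises more cases
    want <- oracleLongestOrf(s, 60L)
    if (is.null(want)) {
      expect_null(got, info = paste("seq", i))
    } else {
      expect_false(is.null(got), info = paste("seq", i))
      expect_equal(got[c("start", "end", "strand")], want,
                   info = paste("seq", i))
    }
  }
})

test_that("redundancy filtering flags near-identical copies only", {
  set.seed(64)
  gseq <- c(g1 = randSeq(400))
  identicalEst <- estContigs(c(e1 = gseq[["g1"]]))
  out <- redundancyFilter(identicalEst, gseq)
  expect_equal(out$status, "redundant")

  # 90% identity is below the 98% threshold
  div <- exonforge:::.mutateSeq(gseq[["g1"]], 40L)
  out2 <- redundancyFilter(estContigs(c(e2 = div)), gseq)
  expect_equal(out2$status, "unscreened")

  # 1% mutations still trip the 98% threshold
  near <- exonforge:::.mutateSeq(gseq[["g1"]], 4L)
  out3 <- redundancyFilter(estContigs(c(e3 = near)), gseq)
  expect_equal(out3$status, "redundant")

  # empty genomic set keeps everything
  out4 <- redundancyFilter(estContigs(c(e4 = randSeq(300))), character(0))
  expect_equal(out4$status, "unscreened")
})

test_that("redundancy filtering is order-independent", {
  e <- generateEstContigs(estContigPlan(), seed = 31)
  ests <- estContigs(e$ests)
  r1 <- redundancyFilter(ests, e$genomicSeqs)
  perm <- withr::with_seed(4, sample(nrow(ests)))
  r2 <- redundancyFilter(ests[perm, ], e$genomicSeqs)
  m1 <- setNames(r1$status, r1$id)
  m2 <- setNames(r2$status, r2$id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("TE/repeat filtering uses the strict 25% union rule", {
  L <- 400L
  mk <- function(cov) {
    GenomicRanges::GRanges("e1", IRanges::IRanges(1L, as.integer(cov * L)))
  }
  ests <- estContigs(c(e1 = strrep("ACGT", 100)))
  expect_equal(teRepeatFilter(ests, mk(0.26))$status, "te_filtered")
  expect_equal(teRepeatFilter(ests, mk(0.25))$status, "unscreened")
  expect_equal(teRepeatFilter(ests)$status, "unscreened")
  expect_equal(teRepeatFilter(ests, teLabels = "e1")$status, "te_filtered")
})

test_that("EST accounting subtracts the filter stages", {
  expect_equal(estContigAccounting(55520, 8451, 26882), 20187)
  expect_error(estContigAccounting(10, 8, 5), "exceed")
})

test_that("the full EST branch reproduces planted statuses and conserves", {
  plan <- estContigPlan(c(orf_ok = 10L, orf_short = 5L, redundant = 8L,
                          repeat_laden = 4L))
  e <- generateEstContigs(plan, seed = 13)
  ests <- estContigs(e$ests)
  ests <- teRepeatFilter(ests, e$masks)
  ests <- redundancyFilter(ests, e$genomicSeqs)
  ests <- orfScreen(ests)
  got <- table(ests$status)
  expect_equal(unname(got[["kept"]]), 10L)
  expect_equal(unname(got[["te_filtered"]]), 4L)
  expect_equal(unname(got[["redundant"]]), 8L)
  expect_equal(unname(got[["no_orf"]]), 5L)
  # statuses are mutually exclusive and cover everything
  expect_equal(sum(got), nrow(ests))
  # kept contigs carry a codon-multiple ORF of >= 150 nt with a strand
  kept <- ests[ests$status == "kept", ]
  orfLen <- kept$orf_end - kept$orf_start + 1L
  expect_true(all(orfLen >= 150L))
  expect_true(all(orfLen %% 3L == 0L))
  expect_true(all(kept$orf_strand %in% c("+", "-")))
})

test_that("candidate-set merging removes duplicates with genomic precedence", {
  set.seed(88)
  # gA carries an ORF so its EST copy passes the ORF screen
  gA <- paste0(randSeq(60), "ATG", strrep("GCA", 55), "TAA", randSeq(60))
  gSeq <- c(gA = gA, gB = randSeq(300))
  regs <- buildConsensusRegions(list(
    augustus = GenomicRanges::GRanges(c("cA", "cB"),
                                      IRanges::IRanges(c(101, 101),
                                                       c(400, 400)))))
  names(regs) <- names(gSeq)
  # an EST identical to gA must lose to the genomic candidate
  ests <- estContigs(c(dup = gSeq[["gA"]],
                       novel = paste0("ATG", strrep("GGA", 60), "TAA")))
  ests <- orfScreen(ests)
  cs <- buildCandidateSet(regs, gSeq, ests)
  lg <- ledger(cs)
  expect_equal(unname(lg[["genomic_kept"]]), 2L)
  expect_equal(unname(lg[["est_redundant"]]), 1L)
  expect_equal(unname(lg[["final"]]),
               unname(lg[["genomic_kept"]] + lg[["est_kept"]]))
  expect_true("novel" %in% names(regions(cs)))
  expect_false("dup" %in% names(regions(cs)))
  ro <- regions(cs)
  expect_setequal(unique(ro$origin), c("genomic", "est"))
})

test_that("identical genomic candidates collapse to one survivor", {
  set.seed(7)
  s <- randSeq(300)
  gSeq <- c(g1 = s, g2 = s)
  regs <- buildConsensusRegions(list(
    augustus = GenomicRanges::GRanges(c("c1", "c2"),
                                      IRanges::IRanges(c(1, 1),
                                                       c(300, 300)))))
  names(regs) <- names(gSeq)
  ests <- orfScreen(estContigs(setNames(character(0), character(0))))
  cs <- buildCandidateSet(regs, gSeq, ests)
  expect_equal(unname(ledger(cs)[["genomic_kept"]]), 1L)
  expect_equal(unname(ledger(cs)[["genomic_redundant"]]), 1L)
})

test_that("planted duplicate fixtures survive exactly as the truth says", {
  plan <- estContigPlan(c(orf_ok = 6L, orf_short = 3L, redundant = 5L,
                          repeat_laden = 2L))
  e <- generateEstContigs(plan, seed = 7)
  ests <- estContigs(e$ests)
  ests <- teRepeatFilter(ests, e$masks)
  ests <- redundancyFilter(ests, e$genomicSeqs)
  ests <- orfScreen(ests)
  gRegs <- buildConsensusRegions(list(
    augustus = GenomicRanges::GRanges(
      paste0("gc", seq_along(e$genomicSeqs)),
      IRanges::IRanges(1L, nchar(e$genomicSeqs)))))
  names(gRegs) <- names(e$genomicSeqs)
  cs <- buildCandidateSet(gRegs, e$genomicSeqs, ests)
  lg <- ledger(cs)
  expect_equal(unname(lg[["est_redundant"]]), 5L)
  expect_equal(unname(lg[["est_kept"]]), 6L)
  expect_equal(unname(lg[["final"]]),
               length(e$genomicSeqs) + 6L)
})
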