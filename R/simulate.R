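# Seeded generators for every input class the pipeline consumes, with
# ground-truth labels. Each generator is a pure function of (plan, seed):
# the RNG state is scoped with withr::with_seed, so the same call yields
# byte-identical output and the caller's RNG is untouched.

#' Simulation plans
#'
#' Plain-list plans with the default study conditions for each generator.
#' \describe{
#'   \item{gssReadPlan}{per-category read counts and the Sanger-like read
#'     length distribution (normal mean 650 sd 100, truncated);}
#'   \item{contigPlan}{contig count/length, planted exon geometry and the
#'     per-source evidence corruption rates (sensitivity 0.8, false
#'     discovery rate 0.1, boundary jitter sd 10 bp);}
#'   \item{estContigPlan}{per-category EST contig counts;}
#'   \item{fieldTrialPlan}{grid dimensions and the planted genotype,
#'     environment, interaction, block, spatial and noise scales.}
#' }
#'
#' @param counts named per-category counts.
#' @return a plan list consumed by the corresponding generator.
#' @name simPlans
NULL

#' @rdname simPlans
#' @export
gssReadPlan <- function(counts = c(vector = 5L, contaminant = 2L,
                                   organelle = 3L, short = 4L,
                                   ambiguous = 2L, trim_casualty = 0L,
                                   clean = 84L)) {
  stopifnot(all(counts >= 0L))
  list(counts = counts,
       readLen = c(mean = 650, sd = 100, min = 240, max = 1000),
       shortLen = c(50L, 99L),
       trimCasualtyLen = c(150L, 219L),
       ambiguousFrac = 0.05,
       nVectors = 3L, vectorLen = 600L,
       contaminantLen = 5000L, organelleLen = 5000L)
}

#' Generate GSS reads with planted removal categories
#'
#' Produces reads that the cleaning cascade must classify exactly as
#' planted: reads with spliced vector segments, exact substrings of the
#' contaminant / organellar references, short reads, reads with more than
#' 3\% undetermined bases, reads long enough to survive screening but not
#' the 60 bp end trim, and clean reads. The reference libraries are
#' themselves generated from the seed and returned.
#'
#' @param plan a [gssReadPlan()].
#' @param seed integer seed.
#' @return list with \code{reads} (named character), \code{quals} (named
#'   list of phred integers), \code{truth} (data.frame \code{id},
#'   \code{category}), and \code{libraries} (list \code{vectors},
#'   \code{contaminants}, \code{organelles}).
#' @export
generateGssReads <- function(plan = gssReadPlan(), seed = 1L) {
  cn <- plan$counts
  if (any(cn < 0L)) stop("infeasible plan: negative counts")
  if (plan$shortLen[2L] >= 100L) {
    stop("infeasible plan: 'short' reads must be shorter than 100 bp")
  }
  withr::with_seed(seed, {
    vectors <- setNames(
      vapply(seq_len(plan$nVectors), function(i) .randSeq(plan$vectorLen),
             character(1)),
      paste0("vec", seq_len(plan$nVectors)))
    contaminants <- c(contam1 = .randSeq(plan$contaminantLen))
    organelles <- c(mito = .randSeq(plan$organelleLen),
                    plastid = .randSeq(plan$organelleLen))
    rlen <- function(n, lo = plan$readLen[["min"]],
                     hi = plan$readLen[["max"]]) {
      pmin(pmax(round(rnorm(n, plan$readLen[["mean"]],
                            plan$readLen[["sd"]])), lo), hi)
    }
    reads <- character(0)
    truth <- list()
    emit <- function(id, seq, category) {
      reads[[id]] <<- seq
      truth[[length(truth) + 1L]] <<- data.frame(id = id,
                                                 category = category)
    }
    for (i in seq_len(cn[["vector"]])) {
      v <- sample(vectors, 1L)
      ins <- substr(v, 1L, 120L)
      emit(sprintf("vec_read%03d", i),
           paste0(ins, .randSeq(rlen(1L) - 120L)), "vector")
    }
    for (i in seq_len(cn[["contaminant"]])) {
      L <- sample(200:400, 1L)
      s <- sample(nchar(contaminants[[1L]]) - L, 1L)
      emit(sprintf("con_read%03d", i),
           substr(contaminants[[1L]], s, s + L - 1L), "contaminant")
    }
    for (i in seq_len(cn[["organelle"]])) {
      org <- sample(organelles, 1L)
      L <- sample(200:400, 1L)
      s <- sample(nchar(org) - L, 1L)
      emit(sprintf("org_read%03d", i), substr(org, s, s + L - 1L),
           "organelle")
    }
    for (i in seq_len(cn[["short"]])) {
      emit(sprintf("sho_read%03d", i),
           .randSeq(sample(plan$shortLen[1L]:plan$shortLen[2L], 1L)),
           "short")
    }
    for (i in seq_len(cn[["ambiguous"]])) {
      L <- rlen(1L)
      s <- strsplit(.randSeq(L), "")[[1]]
      nN <- ceiling(plan$ambiguousFrac * L)
      s[sample(L, nN)] <- "N"
      emit(sprintf("amb_read%03d", i), paste(s, collapse = ""),
           "ambiguous")
    }
    for (i in seq_len(cn[["trim_casualty"]])) {
      emit(sprintf("trm_read%03d", i),
           .randSeq(sample(plan$trimCasualtyLen[1L]:plan$trimCasualtyLen[2L],
                           1L)), "trim_casualty")
    }
    for (i in seq_len(cn[["clean"]])) {
      emit(sprintf("cln_read%03d", i), .randSeq(rlen(1L)), "clean")
    }
    truthDf <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = character(0), category = character(0))
    if (length(reads)) {
      o <- sample(length(reads))
      reads <- reads[o]
    }
    quals <- lapply(reads, function(s) {
      as.integer(pmin(pmax(round(rnorm(nchar(s), 35, 8)), 2L), 60L))
    })
    list(reads = unlist(reads), quals = quals, truth = truthDf,
         libraries = list(vectors = vectors, contaminants = contaminants,
                          organelles = organelles))
  })
}

#' @rdname simPlans
#' @param nContigs,contigLen,exonsPerContig,exonLenRange,minGap planted
#'   contig geometry.
#' @param sources evidence source ids to emit.
#' @param sensitivity,fdr,jitterSd per-source corruption: probability of
#'   emitting each true exon, fraction of emitted intervals that are
#'   false, and Gaussian boundary jitter (bp).
#' @param nRepeats,repeatLenRange planted repeat intervals (negative
#'   track).
#' @export
contigPlan <- function(nContigs = 5L, contigLen = 10000L,
                       exonsPerContig = 8L, exonLenRange = c(60L, 400L),
                       minGap = 200L, sources = DEFAULT_SOURCES,
                       sensitivity = 0.8, fdr = 0.1, jitterSd = 10,
                       nRepeats = 3L, repeatLenRange = c(100L, 300L)) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fdr >= 0, fdr < 1,
            jitterSd >= 0)
  list(nContigs = nContigs, contigLen = contigLen,
       exonsPerContig = exonsPerContig, exonLenRange = exonLenRange,
       minGap = minGap, sources = sources, sensitivity = sensitivity,
       fdr = fdr, jitterSd = jitterSd, nRepeats = nRepeats,
       repeatLenRange = repeatLenRange)
}

#' Generate annotated contigs with planted exons and noisy evidence
#'
#' Plants non-overlapping exons (with strands) on random contigs and
#' derives per-source evidence tracks by dropping exons (1 - sensitivity),
#' jittering boundaries (Gaussian, rounded), and adding false intervals in
#' the gaps (at a rate giving the requested false discovery fraction).
#' Repeat intervals are planted in gaps as the negative track.
#' Conservation evidence is emitted unstranded; all other sources carry
#' the exon's strand.
#'
#' @param plan a [contigPlan()].
#' @param seed integer seed.
#' @return list with \code{contigs} (named character), \code{truthExons}
#'   (\code{GRanges}), \code{tracks} (named list of \code{GRanges}) and
#'   \code{repeats} (\code{GRanges}).
#' @export
generateAnnotatedContigs <- function(plan = contigPlan(), seed = 1L) {
  withr::with_seed(seed, {
    contigs <- setNames(
      vapply(seq_len(plan$nContigs), function(i) .randSeq(plan$contigLen),
             character(1)),
      sprintf("contig%02d", seq_len(plan$nContigs)))
    exons <- list()
    gapZones <- list()
    for (cid in names(contigs)) {
      pos <- plan$minGap
      placed <- 0L
      while (placed < plan$exonsPerContig) {
        L <- sample(plan$exonLenRange[1L]:plan$exonLenRange[2L], 1L)
        if (pos + L + plan$minGap > plan$contigLen) break
        exons[[length(exons) + 1L]] <- data.frame(
          seqnames = cid, start = pos, end = pos + L - 1L,
          strand = sample(c("+", "-"), 1L))
        gapZones[[length(gapZones) + 1L]] <- data.frame(
          seqnames = cid, start = pos + L + 20L,
          end = pos + L + plan$minGap - 20L)
        pos <- pos + L + plan$minGap
        placed <- placed + 1L
      }
    }
    exonDf <- do.call(rbind, exons)
    truthExons <- GenomicRanges::GRanges(exonDf$seqnames,
                                         IRanges::IRanges(exonDf$start,
                                                          exonDf$end),
                                         strand = exonDf$strand)
    gapDf <- do.call(rbind, gapZones)
    sampleGapInterval <- function(len) {
      gi <- sample(nrow(gapDf), 1L)
      zoneLen <- gapDf$end[gi] - gapDf$start[gi] + 1L
      len <- min(len, zoneLen)
      s <- gapDf$start[gi] + sample(max(1L, zoneLen - len + 1L), 1L) - 1L
      list(seqnames = gapDf$seqnames[gi], start = s, end = s + len - 1L)
    }
    tracks <- list()
    for (src in plan$sources) {
      keep <- runif(length(truthExons)) <= plan$sensitivity
      kept <- truthExons[keep]
      st <- GenomicRanges::start(kept)
      en <- GenomicRanges::end(kept)
      if (plan$jitterSd > 0 && length(kept)) {
        st <- pmax(1L, st + as.integer(round(rnorm(length(kept), 0,
                                                   plan$jitterSd))))
        en <- pmin(plan$contigLen,
                   en + as.integer(round(rnorm(length(kept), 0,
                                               plan$jitterSd))))
        bad <- en - st < 20L
        st[bad] <- GenomicRanges::start(kept)[bad]
        en[bad] <- GenomicRanges::end(kept)[bad]
      }
      gr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(kept), IRanges::IRanges(st, en),
        strand = if (src == "conservation") "*" else
          GenomicRanges::strand(kept))
      nFalse <- round(plan$fdr / (1 - plan$fdr) * length(gr))
      if (nFalse > 0L) {
        fi <- lapply(seq_len(nFalse), function(i) {
          g <- sampleGapInterval(sample(80:160, 1L))
          GenomicRanges::GRanges(g$seqnames,
                                 IRanges::IRanges(g$start, g$end),
                                 strand = "*")
        })
        gr <- suppressWarnings(c(gr, do.call(c, fi)))
      }
      tracks[[src]] <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    }
    reps <- lapply(seq_len(plan$nRepeats), function(i) {
      g <- sampleGapInterval(sample(plan$repeatLenRange[1L]:
                                      plan$repeatLenRange[2L], 1L))
      GenomicRanges::GRanges(g$seqnames, IRanges::IRanges(g$start, g$end))
    })
    repeats <- if (length(reps)) suppressWarnings(do.call(c, reps)) else
      GenomicRanges::GRanges()
    list(contigs = contigs, truthExons = truthExons, tracks = tracks,
         repeats = repeats)
  })
}

#' Randomly truncate contigs, updating planted-exon truth
#'
#' Each contig is cut to a sampled length at a uniform random offset,
#' emulating a fragmented assembly; a sampled length at or above the
#' contig length keeps the contig whole. Planted exons are intersected
#' with the window and shifted into the new coordinates (an exon split by
#' the cut survives as its truncated fragment).
#'
#' @param contigs named character vector.
#' @param truthExons \code{GRanges} of planted exons.
#' @param lengthSampler function(n) returning n lengths, or a single
#'   number for a constant length. The default log-normal is calibrated
#'   to a median around 990 bp, a typical fragment scale for a low
#'   coverage survey-sequence assembly.
#' @param seed integer seed.
#' @return list with \code{contigs} and \code{truthExons} after
#'   truncation.
#' @export
truncateContigs <- function(contigs, truthExons,
                            lengthSampler = function(n)
                              round(stats::rlnorm(n, log(990), 0.6)),
                            seed = 1L) {
  if (is.numeric(lengthSampler)) {
    const <- lengthSampler
    lengthSampler <- function(n) rep(const, n)
  }
  withr::with_seed(seed, {
    lens <- lengthSampler(length(contigs))
    outSeq <- character(0)
    outExons <- GenomicRanges::GRanges()
    for (i in seq_along(contigs)) {
      cid <- names(contigs)[i]
      n <- nchar(contigs[[i]])
      L <- min(lens[i], n)
      s <- if (L >= n) 1L else sample(n - L + 1L, 1L)
      outSeq[[cid]] <- substr(contigs[[i]], s, s + L - 1L)
      ex <- truthExons[as.character(
        GenomicRanges::seqnames(truthExons)) == cid]
      if (length(ex)) {
        win <- GenomicRanges::GRanges(cid, IRanges::IRanges(s, s + L - 1L))
        ex <- suppressWarnings(GenomicRanges::pintersect(
          ex, rep(win, length(ex)), ignore.strand = FALSE,
          drop.nohit.ranges = FALSE))
        ex <- ex[GenomicRanges::width(ex) > 0L & S4Vectors::mcols(ex)$hit]
        if (length(ex)) {
          ex <- GenomicRanges::shift(ex, -(s - 1L))
          S4Vectors::mcols(ex) <- NULL
          outExons <- suppressWarnings(c(outExons, ex))
        }
      }
    }
    list(contigs = unlist(outSeq), truthExons = outExons)
  })
}

#' @rdname simPlans
#' @param estLen typical EST contig length (bp).
#' @export
estContigPlan <- function(counts = c(orf_ok = 10L, orf_short = 5L,
                                     redundant = 8L, repeat_laden = 4L),
                          estLen = 400L) {
  stopifnot(all(counts >= 0L))
  list(counts = counts, estLen = estLen)
}

#' Generate EST contigs with planted ORFs, redundancy and repeats
#'
#' Categories: \code{orf_ok} contigs carry a planted 210 bp ORF;
#' \code{orf_short} contigs are verified to carry no ORF of 150 bp or
#' more on either strand; \code{redundant} contigs are 99\%-identity
#' copies of genomic candidate sequences; \code{repeat_laden} contigs
#' carry a planted repeat interval covering 30\% of their length
#' (returned in \code{masks}).
#'
#' @param plan an [estContigPlan()].
#' @param seed integer seed.
#' @param genomicSeqs named character vector of genomic candidate
#'   sequences used as redundancy partners; generated when \code{NULL}.
#' @return list with \code{ests} (named character), \code{masks}
#'   (\code{GRanges} on EST ids), \code{truth} (data.frame \code{id},
#'   \code{category}, \code{partner}) and \code{genomicSeqs}.
#' @export
generateEstContigs <- function(plan = estContigPlan(), seed = 1L,
                               genomicSeqs = NULL) {
  cn <- plan$counts
  withr::with_seed(seed, {
    if (is.null(genomicSeqs)) {
      genomicSeqs <- setNames(
        vapply(seq_len(max(cn[["redundant"]], 1L)),
               function(i) .randSeq(plan$estLen), character(1)),
        sprintf("gexon%03d", seq_len(max(cn[["redundant"]], 1L))))
    }
    ests <- character(0)
    masks <- GenomicRanges::GRanges()
    truth <- list()
    emit <- function(id, seq, category, partner = NA_character_) {
      ests[[id]] <<- seq
      truth[[length(truth) + 1L]] <<- data.frame(id = id,
                                                 category = category,
                                                 partner = partner)
    }
    noStopCodons <- function(nCodon) {
      pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")), 1,
                            paste, collapse = ""),
                      c("TAA", "TAG", "TGA"))
      paste(sample(pool, nCodon, replace = TRUE), collapse = "")
    }
    for (i in seq_len(cn[["orf_ok"]])) {
      orf <- paste0("ATG", noStopCodons(68L), "TAA")   # 210 bp
      repeat {
        s <- paste0(.randSeq(90L), orf, .randSeq(90L))
        hit <- longestOrf(s, 150L)
        if (!is.null(hit)) break
      }
      emit(sprintf("est_orf%03d", i), s, "orf_ok")
    }
    for (i in seq_len(cn[["orf_short"]])) {
      repeat {
        s <- .randSeq(plan$estLen)
        if (is.null(longestOrf(s, 150L))) break
      }
      emit(sprintf("est_noorf%03d", i), s, "orf_short")
    }
    for (i in seq_len(cn[["redundant"]])) {
      partner <- names(genomicSeqs)[((i - 1L) %% length(genomicSeqs)) + 1L]
      src <- genomicSeqs[[partner]]
      nMut <- floor(0.01 * nchar(src))
      emit(sprintf("est_dup%03d", i), .mutateSeq(src, nMut), "redundant",
           partner)
    }
    for (i in seq_len(cn[["repeat_laden"]])) {
      id <- sprintf("est_rep%03d", i)
      L <- plan$estLen
      repLen <- ceiling(0.3 * L)
      repSeq <- strrep("AG", ceiling(repLen / 2))
      repSeq <- substr(repSeq, 1L, repLen)
      s <- paste0(.randSeq(L - repLen), repSeq)
      emit(id, s, "repeat_laden")
      masks <- suppressWarnings(c(
        masks, GenomicRanges::GRanges(id,
                                      IRanges::IRanges(L - repLen + 1L, L))))
    }
    truthDf <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = character(0), category = character(0),
                 partner = character(0))
    if (length(ests)) {
      o <- sample(length(ests))
      ests <- ests[o]
    }
    list(ests = unlist(ests), masks = masks, truth = truthDf,
         genomicSeqs = genomicSeqs)
  })
}

#' @rdname simPlans
#' @param nVarieties,nEnvs,nBlocks trial dimensions (one row per variety
#'   within each block column).
#' @param mu,gSd,eSd,gxeSd,blockSd,spatialAmplitude,noiseSd planted
#'   effect scales (trait units).
#' @export
fieldTrialPlan <- function(nVarieties = 45L, nEnvs = 8L, nBlocks = 6L,
                           mu = 2, gSd = 0.6, eSd = 0.4, gxeSd = 0.1,
                           blockSd = 0.1, spatialAmplitude = 1,
                           noiseSd = 0.3) {
  list(nVarieties = nVarieties, nEnvs = nEnvs, nBlocks = nBlocks,
       mu = mu, gSd = gSd, eSd = eSd, gxeSd = gxeSd, blockSd = blockSd,
       spatialAmplitude = spatialAmplitude, noiseSd = noiseSd)
}

#' Generate a multi-environment field trial with planted effects
#'
#' Each environment is a grid of \code{nVarieties} rows by
#' \code{nBlocks} block columns; every block contains each variety once
#' in randomized row order (a randomized complete block design). The
#' trait value is
#' \code{mu + G + E + GxE + block + spatial(row, column) + noise} with
#' all components drawn at the planted scales; the smooth spatial field
#' is \code{amplitude * sin(pi * row / R) * cos(pi * column / C)}.
#'
#' @param plan a [fieldTrialPlan()].
#' @param seed integer seed.
#' @return list with \code{plots} (data.frame \code{env}, \code{row},
#'   \code{column}, \code{block}, \code{variety}, \code{value}) and
#'   \code{truth} (planted \code{G}, \code{E}, \code{GxE},
#'   \code{spatial} function, per-env block effects).
#' @export
generateFieldTrial <- function(plan = fieldTrialPlan(), seed = 1L) {
  withr::with_seed(seed, {
    vars <- sprintf("V%02d", seq_len(plan$nVarieties))
    envs <- sprintf("E%d", seq_len(plan$nEnvs))
    G <- setNames(rnorm(plan$nVarieties, 0, plan$gSd), vars)
    E <- setNames(rnorm(plan$nEnvs, 0, plan$eSd), envs)
    GxE <- matrix(rnorm(plan$nVarieties * plan$nEnvs, 0, plan$gxeSd),
                  nrow = plan$nVarieties, dimnames = list(vars, envs))
    blocks <- matrix(rnorm(plan$nEnvs * plan$nBlocks, 0, plan$blockSd),
                     nrow = plan$nEnvs, dimnames = list(envs, NULL))
    R <- plan$nVarieties
    C <- plan$nBlocks
    spatialFun <- function(r, c) {
      plan$spatialAmplitude * sin(pi * r / R) * cos(pi * c / C)
    }
    rows <- list()
    for (e in seq_along(envs)) {
      for (b in seq_len(plan$nBlocks)) {
        ord <- sample(vars)
        for (r in seq_len(plan$nVarieties)) {
          v <- ord[r]
          val <- plan$mu + G[[v]] + E[[e]] + GxE[v, e] + blocks[e, b] +
            spatialFun(r, b) + rnorm(1L, 0, plan$noiseSd)
          rows[[length(rows) + 1L]] <- data.frame(
            env = envs[e], row = r, column = b, block = b, variety = v,
            value = val)
        }
      }
    }
    plots <- do.call(rbind, rows)
    rownames(plots) <- NULL
    list(plots = plots,
         truth = list(G = G, E = E, GxE = GxE, blocks = blocks,
                      spatial = spatialFun))
  })
}
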