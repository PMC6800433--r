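# Three-state local-ancestry HMM over ancestry-diagnostic sites: states
# A (both haplotypes from population A), B, and MIXED (one haplotype from
# each source). Emissions depend on the diploid genotype class at each
# diagnostic site; transition probabilities scale with physical distance.

#' Parameters of the ancestry HMM
#'
#' @param epsilon per-site genotyping/assignment error (default 0.01):
#'   each state emits its expected genotype class with probability
#'   1 - epsilon and each of the two other classes with epsilon/2.
#' @param tau per-bp ancestry transition rate. The default 8.8e-8
#'   corresponds to the per-haplotype crossover accumulation of roughly 8
#'   generations since admixture at 1.1 cM/Mb (g * r * 1e-8 per bp).
#' @return a list with class `ancestryParams`.
#' @export
ancestryParams <- function(epsilon = 0.01, tau = 8.8e-8) {
  stopifnot(epsilon > 0, epsilon < 0.5, tau > 0, tau < 1)
  structure(list(epsilon = epsilon, tau = tau), class = "ancestryParams")
}

#' Select ancestry-diagnostic sites from two panels
#'
#' A site is diagnostic when every panel-A genome is homozygous for one
#' base, every panel-B genome homozygous for a different base, and no
#' genome carries N or a heterozygote there.
#'
#' @param panelA,panelB lists of [DiploidGenome-class] objects (>= 1
#'   each) over the same scaffolds.
#' @return a [GenomicRanges::GRanges] of width-1 sites with metadata
#'   columns `alleleA`, `alleleB`.
#' @export
selectDiagnosticSites <- function(panelA, panelB) {
  if (!length(panelA) || !length(panelB))
    stop("both panels must contain at least one genome")
  scs <- names(scaffolds(panelA[[1L]]))
  homRaw <- charToRaw("ACGT")
  out <- lapply(scs, function(sc) {
    rawsA <- lapply(panelA, function(g)
      charToRaw(as.character(scaffolds(g)[[sc]])))
    rawsB <- lapply(panelB, function(g)
      charToRaw(as.character(scaffolds(g)[[sc]])))
    # candidates: first-A vs first-B mismatches; then verify across panels
    cand <- which(rawsA[[1L]] != rawsB[[1L]])
    if (!length(cand)) return(GRanges())
    aBase <- rawsA[[1L]][cand]
    bBase <- rawsB[[1L]][cand]
    ok <- aBase %in% homRaw & bBase %in% homRaw
    for (g in rawsA[-1L]) ok <- ok & g[cand] == aBase
    for (g in rawsB[-1L]) ok <- ok & g[cand] == bBase
    cand <- cand[ok]
    if (!length(cand)) return(GRanges())
    gr <- GRanges(sc, IRanges::IRanges(start = cand, width = 1L))
    gr$alleleA <- strsplit(rawToChar(aBase[ok]), "")[[1L]]
    gr$alleleB <- strsplit(rawToChar(bBase[ok]), "")[[1L]]
    gr
  })
  suppressWarnings(do.call(c, out))
}

# genotype class of the focal genome at each diagnostic site:
# 1 = hom alleleA, 2 = het(alleleA/alleleB), 3 = hom alleleB, 0 = other/N
observeDiagnostic <- function(genome, sites) {
  sc <- as.character(GenomeInfoDb::seqnames(sites))
  obs <- integer(length(sites))
  for (s in unique(sc)) {
    i <- which(sc == s)
    base <- strsplit(rawToChar(charToRaw(as.character(
      scaffolds(genome)[[s]]))[GenomicRanges::start(sites)[i]]), "")[[1L]]
    aA <- sites$alleleA[i]
    aB <- sites$alleleB[i]
    hetCode <- iupacFromPair(aA, aB)
    cls <- integer(length(i))
    cls[base == aA] <- 1L
    cls[base == hetCode] <- 2L
    cls[base == aB] <- 3L
    obs[i] <- cls
  }
  obs
}

# log emission matrix: rows = states (A, MIXED, B), cols = classes 1..3
ancestryLogEmission <- function(epsilon) {
  e <- matrix(epsilon / 2, 3L, 3L)
  e[1L, 1L] <- 1 - epsilon   # state A expects hom alleleA
  e[2L, 2L] <- 1 - epsilon   # MIXED expects het
  e[3L, 3L] <- 1 - epsilon   # state B expects hom alleleB
  log(e)
}

#' Decode local ancestry of a diploid genome
#'
#' Viterbi segmentation of the genome into A / B / MIXED ancestry from
#' the genotype classes observed at diagnostic sites. Between adjacent
#' sites a distance of d bp gives switch probability
#' (1 - exp(-tau * d)) spread equally over the two other states; sites
#' whose genotype matches none of the three expected classes (including
#' N) are treated as missing. Segment boundaries fall at the midpoints
#' between adjacent sites decoded to different states; the first and last
#' segments extend to the scaffold ends. Scaffolds with no diagnostic
#' site are excluded from the analysed universe.
#'
#' @param genome a [DiploidGenome-class].
#' @param sites diagnostic sites from [selectDiagnosticSites()].
#' @param params an [ancestryParams()] list.
#' @param minSites minimum diagnostic sites required overall (default 10).
#' @return an [AncestrySegmentation-class].
#' @export
decodeAncestry <- function(genome, sites, params = ancestryParams(),
                           minSites = 10L) {
  stopifnot(is(genome, "DiploidGenome"))
  if (length(sites) < minSites)
    stop("need at least ", minSites, " diagnostic sites, got ",
         length(sites))
  sites <- GenomicRanges::sort(sites)
  obs <- observeDiagnostic(genome, sites)
  logE <- ancestryLogEmission(params$epsilon)
  sc <- as.character(GenomeInfoDb::seqnames(sites))
  segs <- lapply(unique(sc), function(s) {
    i <- which(sc == s)
    pos <- GenomicRanges::start(sites)[i]
    o <- obs[i]
    nT <- length(i)
    scafLen <- length(scaffolds(genome)[[s]])
    delta <- matrix(0, nT, 3L)
    psi <- matrix(1L, nT, 3L)
    emit <- function(t) if (o[t] == 0L) c(0, 0, 0) else logE[, o[t]]
    delta[1L, ] <- log(rep(1 / 3, 3)) + emit(1L)
    if (nT > 1L) for (t in 2:nT) {
      d <- pos[t] - pos[t - 1L]
      pSwitch <- (1 - exp(-params$tau * d)) / 3
      lT <- matrix(log(pSwitch), 3L, 3L)
      diag(lT) <- log(1 - 2 * pSwitch)
      for (j in 1:3) {
        cand <- delta[t - 1L, ] + lT[, j]
        psi[t, j] <- which.max(cand)
        delta[t, j] <- max(cand) + emit(t)[j]
      }
    }
    path <- integer(nT)
    path[nT] <- which.max(delta[nT, ])
    if (nT > 1L) for (t in (nT - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
    runs <- rle(path)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    # midpoints between last site of a run and first site of the next
    bounds <- floor((pos[ends[-length(ends)]] +
                     pos[starts[-1L]]) / 2)
    segStart <- c(1, bounds + 1)
    segEnd <- c(bounds, scafLen)
    gr <- GRanges(s, IRanges::IRanges(start = segStart, end = segEnd))
    gr$label <- c("A", "MIXED", "B")[runs$values]
    gr
  })
  gr <- suppressWarnings(do.call(c, segs))
  lens <- tapply(GenomicRanges::width(gr), gr$label, sum)
  fractions <- c(A = 0, B = 0, MIXED = 0)
  fractions[names(lens)] <- lens
  fractions <- fractions / sum(GenomicRanges::width(gr))
  new("AncestrySegmentation", segments = gr, fractions = fractions)
}

#' Classify the ancestry of each ROH tract
#'
#' Each tract is labelled by the ancestry state covering the majority of
#' its length; exact ties are labelled MIXED. Because autozygosity implies
#' a single ancestral haplotype, genuine ROH are expected never to be of
#' mixed ancestry — admixture prevents the formation of mixed-ancestry
#' ROH.
#'
#' @param callset a [RohCallSet-class].
#' @param seg an [AncestrySegmentation-class] over the same scaffolds.
#' @return character vector of labels in `{A, B, MIXED}`, one per tract,
#'   named by `scaffold:start-end`.
#' @export
classifyRohAncestry <- function(callset, seg) {
  tr <- tracts(callset)
  sg <- segments(seg)
  labels <- vapply(seq_along(tr), function(i) {
    hits <- GenomicRanges::findOverlaps(tr[i], sg, ignore.strand = TRUE)
    if (!length(hits)) return("MIXED")
    j <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::pintersect(sg[j], rep(tr[i], length(j)))
    cov <- tapply(GenomicRanges::width(ov), sg$label[j], sum)
    top <- names(cov)[cov == max(cov)]
    if (length(top) > 1L) "MIXED" else top
  }, "")
  names(labels) <- sprintf("%s:%d-%d",
                           as.character(GenomeInfoDb::seqnames(tr)),
                           GenomicRanges::start(tr),
                           GenomicRanges::end(tr))
  labels
}
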