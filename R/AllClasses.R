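#' @import methods
#' @importFrom Biostrings DNAStringSet alphabetFrequency
#' @importFrom GenomicRanges GRanges
NULL

#' DiploidGenome: IUPAC-coded diploid consensus sequences
#'
#' One individual's genome as named scaffolds of diploid consensus sequence.
#' Heterozygous sites carry the two-base IUPAC ambiguity code (R,Y,S,W,K,M),
#' masked or failed sites carry N, homozygous sites the base itself.
#' Three- and four-base ambiguity codes are rejected: the consensus is built
#' from biallelic sites only.
#'
#' @slot individualId single identifier string.
#' @slot seqs a [Biostrings::DNAStringSet] of scaffolds with unique names.
#' @export
setClass("DiploidGenome",
  representation(individualId = "character", seqs = "DNAStringSet"))

setValidity("DiploidGenome", function(object) {
  msgs <- character()
  if (length(object@individualId) != 1L || is.na(object@individualId))
    msgs <- c(msgs, "individualId must be a single string")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msgs <- c(msgs, "scaffold names must be present and unique")
  if (length(object@seqs)) {
    af <- alphabetFrequency(object@seqs, baseOnly = FALSE)
    illegal <- setdiff(colnames(af), c(DIPLOID_ALPHABET, "other"))
    badCounts <- rowSums(af[, illegal, drop = FALSE])
    if (any(badCounts > 0)) {
      i <- which(badCounts > 0)[1L]
      # locate first offending character for the error message
      ch <- strsplit(as.character(object@seqs[[i]]), "")[[1L]]
      off <- which(!(ch %in% DIPLOID_ALPHABET))[1L]
      msgs <- c(msgs, sprintf(
        "illegal character '%s' in scaffold '%s' at position %d (allowed: %s)",
        ch[off], nm[i], off, paste(DIPLOID_ALPHABET, collapse = "")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DiploidGenome
#'
#' @param seqs named [Biostrings::DNAStringSet] or named character vector of
#'   scaffold sequences (lowercase is uppercased).
#' @param individualId identifier for the individual.
#' @return a [DiploidGenome-class] object.
#' @examples
#' g <- DiploidGenome(c(s1 = "ACGTRYN"), "ind1")
#' hetSiteCount(g)
#' @export
DiploidGenome <- function(seqs, individualId = "unknown") {
  if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
  new("DiploidGenome", individualId = individualId, seqs = seqs)
}

setMethod("show", "DiploidGenome", function(object) {
  cat("DiploidGenome for", object@individualId, "with",
      length(object@seqs), "scaffold(s),",
      sum(lengths(object@seqs)), "bp total\n")
})

#' HetWindowTrack: windowed heterozygote counts with callable exposures
#'
#' Non-overlapping windows tiling each scaffold, each carrying the count of
#' IUPAC heterozygote codes (`het`), the count of non-N sites (`callable`)
#' and a `missing` flag for windows whose callable fraction is too low to
#' trust (treated as missing observations by the ROH HMM).
#'
#' @slot windows a [GenomicRanges::GRanges] with metadata columns `het`,
#'   `callable`, `missing`.
#' @slot windowSize target window width in bp (last window per scaffold may
#'   be shorter).
#' @slot individualId identifier carried through from the genome.
#' @export
setClass("HetWindowTrack",
  representation(windows = "GRanges", windowSize = "integer",
                 individualId = "character"))

setValidity("HetWindowTrack", function(object) {
  mc <- S4Vectors::mcols(object@windows)
  need <- c("het", "callable", "missing")
  if (!all(need %in% colnames(mc)))
    return("windows must carry het, callable and missing columns")
  w <- GenomicRanges::width(object@windows)
  if (any(mc$het > mc$callable) || any(mc$callable > w) || any(mc$het < 0))
    return("need 0 <= het <= callable <= window width")
  TRUE
})

#' Construct a HetWindowTrack from windows with counts
#'
#' Mostly used internally by [windowHet()]; exposed so tracks can be
#' built from externally computed counts.
#'
#' @param windows [GenomicRanges::GRanges] with metadata columns `het`,
#'   `callable` and optionally `missing` (default: callable fraction
#'   < 0.2).
#' @param windowSize nominal window width in bp.
#' @param individualId identifier.
#' @return a [HetWindowTrack-class].
#' @export
HetWindowTrack <- function(windows, windowSize, individualId = "unknown") {
  if (!"missing" %in% colnames(S4Vectors::mcols(windows)))
    windows$missing <- windows$callable <
      0.2 * GenomicRanges::width(windows)
  new("HetWindowTrack", windows = windows,
      windowSize = as.integer(windowSize), individualId = individualId)
}

setMethod("show", "HetWindowTrack", function(object) {
  cat("HetWindowTrack:", length(object@windows), "windows of",
      object@windowSize, "bp for", object@individualId, "\n")
})

#' RohHmmParams: parameters of the two-state ROH HMM
#'
#' Emissions are Poisson with callable-site exposure: in window t with
#' callable count n_t, the het count is Poisson(lambda_state * n_t).
#' State 1 is inbred (low rate), state 2 outbred; `lambdaIn < lambdaOut`
#' is enforced after fitting.
#'
#' @slot lambdaIn,lambdaOut expected het sites per callable bp in each state.
#' @slot transMat 2x2 per-window transition matrix, rows sum to 1.
#' @slot initProb initial state distribution.
#' @slot degenerate flag set by [fitRohHmm()] when the data had no
#'   heterozygous sites at all.
#' @slot fitLogLik per-iteration log-likelihood trajectory recorded by
#'   [fitRohHmm()] (empty for hand-built parameters).
#' @export
setClass("RohHmmParams",
  representation(lambdaIn = "numeric", lambdaOut = "numeric",
                 transMat = "matrix", initProb = "numeric",
                 degenerate = "logical", fitLogLik = "numeric"),
  prototype(degenerate = FALSE, fitLogLik = numeric(0)))

setValidity("RohHmmParams", function(object) {
  if (length(object@lambdaIn) != 1L || length(object@lambdaOut) != 1L ||
      object@lambdaIn < 0 || object@lambdaOut < 0)
    return("lambdas must be single non-negative numbers")
  if (!object@degenerate && object@lambdaIn > object@lambdaOut)
    return("need lambdaIn <= lambdaOut")
  if (!all(dim(object@transMat) == c(2L, 2L)) ||
      any(object@transMat < 0) || any(object@transMat > 1) ||
      any(abs(rowSums(object@transMat) - 1) > 1e-8))
    return("transMat must be 2x2 stochastic")
  if (length(object@initProb) != 2L || any(object@initProb < 0) ||
      abs(sum(object@initProb) - 1) > 1e-8)
    return("initProb must be a length-2 distribution")
  TRUE
})

#' Construct RohHmmParams
#'
#' @param lambdaIn,lambdaOut per-callable-bp het rates of the inbred and
#'   outbred states.
#' @param transMat 2x2 transition matrix (default: diagonal 0.999).
#' @param initProb initial distribution (default: stationary-ish 0.5/0.5).
#' @param degenerate internal flag, see [fitRohHmm()].
#' @return a [RohHmmParams-class] object.
#' @export
RohHmmParams <- function(lambdaIn, lambdaOut,
                         transMat = matrix(c(0.999, 0.001, 0.001, 0.999), 2,
                                           byrow = TRUE),
                         initProb = c(0.5, 0.5), degenerate = FALSE) {
  new("RohHmmParams", lambdaIn = lambdaIn, lambdaOut = lambdaOut,
      transMat = transMat, initProb = initProb, degenerate = degenerate)
}

setMethod("show", "RohHmmParams", function(object) {
  cat(sprintf("RohHmmParams: lambdaIn=%.3g lambdaOut=%.3g stay=(%.4f, %.4f)%s\n",
              object@lambdaIn, object@lambdaOut,
              object@transMat[1, 1], object@transMat[2, 2],
              if (object@degenerate) " [degenerate]" else ""))
})

#' RohCallSet: called runs of homozygosity for one individual
#'
#' @slot individualId identifier.
#' @slot tracts sorted, non-overlapping [GenomicRanges::GRanges] with a
#'   `meanPosterior` metadata column (mean window posterior of the inbred
#'   state over the tract; NA for truth tracts).
#' @slot minLength minimum tract length (bp) applied when calling.
#' @export
setClass("RohCallSet",
  representation(individualId = "character", tracts = "GRanges",
                 minLength = "numeric"))

setValidity("RohCallSet", function(object) {
  tr <- object@tracts
  if (length(tr)) {
    if (GenomicRanges::isDisjoint(tr) == FALSE)
      return("tracts must be non-overlapping")
    if (any(GenomicRanges::width(tr) < object@minLength))
      return("all tracts must be >= minLength")
  }
  TRUE
})

#' Construct a RohCallSet
#'
#' @param tracts GRanges of ROH tracts (sorted internally); may carry a
#'   `meanPosterior` metadata column.
#' @param individualId identifier.
#' @param minLength the minimum length (bp) the tracts satisfy.
#' @return a [RohCallSet-class] object.
#' @export
RohCallSet <- function(tracts, individualId = "unknown", minLength = 0) {
  tracts <- GenomicRanges::sort(tracts)
  if (!"meanPosterior" %in% colnames(S4Vectors::mcols(tracts)))
    tracts$meanPosterior <- rep(NA_real_, length(tracts))
  new("RohCallSet", individualId = individualId, tracts = tracts,
      minLength = as.numeric(minLength))
}

setMethod("show", "RohCallSet", function(object) {
  cat("RohCallSet for", object@individualId, ":", length(object@tracts),
      "tracts >=", object@minLength / 1e6, "Mb, total",
      round(sum(GenomicRanges::width(object@tracts)) / 1e6, 2), "Mb\n")
})

#' AncestrySegmentation: genome partition into ancestry states
#'
#' Tiling of the analysed scaffolds into segments labelled `A` (homozygous
#' population-A ancestry), `B`, or `MIXED` (one haplotype from each source).
#'
#' @slot segments [GenomicRanges::GRanges] tiling the analysed scaffolds,
#'   with a `label` metadata column.
#' @slot fractions named numeric: fraction of analysed genome per label,
#'   summing to 1.
#' @export
setClass("AncestrySegmentation",
  representation(segments = "GRanges", fractions = "numeric"))

setValidity("AncestrySegmentation", function(object) {
  lab <- object@segments$label
  if (is.null(lab) || !all(lab %in% c("A", "B", "MIXED")))
    return("segments need a label column in {A, B, MIXED}")
  if (abs(sum(object@fractions) - 1) > 1e-6)
    return("fractions must sum to 1")
  TRUE
})

setMethod("show", "AncestrySegmentation", function(object) {
  cat("AncestrySegmentation:", length(object@segments), "segments;",
      paste(sprintf("%s=%.1f%%", names(object@fractions),
                    100 * object@fractions), collapse = " "), "\n")
})

#' PedigreeSpec: a pedigree with designated focal individual
#'
#' @slot founders data.frame with columns `id`, `pop` (in {"A","B"}).
#' @slot matings data.frame with columns `sire`, `dam`, `child`, ordered so
#'   every parent precedes its child.
#' @slot focal id of the individual whose genome is rendered.
#' @export
setClass("PedigreeSpec",
  representation(founders = "data.frame", matings = "data.frame",
                 focal = "character"))

setValidity("PedigreeSpec", function(object) {
  f <- object@founders; m <- object@matings
  if (!all(c("id", "pop") %in% names(f)))
    return("founders need id and pop columns")
  if (!all(f$pop %in% c("A", "B")))
    return("founder pop must be 'A' or 'B'")
  if (nrow(m) && !all(c("sire", "dam", "child") %in% names(m)))
    return("matings need sire, dam, child columns")
  ids <- c(f$id, m$child)
  if (anyDuplicated(ids))
    return(paste0("duplicated individual id: ", ids[duplicated(ids)][1L]))
  known <- f$id
  for (i in seq_len(nrow(m))) {
    miss <- setdiff(c(m$sire[i], m$dam[i]), known)
    if (length(miss))
      return(paste0("parent '", miss[1L], "' of '", m$child[i],
                    "' not defined earlier (cycle or missing parent)"))
    known <- c(known, m$child[i])
  }
  if (!(object@focal %in% ids)) return("focal individual not in pedigree")
  TRUE
})

#' Construct a PedigreeSpec
#'
#' @param founders data.frame(id, pop) of founder individuals.
#' @param matings data.frame(sire, dam, child); parents must precede
#'   children.
#' @param focal id of the focal individual.
#' @return a [PedigreeSpec-class] object.
#' @export
PedigreeSpec <- function(founders, matings, focal) {
  founders <- as.data.frame(founders, stringsAsFactors = FALSE)
  matings <- as.data.frame(matings, stringsAsFactors = FALSE)
  new("PedigreeSpec", founders = founders, matings = matings, focal = focal)
}

setMethod("show", "PedigreeSpec", function(object) {
  cat("PedigreeSpec:", nrow(object@founders), "founders,",
      nrow(object@matings), "matings, focal =", object@focal, "\n")
})

#' PanelPool: founder haplotype pool over a shared reference
#'
#' Variant sites are placed as Poisson processes along a random reference:
#' within-population polymorphic sites at density 2*theta (alleles at
#' frequency 0.5, so the expected heterozygosity of an outbred individual
#' is theta per bp) and between-population fixed differences at density
#' dAB (population A carries the reference allele, B the alternate).
#'
#' @slot refSeqs shared reference scaffolds ([Biostrings::DNAStringSet]).
#' @slot variants data.frame: scaffold, pos (1-based), ref, alt, class in
#'   {polyA, polyB, fixed}.
#' @slot alleles logical matrix (sites x founder haplotype copies): TRUE
#'   where that copy carries the alternate allele. Copy 2i-1 and 2i belong
#'   to founder i.
#' @slot founderPops population of each founder, in copy order.
#' @slot theta,dAB the densities the pool was generated with.
#' @export
setClass("PanelPool",
  representation(refSeqs = "DNAStringSet", variants = "data.frame",
                 alleles = "matrix", founderPops = "character",
                 theta = "numeric", dAB = "numeric"))

setMethod("show", "PanelPool", function(object) {
  cat("PanelPool:", length(object@founderPops), "founders (",
      sum(object@founderPops == "A"), "A /", sum(object@founderPops == "B"),
      "B ),", nrow(object@variants), "variant sites over",
      sum(lengths(object@refSeqs)), "bp\n")
})

#' TruthTracts: ground-truth autozygosity and ancestry of a simulated genome
#'
#' @slot autozygous [GenomicRanges::GRanges] where the two haplotypes
#'   descend from the same founder haplotype copy; metadata column
#'   `truncated` flags tracts cut by a scaffold end.
#' @slot ancestry list of two [GenomicRanges::GRanges] (one per haplotype)
#'   tiling the genome, with a `pop` metadata column in {"A","B"}.
#' @export
setClass("TruthTracts",
  representation(autozygous = "GRanges", ancestry = "list"))

setMethod("show", "TruthTracts", function(object) {
  cat("TruthTracts:", length(object@autozygous), "autozygous tracts (",
      round(sum(GenomicRanges::width(object@autozygous)) / 1e6, 2),
      "Mb )\n")
})

#' PedigreeSim: haplotype descent of a simulated pedigree
#'
#' Records, for every individual, each haplotype as a mosaic of founder
#' haplotype copies (segment table with columns scaffold, start, end, copy).
#' Sequences are rendered lazily from a [PanelPool-class].
#'
#' @slot pedigree the [PedigreeSpec-class] simulated.
#' @slot scaffoldLengths named numeric of scaffold lengths (bp).
#' @slot haplotypes named list: per individual a list(h1, h2) of segment
#'   data.frames.
#' @slot rate recombination rate in cM/Mb.
#' @slot seed the seed used.
#' @export
setClass("PedigreeSim",
  representation(pedigree = "PedigreeSpec", scaffoldLengths = "numeric",
                 haplotypes = "list", rate = "numeric", seed = "integer"))

setMethod("show", "PedigreeSim", function(object) {
  cat("PedigreeSim:", length(object@haplotypes), "individuals over",
      length(object@scaffoldLengths), "scaffold(s), r =", object@rate,
      "cM/Mb, seed", object@seed, "\n")
})
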