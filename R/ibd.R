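# Pairwise IBD-ROH sharing: genomic regions where two individuals' ROH
# overlap (optionally requiring their homozygous calls to agree) as a
# fraction of the analysed genome.

checkSameUniverse <- function(a, b) {
  ua <- sort(GenomeInfoDb::seqlevels(tracts(a)))
  ub <- sort(GenomeInfoDb::seqlevels(tracts(b)))
  if (!identical(ua, ub))
    stop("scaffold universes differ: {", paste(ua, collapse = ","),
         "} vs {", paste(ub, collapse = ","), "}")
}

#' Intersect the ROH of two individuals
#'
#' Per-scaffold interval intersection of the two call sets, merged and
#' sorted. Both call sets must be over the same scaffold universe.
#'
#' @param a,b [RohCallSet-class] objects.
#' @return a [GenomicRanges::GRanges] of shared intervals.
#' @export
intersectRoh <- function(a, b) {
  stopifnot(is(a, "RohCallSet"), is(b, "RohCallSet"))
  checkSameUniverse(a, b)
  GenomicRanges::reduce(GenomicRanges::intersect(tracts(a), tracts(b),
                                                 ignore.strand = TRUE))
}

# Fraction of jointly homozygous sites in `gr` where the two genomes
# carry the same base. Sites where either genome is het or N are not
# informative for haplotype identity and are excluded.
homIdentityFraction <- function(gr, genomeA, genomeB) {
  vapply(seq_along(gr), function(i) {
    sc <- as.character(GenomeInfoDb::seqnames(gr))[i]
    sa <- charToRaw(as.character(Biostrings::subseq(
      scaffolds(genomeA)[[sc]], GenomicRanges::start(gr)[i],
      GenomicRanges::end(gr)[i])))
    sb <- charToRaw(as.character(Biostrings::subseq(
      scaffolds(genomeB)[[sc]], GenomicRanges::start(gr)[i],
      GenomicRanges::end(gr)[i])))
    homRaw <- charToRaw("ACGT")
    joint <- sa %in% homRaw & sb %in% homRaw
    if (!any(joint)) return(NA_real_)
    sum(sa[joint] == sb[joint]) / sum(joint)
  }, numeric(1L))
}

#' Fraction of the genome in ROH shared IBD between two individuals
#'
#' Sum of [intersectRoh()] overlap lengths divided by the analysed genome
#' length. Overlaps shorter than `minOverlap` are discarded (sub-window
#' jitter of tract ends). When both genomes are supplied, each overlap is
#' kept only if the individuals' homozygous calls agree at a fraction of
#' jointly callable homozygous sites of at least `identityThreshold` —
#' interval overlap alone can pair distinct haplotypes.
#'
#' @param a,b [RohCallSet-class] objects over the same scaffolds.
#' @param genomeLength analysed genome length in bp.
#' @param genomes optional list of the two [DiploidGenome-class] objects
#'   (`a` first) enabling the allele-identity check.
#' @param identityThreshold minimum homozygote agreement (default 0.95).
#' @param minOverlap minimum overlap length kept, bp (default 1e6).
#' @return a fraction in [0, 1].
#' @export
ibdFraction <- function(a, b, genomeLength, genomes = NULL,
                        identityThreshold = 0.95, minOverlap = 1e6) {
  ov <- intersectRoh(a, b)
  ov <- ov[GenomicRanges::width(ov) >= minOverlap]
  if (length(ov) && !is.null(genomes)) {
    idf <- homIdentityFraction(ov, genomes[[1L]], genomes[[2L]])
    ov <- ov[!is.na(idf) & idf >= identityThreshold]
  }
  sum(GenomicRanges::width(ov)) / genomeLength
}

#' Pairwise IBD-ROH sharing matrix
#'
#' All pairwise [ibdFraction()] values; symmetric by construction, with
#' each individual's own F_ROH on the diagonal. Off-diagonal entries are
#' bounded by the smaller of the two diagonals.
#'
#' @param callsets named list of [RohCallSet-class] objects (>= 2).
#' @param genomeLength analysed genome length in bp.
#' @param genomes optional named list of [DiploidGenome-class] objects
#'   matching `callsets`, enabling the allele-identity check.
#' @param identityThreshold,minOverlap passed to [ibdFraction()].
#' @return a symmetric numeric matrix with individual ids as dimnames.
#' @export
ibdMatrix <- function(callsets, genomeLength, genomes = NULL,
                      identityThreshold = 0.95, minOverlap = 1e6) {
  stopifnot(length(callsets) >= 2L)
  ids <- vapply(callsets, individualId, "")
  n <- length(callsets)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- sum(GenomicRanges::width(tracts(callsets[[i]]))) /
      genomeLength
    for (j in seq_len(n)) {
      if (j <= i) next
      gij <- if (is.null(genomes)) NULL else list(genomes[[i]], genomes[[j]])
      m[i, j] <- m[j, i] <- ibdFraction(
        callsets[[i]], callsets[[j]], genomeLength, genomes = gij,
        identityThreshold = identityThreshold, minOverlap = minOverlap)
    }
  }
  m
}

#' Write an IBD matrix in wide and long form
#'
#' @param m matrix from [ibdMatrix()].
#' @param path output TSV path (wide form); the long form
#'   (`id_a id_b fraction`) is written next to it with suffix `.long.tsv`.
#' @return `path`, invisibly.
#' @export
writeIbdMatrix <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  long <- data.frame(id_a = rownames(m)[idx[, 1L]],
                     id_b = colnames(m)[idx[, 2L]],
                     fraction = m[idx])
  utils::write.table(long, sub("\\.tsv$", ".long.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
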