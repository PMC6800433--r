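# ROH tract dating: a tract of length L Mb that survived 2g meioses of
# recombination at r cM/Mb has expected age g = 100/(2 r L) generations
# since the parental lineages' common ancestor.

#' Generations since the common ancestor implied by an ROH length
#'
#' Evaluates g = 100 / (2 r L): an autozygous tract is broken by
#' crossovers accumulating over the 2g meioses separating the two copies
#' of the ancestral haplotype, so longer tracts imply more recent
#' ancestors. At r = 1.1 cM/Mb a 15.2 Mb tract dates to ~3 generations
#' and a 5.7 Mb tract to ~8.
#'
#' @param lengthMb tract length(s) in Mb; must be > 0.
#' @param r recombination rate in cM/Mb (default 1.1, domestic cat
#'   average).
#' @return generations (numeric, same length as `lengthMb`).
#' @examples
#' tractGenerations(15.2)  # ~3
#' tractGenerations(5.7)   # ~8
#' @export
tractGenerations <- function(lengthMb, r = 1.1) {
  if (any(lengthMb <= 0) || r <= 0)
    stop("tract length and recombination rate must be positive")
  100 / (2 * r * lengthMb)
}

#' ROH length expected for a common ancestor g generations back
#'
#' Inverse of [tractGenerations()]: L = 100 / (2 r g) Mb.
#'
#' @param g generations since the common ancestor; must be > 0.
#' @param r recombination rate in cM/Mb (default 1.1).
#' @return expected tract length(s) in Mb.
#' @examples
#' generationsToLength(3)  # ~15.2 Mb
#' generationsToLength(8)  # ~5.7 Mb
#' @export
generationsToLength <- function(g, r = 1.1) {
  if (any(g <= 0) || r <= 0)
    stop("generations and recombination rate must be positive")
  100 / (2 * r * g)
}

#' Summarise a ROH call set: F_ROH and length-class histogram
#'
#' F_ROH is the fraction of the analysed genome (the scaffolds included
#' in the analysis, not the full assembly) lying in ROH. The histogram
#' bins tract lengths into generation-defined classes; the default edges
#' \{2, 5.7, 9.1, 15.2, Inf\} Mb are the lengths implied by common
#' ancestors 8, 5 and 3 generations back at r = 1.1 cM/Mb, above the 2 Mb
#' call floor.
#'
#' @param callset a [RohCallSet-class].
#' @param genomeLength total analysed genome length in bp.
#' @param binsMb increasing histogram edges in Mb (default
#'   `c(2, 5.7, 9.1, 15.2, Inf)`).
#' @param r recombination rate used to annotate bins with generations.
#' @return list with `individualId`, `fRoh`, `nTracts`, `histogram`
#'   (data.frame: bin, lowerMb, upperMb, count, generations at the lower
#'   edge), and `meanLengthMb`.
#' @export
summarizeRoh <- function(callset, genomeLength,
                         binsMb = c(2, 5.7, 9.1, 15.2, Inf), r = 1.1) {
  stopifnot(is(callset, "RohCallSet"), genomeLength > 0,
            !is.unsorted(binsMb))
  lens <- GenomicRanges::width(tracts(callset))
  if (sum(lens) > genomeLength)
    stop("total tract length exceeds genome length budget")
  lensMb <- lens / 1e6
  edges <- c(binsMb)
  counts <- if (length(lensMb))
    table(cut(lensMb, breaks = edges, right = FALSE,
              include.lowest = TRUE))
  else table(cut(numeric(0), breaks = edges, right = FALSE))
  hist <- data.frame(
    bin = names(counts),
    lowerMb = edges[-length(edges)],
    upperMb = edges[-1L],
    count = as.integer(counts),
    generationsAtLower = tractGenerations(edges[-length(edges)], r))
  list(individualId = individualId(callset),
       fRoh = sum(lens) / genomeLength,
       nTracts = length(lens),
       histogram = hist,
       meanLengthMb = if (length(lensMb)) mean(lensMb) else NA_real_)
}

#' Write a ROH summary as TSV
#'
#' @param summary result of [summarizeRoh()].
#' @param path output path (histogram table with a `#` header line
#'   carrying F_ROH and the tract count).
#' @return `path`, invisibly.
#' @export
writeRohSummary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# autozyg ROH summary; individual=%s; f_roh=%.6g; n_tracts=%d",
                     summary$individualId, summary$fRoh, summary$nTracts),
             con)
  utils::write.table(summary$histogram, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
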