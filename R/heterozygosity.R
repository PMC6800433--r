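#' Windowed heterozygosity of a diploid consensus genome
#'
#' Tiles each scaffold with non-overlapping windows (the last window of a
#' scaffold may be short) and counts, per window, IUPAC heterozygote codes
#' (`het`) and non-N sites (`callable`). Windows whose callable fraction
#' falls below `minCallableFrac` are flagged `missing`: masked deserts
#' would otherwise mimic homozygosity, so the ROH HMM treats them as
#' missing observations.
#'
#' @param genome a [DiploidGenome-class].
#' @param windowSize window width in bp; default 100 kb, which puts about
#'   100 windows on a 10 Mb tract — ample for Mb-scale segmentation.
#' @param minCallableFrac windows with callable/width below this are
#'   flagged missing (default 0.2).
#' @return a [HetWindowTrack-class].
#' @examples
#' g <- DiploidGenome(c(s1 = "ARNR"), "ex")
#' hetWindows(windowHet(g, windowSize = 4))
#' @export
windowHet <- function(genome, windowSize = 1e5, minCallableFrac = 0.2) {
  stopifnot(is(genome, "DiploidGenome"), windowSize >= 1)
  windowSize <- as.integer(windowSize)
  seqs <- scaffolds(genome)
  lens <- lengths(seqs)
  names(lens) <- names(seqs)
  tiles <- GenomicRanges::tileGenome(lens, tilewidth = windowSize,
                                     cut.last.tile.in.chrom = TRUE)
  hetStr <- paste(HET_CODES, collapse = "")
  perScaffold <- lapply(names(seqs), function(sc) {
    w <- tiles[GenomeInfoDb::seqnames(tiles) == sc]
    v <- Biostrings::Views(seqs[[sc]], start = GenomicRanges::start(w),
                           end = GenomicRanges::end(w))
    lf <- Biostrings::letterFrequency(v, letters = c(hetStr, "N"))
    data.frame(het = lf[, 1L], n = lf[, 2L])
  })
  counts <- do.call(rbind, perScaffold)
  wdt <- GenomicRanges::width(tiles)
  tiles$het <- as.integer(counts$het)
  tiles$callable <- as.integer(wdt - counts$n)
  tiles$missing <- tiles$callable < minCallableFrac * wdt
  new("HetWindowTrack", windows = tiles, windowSize = windowSize,
      individualId = individualId(genome))
}

#' Genome-wide heterozygosity
#'
#' Total IUPAC heterozygote codes divided by total non-N sites across all
#' scaffolds; equivalently the callable-weighted mean of window rates.
#'
#' @param genome a [DiploidGenome-class].
#' @return heterozygous sites per callable bp.
#' @examples
#' genomeHet(DiploidGenome(c(s1 = "AR"), "ex"))  # 0.5
#' @export
genomeHet <- function(genome) {
  stopifnot(is(genome, "DiploidGenome"))
  seqs <- scaffolds(genome)
  hetStr <- paste(HET_CODES, collapse = "")
  lf <- Biostrings::letterFrequency(seqs, letters = c(hetStr, "N"))
  callable <- sum(lengths(seqs)) - sum(lf[, 2L])
  if (callable == 0) stop("no callable (non-N) sites in genome")
  sum(lf[, 1L]) / callable
}

#' Write a HetWindowTrack as TSV
#'
#' Columns: `scaffold start end het_count callable rate` with start/end in
#' 0-based half-open convention; rate is NA for windows with no callable
#' sites. A `#`-prefixed header comment echoes the window size.
#'
#' @param track a [HetWindowTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHetTrack <- function(track, path) {
  w <- hetWindows(track)
  df <- data.frame(
    scaffold = as.character(GenomeInfoDb::seqnames(w)),
    start = GenomicRanges::start(w) - 1L,
    end = GenomicRanges::end(w),
    het_count = w$het,
    callable = w$callable,
    rate = ifelse(w$callable > 0, w$het / w$callable, NA_real_))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# autozyg het windows; window_size=%d; individual=%s",
                     track@windowSize, individualId(track)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a HetWindowTrack TSV written by [writeHetTrack()]
#'
#' @param path path to the TSV.
#' @param minCallableFrac recompute the missing flag with this threshold.
#' @return a [HetWindowTrack-class].
#' @export
readHetTrack <- function(path, minCallableFrac = 0.2) {
  hdr <- readLines(path, n = 1L)
  wsize <- as.integer(sub(".*window_size=(\\d+).*", "\\1", hdr))
  id <- sub(".*individual=([^;]+).*", "\\1", hdr)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  gr <- GRanges(df$scaffold,
                IRanges::IRanges(start = df$start + 1L, end = df$end))
  gr$het <- as.integer(df$het_count)
  gr$callable <- as.integer(df$callable)
  gr$missing <- gr$callable < minCallableFrac * GenomicRanges::width(gr)
  new("HetWindowTrack", windows = gr, windowSize = wsize, individualId = id)
}
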