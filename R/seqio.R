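#' Read an IUPAC-coded diploid consensus FASTA
#'
#' Reads a per-individual consensus FASTA in which heterozygous sites are
#' encoded as two-base IUPAC ambiguity codes and masked sites as N.
#' Lowercase (soft-masked) input is uppercased, not masked. Characters
#' outside the 11-letter alphabet ACGTRYSWKMN (notably the 3/4-base codes
#' V,H,D,B) are rejected with the scaffold and offset named.
#'
#' @param path path to a FASTA file.
#' @param individualId identifier; defaults to the file name without
#'   extension.
#' @return a [DiploidGenome-class].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTRN"), f)
#' readIupacFasta(f, "ex")
#' @export
readIupacFasta <- function(path, individualId = NULL) {
  if (is.null(individualId))
    individualId <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  # strip FASTA description, keep first token as scaffold name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  DiploidGenome(seqs, individualId)
}

#' Write a DiploidGenome as FASTA
#'
#' Sequences are wrapped at 80 columns.
#'
#' @param genome a [DiploidGenome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIupacFasta <- function(genome, path) {
  stopifnot(is(genome, "DiploidGenome"))
  Biostrings::writeXStringSet(scaffolds(genome), path, width = 80L)
  invisible(path)
}

#' Read a genotype table
#'
#' Tab-separated table with header `scaffold pos genotype ref alt`;
#' positions are 1-based (VCF convention), genotype one of `hom_ref`,
#' `het`, `hom_alt`, `missing`, and ref/alt single bases.
#'
#' @param path path to the TSV file.
#' @return data.frame with those five columns.
#' @export
readGenotypeTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character",
                                          "character"))
  need <- c("scaffold", "pos", "genotype", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("genotype table must have columns: ", paste(need, collapse = " "))
  bad <- !tab$genotype %in% c("hom_ref", "het", "hom_alt", "missing")
  if (any(bad))
    stop("unknown genotype '", tab$genotype[bad][1L], "' in ", path)
  tab
}

#' Build a masked diploid consensus from a reference and genotypes
#'
#' Applies per-site genotypes to a haploid reference: heterozygotes become
#' the IUPAC code of the two alleles, hom-alt the alternate base, missing
#' genotypes and all `failedSites` intervals become N; every other position
#' copies the reference. This reproduces the construction of consensus
#' FASTAs from a filtered SNP call set.
#'
#' @param reference a [DiploidGenome-class] (haploid: A/C/G/T/N only) or
#'   named [Biostrings::DNAStringSet].
#' @param table genotype data.frame as from [readGenotypeTable()]; `pos`
#'   is 1-based.
#' @param failedSites optional [GenomicRanges::GRanges] of intervals to
#'   mask to N.
#' @param individualId identifier for the output genome.
#' @return a [DiploidGenome-class] with the same scaffold lengths as the
#'   reference.
#' @examples
#' ref <- DiploidGenome(c(s1 = "AAAA"), "ref")
#' tab <- data.frame(scaffold = "s1", pos = 2L, genotype = "het",
#'                   ref = "A", alt = "G")
#' as.character(scaffolds(buildMaskedFasta(ref, tab)))
#' @export
buildMaskedFasta <- function(reference, table, failedSites = NULL,
                             individualId = "sample") {
  seqs <- if (is(reference, "DiploidGenome")) scaffolds(reference)
          else reference
  if (nrow(table)) {
    bad <- !table$scaffold %in% names(seqs)
    if (any(bad))
      stop("genotype table names unknown scaffold '",
           table$scaffold[bad][1L], "'")
    lens <- stats::setNames(Biostrings::width(seqs),
                            names(seqs))[table$scaffold]
    if (any(table$pos < 1L | table$pos > lens))
      stop("genotype position outside scaffold bounds")
    nonacgt <- !(table$ref %in% c("A", "C", "G", "T")) |
               !(table$alt %in% c("A", "C", "G", "T"))
    if (any(nonacgt & table$genotype %in% c("het", "hom_alt")))
      stop("non-ACGT allele has no biallelic IUPAC code (row ",
           which(nonacgt)[1L], ")")
    newChar <- rep(NA_character_, nrow(table))
    newChar[table$genotype == "hom_ref"] <- table$ref[table$genotype == "hom_ref"]
    newChar[table$genotype == "hom_alt"] <- table$alt[table$genotype == "hom_alt"]
    newChar[table$genotype == "missing"] <- "N"
    isHet <- table$genotype == "het"
    if (any(isHet))
      newChar[isHet] <- iupacFromPair(table$ref[isHet], table$alt[isHet])
  }
  out <- lapply(names(seqs), function(sc) {
    s <- seqs[[sc]]
    if (nrow(table)) {
      rows <- which(table$scaffold == sc)
      if (length(rows))
        s <- Biostrings::replaceLetterAt(s, table$pos[rows], newChar[rows])
    }
    if (!is.null(failedSites)) {
      fs <- failedSites[GenomeInfoDb::seqnames(failedSites) == sc]
      if (length(fs)) {
        at <- unlist(lapply(seq_along(fs), function(i)
          seq.int(GenomicRanges::start(fs)[i], GenomicRanges::end(fs)[i])))
        at <- unique(at[at >= 1 & at <= length(s)])
        s <- Biostrings::replaceLetterAt(s, at, rep("N", length(at)))
      }
    }
    s
  })
  out <- DNAStringSet(out)
  names(out) <- names(seqs)
  DiploidGenome(out, individualId)
}

#' Combine two haploid sequences into a pseudo-diploid consensus
#'
#' Site-wise: equal bases yield that base, differing ACGT bases their
#' two-base IUPAC code, and N in either input yields N. Used e.g. to build
#' pseudo-diploid X chromosomes from two males for cross-population
#' coalescent input.
#'
#' @param hapA,hapB [Biostrings::DNAString] or single character strings of
#'   equal length, aligned to the same coordinates.
#' @return a [Biostrings::DNAString] of the same length.
#' @examples
#' as.character(makePseudodiploid("ACGT", "ACAT"))  # "ACRT"
#' @export
makePseudodiploid <- function(hapA, hapB) {
  a <- toupper(as.character(hapA))
  b <- toupper(as.character(hapB))
  if (nchar(a) != nchar(b))
    stop("length mismatch: ", nchar(a), " vs ", nchar(b), " bp")
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  out <- ra
  rawN <- charToRaw("N")
  isN <- ra == rawN | rb == rawN
  diff <- which(ra != rb & !isN)
  if (length(diff)) {
    codes <- iupacFromPair(strsplit(rawToChar(ra[diff]), "")[[1L]],
                           strsplit(rawToChar(rb[diff]), "")[[1L]])
    out[diff] <- charToRaw(paste(codes, collapse = ""))
  }
  out[isN] <- rawN
  Biostrings::DNAString(rawToChar(out))
}

#' Read a BED file of intervals
#'
#' Standard 0-based half-open BED with 3+ columns; returns 1-based closed
#' [GenomicRanges::GRanges] (the R convention). Lines starting with `#`,
#' `track` or `browser` are skipped. A 4th column, if present, is kept as
#' metadata column `name`.
#'
#' @param path path to a BED file.
#' @return a [GenomicRanges::GRanges].
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineNo <- which(keep)
  if (!length(lineNo))
    return(GRanges())
  fields <- strsplit(lines[lineNo], "\t")
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop("BED line ", lineNo[which(ncol < 3L)[1L]], ": fewer than 3 fields")
  sc <- vapply(fields, `[`, "", 1L)
  st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(st) || anyNA(en))
    stop("BED line ", lineNo[which(is.na(st) | is.na(en))[1L]],
         ": non-numeric coordinate")
  if (any(st < 0))
    stop("BED line ", lineNo[which(st < 0)[1L]], ": negative start")
  if (any(en <= st))
    stop("BED line ", lineNo[which(en <= st)[1L]], ": end <= start")
  gr <- GRanges(sc, IRanges::IRanges(start = st + 1, end = en))
  if (all(ncol >= 4L))
    gr$name <- vapply(fields, `[`, "", 4L)
  gr
}

#' Write intervals as BED
#'
#' Converts 1-based closed [GenomicRanges::GRanges] to 0-based half-open
#' BED3 (plus a 4th column from `nameCol` if given), sorted by scaffold
#' then start.
#'
#' @param intervals a [GenomicRanges::GRanges].
#' @param path output path.
#' @param nameCol optional metadata column to emit as the 4th BED field.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path, nameCol = NULL) {
  o <- order(as.character(GenomeInfoDb::seqnames(intervals)),
             GenomicRanges::start(intervals))
  intervals <- intervals[o]
  df <- data.frame(
    scaffold = as.character(GenomeInfoDb::seqnames(intervals)),
    start = format(GenomicRanges::start(intervals) - 1, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(intervals), scientific = FALSE,
                 trim = TRUE))
  if (!is.null(nameCol))
    df$name <- as.character(S4Vectors::mcols(intervals)[[nameCol]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
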