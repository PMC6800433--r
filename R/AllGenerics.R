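# Accessor generics. Slot access stays internal; users go through these.

#' @rdname accessors
#' @param x an autozyg object.
#' @export
setGeneric("individualId", function(x) standardGeneric("individualId"))

#' Accessors for autozyg classes
#'
#' `individualId()` returns the individual identifier; `scaffolds()` the
#' underlying [Biostrings::DNAStringSet]; `hetWindows()` the window
#' [GenomicRanges::GRanges]; `tracts()` the ROH tract GRanges;
#' `segments()` the ancestry segment GRanges; `ancestryFractions()` the
#' per-label genome fractions; `autozygousTracts()` / `ancestryTracts()`
#' the ground-truth components of a simulation.
#'
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))

#' @rdname accessors
#' @export
setGeneric("hetWindows", function(x) standardGeneric("hetWindows"))

#' @rdname accessors
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))

#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname accessors
#' @export
setGeneric("ancestryFractions",
           function(x) standardGeneric("ancestryFractions"))

#' @rdname accessors
#' @export
setGeneric("autozygousTracts",
           function(x) standardGeneric("autozygousTracts"))

#' @rdname accessors
#' @export
setGeneric("ancestryTracts", function(x) standardGeneric("ancestryTracts"))

#' @rdname accessors
setMethod("individualId", "DiploidGenome", function(x) x@individualId)
#' @rdname accessors
setMethod("individualId", "RohCallSet", function(x) x@individualId)
#' @rdname accessors
setMethod("individualId", "HetWindowTrack", function(x) x@individualId)
#' @rdname accessors
setMethod("scaffolds", "DiploidGenome", function(x) x@seqs)
#' @rdname accessors
setMethod("hetWindows", "HetWindowTrack", function(x) x@windows)
#' @rdname accessors
setMethod("tracts", "RohCallSet", function(x) x@tracts)
#' @rdname accessors
setMethod("segments", "AncestrySegmentation", function(x) x@segments)
#' @rdname accessors
setMethod("ancestryFractions", "AncestrySegmentation",
          function(x) x@fractions)
#' @rdname accessors
setMethod("autozygousTracts", "TruthTracts", function(x) x@autozygous)
#' @rdname accessors
setMethod("ancestryTracts", "TruthTracts", function(x) x@ancestry)

#' Total heterozygous-site count of a genome
#'
#' @param x a [DiploidGenome-class].
#' @return integer count of IUPAC heterozygote codes across scaffolds.
#' @export
hetSiteCount <- function(x) {
  stopifnot(is(x, "DiploidGenome"))
  if (!length(scaffolds(x))) return(0L)
  sum(Biostrings::letterFrequency(scaffolds(x),
                                  letters = paste(HET_CODES, collapse = "")))
}
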