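# Internal constants and small helpers shared across modules.

# Diploid consensus alphabet: 4 bases, 6 two-base ambiguity codes, N.
# Three/four-base codes (V,H,D,B) are rejected: sites are biallelic by
# construction upstream.
DIPLOID_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
HET_CODES <- c("R", "Y", "S", "W", "K", "M")

# unordered base pair -> IUPAC code (includes homozygous pairs)
IUPAC_CODE <- c(
  AA = "A", CC = "C", GG = "G", TT = "T",
  AC = "M", CA = "M",
  AG = "R", GA = "R",
  AT = "W", TA = "W",
  CG = "S", GC = "S",
  CT = "Y", TC = "Y",
  GT = "K", TG = "K"
)

# IUPAC het code -> its two bases (alphabetical)
IUPAC_BASES <- list(
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T")
)

#' Combine two base calls into a diploid IUPAC code
#'
#' Vectorised: equal bases map to themselves, differing ACGT bases to their
#' two-base ambiguity code, and any N propagates as N.
#'
#' @param a,b character vectors of single bases (A/C/G/T/N), same length.
#' @return character vector of IUPAC codes.
#' @keywords internal
iupacFromPair <- function(a, b) {
  out <- IUPAC_CODE[paste0(a, b)]
  out[a == "N" | b == "N"] <- "N"
  bad <- is.na(out)
  if (any(bad)) {
    stop("no biallelic IUPAC code for allele pair ",
         a[bad][1L], "/", b[bad][1L])
  }
  unname(out)
}

# Restore RNG state on exit so seeded helpers do not perturb callers.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# log(sum(exp(x))) without overflow; x finite or -Inf
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Runs of TRUE in a logical vector as (start, end) index pairs.
trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
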