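# Independent oracles and fixture builders used across tests.

library(GenomicRanges)

# Build a HetWindowTrack from raw per-window counts on one or more
# pseudo-scaffolds (counts given as a list, one element per scaffold).
trackFromCounts <- function(k, n, windowSize = 1e5, id = "sim",
                            miss = NULL) {
  if (!is.list(k)) {
    k <- list(k); n <- list(n)
    if (!is.null(miss)) miss <- list(miss)
  }
  grs <- lapply(seq_along(k), function(i) {
    nw <- length(k[[i]])
    gr <- GRanges(paste0("s", i),
                  IRanges::IRanges(start = (seq_len(nw) - 1L) * windowSize + 1L,
                                   width = windowSize))
    gr$het <- as.integer(k[[i]])
    gr$callable <- as.integer(n[[i]])
    gr$missing <- if (is.null(miss)) n[[i]] == 0L else miss[[i]]
    gr
  })
  HetWindowTrack(suppressWarnings(do.call(c, grs)), windowSize, id)
}

# Brute-force HMM log-likelihood: explicit sum over all 2^T state paths.
# Emissions: Poisson(lambda_s * n_t); missing windows contribute 1.
enumLoglik <- function(k, n, lambdas, Tm, pi0, miss = rep(FALSE, length(k))) {
  nT <- length(k)
  paths <- as.matrix(expand.grid(rep(list(1:2), nT)))
  lp <- apply(paths, 1L, function(s) {
    v <- log(pi0[s[1L]])
    for (t in seq_len(nT)) {
      if (!miss[t]) v <- v + dpois(k[t], lambdas[s[t]] * n[t], log = TRUE)
      if (t > 1L) v <- v + log(Tm[s[t - 1L], s[t]])
    }
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Brute-force Viterbi: the argmax path over all 2^T enumerated paths.
enumViterbi <- function(k, n, lambdas, Tm, pi0,
                        miss = rep(FALSE, length(k))) {
  nT <- length(k)
  paths <- as.matrix(expand.grid(rep(list(1:2), nT)))
  lp <- apply(paths, 1L, function(s) {
    v <- log(pi0[s[1L]])
    for (t in seq_len(nT)) {
      if (!miss[t]) v <- v + dpois(k[t], lambdas[s[t]] * n[t], log = TRUE)
      if (t > 1L) v <- v + log(Tm[s[t - 1L], s[t]])
    }
    v
  })
  unname(paths[which.max(lp), ])
}

# bp-level precision/recall of called tracts against a truth GRanges.
# Recall is measured against truth tracts at or above the call floor;
# precision against all truth bp.
rohAccuracy <- function(called, truth, minTruth = 2e6) {
  truthBig <- truth[width(truth) >= minTruth]
  tpPrec <- sum(width(GenomicRanges::intersect(called, truth)))
  tpRec <- sum(width(GenomicRanges::intersect(called, truthBig)))
  list(tpPrec = tpPrec, tpRec = tpRec,
       calledBp = sum(width(called)), truthBp = sum(width(truthBig)),
       precision = if (sum(width(called)) > 0)
         tpPrec / sum(width(called)) else NA_real_,
       recall = if (sum(width(truthBig)) > 0)
         tpRec / sum(width(truthBig)) else NA_real_)
}

# Per-bp AND of two interval sets on a 1 kb grid (intervals must have
# 1 kb-aligned boundaries). Independent bitmap oracle for intersection.
bitmapIntersect <- function(a, b, scaffold, lengthBp, res = 1000L) {
  nbin <- lengthBp / res
  asBits <- function(gr) {
    gr <- gr[seqnames(gr) == scaffold]
    bits <- rep(FALSE, nbin)
    for (i in seq_along(gr)) {
      from <- (start(gr)[i] - 1L) / res + 1L
      to <- end(gr)[i] / res
      bits[from:to] <- TRUE
    }
    bits
  }
  bits <- asBits(a) & asBits(b)
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(GRanges())
  GRanges(scaffold, IRanges::IRanges(start = (starts[keep] - 1L) * res + 1L,
                                     end = ends[keep] * res))
}

# Random 1 kb-aligned interval set on a scaffold, as a RohCallSet.
randomKbCallset <- function(scaffold, lengthBp, nIv, id,
                            minKb = 1, maxKb = 2000) {
  starts <- sort(sample.int(lengthBp / 1000 - maxKb, nIv)) * 1000 + 1
  widths <- sample(seq(minKb, maxKb), nIv, replace = TRUE) * 1000
  gr <- reduce(GRanges(scaffold,
                       IRanges::IRanges(start = starts, width = widths)))
  RohCallSet(gr, individualId = id, minLength = 0)
}

# Tiny random diploid consensus string with given het and N rates.
randomConsensus <- function(len, hetRate = 0.01, nRate = 0.01) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  nHet <- rbinom(1, len, hetRate)
  nN <- rbinom(1, len, nRate)
  idx <- sample.int(len, nHet + nN)
  if (nHet) ch[idx[seq_len(nHet)]] <-
    sample(c("R", "Y", "S", "W", "K", "M"), nHet, replace = TRUE)
  if (nN) ch[idx[nHet + seq_len(nN)]] <- "N"
  paste(ch, collapse = "")
}
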