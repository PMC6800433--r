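# Two-state HMM segmenting the genome into inbred (ROH) and outbred
# regions from windowed heterozygote counts. Emissions are Poisson with
# callable-site exposure: k_t ~ Poisson(lambda_state * n_t). Windows
# flagged missing contribute likelihood 1 in every state.

# Split a HetWindowTrack into per-scaffold observation lists.
trackObs <- function(track) {
  w <- hetWindows(track)
  sc <- as.character(GenomeInfoDb::seqnames(w))
  idx <- split(seq_along(w), factor(sc, levels = unique(sc)))
  lapply(idx, function(i)
    list(k = w$het[i], n = w$callable[i], miss = w$missing[i], idx = i))
}

# T x 2 matrix of log emission densities; missing windows contribute 0.
logEmissions <- function(obs, lambdas) {
  e <- vapply(lambdas, function(l)
    stats::dpois(obs$k, l * obs$n, log = TRUE), numeric(length(obs$k)))
  e <- matrix(e, ncol = 2L)
  e[obs$miss, ] <- 0
  e
}

# forward pass in log space; returns list(alpha = T x 2, logLik)
forwardPass <- function(e, logT, logPi) {
  nT <- nrow(e)
  alpha <- matrix(NA_real_, nT, 2L)
  alpha[1L, ] <- logPi + e[1L, ]
  if (nT > 1L) for (t in 2:nT) {
    for (j in 1:2)
      alpha[t, j] <- logSumExp(alpha[t - 1L, ] + logT[, j]) + e[t, j]
  }
  list(alpha = alpha, logLik = logSumExp(alpha[nT, ]))
}

backwardPass <- function(e, logT) {
  nT <- nrow(e)
  beta <- matrix(0, nT, 2L)
  if (nT > 1L) for (t in (nT - 1L):1L) {
    for (i in 1:2)
      beta[t, i] <- logSumExp(logT[i, ] + e[t + 1L, ] + beta[t + 1L, ])
  }
  beta
}

#' Forward log-likelihood of a window track under the ROH HMM
#'
#' Log-space forward algorithm, summed over scaffolds (each scaffold
#' restarts from the initial distribution). Window emissions are
#' Poisson(lambda_state * callable); missing-flagged windows contribute
#' likelihood 1.
#'
#' @param track a [HetWindowTrack-class].
#' @param params a [RohHmmParams-class]; state 1 is inbred.
#' @return the log-likelihood (finite unless the data are impossible
#'   under `params`, e.g. het counts > 0 with lambda = 0).
#' @export
forwardLoglik <- function(track, params) {
  stopifnot(is(track, "HetWindowTrack"), is(params, "RohHmmParams"))
  if (params@lambdaIn < 0 || params@lambdaOut <= 0 && !params@degenerate)
    stop("lambdas must be positive")
  lambdas <- c(params@lambdaIn, params@lambdaOut)
  logT <- log(params@transMat)
  logPi <- log(params@initProb)
  sum(vapply(trackObs(track), function(obs) {
    forwardPass(logEmissions(obs, lambdas), logT, logPi)$logLik
  }, numeric(1L)))
}

#' Fit the ROH HMM by Baum-Welch EM
#'
#' Expectation-maximisation with an exposure-weighted Poisson M-step:
#' lambda_s = sum(gamma_s * k) / sum(gamma_s * n) over non-missing
#' windows. The log-likelihood is non-decreasing across iterations;
#' fitting stops when the relative improvement drops below `tol` or at
#' `maxIter`. States are ordered lambdaIn < lambdaOut after convergence
#' (EM label switching). With `tol = Inf` the initial parameters are
#' returned after a single E-step (their log-likelihood is recorded).
#'
#' @param track a [HetWindowTrack-class]; at least two scaffolds' worth of
#'   windows is recommended for stable transition estimates.
#' @param init optional [RohHmmParams-class] initial values. Default:
#'   lambdaOut = overall het rate, lambdaIn = that / 10, transition
#'   matrix with diagonal 0.999 (tracts are Mb-scale, windows 100 kb).
#' @param tol relative log-likelihood improvement threshold (default 1e-6).
#' @param maxIter maximum EM iterations (default 100).
#' @return a [RohHmmParams-class] with the `fitLogLik` trajectory filled.
#'   If the track contains no heterozygous sites at all the fit is
#'   degenerate: both lambdas 0, a warning, and `degenerate = TRUE`.
#' @export
fitRohHmm <- function(track, init = NULL, tol = 1e-6, maxIter = 100L) {
  stopifnot(is(track, "HetWindowTrack"))
  obsList <- trackObs(track)
  used <- unlist(lapply(obsList, function(o) o$k[!o$miss]))
  if (length(used) && all(used == 0)) {
    warning("all het counts are zero; returning degenerate fit")
    return(new("RohHmmParams", lambdaIn = 0, lambdaOut = 0,
               transMat = matrix(c(0.999, 0.001, 0.001, 0.999), 2,
                                 byrow = TRUE),
               initProb = c(0.5, 0.5), degenerate = TRUE,
               fitLogLik = numeric(0)))
  }
  if (is.null(init)) {
    usedN <- unlist(lapply(obsList, function(o) o$n[!o$miss]))
    rate <- sum(used) / max(sum(usedN), 1)
    init <- RohHmmParams(lambdaIn = rate / 10, lambdaOut = rate)
  }
  lambdas <- c(init@lambdaIn, init@lambdaOut)
  Tm <- init@transMat
  pi0 <- init@initProb
  llHist <- numeric(0)
  llPrev <- -Inf
  for (iter in seq_len(max(maxIter, 1L))) {
    logT <- log(Tm); logPi <- log(pi0)
    ll <- 0
    gK <- gN <- c(0, 0)               # M-step sums for lambdas
    xiSum <- matrix(0, 2L, 2L)
    gFirst <- c(0, 0)
    gTrans <- c(0, 0)                 # gamma mass over t = 1..T-1
    for (obs in obsList) {
      e <- logEmissions(obs, lambdas)
      fw <- forwardPass(e, logT, logPi)
      beta <- backwardPass(e, logT)
      lg <- fw$alpha + beta - fw$logLik
      gamma <- exp(lg)
      ll <- ll + fw$logLik
      ok <- !obs$miss
      gK <- gK + colSums(gamma[ok, , drop = FALSE] * obs$k[ok])
      gN <- gN + colSums(gamma[ok, , drop = FALSE] * obs$n[ok])
      nT <- nrow(e)
      if (nT > 1L) {
        for (t in seq_len(nT - 1L)) {
          lx <- outer(fw$alpha[t, ], e[t + 1L, ] + beta[t + 1L, ], "+") +
            logT - fw$logLik
          xiSum <- xiSum + exp(lx)
        }
        gTrans <- gTrans + colSums(gamma[-nT, , drop = FALSE])
      }
      gFirst <- gFirst + gamma[1L, ]
    }
    llHist <- c(llHist, ll)
    if (is.infinite(tol)) break
    if (is.finite(llPrev) &&
        (ll - llPrev) < tol * abs(llPrev)) break
    llPrev <- ll
    lambdas <- ifelse(gN > 0, gK / gN, lambdas)
    if (any(gTrans > 0)) Tm <- xiSum / gTrans
    Tm <- pmin(pmax(Tm, 1e-12), 1)
    Tm <- Tm / rowSums(Tm)
    pi0 <- gFirst / sum(gFirst)
    pi0 <- pmin(pmax(pi0, 1e-12), 1)
    pi0 <- pi0 / sum(pi0)
  }
  if (lambdas[1L] > lambdas[2L]) {    # order states: inbred = low rate
    lambdas <- rev(lambdas)
    pi0 <- rev(pi0)
    Tm <- Tm[2:1, 2:1]
  }
  new("RohHmmParams", lambdaIn = lambdas[1L], lambdaOut = lambdas[2L],
      transMat = Tm, initProb = pi0, degenerate = FALSE,
      fitLogLik = llHist)
}

#' Decode the ROH HMM: Viterbi path and posterior state probabilities
#'
#' Viterbi ties are broken toward the outbred state so that ROH calls are
#' conservative. Posteriors come from the forward-backward algorithm and
#' sum to 1 per window.
#'
#' @param track a [HetWindowTrack-class].
#' @param params a fitted [RohHmmParams-class].
#' @return the window [GenomicRanges::GRanges] with added metadata
#'   columns `state` ("inbred"/"outbred") and `postInbred`.
#' @export
decodeRoh <- function(track, params) {
  stopifnot(is(track, "HetWindowTrack"), is(params, "RohHmmParams"))
  w <- hetWindows(track)
  lambdas <- c(params@lambdaIn, params@lambdaOut)
  logT <- log(params@transMat)
  logPi <- log(params@initProb)
  state <- integer(length(w))
  post <- numeric(length(w))
  for (obs in trackObs(track)) {
    e <- logEmissions(obs, lambdas)
    nT <- nrow(e)
    # Viterbi
    delta <- matrix(-Inf, nT, 2L)
    psi <- matrix(1L, nT, 2L)
    delta[1L, ] <- logPi + e[1L, ]
    if (nT > 1L) for (t in 2:nT) for (j in 1:2) {
      cand <- delta[t - 1L, ] + logT[, j]
      # ties toward outbred predecessor (state 2)
      best <- if (cand[2L] >= cand[1L]) 2L else 1L
      psi[t, j] <- best
      delta[t, j] <- cand[best] + e[t, j]
    }
    path <- integer(nT)
    path[nT] <- if (delta[nT, 2L] >= delta[nT, 1L]) 2L else 1L
    if (nT > 1L) for (t in (nT - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
    # posteriors
    fw <- forwardPass(e, logT, logPi)
    beta <- backwardPass(e, logT)
    gamma <- exp(fw$alpha + beta - fw$logLik)
    state[obs$idx] <- path
    post[obs$idx] <- gamma[, 1L]
  }
  w$state <- c("inbred", "outbred")[state]
  w$postInbred <- post
  w
}

#' Extract ROH tracts from a decoded window path
#'
#' Merges consecutive inbred windows into tracts (start of the first
#' window to end of the last; missing-flagged windows inside a run are
#' bridged because the Viterbi path assigns them the flanking state) and
#' drops tracts shorter than `minLength`. Long tracts are callable with
#' high confidence, hence the conservative default floor of 2 Mb.
#'
#' @param decoded GRanges from [decodeRoh()].
#' @param individualId identifier for the call set.
#' @param minLength minimum tract length in bp (default 2e6).
#' @return a [RohCallSet-class]; tracts carry the mean inbred posterior
#'   of their windows.
#' @export
extractTracts <- function(decoded, individualId = "unknown",
                          minLength = 2e6) {
  grl <- split(decoded, factor(as.character(GenomeInfoDb::seqnames(decoded)),
                               levels = unique(as.character(
                                 GenomeInfoDb::seqnames(decoded)))))
  out <- lapply(grl, function(w) {
    runs <- trueRuns(w$state == "inbred")
    if (!nrow(runs)) return(GRanges())
    gr <- GRanges(GenomeInfoDb::seqnames(w)[runs[, 1L]],
                  IRanges::IRanges(
                    start = GenomicRanges::start(w)[runs[, 1L]],
                    end = GenomicRanges::end(w)[runs[, 2L]]))
    gr$meanPosterior <- vapply(seq_len(nrow(runs)), function(i)
      mean(w$postInbred[runs[i, 1L]:runs[i, 2L]]), numeric(1L))
    gr
  })
  gr <- suppressWarnings(do.call(c, unname(out)))
  gr <- gr[GenomicRanges::width(gr) >= minLength]
  RohCallSet(gr, individualId = individualId, minLength = minLength)
}

#' Call ROH from a genome in one step
#'
#' Convenience wrapper: [windowHet()] then [fitRohHmm()], [decodeRoh()]
#' and [extractTracts()].
#'
#' @param genome a [DiploidGenome-class].
#' @param windowSize window width in bp (default 100 kb).
#' @param minLength minimum tract length in bp (default 2 Mb).
#' @param init optional initial [RohHmmParams-class].
#' @return list with elements `callset` ([RohCallSet-class]), `params`
#'   (fitted [RohHmmParams-class]), `track` and `decoded`.
#' @export
callRoh <- function(genome, windowSize = 1e5, minLength = 2e6,
                    init = NULL) {
  track <- windowHet(genome, windowSize = windowSize)
  params <- fitRohHmm(track, init = init)
  decoded <- decodeRoh(track, params)
  callset <- extractTracts(decoded, individualId = individualId(genome),
                           minLength = minLength)
  list(callset = callset, params = params, track = track,
       decoded = decoded)
}
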