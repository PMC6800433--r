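test_that("forward log-likelihood matches brute-force path enumeration", {
  # single window, pi = (1, 0): likelihood is one Poisson term
  p1 <- RohHmmParams(lambdaIn = 2 / 1000, lambdaOut = 0.02,
                     initProb = c(1, 0))
  t1 <- trackFromCounts(2L, 1000L)
  expect_equal(forwardLoglik(t1, p1), dpois(2, 2, log = TRUE))

  set.seed(41)
  for (rep in 1:6) {
    nT <- sample(2:12, 1)
    n <- sample(500:2000, nT, replace = TRUE)
    lamIn <- runif(1, 1e-4, 1e-3)
    lamOut <- lamIn * runif(1, 5, 30)
    stay <- runif(2, 0.7, 0.99)
    Tm <- matrix(c(stay[1], 1 - stay[1], 1 - stay[2], stay[2]), 2,
                 byrow = TRUE)
    pi0 <- c(0.3, 0.7)
    k <- rpois(nT, ifelse(runif(nT) < 0.5, lamIn, lamOut) * n)
    miss <- runif(nT) < 0.15
    track <- trackFromCounts(k, n, miss = miss)
    params <- RohHmmParams(lamIn, lamOut, Tm, pi0)
    got <- forwardLoglik(track, params)
    want <- enumLoglik(k, n, c(lamIn, lamOut), Tm, pi0, miss = miss)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to relabelling states with swapped params", {
  set.seed(43)
  k <- rpois(8, 3)
  track <- trackFromCounts(k, rep(1000L, 8))
  Tm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  a <- RohHmmParams(1e-4, 5e-3, Tm, c(0.4, 0.6))
  b <- new("RohHmmParams", lambdaIn = 5e-3, lambdaOut = 1e-4,
           transMat = Tm[2:1, 2:1], initProb = c(0.6, 0.4),
           degenerate = TRUE, fitLogLik = numeric(0))  # swapped labels
  expect_equal(forwardLoglik(track, a), forwardLoglik(track, b))
})

test_that("multi-scaffold likelihood is the sum of per-scaffold terms", {
  set.seed(44)
  k1 <- rpois(5, 2); k2 <- rpois(4, 6)
  n1 <- rep(800L, 5); n2 <- rep(1200L, 4)
  p <- RohHmmParams(2e-4, 4e-3)
  both <- trackFromCounts(list(k1, k2), list(n1, n2))
  expect_equal(forwardLoglik(both, p),
               forwardLoglik(trackFromCounts(k1, n1), p) +
                 forwardLoglik(trackFromCounts(k2, n2), p))
})

test_that("Baum-Welch recovers parameters and increases the likelihood", {
  set.seed(47)
  nT <- 5000
  lamTrue <- c(5e-5, 1e-3)          # inbred rate = outbred / 20
  stay <- c(0.98, 0.98)
  n <- rep(1e5L, nT)
  s <- integer(nT); s[1] <- 2L
  for (t in 2:nT)
    s[t] <- if (runif(1) < stay[s[t - 1]]) s[t - 1] else 3L - s[t - 1]
  k <- rpois(nT, lamTrue[s] * n)
  # split into 5 pseudo-scaffolds
  idx <- split(seq_len(nT), rep(1:5, each = nT / 5))
  track <- trackFromCounts(lapply(idx, function(i) k[i]),
                           lapply(idx, function(i) n[i]))
  fit <- fitRohHmm(track)
  expect_lt(abs(fit@lambdaIn - lamTrue[1]) / lamTrue[1], 0.10)
  expect_lt(abs(fit@lambdaOut - lamTrue[2]) / lamTrue[2], 0.10)
  # monotone non-decreasing log-likelihood (EM property)
  expect_true(all(diff(fit@fitLogLik) > -1e-6 * abs(fit@fitLogLik[-1])))
  expect_true(fit@lambdaIn < fit@lambdaOut)
})

test_that("tol = Inf returns the initial parameters after bookkeeping", {
  set.seed(48)
  track <- trackFromCounts(rpois(20, 3), rep(1000L, 20))
  init <- RohHmmParams(1e-4, 4e-3)
  fit <- fitRohHmm(track, init = init, tol = Inf)
  expect_equal(fit@lambdaIn, init@lambdaIn)
  expect_equal(fit@lambdaOut, init@lambdaOut)
  expect_length(fit@fitLogLik, 1L)
})

test_that("degenerate all-zero data yield a flagged zero-rate fit", {
  track <- trackFromCounts(rep(0L, 30), rep(1000L, 30))
  expect_warning(fit <- fitRohHmm(track), "degenerate")
  expect_true(fit@degenerate)
  expect_equal(fit@lambdaIn, 0)
  expect_equal(fit@lambdaOut, 0)
})

test_that("Viterbi matches brute-force argmax and posteriors normalise", {
  set.seed(51)
  for (rep in 1:5) {
    nT <- sample(3:10, 1)
    n <- sample(800:1500, nT, replace = TRUE)
    lamIn <- 1e-4; lamOut <- 2e-3
    Tm <- matrix(c(0.95, 0.05, 0.07, 0.93), 2, byrow = TRUE)
    pi0 <- c(0.5, 0.5)
    k <- rpois(nT, ifelse(runif(nT) < 0.5, lamIn, lamOut) * n)
    track <- trackFromCounts(k, n)
    params <- RohHmmParams(lamIn, lamOut, Tm, pi0)
    d <- decodeRoh(track, params)
    want <- enumViterbi(k, n, c(lamIn, lamOut), Tm, pi0)
    expect_equal(match(d$state, c("inbred", "outbred")), want)
    expect_true(all(d$postInbred >= 0 & d$postInbred <= 1))
  }
})

test_that("extreme tracks decode to the obvious single-state path", {
  p <- RohHmmParams(5e-5, 1e-3)
  n <- rep(1e5L, 40)
  dIn <- decodeRoh(trackFromCounts(rep(0L, 40), n), p)
  expect_true(all(dIn$state == "inbred"))
  dOut <- decodeRoh(trackFromCounts(rep(100L, 40), n), p)
  expect_true(all(dOut$state == "outbred"))
})

test_that("extractTracts merges windows and applies the length floor", {
  p <- RohHmmParams(5e-5, 1e-3)
  # 30 inbred windows (3 Mb) then outbred at 100 kb windows
  k <- c(rep(0L, 30), rep(100L, 30))
  d <- decodeRoh(trackFromCounts(k, rep(1e5L, 60)), p)
  cs <- extractTracts(d, "x", minLength = 2e6)
  expect_length(tracts(cs), 1L)
  expect_equal(GenomicRanges::width(tracts(cs)), 3e6)
  expect_gt(tracts(cs)$meanPosterior, 0.99)

  # a 15-window (1.5 Mb) block is dropped at the 2 Mb floor
  k2 <- c(rep(100L, 20), rep(0L, 15), rep(100L, 25))
  d2 <- decodeRoh(trackFromCounts(k2, rep(1e5L, 60)), p)
  expect_length(tracts(extractTracts(d2, "x", minLength = 2e6)), 0L)
  expect_length(tracts(extractTracts(d2, "x", minLength = 1e6)), 1L)
})
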