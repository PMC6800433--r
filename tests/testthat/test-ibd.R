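mkCallset <- function(scaffold, starts, ends, id) {
  RohCallSet(GenomicRanges::GRanges(scaffold,
                                    IRanges::IRanges(starts, ends)),
             individualId = id, minLength = 0)
}

test_that("intersectRoh computes merged per-scaffold intersections", {
  a <- mkCallset("s1", 1, 10e6, "a")
  b <- mkCallset("s1", 5e6 + 1, 15e6, "b")
  ov <- intersectRoh(a, b)
  expect_equal(GenomicRanges::start(ov), 5e6 + 1)
  expect_equal(GenomicRanges::end(ov), 10e6)

  d1 <- mkCallset("s1", 1, 1e6, "d1")
  d2 <- mkCallset("s1", 2e6, 3e6, "d2")
  expect_length(intersectRoh(d1, d2), 0L)

  expect_error(intersectRoh(mkCallset("s1", 1, 10, "x"),
                            mkCallset("s2", 1, 10, "y")),
               "scaffold universes differ")
})

test_that("intersection equals the per-bp bitmap oracle on random sets", {
  set.seed(71)
  for (rep in 1:5) {
    a <- randomKbCallset("s1", 1e7, 6, "a")
    b <- randomKbCallset("s1", 1e7, 6, "b")
    got <- intersectRoh(a, b)
    want <- bitmapIntersect(tracts(a), tracts(b), "s1", 1e7)
    expect_equal(GenomicRanges::start(got), GenomicRanges::start(want))
    expect_equal(GenomicRanges::end(got), GenomicRanges::end(want))
  }
})

test_that("ibdFraction is the shared-ROH fraction of the genome", {
  a <- mkCallset("s1", c(1, 20e6 + 1), c(10e6, 26e6), "a")
  # diagonal: equals F_ROH of the individual
  expect_equal(ibdFraction(a, a, 1e8), 0.16)
  disj <- mkCallset("s1", 40e6, 45e6, "d")
  expect_equal(ibdFraction(a, disj, 1e8), 0)
  # overlaps below minOverlap are discarded
  c1 <- mkCallset("s1", 1, 10e6, "c1")
  c2 <- mkCallset("s1", 9.5e6, 20e6, "c2")
  expect_equal(ibdFraction(c1, c2, 1e8), 0)
  expect_equal(ibdFraction(c1, c2, 1e8, minOverlap = 1e5),
               (10e6 - 9.5e6 + 1) / 1e8)
})

test_that("the homozygote-identity filter drops non-identical overlaps", {
  hom1 <- paste(rep("A", 4e4), collapse = "")
  hom2 <- paste(rep("G", 4e4), collapse = "")
  gA <- DiploidGenome(c(s1 = hom1), "a")
  gB <- DiploidGenome(c(s1 = hom1), "b")
  gC <- DiploidGenome(c(s1 = hom2), "c")
  cs <- function(id) mkCallset("s1", 1, 4e4, id)
  # identical homozygous sequence: overlap kept
  expect_equal(ibdFraction(cs("a"), cs("b"), 1e5,
                           genomes = list(gA, gB), minOverlap = 1e4),
               4e4 / 1e5)
  # same interval, different alleles: rejected as IBD
  expect_equal(ibdFraction(cs("a"), cs("c"), 1e5,
                           genomes = list(gA, gC), minOverlap = 1e4), 0)
})

test_that("ibdMatrix is symmetric, diagonal-bounded, definitionally consistent", {
  x <- mkCallset("s1", 1, 10e6, "x")
  y <- mkCallset("s1", 30e6, 40e6, "y")
  z <- mkCallset("s1", 60e6, 75e6, "z")
  m <- ibdMatrix(list(x, y, z), 1e8)
  expect_true(all(m[upper.tri(m)] == 0))
  expect_equal(diag(m), c(x = (10e6) / 1e8, y = (10e6 + 1) / 1e8,
                          z = (15e6 + 1) / 1e8))

  # duplicated individual: off-diagonal equals the diagonal
  x2 <- mkCallset("s1", 1, 10e6, "x2")
  m2 <- ibdMatrix(list(x, x2), 1e8)
  expect_equal(m2["x", "x2"], m2["x", "x"])

  # random sets: symmetry, bounds, element-wise agreement with ibdFraction
  set.seed(73)
  sets <- lapply(1:4, function(i) randomKbCallset("s1", 1e7, 5,
                                                  paste0("i", i)))
  mr <- ibdMatrix(sets, 1e7, minOverlap = 1e3)
  expect_equal(mr, t(mr))
  for (i in 1:4) for (j in 1:4) {
    expect_lte(mr[i, j], min(mr[i, i], mr[j, j]) + 1e-12)
    if (i < j)
      expect_equal(mr[i, j],
                   ibdFraction(sets[[i]], sets[[j]], 1e7,
                               minOverlap = 1e3))
  }
})

test_that("simulated siblings share more IBD-ROH than unrelated pairs", {
  # two children of the same funnel pedigree vs a focal from an
  # independent pedigree; truth tracts serve as the call sets
  ped <- funnelPedigree(3)
  ped <- PedigreeSpec(ped@founders,
                      rbind(ped@matings,
                            data.frame(sire = ped@matings$sire[nrow(ped@matings)],
                                       dam = ped@matings$dam[nrow(ped@matings)],
                                       child = "sib")),
                      focal = "focal")
  lens <- c(s1 = 1e9)
  sim <- simulatePedigree(ped, lens, seed = 81)
  csOf <- function(sim, id) {
    tt <- autozygousTracts(truthTracts(sim, id))
    RohCallSet(tt[, NULL], individualId = id, minLength = 0)
  }
  focal <- csOf(sim, "focal")
  sib <- csOf(sim, "sib")
  other <- csOf(simulatePedigree(funnelPedigree(3), lens, seed = 4242),
                "focal")
  other@individualId <- "other"
  sibShare <- ibdFraction(focal, sib, 1e9)
  unrelShare <- ibdFraction(focal, other, 1e9)
  expect_gt(sibShare, unrelShare)
})
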