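test_that("panel variant counts follow their Poisson densities", {
  L <- 1e7
  pool <- simulatePanels(c(s1 = L), founderPops = c("A", "A", "B", "B"),
                         theta = 1e-3, dAB = 1e-4, seed = 91)
  v <- pool@variants
  # polymorphic sites per population at density 2*theta
  expA <- 2e-3 * L
  expect_lt(abs(sum(v$class == "polyA") - expA), 4 * sqrt(expA))
  expect_lt(abs(sum(v$class == "polyB") - expA), 4 * sqrt(expA))
  expD <- 1e-4 * L
  expect_lt(abs(sum(v$class == "fixed") - expD), 4 * sqrt(expD))
  expect_false(any(duplicated(v$pos)))
  expect_true(all(v$ref != v$alt))
})

test_that("theta = 0 makes all founder haplotypes identical", {
  pool <- simulatePanels(c(s1 = 1e5), founderPops = c("A", "A"),
                         theta = 0, dAB = 0, seed = 92)
  ped <- PedigreeSpec(data.frame(id = c("f1", "f2"), pop = "A"),
                      data.frame(sire = character(), dam = character(),
                                 child = character()), focal = "f1")
  sim <- simulatePedigree(ped, c(s1 = 1e5), seed = 92)
  g1 <- renderGenome(sim, pool, "f1")
  g2 <- renderGenome(sim, pool, "f2")
  expect_identical(as.character(scaffolds(g1)),
                   as.character(scaffolds(g2)))
  expect_equal(hetSiteCount(g1), 0L)
})

test_that("an outbred individual's heterozygosity recovers theta", {
  theta <- 1e-3
  L <- 2e7
  pool <- simulatePanels(c(s1 = L), founderPops = c("A", "A"),
                         theta = theta, dAB = 0, seed = 93)
  ped <- PedigreeSpec(data.frame(id = c("f1", "f2"), pop = "A"),
                      data.frame(sire = "f1", dam = "f2", child = "kid"),
                      focal = "kid")
  sim <- simulatePedigree(ped, c(s1 = L), seed = 93)
  het <- genomeHet(renderGenome(sim, pool, "kid"))
  se <- sqrt(theta / L)   # Poisson count SE on the rate scale
  expect_lt(abs(het - theta), 3 * se)
})

test_that("meiosis respects the crossover process", {
  hap <- function(copy, L) data.frame(start = 1, end = L, copy = copy)
  L <- 1e8
  # vanishing rate: gamete is one intact parental haplotype
  set.seed(94)
  g0 <- meiosisGamete(hap(1L, L), hap(2L, L), L, rate = 1e-9)
  expect_equal(nrow(g0), 1L)
  expect_true(g0$copy %in% c(1L, 2L))

  # r = 1.1 on 100 Mb: mean 1.1 breakpoints, positions uniform
  nb <- integer(400); pos <- c()
  for (i in 1:400) {
    g <- meiosisGamete(hap(1L, L), hap(2L, L), L, rate = 1.1)
    bp <- attr(g, "breakpoints")
    nb[i] <- length(bp)
    pos <- c(pos, bp)
  }
  expect_lt(abs(mean(nb) - 1.1), 4 * sqrt(1.1 / 400))
  ks <- suppressWarnings(ks.test(pos / L, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("unrelated founders produce no autozygosity; selfing produces it", {
  ped <- PedigreeSpec(data.frame(id = c("f1", "f2"), pop = "A"),
                      data.frame(sire = "f1", dam = "f2", child = "kid"),
                      focal = "kid")
  sim <- simulatePedigree(ped, c(s1 = 5e7), seed = 95)
  expect_length(autozygousTracts(truthTracts(sim)), 0L)

  selfed <- PedigreeSpec(data.frame(id = "f1", pop = "A"),
                         data.frame(sire = "f1", dam = "f1",
                                    child = "kid"), focal = "kid")
  simS <- simulatePedigree(selfed, c(s1 = 5e8), seed = 95)
  a <- autozygousTracts(truthTracts(simS))
  expect_gt(sum(GenomicRanges::width(a)), 0)
  # selfing: expected autozygous fraction 1/2
  expect_lt(abs(sum(GenomicRanges::width(a)) / 5e8 - 0.5), 0.25)
})

test_that("truth tract mean length tracks 100/(2 r g) for a selfing loop", {
  # common ancestor one generation back: expected mean 100/(2*1.1*1) Mb
  lens <- c()
  for (s in 1:6) {
    sc <- simulateScenario("isolated_inbred", g = 1,
                           scaffoldLengths = c(s1 = 1e9), seed = 960 + s,
                           render = FALSE)
    a <- autozygousTracts(sc$truth)
    lens <- c(lens, GenomicRanges::width(a[!a$truncated]) / 1e6)
  }
  expect_gt(length(lens), 20)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 100 / (2 * 1.1)), 3 * se)
})

test_that("identical seeds reproduce identical simulations", {
  run <- function() {
    sc <- simulateScenario("isolated_inbred", g = 2,
                           scaffoldLengths = c(s1 = 5e6, s2 = 5e6),
                           seed = 97, theta = 5e-4, nPanel = 0)
    list(seq = as.character(scaffolds(sc$genome)),
         truth = autozygousTracts(sc$truth))
  }
  a <- run(); b <- run()
  expect_identical(a$seq, b$seq)
  expect_identical(a$truth, b$truth)
})

test_that("focal het sites never fall inside truth autozygous tracts", {
  # find a replicate with autozygous tracts from truth alone, then render
  sc <- NULL
  for (s in 98:110) {
    cand <- simulateScenario("isolated_inbred", g = 2,
                             scaffoldLengths = c(s1 = 5e7), seed = s,
                             render = FALSE)
    if (length(autozygousTracts(cand$truth))) {
      sc <- simulateScenario("isolated_inbred", g = 2,
                             scaffoldLengths = c(s1 = 5e7), seed = s,
                             nPanel = 0)
      break
    }
  }
  a <- autozygousTracts(sc$truth)
  expect_gt(length(a), 0)
  for (i in seq_along(a)) {
    sub <- Biostrings::subseq(scaffolds(sc$genome)[["s1"]],
                              GenomicRanges::start(a)[i],
                              GenomicRanges::end(a)[i])
    hets <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(sub), letters = "RYSWKM")[1]
    expect_equal(unname(hets), 0)
  }
})

test_that("scaffold-end tracts are flagged truncated", {
  found <- FALSE
  for (s in 1:10) {
    sc <- simulateScenario("isolated_inbred", g = 2,
                           scaffoldLengths = c(s1 = 3e7), seed = 990 + s,
                           render = FALSE)
    a <- autozygousTracts(sc$truth)
    edge <- GenomicRanges::start(a) == 1 | GenomicRanges::end(a) == 3e7
    expect_equal(unname(a$truncated), unname(edge))
    if (any(edge)) found <- TRUE
  }
  expect_true(found)  # 30 Mb scaffolds: some tracts must hit an end
})

test_that("an A x B cross is heterozygous-ancestry genome-wide", {
  ped <- PedigreeSpec(data.frame(id = c("fa", "fb"), pop = c("A", "B")),
                      data.frame(sire = "fa", dam = "fb", child = "kid"),
                      focal = "kid")
  sim <- simulatePedigree(ped, c(s1 = 1e7), seed = 99)
  truth <- truthTracts(sim)
  dip <- truthDiploidAncestry(truth)
  expect_equal(dip$label, "MIXED")
  expect_equal(sum(GenomicRanges::width(dip)), 1e7)
  expect_length(autozygousTracts(truth), 0L)
})

test_that("admixed autozygous tracts always lie in single-ancestry regions", {
  for (s in 1:3) {
    sc <- simulateScenario("admixed_inbred", g = 4,
                           scaffoldLengths = c(s1 = 5e8), seed = 1000 + s,
                           render = FALSE)
    a <- autozygousTracts(sc$truth)
    if (!length(a)) next
    dip <- truthDiploidAncestry(sc$truth)
    pure <- GenomicRanges::reduce(dip[dip$label != "MIXED"])
    # every autozygous bp is inside a pure-ancestry region
    inPure <- sum(GenomicRanges::width(
      GenomicRanges::intersect(a[, NULL], pure)))
    expect_equal(inPure, sum(GenomicRanges::width(a)))
  }
})

test_that("scenario bundles are written to disk with a config echo", {
  dir <- file.path(tempdir(), "scen")
  sc <- simulateScenario("isolated_inbred", g = 2,
                         scaffoldLengths = c(s1 = 2e6), seed = 101,
                         theta = 5e-4, nPanel = 1, outDir = dir)
  expect_true(file.exists(file.path(dir, "focal.fa")))
  expect_true(file.exists(file.path(dir, "truth_roh.bed")))
  expect_true(file.exists(file.path(dir, "truth_ancestry_hap1.bed")))
  expect_true(file.exists(file.path(dir, "scenario.yaml")))
  cfg <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  expect_equal(cfg$g, 2)
  expect_equal(cfg$scenario, "isolated_inbred")
  expect_true(file.exists(file.path(dir, "panel_PA1.fa")))
})
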