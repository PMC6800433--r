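test_that("IUPAC FASTA round-trips and alphabet semantics hold", {
  g <- DiploidGenome(c(s1 = "ACGT", s2 = "ARN"), "ind1")
  expect_equal(hetSiteCount(g), 1L)
  f <- tempfile(fileext = ".fa")
  writeIupacFasta(g, f)
  g2 <- readIupacFasta(f, "ind1")
  expect_identical(as.character(scaffolds(g2)), as.character(scaffolds(g)))
  expect_identical(individualId(g2), "ind1")

  # lowercase (soft-masked) input is uppercased, not masked
  f2 <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgtr"), f2)
  expect_identical(as.character(scaffolds(readIupacFasta(f2))[[1]]),
                   "ACGTR")

  # random round-trip including long wrapped lines
  set.seed(11)
  g3 <- DiploidGenome(c(chrA = randomConsensus(500),
                        chrB = randomConsensus(123)), "rt")
  f3 <- tempfile(fileext = ".fa")
  writeIupacFasta(g3, f3)
  expect_identical(as.character(scaffolds(readIupacFasta(f3))),
                   as.character(scaffolds(g3)))
})

test_that("illegal characters and malformed FASTA are rejected with context", {
  # V is a 3-base ambiguity code: outside the biallelic alphabet
  expect_error(DiploidGenome(c(s1 = "ACVG"), "x"),
               "illegal character 'V' in scaffold 's1' at position 3")
  f <- tempfile()
  writeLines("ACGT without a header", f)
  expect_error(readIupacFasta(f), "malformed FASTA")
})

test_that("buildMaskedFasta applies genotypes and masks to the reference", {
  ref <- DiploidGenome(c(s1 = "AAAA", s2 = "CCCC"), "ref")
  tab <- data.frame(
    scaffold = c("s1", "s1", "s2"),
    pos = c(2L, 3L, 1L),
    genotype = c("het", "missing", "hom_alt"),
    ref = c("A", "A", "C"),
    alt = c("G", "T", "T"), stringsAsFactors = FALSE)
  out <- buildMaskedFasta(ref, tab, individualId = "x")
  expect_identical(as.character(scaffolds(out)),
                   c(s1 = "ARNA", s2 = "TCCC"))
  # lengths always preserved
  expect_identical(lengths(scaffolds(out)), lengths(scaffolds(ref)))

  # empty table, no failed sites -> identity
  empty <- tab[0, ]
  expect_identical(as.character(scaffolds(buildMaskedFasta(ref, empty))),
                   as.character(scaffolds(ref)))

  # failed-site intervals are masked to N
  fs <- GenomicRanges::GRanges("s2", IRanges::IRanges(2, 3))
  out2 <- buildMaskedFasta(ref, empty, failedSites = fs)
  expect_identical(as.character(scaffolds(out2))[["s2"]], "CNNC")

  # alleles without a biallelic IUPAC code are rejected
  bad <- data.frame(scaffold = "s1", pos = 1L, genotype = "het",
                    ref = "A", alt = "N", stringsAsFactors = FALSE)
  expect_error(buildMaskedFasta(ref, bad), "IUPAC")
  # positions outside the scaffold are rejected
  off <- data.frame(scaffold = "s1", pos = 9L, genotype = "het",
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  expect_error(buildMaskedFasta(ref, off), "outside")
})

test_that("makePseudodiploid merges haplotypes site-wise", {
  expect_identical(as.character(makePseudodiploid("ACGT", "ACGT")), "ACGT")
  expect_identical(as.character(makePseudodiploid("ACGT", "ACAT")), "ACRT")
  expect_identical(as.character(makePseudodiploid("ANGT", "ACGT")), "ANGT")
  expect_error(makePseudodiploid("ACGT", "ACG"), "length mismatch")

  # symmetric in its arguments
  set.seed(5)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE), collapse = "")
    expect_identical(as.character(makePseudodiploid(a, b)),
                     as.character(makePseudodiploid(b, a)))
  }
})

test_that("BED I/O uses 0-based half-open on disk, sorted on write", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("s1\t0\t10", "s1\t20\t25"), f)
  gr <- readBed(f)
  expect_equal(GenomicRanges::start(gr), c(1, 21))
  expect_equal(GenomicRanges::end(gr), c(10, 25))

  # unsorted input is sorted on write; round-trip is identity
  un <- GenomicRanges::GRanges(c("s2", "s1", "s1"),
                               IRanges::IRanges(c(5, 100, 2),
                                                c(10, 110, 4)))
  f2 <- tempfile(fileext = ".bed")
  writeBed(un, f2)
  expect_identical(readLines(f2),
                   c("s1\t1\t4", "s1\t99\t110", "s2\t4\t10"))
  rt <- readBed(f2)
  f3 <- tempfile(fileext = ".bed")
  writeBed(rt, f3)
  expect_identical(readLines(f2), readLines(f3))

  # invalid coordinates are reported with their line number
  f4 <- tempfile(fileext = ".bed")
  writeLines(c("# comment", "s1\t0\t10", "s1\t7\t7"), f4)
  expect_error(readBed(f4), "line 3: end <= start")
})
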