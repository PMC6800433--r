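# Pedigree/admixture simulator with ground truth.
#
# Haplotypes are represented as mosaics of founder haplotype copies:
# per scaffold a segment table (start, end, copy) tiling [1, L]. Copy
# 2i-1 and 2i belong to the i-th pedigree founder. Meiosis splices the
# two parental mosaics at crossover breakpoints drawn as a Poisson
# process at r/100 events per Mb. Sequences are rendered only on demand,
# so ground-truth-only studies never touch base-level data.

#' Simulate founder haplotype panels over a shared reference
#'
#' Builds a random reference and places variant sites as Poisson
#' processes: within-population polymorphic sites at density 2*theta per
#' bp per population (founder haplotypes draw alleles at frequency 0.5,
#' so an outbred individual's expected heterozygosity is theta per bp)
#' and between-population fixed differences at density dAB (population A
#' carries the reference allele, B the alternate).
#'
#' @param scaffoldLengths named numeric vector of scaffold lengths (bp).
#' @param founderPops character vector in \{"A","B"\}: population of each
#'   founder, in pedigree founder order.
#' @param theta expected heterozygous sites per bp within a population
#'   (default 1e-3).
#' @param dAB per-bp density of fixed inter-population differences
#'   (default 1e-4).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [PanelPool-class].
#' @export
simulatePanels <- function(scaffoldLengths, founderPops, theta = 1e-3,
                           dAB = 1e-4, seed = 1L) {
  stopifnot(theta >= 0, theta < 1, dAB >= 0, dAB < 1,
            all(scaffoldLengths >= 1), all(founderPops %in% c("A", "B")))
  if (is.null(names(scaffoldLengths)))
    names(scaffoldLengths) <- paste0("scaf", seq_along(scaffoldLengths))
  nCopies <- 2L * length(founderPops)
  copyPop <- rep(founderPops, each = 2L)
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    refs <- list()
    varList <- list()
    alleleList <- list()
    baseRaw <- charToRaw("ACGT")
    for (sc in names(scaffoldLengths)) {
      L <- scaffoldLengths[[sc]]
      refIdx <- sample.int(4L, L, replace = TRUE)
      refRaw <- baseRaw[refIdx]
      nA <- stats::rpois(1L, 2 * theta * L)
      nB <- stats::rpois(1L, 2 * theta * L)
      nD <- stats::rpois(1L, dAB * L)
      nTot <- nA + nB + nD
      if (nTot > L) stop("variant density exceeds scaffold length")
      pos <- sample.int(L, nTot)
      cls <- rep(c("polyA", "polyB", "fixed"), c(nA, nB, nD))
      o <- order(pos)
      pos <- pos[o]; cls <- cls[o]
      ref <- bases[refIdx[pos]]
      # alternate allele: uniform over the three other bases
      alt <- bases[(refIdx[pos] - 1L + sample.int(3L, nTot, TRUE)) %% 4L + 1L]
      am <- matrix(FALSE, nTot, nCopies)
      if (nTot) {
        iA <- which(cls == "polyA")
        iB <- which(cls == "polyB")
        iD <- which(cls == "fixed")
        aCols <- which(copyPop == "A")
        bCols <- which(copyPop == "B")
        if (length(iA) && length(aCols))
          am[iA, aCols] <- matrix(
            stats::runif(length(iA) * length(aCols)) < 0.5,
            length(iA), length(aCols))
        if (length(iB) && length(bCols))
          am[iB, bCols] <- matrix(
            stats::runif(length(iB) * length(bCols)) < 0.5,
            length(iB), length(bCols))
        if (length(iD) && length(bCols))
          am[iD, bCols] <- TRUE
      }
      refs[[sc]] <- rawToChar(refRaw)
      varList[[sc]] <- data.frame(scaffold = rep(sc, nTot), pos = pos,
                                  ref = ref, alt = alt, class = cls,
                                  stringsAsFactors = FALSE)
      alleleList[[sc]] <- am
    }
    new("PanelPool",
        refSeqs = DNAStringSet(unlist(refs)),
        variants = do.call(rbind, c(varList, list(make.row.names = FALSE))),
        alleles = do.call(rbind, alleleList),
        founderPops = founderPops, theta = theta, dAB = dAB)
  })
}

# clip a segment table to [from, to]
clipSegments <- function(segs, from, to) {
  keep <- segs$end >= from & segs$start <= to
  s <- segs[keep, , drop = FALSE]
  s$start <- pmax(s$start, from)
  s$end <- pmin(s$end, to)
  s
}

# merge adjacent rows carrying the same copy
mergeSegments <- function(segs) {
  if (nrow(segs) <= 1L) return(segs)
  newRun <- c(TRUE, segs$copy[-1L] != segs$copy[-nrow(segs)])
  grp <- cumsum(newRun)
  data.frame(start = segs$start[newRun],
             end = tapply(segs$end, grp, max)[unique(grp)],
             copy = segs$copy[newRun], row.names = NULL)
}

#' One meiosis: recombine a parental haplotype pair into a gamete
#'
#' Crossover breakpoints are a Poisson process at `rate`/100 events per
#' Mb with no interference; the gamete starts on a uniformly chosen
#' parental haplotype and alternates at each breakpoint. Operates on a
#' single scaffold's segment tables; uses the current RNG stream.
#'
#' @param h1,h2 parental haplotype segment data.frames
#'   (`start`, `end`, `copy`) tiling `1..L`.
#' @param L scaffold length in bp.
#' @param rate recombination rate in cM/Mb (default 1.1); must be > 0
#'   (use a value like 1e-12 for the no-crossover limit).
#' @return gamete segment data.frame; breakpoint positions are attached
#'   as attribute `breakpoints`.
#' @export
meiosisGamete <- function(h1, h2, L, rate = 1.1) {
  stopifnot(rate > 0)
  src <- sample.int(2L, 1L)
  n <- stats::rpois(1L, rate / 100 * L / 1e6)
  bps <- if (n > 0) sort(unique(ceiling(stats::runif(n) * (L - 1L))))
         else integer(0)
  bounds <- c(0, bps, L)
  parents <- list(h1, h2)
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    pieces[[i]] <- clipSegments(parents[[src]], bounds[i] + 1L, bounds[i + 1L])
    src <- 3L - src
  }
  out <- mergeSegments(do.call(rbind, pieces))
  attr(out, "breakpoints") <- bps
  out
}

#' Simulate haplotype descent through a pedigree
#'
#' Founders receive intact haplotype copies (copy 2i-1 and 2i for the
#' i-th founder); each mating draws one gamete from each parent by
#' [meiosisGamete()] per scaffold. Deterministic given the seed. No new
#' mutations arise during propagation: all variation is founder-derived.
#'
#' @param pedigree a [PedigreeSpec-class].
#' @param scaffoldLengths named numeric of scaffold lengths (bp).
#' @param rate recombination rate in cM/Mb (default 1.1).
#' @param seed integer seed.
#' @return a [PedigreeSim-class] holding every individual's haplotype
#'   mosaics.
#' @export
simulatePedigree <- function(pedigree, scaffoldLengths, rate = 1.1,
                             seed = 1L) {
  stopifnot(is(pedigree, "PedigreeSpec"))
  validObject(pedigree)
  if (is.null(names(scaffoldLengths)))
    names(scaffoldLengths) <- paste0("scaf", seq_along(scaffoldLengths))
  scs <- names(scaffoldLengths)
  haps <- list()
  for (i in seq_len(nrow(pedigree@founders))) {
    id <- pedigree@founders$id[i]
    haps[[id]] <- list(
      h1 = lapply(stats::setNames(scs, scs), function(sc)
        data.frame(start = 1, end = scaffoldLengths[[sc]],
                   copy = 2L * i - 1L)),
      h2 = lapply(stats::setNames(scs, scs), function(sc)
        data.frame(start = 1, end = scaffoldLengths[[sc]],
                   copy = 2L * i)))
  }
  withSeed(seed, {
    for (i in seq_len(nrow(pedigree@matings))) {
      m <- pedigree@matings[i, ]
      sire <- haps[[m$sire]]; dam <- haps[[m$dam]]
      h1 <- lapply(stats::setNames(scs, scs), function(sc)
        meiosisGamete(sire$h1[[sc]], sire$h2[[sc]],
                      scaffoldLengths[[sc]], rate))
      h2 <- lapply(stats::setNames(scs, scs), function(sc)
        meiosisGamete(dam$h1[[sc]], dam$h2[[sc]],
                      scaffoldLengths[[sc]], rate))
      haps[[m$child]] <- list(h1 = h1, h2 = h2)
    }
  })
  new("PedigreeSim", pedigree = pedigree,
      scaffoldLengths = stats::setNames(as.numeric(scaffoldLengths), scs),
      haplotypes = haps, rate = rate, seed = as.integer(seed))
}

#' Ground-truth autozygosity and ancestry of a simulated individual
#'
#' Autozygous tracts are the intervals where the two haplotypes carry the
#' same founder haplotype copy; tracts cut by a scaffold end carry
#' `truncated = TRUE` so formula-recovery analyses can exclude them (the
#' exponential tract-length law assumes unbounded chromosomes). Ancestry
#' tracts label each haplotype with the source population of its founder
#' copy.
#'
#' @param sim a [PedigreeSim-class].
#' @param id individual id (default: the pedigree's focal individual).
#' @return a [TruthTracts-class].
#' @export
truthTracts <- function(sim, id = sim@pedigree@focal) {
  hp <- sim@haplotypes[[id]]
  if (is.null(hp)) stop("individual '", id, "' not in simulation")
  pops <- sim@pedigree@founders$pop
  autoList <- list()
  ancList <- list(h1 = list(), h2 = list())
  for (sc in names(sim@scaffoldLengths)) {
    L <- sim@scaffoldLengths[[sc]]
    s1 <- hp$h1[[sc]]; s2 <- hp$h2[[sc]]
    cuts <- sort(unique(c(s1$start, s2$start, L + 1)))
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1L] - 1L
    c1 <- s1$copy[findInterval(starts, s1$start)]
    c2 <- s2$copy[findInterval(starts, s2$start)]
    runs <- trueRuns(c1 == c2)
    if (nrow(runs)) {
      gr <- GRanges(sc, IRanges::IRanges(start = starts[runs[, 1L]],
                                         end = ends[runs[, 2L]]))
      gr$truncated <- GenomicRanges::start(gr) == 1 |
        GenomicRanges::end(gr) == L
      autoList[[sc]] <- gr
    }
    for (h in c("h1", "h2")) {
      s <- hp[[h]][[sc]]
      pop <- pops[ceiling(s$copy / 2)]
      newRun <- c(TRUE, pop[-1L] != pop[-length(pop)])
      grp <- cumsum(newRun)
      gr <- GRanges(sc, IRanges::IRanges(
        start = s$start[newRun],
        end = as.numeric(tapply(s$end, grp, max)[unique(grp)])))
      gr$pop <- pop[newRun]
      ancList[[h]][[sc]] <- gr
    }
  }
  auto <- if (length(autoList))
    suppressWarnings(do.call(c, unname(autoList))) else {
      g <- GRanges(); g$truncated <- logical(0); g
    }
  new("TruthTracts", autozygous = auto,
      ancestry = list(h1 = suppressWarnings(do.call(c, unname(ancList$h1))),
                      h2 = suppressWarnings(do.call(c, unname(ancList$h2)))))
}

#' Diploid truth ancestry segmentation of a simulated individual
#'
#' Combines the two haplotype ancestry tilings into diploid labels:
#' A/A -> "A", B/B -> "B", otherwise "MIXED".
#'
#' @param truth a [TruthTracts-class].
#' @return a [GenomicRanges::GRanges] tiling the genome with a `label`
#'   metadata column.
#' @export
truthDiploidAncestry <- function(truth) {
  h1 <- truth@ancestry$h1
  h2 <- truth@ancestry$h2
  out <- list()
  for (sc in unique(as.character(GenomeInfoDb::seqnames(h1)))) {
    a <- h1[GenomeInfoDb::seqnames(h1) == sc]
    b <- h2[GenomeInfoDb::seqnames(h2) == sc]
    L <- max(GenomicRanges::end(a))
    cuts <- sort(unique(c(GenomicRanges::start(a), GenomicRanges::start(b),
                          L + 1)))
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1L] - 1L
    p1 <- a$pop[findInterval(starts, GenomicRanges::start(a))]
    p2 <- b$pop[findInterval(starts, GenomicRanges::start(b))]
    lab <- ifelse(p1 == p2, p1, "MIXED")
    newRun <- c(TRUE, lab[-1L] != lab[-length(lab)])
    grp <- cumsum(newRun)
    gr <- GRanges(sc, IRanges::IRanges(
      start = starts[newRun],
      end = as.numeric(tapply(ends, grp, max)[unique(grp)])))
    gr$label <- lab[newRun]
    out[[sc]] <- gr
  }
  suppressWarnings(do.call(c, unname(out)))
}

#' Render the IUPAC consensus genome of a simulated individual
#'
#' Copies the shared reference and substitutes, at every variant site,
#' the diploid IUPAC code implied by the founder alleles carried by the
#' individual's two haplotype mosaics. Heterozygous sites therefore never
#' fall inside truth autozygous tracts (no new mutations are simulated).
#'
#' @param sim a [PedigreeSim-class].
#' @param pool the [PanelPool-class] the pedigree founders draw from;
#'   its `founderPops` must match the pedigree founders (same order).
#' @param id individual id (default: focal).
#' @return a [DiploidGenome-class].
#' @export
renderGenome <- function(sim, pool, id = sim@pedigree@focal) {
  renderGenomes(sim, pool, id)[[1L]]
}

#' Render several simulated individuals at once
#'
#' Same as [renderGenome()] but shares the per-scaffold reference
#' decoding across individuals, which is much faster when rendering a
#' focal individual plus reference panels.
#'
#' @inheritParams renderGenome
#' @param ids character vector of individual ids.
#' @return named list of [DiploidGenome-class] objects.
#' @export
renderGenomes <- function(sim, pool, ids) {
  stopifnot(is(pool, "PanelPool"))
  nFounders <- nrow(sim@pedigree@founders)
  if (length(pool@founderPops) < nFounders ||
      !identical(pool@founderPops[seq_len(nFounders)],
                 sim@pedigree@founders$pop))
    stop("pool founder populations do not match the pedigree founders")
  missing <- setdiff(ids, names(sim@haplotypes))
  if (length(missing))
    stop("individual '", missing[1L], "' not in simulation")
  scs <- names(sim@scaffoldLengths)
  # decode the reference once; finalize each genome before the next so
  # per-individual character buffers never accumulate
  refRawList <- lapply(stats::setNames(scs, scs), function(sc)
    charToRaw(as.character(pool@refSeqs[[sc]])))
  rowsList <- lapply(stats::setNames(scs, scs), function(sc)
    which(pool@variants$scaffold == sc))
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    hp <- sim@haplotypes[[id]]
    seqs <- list()
    for (sc in scs) {
      rows <- rowsList[[sc]]
      raw <- refRawList[[sc]]
      if (length(rows)) {
        v <- pool@variants[rows, ]
        baseAt <- function(segs) {
          copyIdx <- segs$copy[findInterval(v$pos, segs$start)]
          alt <- pool@alleles[cbind(rows, copyIdx)]
          ifelse(alt, v$alt, v$ref)
        }
        b1 <- baseAt(hp$h1[[sc]])
        b2 <- baseAt(hp$h2[[sc]])
        raw[v$pos] <- charToRaw(paste(iupacFromPair(b1, b2),
                                      collapse = ""))
      }
      seqs[[sc]] <- rawToChar(raw)
    }
    out[[id]] <- DiploidGenome(unlist(seqs), individualId = id)
  }
  out
}

#' Funnel pedigree with every inbreeding-loop ancestor g generations back
#'
#' Builds a pedigree in which every ancestral path from the focal
#' individual to the top generation has length exactly g, so every
#' autozygous tract has survived 2g meioses and the 100/(2rg) Mb
#' tract-length law applies. The top generation is a pool of `poolSize`
#' founders shared between the maternal and paternal sides and reused
#' round-robin across the 2^(g-1) ancestor slots per side. Expected
#' autozygous genome fraction is 1/(2*poolSize). When poolSize equals
#' the slots per side, no founder repeats within a side, intermediate
#' individuals are outbred, and tract lengths are unbiased exponential;
#' smaller pools make tracts denser at deep g at the cost of a mild
#' upward length bias from crossovers inside autozygous intermediates.
#'
#' @param g generations back to the loop ancestors (>= 1; g = 1 is
#'   selfing).
#' @param poolSize founders in the shared pool; default
#'   `min(2^(g-1), 8)`.
#' @param founderPops populations of the pool founders; default all "A".
#' @return a [PedigreeSpec-class] with focal individual "focal".
#' @export
funnelPedigree <- function(g, poolSize = min(2^(g - 1), 8),
                           founderPops = rep("A", poolSize)) {
  stopifnot(g >= 1, poolSize >= 1, length(founderPops) == poolSize)
  founders <- data.frame(id = paste0("C", seq_len(poolSize)),
                         pop = founderPops, stringsAsFactors = FALSE)
  slots <- 2^(g - 1)
  sideIds <- function(side) {
    # ids by level: level g = founders (round-robin), level 1 = parent
    lev <- vector("list", g)
    lev[[g]] <- founders$id[(seq_len(slots) - 1L) %% poolSize + 1L]
    if (g > 1L) for (l in (g - 1L):1L)
      lev[[l]] <- paste0(side, "L", l, "_", seq_len(2^(l - 1L)))
    lev
  }
  matings <- list()
  for (side in c("m", "p")) {
    lev <- sideIds(side)
    if (g > 1L) for (l in (g - 1L):1L) {
      for (k in seq_len(2^(l - 1L))) {
        matings[[length(matings) + 1L]] <- data.frame(
          sire = lev[[l + 1L]][2L * k - 1L],
          dam = lev[[l + 1L]][2L * k],
          child = lev[[l]][k], stringsAsFactors = FALSE)
      }
    }
  }
  topM <- sideIds("m")[[1L]][1L]
  topP <- sideIds("p")[[1L]][1L]
  matings[[length(matings) + 1L]] <- data.frame(
    sire = topP, dam = topM, child = "focal", stringsAsFactors = FALSE)
  PedigreeSpec(founders, do.call(rbind, matings), focal = "focal")
}

#' Simulate a named inbreeding/admixture scenario with ground truth
#'
#' `isolated_inbred` emulates ongoing inbreeding in a small closed
#' population: a [funnelPedigree()] whose loop ancestors sit g
#' generations back, all from population A. `admixed_inbred` emulates an
#' admixed inbred individual: the same funnel, but one founder of the
#' pool is from population B, so the admixture event coincides with the
#' loop depth and autozygous tracts can be of either pure ancestry —
#' never mixed. Extra unrelated founders (never mated) are carried per
#' population as reference panels for diagnostic-site selection.
#'
#' @param name "isolated_inbred" or "admixed_inbred".
#' @param g generations back to the loop (and, for admixed_inbred, the
#'   admixture event); default 3.
#' @param scaffoldLengths named numeric of scaffold lengths (bp).
#' @param seed integer seed.
#' @param theta,dAB variant densities, see [simulatePanels()].
#' @param rate recombination rate in cM/Mb (default 1.1).
#' @param poolSize loop founder pool size (default `min(2^(g-1), 8)`).
#' @param nPanel unrelated panel individuals rendered per population
#'   (default 4; only with `render = TRUE`).
#' @param render if FALSE, skip sequence simulation entirely and return
#'   ground truth only (fast; used for tract-length studies).
#' @param outDir optional directory: writes `focal.fa`, panel FASTAs,
#'   `truth_roh.bed`, `truth_ancestry_hap1/2.bed` and `scenario.yaml`.
#' @return list with `sim`, `truth`, `pedigree`, and when rendered
#'   `genome`, `pool`, `panels` (named list of panel
#'   [DiploidGenome-class]s); plus `params` echoing the configuration.
#' @export
simulateScenario <- function(name = c("isolated_inbred", "admixed_inbred"),
                             g = 3, scaffoldLengths = c(scaf1 = 5e7),
                             seed = 1L, theta = 1e-3, dAB = 1e-4,
                             rate = 1.1, poolSize = min(2^(g - 1), 8),
                             nPanel = 4L, render = TRUE, outDir = NULL) {
  name <- match.arg(name)
  loopPops <- rep("A", poolSize)
  if (name == "admixed_inbred") loopPops[1L] <- "B"
  ped <- funnelPedigree(g, poolSize, loopPops)
  panelIds <- character(0)
  if (render && nPanel > 0L) {
    panelIds <- c(paste0("PA", seq_len(nPanel)), paste0("PB", seq_len(nPanel)))
    ped <- PedigreeSpec(
      rbind(ped@founders,
            data.frame(id = panelIds, pop = rep(c("A", "B"), each = nPanel),
                       stringsAsFactors = FALSE)),
      ped@matings, ped@focal)
  }
  sim <- simulatePedigree(ped, scaffoldLengths, rate = rate, seed = seed)
  truth <- truthTracts(sim)
  out <- list(sim = sim, truth = truth, pedigree = ped,
              params = list(scenario = name, g = g, seed = seed,
                            theta = theta, dAB = dAB, rate = rate,
                            poolSize = poolSize,
                            scaffoldLengths = as.list(scaffoldLengths)))
  if (render) {
    pool <- simulatePanels(scaffoldLengths, ped@founders$pop,
                           theta = theta, dAB = dAB, seed = seed + 104729L)
    rendered <- renderGenomes(sim, pool, c(ped@focal, panelIds))
    out$pool <- pool
    out$genome <- rendered[[ped@focal]]
    out$panels <- rendered[panelIds]
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeBed(autozygousTracts(truth), file.path(outDir, "truth_roh.bed"))
    writeBed(ancestryTracts(truth)$h1,
             file.path(outDir, "truth_ancestry_hap1.bed"), nameCol = "pop")
    writeBed(ancestryTracts(truth)$h2,
             file.path(outDir, "truth_ancestry_hap2.bed"), nameCol = "pop")
    if (render) {
      writeIupacFasta(out$genome, file.path(outDir, "focal.fa"))
      for (id in names(out$panels))
        writeIupacFasta(out$panels[[id]],
                        file.path(outDir, paste0("panel_", id, ".fa")))
    }
    yaml::write_yaml(out$params, file.path(outDir, "scenario.yaml"))
  }
  out
}
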