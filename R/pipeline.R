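# End-to-end orchestration: simulate -> het -> roh call -> date -> ibd ->
# ancestry, with a single config echoed into every output directory.

#' Build a pipeline configuration
#'
#' Defaults follow the analysis constants: r = 1.1 cM/Mb, 2 Mb minimum
#' ROH length, generation-derived histogram bins, mitochondrial clock
#' 1.15%/Myr.
#'
#' @param scenario "isolated_inbred" or "admixed_inbred".
#' @param g loop depth in generations.
#' @param scaffoldLengths named numeric, bp per scaffold.
#' @param seed integer seed.
#' @param windowSize het window size in bp.
#' @param rate recombination rate, cM/Mb.
#' @param minLength minimum ROH length, bp.
#' @param binsMb ROH histogram bin edges, Mb.
#' @param epsilon,tau ancestry HMM parameters, see [ancestryParams()].
#' @param clockRate mitochondrial clock, fraction diverged per Myr.
#' @param theta,dAB simulator variant densities.
#' @return a named list (class `pipelineConfig`).
#' @export
pipelineConfig <- function(scenario = "isolated_inbred", g = 3,
                           scaffoldLengths = c(scaf1 = 2.5e7,
                                               scaf2 = 2.5e7),
                           seed = 1L, windowSize = 1e5, rate = 1.1,
                           minLength = 2e6,
                           binsMb = c(2, 5.7, 9.1, 15.2, Inf),
                           epsilon = 0.01, tau = 8.8e-8,
                           clockRate = 0.0115, theta = 1e-3, dAB = 1e-4) {
  stopifnot(windowSize > 0, rate > 0, minLength > 0, epsilon > 0,
            tau > 0, clockRate > 0, all(scaffoldLengths > 0))
  structure(list(scenario = scenario, g = g,
                 scaffoldLengths = scaffoldLengths, seed = seed,
                 windowSize = windowSize, rate = rate,
                 minLength = minLength, binsMb = binsMb,
                 epsilon = epsilon, tau = tau, clockRate = clockRate,
                 theta = theta, dAB = dAB),
            class = "pipelineConfig")
}

#' Run the simulation-to-ancestry pipeline
#'
#' Stages run in dependency order: `simulate` (scenario with ground
#' truth), `het` (window track), `roh` (HMM fit, decode, tract calls),
#' `date` (F_ROH and length-class summary), and for the admixed scenario
#' `ancestry` (diagnostic sites, decoding, per-ROH labels). Each output
#' directory receives the config echo (`config.yaml`); progress lines go
#' to stderr, results only to files. Re-running with the same config is
#' byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created).
#' @param stages character subset of
#'   `c("simulate","het","roh","date","ancestry")`; stages whose inputs
#'   are missing raise an error naming the stage.
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("simulate", "het", "roh", "date",
                                   "ancestry")) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  note <- function(...) message("[autozyg] ", ...)
  if ("simulate" %in% stages) {
    note("simulate: ", config$scenario, " g=", config$g)
    res$scenario <- simulateScenario(
      config$scenario, g = config$g,
      scaffoldLengths = config$scaffoldLengths, seed = config$seed,
      theta = config$theta, dAB = config$dAB, rate = config$rate,
      outDir = file.path(outDir, "simulate"))
  }
  if ("het" %in% stages) {
    if (is.null(res$scenario))
      stop("stage 'het' requires stage 'simulate' output")
    note("het: window size ", config$windowSize)
    res$track <- windowHet(res$scenario$genome,
                           windowSize = config$windowSize)
    writeHetTrack(res$track, file.path(outDir, "het_windows.tsv"))
  }
  if ("roh" %in% stages) {
    if (is.null(res$track))
      stop("stage 'roh' requires stage 'het' output")
    note("roh: fitting HMM")
    res$params <- fitRohHmm(res$track)
    res$decoded <- decodeRoh(res$track, res$params)
    res$callset <- extractTracts(
      res$decoded, individualId = individualId(res$track),
      minLength = config$minLength)
    writeBed(tracts(res$callset), file.path(outDir, "roh_calls.bed"))
    yaml::write_yaml(
      list(lambdaIn = res$params@lambdaIn,
           lambdaOut = res$params@lambdaOut,
           transMat = as.list(as.data.frame(res$params@transMat)),
           initProb = res$params@initProb),
      file.path(outDir, "roh_params.yaml"))
  }
  if ("date" %in% stages) {
    if (is.null(res$callset))
      stop("stage 'date' requires stage 'roh' output")
    note("date: summarising tracts")
    res$summary <- summarizeRoh(res$callset,
                                sum(config$scaffoldLengths),
                                binsMb = config$binsMb, r = config$rate)
    writeRohSummary(res$summary, file.path(outDir, "roh_summary.tsv"))
  }
  if ("ancestry" %in% stages && config$scenario == "admixed_inbred") {
    if (is.null(res$scenario) || is.null(res$callset))
      stop("stage 'ancestry' requires stages 'simulate' and 'roh'")
    note("ancestry: decoding diagnostic sites")
    pn <- res$scenario$panels
    isA <- grepl("^PA", names(pn))
    sites <- selectDiagnosticSites(pn[isA], pn[!isA])
    res$ancestry <- decodeAncestry(
      res$scenario$genome, sites,
      ancestryParams(config$epsilon, config$tau))
    writeBed(segments(res$ancestry),
             file.path(outDir, "ancestry_segments.bed"),
             nameCol = "label")
    labels <- classifyRohAncestry(res$callset, res$ancestry)
    utils::write.table(
      data.frame(tract = names(labels), label = unname(labels)),
      file.path(outDir, "roh_ancestry.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.function,
                                           TRUE)],
                   file.path(outDir, "config.yaml"))
  invisible(res)
}
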