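#' Run the full candidate-gene discovery pipeline
#'
#' Orchestrates one seeded end-to-end run: simulate (or accept) a study,
#' filter variant calls to homozygous group differences, annotate the
#' survivors, summarize the substitution spectrum, test differential
#' expression, test pathway enrichment, compute relative expression from
#' the Ct table, and intersect nonsynonymous-SNP genes with DEGs into the
#' candidate list.  Every filter logs its input, per-criterion removal and
#' output counts.
#'
#' @param config a [SimulationConfig-class]; ignored when `study` is
#'   supplied.
#' @param study optional pre-built [MutantStudy-class].
#' @param outdir optional directory; when given, all study inputs and all
#'   stage outputs are written there as plain-text files and their MD5
#'   digests recorded in the manifest.
#' @param minDepthExclusive,requiredReplicates,flank,fdrThreshold,lfcThreshold,alpha
#'   stage thresholds (defaults: depth > 10, 3 replicates, 2 kb flank,
#'   FDR < 0.001, |log2 ratio| >= 1, Q <= 0.05).
#' @param quiet suppress progress messages.
#' @return list of class `emscanRun`: `study`, `filtered`, `annotated`,
#'   `spectrum` (`NULL` with a warning when no SNP survives), `deg`,
#'   `enrichment`, `relExpression`, `candidates`, and `manifest` (config
#'   snapshot, seed, stage counts, timings, file digests, package
#'   version).
#' @export
runPipeline <- function(config = simulationConfig(), study = NULL,
                        outdir = NULL, minDepthExclusive = 10,
                        requiredReplicates = 3, flank = 2000,
                        fdrThreshold = 0.001, lfcThreshold = 1,
                        alpha = 0.05, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    stages[[name]] <<- list(elapsed = proc.time()[["elapsed"]] - t0)
    res
  }
  if (is.null(study)) {
    say("[simulate] seed %d", config@seed)
    study <- tick("simulate", simulateStudy(config))
  } else {
    config <- study@config
  }
  say("[filter-snps] %d call rows", nrow(study@calls))
  if (nrow(study@calls) > 0) {
    filtered <- tick("filter", filterHomozygousDifferences(
      study@calls, minDepthExclusive = minDepthExclusive,
      requiredReplicates = requiredReplicates))
  } else {
    filtered <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           wtGenotype = character(),
                           mutantGenotype = character(),
                           wtMeanDepth = numeric(),
                           mutantMeanDepth = numeric(),
                           stringsAsFactors = FALSE)
    attr(filtered, "log") <- list(
      input = 0L, removed_depth_or_replicates = 0L,
      removed_heterozygous = 0L, removed_conflict = 0L,
      removed_no_group_difference = 0L, output = 0L)
  }
  flog <- attr(filtered, "log")
  stages$filter <- c(stages$filter, flog)
  say(paste0("[filter-snps] input %d; removed: depth/replicates %d, ",
             "heterozygous %d, conflict %d, shared %d; output %d"),
      flog$input, flog$removed_depth_or_replicates,
      flog$removed_heterozygous, flog$removed_conflict,
      flog$removed_no_group_difference, flog$output)
  annotated <- tick("annotate", annotateVariants(
    filtered, study@models, study@genome, flank = flank))
  spectrum <- NULL
  if (nrow(filtered) > 0) {
    spectrum <- tick("spectrum", spectrumSummary(filtered))
    say("[spectrum] %d SNPs, %.2f%% transitions", spectrum@total,
        spectrum@transitionPercent)
  } else {
    warning("no SNP survived filtering: spectrum summary skipped")
  }
  deg <- tick("dge", deTest(study@counts,
                            fdrThreshold = fdrThreshold,
                            lfcThreshold = lfcThreshold))
  nDeg <- sum(deg$isDeg)
  say("[dge] %d genes tested, %d DEGs (%d up, %d down)",
      sum(deg$tested), nDeg,
      sum(deg$isDeg & deg$direction == "up", na.rm = TRUE),
      sum(deg$isDeg & deg$direction == "down", na.rm = TRUE))
  universe <- deg$gene[deg$tested]
  pathways <- S4Vectors::metadata(study@counts)$pathways
  pathways <- pathways[pathways$gene %in% universe, , drop = FALSE]
  enrichment <- if (nDeg > 0) {
    tick("enrich", enrich(deg$gene[deg$isDeg], pathways, universe,
                          alpha = alpha))
  } else {
    suppressWarnings(enrich(character(0), pathways, universe))
  }
  relExpression <- tick("ddct", ddct(study@ct))
  candidates <- tick("candidates", selectCandidates(annotated, deg))
  csum <- attr(candidates, "summary")
  say("[candidates] %d gene(s): %d up, %d down", csum$total, csum$up,
      csum$down)
  manifest <- list(
    tool = "emscan",
    version = as.character(packageVersion("emscan")),
    seed = config@seed,
    config = .configAsList(config),
    thresholds = list(minDepthExclusive = minDepthExclusive,
                      requiredReplicates = requiredReplicates,
                      flank = flank, fdrThreshold = fdrThreshold,
                      lfcThreshold = lfcThreshold, alpha = alpha),
    stages = stages,
    counts = list(truthRecords = nrow(study@truth),
                  callRows = nrow(study@calls),
                  filteredSnps = nrow(filtered),
                  degs = nDeg,
                  significantPathways = sum(enrichment$significant),
                  candidates = csum$total))
  run <- list(study = study, filtered = filtered, annotated = annotated,
              spectrum = spectrum, deg = deg, enrichment = enrichment,
              relExpression = relExpression, candidates = candidates,
              manifest = manifest)
  class(run) <- "emscanRun"
  if (!is.null(outdir)) {
    paths <- writeStudy(study, outdir)
    extra <- c(filtered = file.path(outdir, "filtered_snps.tsv"),
               annotated = file.path(outdir, "annotated_snps.tsv"),
               deg = file.path(outdir, "deg.tsv"),
               enrichment = file.path(outdir, "enrichment.tsv"),
               relExpression = file.path(outdir, "rel_expression.tsv"),
               candidates = file.path(outdir, "candidates.tsv"))
    .writeTsv(filtered, extra["filtered"])
    .writeTsv(annotated, extra["annotated"])
    .writeTsv(deg, extra["deg"])
    .writeTsv(enrichment, extra["enrichment"])
    .writeTsv(relExpression, extra["relExpression"])
    .writeTsv(candidates, extra["candidates"])
    if (!is.null(spectrum))
      .writeTsv(spectrumTable(spectrum),
                file.path(outdir, "spectrum.tsv"))
    all <- c(paths, extra)
    run$manifest$digests <- setNames(
      unname(tools::md5sum(all[file.exists(all)])),
      names(all)[file.exists(all)])
  }
  run
}

.configAsList <- function(config) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  vals$emsSpectrum <- as.list(vals$emsSpectrum)
  vals
}

#' Text report of a pipeline run
#'
#' Summarizes a [runPipeline()] result the way a mutant-screen results
#' section would: filter reduction, spectrum percentages and Ts/Tv fold
#' (truncated reporting mode), effect-class counts, DEG and enrichment
#' counts, and the candidate list.
#'
#' @param run an `emscanRun` list from [runPipeline()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
pipelineReport <- function(run) {
  stopifnot(inherits(run, "emscanRun"))
  m <- run$manifest
  lines <- c(
    sprintf("emscan run (seed %d)", m$seed),
    sprintf("SNP filter: %d loci -> %d homozygous group differences",
            m$stages$filter$input, m$counts$filteredSnps))
  if (!is.null(run$spectrum)) {
    s <- run$spectrum
    lines <- c(lines, sprintf(
      "Spectrum: %d transitions (%.2f%%), %d transversions (%.2f%%), Ts/Tv %.2f-fold",
      s@transitions, s@transitionPercent, s@transversions,
      s@transversionPercent, tsTvFold(s)))
  }
  eff <- effectClassCounts(run$annotated)$effect
  lines <- c(lines, sprintf(
    "Effects: %d nonsynonymous, %d stop-gain, %d synonymous (of %d)",
    eff[["nonsynonymous"]], eff[["stop_gain"]], eff[["synonymous"]],
    sum(eff)))
  lines <- c(lines, sprintf(
    "DEGs: %d (FDR < %g, |log2 ratio| >= %g)", m$counts$degs,
    m$thresholds$fdrThreshold, m$thresholds$lfcThreshold))
  sig <- run$enrichment[run$enrichment$significant, , drop = FALSE]
  if (nrow(sig) > 0)
    lines <- c(lines, sprintf(
      "Enriched: %s",
      paste(sprintf("%s (k=%d, %.2f%% of DEGs, Q=%.3g)", sig$pathway,
                    sig$k, sig$percentOfDegs, sig$q), collapse = "; ")))
  csum <- attr(run$candidates, "summary")
  lines <- c(lines, sprintf(
    "Candidates: %d gene(s) (%d up, %d down)%s", csum$total, csum$up,
    csum$down,
    if (csum$total > 0)
      paste0(": ", paste(unique(run$candidates$gene), collapse = ", "))
    else ""))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.emscanRun <- function(x, ...) {
  cat(sprintf(
    "emscanRun: %d filtered SNPs, %d DEGs, %d candidate gene(s)\n",
    x$manifest$counts$filteredSnps, x$manifest$counts$degs,
    x$manifest$counts$candidates))
  invisible(x)
}
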