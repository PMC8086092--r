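#' Default EMS substitution spectrum
#'
#' EMS alkylates guanine, producing predominantly G:C to A:T transitions;
#' recorded on the forward reference strand this puts most probability
#' mass on C>T and G>A.  The default places 0.45 on each, 0.025 on each of
#' the reverse transitions (A>G, T>C), and splits the remaining 0.05
#' evenly over the eight transversions.
#'
#' @return named numeric vector over the 12 ordered substitution types,
#'   summing to 1.
#' @export
defaultEmsSpectrum <- function() {
  sp <- setNames(rep(0.05 / 8, 12), .subTypes())
  sp["C>T"] <- 0.45
  sp["G>A"] <- 0.45
  sp["A>G"] <- 0.025
  sp["T>C"] <- 0.025
  sp
}

#' Configure a synthetic EMS-mutant study
#'
#' Builds a validated [SimulationConfig-class].  Defaults encode the study
#' design the generator emulates: two groups of three biological
#' replicates, a strongly C>T/G>A-biased mutation spectrum, shared
#' background polymorphisms that both groups carry homozygously,
#' low-depth and heterozygous nuisance calls, one causal homozygous
#' nonsynonymous SNP in a gene that is also differentially expressed
#' (downregulated by default), and a co-downregulated pathway gene set of
#' 16 genes.
#'
#' @param seed integer RNG seed; a fixed seed makes every generated
#'   artifact byte-identical across runs.
#' @param nChromosomes,chromLength genome shape (default 2 x 100 kb).
#' @param nGenes number of protein-coding genes (default 60).
#' @param exonsPerGene inclusive range of exon counts per gene
#'   (default 1-3).
#' @param nTrueMutations planted mutant-line mutations, causal included
#'   (default 40).
#' @param emsSpectrum named substitution-type probabilities summing to 1;
#'   see [defaultEmsSpectrum()].
#' @param nBackgroundSnps cultivar-vs-reference polymorphisms present
#'   homozygously in both groups (default 30).
#' @param replicatesPerGroup biological replicates per group (default 3).
#' @param meanDepth mean site read depth (default 50).
#' @param depthDispersion negative-binomial size parameter of the depth
#'   distribution (default 25; smaller means more overdispersed).
#' @param genotypeErrorRate probability that a locus receives one
#'   corrupted genotype call (a randomly chosen replicate set to
#'   heterozygous or missing); default 0.02.
#' @param nDeGenes genes with a planted expression shift, including the
#'   causal gene and the pathway set (default 20).
#' @param lfcEffect planted |log2 fold change| (default 2).
#' @param nbDispersion negative-binomial dispersion of counts around the
#'   per-gene mean (default 0.001, near-Poisson; see the vignette for why
#'   the default sits at the low-variability end).
#' @param pathwaySize size of the co-downregulated pathway gene set
#'   (default 16).
#' @param causalEffectDirection direction of the causal gene's expression
#'   shift, `"down"` (default) or `"up"`.
#' @param nLowDepthLoci,nHetLoci nuisance loci: mutant-discriminating
#'   calls at very low depth, and heterozygous calls (default 15 each).
#' @param ctNoiseSd Gaussian noise SD on simulated Ct values (default
#'   0.1 cycles).
#' @param ctReplicates qPCR replicates per condition (default 3).
#' @param ctTrueRatios true relative-expression ratios of the simulated
#'   qPCR targets (default 0.25, 0.5, 1, 2).
#' @return a validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 2L,
                             chromLength = 100000L,
                             nGenes = 60L,
                             exonsPerGene = c(1L, 3L),
                             nTrueMutations = 40L,
                             emsSpectrum = defaultEmsSpectrum(),
                             nBackgroundSnps = 30L,
                             replicatesPerGroup = 3L,
                             meanDepth = 50,
                             depthDispersion = 25,
                             genotypeErrorRate = 0.02,
                             nDeGenes = 20L,
                             lfcEffect = 2,
                             nbDispersion = 0.001,
                             pathwaySize = 16L,
                             causalEffectDirection = "down",
                             nLowDepthLoci = 15L,
                             nHetLoci = 15L,
                             ctNoiseSd = 0.1,
                             ctReplicates = 3L,
                             ctTrueRatios = c(0.25, 0.5, 1, 2)) {
  new("SimulationConfig",
      seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene),
      nTrueMutations = as.integer(nTrueMutations),
      emsSpectrum = emsSpectrum,
      nBackgroundSnps = as.integer(nBackgroundSnps),
      replicatesPerGroup = as.integer(replicatesPerGroup),
      meanDepth = meanDepth, depthDispersion = depthDispersion,
      genotypeErrorRate = genotypeErrorRate,
      nDeGenes = as.integer(nDeGenes), lfcEffect = lfcEffect,
      nbDispersion = nbDispersion, pathwaySize = as.integer(pathwaySize),
      causalEffectDirection = causalEffectDirection,
      nLowDepthLoci = as.integer(nLowDepthLoci),
      nHetLoci = as.integer(nHetLoci),
      ctNoiseSd = ctNoiseSd, ctReplicates = as.integer(ctReplicates),
      ctTrueRatios = ctTrueRatios)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  seed %d; genome %d x %d bp; %d genes\n",
              object@seed, object@nChromosomes, object@chromLength,
              object@nGenes))
  cat(sprintf("  %d EMS mutations (C>T+G>A mass %.2f), %d background SNPs\n",
              object@nTrueMutations,
              sum(object@emsSpectrum[c("C>T", "G>A")], na.rm = TRUE),
              object@nBackgroundSnps))
  cat(sprintf("  %d vs %d replicates, depth NB(mu=%g, size=%g), genotype error %g\n",
              object@replicatesPerGroup, object@replicatesPerGroup,
              object@meanDepth, object@depthDispersion,
              object@genotypeErrorRate))
  cat(sprintf("  %d DE genes at |lfc| %g (pathway set %d, causal %s)\n",
              object@nDeGenes, object@lfcEffect, object@pathwaySize,
              object@causalEffectDirection))
})

#' Read / write a simulation configuration
#'
#' The configuration is stored as a flat YAML mapping keyed by the
#' [simulationConfig()] argument names.
#'
#' @param path file path.
#' @return `readSimulationConfig` returns a [SimulationConfig-class];
#'   `writeSimulationConfig` returns `path` invisibly.
#' @export
readSimulationConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if ("emsSpectrum" %in% names(vals))
    vals$emsSpectrum <- unlist(vals$emsSpectrum)
  do.call(simulationConfig, vals)
}

#' @rdname readSimulationConfig
#' @param config a [SimulationConfig-class] object.
#' @export
writeSimulationConfig <- function(config, path) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  vals$emsSpectrum <- as.list(vals$emsSpectrum)
  yaml::write_yaml(vals, path)
  invisible(path)
}

.SENSE_CODONS <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
.STOP_CODONS <- names(GENETIC_CODE)[GENETIC_CODE == "*"]

#' Simulate a reference genome and gene models
#'
#' Generates `nChromosomes` random chromosomes and places
#' non-overlapping, stranded protein-coding genes on them (round-robin
#' across chromosomes, alternating strands within a chromosome, so both
#' strands are represented).  Every CDS starts with ATG, ends with a stop
#' codon, contains no internal stop, and has length divisible by three;
#' exon intervals equal CDS intervals (UTRs are not modelled).
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genome` (a `DNAStringSet` named by chromosome) and
#'   `models` (a [GeneModels-class]).
#' @export
simulateReference <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  nChrom <- config@nChromosomes
  L <- config@chromLength
  chromNames <- sprintf("chr%02d", seq_len(nChrom))
  chromChars <- lapply(seq_len(nChrom), function(i)
    sample(.BASES, L, replace = TRUE))
  geneRows <- vector("list", config@nGenes)
  exonList <- list()
  cdsList <- list()
  if (config@nGenes > 0) {
    chromOf <- rep(seq_len(nChrom), length.out = config@nGenes)
    cursors <- rep(NA_integer_, nChrom)
    perChromCount <- integer(nChrom)
    for (g in seq_len(config@nGenes)) {
      ci <- chromOf[g]
      perChromCount[ci] <- perChromCount[ci] + 1L
      if (is.na(cursors[ci])) cursors[ci] <- sample(100:300, 1)
      nCod <- sample(50:150, 1)
      coding <- c("ATG",
                  sample(.SENSE_CODONS, nCod - 2L, replace = TRUE),
                  sample(.STOP_CODONS, 1))
      codingSeq <- paste0(coding, collapse = "")
      Lc <- 3L * nCod
      k <- sample(seq(config@exonsPerGene[1], config@exonsPerGene[2]), 1)
      if (k > 1) {
        widths <- 10L + as.integer(
          rmultinom(1, Lc - 10L * k, rep(1, k)))
      } else {
        widths <- Lc
      }
      introns <- if (k > 1) sample(50:200, k - 1, replace = TRUE)
        else integer(0)
      span <- Lc + sum(introns)
      startPos <- cursors[ci]
      if (startPos + span + 100L > L)
        stop(sprintf(
          "requested genes do not fit: gene %d needs %d bp beyond position %d on %s (chromLength %d)",
          g, span, startPos, chromNames[ci], L))
      strandChar <- if (perChromCount[ci] %% 2L == 1L) "+" else "-"
      exStarts <- startPos + cumsum(c(0L, head(widths, -1) + introns))
      exEnds <- exStarts + widths - 1L
      placed <- if (strandChar == "+") codingSeq else
        as.character(reverseComplement(DNAString(codingSeq)))
      placedChars <- strsplit(placed, "")[[1]]
      ofs <- cumsum(c(0L, head(widths, -1)))
      for (j in seq_len(k)) {
        chromChars[[ci]][exStarts[j]:exEnds[j]] <-
          placedChars[(ofs[j] + 1L):(ofs[j] + widths[j])]
      }
      gid <- sprintf("gene%03d", g)
      geneRows[[g]] <- data.frame(
        chrom = chromNames[ci], start = exStarts[1],
        end = exEnds[k], strand = strandChar, gene_id = gid,
        stringsAsFactors = FALSE)
      gr <- GRanges(chromNames[ci], IRanges(exStarts, exEnds),
                    strand = strandChar)
      exonList[[gid]] <- gr
      cdsList[[gid]] <- gr
      cursors[ci] <- exEnds[k] + sample(200:1000, 1)
    }
  }
  genome <- DNAStringSet(vapply(chromChars, paste0, character(1),
                                collapse = ""))
  names(genome) <- chromNames
  if (config@nGenes > 0) {
    tab <- do.call(rbind, geneRows)
    ord <- order(tab$chrom, tab$start)
    tab <- tab[ord, ]
    genes <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                     strand = tab$strand)
    genes$gene_id <- tab$gene_id
    models <- GeneModels(genes,
                         GRangesList(exonList[tab$gene_id]),
                         GRangesList(cdsList[tab$gene_id]))
  } else {
    models <- GeneModels()
  }
  list(genome = genome, models = models)
}

## sample a substitution type name from a spectrum
.sampleType <- function(spectrum, n = 1) {
  sample(names(spectrum), n, replace = TRUE, prob = spectrum)
}

#' Plant mutant-line mutations into a reference
#'
#' Draws `nTrueMutations` single-base substitutions from the EMS spectrum
#' at genome positions whose reference base matches each substitution's
#' source base.  Exactly one mutation is flagged causal: it is placed
#' inside the CDS of a randomly chosen gene such that the codon change is
#' nonsynonymous.  `nBackgroundSnps` shared polymorphisms (homozygous
#' alternate in both groups, uniform substitution types) are appended.
#' Every record is annotated with its true region and coding effect.
#'
#' @param genome `DNAStringSet` from [simulateReference()].
#' @param models the matching [GeneModels-class].
#' @param config a [SimulationConfig-class].
#' @return data.frame of truth records: `chrom`, `pos`, `ref`, `alt`,
#'   `region`, `geneId`, `codingEffect`, `causal`, `wtZygosity`,
#'   `mutantZygosity`, `class` (`ems` or `background`).
#' @export
plantMutations <- function(genome, models, config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed + 1L)
  chromNames <- names(genome)
  chromChars <- lapply(chromNames, function(cn)
    strsplit(as.character(genome[[cn]]), "")[[1]])
  names(chromChars) <- chromNames
  ## global position pools per source base
  pool <- list()
  for (b in .BASES) {
    hits <- lapply(chromNames, function(cn)
      which(chromChars[[cn]] == b))
    pool[[b]] <- data.frame(
      chrom = rep(chromNames, lengths(hits)),
      pos = unlist(hits), stringsAsFactors = FALSE)
  }
  used <- new.env(parent = emptyenv())
  takePos <- function(srcBase) {
    p <- pool[[srcBase]]
    if (nrow(p) == 0)
      stop(sprintf(
        "spectrum requires source base '%s' absent from the genome",
        srcBase))
    for (try in 1:1000) {
      i <- sample.int(nrow(p), 1)
      k <- paste0(p$chrom[i], ":", p$pos[i])
      if (is.null(used[[k]])) {
        used[[k]] <- TRUE
        return(p[i, ])
      }
    }
    stop("could not find an unused position; genome too saturated")
  }
  rows <- list()
  nEms <- config@nTrueMutations
  if (nEms > 0) {
    if (length(models) == 0)
      stop("cannot place a causal CDS mutation without gene models")
    ## causal mutation first: a nonsynonymous CDS change drawn from the
    ## spectrum
    candGenes <- geneIds(models)[cdsLengths(models) >= 150]
    causalGene <- sample(candGenes, 1)
    cds <- models@cds[[causalGene]]
    chrom <- as.character(seqnames(cds))[1]
    cdsPositions <- unlist(lapply(seq_along(cds), function(i)
      start(cds)[i]:end(cds)[i]))
    causalRow <- NULL
    for (try in 1:500) {
      type <- .sampleType(config@emsSpectrum)
      src <- substr(type, 1, 1); altB <- substr(type, 3, 3)
      hits <- cdsPositions[chromChars[[chrom]][cdsPositions] == src]
      if (length(hits) == 0) next
      pos <- if (length(hits) == 1) hits else sample(hits, 1)
      eff <- annotateCodingEffect(chrom, pos, src, altB, models, genome,
                                  geneId = causalGene)
      if (eff$codingEffect == "nonsynonymous") {
        causalRow <- data.frame(chrom = chrom, pos = pos, ref = src,
                                alt = altB, stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(causalRow)) {
      ## deterministic fallback: scan spectrum-supported substitutions
      types <- names(config@emsSpectrum)[config@emsSpectrum > 0]
      for (type in types) {
        src <- substr(type, 1, 1); altB <- substr(type, 3, 3)
        for (pos in cdsPositions[chromChars[[chrom]][cdsPositions] == src]) {
          eff <- annotateCodingEffect(chrom, pos, src, altB, models,
                                      genome, geneId = causalGene)
          if (eff$codingEffect == "nonsynonymous") {
            causalRow <- data.frame(chrom = chrom, pos = pos, ref = src,
                                    alt = altB, stringsAsFactors = FALSE)
            break
          }
        }
        if (!is.null(causalRow)) break
      }
    }
    if (is.null(causalRow))
      stop("could not place a nonsynonymous causal mutation under the configured spectrum")
    used[[paste0(causalRow$chrom, ":", causalRow$pos)]] <- TRUE
    rows[[1]] <- causalRow
    if (nEms > 1) {
      types <- .sampleType(config@emsSpectrum, nEms - 1)
      for (i in seq_len(nEms - 1)) {
        src <- substr(types[i], 1, 1); altB <- substr(types[i], 3, 3)
        p <- takePos(src)
        rows[[i + 1L]] <- data.frame(chrom = p$chrom, pos = p$pos,
                                     ref = src, alt = altB,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  ems <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  nBg <- config@nBackgroundSnps
  if (nBg > 0) {
    bgRows <- lapply(seq_len(nBg), function(i) {
      src <- sample(.BASES, 1)
      p <- takePos(src)
      data.frame(chrom = p$chrom, pos = p$pos, ref = src,
                 alt = sample(setdiff(.BASES, src), 1),
                 stringsAsFactors = FALSE)
    })
    bg <- do.call(rbind, bgRows)
  } else {
    bg <- ems[0, ]
  }
  truth <- rbind(ems, bg)
  ann <- annotateVariants(truth, models, genome)
  truth$region <- ann$region
  truth$geneId <- ann$geneId
  truth$codingEffect <- ann$codingEffect
  truth$causal <- FALSE
  if (nrow(ems) > 0) truth$causal[1] <- TRUE
  truth$wtZygosity <- c(rep("hom_ref", nrow(ems)),
                        rep("hom_alt", nrow(bg)))
  truth$mutantZygosity <- rep("hom_alt", nrow(truth))
  truth$class <- c(rep("ems", nrow(ems)), rep("background", nrow(bg)))
  ord <- order(truth$chrom, truth$pos)
  truth <- truth[ord, ]
  rownames(truth) <- NULL
  truth
}

#' Simulate per-replicate variant observations
#'
#' Expands truth records into a per-locus, per-replicate call table.
#' Depths are negative-binomial around `meanDepth`; with probability
#' `genotypeErrorRate` a locus has one randomly chosen replicate call
#' corrupted to heterozygous or missing.  Nuisance loci are appended:
#' `nLowDepthLoci` mutant-discriminating loci at very low depth (removed
#' by the depth rule) and `nHetLoci` loci heterozygous in the mutant
#' replicates (removed by the heterozygosity rule).  Calls with zero depth
#' are reported as genotype missing.
#'
#' @param truth data.frame from [plantMutations()].
#' @param config a [SimulationConfig-class].
#' @param genome optional `DNAStringSet`; when supplied, nuisance loci use
#'   real reference bases (random bases otherwise).
#' @return data.frame of calls with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `group`, `depth`, `genotype` (samples named `WT-1..n` and
#'   `ftdm-1..n`).
#' @export
simulateVariantObservations <- function(truth, config, genome = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed + 2L)
  nrep <- config@replicatesPerGroup
  samples <- c(paste0("WT-", seq_len(nrep)),
               paste0("ftdm-", seq_len(nrep)))
  groupOf <- c(rep("WT", nrep), rep("ftdm", nrep))
  usedKey <- paste0(truth$chrom, ":", truth$pos)
  randomLocus <- function() {
    if (!is.null(genome)) {
      cn <- sample(names(genome), 1)
      repeat {
        pos <- sample.int(length(genome[[cn]]), 1)
        k <- paste0(cn, ":", pos)
        if (!k %in% usedKey) break
      }
      ref <- as.character(subseq(genome[[cn]], pos, pos))
    } else {
      cn <- "chr01"
      pos <- sample.int(max(c(truth$pos, 1000L)) + 10000L, 1)
      ref <- sample(.BASES, 1)
    }
    usedKey <<- c(usedKey, paste0(cn, ":", pos))
    data.frame(chrom = cn, pos = pos, ref = ref,
               alt = sample(setdiff(.BASES, ref), 1),
               stringsAsFactors = FALSE)
  }
  lowDepth <- if (config@nLowDepthLoci > 0)
    do.call(rbind, lapply(seq_len(config@nLowDepthLoci),
                          function(i) randomLocus())) else NULL
  hetLoci <- if (config@nHetLoci > 0)
    do.call(rbind, lapply(seq_len(config@nHetLoci),
                          function(i) randomLocus())) else NULL
  locusClass <- c(rep("truth", nrow(truth)),
                  rep("lowdepth", if (is.null(lowDepth)) 0 else
                    nrow(lowDepth)),
                  rep("het", if (is.null(hetLoci)) 0 else nrow(hetLoci)))
  loci <- rbind(truth[, c("chrom", "pos", "ref", "alt")], lowDepth,
                hetLoci)
  n <- nrow(loci)
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample = character(), group = character(),
                      depth = integer(), genotype = character(),
                      stringsAsFactors = FALSE))
  trueGeno <- matrix("hom_ref", n, 2 * nrep)
  isTruth <- locusClass == "truth"
  if (any(isTruth)) {
    trueGeno[isTruth, seq_len(nrep)] <-
      rep(truth$wtZygosity, nrep)
    trueGeno[isTruth, nrep + seq_len(nrep)] <-
      rep(truth$mutantZygosity, nrep)
  }
  trueGeno[locusClass == "lowdepth", nrep + seq_len(nrep)] <- "hom_alt"
  trueGeno[locusClass == "het", nrep + seq_len(nrep)] <- "het"
  depth <- matrix(0L, n, 2 * nrep)
  normal <- locusClass != "lowdepth"
  depth[normal, ] <- rnbinom(sum(normal) * 2 * nrep,
                             mu = config@meanDepth,
                             size = config@depthDispersion)
  depth[!normal, ] <- rnbinom(sum(!normal) * 2 * nrep, mu = 4, size = 5)
  ## per-locus genotype corruption
  corrupt <- runif(n) < config@genotypeErrorRate
  for (i in which(corrupt & isTruth)) {
    j <- sample.int(2 * nrep, 1)
    trueGeno[i, j] <- sample(c("het", "missing"), 1)
  }
  trueGeno[depth == 0L] <- "missing"
  out <- data.frame(
    chrom = rep(loci$chrom, times = 2 * nrep),
    pos = rep(loci$pos, times = 2 * nrep),
    ref = rep(loci$ref, times = 2 * nrep),
    alt = rep(loci$alt, times = 2 * nrep),
    sample = rep(samples, each = n),
    group = rep(groupOf, each = n),
    depth = as.integer(depth),
    genotype = as.character(trueGeno),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$sample), ]
  rownames(out) <- NULL
  out
}

#' Simulate the gene-by-sample count matrix
#'
#' Negative-binomial counts around log-normal per-gene base means, with
#' library-size factors varying about +/-30\% across samples.  `nDeGenes`
#' genes are shifted by `lfcEffect` log2 units in the mutant group: the
#' causal gene (direction `causalEffectDirection`; its base mean is fixed
#' at 300 so that variant calling and the expression contrast both see
#' it), a coherent co-downregulated pathway set of `pathwaySize` genes,
#' and randomly signed extras.  The pathway membership table (the planted
#' pathway plus arbitrary disjoint gene sets over the remaining genes) is
#' stored in the metadata.
#'
#' @param models a [GeneModels-class].
#' @param truth data.frame from [plantMutations()] (used to identify the
#'   causal gene; may have zero rows).
#' @param config a [SimulationConfig-class].
#' @return a `SummarizedExperiment`: assay `counts`; rowData `geneLength`,
#'   `baseMean`, `isDe`, `deDirection`, `inPathway`; colData `sample`,
#'   `group`; metadata `pathways` (data.frame pathway/gene) and
#'   `deGenes`.
#' @export
simulateCounts <- function(models, truth, config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed + 3L)
  gids <- geneIds(models)
  nG <- length(gids)
  if (nG == 0) stop("no gene models to simulate counts for")
  nrep <- config@replicatesPerGroup
  samples <- c(paste0("WT-", seq_len(nrep)),
               paste0("ftdm-", seq_len(nrep)))
  groups <- c(rep("WT", nrep), rep("ftdm", nrep))
  baseMean <- rlnorm(nG, meanlog = log(200), sdlog = 1)
  names(baseMean) <- gids
  causalGene <- if (any(truth$causal)) truth$geneId[truth$causal] else
    NA_character_
  if (!is.na(causalGene)) baseMean[causalGene] <- 300
  deDir <- setNames(rep(0, nG), gids)
  pathwayGenes <- character(0)
  if (config@nDeGenes > 0) {
    pool <- setdiff(gids, causalGene)
    pathwayGenes <- sample(pool, config@pathwaySize)
    nExtra <- config@nDeGenes - config@pathwaySize -
      as.integer(!is.na(causalGene))
    extras <- sample(setdiff(pool, pathwayGenes), nExtra)
    deDir[pathwayGenes] <- -1
    deDir[extras] <- sample(c(-1, 1), nExtra, replace = TRUE)
    if (!is.na(causalGene))
      deDir[causalGene] <-
        if (config@causalEffectDirection == "down") -1 else 1
  }
  libFactor <- runif(2 * nrep, 0.7, 1.3)
  mu <- outer(baseMean, libFactor)
  mutCols <- nrep + seq_len(nrep)
  mu[, mutCols] <- mu[, mutCols] * 2^(deDir * config@lfcEffect)
  counts <- matrix(0L, nG, 2 * nrep, dimnames = list(gids, samples))
  if (config@nbDispersion > 1e-8) {
    counts[] <- rnbinom(length(mu), mu = mu,
                        size = 1 / config@nbDispersion)
  } else {
    counts[] <- rpois(length(mu), lambda = mu)
  }
  ## arbitrary disjoint gene sets over the non-pathway genes, so the
  ## enrichment stage has a full membership table to chew on
  rest <- setdiff(gids, pathwayGenes)
  restAssign <- sample(rep_len(paste0("pathway_", 2:5), length(rest)))
  pathways <- rbind(
    if (length(pathwayGenes))
      data.frame(pathway = "ga_biosynthesis", gene = pathwayGenes,
                 stringsAsFactors = FALSE),
    data.frame(pathway = restAssign, gene = rest,
               stringsAsFactors = FALSE))
  pathways <- pathways[order(pathways$pathway, pathways$gene), ]
  rownames(pathways) <- NULL
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      geneLength = unname(geneLengths(models)[gids]),
      baseMean = unname(baseMean),
      isDe = unname(deDir != 0),
      deDirection = unname(ifelse(deDir == 0, NA_character_,
                                  ifelse(deDir > 0, "up", "down"))),
      inPathway = gids %in% pathwayGenes,
      row.names = gids),
    colData = S4Vectors::DataFrame(sample = samples, group = groups,
                                   row.names = samples))
  S4Vectors::metadata(se)$pathways <- pathways
  S4Vectors::metadata(se)$deGenes <- names(deDir)[deDir != 0]
  S4Vectors::metadata(se)$causalGene <- causalGene
  se
}

#' Simulate a qPCR Ct table
#'
#' Ct values for target genes and a histone-role reference gene in
#' calibrator (wild-type) and test (mutant) samples, generated from the
#' configured true relative-expression ratios plus Gaussian noise.  True
#' ratios are stored in the `"trueRatios"` attribute for recovery tests.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns `sample`, `condition`, `target`,
#'   `targetCt`, `referenceCt`, `replicate`.
#' @export
simulateCtTable <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed + 4L)
  ratios <- config@ctTrueRatios
  targets <- if (!is.null(names(ratios)) && all(nzchar(names(ratios))))
    names(ratios) else sprintf("target_%d", seq_along(ratios))
  names(ratios) <- targets
  nrep <- config@ctReplicates
  rows <- list()
  for (tg in targets) {
    for (cond in c("calibrator", "test")) {
      shift <- if (cond == "test") -log2(ratios[[tg]]) else 0
      prefix <- if (cond == "test") "ftdm" else "WT"
      for (r in seq_len(nrep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s-%d", prefix, r),
          condition = cond, target = tg,
          targetCt = 25 + shift + rnorm(1, 0, config@ctNoiseSd),
          referenceCt = 20 + rnorm(1, 0, config@ctNoiseSd),
          replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trueRatios") <- ratios
  out
}

#' Simulate a complete study
#'
#' Runs [simulateReference()], [plantMutations()],
#' [simulateVariantObservations()], [simulateCounts()] and
#' [simulateCtTable()] under the configured seed and bundles the results.
#'
#' @param config a [SimulationConfig-class].
#' @return a [MutantStudy-class] object.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  ref <- simulateReference(config)
  truth <- if (config@nTrueMutations > 0 || config@nBackgroundSnps > 0)
    plantMutations(ref$genome, ref$models, config)
  else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), region = character(),
               geneId = character(), codingEffect = character(),
               causal = logical(), wtZygosity = character(),
               mutantZygosity = character(), class = character(),
               stringsAsFactors = FALSE)
  calls <- simulateVariantObservations(truth, config, ref$genome)
  counts <- simulateCounts(ref$models, truth, config)
  ct <- simulateCtTable(config)
  new("MutantStudy", genome = ref$genome, models = ref$models,
      truth = truth, calls = calls, counts = counts, ct = ct,
      config = config)
}

#' @rdname MutantStudy-class
#' @param x a `MutantStudy` object.
#' @export
setGeneric("studyGenome", function(x) standardGeneric("studyGenome"))

#' @rdname MutantStudy-class
#' @export
setMethod("studyGenome", "MutantStudy", function(x) x@genome)

#' @rdname MutantStudy-class
#' @export
setGeneric("studyModels", function(x) standardGeneric("studyModels"))

#' @rdname MutantStudy-class
#' @export
setMethod("studyModels", "MutantStudy", function(x) x@models)

#' @rdname MutantStudy-class
#' @export
setGeneric("truthRecords", function(x) standardGeneric("truthRecords"))

#' @rdname MutantStudy-class
#' @export
setMethod("truthRecords", "MutantStudy", function(x) x@truth)

#' @rdname MutantStudy-class
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname MutantStudy-class
#' @export
setMethod("variantCalls", "MutantStudy", function(x) x@calls)

#' @rdname MutantStudy-class
#' @export
setGeneric("countsSE", function(x) standardGeneric("countsSE"))

#' @rdname MutantStudy-class
#' @export
setMethod("countsSE", "MutantStudy", function(x) x@counts)

#' @rdname MutantStudy-class
#' @export
setGeneric("ctTable", function(x) standardGeneric("ctTable"))

#' @rdname MutantStudy-class
#' @export
setMethod("ctTable", "MutantStudy", function(x) x@ct)

#' @rdname MutantStudy-class
#' @export
setGeneric("studyConfig", function(x) standardGeneric("studyConfig"))

#' @rdname MutantStudy-class
#' @export
setMethod("studyConfig", "MutantStudy", function(x) x@config)

setMethod("show", "MutantStudy", function(object) {
  cat("MutantStudy\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp total\n",
              length(object@genome),
              format(sum(width(object@genome)), big.mark = ",")))
  cat(sprintf("  models: %d genes\n", length(object@models)))
  cat(sprintf("  truth:  %d records (%d EMS, %d background, causal gene %s)\n",
              nrow(object@truth), sum(object@truth$class == "ems"),
              sum(object@truth$class == "background"),
              if (any(object@truth$causal))
                object@truth$geneId[object@truth$causal] else "none"))
  cat(sprintf("  calls:  %d rows; counts: %d x %d; ct: %d rows\n",
              nrow(object@calls), nrow(object@counts),
              ncol(object@counts), nrow(object@ct)))
})

#' Write all study artifacts to a directory
#'
#' Writes `genome.fa` (60-column FASTA), `genes.gff3`, `calls.vcf`
#' (minimal VCF 4.2, FORMAT `GT:DP`), `counts.tsv` (gene id + one column
#' per sample), `gene_lengths.tsv`, `pathways.tsv`, `ct.tsv`,
#' `truth.tsv` and `config.yaml`.  All writers are deterministic: the
#' same study yields byte-identical files.
#'
#' @param study a [MutantStudy-class] object.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "MutantStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "calls.vcf"),
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    ct = file.path(dir, "ct.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  writeXStringSet(study@genome, paths["genome"], width = 60)
  writeGeneModels(study@models, paths["gff"])
  if (nrow(study@calls) > 0) writeVcfCalls(study@calls, paths["vcf"])
  cnt <- as.data.frame(assay(study@counts))
  cnt <- cbind(gene = rownames(cnt), cnt)
  .writeTsv(cnt, paths["counts"])
  .writeTsv(data.frame(gene = rownames(study@counts),
                       length = rowData(study@counts)$geneLength),
            paths["lengths"])
  .writeTsv(S4Vectors::metadata(study@counts)$pathways,
            paths["pathways"])
  .writeTsv(study@ct, paths["ct"])
  .writeTsv(study@truth, paths["truth"])
  writeSimulationConfig(study@config, paths["config"])
  invisible(paths)
}
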