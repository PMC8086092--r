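#' Gene models on a reference genome
#'
#' Container for stranded protein-coding gene models: a gene-level
#' \link[GenomicRanges]{GRanges} plus per-gene exon and CDS
#' \link[GenomicRanges]{GRangesList}s.  Intervals are 1-based and closed
#' (GFF3 convention).  Validity requires intervals sorted and
#' non-overlapping within a gene, matching gene identifiers across slots,
#' and a total CDS length divisible by three for every gene.
#'
#' @slot genes `GRanges` with one range per gene and a `gene_id` metadata
#'   column; strand is `+` or `-`.
#' @slot exons `GRangesList` of exon intervals, named by gene id, ascending
#'   genomic order.
#' @slot cds `GRangesList` of CDS intervals, named by gene id, ascending
#'   genomic order.
#' @seealso [GeneModels()], [readGeneModels()], [writeGeneModels()]
#' @export
setClass("GeneModels",
  slots = c(genes = "GRanges", exons = "GRangesList", cds = "GRangesList"))

setValidity("GeneModels", function(object) {
  ids <- object@genes$gene_id
  if (is.null(ids) && length(object@genes) > 0)
    return("'genes' must carry a gene_id metadata column")
  if (length(object@genes) == 0) {
    if (length(object@exons) || length(object@cds))
      return("exon/CDS lists must be empty when there are no genes")
    return(TRUE)
  }
  if (anyDuplicated(ids)) return("duplicated gene ids")
  if (!identical(names(object@exons), ids) ||
      !identical(names(object@cds), ids))
    return("exon/CDS list names must match genes$gene_id in order")
  if (!all(as.character(strand(object@genes)) %in% c("+", "-")))
    return("gene strand must be '+' or '-'")
  for (nm in c("exons", "cds")) {
    rl <- slot(object, nm)
    starts <- start(rl); ends <- end(rl)
    sorted <- all(vapply(seq_along(rl), function(i) {
      s <- starts[[i]]
      length(s) == 0 || !is.unsorted(s, strictly = TRUE)
    }, logical(1)))
    if (!sorted) return(sprintf("'%s' intervals must be sorted", nm))
    ovl <- any(vapply(seq_along(rl), function(i) {
      s <- starts[[i]]; e <- ends[[i]]
      length(s) > 1 && any(s[-1] <= e[-length(e)])
    }, logical(1)))
    if (ovl) return(sprintf("'%s' intervals overlap within a gene", nm))
  }
  cdsLen <- vapply(width(object@cds), sum, numeric(1))
  if (any(cdsLen %% 3 != 0))
    return("total CDS length must be divisible by 3 for every gene")
  TRUE
})

#' Substitution spectrum summary
#'
#' Counts and percentages of the 12 ordered single-base substitution types
#' (recorded on the forward reference strand, complements kept distinct),
#' with transition/transversion rollups and the Ts/Tv fold ratio in both
#' round-half-up and truncated 2-decimal reporting forms.  The fold ratio
#' is `NA` (undefined) when no transversions were observed.
#'
#' @slot counts named integer, one count per ordered substitution type.
#' @slot transitions,transversions,total integer rollups.
#' @slot percent named numeric, per-type percent of total (half-up, 2 dp).
#' @slot transitionPercent,transversionPercent numeric (half-up, 2 dp).
#' @slot tsTvFold numeric, transitions/transversions rounded half-up, 2 dp.
#' @slot tsTvFoldTruncated numeric, same ratio truncated to 2 dp.
#' @seealso [spectrumSummary()]
#' @export
setClass("SpectrumSummary",
  slots = c(counts = "integer", transitions = "integer",
            transversions = "integer", total = "integer",
            percent = "numeric", transitionPercent = "numeric",
            transversionPercent = "numeric", tsTvFold = "numeric",
            tsTvFoldTruncated = "numeric"))

setValidity("SpectrumSummary", function(object) {
  if (!identical(names(object@counts), .subTypes()))
    return("counts must be named by the 12 ordered substitution types")
  if (sum(object@counts) != object@total)
    return("per-type counts must sum to total")
  if (object@transitions + object@transversions != object@total)
    return("transitions + transversions must equal total")
  TRUE
})

#' Synthetic study configuration
#'
#' Parameters of the synthetic EMS-mutant study generator.  Defaults encode
#' the emulated study design: two groups (wild type and mutant) of three
#' biological replicates, an EMS-biased substitution spectrum with at least
#' 90\% of its mass on C>T and G>A, shared background polymorphisms,
#' low-depth and heterozygous nuisance calls, one causal homozygous
#' nonsynonymous SNP in a gene that is also differentially expressed, and a
#' co-downregulated pathway gene set.
#'
#' @seealso [simulationConfig()] for the constructor and the documented
#'   meaning and default of every field.
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", nChromosomes = "integer",
            chromLength = "integer", nGenes = "integer",
            exonsPerGene = "integer", nTrueMutations = "integer",
            emsSpectrum = "numeric", nBackgroundSnps = "integer",
            replicatesPerGroup = "integer", meanDepth = "numeric",
            depthDispersion = "numeric", genotypeErrorRate = "numeric",
            nDeGenes = "integer", lfcEffect = "numeric",
            nbDispersion = "numeric", pathwaySize = "integer",
            causalEffectDirection = "character",
            nLowDepthLoci = "integer", nHetLoci = "integer",
            ctNoiseSd = "numeric", ctReplicates = "integer",
            ctTrueRatios = "numeric"))

setValidity("SimulationConfig", function(object) {
  cnt <- c(nChromosomes = object@nChromosomes,
           chromLength = object@chromLength, nGenes = object@nGenes,
           replicatesPerGroup = object@replicatesPerGroup,
           ctReplicates = object@ctReplicates)
  if (any(cnt < ifelse(names(cnt) == "nGenes", 0, 1)))
    return("counts must be positive (nGenes may be zero)")
  if (object@nTrueMutations < 0 || object@nBackgroundSnps < 0 ||
      object@nLowDepthLoci < 0 || object@nHetLoci < 0)
    return("locus counts must be non-negative")
  if (object@seed < 0 || object@seed > .Machine$integer.max - 10L)
    return("seed out of range")
  sp <- object@emsSpectrum
  if (is.null(names(sp)) || !all(names(sp) %in% .subTypes()))
    return("emsSpectrum names must be among the 12 substitution types")
  if (abs(sum(sp) - 1) > 1e-9)
    return("emsSpectrum probabilities must sum to 1 within 1e-9")
  if (any(sp < 0)) return("emsSpectrum probabilities must be non-negative")
  if (length(object@exonsPerGene) != 2 ||
      object@exonsPerGene[1] < 1 ||
      object@exonsPerGene[2] < object@exonsPerGene[1])
    return("exonsPerGene must be an increasing pair of positive counts")
  if (object@genotypeErrorRate < 0 || object@genotypeErrorRate > 1)
    return("genotypeErrorRate must be a probability")
  if (object@meanDepth <= 0 || object@depthDispersion <= 0)
    return("meanDepth and depthDispersion must be positive")
  if (object@nbDispersion < 0) return("nbDispersion must be >= 0")
  if (object@ctNoiseSd < 0) return("ctNoiseSd must be >= 0")
  if (any(object@ctTrueRatios <= 0))
    return("ctTrueRatios must be positive")
  if (!object@causalEffectDirection %in% c("up", "down"))
    return("causalEffectDirection must be 'up' or 'down'")
  if (object@nDeGenes > 0 &&
      object@nDeGenes < object@pathwaySize + min(object@nTrueMutations, 1L))
    return("nDeGenes must cover the pathway set plus the causal gene")
  if (object@nDeGenes > object@nGenes)
    return("nDeGenes cannot exceed nGenes")
  TRUE
})

#' A complete synthetic study
#'
#' Bundle of everything one seeded run of the generator produces: genome,
#' gene models, planted truth records, per-replicate variant calls, a
#' gene-by-sample count matrix (as a
#' \link[SummarizedExperiment]{SummarizedExperiment} whose metadata carries
#' the pathway membership table), a qPCR Ct table, and the configuration
#' that produced them.
#'
#' @slot genome `DNAStringSet`, one entry per chromosome.
#' @slot models [GeneModels-class].
#' @slot truth data.frame of planted variant truth records.
#' @slot calls data.frame of per-replicate variant observations.
#' @slot counts `SummarizedExperiment` of counts.
#' @slot ct data.frame of qPCR Ct values.
#' @slot config [SimulationConfig-class].
#' @seealso [simulateStudy()], [writeStudy()]
#' @export
setClass("MutantStudy",
  slots = c(genome = "DNAStringSet", models = "GeneModels",
            truth = "data.frame", calls = "data.frame",
            counts = "SummarizedExperiment", ct = "data.frame",
            config = "SimulationConfig"))

setValidity("MutantStudy", function(object) {
  if (sum(object@truth$causal) > 1)
    return("at most one causal truth record per simulation")
  TRUE
})
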