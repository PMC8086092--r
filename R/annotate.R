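#' Locate variants relative to gene models
#'
#' Assigns each locus a genomic region class with precedence
#' exon > intron > upstream > downstream > intergenic.  Upstream and
#' downstream windows extend `flank` bases from the gene boundary on the
#' gene's own strand (so "upstream" of a minus-strand gene lies at
#' numerically greater coordinates).  Loci on chromosomes absent from the
#' annotation are classified intergenic with a warning.
#'
#' @param loci data.frame with `chrom` and `pos` (1-based) columns.
#' @param models a [GeneModels-class] object.
#' @param flank flank window in bases for the upstream/downstream classes
#'   (default 2000).
#' @return data.frame of `region` and `geneId` (NA for intergenic), one row
#'   per input locus, in input order.
#' @export
locateRegion <- function(loci, models, flank = 2000) {
  stopifnot(is(models, "GeneModels"))
  n <- nrow(loci)
  region <- rep("intergenic", n)
  geneId <- rep(NA_character_, n)
  if (n == 0 || length(models) == 0)
    return(data.frame(region = region, geneId = geneId,
                      stringsAsFactors = FALSE))
  modelChroms <- unique(as.character(seqnames(models@genes)))
  missingChrom <- !(as.character(loci$chrom) %in% modelChroms)
  if (any(missingChrom))
    warning(sprintf(
      "%d locus/loci on chromosome(s) absent from the annotation (%s); classified intergenic",
      sum(missingChrom),
      paste(unique(loci$chrom[missingChrom]), collapse = ", ")))
  q <- GRanges(loci$chrom, IRanges(loci$pos, width = 1))
  genes <- models@genes
  mark <- function(subject, ids, label) {
    ## suppress the seqlevel-mismatch chatter for chromosomes we have
    ## already warned about above
    hits <- suppressWarnings(findOverlaps(q, subject, select = "first"))
    hit <- !is.na(hits)
    region[hit] <<- label
    geneId[hit] <<- ids[hits[hit]]
  }
  ## apply in increasing precedence so later classes override earlier ones
  mark(suppressWarnings(
    GenomicRanges::flank(genes, width = flank, start = FALSE)),
    genes$gene_id, "downstream")
  mark(suppressWarnings(
    GenomicRanges::flank(genes, width = flank, start = TRUE)),
    genes$gene_id, "upstream")
  mark(genes, genes$gene_id, "intron")
  ex <- unlist(models@exons)
  mark(ex, rep(geneIds(models), lengths(models@exons)), "exon")
  data.frame(region = region, geneId = geneId, stringsAsFactors = FALSE)
}

## splice the CDS of one gene out of the genome; returns the coding-strand
## sequence plus the bookkeeping needed to map a genomic position into it
.spliceCds <- function(models, genome, geneId) {
  cds <- models@cds[[geneId]]
  if (is.null(cds) || length(cds) == 0)
    stop(sprintf("gene '%s' has no CDS", geneId))
  chrom <- as.character(seqnames(cds))[1]
  chromSeq <- genome[[chrom]]
  segs <- vapply(seq_along(cds), function(i)
    as.character(subseq(chromSeq, start(cds)[i], end(cds)[i])),
    character(1))
  asc <- paste0(segs, collapse = "")
  L <- nchar(asc)
  if (L %% 3 != 0)
    stop(sprintf("CDS length of gene '%s' (%d) is not divisible by 3",
                 geneId, L))
  strandChar <- as.character(strand(models@genes))[
    match(geneId, geneIds(models))]
  coding <- if (strandChar == "+") asc else
    as.character(reverseComplement(DNAString(asc)))
  list(chrom = chrom, starts = start(cds), ends = end(cds),
       widths = width(cds), strand = strandChar, L = L, coding = coding)
}

.codingEffectOne <- function(sp, pos, ref, alt) {
  idx <- which(pos >= sp$starts & pos <= sp$ends)
  if (length(idx) != 1)
    stop(sprintf("position %d is not inside the CDS", pos))
  before <- if (idx > 1) sum(sp$widths[seq_len(idx - 1)]) else 0L
  ascPos <- before + (pos - sp$starts[idx] + 1L)
  cdsPos <- if (sp$strand == "+") ascPos else sp$L - ascPos + 1L
  refCoding <- if (sp$strand == "+") ref else unname(.complement(ref))
  altCoding <- if (sp$strand == "+") alt else unname(.complement(alt))
  codonIdx <- (cdsPos - 1L) %/% 3L + 1L
  off <- (cdsPos - 1L) %% 3L
  refCodon <- substr(sp$coding, 3L * (codonIdx - 1L) + 1L, 3L * codonIdx)
  if (substr(refCodon, off + 1L, off + 1L) != refCoding)
    stop(sprintf(
      "reference base mismatch at position %d: genome has '%s', variant says '%s'",
      pos, substr(refCodon, off + 1L, off + 1L), refCoding))
  altCodon <- refCodon
  substr(altCodon, off + 1L, off + 1L) <- altCoding
  refAa <- unname(GENETIC_CODE[refCodon])
  altAa <- unname(GENETIC_CODE[altCodon])
  effect <- if (refAa == altAa) "synonymous"
    else if (altAa == "*" && refAa != "*") "stop_gain"
    else if (refAa == "*" && altAa != "*") "stop_loss"
    else "nonsynonymous"
  data.frame(codingEffect = effect, refCodon = refCodon,
             altCodon = altCodon, refAa = refAa, altAa = altAa,
             proteinPos = codonIdx, stringsAsFactors = FALSE)
}

#' Annotate the coding effect of a CDS variant
#'
#' Splices the CDS of the covering gene, reverse-complements it for
#' minus-strand genes, substitutes the variant base in its codon and
#' translates reference and alternate codons with the standard nuclear
#' genetic code.  The effect is `stop_gain` when only the alternate codon
#' is a stop, `stop_loss` when only the reference codon is, `synonymous`
#' when the amino acids agree, `nonsynonymous` otherwise.
#'
#' @param chrom,pos,ref,alt the variant locus (1-based; forward-strand
#'   `ref`/`alt` bases as in a VCF).
#' @param models a [GeneModels-class] object.
#' @param genome `DNAStringSet` named by chromosome.
#' @param geneId optional gene id; when omitted the gene whose CDS contains
#'   the position is looked up (error if none).
#' @return one-row data.frame: `codingEffect`, `refCodon`, `altCodon`,
#'   `refAa`, `altAa`, `proteinPos` (1-based codon index), `geneId`.
#' @export
annotateCodingEffect <- function(chrom, pos, ref, alt, models, genome,
                                 geneId = NULL) {
  stopifnot(is(models, "GeneModels"))
  if (is.null(geneId)) {
    q <- GRanges(chrom, IRanges(pos, width = 1))
    cdsAll <- unlist(models@cds)
    hit <- suppressWarnings(findOverlaps(q, cdsAll, select = "first"))
    if (is.na(hit))
      stop(sprintf("position %s:%d lies in no CDS", chrom, pos))
    geneId <- rep(geneIds(models), lengths(models@cds))[hit]
  }
  sp <- .spliceCds(models, genome, geneId)
  out <- .codingEffectOne(sp, pos, ref, alt)
  out$geneId <- geneId
  out
}

#' Annotate a table of variants
#'
#' Combines [locateRegion()] with codon-level effect annotation: loci whose
#' position falls inside a CDS get a coding effect; all other loci
#' (including exonic positions outside any CDS) are `noncoding`.  CDS
#' splicing is cached per gene, so large locus tables are annotated
#' efficiently.
#'
#' @param loci data.frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @inheritParams locateRegion
#' @param genome `DNAStringSet` named by chromosome.
#' @return the input columns plus `region`, `geneId`, `codingEffect`,
#'   `refCodon`, `altCodon`, `refAa`, `altAa`, `proteinPos`.
#' @export
annotateVariants <- function(loci, models, genome, flank = 2000) {
  reg <- locateRegion(loci, models, flank = flank)
  n <- nrow(loci)
  out <- cbind(loci, reg,
               data.frame(codingEffect = rep("noncoding", n),
                          refCodon = rep(NA_character_, n),
                          altCodon = rep(NA_character_, n),
                          refAa = rep(NA_character_, n),
                          altAa = rep(NA_character_, n),
                          proteinPos = rep(NA_integer_, n),
                          stringsAsFactors = FALSE))
  if (n == 0 || length(models) == 0) return(out)
  cdsAll <- unlist(models@cds)
  cdsGene <- rep(geneIds(models), lengths(models@cds))
  q <- GRanges(loci$chrom, IRanges(loci$pos, width = 1))
  hits <- suppressWarnings(findOverlaps(q, cdsAll, select = "first"))
  inCds <- !is.na(hits)
  for (gid in unique(cdsGene[hits[inCds]])) {
    sp <- .spliceCds(models, genome, gid)
    rows <- which(inCds & cdsGene[hits] == gid)
    for (i in rows) {
      eff <- .codingEffectOne(sp, loci$pos[i], toupper(loci$ref[i]),
                              toupper(loci$alt[i]))
      out$codingEffect[i] <- eff$codingEffect
      out$refCodon[i] <- eff$refCodon
      out$altCodon[i] <- eff$altCodon
      out$refAa[i] <- eff$refAa
      out$altAa[i] <- eff$altAa
      out$proteinPos[i] <- eff$proteinPos
      out$geneId[i] <- gid
    }
  }
  out
}

#' Count variants per effect and region class
#'
#' @param annotations data.frame as returned by [annotateVariants()] (the
#'   `codingEffect` and, if present, `region` columns are used).
#' @return list with `effect` (named integer over the five coding-effect
#'   classes), `region` (named integer over the five region classes, if the
#'   input carries a region column), and `total`.  Each table sums to the
#'   number of input rows.
#' @export
effectClassCounts <- function(annotations) {
  effLevels <- c("synonymous", "nonsynonymous", "stop_gain", "stop_loss",
                 "noncoding")
  regLevels <- c("exon", "intron", "upstream", "downstream", "intergenic")
  n <- if (is.null(nrow(annotations))) 0L else nrow(annotations)
  eff <- table(factor(if (n) annotations$codingEffect else character(0),
                      levels = effLevels))
  out <- list(effect = setNames(as.integer(eff), effLevels), total = n)
  if (n == 0 || !is.null(annotations$region)) {
    reg <- table(factor(if (n) annotations$region else character(0),
                        levels = regLevels))
    out$region <- setNames(as.integer(reg), regLevels)
  }
  out
}
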