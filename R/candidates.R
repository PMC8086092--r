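#' Intersect variant and expression evidence into candidate genes
#'
#' A candidate gene carries at least one group-discriminating homozygous
#' SNP with a protein-altering effect (nonsynonymous; stop-gain loci count
#' as evidence too unless `includeStopGain = FALSE`) and is differentially
#' expressed.  One row is emitted per qualifying SNP; the `"summary"`
#' attribute counts unique candidate genes and their up/down split.
#'
#' @param annotatedSnps data.frame of filtered, annotated SNPs (e.g.
#'   [filterHomozygousDifferences()] output annotated with
#'   [annotateVariants()]): columns `chrom`, `pos`, `ref`, `alt`,
#'   `geneId`, `codingEffect`, `refAa`, `altAa`, `proteinPos`.
#' @param degTable data.frame from [deTest()].
#' @param includeStopGain count stop-gain SNPs as candidate evidence
#'   (default TRUE).
#' @return data.frame with one row per qualifying SNP: `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `codingEffect`, `aaChange` (e.g. `"S123N"`),
#'   `direction`, `log2Ratio`, `fdr`, ranked by (FDR ascending,
#'   |log2 ratio| descending, gene).  Attribute `"summary"`: `total`,
#'   `up`, `down` unique-gene counts.
#' @export
selectCandidates <- function(annotatedSnps, degTable,
                             includeStopGain = TRUE) {
  effects <- c("nonsynonymous", if (includeStopGain) "stop_gain")
  snps <- annotatedSnps[!is.na(annotatedSnps$geneId) &
                          annotatedSnps$codingEffect %in% effects, ,
                        drop = FALSE]
  degs <- degTable[degTable$isDeg, , drop = FALSE]
  snps <- snps[snps$geneId %in% degs$gene, , drop = FALSE]
  if (nrow(snps) == 0) {
    out <- data.frame(gene = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), codingEffect = character(),
                      aaChange = character(), direction = character(),
                      log2Ratio = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- list(total = 0L, up = 0L, down = 0L)
    return(out)
  }
  m <- match(snps$geneId, degs$gene)
  out <- data.frame(
    gene = snps$geneId, chrom = snps$chrom, pos = snps$pos,
    ref = snps$ref, alt = snps$alt, codingEffect = snps$codingEffect,
    aaChange = paste0(snps$refAa, snps$proteinPos, snps$altAa),
    direction = degs$direction[m],
    log2Ratio = degs$log2Ratio[m],
    fdr = degs$fdr[m],
    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, -abs(out$log2Ratio), out$gene, out$pos), ]
  rownames(out) <- NULL
  byGene <- out[!duplicated(out$gene), ]
  attr(out, "summary") <- list(
    total = nrow(byGene),
    up = sum(byGene$direction == "up"),
    down = sum(byGene$direction == "down"))
  out
}

#' Lodging index
#'
#' \deqn{LI = FW(g) \times PH(cm) / (BF \times 10)} where FW is fresh
#' weight, PH plant height and BF the breaking force measured with a
#' digital force gauge.  LI is treated as unitless; lower LI indicates
#' greater lodging resistance.
#'
#' @param fw fresh weight in grams.
#' @param ph plant height in centimetres.
#' @param bf breaking force (gauge units); must be positive.
#' @return the lodging index (vectorized).
#' @export
#' @examples
#' lodgingIndex(100, 150, 15)  # 100
lodgingIndex <- function(fw, ph, bf) {
  if (any(bf <= 0)) stop("breaking force must be positive")
  fw * ph / (bf * 10)
}

#' Percent-of-reference with reporting rounding
#'
#' `100 * value / reference`, rounded per the reporting convention: half-up
#' (default) or truncated, to `digits` decimals.
#'
#' @param value,reference numeric (vectorized).
#' @param digits decimal places (default 2).
#' @param mode `"half_up"` or `"truncate"`.
#' @return the rounded percentage.
#' @export
#' @examples
#' percentOf(75.6, 178, digits = 0)   # 42
#' percentOf(17393, 28008, digits = 1)  # 62.1
percentOf <- function(value, reference, digits = 2,
                      mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  x <- 100 * value / reference
  if (mode == "half_up") roundHalfUp(x, digits) else truncateTo(x, digits)
}

#' Fold ratio with reporting rounding
#'
#' `a / b` rounded per the reporting convention.  Mutant-screen fold
#' ratios are conventionally truncated, so that is the default mode.
#'
#' @param a,b numerator and denominator.
#' @inheritParams percentOf
#' @return the rounded ratio.
#' @export
#' @examples
#' foldRatio(17393, 10615)  # 1.63
foldRatio <- function(a, b, digits = 2, mode = c("truncate", "half_up")) {
  mode <- match.arg(mode)
  x <- a / b
  if (mode == "truncate") truncateTo(x, digits) else roundHalfUp(x, digits)
}

#' Compute lodging indices for a phenotype table
#'
#' @param phenotypes data.frame with `FW` (g), `PH` (cm) and `BF` columns.
#' @return the input with an `LI` column added (recomputed from the other
#'   three fields via [lodgingIndex()]).
#' @export
#' @examples
#' ph <- read.delim(system.file("extdata", "phenotypes_synthetic.tsv",
#'                              package = "emscan"))
#' computeLodgingIndex(ph)
computeLodgingIndex <- function(phenotypes) {
  need <- c("FW", "PH", "BF")
  if (!all(need %in% names(phenotypes)))
    stop("phenotype table must have columns FW, PH, BF")
  phenotypes$LI <- lodgingIndex(phenotypes$FW, phenotypes$PH,
                                phenotypes$BF)
  phenotypes
}
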