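#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \deqn{FPKM_{gs} = count_{gs} \cdot 10^9 / (total_s \cdot length_g)}
#'
#' @param counts integer matrix, genes in rows, samples in columns, or a
#'   `SummarizedExperiment` whose rowData carries a `geneLength` column.
#' @param lengths per-gene transcript lengths in bases (ignored for a
#'   `SummarizedExperiment` input).
#' @return numeric matrix of FPKM values, same dimensions as `counts`.
#' @export
fpkm <- function(counts, lengths = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    lengths <- rowData(counts)$geneLength
    counts <- assay(counts)
  }
  counts <- as.matrix(counts)
  if (is.null(lengths) || length(lengths) != nrow(counts))
    stop("'lengths' must give one transcript length per gene")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every sample must have a positive total count")
  counts * 1e9 / outer(lengths, totals)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up adjustment (a thin wrapper around
#' \code{\link[stats]{p.adjust}} so the pipeline's multiplicity correction
#' is explicit and testable).
#'
#' @param p numeric vector of p-values.
#' @return adjusted values, same order as the input.
#' @export
bhFdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Exact conditional binomial differential-expression contrast
#'
#' Per gene, counts are pooled within each group and the mutant pool is
#' tested against its expectation under equal relative expression with a
#' two-sided exact binomial test conditioned on the pooled total, with the
#' success probability given by the mutant share of the summed library
#' sizes (an Audic-Claverie-style contrast; replicates are treated as
#' technical pools, see the package vignette for the implied variance
#' assumptions).  Log2 ratios are computed from group means of counts per
#' million with a pseudocount of 1.  P-values are BH-adjusted over all
#' tested genes; a gene is flagged differentially expressed when
#' `FDR < fdrThreshold` and `|log2 ratio| >= lfcThreshold`.
#'
#' @param counts integer matrix (genes x samples) or a
#'   `SummarizedExperiment` with a `group` column in its colData.
#' @param groups character vector of group labels per sample (taken from
#'   colData for a `SummarizedExperiment`).
#' @param wtGroup reference group label; the log2 ratio is mutant vs this.
#' @param fdrThreshold,lfcThreshold DEG thresholds (defaults 0.001 and 1).
#' @return data.frame with one row per gene: `gene`, `meanWt`,
#'   `meanMutant` (CPM group means), `log2Ratio`, `pValue`, `fdr`,
#'   `isDeg`, `direction` (`up`/`down` where `isDeg`, else NA), `tested`.
#'   Genes with zero counts everywhere are reported untested with NA
#'   statistics.  Rows are sorted by (FDR, |log2 ratio| descending, gene),
#'   untested genes last.
#' @export
deTest <- function(counts, groups = NULL, wtGroup = "WT",
                   fdrThreshold = 0.001, lfcThreshold = 1) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(groups)) groups <- colData(counts)$group
    counts <- assay(counts)
  }
  counts <- as.matrix(counts)
  if (is.null(groups) || length(groups) != ncol(counts))
    stop("'groups' must label every sample")
  ug <- unique(groups)
  if (length(ug) != 2 || !wtGroup %in% ug)
    stop("exactly two groups including the reference group are required")
  mutGroup <- setdiff(ug, wtGroup)
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(nrow(counts)))
  libSizes <- colSums(counts)
  wtCols <- groups == wtGroup
  a <- rowSums(counts[, wtCols, drop = FALSE])
  b <- rowSums(counts[, !wtCols, drop = FALSE])
  Nw <- sum(libSizes[wtCols]); Nm <- sum(libSizes[!wtCols])
  if (Nw <= 0 || Nm <= 0) stop("both groups need a positive library size")
  p0 <- Nm / (Nm + Nw)
  tested <- (a + b) > 0
  cpm <- t(t(counts) / libSizes) * 1e6
  meanWt <- rowMeans(cpm[, wtCols, drop = FALSE])
  meanMut <- rowMeans(cpm[, !wtCols, drop = FALSE])
  lfc <- log2((meanMut + 1) / (meanWt + 1))
  p <- rep(NA_real_, nrow(counts))
  p[tested] <- vapply(which(tested), function(i)
    stats::binom.test(b[i], a[i] + b[i], p = p0)$p.value, numeric(1))
  fdr <- rep(NA_real_, nrow(counts))
  fdr[tested] <- bhFdr(p[tested])
  isDeg <- tested & fdr < fdrThreshold & abs(lfc) >= lfcThreshold
  isDeg[is.na(isDeg)] <- FALSE
  direction <- ifelse(isDeg, ifelse(lfc > 0, "up", "down"), NA_character_)
  out <- data.frame(gene = genes, meanWt = meanWt, meanMutant = meanMut,
                    log2Ratio = ifelse(tested, lfc, NA_real_),
                    pValue = p, fdr = fdr, isDeg = isDeg,
                    direction = direction, tested = tested,
                    stringsAsFactors = FALSE)
  ord <- order(!out$tested, out$fdr, -abs(out$log2Ratio), out$gene,
               na.last = TRUE)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test of differentially-expressed-gene overlap
#' for each pathway, with Bonferroni correction
#' (\eqn{Q = \min(1, p \times \#pathways)}; BH available for comparison).
#' A pathway is significant when `Q <= alpha`.
#'
#' @param degGenes character vector of DEG identifiers (a subset of
#'   `universe`).
#' @param pathways data.frame with `pathway` and `gene` columns, or a
#'   named list of gene vectors.
#' @param universe character vector of all testable genes (conventionally
#'   the genes with at least one count).
#' @param alpha significance threshold on the corrected Q (default 0.05).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return data.frame with one row per pathway: `pathway`, `k` (DEGs in
#'   pathway), `K` (pathway size in universe), `n` (DEG total), `N`
#'   (universe size), `pValue`, `q`, `significant`, `percentOfDegs`
#'   (100 k/n, half-up, 2 dp).  Sorted by p-value.
#' @export
enrich <- function(degGenes, pathways, universe, alpha = 0.05,
                   correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (is.data.frame(pathways)) {
    pathways <- split(as.character(pathways$gene),
                      as.character(pathways$pathway))
  }
  if (!all(degGenes %in% universe))
    stop("degGenes must be a subset of the universe")
  if (length(degGenes) == 0) {
    warning("empty DEG set: no enrichment computed")
    return(data.frame(pathway = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pValue = numeric(),
                      q = numeric(), significant = logical(),
                      percentOfDegs = numeric(), stringsAsFactors = FALSE))
  }
  N <- length(unique(universe))
  n <- length(unique(degGenes))
  res <- lapply(names(pathways), function(pw) {
    genes <- unique(pathways[[pw]])
    if (!all(genes %in% universe))
      stop(sprintf("pathway '%s' contains genes outside the universe", pw))
    K <- length(genes)
    k <- length(intersect(genes, degGenes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, pValue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- if (correction == "bonferroni")
    pmin(1, out$pValue * nrow(out)) else bhFdr(out$pValue)
  out$significant <- out$q <= alpha
  out$percentOfDegs <- roundHalfUp(100 * out$k / out$n, 2)
  out <- out[order(out$pValue, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}};
#' \eqn{\Delta\Delta Ct} subtracts the mean calibrator \eqn{\Delta Ct} of
#' the same target; relative expression is \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct data.frame with columns `sample`, `condition` (`test` or
#'   `calibrator`), `target`, `targetCt`, `referenceCt`, `replicate`.
#' @return the input rows plus `dCt`, `ddCt` and `relExpression` columns.
#' @export
ddct <- function(ct) {
  need <- c("sample", "condition", "target", "targetCt", "referenceCt")
  if (!all(need %in% names(ct)))
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  badRef <- !is.finite(ct$referenceCt)
  if (any(badRef))
    stop("missing reference-gene Ct in row(s) ",
         paste(which(badRef), collapse = ", "))
  if (any(!is.finite(ct$targetCt)))
    stop("missing target-gene Ct")
  out <- ct
  out$dCt <- out$targetCt - out$referenceCt
  out$ddCt <- NA_real_
  for (tg in unique(out$target)) {
    sel <- out$target == tg
    cal <- sel & out$condition == "calibrator"
    if (!any(cal))
      stop(sprintf("no calibrator samples for target '%s'", tg))
    out$ddCt[sel] <- out$dCt[sel] - mean(out$dCt[cal])
  }
  out$relExpression <- 2^(-out$ddCt)
  out
}
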