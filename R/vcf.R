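.GT_TO_CALL <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
                 "0/1" = "het", "1/0" = "het", "0|1" = "het",
                 "1|0" = "het",
                 "1/1" = "hom_alt", "1|1" = "hom_alt",
                 "./." = "missing", "." = "missing", ".|." = "missing")

.CALL_TO_GT <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                 missing = "./.")

#' Write per-replicate variant calls as minimal VCF 4.2
#'
#' One record per locus, one sample column per replicate, FORMAT `GT:DP`.
#' Sample columns are ordered wild-type group first (then by sample name),
#' loci by chromosome then position.  Output bytes are fully determined by
#' the input table, so identical call tables yield identical files.
#'
#' @param calls data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `group`, `depth`, `genotype` (genotype one of `hom_ref`,
#'   `het`, `hom_alt`, `missing`).
#' @param path output file path.
#' @param wtGroup label of the wild-type group (ordered first).
#' @return `path`, invisibly.
#' @export
writeVcfCalls <- function(calls, path, wtGroup = "WT") {
  need <- c("chrom", "pos", "ref", "alt", "sample", "group", "depth",
            "genotype")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  sampleTab <- unique(calls[, c("sample", "group")])
  sampleTab <- sampleTab[order(sampleTab$group != wtGroup,
                               sampleTab$sample), ]
  samples <- sampleTab$sample
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  loci <- unique(calls[, c("chrom", "pos", "ref", "alt")])
  loci <- loci[order(loci$chrom, loci$pos), ]
  lkey <- paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = "\r")
  gt <- matrix("./.", nrow(loci), length(samples))
  dp <- matrix(0L, nrow(loci), length(samples))
  ri <- match(key, lkey)
  ci <- match(calls$sample, samples)
  gt[cbind(ri, ci)] <- unname(.CALL_TO_GT[calls$genotype])
  dp[cbind(ri, ci)] <- as.integer(calls$depth)
  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(c(loci$chrom[i], loci$pos[i], ".", loci$ref[i], loci$alt[i],
            ".", "PASS", ".", "GT:DP",
            paste0(gt[i, ], ":", dp[i, ])), collapse = "\t")
  }, character(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=emscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF into a variant call table
#'
#' Parses a VCF 4.2 file (via \link[VariantAnnotation]{readVcf}) into the
#' long per-site-per-sample call table the filter operates on.  Only
#' biallelic single-base substitutions are supported: multi-allelic or
#' non-SNP records are rejected with an error listing their file line
#' numbers.  A missing GT yields genotype `missing`; a missing DP yields
#' depth 0.
#'
#' @param path VCF file path.
#' @param groups optional named character vector mapping sample name to
#'   group label; by default the group is the sample name with a trailing
#'   `-<number>` replicate suffix removed (e.g. `WT-1` is group `WT`).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `group`, `depth`, `genotype`, ordered by chromosome, position, sample.
#' @export
readVcfCalls <- function(path, groups = NULL) {
  lines <- readLines(path)
  chromIdx <- grep("^#CHROM", lines)
  if (length(chromIdx) == 0)
    stop("truncated VCF header: no #CHROM column line found")
  chromIdx <- chromIdx[length(chromIdx)]
  cols <- strsplit(lines[chromIdx], "\t", fixed = TRUE)[[1]]
  required <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT")
  missingCols <- setdiff(required, cols)
  if (length(missingCols))
    stop("truncated VCF header: missing column(s) ",
         paste(missingCols, collapse = ", "))
  if (length(cols) <= length(required))
    stop("VCF has no sample columns")
  vcf <- VariantAnnotation::readVcf(path)
  n <- nrow(vcf)
  recLine <- chromIdx + seq_len(n)
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(rr$REF)
  altList <- rr$ALT
  bad <- S4Vectors::elementNROWS(altList) != 1
  alts <- rep(NA_character_, n)
  alts[!bad] <- vapply(which(!bad), function(i)
    as.character(altList[[i]][1]), character(1))
  bad <- bad | nchar(refs) != 1 | is.na(alts) | nchar(alts) != 1 |
    !(refs %in% .BASES) | !(alts %in% .BASES)
  if (any(bad))
    stop("non-SNP or multi-allelic record(s) at line(s) ",
         paste(recLine[bad], collapse = ", "),
         "; only biallelic single-base substitutions are supported")
  samples <- cols[-seq_along(required)]
  g <- VariantAnnotation::geno(vcf)
  gtMat <- if ("GT" %in% names(g)) g$GT else
    matrix(".", n, length(samples), dimnames = list(NULL, samples))
  dpMat <- if ("DP" %in% names(g)) g$DP else
    matrix(NA_integer_, n, length(samples), dimnames = list(NULL, samples))
  if (is.null(groups)) {
    groups <- setNames(sub("-[0-9]+$", "", samples), samples)
  } else if (is.null(names(groups)) || !all(samples %in% names(groups))) {
    stop("'groups' must be named by every sample in the VCF")
  }
  out <- data.frame(
    chrom = rep(as.character(seqnames(rr)), times = length(samples)),
    pos = rep(start(rr), times = length(samples)),
    ref = rep(refs, times = length(samples)),
    alt = rep(alts, times = length(samples)),
    sample = rep(samples, each = n),
    group = rep(unname(groups[samples]), each = n),
    depth = as.integer(dpMat),
    genotype = unname(.GT_TO_CALL[as.character(gtMat)]),
    stringsAsFactors = FALSE)
  out$genotype[is.na(out$genotype)] <- "missing"
  out$depth[is.na(out$depth)] <- 0L
  out <- out[order(out$chrom, out$pos, out$sample), ]
  rownames(out) <- NULL
  out
}
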