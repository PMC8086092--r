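#' Three-step homozygous-SNP filter
#'
#' Reduces a per-replicate variant call table to the loci that
#' discriminate the mutant group from the wild type, following the manual
#' screening protocol of EMS mutant mapping: (1) calls with read depth of
#' `minDepthExclusive` or less are removed (survivors need depth strictly
#' greater, i.e. \eqn{\ge} 11 at the default); (2) a locus must retain a
#' passing call in at least `requiredReplicates` biological replicates of
#' each group; (3) any retained heterozygous call discards the locus.  A
#' surviving locus must additionally be unanimously homozygous within each
#' group, with the two groups' genotypes differing (shared homozygous
#' polymorphisms carry no group information and are dropped).
#'
#' @param calls data.frame of per-replicate calls (see [readVcfCalls()]):
#'   columns `chrom`, `pos`, `ref`, `alt`, `sample`, `group`, `depth`,
#'   `genotype`.  Exactly two groups are required, each with at least
#'   `requiredReplicates` samples.
#' @param minDepthExclusive depth threshold; calls at or below it are
#'   filtered (default 10).
#' @param requiredReplicates minimum passing replicates per group
#'   (default 3).
#' @param wtGroup label of the wild-type group.
#' @return data.frame of surviving loci ordered by chromosome then
#'   position, with columns `chrom`, `pos`, `ref`, `alt`, `wtGenotype`,
#'   `mutantGenotype`, `wtMeanDepth`, `mutantMeanDepth`.  The attribute
#'   `"log"` records the input locus count and the number removed by each
#'   criterion (depth/replicate support, heterozygosity, within-group
#'   conflict, no group difference).
#' @export
filterHomozygousDifferences <- function(calls, minDepthExclusive = 10,
                                        requiredReplicates = 3,
                                        wtGroup = "WT") {
  groups <- unique(calls$group)
  if (length(groups) != 2)
    stop("calls must contain exactly two groups, got: ",
         paste(groups, collapse = ", "))
  if (!wtGroup %in% groups)
    stop(sprintf("wild-type group '%s' not present in calls", wtGroup))
  mutGroup <- setdiff(groups, wtGroup)
  for (g in groups) {
    nrep <- length(unique(calls$sample[calls$group == g]))
    if (nrep < requiredReplicates)
      stop(sprintf(
        "group '%s' has %d replicate(s); at least %d are required",
        g, nrep, requiredReplicates))
  }
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  passing <- calls$depth > minDepthExclusive & calls$genotype != "missing"
  loci <- unique(calls[, c("chrom", "pos", "ref", "alt")])
  lkey <- paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = "\r")
  n <- nrow(loci)
  consensus <- function(geno) {
    u <- unique(geno)
    if (length(u) == 1) u else NA_character_
  }
  wtG <- character(n); mutG <- character(n)
  wtD <- numeric(n); mutD <- numeric(n)
  status <- character(n)
  idxByLocus <- split(seq_len(nrow(calls)), match(key, lkey))
  for (i in seq_len(n)) {
    rows <- idxByLocus[[as.character(i)]]
    keep <- rows[passing[rows]]
    wtKeep <- keep[calls$group[keep] == wtGroup]
    mutKeep <- keep[calls$group[keep] == mutGroup]
    if (length(wtKeep) < requiredReplicates ||
        length(mutKeep) < requiredReplicates) {
      status[i] <- "depth_or_replicates"
      next
    }
    if (any(calls$genotype[keep] == "het")) {
      status[i] <- "heterozygous"
      next
    }
    gw <- consensus(calls$genotype[wtKeep])
    gm <- consensus(calls$genotype[mutKeep])
    if (is.na(gw) || is.na(gm)) {
      status[i] <- "conflict"
      next
    }
    if (gw == gm) {
      status[i] <- "no_group_difference"
      next
    }
    status[i] <- "pass"
    wtG[i] <- gw; mutG[i] <- gm
    wtD[i] <- mean(calls$depth[wtKeep])
    mutD[i] <- mean(calls$depth[mutKeep])
  }
  keepLoci <- status == "pass"
  out <- data.frame(
    chrom = loci$chrom[keepLoci], pos = loci$pos[keepLoci],
    ref = loci$ref[keepLoci], alt = loci$alt[keepLoci],
    wtGenotype = wtG[keepLoci], mutantGenotype = mutG[keepLoci],
    wtMeanDepth = wtD[keepLoci], mutantMeanDepth = mutD[keepLoci],
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  attr(out, "log") <- list(
    input = n,
    removed_depth_or_replicates = sum(status == "depth_or_replicates"),
    removed_heterozygous = sum(status == "heterozygous"),
    removed_conflict = sum(status == "conflict"),
    removed_no_group_difference = sum(status == "no_group_difference"),
    output = sum(keepLoci))
  out
}
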