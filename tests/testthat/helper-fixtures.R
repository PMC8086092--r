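suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(SummarizedExperiment)
})

## Hand-built three-gene fixture with known codons on both strands:
##   geneA (+, one exon, 3001-3015):  ATG GGA CAA TGT TAA
##   geneB (-, one exon, 6001-6015):  coding ATG CAT AAG GAG TGA
##   geneC (+, two exons 501-509 / 610-618, intron between):
##                                    ATG AAA CCC GGG TTT TAA split 9+9
makeToyReference <- function() {
  chars <- rep("T", 9000)
  put <- function(chars, start, seq) {
    s <- strsplit(seq, "")[[1]]
    chars[start:(start + length(s) - 1)] <- s
    chars
  }
  chars <- put(chars, 3001, "ATGGGACAATGTTAA")
  codB <- "ATGCATAAGGAGTGA"
  rcB <- as.character(reverseComplement(DNAString(codB)))
  chars <- put(chars, 6001, rcB)
  codC <- "ATGAAACCCGGGTTTTAA"
  chars <- put(chars, 501, substr(codC, 1, 9))
  chars <- put(chars, 610, substr(codC, 10, 18))
  genome <- DNAStringSet(paste0(chars, collapse = ""))
  names(genome) <- "chrT"
  genes <- GRanges("chrT",
                   IRanges(c(501, 3001, 6001), c(618, 3015, 6015)),
                   strand = c("+", "+", "-"))
  genes$gene_id <- c("geneC", "geneA", "geneB")
  grl <- function(starts, ends, strand)
    GRanges("chrT", IRanges(starts, ends), strand = strand)
  exons <- GRangesList(
    geneC = grl(c(501, 610), c(509, 618), "+"),
    geneA = grl(3001, 3015, "+"),
    geneB = grl(6001, 6015, "-"))
  models <- GeneModels(genes, exons, exons)
  list(genome = genome, models = models)
}

## Five-locus filter fixture: one low-depth, one heterozygous, one with
## only two passing mutant replicates, one shared homozygous, one true
## group-discriminating locus.
makeFiveLocusCalls <- function() {
  samples <- c(paste0("WT-", 1:3), paste0("ftdm-", 1:3))
  groups <- rep(c("WT", "ftdm"), each = 3)
  locus <- function(pos, ref, alt, depths, genos) {
    data.frame(chrom = "chr01", pos = pos, ref = ref, alt = alt,
               sample = samples, group = groups, depth = depths,
               genotype = genos, stringsAsFactors = FALSE)
  }
  rbind(
    locus(100, "C", "T", c(50, 50, 50, 50, 10, 50),
          c(rep("hom_ref", 3), rep("hom_alt", 3))),
    locus(200, "G", "A", rep(50, 6),
          c(rep("hom_ref", 3), "het", "hom_alt", "hom_alt")),
    locus(300, "A", "G", rep(50, 6),
          c(rep("hom_ref", 3), "hom_alt", "hom_alt", "missing")),
    locus(400, "C", "T", rep(50, 6), rep("hom_alt", 6)),
    locus(500, "G", "A", c(30, 40, 50, 60, 70, 80),
          c(rep("hom_ref", 3), rep("hom_alt", 3))))
}

## Independent full-protein oracle: mutate the genome base, re-extract and
## translate the entire CDS of the gene, and diff the two proteins.
oracleEffect <- function(genome, models, chrom, pos, ref, alt, geneId) {
  chars <- strsplit(as.character(genome[[chrom]]), "")[[1]]
  stopifnot(chars[pos] == ref)
  mut <- chars
  mut[pos] <- alt
  strandOf <- as.character(strand(geneRanges(models)))[
    match(geneId, geneIds(models))]
  extract <- function(v) {
    cds <- cdsRanges(models)[[geneId]]
    s <- paste0(unlist(lapply(seq_along(cds), function(i)
      v[start(cds)[i]:end(cds)[i]])), collapse = "")
    if (strandOf == "-")
      s <- as.character(reverseComplement(DNAString(s)))
    s
  }
  tr <- function(s) strsplit(as.character(
    translate(DNAString(s), no.init.codon = TRUE)), "")[[1]]
  p0 <- tr(extract(chars))
  p1 <- tr(extract(mut))
  d <- which(p0 != p1)
  if (length(d) == 0)
    return(list(effect = "synonymous", proteinPos = NA_integer_))
  d <- d[1]
  eff <- if (p1[d] == "*") "stop_gain"
    else if (p0[d] == "*") "stop_loss"
    else "nonsynonymous"
  list(effect = eff, proteinPos = d, refAa = p0[d], altAa = p1[d])
}

## Exhaustive hypergeometric enumeration: universe 1..N, pathway 1..K,
## every size-n draw; upper-tail probability of overlap >= k.
enumHyperTail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}
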