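test_that("VCF writer and reader round-trip the supported dialect", {
  cfg <- simulationConfig(seed = 2, nGenes = 20, chromLength = 60000,
                          nTrueMutations = 10, nBackgroundSnps = 4,
                          nDeGenes = 18, pathwaySize = 10)
  study <- simulateStudy(cfg)
  p <- tempfile(fileext = ".vcf")
  writeVcfCalls(variantCalls(study), p)
  back <- readVcfCalls(p)
  orig <- variantCalls(study)
  orig <- orig[order(orig$chrom, orig$pos, orig$sample), ]
  rownames(orig) <- NULL
  orig$depth <- as.integer(orig$depth)
  expect_equal(back, orig)
  ## six samples per locus
  expect_true(all(table(paste(back$chrom, back$pos)) == 6))
})

test_that("non-SNP and multi-allelic records are rejected with line numbers", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tWT-1",
    "chr01\t10\t.\tC\tT\t.\tPASS\t.\tGT:DP\t0/0:30",
    "chr01\t20\t.\tC\tAT\t.\tPASS\t.\tGT:DP\t0/0:30"), p)
  expect_error(readVcfCalls(p), "line\\(s\\) 6")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tWT-1",
    "chr01\t30\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1"), p)
  expect_error(readVcfCalls(p), "multi-allelic")
})

test_that("a truncated header names the missing column", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tFORMAT\tWT-1"), p)
  expect_error(readVcfCalls(p), "INFO")
  writeLines("##fileformat=VCFv4.2", p)
  expect_error(readVcfCalls(p), "#CHROM")
})

test_that("missing GT or DP fields degrade to missing genotype / depth 0", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tWT-1\tftdm-1",
    "chr01\t10\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
    "chr01\t20\t.\tG\tA\t.\tPASS\t.\tGT:DP\t./.:.\t1/1:12"), p)
  calls <- readVcfCalls(p)
  expect_equal(calls$depth[calls$pos == 10], c(0L, 0L))
  expect_equal(calls$genotype[calls$pos == 20 & calls$sample == "WT-1"],
               "missing")
  expect_equal(calls$group, c("ftdm", "WT")[match(calls$sample,
                                                  c("ftdm-1", "WT-1"))])
})

test_that("substitution classification follows the purine/pyrimidine rule", {
  expect_equal(classifySubstitution("C", "T"), "transition")
  expect_equal(classifySubstitution("C", "G"), "transversion")
  ## all 12 ordered pairs: 4 transitions, 8 transversions
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classifySubstitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_error(classifySubstitution("A", "A"), "differ")
})

test_that("the hand fixture is reduced to exactly its discriminating locus", {
  calls <- makeFiveLocusCalls()
  surv <- filterHomozygousDifferences(calls)
  expect_equal(nrow(surv), 1)
  expect_equal(surv$pos, 500)
  expect_equal(surv$wtGenotype, "hom_ref")
  expect_equal(surv$mutantGenotype, "hom_alt")
  expect_equal(surv$wtMeanDepth, mean(c(30, 40, 50)))
  flog <- attr(surv, "log")
  expect_equal(flog$input, 5)
  expect_equal(flog$removed_depth_or_replicates, 2) # depth-10 and missing
  expect_equal(flog$removed_heterozygous, 1)
  expect_equal(flog$removed_no_group_difference, 1)
  expect_equal(flog$output, 1)
})

test_that("a depth exactly at the threshold is filtered (strict rule)", {
  calls <- makeFiveLocusCalls()
  one <- calls[calls$pos == 100, ]
  expect_true(any(one$depth == 10))
  surv <- filterHomozygousDifferences(one)
  expect_equal(nrow(surv), 0)
  ## depth 11 passes
  one$depth[one$depth == 10] <- 11
  expect_equal(nrow(filterHomozygousDifferences(one)), 1)
})

test_that("group configuration errors are raised", {
  calls <- makeFiveLocusCalls()
  expect_error(
    filterHomozygousDifferences(calls[calls$sample != "WT-3", ]),
    "replicate")
  expect_error(
    filterHomozygousDifferences(calls[calls$group == "WT", ]),
    "two groups")
})

test_that("filtering is monotone in its thresholds and idempotent", {
  for (seed in 1:5) {
    cfg <- simulationConfig(seed = 300 + seed, replicatesPerGroup = 4,
                            genotypeErrorRate = 0.2, meanDepth = 20,
                            depthDispersion = 3, nTrueMutations = 30,
                            nBackgroundSnps = 10)
    ref <- simulateReference(cfg)
    truth <- plantMutations(ref$genome, ref$models, cfg)
    calls <- simulateVariantObservations(truth, cfg, ref$genome)
    key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    base <- filterHomozygousDifferences(calls, 10, 3)
    deeper <- filterHomozygousDifferences(calls, 15, 3)
    stricter <- filterHomozygousDifferences(calls, 10, 4)
    expect_true(all(key(deeper) %in% key(base)))
    expect_true(all(key(stricter) %in% key(base)))
    ## idempotence: re-filtering the surviving loci changes nothing
    again <- filterHomozygousDifferences(
      calls[key(calls) %in% key(base), ], 10, 3)
    attr(base, "log") <- NULL
    attr(again, "log") <- NULL
    expect_equal(again, base)
  }
})

test_that("spectrum summaries reproduce reported EMS percentages", {
  loci <- data.frame(
    ref = c(rep("A", 48), rep("C", 96), "G", "T"),
    alt = c(rep("G", 48), rep("T", 96), "T", "A"),
    stringsAsFactors = FALSE)
  s <- spectrumSummary(loci)
  expect_equal(s@total, 146L)
  expect_equal(unname(substitutionCounts(s)["C>T"]), 96L)
  expect_equal(unname(substitutionPercent(s)["C>T"]), 65.75)
  expect_equal(unname(substitutionPercent(s)["A>G"]), 32.88)
  expect_equal(transitionPercent(s), 98.63)
  expect_equal(transversionPercent(s), 1.37)
  ## conservation invariants
  expect_equal(sum(substitutionCounts(s)), s@total)
  expect_lt(abs(transitionPercent(s) + transversionPercent(s) - 100),
            0.011)
})

test_that("degenerate spectra are handled", {
  s <- spectrumSummary(data.frame(ref = rep("C", 5), alt = rep("T", 5)))
  expect_equal(unname(substitutionPercent(s)["C>T"]), 100)
  expect_true(is.na(tsTvFold(s)))
  expect_error(spectrumSummary(data.frame(ref = character(),
                                          alt = character())),
               "empty")
})

test_that("transition percent plus transversion percent is conserved", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    s <- spectrumSummary(data.frame(ref = ref, alt = alt))
    expect_equal(sum(substitutionCounts(s)), n)
    expect_equal(transitionCount(s) + transversionCount(s), n)
    expect_lt(abs(transitionPercent(s) + transversionPercent(s) - 100),
              0.011)
  }
})

test_that("region classification honours precedence and strand geometry", {
  toy <- makeToyReference()
  loci <- data.frame(
    chrom = "chrT",
    pos = c(3005,  # inside geneA exon
            550,   # between the two exons of geneC -> intron
            7515,  # 1500 bases 5' of minus-strand geneB -> upstream
            5500,  # 3' of geneB on its own strand -> downstream
            100,   # within 2 kb 5' of geneC -> upstream
            8990)) # beyond every flank -> intergenic
  reg <- locateRegion(loci, toy$models)
  expect_equal(reg$region, c("exon", "intron", "upstream", "downstream",
                             "upstream", "intergenic"))
  expect_equal(reg$geneId, c("geneA", "geneC", "geneB", "geneB",
                             "geneC", NA))
  ## narrower flank demotes the upstream call to intergenic
  reg2 <- locateRegion(loci[3, , drop = FALSE], toy$models, flank = 1000)
  expect_equal(reg2$region, "intergenic")
  expect_warning(
    out <- locateRegion(data.frame(chrom = "chrZ", pos = 5), toy$models),
    "absent")
  expect_equal(out$region, "intergenic")
})

test_that("codon effects match the genetic code on the plus strand", {
  toy <- makeToyReference()
  ## geneA codon 2 GGA -> GAA: Gly -> Glu
  eff <- annotateCodingEffect("chrT", 3005, "G", "A", toy$models,
                              toy$genome)
  expect_equal(eff$codingEffect, "nonsynonymous")
  expect_equal(eff$refCodon, "GGA")
  expect_equal(eff$altCodon, "GAA")
  expect_equal(eff$refAa, "G")
  expect_equal(eff$altAa, "E")
  expect_equal(eff$proteinPos, 2L)
  ## geneA codon 3 CAA -> TAA: stop gain
  eff <- annotateCodingEffect("chrT", 3007, "C", "T", toy$models,
                              toy$genome)
  expect_equal(eff$codingEffect, "stop_gain")
  ## third-position wobble in geneC codon 2 (AAA -> AAG): synonymous
  eff <- annotateCodingEffect("chrT", 506, "A", "G", toy$models,
                              toy$genome)
  expect_equal(eff$codingEffect, "synonymous")
  ## outside any CDS
  expect_error(annotateCodingEffect("chrT", 1000, "T", "A", toy$models,
                                    toy$genome), "no CDS")
  ## reference mismatch is caught
  expect_error(annotateCodingEffect("chrT", 3005, "C", "A", toy$models,
                                    toy$genome), "mismatch")
})

test_that("minus-strand annotation equals the full-protein oracle", {
  toy <- makeToyReference()
  cds <- cdsRanges(toy$models)[["geneB"]]
  chars <- strsplit(as.character(toy$genome[["chrT"]]), "")[[1]]
  for (pos in start(cds):end(cds)) {
    ref <- chars[pos]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- annotateCodingEffect("chrT", pos, ref, alt, toy$models,
                                  toy$genome)
      want <- oracleEffect(toy$genome, toy$models, "chrT", pos, ref, alt,
                           "geneB")
      expect_equal(got$codingEffect, want$effect,
                   label = sprintf("pos %d %s>%s", pos, ref, alt))
      if (want$effect != "synonymous")
        expect_equal(got$proteinPos, want$proteinPos)
    }
  }
})

test_that("strand symmetry: a minus-strand gene annotates like its flipped image", {
  toy <- makeToyReference()
  ## plus-strand image of geneB: place its coding sequence forward on a
  ## fresh chromosome at the same offset
  codB <- "ATGCATAAGGAGTGA"
  chars <- rep("T", 9000)
  chars[6001:6015] <- strsplit(codB, "")[[1]]
  genomeP <- DNAStringSet(paste0(chars, collapse = ""))
  names(genomeP) <- "chrT"
  genes <- GRanges("chrT", IRanges(6001, 6015), strand = "+")
  genes$gene_id <- "geneBplus"
  grl <- GRangesList(geneBplus = GRanges("chrT", IRanges(6001, 6015),
                                         strand = "+"))
  modelsP <- GeneModels(genes, grl, grl)
  charsM <- strsplit(as.character(toy$genome[["chrT"]]), "")[[1]]
  L <- 6015 + 6001  # coordinate flip within the gene: pos -> L - pos
  for (pos in 6001:6015) {
    ref <- charsM[pos]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      minus <- annotateCodingEffect("chrT", pos, ref, alt, toy$models,
                                    toy$genome, geneId = "geneB")
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      plus <- annotateCodingEffect("chrT", L - pos, unname(comp[ref]),
                                   unname(comp[alt]), modelsP, genomeP,
                                   geneId = "geneBplus")
      expect_equal(minus$codingEffect, plus$codingEffect)
      expect_equal(minus$refCodon, plus$refCodon)
      expect_equal(minus$altCodon, plus$altCodon)
      expect_equal(minus$proteinPos, plus$proteinPos)
    }
  }
})

test_that("effect class counts total the input and match truth labels", {
  counts <- effectClassCounts(data.frame())
  expect_equal(sum(counts$effect), 0)
  cfg <- simulationConfig(seed = 31, nTrueMutations = 80,
                          nBackgroundSnps = 20)
  ref <- simulateReference(cfg)
  truth <- plantMutations(ref$genome, ref$models, cfg)
  cc <- effectClassCounts(truth)
  expect_equal(cc$total, nrow(truth))
  expect_equal(sum(cc$effect), nrow(truth))
  expect_equal(sum(cc$region), nrow(truth))
  expect_equal(unname(cc$effect["nonsynonymous"]),
               sum(truth$codingEffect == "nonsynonymous"))
  expect_equal(unname(cc$region["intergenic"]),
               sum(truth$region == "intergenic"))
})
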