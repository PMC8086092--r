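test_that("a zero-gene config yields a genome with empty annotation", {
  cfg <- simulationConfig(seed = 1, nGenes = 0, nTrueMutations = 0,
                          nBackgroundSnps = 0, nDeGenes = 0,
                          pathwaySize = 0)
  ref <- simulateReference(cfg)
  expect_length(ref$genome, 2)
  expect_equal(length(ref$models), 0)
  p <- tempfile(fileext = ".gff3")
  writeGeneModels(ref$models, p)
  expect_equal(length(readGeneModels(p)), 0)
})

test_that("every simulated CDS is a clean open reading frame", {
  cfg <- simulationConfig(seed = 42, nGenes = 30, nDeGenes = 18,
                          pathwaySize = 10)
  ref <- simulateReference(cfg)
  strands <- as.character(strand(geneRanges(ref$models)))
  expect_setequal(unique(strands), c("+", "-"))
  for (gid in geneIds(ref$models)) {
    cds <- cdsRanges(ref$models)[[gid]]
    chrom <- as.character(seqnames(cds))[1]
    s <- paste0(vapply(seq_along(cds), function(i)
      as.character(subseq(ref$genome[[chrom]], start(cds)[i],
                          end(cds)[i])), character(1)), collapse = "")
    if (strands[match(gid, geneIds(ref$models))] == "-")
      s <- as.character(reverseComplement(DNAString(s)))
    expect_equal(nchar(s) %% 3, 0)
    aa <- as.character(translate(DNAString(s), no.init.codon = TRUE))
    expect_equal(substr(s, 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    ## no internal stop
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("requested genes that cannot fit raise a sizing error", {
  expect_error(
    simulateReference(simulationConfig(seed = 1, nGenes = 40,
                                       chromLength = 3000,
                                       nDeGenes = 0, pathwaySize = 0)),
    "do not fit")
})

test_that("identical config and seed give byte-identical artifacts", {
  cfg <- simulationConfig(seed = 11, nGenes = 20, chromLength = 60000,
                          nTrueMutations = 12, nBackgroundSnps = 5,
                          nDeGenes = 18, pathwaySize = 10)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  writeStudy(simulateStudy(cfg), d1)
  writeStudy(simulateStudy(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e7),
                     readBin(file.path(d2, f), "raw", n = 1e7),
                     label = f)
  }
})

test_that("a point-mass spectrum plants only that substitution", {
  cfg <- simulationConfig(seed = 5, emsSpectrum = c("C>T" = 1),
                          nTrueMutations = 25, nBackgroundSnps = 0)
  ref <- simulateReference(cfg)
  truth <- plantMutations(ref$genome, ref$models, cfg)
  expect_true(all(truth$ref == "C"))
  expect_true(all(truth$alt == "T"))
})

test_that("planted mutation types follow the configured spectrum", {
  cfg <- simulationConfig(seed = 19, nTrueMutations = 1000,
                          nBackgroundSnps = 0)
  ref <- simulateReference(cfg)
  truth <- plantMutations(ref$genome, ref$models, cfg)
  mass <- sum(truth$ref == "C" & truth$alt == "T" |
                truth$ref == "G" & truth$alt == "A") / nrow(truth)
  p <- sum(defaultEmsSpectrum()[c("C>T", "G>A")])
  expect_lt(abs(mass - p), 3 * sqrt(p * (1 - p) / nrow(truth)))

  ## chi-square goodness of fit at larger n
  cfg2 <- simulationConfig(seed = 20, nTrueMutations = 10000,
                           nBackgroundSnps = 0)
  ref2 <- simulateReference(cfg2)
  truth2 <- plantMutations(ref2$genome, ref2$models, cfg2)
  obs <- table(factor(paste0(truth2$ref, ">", truth2$alt),
                      levels = names(defaultEmsSpectrum())))
  gof <- suppressWarnings(
    chisq.test(as.integer(obs), p = defaultEmsSpectrum()))
  expect_gt(gof$p.value, 0.001)
})

test_that("truth labels agree with the annotation module (round trip)", {
  cfg <- simulationConfig(seed = 9, nTrueMutations = 60,
                          nBackgroundSnps = 10)
  ref <- simulateReference(cfg)
  truth <- plantMutations(ref$genome, ref$models, cfg)
  expect_equal(sum(truth$causal), 1)
  ann <- annotateVariants(truth[, c("chrom", "pos", "ref", "alt")],
                          ref$models, ref$genome)
  expect_identical(ann$region, truth$region)
  expect_identical(ann$codingEffect, truth$codingEffect)
  causal <- truth[truth$causal, ]
  eff <- annotateCodingEffect(causal$chrom, causal$pos, causal$ref,
                              causal$alt, ref$models, ref$genome)
  expect_equal(eff$codingEffect, "nonsynonymous")
  expect_equal(causal$mutantZygosity, "hom_alt")
})

test_that("noiseless deep observations always pass the full filter", {
  for (seed in 1:5) {
    cfg <- simulationConfig(seed = seed, genotypeErrorRate = 0,
                            meanDepth = 200, depthDispersion = 100,
                            nTrueMutations = 10, nBackgroundSnps = 5)
    ref <- simulateReference(cfg)
    truth <- plantMutations(ref$genome, ref$models, cfg)
    calls <- simulateVariantObservations(truth, cfg, ref$genome)
    surv <- filterHomozygousDifferences(calls)
    causal <- truth[truth$causal, ]
    expect_true(any(surv$chrom == causal$chrom & surv$pos == causal$pos),
                label = sprintf("seed %d", seed))
  }
})

test_that("background SNPs are shared by both groups and filtered out", {
  cfg <- simulationConfig(seed = 13, genotypeErrorRate = 0,
                          nTrueMutations = 8, nBackgroundSnps = 12)
  ref <- simulateReference(cfg)
  truth <- plantMutations(ref$genome, ref$models, cfg)
  bg <- truth[truth$class == "background", ]
  expect_true(all(bg$wtZygosity == bg$mutantZygosity))
  calls <- simulateVariantObservations(truth, cfg, ref$genome)
  surv <- filterHomozygousDifferences(calls)
  survKey <- paste(surv$chrom, surv$pos)
  expect_false(any(paste(bg$chrom, bg$pos) %in% survKey))
})

test_that("causal locus survives filtering in most seeds at defaults", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- simulationConfig(seed = seed)
    ref <- simulateReference(cfg)
    truth <- plantMutations(ref$genome, ref$models, cfg)
    calls <- simulateVariantObservations(truth, cfg, ref$genome)
    surv <- filterHomozygousDifferences(calls)
    causal <- truth[truth$causal, ]
    hits <- hits + any(surv$chrom == causal$chrom &
                         surv$pos == causal$pos)
  }
  expect_gte(hits, 18)
})

test_that("simulated counts carry the planted structure", {
  cfg <- simulationConfig(seed = 23)
  ref <- simulateReference(cfg)
  truth <- plantMutations(ref$genome, ref$models, cfg)
  se <- simulateCounts(ref$models, truth, cfg)
  expect_equal(dim(se), c(60L, 6L))
  expect_equal(sum(rowData(se)$isDe), 20)
  md <- S4Vectors::metadata(se)
  expect_equal(md$causalGene, truth$geneId[truth$causal])
  expect_true(md$causalGene %in% md$deGenes)
  expect_equal(sum(rowData(se)$inPathway), 16)
  ## pathway genes are coherently downregulated
  expect_true(all(rowData(se)$deDirection[rowData(se)$inPathway] ==
                    "down"))
  ## determinism
  se2 <- simulateCounts(ref$models, truth, cfg)
  expect_identical(assay(se), assay(se2))
})

test_that("planted fold changes are recovered as DEGs with the right sign", {
  hits <- 0; signOk <- TRUE
  for (seed in 1:20) {
    cfg <- simulationConfig(seed = 100 + seed)
    ref <- simulateReference(cfg)
    truth <- plantMutations(ref$genome, ref$models, cfg)
    se <- simulateCounts(ref$models, truth, cfg)
    deg <- deTest(se)
    cg <- S4Vectors::metadata(se)$causalGene
    row <- deg[deg$gene == cg, ]
    if (isTRUE(row$isDeg)) {
      hits <- hits + 1
      signOk <- signOk && row$direction == "down"
    }
  }
  expect_gte(hits, 18)
  expect_true(signOk)
})

test_that("noiseless Ct tables recover the configured true ratios", {
  cfg <- simulationConfig(seed = 3, ctNoiseSd = 0)
  ct <- simulateCtTable(cfg)
  res <- ddct(ct)
  tr <- attr(ct, "trueRatios")
  for (tg in names(tr)) {
    test <- res[res$target == tg & res$condition == "test", ]
    expect_equal(test$relExpression, rep(tr[[tg]], nrow(test)),
                 tolerance = 1e-12)
    cal <- res[res$target == tg & res$condition == "calibrator", ]
    expect_equal(cal$ddCt, rep(0, nrow(cal)), tolerance = 1e-12)
  }
})

test_that("noisy Ct replication recovers ratios within a few percent", {
  cfg <- simulationConfig(seed = 8, ctNoiseSd = 0.1, ctReplicates = 50,
                          ctTrueRatios = c(0.25, 0.5, 2))
  res <- ddct(simulateCtTable(cfg))
  tr <- attr(simulateCtTable(cfg), "trueRatios")
  for (tg in names(tr)) {
    est <- mean(res$relExpression[res$target == tg &
                                    res$condition == "test"])
    expect_lt(abs(est - tr[[tg]]) / tr[[tg]], 0.05)
  }
})
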