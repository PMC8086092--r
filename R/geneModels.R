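#' Construct a GeneModels object
#'
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param exons,cds `GRangesList`s named by gene id, ascending genomic
#'   order within each gene.
#' @return A validated [GeneModels-class] object.
#' @export
GeneModels <- function(genes = GRanges(),
                       exons = GRangesList(),
                       cds = GRangesList()) {
  new("GeneModels", genes = genes, exons = exons, cds = cds)
}

#' @rdname GeneModels
#' @param x a `GeneModels` object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels
#' @export
setMethod("geneIds", "GeneModels", function(x) {
  as.character(x@genes$gene_id)
})

#' @rdname GeneModels
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModels
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname GeneModels
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModels
#' @export
setMethod("exonRanges", "GeneModels", function(x) x@exons)

#' @rdname GeneModels
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname GeneModels
#' @export
setMethod("cdsRanges", "GeneModels", function(x) x@cds)

#' @rdname GeneModels
#' @details `geneLengths()` returns the summed exon width per gene (the
#'   transcript length used for FPKM); `cdsLengths()` the summed CDS width.
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname GeneModels
#' @export
setMethod("geneLengths", "GeneModels", function(x) {
  setNames(vapply(width(x@exons), sum, numeric(1)), geneIds(x))
})

#' @rdname GeneModels
#' @export
setGeneric("cdsLengths", function(x) standardGeneric("cdsLengths"))

#' @rdname GeneModels
#' @export
setMethod("cdsLengths", "GeneModels", function(x) {
  setNames(vapply(width(x@cds), sum, numeric(1)), geneIds(x))
})

setMethod("length", "GeneModels", function(x) length(x@genes))

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d genes on %d sequence(s)\n",
              length(object),
              length(unique(as.character(seqnames(object@genes))))))
  if (length(object)) {
    st <- table(as.character(strand(object@genes)))
    cat(sprintf("  strands: %s\n",
                paste(sprintf("%s: %d", names(st), st), collapse = ", ")))
    cat(sprintf("  CDS length: %d-%d nt\n",
                as.integer(min(cdsLengths(object))),
                as.integer(max(cdsLengths(object)))))
  }
})

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features (1-based, closed intervals) with CDS
#' phase computed in transcription order, via
#' \link[rtracklayer]{export}.
#'
#' @param models a [GeneModels-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  stopifnot(is(models, "GeneModels"))
  feats <- list()
  gr <- models@genes
  for (i in seq_along(gr)) {
    gid <- gr$gene_id[i]
    mid <- paste0(gid, ".t1")
    strandChar <- as.character(strand(gr[i]))
    g <- granges(gr[i])
    g$source <- "emscan"; g$type <- "gene"; g$ID <- gid
    m <- granges(gr[i])
    m$source <- "emscan"; m$type <- "mRNA"; m$ID <- mid; m$Parent <- gid
    ex <- models@exons[[gid]]
    ex$source <- "emscan"; ex$type <- "exon"; ex$Parent <- mid
    cds <- models@cds[[gid]]
    w <- width(cds)
    tx <- if (strandChar == "-") rev(seq_along(cds)) else seq_along(cds)
    phase <- integer(length(cds))
    done <- 0L
    for (j in tx) {
      phase[j] <- (3L - done %% 3L) %% 3L
      done <- done + w[j]
    }
    cds$source <- "emscan"; cds$type <- "CDS"; cds$Parent <- mid
    cds$phase <- phase
    feats[[length(feats) + 1L]] <- list(g, m, ex, cds)
  }
  if (length(feats)) {
    flat <- do.call(c, lapply(feats, function(f)
      suppressWarnings(do.call(c, lapply(f, function(x) {
        mc <- mcols(x)
        for (col in c("source", "type", "ID", "Parent", "phase"))
          if (is.null(mc[[col]])) mc[[col]] <- NA
        mcols(x) <- mc[, c("source", "type", "ID", "Parent", "phase")]
        x
      })))))
  } else {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rtracklayer::export(flat, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Rebuilds a [GeneModels-class] object from a GFF3 file containing
#' gene/mRNA/exon/CDS features linked by ID/Parent attributes (the dialect
#' written by [writeGeneModels()]; one mRNA per gene).
#'
#' @param path GFF3 file path.
#' @return A [GeneModels-class] object.
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  if (length(genes) == 0)
    return(GeneModels())
  genes <- genes[order(as.character(seqnames(genes)), start(genes))]
  gids <- as.character(genes$ID)
  mrna <- gff[gff$type == "mRNA"]
  mrnaParent <- vapply(mrna$Parent, `[[`, character(1), 1L)
  geneOfMrna <- setNames(mrnaParent, as.character(mrna$ID))
  pickChildren <- function(type) {
    ch <- gff[gff$type == type]
    par <- vapply(ch$Parent, `[[`, character(1), 1L)
    gid <- unname(geneOfMrna[par])
    out <- setNames(
      lapply(gids, function(g) {
        r <- granges(ch[!is.na(gid) & gid == g])
        sort(r)
      }), gids)
    GRangesList(out)
  }
  gr <- granges(genes)
  gr$gene_id <- gids
  GeneModels(genes = gr, exons = pickChildren("exon"),
             cds = pickChildren("CDS"))
}
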