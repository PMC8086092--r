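#' Classify a substitution as transition or transversion
#'
#' A substitution is a transition when both bases are purines (A, G) or
#' both are pyrimidines (C, T); otherwise it is a transversion.  Note that
#' some mutant-screen reports label C>G or G>T changes "transitions"; this
#' function uses the standard biochemical definition.
#'
#' @param ref,alt single reference and alternate bases (vectorized).
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
#' @examples
#' classifySubstitution("C", "T")  # transition
#' classifySubstitution("C", "G")  # transversion
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt))
    stop("ref and alt must have equal length")
  if (!all(ref %in% .BASES) || !all(alt %in% .BASES))
    stop("bases must be one of A, C, G, T")
  if (any(ref == alt))
    stop("ref and alt must differ")
  purine <- c("A", "G")
  ts <- (ref %in% purine) == (alt %in% purine)
  ifelse(ts, "transition", "transversion")
}

#' Summarize a substitution spectrum
#'
#' Tabulates the 12 ordered substitution types of a set of SNP loci
#' (recorded on the forward reference strand; complementary pairs such as
#' A>G and T>C are kept distinct), with transition/transversion rollups,
#' per-type percentages (rounded half-up to 2 decimals), and the
#' transition/transversion fold ratio reported both rounded half-up and
#' truncated to 2 decimals.
#'
#' @param loci data.frame with `ref` and `alt` single-base columns (extra
#'   columns are ignored).
#' @return A [SpectrumSummary-class] object.
#' @export
spectrumSummary <- function(loci) {
  if (is.null(nrow(loci)) || nrow(loci) == 0)
    stop("empty locus list: a spectrum summary needs at least one SNP")
  types <- paste0(toupper(loci$ref), ">", toupper(loci$alt))
  if (!all(types %in% .subTypes()))
    stop("loci contain invalid ref/alt bases")
  counts <- table(factor(types, levels = .subTypes()))
  counts <- setNames(as.integer(counts), .subTypes())
  tsTypes <- c("A>G", "G>A", "C>T", "T>C")
  transitions <- sum(counts[tsTypes])
  total <- sum(counts)
  transversions <- total - transitions
  pct <- roundHalfUp(100 * counts / total, 2)
  fold <- if (transversions == 0) NA_real_ else transitions / transversions
  new("SpectrumSummary",
      counts = counts,
      transitions = as.integer(transitions),
      transversions = as.integer(transversions),
      total = as.integer(total),
      percent = pct,
      transitionPercent = roundHalfUp(100 * transitions / total, 2),
      transversionPercent = roundHalfUp(100 * transversions / total, 2),
      tsTvFold = if (is.na(fold)) NA_real_ else roundHalfUp(fold, 2),
      tsTvFoldTruncated = if (is.na(fold)) NA_real_ else truncateTo(fold, 2))
}

#' @rdname SpectrumSummary-class
#' @param x a `SpectrumSummary` object.
#' @export
setGeneric("substitutionCounts",
           function(x) standardGeneric("substitutionCounts"))

#' @rdname SpectrumSummary-class
#' @export
setMethod("substitutionCounts", "SpectrumSummary", function(x) x@counts)

#' @rdname SpectrumSummary-class
#' @export
setGeneric("substitutionPercent",
           function(x) standardGeneric("substitutionPercent"))

#' @rdname SpectrumSummary-class
#' @export
setMethod("substitutionPercent", "SpectrumSummary", function(x) x@percent)

#' @rdname SpectrumSummary-class
#' @export
setGeneric("transitionCount", function(x) standardGeneric("transitionCount"))

#' @rdname SpectrumSummary-class
#' @export
setMethod("transitionCount", "SpectrumSummary", function(x) x@transitions)

#' @rdname SpectrumSummary-class
#' @export
setGeneric("transversionCount",
           function(x) standardGeneric("transversionCount"))

#' @rdname SpectrumSummary-class
#' @export
setMethod("transversionCount", "SpectrumSummary",
          function(x) x@transversions)

#' @rdname SpectrumSummary-class
#' @export
setGeneric("transitionPercent",
           function(x) standardGeneric("transitionPercent"))

#' @rdname SpectrumSummary-class
#' @export
setMethod("transitionPercent", "SpectrumSummary",
          function(x) x@transitionPercent)

#' @rdname SpectrumSummary-class
#' @export
setGeneric("transversionPercent",
           function(x) standardGeneric("transversionPercent"))

#' @rdname SpectrumSummary-class
#' @export
setMethod("transversionPercent", "SpectrumSummary",
          function(x) x@transversionPercent)

#' @rdname SpectrumSummary-class
#' @param truncated report the truncated (`TRUE`) or half-up rounded
#'   (`FALSE`) 2-decimal form of the transitions/transversions ratio.
#' @export
setGeneric("tsTvFold", function(x, truncated = TRUE)
  standardGeneric("tsTvFold"))

#' @rdname SpectrumSummary-class
#' @export
setMethod("tsTvFold", "SpectrumSummary", function(x, truncated = TRUE) {
  if (truncated) x@tsTvFoldTruncated else x@tsTvFold
})

#' Spectrum summary as a data.frame
#'
#' @param summary a [SpectrumSummary-class] object.
#' @return data.frame with one row per substitution type: type, class
#'   (transition/transversion), count, percent.
#' @export
spectrumTable <- function(summary) {
  stopifnot(is(summary, "SpectrumSummary"))
  types <- .subTypes()
  data.frame(
    type = types,
    class = classifySubstitution(substr(types, 1, 1), substr(types, 3, 3)),
    count = unname(summary@counts),
    percent = unname(summary@percent),
    stringsAsFactors = FALSE)
}

setMethod("show", "SpectrumSummary", function(object) {
  cat(sprintf("SpectrumSummary of %d SNPs\n", object@total))
  cat(sprintf("  transitions:   %6d (%.2f%%)\n",
              object@transitions, object@transitionPercent))
  cat(sprintf("  transversions: %6d (%.2f%%)\n",
              object@transversions, object@transversionPercent))
  if (is.na(object@tsTvFold)) {
    cat("  Ts/Tv fold: undefined (no transversions)\n")
  } else {
    cat(sprintf("  Ts/Tv fold: %.2f (truncated %.2f)\n",
                object@tsTvFold, object@tsTvFoldTruncated))
  }
  nz <- object@counts[object@counts > 0]
  if (length(nz))
    cat("  top types:",
        paste(sprintf("%s=%d", names(sort(nz, decreasing = TRUE)),
                      sort(nz, decreasing = TRUE)),
              collapse = " "), "\n")
})
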