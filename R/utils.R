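#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention used for the
#' percentages and ratios reported by this package), as opposed to base R's
#' round-half-to-even.  A small epsilon guards against binary representation
#' of values that are exact halves in decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(2.675, 2)   # 2.68 (base round() gives 2.67)
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Truncate to a number of decimal places
#'
#' Drops (never rounds) digits beyond `digits` decimals.  Fold ratios in
#' mutant-screen reports are conventionally truncated (17393/10615 is
#' reported as 1.63-fold, not 1.64).
#'
#' @inheritParams roundHalfUp
#' @return `x` truncated to `digits` decimals.
#' @export
truncateTo <- function(x, digits = 0) {
  f <- 10^digits
  trunc(x * f + sign(x) * sqrt(.Machine$double.eps)) / f
}

.BASES <- c("A", "C", "G", "T")

## ordered 12-type substitution catalogue, forward reference strand
.subTypes <- function() {
  unlist(lapply(.BASES, function(r) paste0(r, ">", setdiff(.BASES, r))))
}

.complement <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
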