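# Plain-text interchange: factorial CSV (parent1,parent2,yield), marker
# TSV (parent_id + one column per marker, -1/1), effects JSON, optional
# VCF import for inbred parents.

#' Read / write a factorial as CSV
#'
#' The CSV has a header `parent1,parent2,yield` and one row per realized
#' hybrid.
#'
#' @param path file path.
#' @return `readFactorial` returns a [Factorial-class].
#' @export
readFactorial <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  Factorial(df)
}

#' @rdname readFactorial
#' @param factorial a [Factorial-class] to write.
#' @export
writeFactorial <- function(factorial, path) {
  utils::write.csv(crosses(factorial), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a marker panel as TSV
#'
#' First column `parent_id`, one column per marker; entries -1/1, empty
#' or NA for missing.
#'
#' @param path file path.
#' @return `readMarkerPanel` returns a [MarkerPanel-class].
#' @export
readMarkerPanel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopifnot(names(df)[1] == "parent_id")
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df$parent_id
  storage.mode(g) <- "double"
  MarkerPanel(g)
}

#' @rdname readMarkerPanel
#' @param panel a [MarkerPanel-class] to write.
#' @export
writeMarkerPanel <- function(panel, path) {
  g <- genotypes(panel)
  df <- data.frame(parent_id = rownames(g), g, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write simulated true effects as a JSON manifest
#'
#' @param effects a `TrueEffects` list from [simulateFactorial()].
#' @param path file path.
#' @export
writeTrueEffects <- function(effects, path) {
  jsonlite::write_json(
    list(mu = effects$mu, gca1 = as.list(effects$gca1),
         gca2 = as.list(effects$gca2), sca = as.list(effects$sca)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import inbred-parent genotypes from a VCF
#'
#' Maps homozygous REF to -1, homozygous ALT to 1; heterozygous or
#' missing calls become NA (inbred parents are expected homozygous).
#' Requires the suggested package `vcfR`.
#'
#' @param path VCF file path (may be uncompressed).
#' @return A [MarkerPanel-class] (samples x markers).
#' @export
readMarkersVCF <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readMarkersVCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- -1
  code[gt %in% c("1/1", "1|1")] <- 1
  MarkerPanel(t(code))
}

#' Export a feature table as TSV
#'
#' Row keys are serialized as `parent1:parent2` in the first column;
#' missing values are written as `NA`.
#'
#' @param ft a [FeatureTable-class].
#' @param path file path.
#' @export
writeFeatureTable <- function(ft, path) {
  df <- data.frame(hybrid = rowKeys(ft), featureValues(ft),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
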