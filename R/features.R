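#' Encode hybrid parentage as predictors
#'
#' The parentage predictor set: for each hybrid only the identities of
#' its two parents. Non-one-hot encoding yields two nominal factor
#' columns (`parent1`, `parent2`); one-hot encoding yields n1 + n2 binary
#' indicator columns with exactly two active positions per row.
#'
#' @param factorial a [Factorial-class] providing the parent universe.
#' @param hybrids hybrid pairs (data.frame / matrix / list); defaults to
#'   the realized crosses.
#' @param onehot logical.
#' @return A [FeatureTable-class] of kind `parentage` or
#'   `parentage-onehot`.
#' @examples
#' f <- Factorial(data.frame(parent1 = c("A", "B"), parent2 = c("X", "Y"),
#'                           yield = 1:2))
#' encodeParentage(f, onehot = TRUE)
#' @export
encodeParentage <- function(factorial, hybrids = crosses(factorial),
                            onehot = FALSE) {
  stopifnot(is(factorial, "Factorial"))
  hy <- asPairs(hybrids)
  bad1 <- setdiff(unique(hy$parent1), parents1(factorial))
  bad2 <- setdiff(unique(hy$parent2), parents2(factorial))
  if (length(bad1) || length(bad2))
    stop(sprintf("unknown parent(s): %s", paste(c(bad1, bad2), collapse = ", ")))
  keys <- pairKey(hy$parent1, hy$parent2)
  if (!onehot) {
    vals <- data.frame(
      parent1 = factor(hy$parent1, levels = parents1(factorial)),
      parent2 = factor(hy$parent2, levels = parents2(factorial)))
    return(new("FeatureTable", rowKeys = keys, values = vals,
               encodingKind = "parentage", dropped = character()))
  }
  m1 <- outer(hy$parent1, parents1(factorial), `==`) * 1
  m2 <- outer(hy$parent2, parents2(factorial), `==`) * 1
  vals <- as.data.frame(cbind(m1, m2))
  names(vals) <- c(paste0("g1_", parents1(factorial)),
                   paste0("g2_", parents2(factorial)))
  new("FeatureTable", rowKeys = keys, values = vals,
      encodingKind = "parentage-onehot", dropped = character())
}

#' Encode cross-yield predictors
#'
#' For hybrid (i, j), the column of group-2 parent q holds the observed
#' yield of cross (i, q) and the column of group-1 parent p holds the
#' yield of cross (p, j) — i.e. the performance of each parent in its
#' other realized crosses. Yields of excluded pairs (the test-set guard)
#' and the hybrid's own yield never appear in its row; unrealized crosses
#' are missing. Columns that end up constant or all-missing are dropped
#' and recorded in the `dropped` slot. In sparse unbalanced factorials
#' the resulting table is mostly missing by construction.
#'
#' @param factorial a [Factorial-class].
#' @param hybrids hybrid pairs; defaults to the realized crosses.
#' @param exclude pairs whose yields must not appear anywhere in the
#'   table (must cover the response pairs being predicted).
#' @return A [FeatureTable-class] of kind `yield-features`.
#' @examples
#' f <- Factorial(data.frame(parent1 = c("A", "A", "B"),
#'                           parent2 = c("X", "Y", "X"),
#'                           yield = c(10, 12, 8)))
#' encodeYieldFeatures(f, exclude = data.frame(parent1 = "A", parent2 = "X"))
#' @export
encodeYieldFeatures <- function(factorial, hybrids = crosses(factorial),
                                exclude = NULL) {
  stopifnot(is(factorial, "Factorial"))
  hy <- asPairs(hybrids)
  cr <- crosses(factorial)
  yl <- stats::setNames(cr$yield, pairKey(cr$parent1, cr$parent2))
  if (!is.null(exclude) && nrow(asPairs(exclude))) {
    ex <- asPairs(exclude)
    yl <- yl[setdiff(names(yl), pairKey(ex$parent1, ex$parent2))]
  }
  p1 <- parents1(factorial)
  p2 <- parents2(factorial)
  keys <- pairKey(hy$parent1, hy$parent2)
  # group-2 parent columns: yield(i, q); group-1 parent columns: yield(p, j)
  m2 <- matrix(yl[pairKey(rep(hy$parent1, each = length(p2)),
                          rep(p2, times = nrow(hy)))],
               nrow = nrow(hy), byrow = TRUE,
               dimnames = list(NULL, paste0("g2_", p2)))
  m1 <- matrix(yl[pairKey(rep(p1, times = nrow(hy)),
                          rep(hy$parent2, each = length(p1)))],
               nrow = nrow(hy), byrow = TRUE,
               dimnames = list(NULL, paste0("g1_", p1)))
  vals <- cbind(m2, m1)
  # the hybrid's own yield never appears in its row
  own2 <- cbind(seq_len(nrow(hy)), match(paste0("g2_", hy$parent2), colnames(vals)))
  own1 <- cbind(seq_len(nrow(hy)), match(paste0("g1_", hy$parent1), colnames(vals)))
  vals[own2] <- NA_real_
  vals[own1] <- NA_real_
  vals <- as.data.frame(vals)
  # a column is uninformative when all-missing, or constant across two or
  # more observed entries; a single observed yield is kept
  constant <- vapply(vals, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || (length(v) >= 2 && max(v) - min(v) < 1e-12)
  }, logical(1))
  dropped <- names(vals)[constant]
  if (length(dropped))
    message(sprintf("dropping %d constant or all-missing yield-feature columns",
                    length(dropped)))
  new("FeatureTable", rowKeys = keys,
      values = vals[, !constant, drop = FALSE],
      encodingKind = "yield-features", dropped = dropped)
}

#' Encode virtual-hybrid marker genotypes
#'
#' Hybrid genotype at a locus is the parent-dosage midpoint
#' (x_parent1 + x_parent2) / 2: exactly -1, 0, 1 for homozygous first
#' allele, heterozygous, homozygous second allele when the parents carry
#' raw -1/1 codes, and an intermediate real dosage for imputed parents.
#'
#' @param panel1,panel2 imputed [MarkerPanel-class] objects for the two
#'   parent groups; must cover identical marker sets.
#' @param pairs hybrid pairs.
#' @return A [FeatureTable-class] of kind `markers`.
#' @examples
#' g1 <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "B"), "m1"))
#' g2 <- matrix(c(-1, 1), 2, 1, dimnames = list(c("X", "Y"), "m1"))
#' encodeHybridGenotypes(MarkerPanel(g1), MarkerPanel(g2),
#'                       data.frame(parent1 = "A", parent2 = "X"))
#' @export
encodeHybridGenotypes <- function(panel1, panel2, pairs) {
  stopifnot(is(panel1, "MarkerPanel"), is(panel2, "MarkerPanel"))
  g1 <- genotypes(panel1)
  g2 <- genotypes(panel2)
  if (!identical(colnames(g1), colnames(g2)))
    stop("the two panels must cover identical marker sets")
  if (anyNA(g1) || anyNA(g2))
    stop("panels must be imputed before building hybrid genotypes")
  pr <- asPairs(pairs)
  bad1 <- setdiff(unique(pr$parent1), rownames(g1))
  bad2 <- setdiff(unique(pr$parent2), rownames(g2))
  if (length(bad1) || length(bad2))
    stop(sprintf("unknown parent(s): %s", paste(c(bad1, bad2), collapse = ", ")))
  vals <- (g1[pr$parent1, , drop = FALSE] + g2[pr$parent2, , drop = FALSE]) / 2
  vals <- as.data.frame(vals, row.names = NULL)
  new("FeatureTable", rowKeys = pairKey(pr$parent1, pr$parent2),
      values = vals, encodingKind = "markers", dropped = character())
}

#' Combine two feature tables column-wise
#'
#' Merges the parentage-based predictors with genotypic marker data (or
#' any two tables over the same hybrids). Row keys must match in order;
#' column-name collisions are resolved by deterministic suffixing.
#'
#' @param parentage,markers two [FeatureTable-class] objects with
#'   identical row keys in identical order.
#' @return A [FeatureTable-class] of kind `combined`.
#' @examples
#' f <- Factorial(data.frame(parent1 = c("A", "B"), parent2 = c("X", "Y"),
#'                           yield = 1:2))
#' pa <- encodeParentage(f)
#' combineFeatures(pa, pa)
#' @export
combineFeatures <- function(parentage, markers) {
  stopifnot(is(parentage, "FeatureTable"), is(markers, "FeatureTable"))
  if (!identical(parentage@rowKeys, markers@rowKeys))
    stop("row keys differ between the two feature tables")
  vals <- cbind(parentage@values, markers@values)
  names(vals) <- make.unique(c(names(parentage@values),
                               names(markers@values)), sep = "_dup")
  new("FeatureTable", rowKeys = parentage@rowKeys, values = vals,
      encodingKind = "combined",
      dropped = union(parentage@dropped, markers@dropped))
}

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureTable", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("rowKeys", function(object) standardGeneric("rowKeys"))
#' @rdname accessors
#' @export
setMethod("rowKeys", "FeatureTable", function(object) object@rowKeys)

#' @rdname accessors
#' @export
setGeneric("encodingKind", function(object) standardGeneric("encodingKind"))
#' @rdname accessors
#' @export
setMethod("encodingKind", "FeatureTable", function(object) object@encodingKind)

# subset rows of a feature table (internal)
subsetFeatureTable <- function(ft, idx) {
  new("FeatureTable", rowKeys = ft@rowKeys[idx],
      values = ft@values[idx, , drop = FALSE],
      encodingKind = ft@encodingKind, dropped = ft@dropped)
}
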