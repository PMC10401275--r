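# internal helpers shared across modules

# hybrid key "parent1:parent2"; parent IDs must not contain ":"
pairKey <- function(parent1, parent2) paste(parent1, parent2, sep = ":")

splitPairKey <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(parent1 = vapply(parts, `[`, "", 1L),
             parent2 = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# coerce a pairs argument (data.frame, 2-col matrix, or list of length-2
# vectors) to a data.frame with character parent1/parent2
asPairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("parent1", "parent2") %in% names(pairs)))
    data.frame(parent1 = as.character(pairs$parent1),
               parent2 = as.character(pairs$parent2),
               stringsAsFactors = FALSE)
  } else if (is.matrix(pairs)) {
    data.frame(parent1 = as.character(pairs[, 1]),
               parent2 = as.character(pairs[, 2]),
               stringsAsFactors = FALSE)
  } else if (is.list(pairs)) {
    data.frame(parent1 = vapply(pairs, function(p) as.character(p[[1]]), ""),
               parent2 = vapply(pairs, function(p) as.character(p[[2]]), ""),
               stringsAsFactors = FALSE)
  } else {
    stop("pairs must be a data.frame, 2-column matrix, or list of pairs")
  }
}

# guarded Pearson correlation: error on degenerate observed vector is the
# caller's concern; constant predictions get r = 0 with a warning, the
# convention used for scoring stacked ensembles
safePearson <- function(yObs, yPred) {
  if (stats::sd(yPred) < 1e-12) {
    warning("constant predictions; reporting correlation 0")
    return(0)
  }
  stats::cor(yObs, yPred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
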