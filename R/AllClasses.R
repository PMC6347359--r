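#' SLInteractionSet: a canonical set of synthetic-lethal gene pairs
#'
#' Stores unordered human (or yeast) gene pairs in canonical order together
#' with their provenance: \code{"yeast_derived"} for pairs transferred from a
#' genetic-interaction screen via orthology, \code{"predicted"} for pairs
#' called by the classifier. A pair supported by both routes carries both
#' tags.
#'
#' @slot pairs data.frame with character columns \code{gene_a},
#'   \code{gene_b} (canonical order, no self-pairs, no duplicates) and
#'   \code{provenance} (one or more of \code{yeast_derived},
#'   \code{predicted}, semicolon-separated).
#'
#' @seealso \code{\link{SLInteractionSet}} (constructor),
#'   \code{\link{slPairs}}, \code{\link{geneUniverse}},
#'   \code{\link{mergeSLSets}}
#' @export
setClass("SLInteractionSet", slots = c(pairs = "data.frame"))

.validProvenance <- c("yeast_derived", "predicted")

setValidity("SLInteractionSet", function(object) {
  p <- object@pairs
  msgs <- character()
  need <- c("gene_a", "gene_b", "provenance")
  if (!all(need %in% names(p))) {
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  }
  if (any(p$gene_a == p$gene_b)) msgs <- c(msgs, "self-pairs are not allowed")
  if (nrow(p)) {
    o <- .orderPair(p$gene_a, p$gene_b)
    if (any(o$a != p$gene_a)) {
      msgs <- c(msgs, "pairs must be stored in canonical order")
    }
    if (anyDuplicated(.pairKey(p$gene_a, p$gene_b))) {
      msgs <- c(msgs, "duplicate pairs are not allowed")
    }
    tags <- unique(unlist(strsplit(p$provenance, ";", fixed = TRUE)))
    if (!all(tags %in% .validProvenance)) {
      msgs <- c(msgs, paste("provenance tags must be in",
                            paste(.validProvenance, collapse = "/")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an SLInteractionSet
#'
#' Canonicalizes the supplied pairs (drops self-pairs, collapses ordered and
#' reversed duplicates) and attaches provenance tags. Duplicated pairs with
#' different provenance keep the union of tags.
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b} and
#'   optionally \code{provenance}.
#' @param provenance Default provenance tag applied where the input has no
#'   provenance column.
#' @return An \linkS4class{SLInteractionSet}.
#' @examples
#' SLInteractionSet(data.frame(gene_a = c("VEGFA", "BCL2"),
#'                             gene_b = c("BCL2", "PARP1")))
#' @export
SLInteractionSet <- function(pairs = data.frame(gene_a = character(),
                                                gene_b = character()),
                             provenance = "yeast_derived") {
  stopifnot(is.data.frame(pairs))
  prov <- if ("provenance" %in% names(pairs)) {
    as.character(pairs$provenance)
  } else {
    rep(provenance, nrow(pairs))
  }
  a <- as.character(pairs$gene_a)
  b <- as.character(pairs$gene_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; prov <- prov[keep]
  o <- .orderPair(a, b)
  key <- .pairKey(o$a, o$b)
  first <- !duplicated(key)
  # union of provenance tags per pair (vectorised over the tag vocabulary)
  tagList <- strsplit(prov, ";", fixed = TRUE)
  expKey <- rep(key, lengths(tagList))
  expTag <- unlist(tagList)
  k0 <- key[first]
  hasY <- k0 %in% expKey[expTag == "yeast_derived"]
  hasP <- k0 %in% expKey[expTag == "predicted"]
  u <- c("", "yeast_derived", "predicted",
         "yeast_derived;predicted")[1L + hasY + 2L * hasP]
  df <- data.frame(gene_a = o$a[first], gene_b = o$b[first],
                   provenance = u, stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  new("SLInteractionSet", pairs = df)
}

#' @describeIn SLInteractionSet-class Number of pairs in the set.
#' @param x An \code{SLInteractionSet}.
#' @export
setMethod("length", "SLInteractionSet", function(x) nrow(x@pairs))

setMethod("show", "SLInteractionSet", function(object) {
  p <- object@pairs
  cat("SLInteractionSet with", nrow(p), "pairs over",
      length(geneUniverse(object)), "genes\n")
  if (nrow(p)) {
    tab <- table(p$provenance)
    cat("  provenance:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    print(head(p, 4L))
    if (nrow(p) > 4L) cat("  ...\n")
  }
  invisible(NULL)
})

#' Accessors for SLInteractionSet
#'
#' \code{slPairs} returns the underlying canonical pair table;
#' \code{geneUniverse} the sorted set of all endpoint genes;
#' \code{containsPair} a logical vector saying whether each supplied
#' unordered pair belongs to the set.
#'
#' @param x An \linkS4class{SLInteractionSet}.
#' @return \code{slPairs}: data.frame; \code{geneUniverse}: character
#'   vector; \code{containsPair}: logical vector.
#' @examples
#' sl <- SLInteractionSet(data.frame(gene_a = "BCL2", gene_b = "VEGFA"))
#' slPairs(sl)
#' geneUniverse(sl)
#' containsPair(sl, "VEGFA", "BCL2")
#' @export
slPairs <- function(x) {
  stopifnot(is(x, "SLInteractionSet"))
  x@pairs
}

#' @rdname slPairs
#' @export
geneUniverse <- function(x) {
  stopifnot(is(x, "SLInteractionSet"))
  sort(unique(c(x@pairs$gene_a, x@pairs$gene_b)), method = "radix")
}

#' @rdname slPairs
#' @param gene_a,gene_b Character vectors of endpoint genes (recycled).
#' @export
containsPair <- function(x, gene_a, gene_b) {
  stopifnot(is(x, "SLInteractionSet"))
  o <- .orderPair(as.character(gene_a), as.character(gene_b))
  .pairKey(o$a, o$b) %in% .pairKey(x@pairs$gene_a, x@pairs$gene_b)
}

#' Merge two SL interaction sets
#'
#' Set union of the pairs; a pair present in both inputs keeps the union of
#' its provenance tags. The size identity |A union B| = |A| + |B| - |A
#' intersect B| holds by construction.
#'
#' @param a,b \linkS4class{SLInteractionSet} objects.
#' @return An \linkS4class{SLInteractionSet}.
#' @examples
#' a <- SLInteractionSet(data.frame(gene_a = "A", gene_b = "B"))
#' b <- SLInteractionSet(data.frame(gene_a = "B", gene_b = "C"),
#'                       provenance = "predicted")
#' length(mergeSLSets(a, b))
#' @export
mergeSLSets <- function(a, b) {
  stopifnot(is(a, "SLInteractionSet"), is(b, "SLInteractionSet"))
  SLInteractionSet(rbind(a@pairs, b@pairs))
}

#' Read / write an SL pair table
#'
#' The on-disk format is a TSV with header \code{gene_a}, \code{gene_b},
#' \code{provenance}, one row per canonical pair. Writing then re-reading a
#' set reproduces it exactly.
#'
#' @param x An \linkS4class{SLInteractionSet}.
#' @param file Path to a TSV file.
#' @return \code{readSLSet} returns an \linkS4class{SLInteractionSet};
#'   \code{writeSLSet} returns \code{file} invisibly.
#' @export
writeSLSet <- function(x, file) {
  stopifnot(is(x, "SLInteractionSet"))
  write.table(x@pairs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSLSet
#' @export
readSLSet <- function(file) {
  df <- read.delim(file, colClasses = "character")
  SLInteractionSet(df)
}

#' SLClassifier: a fitted SL random-forest model with its metadata
#'
#' Wraps the fitted tree ensemble together with everything needed to apply
#' it safely: the tree-count grid searched, the cross-validated accuracy per
#' grid point, the chosen ensemble size, the RNG seed and the feature-order
#' version the model was trained under (checked at prediction time).
#'
#' @slot forest The fitted \code{randomForest} object.
#' @slot ntree Chosen ensemble size.
#' @slot grid Integer vector of candidate ensemble sizes.
#' @slot cvAccuracy Mean cross-validated accuracy per grid point.
#' @slot seed Integer seed used for fold assignment and fitting.
#' @slot featureVersion Feature-order version string.
#' @seealso \code{\link{trainClassifier}}, \code{\link{predictCandidates}}
#' @export
setClass("SLClassifier",
         slots = c(forest = "ANY", ntree = "integer", grid = "integer",
                   cvAccuracy = "numeric", seed = "integer",
                   featureVersion = "character"))

setMethod("show", "SLClassifier", function(object) {
  cat("SLClassifier (random forest,", object@ntree, "trees)\n")
  cat("  grid searched:", paste(object@grid, collapse = ", "), "\n")
  cat("  CV accuracy:  ",
      paste(sprintf("%.3f", object@cvAccuracy), collapse = ", "), "\n")
  cat("  feature version:", object@featureVersion,
      " seed:", object@seed, "\n")
  invisible(NULL)
})
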