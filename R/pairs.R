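# Canonical unordered gene pairs.
#
# All pair-valued containers in the package store pairs in canonical order:
# gene_a precedes gene_b under byte-wise (C locale) lexicographic ordering,
# so pair identity is independent of the locale R happens to run under.

# Byte-order rank of each string within the pooled vocabulary.
.cRank <- function(x) {
  u <- sort(unique(x), method = "radix")
  match(x, u)
}

# Vectorised canonical ordering of two gene vectors: list(a, b) with a < b.
.orderPair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (!length(a)) return(list(a = character(), b = character()))
  pool <- c(a, b)
  r <- .cRank(pool)
  n <- length(a)
  ra <- r[seq_len(n)]
  rb <- r[n + seq_len(n)]
  swap <- ra > rb
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

.pairKey <- function(a, b) paste(a, b, sep = "\r")

#' Canonicalize a table of gene pairs
#'
#' Orders every pair so that \code{gene_a} precedes \code{gene_b} under a
#' fixed byte-wise lexicographic ordering, removes self-pairs, and collapses
#' duplicates (including reversed duplicates) to a single row.
#'
#' @param pairs A data.frame with character columns \code{gene_a} and
#'   \code{gene_b} (additional columns are dropped).
#' @return A data.frame with columns \code{gene_a}, \code{gene_b}; one row
#'   per distinct unordered pair, rows sorted canonically.
#' @examples
#' canonicalizePairs(data.frame(gene_a = c("B", "A", "A"),
#'                              gene_b = c("A", "B", "A")))
#' @export
canonicalizePairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  a <- as.character(pairs$gene_a)
  b <- as.character(pairs$gene_b)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  o <- .orderPair(a, b)
  key <- .pairKey(o$a, o$b)
  dup <- duplicated(key)
  out <- data.frame(gene_a = o$a[!dup], gene_b = o$b[!dup],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All C(n,2) canonical pairs over a gene vector, as a data.frame.
.allPairs <- function(genes) {
  genes <- sort(unique(as.character(genes)), method = "radix")
  if (length(genes) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- combn(length(genes), 2L)
  data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}
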