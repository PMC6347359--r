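# Yeast screen -> human SL pairs.
#
# A genetic-interaction screen records a fitness-epistasis score (epsilon)
# and a p-value per double knockout. Strongly negative epsilon at low p is
# the operational definition of a synthetic-lethal-like (aggravating)
# interaction; the retained yeast pairs are then transferred to human gene
# symbols through the union of several orthology resources.

#' Read a genetic-interaction screen table
#'
#' Expects a TSV with header columns \code{query_gene}, \code{array_gene},
#' \code{epsilon}, \code{p_value} (one double-knockout measurement per row).
#'
#' @param file Path to the TSV.
#' @return data.frame with those four columns.
#' @export
readGeneticInteractions <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("query_gene", "array_gene", "epsilon", "p_value")
  if (!all(need %in% names(df))) {
    stop("screen file must have columns ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Filter a screen for synthetic-lethal (aggravating) interactions
#'
#' Retains measurements with \code{p_value < pMax} and
#' \code{epsilon < epsMax} (both strict), i.e. significantly negative
#' genetic interactions, and collapses them to canonical unordered gene
#' pairs: reversed query/array duplicates become one pair and self-pairs
#' are dropped.
#'
#' @param records data.frame of screen measurements with columns
#'   \code{query_gene}, \code{array_gene}, \code{epsilon}, \code{p_value}.
#' @param pMax Significance cutoff (default 0.05).
#' @param epsMax Interaction-score cutoff (default -0.08); only scores
#'   strictly below it are retained.
#' @return data.frame of canonical pairs (\code{gene_a}, \code{gene_b}).
#'   Rows with a p-value outside [0,1], a non-finite epsilon or an empty
#'   gene identifier raise an error naming the offending rows.
#' @examples
#' rec <- data.frame(query_gene = c("YA", "YB"), array_gene = c("YB", "YA"),
#'                   epsilon = c(-0.2, -0.3), p_value = c(0.001, 0.01))
#' filterNegativeInteractions(rec)
#' @export
filterNegativeInteractions <- function(records, pMax = 0.05, epsMax = -0.08) {
  stopifnot(is.data.frame(records))
  need <- c("query_gene", "array_gene", "epsilon", "p_value")
  stopifnot(all(need %in% names(records)))
  p <- records$p_value
  e <- records$epsilon
  bad <- which(!is.finite(p) | p < 0 | p > 1 | !is.finite(e) |
                 !nzchar(records$query_gene) | !nzchar(records$array_gene))
  if (length(bad)) {
    stop("malformed screen rows (p-value outside [0,1], non-finite epsilon ",
         "or empty gene): rows ",
         paste(head(bad, 10L), collapse = ", "))
  }
  keep <- p < pMax & e < epsMax
  canonicalizePairs(data.frame(gene_a = records$query_gene[keep],
                               gene_b = records$array_gene[keep],
                               stringsAsFactors = FALSE))
}

#' Read an ortholog table
#'
#' Expects a TSV with header columns \code{yeast_gene}, \code{human_gene},
#' \code{source}.
#'
#' @param file Path to the TSV.
#' @return data.frame with those three columns, duplicate rows removed.
#' @export
readOrthologTable <- function(file) {
  df <- read.delim(file, colClasses = "character")
  need <- c("yeast_gene", "human_gene", "source")
  if (!all(need %in% names(df))) {
    stop("ortholog file must have columns ", paste(need, collapse = ", "))
  }
  unique(df[need])
}

#' Merge ortholog assignments from several resources
#'
#' A yeast gene's human image is the union of its assignments across all
#' supplied tables; resources are treated symmetrically and repeated
#' records are idempotent.
#'
#' @param tables A list of ortholog data.frames (columns \code{yeast_gene},
#'   \code{human_gene}; a \code{source} column is ignored for the union).
#' @return Named list mapping each yeast gene to the sorted character
#'   vector of its human orthologs.
#' @examples
#' mergeOrthologSources(list(
#'   data.frame(yeast_gene = "y1", human_gene = "H1"),
#'   data.frame(yeast_gene = "y1", human_gene = "H2")))
#' @export
mergeOrthologSources <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  all <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(all(c("yeast_gene", "human_gene") %in% names(t)))
    ok <- nzchar(t$yeast_gene) & nzchar(t$human_gene)
    data.frame(yeast_gene = as.character(t$yeast_gene)[ok],
               human_gene = as.character(t$human_gene)[ok],
               stringsAsFactors = FALSE)
  }))
  all <- unique(all)
  lapply(split(all$human_gene, all$yeast_gene),
         function(h) sort(unique(h), method = "radix"))
}

#' Map yeast SL pairs to human gene pairs
#'
#' Each yeast pair (y1, y2) is expanded to every canonical human pair
#' (h1, h2) with h1 an ortholog of y1 and h2 an ortholog of y2. A pair with
#' either endpoint lacking any human ortholog contributes nothing; human
#' self-pairs (both endpoints mapping to the same symbol) are excluded; the
#' result is deduplicated.
#'
#' @param yeastPairs data.frame of canonical yeast pairs (\code{gene_a},
#'   \code{gene_b}), e.g. from \code{\link{filterNegativeInteractions}}.
#' @param orthologMap Named list from \code{\link{mergeOrthologSources}}.
#' @return An \linkS4class{SLInteractionSet} with provenance
#'   \code{"yeast_derived"}.
#' @examples
#' yp <- data.frame(gene_a = "y1", gene_b = "y2")
#' mapPairsToHuman(yp, list(y1 = c("H1", "H3"), y2 = "H2"))
#' @export
mapPairsToHuman <- function(yeastPairs, orthologMap) {
  stopifnot(is.data.frame(yeastPairs), is.list(orthologMap))
  out_a <- character()
  out_b <- character()
  for (i in seq_len(nrow(yeastPairs))) {
    ha <- orthologMap[[yeastPairs$gene_a[i]]]
    hb <- orthologMap[[yeastPairs$gene_b[i]]]
    if (is.null(ha) || is.null(hb)) next
    grid <- expand.grid(a = ha, b = hb, stringsAsFactors = FALSE)
    out_a <- c(out_a, grid$a)
    out_b <- c(out_b, grid$b)
  }
  SLInteractionSet(data.frame(gene_a = out_a, gene_b = out_b,
                              stringsAsFactors = FALSE),
                   provenance = "yeast_derived")
}
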