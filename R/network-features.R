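# Per-node graph statistics and per-pair feature vectors on the human
# gene-interaction network.
#
# Conventions (fixed; only relative values feed the classifier):
#   * betweenness  — unnormalized count of dependent shortest-path pairs,
#     endpoints excluded (the classical Freeman count on the undirected
#     graph, each unordered pair counted once).
#   * closeness    — component-restricted: (n_c - 1) / sum of distances to
#     the other members of the node's connected component (n_c = component
#     size); 0 for isolated nodes. Lies in [0, 1].
#   * clustering   — local clustering coefficient; 0 for degree < 2.
#   * shortest path between disconnected nodes — sentinel value equal to
#     the number of nodes in the network, i.e. one more than any realizable
#     hop count ("farther than any real path"), keeping features finite and
#     ordinal.

#' Annotation namespaces used for pair features
#'
#' The five per-gene annotation namespaces feeding the Dice-coefficient
#' features: KEGG pathways, PANTHER pathways, a GO slim, MeSH disease
#' associations and drug associations.
#'
#' @return Character vector of the five namespace names, in feature order.
#' @export
slNamespaces <- function() {
  c("pathway_kegg", "pathway_panther", "go_slim", "disease_mesh",
    "drug_assoc")
}

#' Feature-order version
#'
#' Identifier of the frozen 10-feature layout (5 Dice values, 4 endpoint
#' mean statistics, shortest path). Feature tables carry it and
#' \code{\link{predictCandidates}} refuses tables whose version differs
#' from the model's, so a trained model is never silently applied to
#' reordered features.
#'
#' @return A version string.
#' @export
slFeatureVersion <- function() "slfeat/1"

#' @rdname slFeatureVersion
#' @export
slFeatureNames <- function() {
  c(paste0("dice_", slNamespaces()),
    paste0("mean_", c("degree", "betweenness", "closeness", "clustering")),
    "shortest_path")
}

#' Dice coefficient of two term sets
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 0 when both sets are empty
#' (two genes about which nothing is annotated carry no evidence of
#' similarity).
#'
#' @param a,b Character vectors of term identifiers (duplicates ignored).
#' @return A number in [0, 1].
#' @examples
#' diceCoefficient(c("k1", "k2"), c("k2", "k3"))  # 0.5
#' @export
diceCoefficient <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  denom <- length(a) + length(b)
  if (denom == 0L) return(0)
  2 * length(intersect(a, b)) / denom
}

#' Build an interaction network from an edge list
#'
#' Returns a simple undirected \pkg{igraph} graph: self-loops and duplicate
#' (including reversed) edges are removed. \code{isolates} adds named nodes
#' that have no edges.
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b}.
#' @param isolates Optional character vector of additional node names.
#' @return An \code{igraph} object.
#' @export
makeNetwork <- function(edges, isolates = character()) {
  stopifnot(is.data.frame(edges))
  edges <- canonicalizePairs(edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  extra <- setdiff(isolates, igraph::V(g)$name)
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  igraph::simplify(g)
}

#' @rdname makeNetwork
#' @param file Path to an edge-list TSV with header \code{gene_a},
#'   \code{gene_b}.
#' @export
readNetwork <- function(file) {
  makeNetwork(read.delim(file, colClasses = "character"))
}

#' Per-node graph statistics
#'
#' Degree, unnormalized betweenness, component-restricted closeness and
#' local clustering coefficient for every node (see the conventions in the
#' package vignette). Deterministic for a given graph.
#'
#' @param network An \code{igraph} object.
#' @return data.frame with columns \code{gene}, \code{degree},
#'   \code{betweenness}, \code{closeness}, \code{clustering}; one row per
#'   node. Empty graph gives zero rows.
#' @export
nodeStatistics <- function(network) {
  stopifnot(inherits(network, "igraph"))
  n <- igraph::vcount(network)
  if (n == 0L) {
    return(data.frame(gene = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      clustering = numeric()))
  }
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(network)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else length(di) / sum(di)
  }, numeric(1))
  clu <- igraph::transitivity(network, type = "local", isolates = "zero")
  data.frame(gene = igraph::V(network)$name, degree = as.integer(deg),
             betweenness = as.numeric(btw), closeness = clo,
             clustering = as.numeric(clu), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Shortest-path hop count between two genes
#'
#' Minimal number of edges between \code{a} and \code{b}; for nodes in
#' different components the disconnected sentinel (number of nodes in the
#' network) is returned.
#'
#' @param network An \code{igraph} object.
#' @param a,b Node names; unknown names raise an error naming the gene.
#' @return Non-negative number of hops, or the sentinel.
#' @export
shortestPathLength <- function(network, a, b) {
  stopifnot(inherits(network, "igraph"))
  nodes <- igraph::V(network)$name
  for (g in c(a, b)) {
    if (!g %in% nodes) stop("unknown node: ", g)
  }
  d <- igraph::distances(network, v = a, to = b)[1, 1]
  if (is.infinite(d)) igraph::vcount(network) else as.numeric(d)
}

#' Turn a long annotation table into per-gene profiles
#'
#' @param annotations data.frame with columns \code{gene},
#'   \code{namespace}, \code{term} (one term per row).
#' @param namespaces Namespace vocabulary; rows outside it raise an error.
#' @return Named list: for each gene a named list of per-namespace term
#'   vectors (all namespaces present, possibly empty).
#' @export
annotationProfiles <- function(annotations, namespaces = slNamespaces()) {
  stopifnot(is.data.frame(annotations),
            all(c("gene", "namespace", "term") %in% names(annotations)))
  bad <- setdiff(unique(annotations$namespace), namespaces)
  if (length(bad)) stop("unknown namespace(s): ", paste(bad, collapse = ", "))
  empty <- stats::setNames(
    replicate(length(namespaces), character(), simplify = FALSE), namespaces)
  byGene <- split(annotations[c("namespace", "term")], annotations$gene)
  lapply(byGene, function(df) {
    p <- empty
    for (ns in unique(df$namespace)) {
      p[[ns]] <- unique(df$term[df$namespace == ns])
    }
    p
  })
}

#' @rdname annotationProfiles
#' @param file Path to a TSV with header \code{gene}, \code{namespace},
#'   \code{term}.
#' @export
readAnnotations <- function(file, namespaces = slNamespaces()) {
  annotationProfiles(read.delim(file, colClasses = "character"), namespaces)
}

#' Genes annotated in every required namespace
#'
#' Mirrors the restriction of the modeling universe to highly annotated
#' genes: a gene qualifies only if it has at least one term in each
#' required namespace.
#'
#' @param profiles Profiles from \code{\link{annotationProfiles}}.
#' @param required Namespaces that must all be non-empty.
#' @return Sorted character vector of qualifying genes.
#' @export
eligibleNodes <- function(profiles, required = slNamespaces()) {
  ok <- vapply(profiles, function(p) {
    all(vapply(required, function(ns) length(p[[ns]]) > 0L, logical(1)))
  }, logical(1))
  sort(names(profiles)[ok], method = "radix")
}

#' Feature vector for one gene pair
#'
#' The 10 features, in frozen order: Dice coefficient of the two genes'
#' term sets in each of the five namespaces; the endpoint means of degree,
#' betweenness, closeness and clustering; and the shortest-path hop count
#' (disconnected sentinel = network size). Symmetric under endpoint swap.
#'
#' @param gene_a,gene_b Endpoint gene symbols.
#' @param profiles Profiles from \code{\link{annotationProfiles}}; missing
#'   genes raise an error naming the gene, unless \code{permissive} is set,
#'   in which case missing namespaces are treated as empty term sets.
#' @param nodeStats data.frame from \code{\link{nodeStatistics}}.
#' @param network The \code{igraph} network.
#' @param permissive Treat genes absent from \code{profiles} as carrying
#'   empty term sets (default \code{FALSE}).
#' @return Named numeric vector of length 10 (names
#'   \code{slFeatureNames()}).
#' @export
buildPairFeatures <- function(gene_a, gene_b, profiles, nodeStats, network,
                              permissive = FALSE) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% nodeStats$gene) stop("gene not in network: ", g)
    if (!permissive && is.null(profiles[[g]])) {
      stop("gene not in annotation profiles: ", g)
    }
  }
  empty <- stats::setNames(
    replicate(length(slNamespaces()), character(), simplify = FALSE),
    slNamespaces())
  pa <- if (is.null(profiles[[gene_a]])) empty else profiles[[gene_a]]
  pb <- if (is.null(profiles[[gene_b]])) empty else profiles[[gene_b]]
  dice <- vapply(slNamespaces(), function(ns) {
    diceCoefficient(pa[[ns]], pb[[ns]])
  }, numeric(1))
  ia <- match(gene_a, nodeStats$gene)
  ib <- match(gene_b, nodeStats$gene)
  cols <- c("degree", "betweenness", "closeness", "clustering")
  means <- vapply(cols, function(cn) {
    mean(c(nodeStats[[cn]][ia], nodeStats[[cn]][ib]))
  }, numeric(1))
  sp <- shortestPathLength(network, gene_a, gene_b)
  stats::setNames(c(dice, means, sp), slFeatureNames())
}

#' Feature table for many gene pairs
#'
#' Vectorised version of \code{\link{buildPairFeatures}}: computes the
#' 10-feature vector for every row of a pair table, using a single
#' all-pairs distance computation. The result carries the feature-order
#' version as attribute \code{"feature_version"}.
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b}.
#' @inheritParams buildPairFeatures
#' @return data.frame: \code{gene_a}, \code{gene_b} plus the 10 feature
#'   columns.
#' @export
pairFeatureMatrix <- function(pairs, profiles, nodeStats, network,
                              permissive = FALSE) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L)
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  missNet <- setdiff(genes, nodeStats$gene)
  if (length(missNet)) {
    stop("gene not in network: ", paste(head(missNet, 5L), collapse = ", "))
  }
  if (!permissive) {
    missAnn <- setdiff(genes, names(profiles))
    if (length(missAnn)) {
      stop("gene not in annotation profiles: ",
           paste(head(missAnn, 5L), collapse = ", "))
    }
  }
  d <- igraph::distances(network, v = genes, to = genes)
  sentinel <- igraph::vcount(network)
  empty <- stats::setNames(
    replicate(length(slNamespaces()), character(), simplify = FALSE),
    slNamespaces())
  statIdxA <- match(pairs$gene_a, nodeStats$gene)
  statIdxB <- match(pairs$gene_b, nodeStats$gene)
  feat <- matrix(NA_real_, nrow(pairs), 10L,
                 dimnames = list(NULL, slFeatureNames()))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    pa <- if (is.null(profiles[[ga]])) empty else profiles[[ga]]
    pb <- if (is.null(profiles[[gb]])) empty else profiles[[gb]]
    feat[i, 1:5] <- vapply(slNamespaces(), function(ns) {
      diceCoefficient(pa[[ns]], pb[[ns]])
    }, numeric(1))
  }
  cols <- c("degree", "betweenness", "closeness", "clustering")
  for (j in seq_along(cols)) {
    feat[, 5L + j] <- (nodeStats[[cols[j]]][statIdxA] +
                         nodeStats[[cols[j]]][statIdxB]) / 2
  }
  sp <- d[cbind(match(pairs$gene_a, genes), match(pairs$gene_b, genes))]
  feat[, 10L] <- ifelse(is.infinite(sp), sentinel, sp)
  out <- cbind(pairs[c("gene_a", "gene_b")], as.data.frame(feat))
  rownames(out) <- NULL
  attr(out, "feature_version") <- slFeatureVersion()
  out
}

#' Write / read a pair-feature table
#'
#' TSV with a comment header line recording the feature-order version,
#' then columns \code{gene_a}, \code{gene_b} and the 10 features.
#'
#' @param features data.frame from \code{\link{pairFeatureMatrix}}.
#' @param file Path.
#' @return \code{readPairFeatures} returns the table with its
#'   \code{"feature_version"} attribute restored.
#' @export
writePairFeatures <- function(features, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_version=",
                    attr(features, "feature_version")), con)
  write.table(features, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePairFeatures
#' @export
readPairFeatures <- function(file) {
  first <- readLines(file, n = 1L)
  ver <- sub("^# feature_version=", "", first)
  df <- read.delim(file, comment.char = "#")
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  attr(df, "feature_version") <- ver
  df
}
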