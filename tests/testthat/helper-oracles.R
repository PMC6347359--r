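# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (igraph, the matching functions) and
# recompute everything by exhaustive enumeration on small instances.

# --- graphs -----------------------------------------------------------------

# adjacency matrix from an edge data.frame over `nodes`
adjFromEdges <- function(edges, nodes) {
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a != b) adj[a, b] <- adj[b, a] <- 1L
  }
  adj
}

# Floyd-Warshall all-pairs shortest distances
bfDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1L] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# all simple paths s -> t (lists of vertex indices)
bfAllPaths <- function(adj, s, t) {
  paths <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in which(adj[v, ] == 1L)) {
      if (!(w %in% path)) rec(c(path, w))
    }
  }
  rec(s)
  paths
}

# degree / betweenness / closeness / clustering by exhaustive enumeration
bfNodeStats <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  d <- bfDistances(adj)
  btw <- numeric(n)
  if (n >= 2L) {
    for (s in seq_len(n - 1L)) {
      for (t in seq.int(s + 1L, n)) {
        if (!is.finite(d[s, t])) next
        ps <- bfAllPaths(adj, s, t)
        lens <- vapply(ps, length, integer(1)) - 1L
        sp <- ps[lens == d[s, t]]
        for (v in seq_len(n)) {
          if (v == s || v == t) next
          through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
          btw[v] <- btw[v] + through / length(sp)
        }
      }
    }
  }
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else length(di) / sum(di)
  }, numeric(1))
  clu <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1L)
    if (length(nb) < 2L) return(0)
    pr <- combn(nb, 2L)
    mean(adj[cbind(pr[1L, ], pr[2L, ])] == 1L)
  }, numeric(1))
  data.frame(gene = nodes, degree = as.integer(rowSums(adj)),
             betweenness = btw, closeness = clo, clustering = clu,
             stringsAsFactors = FALSE, row.names = NULL)
}

# random small graph as an edge data.frame over letter-named nodes
randomSmallGraph <- function(nNodes, p) {
  nodes <- LETTERS[seq_len(nNodes)]
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p
  data.frame(gene_a = pairs[keep, 1L], gene_b = pairs[keep, 2L],
             stringsAsFactors = FALSE)
}

# --- matching ---------------------------------------------------------------

pairKeyOracle <- function(a, b) {
  vapply(seq_along(a), function(i) {
    paste(sort(c(a[i], b[i]), method = "radix"), collapse = "+")
  }, character(1))
}

# Exhaustive triple loop over (drug pair, SL pair) with the
# single-drug-covers-both exclusion over `universe` (a targets list).
# Returns sorted keys "d1+d2|g1+g2" (drugs and genes unordered).
bfMatchKeys <- function(targetsList, slp, universe = targetsList,
                        drugPairs = NULL) {
  ids <- names(targetsList)
  covered <- logical(nrow(slp))
  for (tg in universe) {
    covered <- covered | (slp$gene_a %in% tg & slp$gene_b %in% tg)
  }
  if (is.null(drugPairs)) {
    if (length(ids) < 2L) return(character())
    idx <- t(combn(ids, 2L))
    drugPairs <- data.frame(drug_a = idx[, 1L], drug_b = idx[, 2L],
                            stringsAsFactors = FALSE)
  }
  keys <- character()
  for (i in seq_len(nrow(drugPairs))) {
    t1 <- targetsList[[drugPairs$drug_a[i]]]
    t2 <- targetsList[[drugPairs$drug_b[i]]]
    for (j in seq_len(nrow(slp))) {
      if (covered[j]) next
      g1 <- slp$gene_a[j]; g2 <- slp$gene_b[j]
      hit <- (g1 %in% t1 && g2 %in% t2) || (g2 %in% t1 && g1 %in% t2)
      if (hit) {
        keys <- c(keys, paste(
          pairKeyOracle(drugPairs$drug_a[i], drugPairs$drug_b[i]),
          pairKeyOracle(g1, g2), sep = "|"))
      }
    }
  }
  sort(unique(keys))
}

matchKeysFromDF <- function(m) {
  if (!nrow(m)) return(character())
  sort(unique(paste(pairKeyOracle(m$drug_a, m$drug_b),
                    pairKeyOracle(m$gene_a, m$gene_b), sep = "|")))
}

# random toy drug/SL world for matching-equivalence tests
randomMatchWorld <- function(nDrugs, nSL, nGenes = 10L) {
  genes <- sprintf("g%02d", seq_len(nGenes))
  targets <- lapply(seq_len(nDrugs), function(i) {
    k <- sample(0:3, 1L)
    if (k == 0L) character() else sample(genes, k)
  })
  names(targets) <- sprintf("d%02d", seq_len(nDrugs))
  pr <- t(combn(genes, 2L))
  pick <- sample.int(nrow(pr), min(nSL, nrow(pr)))
  slp <- data.frame(gene_a = pr[pick, 1L], gene_b = pr[pick, 2L],
                    stringsAsFactors = FALSE)
  drugs <- data.frame(
    drug_id = names(targets), name = names(targets), synonyms = "",
    modality = "drug",
    targets = vapply(targets, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE)
  list(drugs = drugs, targets = targets, slp = slp,
       slSet = SLInteractionSet(slp))
}

# --- metrics ----------------------------------------------------------------

bfConfusionMetrics <- function(truth, scores, threshold) {
  pos <- truth == "positive"
  call <- scores >= threshold
  tp <- sum(call & pos); fp <- sum(call & !pos)
  tn <- sum(!call & !pos); fn <- sum(!call & pos)
  safe <- function(x, y) if (y == 0) NA_real_ else x / y
  p <- safe(tp, tp + fp); r <- safe(tp, tp + fn)
  list(accuracy = (tp + tn) / length(truth), precision = p, recall = r,
       f1 = if (is.na(p) || is.na(r) || p + r == 0) NA_real_
            else 2 * p * r / (p + r),
       specificity = safe(tn, tn + fp), tp = tp, fp = fp, tn = tn, fn = fn)
}

# instance table with given labels and a single informative feature
toyInstances <- function(x, label) {
  feat <- matrix(0, length(x), 10L,
                 dimnames = list(NULL, slFeatureNames()))
  feat[, 1L] <- x
  out <- cbind(data.frame(gene_a = sprintf("a%04d", seq_along(x)),
                          gene_b = sprintf("b%04d", seq_along(x)),
                          stringsAsFactors = FALSE),
               as.data.frame(feat))
  out$label <- factor(label, levels = c("negative", "positive"))
  attr(out, "feature_version") <- slFeatureVersion()
  out
}
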