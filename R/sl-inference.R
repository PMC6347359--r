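# Classifier stage: balanced negative sampling, train/test split,
# cross-validated random-forest training, metric evaluation, prediction of
# putative SL pairs, and merging of yeast-derived and predicted sets.

# Run expr under a fixed seed, restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Sample negative (non-SL) gene pairs
#'
#' Draws \code{n} distinct canonical pairs uniformly at random between
#' eligible genes that take part in no known SL interaction, mirroring the
#' balanced-negative-sampling protocol: negatives are drawn between highly
#' annotated endpoints outside the known SL set.
#'
#' @param eligible Character vector of eligible genes (e.g. from
#'   \code{\link{eligibleNodes}}).
#' @param knownSL \linkS4class{SLInteractionSet} of known SL pairs (or
#'   \code{NULL}); genes appearing in it are removed from the candidate
#'   endpoints.
#' @param n Number of pairs to draw; must not exceed the number of distinct
#'   candidate pairs (the error reports the maximum).
#' @param seed Integer seed; identical seeds give identical samples.
#' @return data.frame of canonical pairs (\code{gene_a}, \code{gene_b}).
#' @export
sampleNegativePairs <- function(eligible, knownSL, n, seed) {
  eligible <- sort(unique(as.character(eligible)), method = "radix")
  if (!is.null(knownSL)) {
    stopifnot(is(knownSL, "SLInteractionSet"))
    eligible <- setdiff(eligible, geneUniverse(knownSL))
  }
  m <- length(eligible)
  avail <- if (m < 2L) 0 else choose(m, 2L)
  if (n > avail) {
    stop("requested ", n, " negative pairs but only ", avail,
         " distinct candidate pairs exist")
  }
  if (n == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  universe <- .allPairs(eligible)
  idx <- .withSeed(seed, sample.int(nrow(universe), n))
  out <- universe[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a labeled instance table
#'
#' Binds positive and negative feature tables into one instance table with
#' a \code{label} column, refusing pairs that occur with both labels.
#'
#' @param positives,negatives Feature tables from
#'   \code{\link{pairFeatureMatrix}}.
#' @return data.frame with \code{gene_a}, \code{gene_b}, \code{label}
#'   (factor positive/negative) and the feature columns; carries the
#'   feature-version attribute.
#' @export
makeInstances <- function(positives, negatives) {
  va <- attr(positives, "feature_version")
  vb <- attr(negatives, "feature_version")
  if (!identical(va, vb)) {
    stop("feature-version mismatch between positives and negatives")
  }
  kp <- .pairKey(positives$gene_a, positives$gene_b)
  kn <- .pairKey(negatives$gene_a, negatives$gene_b)
  both <- intersect(kp, kn)
  if (length(both)) stop("pair(s) labeled both positive and negative")
  out <- rbind(cbind(positives, label = "positive"),
               cbind(negatives, label = "negative"))
  out$label <- factor(out$label, levels = c("negative", "positive"))
  rownames(out) <- NULL
  attr(out, "feature_version") <- va
  out
}

#' Class-balanced train/test split
#'
#' Splits a labeled instance table so that each class contributes
#' \code{round(trainFraction * n_class)} instances to the training set;
#' with a balanced input both splits stay balanced (per-class counts differ
#' by at most 1). Splits are disjoint, exhaustive and seeded.
#'
#' @param instances data.frame from \code{\link{makeInstances}}.
#' @param trainFraction Fraction per class assigned to training (default
#'   2/3).
#' @param seed Integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
splitTrainTest <- function(instances, trainFraction = 2 / 3, seed) {
  stopifnot(is.data.frame(instances), "label" %in% names(instances),
            trainFraction > 0, trainFraction < 1)
  counts <- table(instances$label)
  if (any(counts < 2L)) stop("need at least 2 instances per class")
  trainIdx <- .withSeed(seed, {
    unlist(lapply(levels(instances$label), function(cl) {
      idx <- which(instances$label == cl)
      sample(idx, round(trainFraction * length(idx)))
    }))
  })
  train <- instances[sort(trainIdx), , drop = FALSE]
  test <- instances[setdiff(seq_len(nrow(instances)), trainIdx), ,
                    drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  attr(train, "feature_version") <- attr(instances, "feature_version")
  attr(test, "feature_version") <- attr(instances, "feature_version")
  list(train = train, test = test)
}

.featureColumns <- function(instances) {
  miss <- setdiff(slFeatureNames(), names(instances))
  if (length(miss)) {
    stop("instance table lacks feature column(s): ",
         paste(miss, collapse = ", "))
  }
  as.matrix(instances[slFeatureNames()])
}

#' Train the SL random-forest classifier
#'
#' Fits a random forest on the training instances, choosing the ensemble
#' size from \code{treeGrid} by stratified \code{cvFolds}-fold
#' cross-validated accuracy (ties resolved to the smallest size), then
#' refits the chosen size on the full training set. Per-tree
#' hyperparameters are \pkg{randomForest} defaults and are recorded with
#' the model.
#'
#' @param train Labeled instance table (balanced), from
#'   \code{\link{splitTrainTest}}.
#' @param cvFolds Number of cross-validation folds (default 10).
#' @param treeGrid Candidate ensemble sizes (default
#'   \code{c(25, 50, 93, 150, 300)}).
#' @param seed Integer seed controlling fold assignment and tree growing.
#' @return An \linkS4class{SLClassifier}. All-constant features trigger a
#'   warning but not an error.
#' @export
trainClassifier <- function(train, cvFolds = 10L,
                            treeGrid = c(25L, 50L, 93L, 150L, 300L), seed) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  x <- .featureColumns(train)
  y <- factor(train$label, levels = c("negative", "positive"))
  if (any(table(y) < cvFolds)) {
    stop("need at least cvFolds instances per class")
  }
  constant <- apply(x, 2L, function(col) length(unique(col)) == 1L)
  if (all(constant)) {
    warning("all features are constant; the model cannot learn")
    # the tree ensemble cannot split a fully constant matrix; break the
    # degeneracy with an infinitesimal seeded jitter (chance-level model)
    x <- x + .withSeed(seed + 2L,
                       matrix(rnorm(length(x), 0, 1e-9), nrow(x)))
  } else if (any(constant)) {
    warning("constant feature(s): ",
            paste(colnames(x)[constant], collapse = ", "))
  }
  treeGrid <- sort(unique(as.integer(treeGrid)))
  cvAcc <- .withSeed(seed, {
    fold <- integer(nrow(x))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(cvFolds), length(idx))
    }
    vapply(treeGrid, function(nt) {
      correct <- 0L
      for (k in seq_len(cvFolds)) {
        hold <- fold == k
        fit <- randomForest::randomForest(x[!hold, , drop = FALSE],
                                          y[!hold], ntree = nt)
        pred <- predict(fit, x[hold, , drop = FALSE])
        correct <- correct + sum(pred == y[hold])
      }
      correct / nrow(x)
    }, numeric(1))
  })
  best <- treeGrid[which.max(cvAcc)] # which.max takes the first (smallest)
  forest <- .withSeed(seed + 1L,
                      randomForest::randomForest(x, y, ntree = best))
  new("SLClassifier", forest = forest, ntree = as.integer(best),
      grid = treeGrid, cvAccuracy = as.numeric(cvAcc),
      seed = as.integer(seed),
      featureVersion = slFeatureVersion())
}

#' Classification metrics from labels and scores
#'
#' Confusion-matrix metrics at a score threshold plus the rank-based AUC
#' (Mann-Whitney formulation, ties sharing midranks). Ratios with a zero
#' denominator are reported as \code{NA} ("not applicable"), never
#' silently 0.
#'
#' @param truth Factor or character vector with levels negative/positive.
#' @param scores Numeric positive-class scores.
#' @param threshold Scores \code{>= threshold} are called positive
#'   (default 0.5).
#' @return Named list: \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{specificity}, \code{auc}, plus the confusion counts
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @examples
#' classifierMetrics(c("positive", "negative"), c(0.9, 0.1))
#' @export
classifierMetrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.character(truth)
  stopifnot(all(truth %in% c("negative", "positive")),
            length(truth) == length(scores))
  pos <- truth == "positive"
  call <- scores >= threshold
  tp <- sum(call & pos); fp <- sum(call & !pos)
  tn <- sum(!call & !pos); fn <- sum(!call & pos)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  npos <- sum(pos); nneg <- sum(!pos)
  auc <- if (npos == 0 || nneg == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  list(accuracy = rat(tp + tn, length(truth)), precision = precision,
       recall = recall, f1 = f1, specificity = rat(tn, tn + fp), auc = auc,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Evaluate a trained classifier on a test set
#'
#' Scores the test instances with the model's positive-class vote fraction
#' and computes \code{\link{classifierMetrics}}. Requires both classes to
#' be present.
#'
#' @param model An \linkS4class{SLClassifier}.
#' @param test Labeled instance table.
#' @param threshold Positive-call threshold (default 0.5).
#' @return The metric list from \code{\link{classifierMetrics}}.
#' @export
evaluateClassifier <- function(model, test, threshold = 0.5) {
  stopifnot(is(model, "SLClassifier"), is.data.frame(test),
            "label" %in% names(test), nrow(test) > 0L)
  if (length(unique(as.character(test$label))) < 2L) {
    stop("test set must contain both classes")
  }
  scores <- predict(model@forest, .featureColumns(test),
                    type = "prob")[, "positive"]
  classifierMetrics(test$label, scores, threshold)
}

#' Predict putative SL pairs among candidate gene pairs
#'
#' Applies the classifier to a candidate feature table and returns the
#' pairs whose positive-class score reaches the threshold, canonicalized,
#' deduplicated, and with pairs already in the known SL set removed.
#'
#' @param model An \linkS4class{SLClassifier}.
#' @param candidates Feature table from \code{\link{pairFeatureMatrix}};
#'   its feature version must match the model's (error otherwise).
#' @param threshold Positive-class score threshold (default 0.5); scores
#'   \code{>= threshold} are returned.
#' @param knownSL Optional \linkS4class{SLInteractionSet} to exclude.
#' @return An \linkS4class{SLInteractionSet} with provenance
#'   \code{"predicted"}.
#' @export
predictCandidates <- function(model, candidates, threshold = 0.5,
                              knownSL = NULL) {
  stopifnot(is(model, "SLClassifier"), is.data.frame(candidates))
  ver <- attr(candidates, "feature_version")
  if (!identical(ver, model@featureVersion)) {
    stop("feature-version mismatch: candidates built with ",
         if (is.null(ver)) "<none>" else ver, ", model expects ",
         model@featureVersion)
  }
  if (nrow(candidates) == 0L) {
    return(SLInteractionSet(provenance = "predicted"))
  }
  scores <- predict(model@forest, .featureColumns(candidates),
                    type = "prob")[, "positive"]
  hits <- candidates[scores >= threshold, c("gene_a", "gene_b"),
                     drop = FALSE]
  out <- SLInteractionSet(hits, provenance = "predicted")
  if (!is.null(knownSL) && length(out)) {
    keep <- !containsPair(knownSL, slPairs(out)$gene_a, slPairs(out)$gene_b)
    out <- SLInteractionSet(slPairs(out)[keep, , drop = FALSE],
                            provenance = "predicted")
  }
  out
}
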