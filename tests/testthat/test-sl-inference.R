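test_that("negative sampling avoids SL endpoints and is seeded", {
  known <- SLInteractionSet(data.frame(gene_a = "A", gene_b = "Q"))
  out <- sampleNegativePairs(c("A", "B", "C"), known, 1, seed = 1)
  expect_identical(out, data.frame(gene_a = "B", gene_b = "C"))
  expect_equal(nrow(sampleNegativePairs(c("A", "B", "C"), NULL, 0,
                                        seed = 1)), 0L)
  expect_error(sampleNegativePairs(c("A", "B", "C"), known, 2, seed = 1),
               "only 1")
  genes <- sprintf("g%02d", 1:20)
  s1 <- sampleNegativePairs(genes, NULL, 15, seed = 7)
  s2 <- sampleNegativePairs(genes, NULL, 15, seed = 7)
  s3 <- sampleNegativePairs(genes, NULL, 15, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("negative sampling never emits a known SL pair", {
  set.seed(2)
  for (i in 1:10) {
    w <- randomMatchWorld(nDrugs = 4, nSL = 10, nGenes = 12)
    genes <- sprintf("g%02d", 1:12)
    free <- setdiff(genes, geneUniverse(w$slSet))
    if (choose(length(free), 2) < 3) next
    neg <- sampleNegativePairs(genes, w$slSet, 3, seed = i)
    expect_false(any(containsPair(w$slSet, neg$gene_a, neg$gene_b)))
    expect_true(all(c(neg$gene_a, neg$gene_b) %in% free))
  }
})

test_that("train/test split is balanced, disjoint, exhaustive and seeded", {
  inst <- toyInstances(rnorm(12), rep(c("positive", "negative"), each = 6))
  sp <- splitTrainTest(inst, 2 / 3, seed = 1)
  expect_equal(as.vector(table(sp$train$label)), c(4, 4))
  expect_equal(as.vector(table(sp$test$label)), c(2, 2))
  key <- function(d) paste(d$gene_a, d$gene_b)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(inst))
  sp2 <- splitTrainTest(inst, 2 / 3, seed = 1)
  expect_identical(key(sp2$train), key(sp$train))
  expect_error(splitTrainTest(toyInstances(rnorm(3), c("positive",
                                                       "negative",
                                                       "negative")),
                              seed = 1), "at least 2")
})

test_that("a 1,049-per-class split stays balanced within one instance", {
  n <- 1049L
  inst <- toyInstances(rnorm(2 * n), rep(c("positive", "negative"),
                                         each = n))
  sp <- splitTrainTest(inst, 2 / 3, seed = 3)
  trainCounts <- table(sp$train$label)
  testCounts <- table(sp$test$label)
  expect_lte(max(trainCounts) - min(trainCounts), 1)
  expect_lte(max(testCounts) - min(testCounts), 1)
  expect_true(all(abs(trainCounts - 2 / 3 * n) <= 1))
  expect_true(all(testCounts %in% c(349L, 350L)))
})

test_that("grid selection prefers the smallest size on separable data", {
  set.seed(4)
  x <- c(rnorm(60, 2, 0.1), rnorm(60, -2, 0.1))
  inst <- toyInstances(x, rep(c("positive", "negative"), each = 60))
  model <- suppressWarnings( # 9 of the 10 toy features are constant
    trainClassifier(inst, cvFolds = 5, treeGrid = c(10, 40), seed = 1))
  expect_s4_class(model, "SLClassifier")
  expect_equal(model@cvAccuracy, c(1, 1))
  expect_equal(model@ntree, 10L)
  expect_identical(model@featureVersion, slFeatureVersion())
  # degenerate all-constant features warn but still train
  instConst <- toyInstances(rep(0, 40),
                            rep(c("positive", "negative"), each = 20))
  expect_warning(trainClassifier(instConst, cvFolds = 2, treeGrid = 10,
                                 seed = 1), "constant")
})

test_that("pure-noise features give chance-level test accuracy", {
  set.seed(9)
  inst <- toyInstances(rnorm(200),
                       rep(c("positive", "negative"), each = 100))
  sp <- splitTrainTest(inst, 2 / 3, seed = 2)
  model <- suppressWarnings(
    trainClassifier(sp$train, cvFolds = 5, treeGrid = 50, seed = 2))
  m <- evaluateClassifier(model, sp$test)
  expect_gte(m$accuracy, 0.4)
  expect_lte(m$accuracy, 0.6)
})

test_that("metrics reproduce hand confusion-matrix arithmetic", {
  # TP=3, FP=1, TN=4, FN=2
  truth <- c(rep("positive", 5), rep("negative", 5))
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2, 0.1, 0.05)
  m <- classifierMetrics(truth, scores, threshold = 0.5)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$specificity, 0.8)
  # perfect predictions
  p <- classifierMetrics(c("positive", "negative"), c(1, 0))
  expect_equal(unlist(p[c("accuracy", "precision", "recall", "f1",
                          "specificity", "auc")]),
               setNames(rep(1, 6), c("accuracy", "precision", "recall",
                                     "f1", "specificity", "auc")))
  # constant scores on a balanced set: AUC 0.5, no positive calls below
  # threshold are hidden as zeros
  cst <- classifierMetrics(rep(c("positive", "negative"), 5), rep(0.3, 10),
                           threshold = 0.5)
  expect_equal(cst$auc, 0.5)
  expect_true(is.na(cst$precision)) # 0/0, reported as not-applicable
})

test_that("metrics agree with the brute-force oracle on random vectors", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("positive", "negative")
    scores <- round(runif(n), 2) # ties occur
    thr <- runif(1)
    got <- classifierMetrics(truth, scores, thr)
    exp <- bfConfusionMetrics(truth, scores, thr)
    for (f in names(exp)) expect_equal(got[[f]], exp[[f]])
    if (!is.na(got$precision) && !is.na(got$recall) &&
        got$precision + got$recall > 0) {
      expect_equal(got$f1,
                   2 * got$precision * got$recall /
                     (got$precision + got$recall), tolerance = 1e-9)
    }
  }
})

test_that("rank-based AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:10) {
    truth <- sample(c("positive", "negative"), 40, replace = TRUE)
    truth[1:2] <- c("positive", "negative")
    scores <- round(runif(40), 2)
    got <- classifierMetrics(truth, scores)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("negative",
                                                       "positive"),
      direction = "<", quiet = TRUE)))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("candidate prediction respects threshold, dedupe and versioning", {
  set.seed(21)
  x <- c(rnorm(40, 2, 0.2), rnorm(40, -2, 0.2))
  inst <- toyInstances(x, rep(c("positive", "negative"), each = 40))
  model <- suppressWarnings(
    trainClassifier(inst, cvFolds = 4, treeGrid = 25, seed = 5))
  cand <- inst[, setdiff(names(inst), "label")]
  attr(cand, "feature_version") <- slFeatureVersion()
  expect_equal(length(predictCandidates(model, cand, threshold = 0)),
               nrow(cand))
  expect_equal(length(predictCandidates(model, cand, threshold = 1.01)), 0L)
  known <- SLInteractionSet(cand[1:5, c("gene_a", "gene_b")])
  out <- predictCandidates(model, cand, threshold = 0, knownSL = known)
  expect_false(any(containsPair(known, slPairs(out)$gene_a,
                                slPairs(out)$gene_b)))
  badCand <- cand
  attr(badCand, "feature_version") <- "slfeat/0"
  expect_error(predictCandidates(model, badCand), "feature-version")
})

test_that("held-out true SL pairs are recovered on a planted world", {
  cfg <- syntheticWorldConfig(n_genes = 300, edge_density = 0.03,
                              n_true_sl = 300, annotation_coverage = 1,
                              seed = 1)
  inst <- benchmarkInstances(cfg)
  sp <- splitTrainTest(inst, 2 / 3, seed = 1)
  model <- trainClassifier(sp$train, cvFolds = 5, treeGrid = 93, seed = 1)
  heldPos <- sp$test[sp$test$label == "positive", ]
  cand <- heldPos[, setdiff(names(heldPos), "label")]
  attr(cand, "feature_version") <- attr(inst, "feature_version")
  rec <- predictCandidates(model, cand, threshold = 0.5)
  expect_gte(length(rec) / nrow(cand), 0.6)
})

test_that("merging SL sets obeys the union size law and keeps provenance", {
  mk <- function(a, b, prov = "yeast_derived") {
    SLInteractionSet(data.frame(gene_a = a, gene_b = b), provenance = prov)
  }
  a <- mk(c("A", "B", "C"), c("X", "Y", "Z"))
  b <- mk(c("D", "E"), c("X", "Y"), "predicted")
  expect_length(mergeSLSets(a, b), 5L)
  a2 <- mk(c("A", "B", "C", "D", "E"), c("X", "Y", "Z", "X", "Y"))
  b2 <- mk(c("A", "B", "F", "G"), c("X", "Y", "X", "Y"), "predicted")
  m <- mergeSLSets(a2, b2) # 2 shared pairs: 5 + 4 - 2
  expect_length(m, 7L)
  shared <- slPairs(m)
  both <- shared[shared$gene_a == "A" & shared$gene_b == "X", "provenance"]
  expect_identical(both, "yeast_derived;predicted")
  # property: |A u B| = |A| + |B| - |A n B| on random sets
  set.seed(29)
  pr <- t(combn(sprintf("G%02d", 1:14), 2))
  for (i in 1:20) {
    ia <- sample.int(nrow(pr), sample(5:30, 1))
    ib <- sample.int(nrow(pr), sample(5:30, 1))
    A <- mk(pr[ia, 1], pr[ia, 2])
    B <- mk(pr[ib, 1], pr[ib, 2], "predicted")
    expect_length(mergeSLSets(A, B),
                  length(unique(ia)) + length(unique(ib)) -
                    length(intersect(unique(ia), unique(ib))))
  }
})

test_that("the seeded pipeline is byte-identical across reruns", {
  cfg <- syntheticWorldConfig(n_genes = 120, n_true_sl = 60,
                              annotation_coverage = 1, seed = 6)
  runOnce <- function() {
    inst <- benchmarkInstances(cfg)
    sp <- splitTrainTest(inst, 2 / 3, seed = 6)
    model <- trainClassifier(sp$train, cvFolds = 3, treeGrid = 25, seed = 6)
    cand <- sp$test[, setdiff(names(sp$test), "label")]
    attr(cand, "feature_version") <- attr(inst, "feature_version")
    pred <- predictCandidates(model, cand, threshold = 0.5)
    f <- tempfile(fileext = ".tsv")
    writeSLSet(pred, f)
    f
  }
  f1 <- runOnce()
  f2 <- runOnce()
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted-signal worlds beat matched null worlds, paired by seed", {
  accs <- vapply(1:5, function(s) {
    vapply(c(TRUE, FALSE), function(signal) {
      cfg <- syntheticWorldConfig(n_genes = 150, edge_density = 0.04,
                                  n_true_sl = 120,
                                  annotation_coverage = 1,
                                  annotation_overlap_boost =
                                    if (signal) 2 else 0,
                                  topology_boost = if (signal) 0.7 else 0,
                                  seed = s)
      inst <- benchmarkInstances(cfg)
      sp <- splitTrainTest(inst, 2 / 3, seed = s)
      model <- trainClassifier(sp$train, cvFolds = 3, treeGrid = 50,
                               seed = s)
      evaluateClassifier(model, sp$test)$accuracy
    }, numeric(1))
  }, numeric(2))
  expect_true(all(accs[1, ] > accs[2, ]))
})
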