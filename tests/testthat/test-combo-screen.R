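fig3 <- fixtureFig3()

toyTrial <- function(id, phase = "III", type = "interventional",
                     conditions = "ovarian cancer",
                     arms = list(c("drugA", "drugB"))) {
  list(trial_id = id, phase = phase, study_type = type,
       conditions = conditions, arms = arms)
}

test_that("trial filtering applies phase, condition, type and arm rules", {
  trials <- list(
    toyTrial("T1"),                                   # keeps
    toyTrial("T2", phase = "II"),                     # wrong phase
    toyTrial("T3", conditions = "hypertension"),      # wrong condition
    toyTrial("T4", type = "observational"),           # wrong type
    toyTrial("T5", arms = list("drugA")),             # single-drug arm
    toyTrial("T6", phase = "IV",
             conditions = c("Neoplasms, Ovarian", "fatigue")) # keeps
  )
  kept <- filterTrials(trials)
  expect_setequal(vapply(kept, `[[`, character(1), "trial_id"),
                  c("T1", "T6"))
  # condition match is exact (case-insensitive), not substring
  sub <- toyTrial("T7", conditions = "recurrent ovarian cancer stage III")
  expect_length(filterTrials(list(sub)), 0L)
})

test_that("tested combinations resolve synonyms and tally trials", {
  drugs <- data.frame(
    drug_id = c("d1", "d2", "d3"),
    name = c("Alphadrug", "Betadrug", "Gammadrug"),
    synonyms = c("alpha-1|al", "", "gd"),
    modality = "drug",
    targets = c("G1", "G2", "G3"))
  trials <- list(
    toyTrial("T1", arms = list(c("alphadrug", "Betadrug"))),
    toyTrial("T2", arms = list(c("AL", "betadrug"))), # synonym resolves
    toyTrial("T3", arms = list(c("Alphadrug", "Gammadrug"),
                               c("Betadrug", "gd"))),
    toyTrial("T4", arms = list(c("Betadrug", "Gammadrug"))))
  combos <- extractTestedCombinations(trials, drugs)
  got <- setNames(combos$n_trials, combos$combo_id)
  expect_equal(got[["d1|d2"]], 2L)
  expect_equal(got[["d1|d3"]], 1L)
  expect_equal(got[["d2|d3"]], 2L)
  expect_equal(nrow(combos), 3L)
  # unresolvable names warn; the arm survives while >= 2 drugs remain
  t5 <- list(toyTrial("T5", arms = list(c("Alphadrug", "Betadrug",
                                          "mysterytonic"))))
  expect_warning(c5 <- extractTestedCombinations(t5, drugs),
                 "mysterytonic")
  expect_equal(c5$combo_id, "d1|d2")
})

test_that("pairwise expansion enumerates C(n,2) drug pairs", {
  expect_identical(expandPairwise(c("a", "b")),
                   data.frame(drug_a = "a", drug_b = "b"))
  expect_equal(nrow(expandPairwise(c("a", "b", "c"))), 3L)
  expect_equal(nrow(expandPairwise(c("a", "b", "c", "d"))), 6L)
  expect_error(expandPairwise("a"), "at least two")
})

test_that("drugs without protein targets are excluded from matching", {
  drugs <- data.frame(
    drug_id = sprintf("d%02d", 1:10), name = sprintf("n%02d", 1:10),
    synonyms = "", modality = "drug",
    targets = c("VEGFA", "", "A|B", "", "C", "D", "", "E", "F|G", "H"))
  kept <- filterDrugsWithProteinTargets(drugs)
  expect_equal(nrow(kept), 7L)
  expect_false(any(kept$targets == ""))
})

test_that("tested combinations recover the published SL matches", {
  res <- screenTestedCombinations(
    data.frame(combo_id = vapply(fig3$combinations, paste, character(1),
                                 collapse = "|"),
               n_trials = 1L)[
      , , drop = FALSE] |>
      transform(drugs = I(fig3$combinations)),
    fig3$drugs, fig3$sl)
  m <- res$matches
  # bevacizumab + paclitaxel addresses the VEGFA-BCL2 pair
  bp <- m[m$drug_a == "bevacizumab" & m$drug_b == "paclitaxel", ]
  expect_true(any(bp$gene_a == "VEGFA" & bp$gene_b == "BCL2"))
  # olaparib + cediranib addresses PARP1-KDR and PARP2-KDR
  oc <- m[(m$drug_a == "cediranib" & m$drug_b == "olaparib"), ]
  expect_setequal(paste(oc$gene_a, oc$gene_b),
                  c("KDR PARP1", "KDR PARP2"))
  # valproic acid + hydralazine addresses ALDH5A1-AOC3
  vh <- m[m$drug_b == "valproic acid", ]
  expect_true(any(vh$gene_a == "AOC3" & vh$gene_b == "ALDH5A1"))
})

test_that("a single drug covering both SL partners suppresses the match", {
  drugs <- data.frame(
    drug_id = c("dA", "dB", "dC"), name = c("A", "B", "C"), synonyms = "",
    modality = "drug",
    targets = c("G1", "G2", "G1|G2")) # dC covers the whole pair
  sl <- SLInteractionSet(data.frame(gene_a = "G1", gene_b = "G2"))
  m <- findSLMatches("dA", "dB", drugs, sl)
  expect_equal(nrow(m), 0L)
  # without the covering drug in the universe the match appears
  m2 <- findSLMatches("dA", "dB", drugs[1:2, ], sl,
                      testedDrugs = drugs[1:2, ])
  expect_equal(nrow(m2), 1L)
})

test_that("match finding is symmetric in drug order", {
  m1 <- findSLMatches("paclitaxel", "veliparib", fig3$drugs, fig3$sl)
  m2 <- findSLMatches("veliparib", "paclitaxel", fig3$drugs, fig3$sl)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 2L) # PARP1-BCL2 and PARP2-BCL2
})

test_that("novel proposals exclude tested pairs and find published rows", {
  # extend the SL set with the ERBB2-VEGFA pair from the published ranking
  sl <- mergeSLSets(fig3$sl, SLInteractionSet(
    data.frame(gene_a = "ERBB2", gene_b = "VEGFA")))
  tested <- unique(do.call(rbind, lapply(fig3$combinations,
                                         expandPairwise)))
  novel <- proposeNovelCombinations(fig3$drugs, tested, sl)
  pb <- novel[novel$drug_a == "bevacizumab" &
                novel$drug_b == "pertuzumab", ]
  expect_true(any(pb$gene_a == "VEGFA" & pb$gene_b == "ERBB2"))
  expect_true(all(novel$status == "novel"))
  # no tested drug pair ever appears among proposals
  testedKeys <- pairKeyOracle(tested$drug_a, tested$drug_b)
  expect_false(any(pairKeyOracle(novel$drug_a, novel$drug_b) %in%
                     testedKeys))
})

test_that("matching equals brute-force enumeration on random toy worlds", {
  set.seed(41)
  for (i in 1:10) {
    w <- randomMatchWorld(nDrugs = sample(4:8, 1), nSL = sample(5:15, 1))
    withTargets <- filterDrugsWithProteinTargets(w$drugs)
    novel <- proposeNovelCombinations(
      w$drugs, data.frame(drug_a = character(), drug_b = character()),
      w$slSet)
    oracle <- bfMatchKeys(w$targets[withTargets$drug_id], w$slp,
                          universe = w$targets[withTargets$drug_id])
    expect_identical(matchKeysFromDF(novel), oracle)
  }
})

test_that("annotation-degree ranking reproduces published sums and order", {
  counts <- fixtureTable1()
  ranked <- rankByAnnotationDegree(fixtureTable1Pairs(), counts)
  expect_equal(ranked$annotation_degree[ranked$gene_a == "ERBB2" &
                                          ranked$gene_b == "VEGFA"], 1262)
  expect_equal(ranked$annotation_degree[ranked$gene_a == "BCL2" &
                                          ranked$gene_b == "PARP1"], 107)
  expect_equal(ranked$annotation_degree[ranked$gene_a == "EGFR" &
                                          ranked$gene_b == "SRC"], 749)
  expect_identical(c(ranked$gene_a[1], ranked$gene_b[1]),
                   c("ERBB2", "VEGFA"))
  expect_equal(ranked$count_a[1], 695)
  expect_equal(ranked$count_b[1], 567)
})

test_that("ranking is a stable, non-increasing permutation of its input", {
  set.seed(43)
  m <- fixtureTable1Pairs()
  counts <- fixtureTable1()
  ranked <- rankByAnnotationDegree(m, counts)
  expect_equal(nrow(ranked), nrow(m))
  expect_true(all(diff(ranked$annotation_degree) <= 0))
  shuffled <- m[sample.int(nrow(m)), ]
  expect_identical(rankByAnnotationDegree(shuffled, counts)[
    c("drug_a", "drug_b", "gene_a", "gene_b")],
    ranked[c("drug_a", "drug_b", "gene_a", "gene_b")])
  # zero counts rank last; missing counts warn and score 0
  m0 <- rbind(m[1, ], transform(m[1, ], gene_a = "ZZZ9", gene_b = "ZZZ8"))
  expect_warning(r0 <- rankByAnnotationDegree(m0, counts), "ZZZ")
  expect_equal(r0$annotation_degree[2], 0)
})

test_that("tested and novel match sets are disjoint in drug-pair space", {
  set.seed(47)
  for (i in 1:5) {
    w <- randomMatchWorld(nDrugs = 6, nSL = 12)
    tested <- expandPairwise(sample(w$drugs$drug_id, 3))
    sc <- screenTestedCombinations(
      data.frame(combo_id = "x", n_trials = 1L) |>
        transform(drugs = I(list(unique(c(tested$drug_a,
                                          tested$drug_b))))),
      w$drugs, w$slSet)
    novel <- proposeNovelCombinations(w$drugs, sc$testedPairs, w$slSet)
    expect_length(intersect(
      pairKeyOracle(sc$matches$drug_a, sc$matches$drug_b),
      pairKeyOracle(novel$drug_a, novel$drug_b)), 0)
  }
})

test_that("ranked matches round-trip through the result TSV", {
  ranked <- rankByAnnotationDegree(fixtureTable1Pairs(), fixtureTable1())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMatches(ranked, f)
  back <- read.delim(f)
  expect_equal(names(back), c("drug_a", "drug_b", "synlet_a", "synlet_b",
                              "annotation_degree", "count_a", "count_b",
                              "status"))
  expect_equal(back$annotation_degree, ranked$annotation_degree)
})
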