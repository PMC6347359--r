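# Seeded generators for every pipeline input, with planted ground truth:
# a set of "true" SL pairs that (i) share extra annotation terms, (ii) sit
# closer together in the interaction network, (iii) appear as strong
# negative interactions in the emulated yeast screen, and (iv) are
# addressed by planted clinical-trial drug combinations. Each generator
# records what it planted so every downstream stage has an oracle.

#' Configuration of a synthetic world
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' The defaults describe a small world (200 genes, 40 SL pairs, 20 drugs,
#' 30 trials) sized so the complete pipeline runs in seconds; see
#' \code{\link{slBenchmarkConfig}} for the larger classifier benchmark.
#'
#' @param n_genes Number of human genes (>= 10).
#' @param edge_density Probability of a background network edge.
#' @param vocab_size Terms per annotation namespace.
#' @param terms_per_gene Mean number of terms a gene draws per namespace.
#' @param annotation_coverage Probability that a gene is annotated at all
#'   in a given namespace.
#' @param n_true_sl Number of planted true SL pairs.
#' @param sl_gene_fraction Fraction of genes eligible as SL endpoints; the
#'   remaining genes stay SL-free so negatives can be sampled.
#' @param annotation_overlap_boost Mean number of extra terms per
#'   namespace shared by the two endpoints of a true SL pair (0 = null
#'   world, no annotation signal).
#' @param topology_boost Probability of planting a direct edge on a true
#'   SL pair (otherwise a shared neighbour is planted; 0 = no topology
#'   signal).
#' @param n_yeast_genes Number of yeast genes in the emulated screen.
#' @param ortholog_rate Probability that a human gene outside the SL set
#'   has a yeast ortholog (SL genes always get one, so pairs can map).
#' @param one_to_many_rate Probability that a yeast gene maps to a second
#'   human gene.
#' @param n_drugs Number of drugs in the corpus.
#' @param targets_per_drug Mean (Poisson) number of random protein targets
#'   per drug.
#' @param n_trials Total number of trial records.
#' @param n_planted_trials Number of trials planted to study an
#'   SL-addressing combination (the rest are distractors failing at least
#'   one filter rule).
#' @param seed Integer master seed; every generator derives its stream
#'   from it, so the same config yields an identical world.
#' @return A validated list of class \code{SyntheticWorldConfig}.
#' @export
syntheticWorldConfig <- function(n_genes = 200L, edge_density = 0.05,
                                 vocab_size = 50L, terms_per_gene = 4,
                                 annotation_coverage = 0.95,
                                 n_true_sl = 40L, sl_gene_fraction = 0.5,
                                 annotation_overlap_boost = 2,
                                 topology_boost = 0.7,
                                 n_yeast_genes = 150L, ortholog_rate = 0.7,
                                 one_to_many_rate = 0.2, n_drugs = 20L,
                                 targets_per_drug = 2, n_trials = 30L,
                                 n_planted_trials = 8L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), edge_density = edge_density,
              vocab_size = as.integer(vocab_size),
              terms_per_gene = terms_per_gene,
              annotation_coverage = annotation_coverage,
              n_true_sl = as.integer(n_true_sl),
              sl_gene_fraction = sl_gene_fraction,
              annotation_overlap_boost = annotation_overlap_boost,
              topology_boost = topology_boost,
              n_yeast_genes = as.integer(n_yeast_genes),
              ortholog_rate = ortholog_rate,
              one_to_many_rate = one_to_many_rate,
              n_drugs = as.integer(n_drugs),
              targets_per_drug = targets_per_drug,
              n_trials = as.integer(n_trials),
              n_planted_trials = as.integer(n_planted_trials),
              seed = as.integer(seed))
  probs <- c(cfg$edge_density, cfg$annotation_coverage, cfg$ortholog_rate,
             cfg$one_to_many_rate, cfg$sl_gene_fraction, cfg$topology_boost)
  stopifnot(cfg$n_genes >= 10L, all(probs >= 0), all(probs <= 1),
            cfg$annotation_overlap_boost >= 0, cfg$vocab_size >= 1L,
            cfg$n_true_sl >= 1L, cfg$n_drugs >= 2L,
            cfg$n_planted_trials <= cfg$n_trials)
  nSLGenes <- floor(cfg$sl_gene_fraction * cfg$n_genes)
  if (choose(nSLGenes, 2L) < cfg$n_true_sl) {
    stop("not enough SL-eligible genes for n_true_sl pairs")
  }
  class(cfg) <- "SyntheticWorldConfig"
  cfg
}

#' Classifier benchmark configuration
#'
#' The fixed world used to benchmark the SL classifier: 600 genes, 1,000
#' planted SL pairs confined to half of the genes (the other half stays
#' SL-free to supply negatives), full annotation coverage, and either the
#' default planted signal (\code{signal = TRUE}) or a matched null world
#' with no annotation or topology signal (\code{signal = FALSE}).
#'
#' @param signal Plant annotation/topology signal on SL pairs?
#' @param seed Master seed.
#' @return A \code{SyntheticWorldConfig}.
#' @export
slBenchmarkConfig <- function(signal = TRUE, seed = 1L) {
  syntheticWorldConfig(
    n_genes = 600L, edge_density = 0.02, vocab_size = 50L,
    terms_per_gene = 4, annotation_coverage = 1,
    n_true_sl = 1000L, sl_gene_fraction = 0.5,
    annotation_overlap_boost = if (signal) 2 else 0,
    topology_boost = if (signal) 0.7 else 0,
    n_drugs = 20L, n_trials = 30L, n_planted_trials = 8L,
    seed = as.integer(seed))
}

.worldGenes <- function(config) sprintf("G%04d", seq_len(config$n_genes))

.subSeed <- function(config, k) (config$seed %% 100000L) * 17L + k

#' Planted true SL pairs of a synthetic world
#'
#' Samples \code{n_true_sl} distinct canonical pairs among the SL-eligible
#' gene block (the first \code{sl_gene_fraction} of the gene universe).
#'
#' @param config A \code{SyntheticWorldConfig}.
#' @return data.frame of canonical pairs (\code{gene_a}, \code{gene_b}).
#' @export
sampleTrueSLPairs <- function(config) {
  genes <- .worldGenes(config)
  slGenes <- genes[seq_len(floor(config$sl_gene_fraction * config$n_genes))]
  universe <- .allPairs(slGenes)
  idx <- .withSeed(.subSeed(config, 1L),
                   sample.int(nrow(universe), config$n_true_sl))
  out <- universe[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate the human interaction network
#'
#' An Erdos-Renyi background graph at \code{edge_density} over the full
#' gene universe, with extra edges planted on true-SL pairs: with
#' probability \code{topology_boost} the pair itself is connected,
#' otherwise both endpoints are wired to a shared random neighbour. SL
#' pairs therefore sit stochastically closer than random pairs whenever
#' \code{topology_boost > 0}.
#'
#' @param config A \code{SyntheticWorldConfig}.
#' @param trueSL Planted SL pairs (default
#'   \code{\link{sampleTrueSLPairs}(config)}).
#' @return An \code{igraph} over all genes (isolates retained). A
#'   configuration that yields no edges at all is an error.
#' @export
generateInteractionNetwork <- function(config,
                                       trueSL = sampleTrueSLPairs(config)) {
  genes <- .worldGenes(config)
  edges <- .withSeed(.subSeed(config, 2L), {
    base <- .allPairs(genes)
    base <- base[runif(nrow(base)) < config$edge_density, , drop = FALSE]
    planted_a <- character()
    planted_b <- character()
    if (config$topology_boost > 0 && nrow(trueSL)) {
      for (i in seq_len(nrow(trueSL))) {
        a <- trueSL$gene_a[i]; b <- trueSL$gene_b[i]
        if (runif(1) < config$topology_boost) {
          planted_a <- c(planted_a, a); planted_b <- c(planted_b, b)
        } else {
          c3 <- sample(setdiff(genes, c(a, b)), 1L)
          planted_a <- c(planted_a, a, c3)
          planted_b <- c(planted_b, c3, b)
        }
      }
    }
    rbind(base, data.frame(gene_a = planted_a, gene_b = planted_b,
                           stringsAsFactors = FALSE))
  })
  if (!nrow(edges)) stop("configuration yields an empty edge set")
  makeNetwork(edges, isolates = genes)
}

#' Generate per-gene annotations
#'
#' Every gene draws, per namespace, a random term set from the namespace
#' vocabulary (with probability \code{annotation_coverage} of being
#' annotated at all). Each true SL pair then receives additional shared
#' terms per namespace at mean rate \code{annotation_overlap_boost},
#' raising the endpoints' Dice coefficients; with boost 0 the SL and
#' non-SL Dice distributions coincide.
#'
#' @param config A \code{SyntheticWorldConfig}.
#' @param trueSL Planted SL pairs.
#' @return Long data.frame (\code{gene}, \code{namespace}, \code{term}).
#' @export
generateAnnotations <- function(config,
                                trueSL = sampleTrueSLPairs(config)) {
  genes <- .worldGenes(config)
  nss <- slNamespaces()
  .withSeed(.subSeed(config, 3L), {
    rows <- vector("list", length(genes) * length(nss))
    k <- 0L
    for (g in genes) {
      for (ns in nss) {
        k <- k + 1L
        if (runif(1) < config$annotation_coverage) {
          nTerms <- 1L + rpois(1L, max(config$terms_per_gene - 1, 0))
          nTerms <- min(nTerms, config$vocab_size)
          terms <- sprintf("%s:t%03d", ns,
                           sample.int(config$vocab_size, nTerms))
          rows[[k]] <- data.frame(gene = g, namespace = ns, term = terms,
                                  stringsAsFactors = FALSE)
        }
      }
    }
    extra <- list()
    if (config$annotation_overlap_boost > 0 && nrow(trueSL)) {
      for (i in seq_len(nrow(trueSL))) {
        for (ns in nss) {
          nShared <- rpois(1L, config$annotation_overlap_boost)
          if (nShared > 0L) {
            nShared <- min(nShared, config$vocab_size)
            terms <- sprintf("%s:t%03d", ns,
                             sample.int(config$vocab_size, nShared))
            extra[[length(extra) + 1L]] <- data.frame(
              gene = rep(c(trueSL$gene_a[i], trueSL$gene_b[i]),
                         each = nShared),
              namespace = ns, term = rep(terms, 2L),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- unique(do.call(rbind, c(rows, extra)))
    rownames(out) <- NULL
    out
  })
}

#' Generate an emulated yeast genetic-interaction screen
#'
#' Planted pairs are emitted with interaction scores below -0.08 and
#' p-values below 0.05 (so all survive the default filter; a few are also
#' emitted in reversed query/array order to exercise deduplication);
#' filler measurements draw score and p-value from wide null
#' distributions and mostly fail the cutoffs. The exact set of pairs
#' passing the default cutoffs — planted or accidental filler — is
#' recorded for oracle testing.
#'
#' @param config A \code{SyntheticWorldConfig}.
#' @param plantedPairs data.frame of yeast gene pairs to plant.
#' @param nFiller Number of filler measurements (default
#'   \code{max(60, 3 * nrow(plantedPairs))}).
#' @return list with \code{records} (the screen table) and
#'   \code{pass_pairs} (canonical pairs passing p < 0.05, score < -0.08,
#'   computed by the generator's own bookkeeping).
#' @export
generateYeastScreen <- function(config, plantedPairs,
                                nFiller = max(60L,
                                              3L * nrow(plantedPairs))) {
  yGenes <- sprintf("y%04d", seq_len(config$n_yeast_genes))
  .withSeed(.subSeed(config, 4L), {
    nP <- nrow(plantedPairs)
    planted <- if (nP) {
      data.frame(query_gene = plantedPairs$gene_a,
                 array_gene = plantedPairs$gene_b,
                 epsilon = runif(nP, -0.6, -0.09),
                 p_value = runif(nP, 0, 0.049),
                 stringsAsFactors = FALSE)
    } else NULL
    # reversed re-measurements of a few planted pairs
    rev <- if (nP >= 2L) {
      ri <- sample.int(nP, max(1L, nP %/% 5L))
      data.frame(query_gene = plantedPairs$gene_b[ri],
                 array_gene = plantedPairs$gene_a[ri],
                 epsilon = runif(length(ri), -0.6, -0.09),
                 p_value = runif(length(ri), 0, 0.049),
                 stringsAsFactors = FALSE)
    } else NULL
    fq <- sample(yGenes, nFiller, replace = TRUE)
    fa <- sample(yGenes, nFiller, replace = TRUE)
    ok <- fq != fa
    filler <- data.frame(query_gene = fq[ok], array_gene = fa[ok],
                         epsilon = rnorm(sum(ok), 0, 0.12),
                         p_value = runif(sum(ok)),
                         stringsAsFactors = FALSE)
    records <- rbind(planted, rev, filler)
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    rownames(records) <- NULL
    pass <- records[records$p_value < 0.05 & records$epsilon < -0.08 &
                      records$query_gene != records$array_gene, ,
                    drop = FALSE]
    key <- vapply(seq_len(nrow(pass)), function(i) {
      paste(sort(c(pass$query_gene[i], pass$array_gene[i]),
                 method = "radix"), collapse = "\r")
    }, character(1))
    first <- !duplicated(key)
    passPairs <- data.frame(
      gene_a = vapply(strsplit(key[first], "\r", fixed = TRUE), `[`,
                      character(1), 1L),
      gene_b = vapply(strsplit(key[first], "\r", fixed = TRUE), `[`,
                      character(1), 2L),
      stringsAsFactors = FALSE)
    passPairs <- passPairs[order(passPairs$gene_a, passPairs$gene_b,
                                 method = "radix"), , drop = FALSE]
    rownames(passPairs) <- NULL
    list(records = records, pass_pairs = passPairs)
  })
}

# Yeast ortholog machinery for a coherent world: yeast gene "y<g>" maps to
# human gene g for every SL endpoint (guaranteeing the planted pairs can
# map) and for a random ortholog_rate fraction of the other genes;
# one_to_many_rate adds a second human image. Records are split across
# three emulated resources.
.generateOrthology <- function(config, trueSL) {
  genes <- .worldGenes(config)
  slGenes <- unique(c(trueSL$gene_a, trueSL$gene_b))
  .withSeed(.subSeed(config, 5L), {
    others <- setdiff(genes, slGenes)
    mapped <- c(slGenes, others[runif(length(others)) < config$ortholog_rate])
    rec <- data.frame(yeast_gene = paste0("y", mapped), human_gene = mapped,
                      stringsAsFactors = FALSE)
    extra <- rec$yeast_gene[runif(nrow(rec)) < config$one_to_many_rate]
    if (length(extra)) {
      rec <- rbind(rec, data.frame(
        yeast_gene = extra,
        human_gene = sample(genes, length(extra), replace = TRUE),
        stringsAsFactors = FALSE))
      rec <- unique(rec)
    }
    sources <- c("roundupEmu", "omaEmu", "homologeneEmu")
    tables <- lapply(seq_along(sources), function(s) {
      keep <- runif(nrow(rec)) < 0.7
      if (s == 1L) keep <- keep | !duplicated(rec$yeast_gene) # cover all
      df <- rec[keep, , drop = FALSE]
      df$source <- sources[s]
      rownames(df) <- NULL
      df
    })
    tables
  })
}

#' Generate the drug corpus and trial registry
#'
#' Drugs receive random protein-target sets; \code{n_planted_trials}
#' combinations are planted so that each addresses one true SL pair (two
#' reserved drugs, one targeting each SL partner, with the guarantee that
#' no drug in the corpus targets both partners of a planted pair). Planted
#' trials are phase III/IV interventional ovarian-cancer trials carrying
#' the combination in an arm; distractor trials each violate at least one
#' of the phase / condition / study-type / multi-drug-arm rules.
#'
#' @param config A \code{SyntheticWorldConfig}.
#' @param slSet \linkS4class{SLInteractionSet} of true SL pairs.
#' @return list with \code{drugs} (drug data.frame), \code{trials} (trial
#'   list) and \code{ground_truth}: a data.frame of planted combinations
#'   (\code{drug_a}, \code{drug_b}, \code{gene_a}, \code{gene_b},
#'   \code{trial_id}) plus the distractor trial ids.
#' @export
generateDrugCorpus <- function(config, slSet) {
  stopifnot(is(slSet, "SLInteractionSet"))
  genes <- .worldGenes(config)
  slp <- slPairs(slSet)
  .withSeed(.subSeed(config, 6L), {
    nD <- config$n_drugs
    drugIds <- sprintf("D%03d", seq_len(nD))
    drugNames <- paste0("drug", seq_len(nD))
    synonyms <- paste0("dg-", seq_len(nD))
    modality <- ifelse(runif(nD) < 0.2, "biological", "drug")
    targets <- lapply(seq_len(nD), function(i) {
      k <- rpois(1L, config$targets_per_drug)
      if (k == 0L) character() else sample(genes, min(k, length(genes)))
    })
    # choose planted SL pairs with pairwise-disjoint endpoints
    nPlant <- min(config$n_planted_trials, nD %/% 2L)
    chosen <- integer()
    used <- character()
    for (i in sample.int(nrow(slp))) {
      if (length(chosen) >= nPlant) break
      gs <- c(slp$gene_a[i], slp$gene_b[i])
      if (!any(gs %in% used)) {
        chosen <- c(chosen, i)
        used <- c(used, gs)
      }
    }
    nPlant <- length(chosen)
    if (nPlant == 0L) stop("could not plant any SL-addressing combination")
    plantA <- drugIds[2L * seq_len(nPlant) - 1L]
    plantB <- drugIds[2L * seq_len(nPlant)]
    for (j in seq_len(nPlant)) {
      i <- chosen[j]
      ia <- match(plantA[j], drugIds); ib <- match(plantB[j], drugIds)
      targets[[ia]] <- unique(c(targets[[ia]], slp$gene_a[i]))
      targets[[ib]] <- unique(c(targets[[ib]], slp$gene_b[i]))
    }
    # repair: no drug may cover both partners of a planted pair
    for (j in seq_len(nPlant)) {
      ga <- slp$gene_a[chosen[j]]; gb <- slp$gene_b[chosen[j]]
      for (d in seq_len(nD)) {
        if (all(c(ga, gb) %in% targets[[d]])) {
          drop <- if (drugIds[d] == plantA[j]) gb else ga
          targets[[d]] <- setdiff(targets[[d]], drop)
        }
      }
    }
    drugs <- data.frame(
      drug_id = drugIds, name = drugNames, synonyms = synonyms,
      modality = modality,
      targets = vapply(targets, paste, character(1), collapse = "|"),
      stringsAsFactors = FALSE)
    # trials
    terms <- slConditionTerms()
    trials <- vector("list", config$n_trials)
    planted_trial <- character(nPlant)
    for (j in seq_len(nPlant)) {
      id <- sprintf("NCT%05d", j)
      planted_trial[j] <- id
      armNames <- c(drugNames[match(plantA[j], drugIds)],
                    # resolve via synonym for odd plantings
                    if (j %% 2L == 0L) synonyms[match(plantB[j], drugIds)]
                    else drugNames[match(plantB[j], drugIds)])
      if (j %% 3L == 0L) { # a triple regimen now and then
        armNames <- c(armNames, drugNames[sample.int(nD, 1L)])
      }
      trials[[j]] <- list(
        trial_id = id, phase = if (j %% 2L) "III" else "IV",
        study_type = "interventional",
        conditions = c(terms[1L + (j %% length(terms))], "fatigue"),
        arms = list(armNames))
    }
    distractorKinds <- c("phase", "condition", "type", "arm")
    for (j in seq.int(nPlant + 1L, length.out = config$n_trials - nPlant)) {
      id <- sprintf("NCT%05d", j)
      kind <- distractorKinds[1L + (j %% length(distractorKinds))]
      two <- drugNames[sample.int(nD, 2L)]
      trials[[j]] <- switch(kind,
        phase = list(trial_id = id, phase = "II",
                     study_type = "interventional",
                     conditions = terms[1L], arms = list(two)),
        condition = list(trial_id = id, phase = "III",
                         study_type = "interventional",
                         conditions = c("hypertension"),
                         arms = list(two)),
        type = list(trial_id = id, phase = "III",
                    study_type = "observational",
                    conditions = terms[2L], arms = list(two)),
        arm = list(trial_id = id, phase = "IV",
                   study_type = "interventional",
                   conditions = terms[3L], arms = list(two[1L])))
    }
    gt <- data.frame(drug_a = plantA, drug_b = plantB,
                     gene_a = slp$gene_a[chosen],
                     gene_b = slp$gene_b[chosen],
                     trial_id = planted_trial, stringsAsFactors = FALSE)
    list(drugs = drugs, trials = trials,
         ground_truth = list(planted = gt,
                             distractor_trial_ids = setdiff(
                               vapply(trials, `[[`, character(1),
                                      "trial_id"), planted_trial)))
  })
}

#' Generate a complete synthetic world
#'
#' Runs every generator coherently: true SL pairs; the interaction
#' network and annotations with planted signal; the yeast screen over the
#' orthology preimages of a subset of the true SL pairs plus three
#' ortholog tables that map them back; per-gene publication counts; and
#' the drug/trial corpus with planted SL-addressing combinations.
#'
#' @param config A \code{SyntheticWorldConfig}.
#' @param yeastFraction Fraction of true SL pairs planted into the yeast
#'   screen (default 0.6).
#' @return A list with elements \code{config}, \code{genes},
#'   \code{true_sl} (pair data.frame), \code{sl_set}
#'   (\linkS4class{SLInteractionSet}), \code{network},
#'   \code{annotations}, \code{screen}, \code{pass_pairs},
#'   \code{ortholog_tables}, \code{planted_yeast_pairs},
#'   \code{pmid_counts}, \code{drugs}, \code{trials},
#'   \code{ground_truth}.
#' @export
generateWorld <- function(config = syntheticWorldConfig(),
                          yeastFraction = 0.6) {
  trueSL <- sampleTrueSLPairs(config)
  network <- generateInteractionNetwork(config, trueSL)
  annotations <- generateAnnotations(config, trueSL)
  slSet <- SLInteractionSet(trueSL, provenance = "yeast_derived")
  nY <- max(1L, round(yeastFraction * nrow(trueSL)))
  yeastIdx <- .withSeed(.subSeed(config, 7L),
                        sort(sample.int(nrow(trueSL), nY)))
  plantedYeast <- data.frame(gene_a = paste0("y", trueSL$gene_a[yeastIdx]),
                             gene_b = paste0("y", trueSL$gene_b[yeastIdx]),
                             stringsAsFactors = FALSE)
  screen <- generateYeastScreen(config, plantedYeast)
  orthoTables <- .generateOrthology(config, trueSL)
  counts <- .withSeed(.subSeed(config, 8L), {
    stats::setNames(rpois(config$n_genes, 30), .worldGenes(config))
  })
  corpus <- generateDrugCorpus(config, slSet)
  list(config = config, genes = .worldGenes(config), true_sl = trueSL,
       sl_set = slSet, network = network, annotations = annotations,
       screen = screen$records, pass_pairs = screen$pass_pairs,
       ortholog_tables = orthoTables,
       planted_yeast_pairs = plantedYeast,
       planted_yeast_human = trueSL[yeastIdx, , drop = FALSE],
       pmid_counts = counts, drugs = corpus$drugs, trials = corpus$trials,
       ground_truth = corpus$ground_truth)
}

#' Write a synthetic world to disk
#'
#' Emits every input in the exact file format the pipeline consumes
#' (screen TSV, ortholog TSVs, network edge-list TSV, annotation TSV,
#' drug TSV, trial JSON-lines, publication-count TSV) plus a ground-truth
#' JSON with the planted SL pairs, combinations and filter pass-set.
#'
#' @param world A world from \code{\link{generateWorld}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write.table(world$screen, fp("screen.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (i in seq_along(world$ortholog_tables)) {
    write.table(world$ortholog_tables[[i]],
                fp(sprintf("orthologs_%d.tsv", i)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  el <- igraph::as_data_frame(world$network, what = "edges")
  names(el) <- c("gene_a", "gene_b")
  write.table(el, fp("network.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(world$annotations, fp("annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeDrugs(world$drugs, fp("drugs.tsv"))
  writeTrials(world$trials, fp("trials.jsonl"))
  write.table(data.frame(gene = names(world$pmid_counts),
                         pmid_count = as.integer(world$pmid_counts)),
              fp("pmid_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSLSet(world$sl_set, fp("sl_pairs.tsv"))
  gt <- list(true_sl = world$true_sl, pass_pairs = world$pass_pairs,
             planted_combinations = world$ground_truth$planted,
             distractor_trial_ids = world$ground_truth$distractor_trial_ids)
  jsonlite::write_json(gt, fp("ground_truth.json"), dataframe = "rows")
  invisible(dir)
}

#' Build the balanced labeled instance table of a benchmark world
#'
#' Positives are the world's planted SL pairs; negatives are sampled
#' between eligible (fully annotated) genes taking part in no SL pair,
#' one negative per positive. Features are computed on the world's
#' network and annotations.
#'
#' @param config A \code{SyntheticWorldConfig}, typically
#'   \code{\link{slBenchmarkConfig}}.
#' @return A labeled instance table (see \code{\link{makeInstances}}).
#' @export
benchmarkInstances <- function(config) {
  trueSL <- sampleTrueSLPairs(config)
  network <- generateInteractionNetwork(config, trueSL)
  profiles <- annotationProfiles(generateAnnotations(config, trueSL))
  stats <- nodeStatistics(network)
  slSet <- SLInteractionSet(trueSL, provenance = "yeast_derived")
  eligible <- eligibleNodes(profiles)
  negatives <- sampleNegativePairs(eligible, slSet, nrow(trueSL),
                                   seed = .subSeed(config, 9L))
  pos <- pairFeatureMatrix(trueSL, profiles, stats, network)
  neg <- pairFeatureMatrix(negatives, profiles, stats, network)
  makeInstances(pos, neg)
}

#' Train and evaluate the classifier on a benchmark world
#'
#' Convenience wrapper: builds \code{\link{benchmarkInstances}}, performs
#' the balanced 2/3 - 1/3 split, trains with 10-fold cross-validation
#' over the default tree grid, and evaluates on the held-out third.
#'
#' @param config A \code{SyntheticWorldConfig}.
#' @param trainFraction,cvFolds,treeGrid,threshold Passed through to
#'   \code{\link{splitTrainTest}}, \code{\link{trainClassifier}} and
#'   \code{\link{evaluateClassifier}}.
#' @return list with \code{model} (\linkS4class{SLClassifier}),
#'   \code{metrics} and the \code{split}.
#' @export
runSLBenchmark <- function(config = slBenchmarkConfig(),
                           trainFraction = 2 / 3, cvFolds = 10L,
                           treeGrid = c(25L, 50L, 93L, 150L, 300L),
                           threshold = 0.5) {
  instances <- benchmarkInstances(config)
  split <- splitTrainTest(instances, trainFraction,
                          seed = .subSeed(config, 10L))
  model <- trainClassifier(split$train, cvFolds = cvFolds,
                           treeGrid = treeGrid,
                           seed = .subSeed(config, 11L))
  metrics <- evaluateClassifier(model, split$test, threshold)
  list(model = model, metrics = metrics, split = split)
}

#' In-paper worked example: drugs, tested combinations and SL pairs
#'
#' The fixed 14-drug worked example used throughout the tests: taxanes and
#' targeted agents with their protein-target sets, the twelve late-stage
#' tested combinations (nine involving paclitaxel), and the twelve SL
#' pairs they address.
#'
#' @return list with \code{drugs} (drug data.frame),
#'   \code{combinations} (list of 12 drug-id vectors) and \code{sl}
#'   (\linkS4class{SLInteractionSet}).
#' @export
fixtureFig3 <- function() {
  spec <- list(
    paclitaxel = c("BCL2", "TUBB1"),
    docetaxel = "BCL2",
    veliparib = c("PARP1", "PARP2"),
    olaparib = c("PARP1", "PARP2"),
    pertuzumab = "ERBB2",
    trastuzumab = "ERBB2",
    bevacizumab = "VEGFA",
    gemcitabine = "RRM1",
    fosbretabulin = "TUBB",
    `interferon gamma-1b` = c("IFNGR1", "IFNGR2"),
    cediranib = "KDR",
    nintedanib = c("KDR", "FGFR1", "FGFR2", "FGFR3", "PDGFA", "PDGFB",
                   "SRC", "LCK"),
    `valproic acid` = "ALDH5A1",
    hydralazine = "AOC3")
  biological <- c("pertuzumab", "trastuzumab", "bevacizumab",
                  "interferon gamma-1b")
  drugs <- data.frame(
    drug_id = names(spec), name = names(spec), synonyms = "",
    modality = ifelse(names(spec) %in% biological, "biological", "drug"),
    targets = vapply(spec, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE)
  rownames(drugs) <- NULL
  partners <- c("veliparib", "pertuzumab", "trastuzumab", "bevacizumab",
                "gemcitabine", "fosbretabulin", "interferon gamma-1b",
                "cediranib", "nintedanib")
  combinations <- c(lapply(partners, function(p) c("paclitaxel", p)),
                    list(c("docetaxel", "bevacizumab"),
                         c("olaparib", "cediranib"),
                         c("valproic acid", "hydralazine")))
  sl <- SLInteractionSet(data.frame(
    gene_a = c("PARP1", "PARP2", "ERBB2", "VEGFA", "RRM1", "TUBB", "KDR",
               "TUBB1", "TUBB1", "PARP1", "PARP2", "ALDH5A1"),
    gene_b = c("BCL2", "BCL2", "BCL2", "BCL2", "BCL2", "BCL2", "BCL2",
               "IFNGR1", "IFNGR2", "KDR", "KDR", "AOC3"),
    stringsAsFactors = FALSE), provenance = "yeast_derived")
  list(drugs = drugs, combinations = combinations, sl = sl)
}

#' In-paper worked example: per-gene publication counts
#'
#' The disease-specific publication counts of the SL partner genes in the
#' published ranking of proposed combinations, used to verify the
#' annotation-degree arithmetic.
#'
#' @return Named numeric vector: gene symbol to publication count.
#' @export
fixtureTable1 <- function() {
  c(ERBB2 = 695, EGFR = 636, VEGFA = 567, JUN = 536, TOP1 = 128,
    SRC = 113, BCL2 = 66, PARP1 = 41, FGFR2 = 24, PDGFB = 23, KDR = 22,
    PDGFA = 19, FGFR1 = 18, ABL1 = 10, FGFR3 = 7, LCK = 7, PARP2 = 2,
    SPHK1 = 2, ESD = 2)
}

#' @rdname fixtureTable1
#' @details \code{fixtureTable1Pairs} returns the distinct published
#'   SL pairs of the ranking table with one representative proposed drug
#'   pair each, for ranking tests.
#' @export
fixtureTable1Pairs <- function() {
  data.frame(
    drug_a = c("pertuzumab", "pertuzumab", "pertuzumab", "trastuzumab",
               "pertuzumab", "pertuzumab", "pertuzumab", "pertuzumab",
               "pertuzumab", "pertuzumab", "pertuzumab", "pertuzumab",
               "pertuzumab", "pertuzumab", "pertuzumab", "trastuzumab",
               "trastuzumab", "vinblastine", "bevacizumab", "bevacizumab",
               "bevacizumab", "bevacizumab", "topotecan", "topotecan",
               "docetaxel"),
    drug_b = c("bevacizumab", "saracatinib", "docetaxel", "nintedanib",
               "olaparib", "nintedanib", "nintedanib", "cediranib",
               "nintedanib", "nintedanib", "saracatinib", "nintedanib",
               "nintedanib", "olaparib", "phenoxodiol", "nintedanib",
               "nintedanib", "paclitaxel", "nintedanib", "cediranib",
               "nintedanib", "nintedanib", "glutathione", "phenoxodiol",
               "veliparib"),
    gene_a = c("ERBB2", "ERBB2", "ERBB2", "EGFR", "ERBB2", "ERBB2",
               "ERBB2", "ERBB2", "ERBB2", "ERBB2", "ERBB2", "ERBB2",
               "ERBB2", "ERBB2", "ERBB2", "EGFR", "EGFR", "JUN", "VEGFA",
               "VEGFA", "VEGFA", "VEGFA", "TOP1", "TOP1", "BCL2"),
    gene_b = c("VEGFA", "SRC", "BCL2", "SRC", "PARP1", "FGFR2", "PDGFB",
               "KDR", "PDGFA", "FGFR1", "ABL1", "FGFR3", "LCK", "PARP2",
               "SPHK1", "FGFR1", "LCK", "BCL2", "PDGFB", "KDR", "PDGFA",
               "FGFR3", "ESD", "SPHK1", "PARP1"),
    status = "novel", stringsAsFactors = FALSE)
}
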