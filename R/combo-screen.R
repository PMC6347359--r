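# Clinical-trial screening: filter a registry export to late-stage
# interventional trials on the disease of interest, expand studied regimens
# to pairwise drug combinations, match them against the SL set (each drug
# targeting one SL partner, no single drug covering both), propose novel
# combinations from the same drug universe, and rank matches by the summed
# per-gene publication count ("annotation degree").

#' Condition terms defining the ovarian-cancer trial corpus
#'
#' The controlled condition strings a trial must carry (case-insensitive
#' exact match on a condition entry) to count as an ovarian-cancer trial;
#' this excludes trials merely enrolling ovarian-cancer patients for an
#' unrelated condition.
#'
#' @return Character vector of six condition strings.
#' @export
slConditionTerms <- function() {
  c("ovarian cancer", "ovarian neoplasms", "neoplasm of ovary",
    "ovarian carcinoma", "ovarian epithelial cancer", "neoplasms, ovarian")
}

#' Read / write a drug table
#'
#' TSV with header \code{drug_id}, \code{name}, \code{synonyms}
#' (pipe-separated, may be empty), \code{modality} (\code{drug} or
#' \code{biological}) and \code{targets} (pipe-separated human gene
#' symbols, may be empty).
#'
#' @param file Path.
#' @param drugs Drug data.frame.
#' @return \code{readDrugs}: the drug data.frame.
#' @export
readDrugs <- function(file) {
  df <- read.delim(file, colClasses = "character")
  need <- c("drug_id", "name", "synonyms", "modality", "targets")
  if (!all(need %in% names(df))) {
    stop("drug file must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$drug_id)) stop("duplicate drug_id in drug file")
  df[need]
}

#' @rdname readDrugs
#' @export
writeDrugs <- function(drugs, file) {
  write.table(drugs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.splitPipe <- function(x) {
  lapply(strsplit(x, "|", fixed = TRUE), function(v) v[nzchar(v)])
}

#' Per-drug protein-target sets
#'
#' @param drugs Drug data.frame (see \code{\link{readDrugs}}).
#' @return Named list: \code{drug_id} to character vector of target gene
#'   symbols (possibly empty).
#' @export
drugTargets <- function(drugs) {
  stats::setNames(.splitPipe(drugs$targets), drugs$drug_id)
}

#' Case-insensitive drug-name index
#'
#' Maps lower-cased canonical names and synonyms to \code{drug_id}, for
#' resolving the free-text drug names found in trial arms.
#'
#' @param drugs Drug data.frame.
#' @return Named character vector (names are lower-cased drug names).
#' @export
drugNameIndex <- function(drugs) {
  syn <- .splitPipe(drugs$synonyms)
  names <- c(tolower(drugs$name),
             tolower(unlist(syn)))
  ids <- c(drugs$drug_id, rep(drugs$drug_id, lengths(syn)))
  idx <- stats::setNames(ids, names)
  idx[!duplicated(names(idx))]
}

#' Read / write trial records
#'
#' One JSON object per line with fields \code{trial_id}, \code{phase}
#' (\code{I}/\code{II}/\code{III}/\code{IV}/\code{other}),
#' \code{study_type}, \code{conditions} (array of strings) and \code{arms}
#' (array of arrays of drug names; each inner array is one studied
#' combination).
#'
#' @param file Path to a JSON-lines file.
#' @param trials List of trial records.
#' @return \code{readTrials}: a list of trial records (each a list).
#' @export
readTrials <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    t <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    t$conditions <- vapply(t$conditions, as.character, character(1))
    t$arms <- lapply(t$arms, function(a) {
      vapply(a, as.character, character(1))
    })
    t
  })
}

#' @rdname readTrials
#' @export
writeTrials <- function(trials, file) {
  lines <- vapply(trials, function(t) {
    jsonlite::toJSON(list(trial_id = jsonlite::unbox(t$trial_id),
                          phase = jsonlite::unbox(t$phase),
                          study_type = jsonlite::unbox(t$study_type),
                          conditions = t$conditions,
                          arms = lapply(t$arms, identity)))
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Filter trials to the relevant corpus
#'
#' Retains trials satisfying all of: phase in \code{phases};
#' interventional study type; at least one condition equal
#' (case-insensitively) to one of \code{conditionTerms}; and at least one
#' arm combining two or more drugs/biologicals.
#'
#' @param trials List of trial records (see \code{\link{readTrials}}).
#' @param phases Admissible phases (default III and IV — combinations with
#'   prior efficacy evidence).
#' @param conditionTerms Controlled condition strings (default
#'   \code{\link{slConditionTerms}}).
#' @return The retained sublist, in input order.
#' @export
filterTrials <- function(trials, phases = c("III", "IV"),
                         conditionTerms = slConditionTerms()) {
  terms <- tolower(conditionTerms)
  keep <- vapply(trials, function(t) {
    t$phase %in% phases &&
      identical(tolower(t$study_type), "interventional") &&
      any(tolower(t$conditions) %in% terms) &&
      any(vapply(t$arms, length, integer(1)) >= 2L)
  }, logical(1))
  trials[keep]
}

#' Extract the tested drug combinations
#'
#' Resolves the drug names of every multi-drug arm through the name index
#' (canonical names and synonyms, case-insensitive) and tallies distinct
#' drug-id sets with the number of trials studying each. Unresolvable
#' names are dropped with a warning; an arm survives as long as at least
#' two resolvable drugs remain.
#'
#' @param trials Filtered trial list.
#' @param drugs Drug data.frame.
#' @return data.frame with a list-column \code{drugs} (sorted drug-id
#'   vectors), \code{combo_id} (ids joined by \code{"|"}) and
#'   \code{n_trials}.
#' @export
extractTestedCombinations <- function(trials, drugs) {
  idx <- drugNameIndex(drugs)
  perTrial <- lapply(trials, function(t) {
    combos <- lapply(t$arms, function(arm) {
      ids <- idx[tolower(arm)]
      if (anyNA(ids)) {
        warning("unresolvable drug name(s) in trial ", t$trial_id, ": ",
                paste(arm[is.na(ids)], collapse = ", "))
        ids <- ids[!is.na(ids)]
      }
      sort(unique(unname(ids)), method = "radix")
    })
    combos <- combos[vapply(combos, length, integer(1)) >= 2L]
    unique(vapply(combos, paste, character(1), collapse = "|"))
  })
  all <- unlist(perTrial)
  if (!length(all)) {
    return(data.frame(combo_id = character(), n_trials = integer()))
  }
  tab <- table(all)
  out <- data.frame(combo_id = names(tab), n_trials = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$drugs <- strsplit(out$combo_id, "|", fixed = TRUE)
  out <- out[order(out$combo_id, method = "radix"), ]
  rownames(out) <- NULL
  out[c("combo_id", "drugs", "n_trials")]
}

#' All pairwise drug combinations of a regimen
#'
#' Regimens with more than two drugs are evaluated through all their
#' C(n, 2) unordered drug pairs.
#'
#' @param combination Character vector of two or more drug ids.
#' @return data.frame of canonical drug pairs (\code{drug_a},
#'   \code{drug_b}); a singleton combination is an error.
#' @examples
#' expandPairwise(c("d1", "d2", "d3"))
#' @export
expandPairwise <- function(combination) {
  combination <- unique(as.character(combination))
  if (length(combination) < 2L) {
    stop("a combination must contain at least two distinct drugs")
  }
  p <- .allPairs(combination)
  names(p) <- c("drug_a", "drug_b")
  p
}

#' Keep drugs with at least one protein target
#'
#' SL interactions connect two protein-coding genes, so drugs without any
#' protein target (e.g. DNA cross-linkers) cannot address one and are
#' excluded from matching.
#'
#' @param drugs Drug data.frame.
#' @return The subset with non-empty target sets.
#' @export
filterDrugsWithProteinTargets <- function(drugs) {
  keep <- lengths(drugTargets(drugs)) >= 1L
  out <- drugs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Keys of SL pairs both of whose endpoints are targeted by one drug in the
# universe — such pairs are never emitted as matches for any drug pair.
.singleDrugCoveredKeys <- function(targetsList, slSet) {
  p <- slPairs(slSet)
  if (!nrow(p)) return(character())
  keys <- .pairKey(p$gene_a, p$gene_b)
  covered <- rep(FALSE, nrow(p))
  for (tg in targetsList) {
    if (length(tg) >= 2L) {
      covered <- covered | (p$gene_a %in% tg & p$gene_b %in% tg)
    }
  }
  keys[covered]
}

# Matches for one canonical drug pair. Returns zero-row df if none.
.matchOnePair <- function(d1, d2, targetsList, slSet, coveredKeys) {
  t1 <- targetsList[[d1]]
  t2 <- targetsList[[d2]]
  if (!length(t1) || !length(t2)) return(NULL)
  grid <- expand.grid(g1 = t1, g2 = t2, stringsAsFactors = FALSE)
  grid <- grid[grid$g1 != grid$g2, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  o <- .orderPair(grid$g1, grid$g2)
  key <- .pairKey(o$a, o$b)
  ok <- containsPair(slSet, grid$g1, grid$g2) & !(key %in% coveredKeys)
  grid <- grid[ok, , drop = FALSE]
  key <- key[ok]
  if (!nrow(grid)) return(NULL)
  # one row per unordered SL pair; deterministic pick of the assignment
  ord <- order(grid$g1, grid$g2, method = "radix")
  grid <- grid[ord, , drop = FALSE]
  key <- key[ord]
  grid <- grid[!duplicated(key), , drop = FALSE]
  data.frame(drug_a = d1, drug_b = d2, gene_a = grid$g1, gene_b = grid$g2,
             stringsAsFactors = FALSE)
}

#' SL matches addressed by a drug pair
#'
#' Finds every SL pair (gene_a, gene_b) such that one drug of the pair
#' targets gene_a and the other targets gene_b, subject to the exclusion
#' that no single drug in the tested-drug universe targets both SL
#' partners (a combination is only needed where one drug cannot cover the
#' pair alone). Symmetric in drug order.
#'
#' @param drug_a,drug_b Drug ids.
#' @param drugs Drug data.frame providing target sets.
#' @param slSet \linkS4class{SLInteractionSet}.
#' @param testedDrugs Drug data.frame defining the universe for the
#'   single-drug exclusion (default: \code{drugs}).
#' @param status Status tag for the emitted matches (default
#'   \code{"tested"}).
#' @return data.frame with columns \code{drug_a}, \code{drug_b} (canonical
#'   drug order), \code{gene_a} (targeted by \code{drug_a}), \code{gene_b}
#'   (targeted by \code{drug_b}), \code{status}; zero rows if none.
#' @export
findSLMatches <- function(drug_a, drug_b, drugs, slSet,
                          testedDrugs = drugs, status = "tested") {
  stopifnot(is(slSet, "SLInteractionSet"), drug_a != drug_b)
  targetsList <- drugTargets(drugs)
  for (d in c(drug_a, drug_b)) {
    if (!d %in% names(targetsList)) stop("unknown drug id: ", d)
  }
  covered <- .singleDrugCoveredKeys(drugTargets(testedDrugs), slSet)
  o <- .orderPair(drug_a, drug_b)
  swapped <- !identical(o$a, drug_a)
  m <- .matchOnePair(o$a, o$b, targetsList, slSet, covered)
  if (is.null(m)) {
    return(data.frame(drug_a = character(), drug_b = character(),
                      gene_a = character(), gene_b = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  m$status <- status
  m
}

#' Screen tested combinations against the SL set
#'
#' Expands every tested combination to its pairwise drug pairs and
#' collects all SL matches (status \code{"tested"}). Drugs without protein
#' targets are ignored inside pairs; the single-drug exclusion uses the
#' full tested-drug universe.
#'
#' @param combos Combination table from
#'   \code{\link{extractTestedCombinations}} (or any data.frame with a
#'   list-column \code{drugs}).
#' @param drugs Drug data.frame (the tested-drug universe).
#' @param slSet \linkS4class{SLInteractionSet}.
#' @return list with \code{matches} (match data.frame as in
#'   \code{\link{findSLMatches}}) and \code{testedPairs} (data.frame of
#'   all distinct canonical tested drug pairs, matched or not).
#' @export
screenTestedCombinations <- function(combos, drugs, slSet) {
  targetsList <- drugTargets(drugs)
  covered <- .singleDrugCoveredKeys(targetsList, slSet)
  pairs <- unique(do.call(rbind, lapply(combos$drugs, expandPairwise)))
  if (is.null(pairs)) {
    pairs <- data.frame(drug_a = character(), drug_b = character())
  }
  rownames(pairs) <- NULL
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    .matchOnePair(pairs$drug_a[i], pairs$drug_b[i], targetsList, slSet,
                  covered)
  })
  matches <- do.call(rbind, rows)
  if (is.null(matches)) {
    matches <- data.frame(drug_a = character(), drug_b = character(),
                          gene_a = character(), gene_b = character(),
                          stringsAsFactors = FALSE)
  }
  matches$status <- rep("tested", nrow(matches))
  list(matches = matches, testedPairs = pairs)
}

#' Propose novel SL-addressing drug combinations
#'
#' Enumerates all unordered pairs of the supplied drugs (those with
#' protein targets), drops pairs already tested, and emits every SL match
#' under the same single-drug exclusion as \code{\link{findSLMatches}},
#' with status \code{"novel"}.
#'
#' @param drugs Drug data.frame; restricted internally to drugs with
#'   protein targets.
#' @param testedPairs data.frame of canonical tested drug pairs
#'   (\code{drug_a}, \code{drug_b}), e.g. from
#'   \code{\link{screenTestedCombinations}}.
#' @param slSet \linkS4class{SLInteractionSet}.
#' @return Match data.frame with status \code{"novel"}.
#' @export
proposeNovelCombinations <- function(drugs, testedPairs, slSet) {
  drugs <- filterDrugsWithProteinTargets(drugs)
  targetsList <- drugTargets(drugs)
  covered <- .singleDrugCoveredKeys(targetsList, slSet)
  pairs <- .allPairs(drugs$drug_id)
  names(pairs) <- c("drug_a", "drug_b")
  if (nrow(testedPairs)) {
    testedKey <- .pairKey(testedPairs$drug_a, testedPairs$drug_b)
    pairs <- pairs[!.pairKey(pairs$drug_a, pairs$drug_b) %in% testedKey, ,
                   drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    .matchOnePair(pairs$drug_a[i], pairs$drug_b[i], targetsList, slSet,
                  covered)
  })
  matches <- do.call(rbind, rows)
  if (is.null(matches)) {
    matches <- data.frame(drug_a = character(), drug_b = character(),
                          gene_a = character(), gene_b = character(),
                          stringsAsFactors = FALSE)
  }
  matches$status <- rep("novel", nrow(matches))
  rownames(matches) <- NULL
  matches
}

#' Read a per-gene publication-count table
#'
#' TSV with header \code{gene}, \code{pmid_count}.
#'
#' @param file Path.
#' @return Named integer vector of counts.
#' @export
readPmidCounts <- function(file) {
  df <- read.delim(file)
  stopifnot(all(c("gene", "pmid_count") %in% names(df)))
  stats::setNames(as.integer(df$pmid_count), as.character(df$gene))
}

#' Rank SL matches by annotation degree
#'
#' The annotation degree of a match is the sum of the disease-specific
#' publication counts of its two SL partner genes; matches are sorted in
#' non-increasing degree order with a deterministic lexicographic
#' tie-break on (gene_a, gene_b, drug_a, drug_b). Genes missing from the
#' count table score 0 with a warning.
#'
#' @param matches Match data.frame (see \code{\link{findSLMatches}}).
#' @param counts Named numeric vector of per-gene publication counts, or a
#'   data.frame with columns \code{gene}, \code{pmid_count}.
#' @return The matches with added columns \code{count_a}, \code{count_b},
#'   \code{annotation_degree}, sorted.
#' @examples
#' m <- data.frame(drug_a = "pertuzumab", drug_b = "bevacizumab",
#'                 gene_a = "ERBB2", gene_b = "VEGFA", status = "novel")
#' rankByAnnotationDegree(m, c(ERBB2 = 695, VEGFA = 567))
#' @export
rankByAnnotationDegree <- function(matches, counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(as.numeric(counts$pmid_count),
                              as.character(counts$gene))
  }
  lookup <- function(g) {
    v <- counts[g]
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  miss <- setdiff(unique(c(matches$gene_a, matches$gene_b)), names(counts))
  if (length(miss)) {
    warning("no publication count for gene(s): ",
            paste(miss, collapse = ", "), "; using 0")
  }
  out <- matches
  out$count_a <- lookup(matches$gene_a)
  out$count_b <- lookup(matches$gene_b)
  out$annotation_degree <- out$count_a + out$count_b
  ord <- order(-out$annotation_degree, out$gene_a, out$gene_b, out$drug_a,
               out$drug_b, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ranked matches as a result table
#'
#' TSV with columns \code{drug_a}, \code{drug_b}, \code{synlet_a},
#' \code{synlet_b}, \code{annotation_degree}, \code{count_a},
#' \code{count_b}, \code{status}.
#'
#' @param ranked Output of \code{\link{rankByAnnotationDegree}}.
#' @param file Path.
#' @export
writeMatches <- function(ranked, file) {
  out <- data.frame(drug_a = ranked$drug_a, drug_b = ranked$drug_b,
                    synlet_a = ranked$gene_a, synlet_b = ranked$gene_b,
                    annotation_degree = ranked$annotation_degree,
                    count_a = ranked$count_a, count_b = ranked$count_b,
                    status = ranked$status)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
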