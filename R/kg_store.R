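# Heterogeneous drug/protein knowledge graph: construction, file I/O,
# degree computation, and train/valid/test splits (uniform and weak-nodes).

RELATION_KINDS <- c("poly_side_effect", "ppi", "drug_target", "similarity")

#' Construct a polypharmacy knowledge graph from in-memory tables
#'
#' Builds the heterogeneous knowledge graph used throughout the package:
#' drug and protein entities, one relation per polypharmacy side-effect
#' label plus protein-protein interaction (PPI) and drug-target relations,
#' and a deduplicated triple store. Mono (single-drug) side effects are kept
#' in a side table, not as graph triples.
#'
#' @param combo data.frame with columns `drug1`, `drug2`, `side_effect_id`
#'   and optionally `side_effect_name`; one row per known polypharmacy
#'   side-effect assertion.
#' @param ppi data.frame with columns `gene1`, `gene2`.
#' @param targets data.frame with columns `drug`, `gene`.
#' @param mono data.frame with columns `drug`, `mono_side_effect_id`.
#' @param smiles data.frame with columns `drug_id`, `canonical_smiles`;
#'   drugs absent from this table are recorded as missing-SMILES (not fatal,
#'   the chemistry layer substitutes a fallback vector).
#' @return An object of class `simvec_kg`: a list with data.tables
#'   `entities` (`entity_id`, `kind`, `external_id`, `smiles`), `relations`
#'   (`relation_id`, `kind`, `label`), `triples` (`head`, `relation`,
#'   `tail`, `weight`), and `mono` (`drug` entity id, `effect` label).
#'   Entity and relation ids are dense 1-based integers.
#' @export
kg_build <- function(combo = NULL, ppi = NULL, targets = NULL, mono = NULL,
                     smiles = NULL) {
  combo <- normalize_table(combo, c("drug1", "drug2", "side_effect_id"), "combo")
  ppi <- normalize_table(ppi, c("gene1", "gene2"), "ppi")
  targets <- normalize_table(targets, c("drug", "gene"), "targets")
  mono <- normalize_table(mono, c("drug", "mono_side_effect_id"), "mono")
  smiles <- normalize_table(smiles, c("drug_id", "canonical_smiles"), "smiles")

  drug_ids <- sort(unique(c(combo$drug1, combo$drug2, targets$drug,
                            mono$drug, smiles$drug_id)))
  protein_ids <- sort(unique(c(ppi$gene1, ppi$gene2, targets$gene)))
  assert_that(length(intersect(drug_ids, protein_ids)) == 0L,
              "an identifier appears both as a drug and as a protein")
  entities <- data.table(
    entity_id = seq_len(length(drug_ids) + length(protein_ids)),
    kind = rep(c("drug", "protein"), c(length(drug_ids), length(protein_ids))),
    external_id = c(drug_ids, protein_ids)
  )
  smap <- setNames(smiles$canonical_smiles, smiles$drug_id)
  entities[, smiles := ifelse(kind == "drug", unname(smap[external_id]),
                              NA_character_)]
  eid <- setNames(entities$entity_id, entities$external_id)

  se_labels <- sort(unique(combo$side_effect_id))
  relations <- data.table(
    relation_id = seq_len(length(se_labels) + 2L),
    kind = c(rep("poly_side_effect", length(se_labels)), "ppi", "drug_target"),
    label = c(se_labels, "ppi", "drug_target")
  )
  rid <- setNames(relations$relation_id, relations$label)

  triples <- rbindlist(list(
    if (nrow(combo)) data.table(head = eid[combo$drug1],
                                relation = rid[combo$side_effect_id],
                                tail = eid[combo$drug2]),
    if (nrow(ppi)) data.table(head = eid[ppi$gene1], relation = rid[["ppi"]],
                              tail = eid[ppi$gene2]),
    if (nrow(targets)) data.table(head = eid[targets$drug],
                                  relation = rid[["drug_target"]],
                                  tail = eid[targets$gene])
  ))
  if (is.null(triples) || nrow(triples) == 0L) {
    triples <- data.table(head = integer(), relation = integer(),
                          tail = integer())
  }
  triples <- unique(triples)
  triples[, weight := 1]

  mono_dt <- if (nrow(mono)) {
    unique(data.table(drug = unname(eid[mono$drug]),
                      effect = mono$mono_side_effect_id))
  } else data.table(drug = integer(), effect = character())

  missing_smiles <- drug_ids[is.na(smap[drug_ids]) | !(drug_ids %in% names(smap))]
  kg <- structure(list(entities = entities, relations = relations,
                       triples = triples, mono = mono_dt),
                  class = "simvec_kg")
  attr(kg, "missing_smiles") <- missing_smiles
  kg
}

normalize_table <- function(x, cols, what) {
  if (is.null(x)) {
    x <- as.data.table(setNames(rep(list(character()), length(cols)), cols))
    return(x)
  }
  x <- as.data.table(x)
  missing <- setdiff(cols, names(x))
  assert_that(length(missing) == 0L,
              sprintf("%s table lacks column(s): %s", what,
                      paste(missing, collapse = ", ")))
  x <- unique(x[, cols, with = FALSE])
  for (cc in cols) x[[cc]] <- as.character(x[[cc]])
  x
}

#' Load a knowledge graph from Decagon-style edge-list files
#'
#' Reads comma- or tab-separated tables (delimiter auto-detected, header row
#' required) and assembles them with [kg_build()]. Duplicate rows are
#' deduplicated and row counts are reported via `message()`.
#'
#' @param combo_file,ppi_file,targets_file,mono_file,smiles_file paths to the
#'   edge tables; any but `combo_file` may be `NULL`. Expected columns as in
#'   [kg_build()].
#' @param quiet suppress the row-count log messages.
#' @return A `simvec_kg` object.
#' @export
load_kg <- function(combo_file, ppi_file = NULL, targets_file = NULL,
                    mono_file = NULL, smiles_file = NULL, quiet = FALSE) {
  read1 <- function(path, what) {
    if (is.null(path)) return(NULL)
    assert_that(file.exists(path), sprintf("%s file not found: %s", what, path))
    x <- fread(path, header = TRUE, colClasses = "character")
    if (!quiet) message(sprintf("%s: read %d rows from %s", what, nrow(x), path))
    x
  }
  kg <- kg_build(combo = read1(combo_file, "combo"),
                 ppi = read1(ppi_file, "ppi"),
                 targets = read1(targets_file, "targets"),
                 mono = read1(mono_file, "mono"),
                 smiles = read1(smiles_file, "smiles"))
  if (!quiet && length(attr(kg, "missing_smiles"))) {
    message(sprintf("%d drug(s) without SMILES; fallback vectors will be used",
                    length(attr(kg, "missing_smiles"))))
  }
  kg
}

#' @export
print.simvec_kg <- function(x, ...) {
  nk <- table(x$entities$kind)
  cat(sprintf(
    "simvec_kg: %d drugs, %d proteins, %d relations (%d side effects), %d triples, %d mono records\n",
    nk[["drug"]] %||% 0L, if ("protein" %in% names(nk)) nk[["protein"]] else 0L,
    nrow(x$relations), sum(x$relations$kind == "poly_side_effect"),
    nrow(x$triples), nrow(x$mono)))
  invisible(x)
}

kg_relation_ids <- function(kg, kinds) {
  kg$relations$relation_id[kg$relations$kind %in% kinds]
}

kg_drug_ids <- function(kg) kg$entities$entity_id[kg$entities$kind == "drug"]
kg_protein_ids <- function(kg) kg$entities$entity_id[kg$entities$kind == "protein"]

#' Node degrees over non-similarity triples
#'
#' Degree of every entity, counting each triple once per incident endpoint
#' (a self-loop counts twice). Similarity edges never contribute.
#'
#' @param kg a `simvec_kg`.
#' @param scope `"all"` counts side-effect, PPI and drug-target triples;
#'   `"drug_drug_only"` counts only polypharmacy side-effect triples.
#' @param triples optional triple table to use instead of `kg$triples`
#'   (e.g. the train partition, to avoid leaking held-out edges).
#' @return Integer vector of length `nrow(kg$entities)`, indexed by entity id.
#' @export
kg_degrees <- function(kg, scope = c("all", "drug_drug_only"), triples = NULL) {
  scope <- match.arg(scope)
  triples <- triples %||% kg$triples
  kinds <- if (scope == "all") c("poly_side_effect", "ppi", "drug_target")
           else "poly_side_effect"
  rids <- kg_relation_ids(kg, kinds)
  tt <- triples[triples$relation %in% rids, ]
  deg <- integer(nrow(kg$entities))
  if (nrow(tt)) {
    cnt <- table(c(tt$head, tt$tail))
    deg[as.integer(names(cnt))] <- as.integer(cnt)
  }
  deg
}

#' Degree of a single entity
#'
#' @inheritParams kg_degrees
#' @param entity an entity id present in the graph.
#' @return A non-negative integer.
#' @export
kg_degree <- function(kg, entity, scope = c("all", "drug_drug_only"),
                      triples = NULL) {
  assert_that(length(entity) == 1L && entity %in% kg$entities$entity_id,
              sprintf("unknown entity id: %s", entity))
  kg_degrees(kg, scope, triples)[entity]
}

new_split <- function(train, valid, test, mode, seed, weak_drugs = NULL) {
  structure(list(train = train, valid = valid, test = test, mode = mode,
                 seed = seed, weak_drugs = weak_drugs,
                 n_weak_drugs = length(weak_drugs),
                 n_weak_triples = if (is.null(weak_drugs)) NA_integer_
                                  else nrow(valid) + nrow(test)),
            class = "simvec_split")
}

#' @export
print.simvec_split <- function(x, ...) {
  cat(sprintf("simvec_split (%s): train %d / valid %d / test %d triples",
              x$mode, nrow(x$train), nrow(x$valid), nrow(x$test)))
  if (!is.null(x$weak_drugs)) {
    cat(sprintf("; %d weak drugs, %d weak triples", x$n_weak_drugs,
                x$n_weak_triples))
  }
  cat("\n")
  invisible(x)
}

#' Per-relation stratified uniform split
#'
#' Randomly partitions the polypharmacy side-effect triples of each relation
#' into train/valid/test at the given fractions. PPI and drug-target triples
#' always stay in train: only drug-drug side-effect edges are evaluated.
#' A side-effect relation with fewer than 3 triples goes entirely to train
#' (with a warning).
#'
#' @param kg a `simvec_kg`.
#' @param fractions length-3 positive numeric summing to 1 (train, valid, test).
#' @param seed integer seed; identical inputs give identical splits.
#' @return A `simvec_split` with disjoint `train`, `valid`, `test` tables.
#' @export
uniform_split <- function(kg, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  assert_that(length(fractions) == 3L && all(fractions >= 0) &&
                abs(sum(fractions) - 1) < 1e-8 && fractions[1] > 0,
              "fractions must be non-negative and sum to 1")
  poly <- kg_relation_ids(kg, "poly_side_effect")
  tt <- kg$triples
  is_poly <- tt$relation %in% poly
  parts <- with_seed(derive_seed(seed, 101L), {
    out <- list(train = list(tt[!is_poly, ]), valid = list(), test = list())
    small <- character()
    for (r in poly) {
      tr <- tt[is_poly & tt$relation == r, ]
      n <- nrow(tr)
      if (n == 0L) next
      if (n < 3L && any(fractions[2:3] > 0)) {
        small <- c(small, as.character(r))
        out$train <- c(out$train, list(tr))
        next
      }
      idx <- sample.int(n)
      n_valid <- round(fractions[2] * n)
      n_test <- round(fractions[3] * n)
      n_train <- n - n_valid - n_test
      out$train <- c(out$train, list(tr[idx[seq_len(n_train)], ]))
      out$valid <- c(out$valid, list(tr[idx[n_train + seq_len(n_valid)], ]))
      out$test <- c(out$test, list(tr[idx[n_train + n_valid + seq_len(n_test)], ]))
    }
    if (length(small)) {
      warning(sprintf("relation(s) with < 3 triples kept fully in train: %s",
                      paste(small, collapse = ", ")))
    }
    out
  })
  bind0 <- function(l) if (length(l)) rbindlist(l) else
    kg$triples[0, ]
  new_split(bind0(parts$train), bind0(parts$valid), bind0(parts$test),
            mode = "uniform", seed = seed)
}

#' Identify the weakest drug nodes
#'
#' The `n` drugs with the smallest drug-drug (polypharmacy) degree, ties
#' broken by ascending external id, then entity id.
#'
#' @inheritParams uniform_split
#' @param n number of weak drugs to select.
#' @return Integer vector of entity ids.
#' @export
weak_drug_set <- function(kg, n) {
  drugs <- kg$entities[kg$entities$kind == "drug", ]
  assert_that(n > 0 && n < nrow(drugs),
              "n_weak_drugs must be in (0, number of drug nodes)")
  deg <- kg_degrees(kg, "drug_drug_only")[drugs$entity_id]
  ord <- order(deg, drugs$external_id, drugs$entity_id)
  drugs$entity_id[ord[seq_len(n)]]
}

#' Weak-nodes split: hold out every triple touching the weakest drugs
#'
#' Emulates prediction for newly developed drugs: the `n_weak_drugs`
#' lowest-degree drugs (drug-drug degree, ties by external id) define the
#' weak set; every polypharmacy triple incident to a weak drug is a "weak
#' triple". Weak triples are shuffled and assigned alternately to test and
#' validation (test receives the extra one when their number M is odd); all
#' remaining triples, including all PPI and drug-target edges, form train.
#'
#' @inheritParams uniform_split
#' @param n_weak_drugs number of weak drugs (paper-style N); the realized
#'   number of weak triples (M) is recorded on the result, not enforced.
#' @return A `simvec_split` with `weak_drugs`, `n_weak_drugs`,
#'   `n_weak_triples` filled in.
#' @export
weak_nodes_split <- function(kg, n_weak_drugs, seed = 1L) {
  weak <- weak_drug_set(kg, n_weak_drugs)
  poly <- kg_relation_ids(kg, "poly_side_effect")
  tt <- kg$triples
  is_weak <- tt$relation %in% poly & (tt$head %in% weak | tt$tail %in% weak)
  weak_tr <- tt[is_weak, ]
  m <- nrow(weak_tr)
  idx <- with_seed(derive_seed(seed, 202L), sample.int(max(m, 1L)))
  if (m == 0L) idx <- integer()
  test_rows <- idx[seq_along(idx) %% 2L == 1L]   # odd positions -> test (gets extra)
  valid_rows <- idx[seq_along(idx) %% 2L == 0L]
  train <- tt[!is_weak, ]
  n_strong_drugs <- sum(kg$entities$kind == "drug") - length(weak)
  if (n_strong_drugs <= 1L) {
    warning("all but one drug marked weak; train holds no drug-drug variety")
  }
  new_split(train, weak_tr[valid_rows, ], weak_tr[test_rows, ],
            mode = "weak", seed = seed, weak_drugs = weak)
}

#' Export a split as three TSV triple files plus a JSON manifest
#'
#' Triples are written with external entity ids and relation labels so the
#' files remain meaningful outside this session; `manifest.json` records the
#' mode, seed and realized weak-split statistics.
#'
#' @param split a `simvec_split`.
#' @param kg the graph the split was made from.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, kg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- setNames(kg$entities$external_id, kg$entities$entity_id)
  rel <- setNames(kg$relations$label, kg$relations$relation_id)
  for (part in c("train", "valid", "test")) {
    tr <- split[[part]]
    fwrite(data.table(head = unname(ext[as.character(tr$head)]),
                      relation = unname(rel[as.character(tr$relation)]),
                      tail = unname(ext[as.character(tr$tail)])),
           file.path(dir, paste0(part, ".tsv")), sep = "\t")
  }
  manifest <- list(mode = split$mode, seed = split$seed,
                   n_weak_drugs = split$n_weak_drugs,
                   n_weak_triples = split$n_weak_triples,
                   weak_drugs = if (is.null(split$weak_drugs)) NULL
                                else unname(ext[as.character(split$weak_drugs)]))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Re-import a split written by [write_split()]
#'
#' @param dir directory holding `train.tsv`, `valid.tsv`, `test.tsv`,
#'   `manifest.json`.
#' @param kg the graph whose ids the triples are mapped back onto.
#' @return A `simvec_split`.
#' @export
read_split <- function(dir, kg) {
  eid <- setNames(kg$entities$entity_id, kg$entities$external_id)
  rid <- setNames(kg$relations$relation_id, kg$relations$label)
  rd <- function(part) {
    x <- fread(file.path(dir, paste0(part, ".tsv")), colClasses = "character")
    data.table(head = unname(eid[x$head]), relation = unname(rid[x$relation]),
               tail = unname(eid[x$tail]), weight = 1)
  }
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  weak <- if (!is.null(manifest$weak_drugs)) unname(eid[manifest$weak_drugs])
  new_split(rd("train"), rd("valid"), rd("test"), mode = manifest$mode,
            seed = manifest$seed, weak_drugs = weak)
}
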