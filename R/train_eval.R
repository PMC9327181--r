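# The 3-step training loop (side-effect edges, weighted similarity edges,
# weak-node anchoring), early stopping on validation macro ROC AUC, and the
# per-relation ROC/PR evaluation protocol.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (0.001 in the enhanced
#'   configuration; 0.005 suits the plain trilinear baseline).
#' @param epochs_max maximum number of epochs.
#' @param early_stop_epsilon minimal improvement in validation macro ROC AUC
#'   that counts as progress.
#' @param early_stop_patience consecutive non-improving epochs tolerated
#'   before stopping.
#' @param batch_size minibatch size.
#' @param K embedding length per part.
#' @param lambda N3 regularization weight.
#' @param components named logical list enabling `chemical_init`,
#'   `similarity_edges`, `weak_anchor_loss`; all off reproduces the plain
#'   trilinear (TriVec-style) baseline exactly.
#' @param drug_init overrides the drug initialization; default follows
#'   `components$chemical_init` (`chemical` if on else `xavier`); set
#'   `"mono_se"` for single-side-effect initialization.
#' @param sampler a [sampler_spec()].
#' @param scheme a [weighting_scheme()] for similarity edges.
#' @param min_weight prune similarity edges at or below this weight.
#' @param n_sim_neighbors anchors per weak drug in the step-3 loss.
#' @param weak_fraction fraction of drugs (lowest train drug-drug degree)
#'   treated as weak during training.
#' @param seed master seed for initialization, batching and sampling.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, epochs_max = 50L,
                         early_stop_epsilon = 0.001,
                         early_stop_patience = 7L, batch_size = 512L,
                         K = 100L, lambda = 0.01,
                         components = list(), drug_init = NULL,
                         sampler = sampler_spec("uniform"),
                         scheme = weighting_scheme("window"),
                         min_weight = 0, n_sim_neighbors = 6L,
                         weak_fraction = 1 / 6, seed = 1L) {
  comp <- modifyList(list(chemical_init = FALSE, similarity_edges = FALSE,
                          weak_anchor_loss = FALSE), components)
  assert_that(early_stop_patience >= 1L && early_stop_epsilon >= 0,
              "patience must be >= 1 and epsilon >= 0")
  drug_init <- drug_init %||% if (comp$chemical_init) "chemical" else "xavier"
  structure(list(learning_rate = learning_rate,
                 epochs_max = as.integer(epochs_max),
                 early_stop_epsilon = early_stop_epsilon,
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size), K = as.integer(K),
                 lambda = lambda, components = comp, drug_init = drug_init,
                 sampler = sampler, scheme = scheme, min_weight = min_weight,
                 n_sim_neighbors = as.integer(n_sim_neighbors),
                 weak_fraction = weak_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# ---- metrics ---------------------------------------------------------------

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks for ties.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "roc_auc needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: mean, over the positives in score-descending order,
#' of the precision at each positive's rank.
#'
#' @inheritParams roc_auc
#' @return AP in `(0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  assert_that(sum(labels == 1) > 0, "auc_pr needs at least one positive")
  o <- order(-scores)
  lab <- labels[o]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec * lab) / sum(lab)
}

# frozen filtered evaluation negatives: one uniform corruption per positive
evaluation_negatives <- function(kg, triples, seed, forbidden) {
  uniform_corrupt(kg, triples, neg_ratio = 1L, seed = derive_seed(seed, 601L),
                  forbidden = forbidden)
}

all_positive_keys <- function(kg, extra = NULL) {
  keys <- triple_key(kg$triples$head, kg$triples$relation, kg$triples$tail)
  unique(c(keys, extra))
}

#' Per-relation ROC/PR evaluation of a model
#'
#' For every polypharmacy side-effect relation present in `triples`,
#' generates one filtered uniform negative per positive (seeded, excluded
#' from all known positives), scores both sets, and computes ROC AUC and
#' average precision. The headline metrics are the unweighted (macro)
#' averages over relations; FPR and FNR are pooled over all relations at the
#' `sigmoid(score) > threshold` decision rule.
#'
#' @param model a `trivec_model`.
#' @param kg the graph (supplies relation kinds and the filter set).
#' @param triples evaluation triples (e.g. `split$test`).
#' @param seed seed for the frozen negatives.
#' @param threshold sigmoid decision threshold for FPR/FNR.
#' @param negatives optionally precomputed negatives (as returned by
#'   [uniform_corrupt()]) to reuse across epochs.
#' @return List with `per_relation` (data.table), `macro_roc_auc`,
#'   `macro_auc_pr`, `fpr`, `fnr`, `n_pos`.
#' @export
evaluate <- function(model, kg, triples, seed = 1L, threshold = 0.5,
                     negatives = NULL) {
  triples <- as.data.table(triples)
  poly <- kg_relation_ids(kg, "poly_side_effect")
  triples <- triples[triples$relation %in% poly, ]
  assert_that(nrow(triples) > 0L, "no side-effect triples to evaluate")
  if (is.null(negatives)) {
    negatives <- evaluation_negatives(kg, triples, seed,
                                      forbidden = all_positive_keys(kg))
  }
  pos_scores <- score_triples(model, triples$head, triples$relation,
                              triples$tail)
  neg_scores <- score_triples(model, negatives$head, negatives$relation,
                              negatives$tail)
  labels <- setNames(kg$relations$label, kg$relations$relation_id)
  per_rel <- rbindlist(lapply(sort(unique(triples$relation)), function(rr) {
    sp <- pos_scores[triples$relation == rr]
    sn <- neg_scores[negatives$relation == rr]
    if (!length(sn)) {
      warning(sprintf("relation %s: no negatives generated; skipped", rr))
      return(NULL)
    }
    s <- c(sp, sn); l <- rep(1:0, c(length(sp), length(sn)))
    data.table(relation = rr, label = labels[[as.character(rr)]],
               n_pos = length(sp), roc_auc = roc_auc(s, l),
               auc_pr = auc_pr(s, l))
  }))
  pred_pos <- sigmoid(pos_scores) > threshold
  pred_neg <- sigmoid(neg_scores) > threshold
  list(per_relation = per_rel,
       macro_roc_auc = mean(per_rel$roc_auc),
       macro_auc_pr = mean(per_rel$auc_pr),
       fpr = mean(pred_neg), fnr = mean(!pred_pos),
       n_pos = nrow(triples))
}

# ---- training --------------------------------------------------------------

# static per-run state assembled once before the epoch loop
build_trainer <- function(kg, split, config, profiles) {
  needs_prof <- config$components$chemical_init ||
    config$components$similarity_edges ||
    config$sampler$kind == "strong_nscaching" ||
    config$drug_init == "chemical"
  if (needs_prof) {
    assert_that(inherits(profiles, "chem_profiles"),
                "this configuration requires chemical profiles")
  }
  st <- list(forbidden = triple_key(split$train$head, split$train$relation,
                                    split$train$tail))
  if (config$components$similarity_edges) {
    scheme <- config$scheme
    if (scheme$kind == "window" && profiles$kind != "descriptor") {
      scheme <- weighting_scheme("proportional")   # native metric fallback
    }
    enh <- build_similarity_edges(kg, profiles, scheme,
                                  train_triples = split$train,
                                  min_weight = config$min_weight)
    st$kg <- enh$kg
    st$sim_edges <- enh$edges
  } else {
    st$kg <- kg
  }
  drugs <- kg_drug_ids(kg)
  deg <- kg_degrees(kg, "drug_drug_only", split$train)
  st$train_degrees <- deg
  if (config$components$weak_anchor_loss ||
      config$sampler$kind == "strong_nscaching") {
    ext <- setNames(kg$entities$external_id, kg$entities$entity_id)
    n_weak <- max(1L, floor(length(drugs) * config$weak_fraction))
    ord <- order(deg[drugs], ext[as.character(drugs)], drugs)
    st$weak_train <- drugs[ord[seq_len(n_weak)]]
    st$strong_train <- setdiff(drugs, st$weak_train)
  }
  if (config$components$weak_anchor_loss) {
    st$neighbors <- mono_neighbors(kg, st$weak_train, st$strong_train,
                                   config$n_sim_neighbors)
  }
  if (config$sampler$kind == "strong_nscaching") {
    sm <- vapply(st$weak_train, function(w) {
      nn <- nearest_strong_neighbor(ext[[as.character(w)]],
                                    ext[as.character(st$strong_train)],
                                    profiles)
      kg$entities$entity_id[kg$entities$external_id == nn]
    }, integer(1L))
    st$strong_map <- setNames(sm, st$weak_train)
  }
  st
}

sample_negatives <- function(trainer, config, batch, seed) {
  sp <- config$sampler
  switch(sp$kind,
    uniform = uniform_corrupt(trainer$kg, batch, sp$neg_ratio, seed,
                              trainer$forbidden),
    bernoulli = bernoulli_corrupt(trainer$kg, batch, sp$neg_ratio, seed,
                                  trainer$forbidden,
                                  reference_triples = NULL),
    strong_nscaching = strong_cache_sample(trainer$cache, trainer$kg, batch,
                                           sp, trainer$strong_map,
                                           trainer$train_degrees,
                                           sp$neg_ratio, seed,
                                           trainer$forbidden),
    # nscaching / nscaching_61 / exploration
    cache_sample(trainer$cache, trainer$kg, batch, sp$neg_ratio, seed,
                 trainer$forbidden))
}

#' One pass of the 3-step training process
#'
#' Step 1 runs minibatch updates over the train side-effect / PPI / target
#' triples with the ranking loss and sampled negatives; step 2 runs
#' minibatches over the weighted similarity edges (skipped when disabled);
#' step 3 takes one gradient step on the weak-node anchor loss (skipped when
#' disabled). Cache-based samplers receive one cache update per epoch
#' (performed inside [fit()]).
#'
#' @param model a `trivec_model`.
#' @param trainer internal state from `build_trainer` (exposed for tests via
#'   [fit()]'s return value).
#' @param config a [train_config()].
#' @param epoch epoch number (seeds batching and sampling).
#' @return List `model` (updated) and `losses` (mean step-1/2/3 losses).
#' @keywords internal
train_epoch <- function(model, trainer, config, epoch) {
  lr <- config$learning_rate
  train <- with_seed(
    derive_seed(config$seed, 700L + epoch),
    trainer$split_train[sample.int(nrow(trainer$split_train)), ])
  n <- nrow(train)
  starts <- seq(1L, n, by = config$batch_size)
  loss1 <- numeric(length(starts))
  for (bi in seq_along(starts)) {
    rows <- starts[bi]:min(starts[bi] + config$batch_size - 1L, n)
    batch <- train[rows, ]
    neg <- sample_negatives(trainer, config, batch,
                            derive_seed(config$seed, 800L + epoch * 37L + bi))
    lg <- loss_grad_core(model, batch, neg)
    if (!is.finite(lg$loss)) {
      stop(sprintf("training diverged at epoch %d batch %d (loss %g)",
                   epoch, bi, lg$loss))
    }
    model <- adam_step(model, lg$grads, lr)
    loss1[bi] <- lg$loss
  }
  loss2 <- NA_real_
  if (config$components$similarity_edges && nrow(trainer$sim_edges)) {
    edges <- with_seed(derive_seed(config$seed, 900L + epoch),
                       trainer$sim_edges[sample.int(nrow(trainer$sim_edges)), ])
    ne <- nrow(edges)
    estarts <- seq(1L, ne, by = config$batch_size)
    l2 <- numeric(length(estarts))
    for (bi in seq_along(estarts)) {
      rows <- estarts[bi]:min(estarts[bi] + config$batch_size - 1L, ne)
      batch <- edges[rows, ]
      # similarity graph is near-complete: corruptions are random drug pairs,
      # not filtered against it
      neg <- uniform_corrupt(trainer$kg, batch, 1L,
                             derive_seed(config$seed, 950L + epoch * 37L + bi))
      lg <- loss_grad_core(model, batch, neg, triple_weights = batch$weight)
      model <- adam_step(model, lg$grads, lr)
      l2[bi] <- lg$loss
    }
    loss2 <- mean(l2)
  }
  loss3 <- NA_real_
  if (config$components$weak_anchor_loss) {
    wa <- weak_anchor_core(model, trainer$neighbors)
    model <- adam_step(model, wa$grads, lr)
    loss3 <- wa$loss
  }
  list(model = model, losses = c(main = mean(loss1), similarity = loss2,
                                 anchor = loss3))
}

#' Fit the model with early stopping on validation macro ROC AUC
#'
#' Runs [train_epoch()] until the validation macro ROC AUC fails to improve
#' by more than `early_stop_epsilon` for `early_stop_patience` consecutive
#' epochs, or `epochs_max` is reached. Validation negatives are generated
#' once (frozen) so the early-stopping signal is comparable across epochs.
#' The best-validation checkpoint is returned.
#'
#' @param kg a `simvec_kg`.
#' @param split a `simvec_split` with a nonempty validation set.
#' @param config a [train_config()].
#' @param profiles optional `chem_profiles` (required when chemical
#'   initialization, similarity edges or strong-neighbor sampling are on).
#' @return List with `model` (best checkpoint), `history` (per-epoch losses
#'   and validation AUC), `best_epoch`, `config`, and `trainer` internals.
#' @export
fit <- function(kg, split, config = train_config(), profiles = NULL) {
  assert_that(nrow(split$valid) > 0L, "validation set is empty")
  trainer <- build_trainer(kg, split, config, profiles)
  trainer$split_train <- split$train
  init <- init_spec(config$drug_init,
                    profiles = if (config$drug_init == "chemical") profiles,
                    jitter = 0.01)
  model <- trivec_model(trainer$kg, K = config$K, lambda = config$lambda,
                        init = init, seed = config$seed)
  if (uses_cache(config$sampler)) {
    trainer$cache <- cache_init(trainer$kg, split$train, config$sampler,
                                derive_seed(config$seed, 111L))
  }
  valid_neg <- evaluation_negatives(kg, split$valid, config$seed,
                                    forbidden = all_positive_keys(kg))
  best <- list(metric = -Inf, model = model, epoch = 0L)
  stall <- 0L
  hist <- vector("list", config$epochs_max)
  for (epoch in seq_len(config$epochs_max)) {
    if (uses_cache(config$sampler)) {
      cache_update(trainer$cache, model, trainer$kg, config$sampler,
                   derive_seed(config$seed, 120L + epoch))
    }
    step <- train_epoch(model, trainer, config, epoch)
    model <- step$model
    ev <- evaluate(model, kg, split$valid, negatives = valid_neg)
    hist[[epoch]] <- data.table(epoch = epoch,
                                loss_main = step$losses[["main"]],
                                loss_similarity = step$losses[["similarity"]],
                                loss_anchor = step$losses[["anchor"]],
                                valid_roc_auc = ev$macro_roc_auc)
    if (ev$macro_roc_auc > best$metric + config$early_stop_epsilon) {
      best <- list(metric = ev$macro_roc_auc, model = model, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  }
  list(model = best$model, history = rbindlist(hist[!vapply(hist, is.null,
                                                            logical(1L))]),
       best_epoch = best$epoch, best_valid_roc_auc = best$metric,
       config = config, trainer = trainer)
}

#' Rank candidate side effects for a drug pair
#'
#' Scores every polypharmacy side-effect relation for the (a, r, b) triple,
#' symmetrized as `max(phi(a, r, b), phi(b, r, a))`, and returns the top-k
#' in descending order.
#'
#' @param model a `trivec_model`.
#' @param kg the graph.
#' @param drug_a,drug_b drug external ids.
#' @param top_k number of relations to return (clamped to the relation
#'   count).
#' @return data.table with `relation`, `label`, `score`.
#' @export
predict_side_effects <- function(model, kg, drug_a, drug_b, top_k = 10L) {
  eid <- setNames(kg$entities$entity_id, kg$entities$external_id)
  assert_that(drug_a %in% names(eid) && drug_b %in% names(eid),
              "unknown drug id")
  a <- eid[[drug_a]]; b <- eid[[drug_b]]
  poly <- kg_relation_ids(kg, "poly_side_effect")
  s_ab <- score_triples(model, rep(a, length(poly)), poly,
                        rep(b, length(poly)))
  s_ba <- score_triples(model, rep(b, length(poly)), poly,
                        rep(a, length(poly)))
  s <- pmax(s_ab, s_ba)
  labels <- setNames(kg$relations$label, kg$relations$relation_id)
  out <- data.table(relation = poly, label = labels[as.character(poly)],
                    score = s)
  setorder(out, -score, relation)
  out[seq_len(min(top_k, nrow(out))), ]
}
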