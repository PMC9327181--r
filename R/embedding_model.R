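# Trilinear triple-part embedding model: entity/relation triples of vectors,
# the trilinear scorer, the softmax ranking loss with N3 regularization, the
# weighted similarity-edge loss, and the weak-node anchor (MSE) loss.
# Gradients are derived analytically; optimization uses Adam.

#' Drug-node initialization specification
#'
#' Proteins and relations are always Xavier-initialized; drugs can instead
#' start from chemical profiles (`chemical`) or from a binary indicator over
#' the most frequent single (mono) side effects (`mono_se`). Structured
#' initializations are rescaled to the Xavier standard deviation and receive
#' a small seeded Gaussian jitter (fraction `jitter` of that scale) so that
#' identical twins can still diverge during training.
#'
#' @param drug_init `"xavier"`, `"chemical"` or `"mono_se"`.
#' @param profiles `chem_profiles` (required for `chemical`).
#' @param jitter jitter fraction.
#' @return An `init_spec` object.
#' @export
init_spec <- function(drug_init = c("xavier", "chemical", "mono_se"),
                      profiles = NULL, jitter = 0.01) {
  drug_init <- match.arg(drug_init)
  if (drug_init == "chemical") {
    assert_that(inherits(profiles, "chem_profiles"),
                "chemical initialization requires chem_profiles")
  }
  structure(list(drug_init = drug_init, profiles = profiles, jitter = jitter),
            class = "init_spec")
}

# rescale a vector so its component sd matches `target_sd` (zero vectors stay zero)
rescale_to <- function(v, target_sd) {
  s <- sd(v)
  if (is.na(s) || s == 0) return(v * 0)
  v * (target_sd / s)
}

#' Initialize a trilinear embedding model over a knowledge graph
#'
#' Each entity i carries three K-vectors (e1, e2, e3) and each relation j
#' three K-vectors (w1, w2, w3). Xavier initialization draws N(0, 1/K)
#' entries; chemical / mono-side-effect initializations copy the structured
#' vector into all three parts (padded or truncated to K), rescaled to the
#' Xavier scale, plus jitter per [init_spec()].
#'
#' @param kg a `simvec_kg`.
#' @param K embedding length per part.
#' @param lambda N3 regularization weight.
#' @param init an [init_spec()].
#' @param seed integer seed; identical inputs give identical tables.
#' @return A `trivec_model`: lists `E` and `R` of three matrices each, plus
#'   `K`, `lambda` and bookkeeping.
#' @export
trivec_model <- function(kg, K = 100L, lambda = 0.01, init = init_spec(),
                         seed = 1L) {
  n_ent <- nrow(kg$entities)
  n_rel <- nrow(kg$relations)
  xsd <- 1 / sqrt(K)
  model <- with_seed(derive_seed(seed, 301L), {
    E <- lapply(1:3, function(m) matrix(rnorm(n_ent * K, sd = xsd), n_ent, K))
    R <- lapply(1:3, function(m) matrix(rnorm(n_rel * K, sd = xsd), n_rel, K))
    drugs <- kg$entities[kg$entities$kind == "drug", ]
    if (init$drug_init != "xavier" && nrow(drugs)) {
      base <- switch(init$drug_init,
        chemical = {
          m0 <- init$profiles$mat
          out <- matrix(0, nrow(drugs), K)
          hit <- drugs$external_id %in% rownames(m0)
          if (any(!hit)) {
            warning(sprintf("%d drug(s) lack chemical profiles; zero fallback",
                            sum(!hit)))
          }
          d <- min(ncol(m0), K)
          out[hit, seq_len(d)] <- m0[drugs$external_id[hit], seq_len(d)]
          out
        },
        mono_se = {
          freq <- sort(table(kg$mono$effect), decreasing = TRUE)
          vocab <- names(freq)[order(-as.integer(freq), names(freq))]
          vocab <- head(vocab, K)
          out <- matrix(0, nrow(drugs), K)
          if (nrow(kg$mono)) {
            mm <- kg$mono[kg$mono$effect %in% vocab, ]
            ridx <- match(mm$drug, drugs$entity_id)
            cidx <- match(mm$effect, vocab)
            keep <- !is.na(ridx)
            out[cbind(ridx[keep], cidx[keep])] <- 1
          }
          out
        })
      base <- t(apply(base, 1L, rescale_to, target_sd = xsd))
      for (m in 1:3) {
        E[[m]][drugs$entity_id, ] <- base +
          matrix(rnorm(length(base), sd = init$jitter * xsd), nrow(base))
      }
    }
    list(E = E, R = R)
  })
  structure(list(E = model$E, R = model$R, K = K, lambda = lambda,
                 n_entities = n_ent, n_relations = n_rel,
                 drug_init = init$drug_init, opt = NULL),
            class = "trivec_model")
}

#' @export
print.trivec_model <- function(x, ...) {
  cat(sprintf("trivec_model: %d entities, %d relations, K = %d, lambda = %g, drug init = %s\n",
              x$n_entities, x$n_relations, x$K, x$lambda, x$drug_init))
  invisible(x)
}

#' Trilinear triple score
#'
#' `phi(s, p, o) = sum_k e_s1 w_p1 e_o3 + e_s2 w_p2 e_o2 + e_s3 w_p3 e_o1`,
#' vectorized over equal-length id vectors.
#'
#' @param model a `trivec_model`.
#' @param h,r,t entity / relation / entity id vectors.
#' @return Numeric score vector.
#' @export
score_triples <- function(model, h, r, t) {
  assert_that(all(h >= 1 & h <= model$n_entities) &&
                all(t >= 1 & t <= model$n_entities) &&
                all(r >= 1 & r <= model$n_relations),
              "unknown entity or relation id")
  E <- model$E; R <- model$R
  rowSums(E[[1]][h, , drop = FALSE] * R[[1]][r, , drop = FALSE] *
            E[[3]][t, , drop = FALSE]) +
    rowSums(E[[2]][h, , drop = FALSE] * R[[2]][r, , drop = FALSE] *
              E[[2]][t, , drop = FALSE]) +
    rowSums(E[[3]][h, , drop = FALSE] * R[[3]][r, , drop = FALSE] *
              E[[1]][t, , drop = FALSE])
}

zero_grads <- function(model) {
  list(E = lapply(model$E, function(m) m * 0),
       R = lapply(model$R, function(m) m * 0))
}

# accumulate d(sum c_i * phi_i)/d(params) into g for long-form triples
accumulate_phi_grad <- function(g, model, h, r, t, coef) {
  if (!length(h)) return(g)
  E <- model$E; R <- model$R
  E1h <- E[[1]][h, , drop = FALSE]; E2h <- E[[2]][h, , drop = FALSE]
  E3h <- E[[3]][h, , drop = FALSE]
  E1t <- E[[1]][t, , drop = FALSE]; E2t <- E[[2]][t, , drop = FALSE]
  E3t <- E[[3]][t, , drop = FALSE]
  R1 <- R[[1]][r, , drop = FALSE]; R2 <- R[[2]][r, , drop = FALSE]
  R3 <- R[[3]][r, , drop = FALSE]
  g$E[[1]] <- index_add(g$E[[1]], h, coef * (R1 * E3t))
  g$E[[2]] <- index_add(g$E[[2]], h, coef * (R2 * E2t))
  g$E[[3]] <- index_add(g$E[[3]], h, coef * (R3 * E1t))
  g$E[[3]] <- index_add(g$E[[3]], t, coef * (E1h * R1))
  g$E[[2]] <- index_add(g$E[[2]], t, coef * (E2h * R2))
  g$E[[1]] <- index_add(g$E[[1]], t, coef * (E3h * R3))
  g$R[[1]] <- index_add(g$R[[1]], r, coef * (E1h * E3t))
  g$R[[2]] <- index_add(g$R[[2]], r, coef * (E2h * E2t))
  g$R[[3]] <- index_add(g$R[[3]], r, coef * (E3h * E1t))
  g
}

# core loss/gradient of the two-sided softmax ranking loss with N3 penalty.
# positives: data.table(head, relation, tail); negatives: data.table
# (pos_index, slot in {"head","tail"}, entity). triple_weights scales each
# positive's whole per-triple loss (similarity-edge weighting). Candidate
# sets are {true} union that slot's negatives; a slot without negatives
# contributes a collapsed (zero) log-sum-exp term, per the loss definition.
loss_grad_core <- function(model, positives, negatives = NULL,
                           triple_weights = NULL, lambda = model$lambda,
                           with_grad = TRUE) {
  B <- nrow(positives)
  assert_that(B > 0L, "empty positive batch")
  if (!is.null(negatives) && nrow(negatives) && !("entity" %in% names(negatives))) {
    # sampler output form: full corrupted triples + slot
    negatives <- data.table(pos_index = negatives$pos_index,
                            slot = negatives$slot,
                            entity = ifelse(negatives$slot == "head",
                                            negatives$head, negatives$tail))
  }
  w <- triple_weights %||% rep(1, B)
  h <- positives$head; r <- positives$relation; t <- positives$tail
  phi_pos <- score_triples(model, h, r, t)
  g <- if (with_grad) zero_grads(model) else NULL

  per_triple <- numeric(B)
  side <- function(slot) {
    # long-form candidates: true entity first, then the slot's negatives
    idx <- seq_len(B)
    cand_ent <- if (slot == "tail") t else h
    long_i <- idx; long_e <- cand_ent; is_true <- rep(TRUE, B)
    if (!is.null(negatives) && nrow(negatives)) {
      nn <- negatives[negatives$slot == slot, ]
      if (nrow(nn)) {
        long_i <- c(long_i, nn$pos_index)
        long_e <- c(long_e, nn$entity)
        is_true <- c(is_true, rep(FALSE, nrow(nn)))
      }
    }
    if (slot == "tail") {
      hh <- h[long_i]; tt <- long_e
    } else {
      hh <- long_e; tt <- t[long_i]
    }
    rr <- r[long_i]
    phi <- score_triples(model, hh, rr, tt)
    lse <- grouped_logsumexp(phi, long_i, B)
    per_triple <<- per_triple + (lse - phi_pos)
    if (with_grad) {
      coef <- exp(phi - lse[long_i])       # softmax weights
      coef[is_true] <- coef[is_true] - 1   # minus the positive-score term
      coef <- coef * w[long_i] / B
      g <<- accumulate_phi_grad(g, model, hh, rr, tt, coef)
    }
  }
  side("tail")
  side("head")

  # N3 regularization on the touched (positive-triple) embeddings
  if (lambda > 0) {
    E <- model$E; R <- model$R
    reg <- numeric(B)
    for (m in 1:3) {
      reg <- reg + rowSums(abs(E[[m]][h, , drop = FALSE])^3) +
        rowSums(abs(R[[m]][r, , drop = FALSE])^3) +
        rowSums(abs(E[[m]][t, , drop = FALSE])^3)
    }
    per_triple <- per_triple + (lambda / 3) * reg
    if (with_grad) {
      for (m in 1:3) {
        dcube <- function(x) sign(x) * x^2
        cw <- (lambda / 3) * 3 * w / B     # d|x|^3 = 3 sign(x) x^2
        g$E[[m]] <- index_add(g$E[[m]], h, cw * dcube(E[[m]][h, , drop = FALSE]))
        g$E[[m]] <- index_add(g$E[[m]], t, cw * dcube(E[[m]][t, , drop = FALSE]))
        g$R[[m]] <- index_add(g$R[[m]], r, cw * dcube(R[[m]][r, , drop = FALSE]))
      }
    }
  }
  list(loss = mean(w * per_triple), grads = g)
}

#' Two-sided softmax ranking loss with N3 regularization
#'
#' Per positive triple (s, p, o) with tail candidates o' and head candidates
#' s' (each candidate set = the sampled negatives for that slot plus the
#' true entity):
#' `-phi_spo + log sum_o' exp(phi_spo') - phi_spo + log sum_s' exp(phi_s'po)
#'  + (lambda/3) sum_k sum_m (|e_s^m|^3 + |w_p^m|^3 + |e_o^m|^3)`.
#' The batch loss is the mean over positives.
#'
#' @param model a `trivec_model`.
#' @param positives data.frame with columns `head`, `relation`, `tail`.
#' @param negatives optional data.frame with columns `pos_index` (row in
#'   `positives`), `slot` (`"head"` or `"tail"`), `entity` (the corruption).
#' @param lambda regularization weight (defaults to the model's).
#' @return The scalar batch loss.
#' @export
trivec_loss <- function(model, positives, negatives = NULL,
                        lambda = model$lambda) {
  loss_grad_core(model, as.data.table(positives),
                 if (!is.null(negatives)) as.data.table(negatives),
                 lambda = lambda, with_grad = FALSE)$loss
}

#' Weighted similarity-edge loss
#'
#' Each similarity triple's ranking loss is scaled by its edge weight:
#' `L = weight(h, t) * L_trivec(h, r_sim, t)`; the batch value is the mean
#' of the weighted per-triple losses.
#'
#' @param model a `trivec_model`.
#' @param edges data.frame with `head`, `relation`, `tail`, `weight`.
#' @inheritParams trivec_loss
#' @return The scalar batch loss.
#' @export
similarity_edge_loss <- function(model, edges, negatives = NULL,
                                 lambda = model$lambda) {
  edges <- as.data.table(edges)
  assert_that(all(edges$weight > 0 & edges$weight <= 1) || nrow(edges) == 0L,
              "similarity-edge weights must lie in (0, 1]")
  loss_grad_core(model, edges,
                 if (!is.null(negatives)) as.data.table(negatives),
                 triple_weights = edges$weight, lambda = lambda,
                 with_grad = FALSE)$loss
}

# neighbors by shared mono side effects: for each weak drug, the
# n_sim_neighbors pool drugs with the largest overlap (ties by external id)
mono_neighbors <- function(kg, weak_drugs, pool, n_sim_neighbors = 6L) {
  mono <- kg$mono
  ext <- setNames(kg$entities$external_id, kg$entities$entity_id)
  assert_that(nrow(mono) > 0L, "mono side-effect table is empty")
  eff <- sort(unique(mono$effect))
  all_d <- sort(unique(c(weak_drugs, pool)))
  mm <- matrix(0L, length(all_d), length(eff),
               dimnames = list(all_d, eff))
  hit <- mono[mono$drug %in% all_d, ]
  if (nrow(hit)) mm[cbind(match(hit$drug, all_d), match(hit$effect, eff))] <- 1L
  common <- mm[as.character(weak_drugs), , drop = FALSE] %*%
    t(mm[as.character(pool), , drop = FALSE])
  n_take <- min(n_sim_neighbors, length(pool))
  if (n_take < n_sim_neighbors) {
    warning(sprintf("only %d neighbor candidates available (asked %d)",
                    length(pool), n_sim_neighbors))
  }
  out <- lapply(seq_along(weak_drugs), function(i) {
    ord <- order(-common[i, ], ext[as.character(pool)], pool)
    pool[ord[seq_len(n_take)]]
  })
  names(out) <- as.character(weak_drugs)
  out
}

weak_anchor_core <- function(model, neighbors, with_grad = TRUE) {
  weak <- as.integer(names(neighbors))
  K3 <- 3L * model$K
  concat <- function(ids) cbind(model$E[[1]][ids, , drop = FALSE],
                                model$E[[2]][ids, , drop = FALSE],
                                model$E[[3]][ids, , drop = FALSE])
  x <- concat(weak)
  target <- do.call(rbind, lapply(neighbors, function(nb)
    colMeans(concat(nb))))
  diff <- x - target
  loss <- mean(rowMeans(diff^2))
  g <- NULL
  if (with_grad) {
    g <- zero_grads(model)
    coefs <- 2 * diff / (K3 * length(weak))   # anchors detached: weak rows only
    for (m in 1:3) {
      cols <- (m - 1L) * model$K + seq_len(model$K)
      g$E[[m]] <- index_add(g$E[[m]], weak, coefs[, cols, drop = FALSE])
    }
  }
  list(loss = loss, grads = g)
}

#' Weak-node anchor loss from shared single side effects
#'
#' For each weak drug, find its `n_sim_neighbors` non-weak drugs with the
#' most shared mono (single) side effects; the loss is the mean (over weak
#' drugs) of the mean squared difference between the weak drug's
#' concatenated embedding parts and the element-wise mean of its neighbors'
#' concatenated parts. Only weak-drug embeddings receive gradient from this
#' loss: the anchors are targets, not co-trained.
#'
#' @param model a `trivec_model`.
#' @param kg the graph (supplies the mono table and external ids for ties).
#' @param weak_drugs entity ids of the weak drugs.
#' @param pool entity ids of the candidate (non-weak) anchor drugs.
#' @param n_sim_neighbors number of anchors per weak drug.
#' @return The scalar loss.
#' @export
weak_node_anchor_loss <- function(model, kg, weak_drugs, pool,
                                  n_sim_neighbors = 6L) {
  assert_that(length(intersect(weak_drugs, pool)) == 0L,
              "weak drugs must be disjoint from the neighbor pool")
  nb <- mono_neighbors(kg, weak_drugs, pool, n_sim_neighbors)
  weak_anchor_core(model, nb, with_grad = FALSE)$loss
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  z <- zero_grads(model)
  list(m = z, v = rapply(z, function(x) x, how = "replace"), t = 0L)
}

adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(model$opt)) model$opt <- adam_init(model)
  st <- model$opt
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (grp in c("E", "R")) {
    for (m in 1:3) {
      gmat <- grads[[grp]][[m]]
      st$m[[grp]][[m]] <- beta1 * st$m[[grp]][[m]] + (1 - beta1) * gmat
      st$v[[grp]][[m]] <- beta2 * st$v[[grp]][[m]] + (1 - beta2) * gmat^2
      mhat <- st$m[[grp]][[m]] / bc1
      vhat <- st$v[[grp]][[m]] / bc2
      model[[grp]][[m]] <- model[[grp]][[m]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  model$opt <- st
  model
}

#' Write a model checkpoint as plain-text arrays plus a manifest
#'
#' @param model a `trivec_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in 1:3) {
    fwrite(as.data.table(model$E[[m]]), file.path(dir, sprintf("entity_%d.tsv", m)),
           sep = "\t")
    fwrite(as.data.table(model$R[[m]]), file.path(dir, sprintf("relation_%d.tsv", m)),
           sep = "\t")
  }
  manifest <- list(K = model$K, lambda = model$lambda,
                   n_entities = model$n_entities,
                   n_relations = model$n_relations,
                   drug_init = model$drug_init)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a checkpoint written by [write_model()]
#'
#' @param dir checkpoint directory.
#' @return A `trivec_model` (optimizer state not restored).
#' @export
read_model <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  E <- lapply(1:3, function(m)
    as.matrix(fread(file.path(dir, sprintf("entity_%d.tsv", m)))))
  R <- lapply(1:3, function(m)
    as.matrix(fread(file.path(dir, sprintf("relation_%d.tsv", m)))))
  structure(list(E = lapply(E, unname), R = lapply(R, unname),
                 K = manifest$K, lambda = manifest$lambda,
                 n_entities = manifest$n_entities,
                 n_relations = manifest$n_relations,
                 drug_init = manifest$drug_init, opt = NULL),
            class = "trivec_model")
}
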