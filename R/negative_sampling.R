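# Negative-triple generation: uniform and Bernoulli corruption, cache-based
# sampling (NSCaching, 6:1, Exploration) and the degree-conditioned
# strong-neighbor redirection.

#' Negative-sampler specification
#'
#' @param kind sampler family; `nscaching_61` is NSCaching with 6 negatives
#'   per positive, `exploration` doubles the number of fresh candidates per
#'   cache update, `strong_nscaching` redirects weak drugs to their nearest
#'   strong neighbor's cache.
#' @param neg_ratio negatives per positive (default 1; 6 for `nscaching_61`).
#' @param cache_size cache entries kept per (head, relation) / (relation,
#'   tail) key.
#' @param n_random fresh uniformly drawn candidates per cache update.
#' @param alpha decay exponent of the strong-redirect probability
#'   `p(h) = 1 / log(deg_h)^alpha`.
#' @return A `sampler_spec` object.
#' @export
sampler_spec <- function(kind = c("uniform", "bernoulli", "nscaching",
                                  "nscaching_61", "exploration",
                                  "strong_nscaching"),
                         neg_ratio = NULL, cache_size = 30L, n_random = 30L,
                         alpha = 1 / 3) {
  kind <- match.arg(kind)
  neg_ratio <- neg_ratio %||% if (kind == "nscaching_61") 6L else 1L
  assert_that(neg_ratio >= 1L, "neg_ratio must be >= 1")
  structure(list(kind = kind, neg_ratio = as.integer(neg_ratio),
                 cache_size = as.integer(cache_size),
                 n_random = as.integer(n_random), alpha = alpha),
            class = "sampler_spec")
}

uses_cache <- function(spec) {
  spec$kind %in% c("nscaching", "nscaching_61", "exploration",
                   "strong_nscaching")
}

entity_kind_vector <- function(kg) {
  setNames(kg$entities$kind, kg$entities$entity_id)
}

kind_pools <- function(kg) {
  list(drug = kg_drug_ids(kg), protein = kg_protein_ids(kg))
}

# replace the entity in the given slot of each (replicated) positive with a
# uniformly drawn same-kind entity, rejecting known positives; bounded retries
corrupt_with_slots <- function(kg, positives, slots, seed, forbidden = NULL,
                               max_retries = 25L) {
  n <- nrow(positives)
  pools <- kind_pools(kg)
  ekind <- entity_kind_vector(kg)
  out <- data.table(pos_index = positives$pos_index,
                    head = positives$head, relation = positives$relation,
                    tail = positives$tail, slot = slots)
  with_seed(derive_seed(seed, 404L), {
    pending <- seq_len(n)
    for (round in seq_len(max_retries)) {
      if (!length(pending)) break
      for (kd in names(pools)) {
        pool <- pools[[kd]]
        if (length(pool) < 2L) next
        sel_head <- pending[out$slot[pending] == "head" &
                              ekind[as.character(out$head[pending])] == kd]
        sel_tail <- pending[out$slot[pending] == "tail" &
                              ekind[as.character(out$tail[pending])] == kd]
        if (length(sel_head)) {
          out$head[sel_head] <- pool[sample.int(length(pool), length(sel_head),
                                                replace = TRUE)]
        }
        if (length(sel_tail)) {
          out$tail[sel_tail] <- pool[sample.int(length(pool), length(sel_tail),
                                                replace = TRUE)]
        }
      }
      key <- triple_key(out$head[pending], out$relation[pending],
                        out$tail[pending])
      bad <- out$head[pending] == out$tail[pending] |
        (if (!is.null(forbidden)) key %chin% forbidden else FALSE) |
        (out$slot[pending] == "head" &
           out$head[pending] == positives$head[pending]) |
        (out$slot[pending] == "tail" &
           out$tail[pending] == positives$tail[pending])
      pending <- pending[bad]
    }
    if (length(pending)) {
      warning(sprintf("could not corrupt %d triple(s) within retry bound; dropped",
                      length(pending)))
      out <- out[-pending, ]
    }
  })
  out
}

replicate_positives <- function(positives, neg_ratio) {
  positives <- as.data.table(positives)
  n <- nrow(positives)
  idx <- rep(seq_len(n), times = neg_ratio)
  cbind(data.table(pos_index = idx), positives[idx, c("head", "relation", "tail"),
                                               with = FALSE])
}

#' Uniform filtered negative sampling
#'
#' For each requested negative a fair coin chooses head or tail; the chosen
#' slot is replaced by a uniformly drawn entity of the same kind. Corruptions
#' that reproduce a known positive (the `forbidden` key set), keep the
#' original entity, or create a self-loop are resampled up to a bounded
#' retry count; unfixable ones are dropped with a warning.
#'
#' @param kg a `simvec_kg`.
#' @param positives data.frame with `head`, `relation`, `tail`.
#' @param neg_ratio negatives per positive.
#' @param seed integer seed.
#' @param forbidden character vector of [triple_key()] strings to exclude
#'   (typically all train positives, or all known positives at evaluation).
#' @return data.table with `pos_index`, `head`, `relation`, `tail`, `slot`.
#' @export
uniform_corrupt <- function(kg, positives, neg_ratio = 1L, seed = 1L,
                            forbidden = NULL) {
  rep_pos <- replicate_positives(positives, neg_ratio)
  slots <- with_seed(derive_seed(seed, 405L),
                     sample(c("head", "tail"), nrow(rep_pos), replace = TRUE))
  corrupt_with_slots(kg, rep_pos, slots, seed, forbidden)
}

#' Relation cardinality statistics (tails-per-head, heads-per-tail)
#'
#' @param triples reference (train) triple table.
#' @return data.table with `relation`, `tph`, `hpt`.
#' @export
relation_cardinality <- function(triples) {
  tt <- as.data.table(triples)
  tph <- tt[, .(n_tails = .N), by = .(relation, head)][
    , .(tph = mean(n_tails)), by = relation]
  hpt <- tt[, .(n_heads = .N), by = .(relation, tail)][
    , .(hpt = mean(n_heads)), by = relation]
  merge(tph, hpt, by = "relation")
}

#' Bernoulli negative sampling
#'
#' Chooses the corrupted slot per positive with probability
#' `P(head) = tph / (tph + hpt)` computed from the reference triples of the
#' positive's relation (reducing false negatives for skewed relations),
#' then corrupts as in [uniform_corrupt()].
#'
#' @inheritParams uniform_corrupt
#' @param reference_triples triples from which tph/hpt are estimated
#'   (default: the positives themselves; pass the train table in training).
#' @return data.table as [uniform_corrupt()].
#' @export
bernoulli_corrupt <- function(kg, positives, neg_ratio = 1L, seed = 1L,
                              forbidden = NULL, reference_triples = NULL) {
  card <- relation_cardinality(reference_triples %||% positives)
  p_head <- setNames(card$tph / (card$tph + card$hpt), card$relation)
  rep_pos <- replicate_positives(positives, neg_ratio)
  pr <- p_head[as.character(rep_pos$relation)]
  assert_that(!anyNA(pr), "a relation lacks reference triples for tph/hpt")
  slots <- with_seed(derive_seed(seed, 406L),
                     ifelse(runif(nrow(rep_pos)) < pr, "head", "tail"))
  corrupt_with_slots(kg, rep_pos, slots, seed, forbidden)
}

cache_key_tail <- function(h, r) paste(h, r, sep = "|")
cache_key_head <- function(r, t) paste(r, t, sep = "|")

# candidate pool (same kind as the slot's observed entity) minus known
# positives for that key
draw_candidates <- function(pool, exclude, size) {
  avail <- setdiff(pool, exclude)
  if (!length(avail)) return(integer())
  avail[sample.int(length(avail), min(size, length(avail)))]
}

#' Initialize negative caches from the training triples
#'
#' One tail cache per observed (head, relation) and one head cache per
#' (relation, tail), each filled with up to `cache_size` uniformly drawn
#' same-kind entities that do not form a training positive.
#'
#' @param kg a `simvec_kg`.
#' @param train_triples training triple table.
#' @param spec a cache-based [sampler_spec()].
#' @param seed integer seed.
#' @return A `negative_cache`: environment with lists `tail` and `head`
#'   keyed by `"h|r"` / `"r|t"`, entries `list(cand, score)`.
#' @export
cache_init <- function(kg, train_triples, spec, seed = 1L) {
  assert_that(uses_cache(spec), "spec is not cache-based")
  tt <- as.data.table(train_triples)
  ekind <- entity_kind_vector(kg)
  pools <- kind_pools(kg)
  tails_by_key <- split(tt$tail, cache_key_tail(tt$head, tt$relation))
  heads_by_key <- split(tt$head, cache_key_head(tt$relation, tt$tail))
  cache <- new.env(parent = emptyenv())
  with_seed(derive_seed(seed, 501L), {
    cache$tail <- lapply(tails_by_key, function(pos_tails) {
      pool <- pools[[ekind[as.character(pos_tails[1L])]]]
      list(cand = draw_candidates(pool, pos_tails, spec$cache_size),
           score = NULL)
    })
    cache$head <- lapply(heads_by_key, function(pos_heads) {
      pool <- pools[[ekind[as.character(pos_heads[1L])]]]
      list(cand = draw_candidates(pool, pos_heads, spec$cache_size),
           score = NULL)
    })
  })
  cache$positive_tails <- tails_by_key
  cache$positive_heads <- heads_by_key
  class(cache) <- "negative_cache"
  cache
}

#' Refresh negative caches with the current model scores
#'
#' For every cache entry, draws `n_random` fresh non-positive candidates
#' (twice that for the `exploration` kind), scores cache plus fresh with the
#' current model, and retains `cache_size` entries by importance sampling
#' proportional to the softmax of the scores, so hard (high-scoring)
#' negatives concentrate in the cache while retention stays stochastic.
#'
#' @param cache a `negative_cache` from [cache_init()].
#' @param model the current `trivec_model`.
#' @param kg the graph.
#' @param spec the cache-based [sampler_spec()].
#' @param seed integer seed.
#' @return The updated cache (same environment, invisibly).
#' @export
cache_update <- function(cache, model, kg, spec, seed = 1L) {
  n_fresh <- spec$n_random * if (spec$kind == "exploration") 2L else 1L
  ekind <- entity_kind_vector(kg)
  pools <- kind_pools(kg)
  upd <- function(entries, positives, score_fun) {
    keys <- names(entries)
    for (k in keys) {
      ent <- entries[[k]]
      pos <- positives[[k]]
      pool <- pools[[ekind[as.character(pos[1L])]]]
      fresh <- if (n_fresh > 0L) draw_candidates(pool, c(pos, ent$cand), n_fresh)
               else integer()
      if (!length(fresh) && length(ent$cand) <= spec$cache_size) {
        next                         # nothing new to rank
      }
      cand <- c(ent$cand, fresh)
      sc <- score_fun(k, cand)
      keep_n <- min(spec$cache_size, length(cand))
      p <- exp(sc - max(sc))
      keep <- sample.int(length(cand), keep_n, prob = p / sum(p))
      entries[[k]] <- list(cand = cand[keep], score = sc[keep])
    }
    entries
  }
  with_seed(derive_seed(seed, 502L), {
    cache$tail <- upd(cache$tail, cache$positive_tails, function(k, cand) {
      hr <- as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
      score_triples(model, rep(hr[1L], length(cand)),
                    rep(hr[2L], length(cand)), cand)
    })
    cache$head <- upd(cache$head, cache$positive_heads, function(k, cand) {
      rt <- as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
      score_triples(model, cand, rep(rt[1L], length(cand)),
                    rep(rt[2L], length(cand)))
    })
  })
  invisible(cache)
}

# draw negatives for one positive from given tail-/head-cache keys
draw_from_caches <- function(cache, tail_key, head_key, n) {
  tl <- cache$tail[[tail_key]]$cand %||% integer()
  hd <- cache$head[[head_key]]$cand %||% integer()
  pool <- data.table(entity = c(tl, hd),
                     slot = rep(c("tail", "head"), c(length(tl), length(hd))))
  if (!nrow(pool)) return(NULL)
  pool[sample.int(nrow(pool), n, replace = TRUE), ]
}

#' Sample negatives from the caches
#'
#' Draws `neg_ratio` negatives per positive uniformly from the union of the
#' positive's tail cache (corrupting the tail) and head cache (corrupting
#' the head); positives without any cache entry fall back to
#' [uniform_corrupt()] with a warning.
#'
#' @param cache a `negative_cache`.
#' @inheritParams uniform_corrupt
#' @return data.table as [uniform_corrupt()].
#' @export
cache_sample <- function(cache, kg, positives, neg_ratio = 1L, seed = 1L,
                         forbidden = NULL) {
  strong_cache_sample(cache, kg, positives, spec = NULL, strong_map = NULL,
                      degrees = NULL, neg_ratio = neg_ratio, seed = seed,
                      forbidden = forbidden)
}

#' Strong-redirect probability for a weak drug
#'
#' `p(h) = 1 / log(deg_h)^alpha` with natural log, degree clamped to at
#' least 2 and the probability capped at 1 (so degree <= e gives certain
#' redirection). Large `alpha` drives p to 0 and recovers plain NSCaching.
#'
#' @param deg degree vector.
#' @param alpha decay exponent.
#' @return Probabilities in `(0, 1]`.
#' @export
p_strong_redirect <- function(deg, alpha = 1 / 3) {
  pmin(1, 1 / log(pmax(deg, 2))^alpha)
}

#' Cache sampling with strong-neighbor redirection for weak drugs
#'
#' As [cache_sample()], but when a weak drug occupies a cache key slot its
#' lookup is redirected, with probability `p(h) = 1/log(deg_h)^alpha`, to
#' the cache keys of its chemically nearest strong neighbor (both the tail
#' and the head key are redirected when the weak drug occupies the
#' corresponding slot).
#'
#' @param cache a `negative_cache`.
#' @param kg a `simvec_kg`.
#' @param positives data.frame with `head`, `relation`, `tail`.
#' @param spec a `strong_nscaching` [sampler_spec()] (NULL = no redirection).
#' @param strong_map named integer vector: weak entity id -> strong entity id
#'   (from [nearest_strong_neighbor()]); missing entries use the drug's own
#'   cache with a warning.
#' @param degrees degree vector indexed by entity id (train drug-drug
#'   degrees).
#' @param neg_ratio,seed,forbidden as in [uniform_corrupt()].
#' @return data.table as [uniform_corrupt()].
#' @export
strong_cache_sample <- function(cache, kg, positives, spec, strong_map,
                                degrees, neg_ratio = 1L, seed = 1L,
                                forbidden = NULL) {
  positives <- as.data.table(positives)
  n <- nrow(positives)
  redirect <- !is.null(spec) && spec$kind == "strong_nscaching"
  out <- vector("list", n)
  fallback <- integer()
  with_seed(derive_seed(seed, 503L), {
    for (i in seq_len(n)) {
      h <- positives$head[i]; r <- positives$relation[i]
      t <- positives$tail[i]
      kh <- h; kt <- t
      if (redirect) {
        for (end in c("h", "t")) {
          e <- if (end == "h") h else t
          if (as.character(e) %in% names(strong_map)) {
            p <- p_strong_redirect(degrees[e], spec$alpha)
            if (runif(1L) < p) {
              if (end == "h") kh <- strong_map[[as.character(e)]]
              else kt <- strong_map[[as.character(e)]]
            }
          }
        }
      }
      draw <- draw_from_caches(cache, cache_key_tail(kh, r),
                               cache_key_head(r, kt), neg_ratio)
      if (is.null(draw)) { fallback <- c(fallback, i); next }
      neg <- data.table(pos_index = i, head = h, relation = r, tail = t,
                        slot = draw$slot)
      neg$head[draw$slot == "head"] <- draw$entity[draw$slot == "head"]
      neg$tail[draw$slot == "tail"] <- draw$entity[draw$slot == "tail"]
      keep <- !(triple_key(neg$head, neg$relation, neg$tail) %chin%
                  (forbidden %||% character()))
      out[[i]] <- neg[keep, ]
    }
  })
  if (length(fallback)) {
    warning(sprintf("%d positive(s) had no cache entry; uniform fallback",
                    length(fallback)))
    fb <- uniform_corrupt(kg, positives[fallback, ], neg_ratio,
                          derive_seed(seed, 504L), forbidden)
    fb$pos_index <- fallback[fb$pos_index]
    out <- c(out, list(fb))
  }
  rbindlist(out[!vapply(out, is.null, logical(1L))])
}

#' Dump cache contents for inspection
#'
#' @param cache a `negative_cache`.
#' @param path optional TSV path; when given the table is also written.
#' @return data.table with `side`, `key`, `candidate`, `score`.
#' @export
cache_dump <- function(cache, path = NULL) {
  one <- function(entries, side) rbindlist(lapply(names(entries), function(k) {
    e <- entries[[k]]
    if (!length(e$cand)) return(NULL)
    dt <- data.table(side = side, candidate = e$cand,
                     score = if (is.null(e$score)) NA_real_ else e$score)
    dt[, key := k]
    dt[, c("side", "key", "candidate", "score"), with = FALSE]
  }))
  out <- rbindlist(list(one(cache$tail, "tail"), one(cache$head, "head")))
  if (!is.null(path)) fwrite(out, path, sep = "\t")
  out
}
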