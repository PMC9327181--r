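train_keys <- function(tt) simvec:::triple_key(tt$head, tt$relation, tt$tail)

test_that("uniform corruption flips a fair coin and respects the filter", {
  kgr <- random_kg(n_drugs = 12L, n_triples = 50L, seed = 21L)
  pos <- kgr$triples
  forb <- train_keys(pos)
  neg <- uniform_corrupt(kgr, pos, neg_ratio = 1L, seed = 1L, forbidden = forb)
  expect_equal(nrow(neg), nrow(pos))
  expect_false(any(train_keys(neg) %in% forb))
  expect_true(all(neg$head != neg$tail))
  # the untouched slot is preserved
  kept_head <- neg$slot == "tail"
  expect_equal(neg$head[kept_head], pos$head[neg$pos_index][kept_head])
  # neg_ratio = 6 gives six negatives per positive
  neg6 <- uniform_corrupt(kgr, pos[1:5, ], neg_ratio = 6L, seed = 2L,
                          forbidden = forb)
  expect_equal(as.integer(table(neg6$pos_index)), rep(6L, 5L))
  # head/tail ratio is a fair coin over 1e4 draws
  big <- uniform_corrupt(kgr, pos[rep(1L, 10000L), ], neg_ratio = 1L,
                         seed = 3L)
  p_head <- mean(big$slot == "head")
  expect_lt(abs(p_head - 0.5), 0.02)
  # exhaustion on a 2-drug graph where every corruption is a positive
  kg2 <- kg_build(combo = data.frame(drug1 = c("a", "b"), drug2 = c("b", "a"),
                                     side_effect_id = "s1"))
  forb2 <- train_keys(kg2$triples)
  expect_warning(n2 <- uniform_corrupt(kg2, kg2$triples[1, ], 1L, seed = 4L,
                                       forbidden = forb2), "retry")
  expect_equal(nrow(n2), 0L)
})

test_that("bernoulli corruption uses relation cardinality for the slot choice", {
  # relation with tph = 3, hpt = 1: head h1 links to 3 tails
  combo <- data.frame(drug1 = c("h1", "h1", "h1"),
                      drug2 = c("t1", "t2", "t3"),
                      side_effect_id = "s1")
  kg <- kg_build(combo = combo,
                 smiles = data.frame(drug_id = sprintf("z%d", 1:6),
                                     canonical_smiles = NA))
  card <- relation_cardinality(kg$triples)
  expect_equal(card$tph, 3)
  expect_equal(card$hpt, 1)
  # brute force on a second toy: 2 heads x {2,1} tails
  combo2 <- data.frame(drug1 = c("a", "a", "b"), drug2 = c("c", "d", "c"),
                       side_effect_id = "s9")
  card2 <- relation_cardinality(kg_build(combo = combo2)$triples)
  expect_equal(card2$tph, mean(c(2, 1)))
  expect_equal(card2$hpt, mean(c(2, 1)))
  # empirical head-corruption frequency ~ tph/(tph+hpt) = 0.75 within 3 SD
  pos_rep <- kg$triples[rep(1L, 10000L), ]
  neg <- bernoulli_corrupt(kg, pos_rep, seed = 5L,
                           reference_triples = kg$triples)
  p_hat <- mean(neg$slot == "head")
  se3 <- 3 * sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(p_hat - 0.75), se3)
  # 1-to-1 relation: fair coin
  kg11 <- kg_build(combo = data.frame(drug1 = c("a", "b"),
                                      drug2 = c("c", "d"),
                                      side_effect_id = "s1"))
  neg11 <- bernoulli_corrupt(kg11, kg11$triples[rep(1:2, 5000L), ], seed = 6L,
                             reference_triples = kg11$triples)
  expect_lt(abs(mean(neg11$slot == "head") - 0.5), 0.02)
})

test_that("cache initialization honors size, filter and seed contracts", {
  kgr <- random_kg(n_drugs = 15L, n_triples = 60L, seed = 31L)
  spec <- sampler_spec("nscaching", cache_size = 5L)
  cc <- cache_init(kgr, kgr$triples, spec, seed = 9L)
  sizes <- vapply(cc$tail, function(e) length(e$cand), integer(1L))
  expect_true(all(sizes <= 5L))
  # no cached tail forms a training positive
  for (k in names(cc$tail)) {
    hr <- as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
    keys <- simvec:::triple_key(hr[1L], hr[2L], cc$tail[[k]]$cand)
    expect_false(any(keys %in% train_keys(kgr$triples)))
  }
  cc2 <- cache_init(kgr, kgr$triples, spec, seed = 9L)
  expect_identical(cache_dump(cc), cache_dump(cc2))
})

test_that("cache update keeps hard negatives and exploration doubles the draw", {
  kgr <- random_kg(n_drugs = 30L, n_triples = 100L, seed = 41L)
  model <- trivec_model(kgr, K = 4L, seed = 2L)
  # n_random = 0 leaves the cache unchanged
  spec0 <- sampler_spec("nscaching", cache_size = 5L, n_random = 0L)
  cc <- cache_init(kgr, kgr$triples, spec0, seed = 1L)
  before <- cache_dump(cc)[, c("side", "key", "candidate")]
  cache_update(cc, model, kgr, spec0, seed = 2L)
  expect_identical(cache_dump(cc)[, c("side", "key", "candidate")], before)
  # with a cache large enough to retain everything, candidate growth per
  # update equals the fresh-draw size: n_random vs 2 * n_random
  grow <- function(kind) {
    # init below the pool size, then update with a retention bound large
    # enough to keep everything: growth = the fresh-draw size
    cc <- cache_init(kgr, kgr$triples,
                     sampler_spec(kind, cache_size = 5L, n_random = 4L),
                     seed = 3L)
    spec <- sampler_spec(kind, cache_size = 1000L, n_random = 4L)
    k <- names(cc$tail)[1L]
    n0 <- length(cc$tail[[k]]$cand)
    cache_update(cc, model, kgr, spec, seed = 4L)
    length(cc$tail[[k]]$cand) - n0
  }
  expect_equal(grow("nscaching"), 4L)
  expect_equal(grow("exploration"), 8L)
  # mean cached score trends upward under a frozen model (5 seeds, 20 updates)
  spec <- sampler_spec("nscaching", cache_size = 5L, n_random = 10L)
  deltas <- vapply(1:5, function(s) {
    cc <- cache_init(kgr, kgr$triples, spec, seed = s)
    key <- names(cc$tail)[1:10]
    mean_score <- function() {
      sc <- unlist(lapply(key, function(k) {
        hr <- as.integer(strsplit(k, "|", fixed = TRUE)[[1L]])
        cand <- cc$tail[[k]]$cand
        score_triples(model, rep(hr[1L], length(cand)),
                      rep(hr[2L], length(cand)), cand)
      }))
      mean(sc)
    }
    m0 <- mean_score()
    for (u in 1:20) cache_update(cc, model, kgr, spec, seed = 100 * s + u)
    mean_score() - m0
  }, numeric(1L))
  expect_gt(mean(deltas), 0)
})

test_that("cache sampling draws filtered negatives and falls back gracefully", {
  kgr <- random_kg(n_drugs = 15L, n_triples = 60L, seed = 51L)
  spec <- sampler_spec("nscaching", cache_size = 5L)
  cc <- cache_init(kgr, kgr$triples, spec, seed = 1L)
  forb <- train_keys(kgr$triples)
  neg <- cache_sample(cc, kgr, kgr$triples, neg_ratio = 1L, seed = 2L,
                      forbidden = forb)
  expect_false(any(train_keys(neg) %in% forb))
  # neg_ratio 6 returns 6 per positive (with replacement when caches are small)
  neg6 <- cache_sample(cc, kgr, kgr$triples[1:3, ], neg_ratio = 6L, seed = 3L,
                       forbidden = NULL)
  expect_equal(as.integer(table(neg6$pos_index)), rep(6L, 3L))
  # positive with no cache entry on either side falls back to uniform corruption
  drugs <- kgr$entities$entity_id[kgr$entities$kind == "drug"]
  ghost <- NULL
  for (r in unique(kgr$triples$relation)) {
    for (h in drugs) for (t in drugs) {
      if (h != t && is.null(cc$tail[[paste(h, r, sep = "|")]]) &&
          is.null(cc$head[[paste(r, t, sep = "|")]])) {
        ghost <- data.frame(head = h, relation = r, tail = t)
        break
      }
    }
    if (!is.null(ghost)) break
  }
  expect_false(is.null(ghost))
  expect_warning(fb <- cache_sample(cc, kgr, ghost, 1L, seed = 4L,
                                    forbidden = forb), "fallback|no cache")
  expect_equal(nrow(fb), 1L)
})

test_that("strong-neighbor redirection follows the degree-decay probability", {
  expect_equal(p_strong_redirect(exp(2), alpha = 1), 0.5)
  expect_equal(p_strong_redirect(exp(1), alpha = 1), 1)   # clamped at 1
  expect_equal(p_strong_redirect(1, alpha = 1), 1)        # deg clamped to 2
  expect_lt(p_strong_redirect(exp(2), alpha = 50), 1e-10) # NSCaching limit
  expect_true(all(diff(p_strong_redirect(c(3, 10, 100, 1000))) < 0))

  kgr <- random_kg(n_drugs = 15L, n_triples = 60L, seed = 61L)
  spec <- sampler_spec("strong_nscaching", cache_size = 5L, alpha = 1 / 3)
  cc <- cache_init(kgr, kgr$triples, spec, seed = 1L)
  deg <- kg_degrees(kgr, "drug_drug_only")
  drugs <- kgr$entities$entity_id[kgr$entities$kind == "drug"]
  weak <- drugs[order(deg[drugs])][1:3]
  strong_map <- setNames(rep(drugs[which.max(deg[drugs])], 3L), weak)
  forb <- train_keys(kgr$triples)
  neg <- strong_cache_sample(cc, kgr, kgr$triples, spec, strong_map, deg,
                             neg_ratio = 1L, seed = 2L, forbidden = forb)
  expect_false(any(train_keys(neg) %in% forb))
  expect_gt(nrow(neg), 0L)
})

test_that("no sampler emits a training positive on exhaustive toy graphs", {
  kgr <- random_kg(n_drugs = 10L, n_rel = 2L, n_triples = 45L, seed = 71L)
  forb <- train_keys(kgr$triples)
  model <- trivec_model(kgr, K = 3L, seed = 1L)
  for (kind in c("uniform", "bernoulli", "nscaching", "nscaching_61",
                 "exploration", "strong_nscaching")) {
    spec <- sampler_spec(kind, cache_size = 4L, n_random = 4L)
    neg <- if (kind == "uniform") {
      uniform_corrupt(kgr, kgr$triples, spec$neg_ratio, seed = 5L,
                      forbidden = forb)
    } else if (kind == "bernoulli") {
      bernoulli_corrupt(kgr, kgr$triples, spec$neg_ratio, seed = 5L,
                        forbidden = forb, reference_triples = kgr$triples)
    } else {
      cc <- cache_init(kgr, kgr$triples, spec, seed = 5L)
      cache_update(cc, model, kgr, spec, seed = 6L)
      if (kind == "strong_nscaching") {
        deg <- kg_degrees(kgr, "drug_drug_only")
        drugs <- kgr$entities$entity_id[kgr$entities$kind == "drug"]
        weak <- drugs[order(deg[drugs])][1:2]
        sm <- setNames(rep(drugs[which.max(deg[drugs])], 2L), weak)
        strong_cache_sample(cc, kgr, kgr$triples, spec, sm, deg,
                            spec$neg_ratio, seed = 7L, forbidden = forb)
      } else {
        cache_sample(cc, kgr, kgr$triples, spec$neg_ratio, seed = 7L,
                     forbidden = forb)
      }
    }
    expect_false(any(train_keys(neg) %in% forb), label = kind)
  }
})
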