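# Seeded generator of fully synthetic Decagon-style inputs: a heterogeneous
# drug/protein graph with a controllable (power-law) drug degree skew,
# multiple side-effect relation types, mono side effects, and binary drug
# feature vectors whose pairwise Tanimoto similarity drives edge formation
# when the planted signal is on.

#' Specification of a synthetic polypharmacy benchmark
#'
#' Drugs belong to latent chemical clusters; each drug's binary feature
#' vector is its cluster prototype with bit flips, so within-cluster
#' Tanimoto similarity is high. With probability `signal_strength` an edge's
#' partner drug is drawn proportionally to feature Tanimoto (sharpened), so
#' chemically similar drugs share side effects; at 0 edges are degree-driven
#' noise. Per-drug propensities follow a power law with exponent
#' `degree_exponent`, guaranteeing a weak tail of low-degree drugs. Mono
#' side effects are cluster-correlated, mirroring the feature signal.
#'
#' @param n_drugs,n_proteins,n_poly_relations,n_mono_effects counts.
#' @param degree_exponent power-law exponent of the degree skew (> 1).
#' @param signal_strength probability in `[0, 1]` that an edge is driven by
#'   feature similarity rather than noise.
#' @param feature_dim length of the binary feature vectors.
#' @param edges_per_relation drug-drug triples drawn per side-effect
#'   relation (before deduplication).
#' @param n_clusters latent chemical clusters.
#' @param seed master seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_drugs = 60L, n_proteins = 200L,
                       n_poly_relations = 8L, n_mono_effects = 20L,
                       degree_exponent = 2, signal_strength = 0.9,
                       feature_dim = 100L, edges_per_relation = 220L,
                       n_clusters = 6L, seed = 1L) {
  assert_that(all(c(n_drugs, n_proteins, n_poly_relations, n_mono_effects,
                    feature_dim, edges_per_relation, n_clusters) > 0),
              "all counts must be positive")
  assert_that(signal_strength >= 0 && signal_strength <= 1,
              "signal_strength must be in [0, 1]")
  assert_that(degree_exponent > 1, "degree_exponent must exceed 1")
  structure(as.list(environment()), class = "synth_spec")
}

synth_ids <- function(spec) {
  list(drugs = sprintf("D%03d", seq_len(spec$n_drugs)),
       proteins = sprintf("G%04d", seq_len(spec$n_proteins)),
       rels = sprintf("SE%02d", seq_len(spec$n_poly_relations)),
       monos = sprintf("M%02d", seq_len(spec$n_mono_effects)))
}

#' Generate synthetic Decagon-style tables
#'
#' Produces the five tables consumed by [kg_build()] / [load_kg()] plus the
#' binary feature table that stands in for chemical profiles (synthetic
#' drugs carry raw feature vectors instead of SMILES). Deterministic under
#' the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @param dir optional directory; when given, tables are written as CSV
#'   (`combo.csv`, `ppi.csv`, `targets.csv`, `mono.csv`, `features.csv`)
#'   together with the serialized spec (`spec.json`).
#' @return List of data.tables `combo`, `ppi`, `targets`, `mono`,
#'   `features`, plus `feature_matrix` (drugs x feature_dim, rownames =
#'   drug ids).
#' @export
synth_generate <- function(spec, dir = NULL) {
  ids <- synth_ids(spec)
  out <- with_seed(derive_seed(spec$seed, 1001L), {
    n <- spec$n_drugs
    cluster <- sample(rep_len(seq_len(spec$n_clusters), n))
    proto <- matrix(rbinom(spec$n_clusters * spec$feature_dim, 1L, 0.25),
                    spec$n_clusters, spec$feature_dim)
    flips <- matrix(rbinom(n * spec$feature_dim, 1L, 0.08), n,
                    spec$feature_dim)
    feats <- (proto[cluster, , drop = FALSE] + flips) %% 2L
    rownames(feats) <- ids$drugs
    sim <- tanimoto_matrix(feats)
    diag(sim) <- 0
    sim_sharp <- sim^3

    # per-drug propensity: power law over a random drug order
    u <- runif(n, min = 0.02)
    w <- u^(-1 / (spec$degree_exponent - 1))
    w <- w / sum(w)

    combos <- vector("list", spec$n_poly_relations)
    for (r in seq_len(spec$n_poly_relations)) {
      m <- spec$edges_per_relation
      h <- sample.int(n, m, replace = TRUE, prob = w)
      use_sig <- runif(m) < spec$signal_strength
      t <- integer(m)
      for (i in seq_len(m)) {
        p <- if (use_sig[i]) w * (sim_sharp[h[i], ] + 1e-6) else w
        p[h[i]] <- 0
        t[i] <- sample.int(n, 1L, prob = p)
      }
      # store unordered pairs canonically so duplicates collapse
      a <- pmin(h, t); b <- pmax(h, t)
      combos[[r]] <- unique(data.table(drug1 = ids$drugs[a],
                                       drug2 = ids$drugs[b],
                                       side_effect_id = ids$rels[r]))
    }
    combo <- rbindlist(combos)
    combo[, side_effect_name := paste0("effect_", side_effect_id)]

    ppi <- unique(data.table(
      gene1 = ids$proteins[sample.int(spec$n_proteins, 2L * spec$n_proteins,
                                      replace = TRUE)],
      gene2 = ids$proteins[sample.int(spec$n_proteins, 2L * spec$n_proteins,
                                      replace = TRUE)]))
    ppi <- ppi[gene1 != gene2, ]

    n_targets <- pmax(1L, rpois(n, 2))
    targets <- data.table(
      drug = rep(ids$drugs, n_targets),
      gene = ids$proteins[sample.int(spec$n_proteins, sum(n_targets),
                                     replace = TRUE)])
    targets <- unique(targets)

    mono_cluster <- rep_len(seq_len(spec$n_clusters), spec$n_mono_effects)
    mono_rows <- lapply(seq_len(spec$n_mono_effects), function(m) {
      p <- ifelse(cluster == mono_cluster[m], 0.55, 0.08)
      has <- runif(n) < p
      if (!any(has)) has[sample.int(n, 1L)] <- TRUE
      data.table(drug = ids$drugs[has], mono_side_effect_id = ids$monos[m])
    })
    mono <- rbindlist(mono_rows)

    features <- data.table(drug_id = ids$drugs)
    fcols <- as.data.table(feats)
    setnames(fcols, sprintf("v%d", seq_len(spec$feature_dim) - 1L))
    features <- cbind(features, fcols)
    list(combo = combo, ppi = ppi, targets = targets, mono = mono,
         features = features, feature_matrix = feats)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("combo", "ppi", "targets", "mono", "features")) {
      fwrite(out[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
    writeLines(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE),
               file.path(dir, "spec.json"))
  }
  out
}

#' Assemble a synthetic benchmark: graph, weak split and uniform split
#'
#' Generates the tables, loads them through the standard graph constructor,
#' and returns both split flavors (shared seed) together with the drug
#' feature vectors wrapped as morgan-kind chemical profiles.
#'
#' @param spec a [synth_spec()]; the default is the desk-scale benchmark
#'   (60 drugs, 200 proteins, 8 side-effect relations, 20 mono effects).
#' @param n_weak number of weak drugs held out by the weak-nodes split.
#' @return List `kg`, `weak_split`, `uniform_split`, `profiles`, `tables`.
#' @export
make_benchmark <- function(spec = synth_spec(), n_weak = 10L) {
  assert_that(n_weak < spec$n_drugs, "n_weak must be below n_drugs")
  tabs <- synth_generate(spec)
  smiles <- data.table(drug_id = rownames(tabs$feature_matrix),
                       canonical_smiles = NA_character_)
  kg <- kg_build(combo = tabs$combo, ppi = tabs$ppi, targets = tabs$targets,
                 mono = tabs$mono, smiles = smiles)
  profiles <- chem_profiles(tabs$feature_matrix, "morgan")
  list(kg = kg,
       weak_split = weak_nodes_split(kg, n_weak, seed = spec$seed),
       uniform_split = uniform_split(kg, seed = spec$seed),
       profiles = profiles, tables = tabs)
}
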