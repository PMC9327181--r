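suppressMessages(library(data.table))

# three-drug toy graph: degrees (drug-drug) a=1, b=2, c=3 via s1:(a,b), s1:(b,c), s2:(a?,...)
toy_kg <- function() {
  kg_build(
    combo = data.frame(drug1 = c("a", "b", "c"),
                       drug2 = c("b", "c", "d"),
                       side_effect_id = c("s1", "s1", "s2")),
    ppi = data.frame(gene1 = c("g1"), gene2 = c("g2")),
    targets = data.frame(drug = c("a", "b"), gene = c("g1", "g2")),
    mono = data.frame(drug = c("a", "a", "b", "c", "d"),
                      mono_side_effect_id = c("m1", "m2", "m1", "m2", "m3")),
    smiles = data.frame(drug_id = c("a", "b", "c", "d"),
                        canonical_smiles = c("CCO", "OCC", "c1ccccc1O", NA)))
}

# random small KG for property tests: n_drugs drugs, a few relations
random_kg <- function(n_drugs = 12L, n_rel = 3L, n_triples = 40L, seed = 1L) {
  withr::with_seed(seed, {
    drugs <- sprintf("d%02d", seq_len(n_drugs))
    combo <- data.frame(
      drug1 = drugs[sample.int(n_drugs, n_triples, replace = TRUE)],
      drug2 = drugs[sample.int(n_drugs, n_triples, replace = TRUE)],
      side_effect_id = sprintf("s%d", sample.int(n_rel, n_triples,
                                                 replace = TRUE)))
    combo <- combo[combo$drug1 != combo$drug2, ]
    kg_build(combo = combo,
             smiles = data.frame(drug_id = drugs, canonical_smiles = NA))
  })
}

# small fitted-model ingredients for training tests
desk_benchmark <- function(seed = 3L, n_drugs = 60L) {
  make_benchmark(synth_spec(n_drugs = n_drugs, seed = seed), n_weak = 10L)
}

full_components <- list(chemical_init = TRUE, similarity_edges = TRUE,
                        weak_anchor_loss = TRUE)

has_chemtools <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}
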