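# Degree-inverse node weights and the weighted drug-drug similarity edge set
# that augments the knowledge graph.

#' Similarity-edge weighting scheme
#'
#' `proportional` weights an edge by similarity(h,t) * InvDeg(h) * InvDeg(t);
#' `window` uses a Gaussian kernel whose width interpolates between
#' `l_bound` and `u_bound` with the InvDeg product, so poorly connected
#' pairs get a wider (more permissive) window. Bounds are expressed in the
#' units of the profile space (standardized descriptor distance in the
#' reference configuration).
#'
#' @param kind `"proportional"` or `"window"`.
#' @param l_bound,u_bound window bounds, `l_bound < u_bound` (window only).
#' @return A `weighting_scheme` object.
#' @export
weighting_scheme <- function(kind = c("proportional", "window"),
                             l_bound = 1, u_bound = 4) {
  kind <- match.arg(kind)
  if (kind == "window") {
    assert_that(l_bound > 0 && l_bound < u_bound,
                "window scheme needs 0 < l_bound < u_bound")
  }
  structure(list(kind = kind, l_bound = l_bound, u_bound = u_bound),
            class = "weighting_scheme")
}

#' Inverse proportion of the normalized drug degree
#'
#' `InvDeg(x) = 1 - (deg_x - min_i deg_i) / (max_i deg_i - min_i deg_i)`,
#' with degrees counted over train drug-drug (polypharmacy) triples and the
#' min/max over all drug nodes. The maximal-degree drug maps to 0 and the
#' minimal-degree drug to 1. Degrees are taken from the training partition
#' so the enhancement never sees held-out edges.
#'
#' @param kg a `simvec_kg`.
#' @param triples triple table defining degrees (typically `split$train`);
#'   defaults to all graph triples.
#' @param drugs optional entity ids to return (default: all drugs).
#' @return Named numeric vector in `[0, 1]` indexed by entity id; all-equal
#'   degrees degenerate to 1 for every drug (with a warning).
#' @export
inv_deg <- function(kg, triples = NULL, drugs = NULL) {
  all_drugs <- kg_drug_ids(kg)
  deg <- kg_degrees(kg, "drug_drug_only", triples)[all_drugs]
  rng <- range(deg)
  if (rng[1] == rng[2]) {
    warning("all drug degrees equal; InvDeg degenerates to 1 for every drug")
    iv <- rep(1, length(all_drugs))
  } else {
    iv <- 1 - (deg - rng[1]) / (rng[2] - rng[1])
  }
  names(iv) <- all_drugs
  if (!is.null(drugs)) iv <- iv[as.character(drugs)]
  iv
}

#' Proportional similarity-edge weight
#'
#' @param similarity similarity of the two drugs, in `[0, 1]`.
#' @param inv_deg_h,inv_deg_t the endpoints' [inv_deg()] values.
#' @return `similarity * inv_deg_h * inv_deg_t`, symmetric in the endpoints.
#' @export
weight_proportional <- function(similarity, inv_deg_h, inv_deg_t) {
  assert_that(all(c(similarity, inv_deg_h, inv_deg_t) >= 0) &&
                all(c(similarity, inv_deg_h, inv_deg_t) <= 1),
              "weight_proportional inputs must lie in [0, 1]")
  similarity * inv_deg_h * inv_deg_t
}

#' Window similarity-edge weight
#'
#' `window = l_bound + InvDeg(h) * InvDeg(t) * (u_bound - l_bound)`;
#' `weight = exp(-||h_vec - t_vec||^2 / window^2)`. Weakly connected pairs
#' (InvDeg product near 1) get the widest window, hence relatively larger
#' weights at the same descriptor distance.
#'
#' @param h_vec,t_vec the drugs' descriptor vectors.
#' @param inv_deg_h,inv_deg_t the endpoints' [inv_deg()] values.
#' @param scheme a window [weighting_scheme()].
#' @return Weight in `(0, 1]`.
#' @export
weight_window <- function(h_vec, t_vec, inv_deg_h, inv_deg_t, scheme) {
  assert_that(inherits(scheme, "weighting_scheme") && scheme$kind == "window",
              "scheme must be a window weighting_scheme")
  assert_that(length(h_vec) == length(t_vec), "vector length mismatch")
  win <- scheme$l_bound + inv_deg_h * inv_deg_t * (scheme$u_bound - scheme$l_bound)
  exp(-sum((h_vec - t_vec)^2) / win^2)
}

# ensure the graph carries exactly one similarity relation; returns its id
similarity_relation_id <- function(kg) {
  sim <- kg$relations$relation_id[kg$relations$kind == "similarity"]
  if (length(sim)) sim[1L] else NA_integer_
}

#' Add the (single) similarity relation to a graph
#'
#' @param kg a `simvec_kg`.
#' @return The graph with a `similarity` relation appended (idempotent).
#' @export
add_similarity_relation <- function(kg) {
  if (!is.na(similarity_relation_id(kg))) return(kg)
  kg$relations <- rbind(kg$relations,
                        data.table(relation_id = nrow(kg$relations) + 1L,
                                   kind = "similarity", label = "similarity"))
  kg
}

#' Build the weighted drug-drug similarity edge set
#'
#' One undirected weighted triple per unordered drug pair with weight above
#' `min_weight` (default 0 keeps the complete graph). Weights come either
#' from the proportional scheme applied to the profile set's native
#' similarity, or from the window scheme applied to descriptor distances.
#'
#' @param kg a `simvec_kg` (a similarity relation is added if absent).
#' @param profiles a `chem_profiles` covering all drugs (fallback rows allowed).
#' @param scheme a [weighting_scheme()].
#' @param train_triples triples defining InvDeg degrees (use the train split).
#' @param min_weight prune edges at or below this weight.
#' @param sigma Gaussian width for descriptor similarity under the
#'   proportional scheme.
#' @return List with the updated `kg` and `edges`, a data.table of
#'   similarity triples (`head`, `relation`, `tail`, `weight`).
#' @export
build_similarity_edges <- function(kg, profiles, scheme = weighting_scheme(),
                                   train_triples = NULL, min_weight = 0,
                                   sigma = NULL) {
  kg <- add_similarity_relation(kg)
  rsim <- similarity_relation_id(kg)
  drugs <- kg$entities[kg$entities$kind == "drug", ]
  iv <- inv_deg(kg, triples = train_triples)
  # align profile rows with the drug table; missing drugs get zero fallback
  m <- matrix(0, nrow = nrow(drugs), ncol = ncol(profiles$mat),
              dimnames = list(drugs$external_id, colnames(profiles$mat)))
  hit <- drugs$external_id %in% rownames(profiles$mat)
  m[hit, ] <- profiles$mat[drugs$external_id[hit], , drop = FALSE]
  if (any(!hit)) {
    warning(sprintf("%d drug(s) lack profiles; zero fallback used", sum(!hit)))
  }
  aligned <- chem_profiles(m, profiles$kind)

  ivp <- outer(unname(iv), unname(iv))             # InvDeg(h) * InvDeg(t)
  if (scheme$kind == "proportional") {
    w <- pairwise_similarity(aligned, sigma = sigma) * ivp
  } else {
    assert_that(profiles$kind == "descriptor",
                "window weighting pairs with descriptor profiles")
    win <- scheme$l_bound + ivp * (scheme$u_bound - scheme$l_bound)
    d2 <- as.matrix(stats::dist(m))^2
    w <- exp(-d2 / win^2)
  }
  ut <- upper.tri(w)
  idx <- which(ut & w > min_weight, arr.ind = TRUE)
  edges <- data.table(head = drugs$entity_id[idx[, 1L]],
                      relation = rsim,
                      tail = drugs$entity_id[idx[, 2L]],
                      weight = w[idx])
  list(kg = kg, edges = edges)
}
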