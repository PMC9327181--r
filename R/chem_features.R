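# Per-drug chemical feature vectors (circular fingerprints, molecular
# descriptors, external hyperbolic embeddings) and the similarity metrics
# used for node initialization, similarity-edge weighting and strong-neighbor
# lookup.

#' Construct a chemical profile set
#'
#' A profile set is a drugs-by-dimensions numeric matrix with one row per
#' drug (rownames = drug external ids) tagged with the feature kind, which
#' fixes the compatible similarity metric: `morgan` (binary fingerprints,
#' Tanimoto), `descriptor` (standardized descriptors, Gaussian kernel) or
#' `external_embedding` (hyperboloid-model coordinates, Lorentz similarity).
#'
#' @param mat numeric matrix, rownames are drug external ids.
#' @param kind one of `"morgan"`, `"descriptor"`, `"external_embedding"`.
#' @return A `chem_profiles` object.
#' @export
chem_profiles <- function(mat, kind = c("morgan", "descriptor",
                                        "external_embedding")) {
  kind <- match.arg(kind)
  assert_that(is.matrix(mat) && !is.null(rownames(mat)),
              "profiles must be a matrix with drug ids as rownames")
  if (kind == "morgan") {
    assert_that(all(mat %in% c(0, 1)), "morgan profiles must be binary")
  }
  structure(list(mat = mat, kind = kind), class = "chem_profiles")
}

#' @export
print.chem_profiles <- function(x, ...) {
  cat(sprintf("chem_profiles (%s): %d drugs x %d dims\n", x$kind,
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

smiles_to_sdf <- function(smiles_vec) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES featurization needs ChemmineR + ChemmineOB", call. = FALSE)
  }
  ChemmineR::smiles2sdf(smiles_vec)
}

#' Folded circular (Morgan-style) fingerprint from SMILES
#'
#' Computes extended-connectivity fingerprints via OpenBabel (`ECFP<2r>`,
#' so the default radius 3 maps to ECFP6) and folds them to `n_bits` by
#' OR-ing bits with equal index modulo `n_bits`. Deterministic for a fixed
#' canonical SMILES; two SMILES spellings of the same molecule give the same
#' fingerprint.
#'
#' @param smiles character vector of SMILES strings (may contain `NA`).
#' @param radius fingerprint radius (0-5).
#' @param n_bits folded length.
#' @return Binary matrix, one row per input; unparseable or missing SMILES
#'   rows are the zero vector (fallback), with a warning naming them.
#' @export
morgan_fingerprints <- function(smiles, radius = 3L, n_bits = 100L) {
  assert_that(radius %in% 0:5, "radius must be in 0..5")
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES featurization needs ChemmineOB", call. = FALSE)
  }
  fp_type <- sprintf("ECFP%d", 2L * radius)
  out <- matrix(0, nrow = length(smiles), ncol = n_bits)
  rownames(out) <- names(smiles)
  parsed <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    if (is.na(smiles[i]) || !nzchar(smiles[i])) next
    full <- tryCatch(suppressWarnings(ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles[[i]], identity), fp_type)),
      error = function(e) NULL)
    if (is.null(full) || sum(full) == 0) next
    full <- as.numeric(full)
    fold_idx <- (seq_along(full) - 1L) %% n_bits + 1L
    out[i, ] <- as.numeric(rowsum(full, fold_idx) > 0)
    parsed[i] <- TRUE
  }
  if (any(!parsed)) {
    warning(sprintf("%d SMILES missing/unparseable; zero-vector fallback used",
                    sum(!parsed)))
  }
  attr(out, "fallback") <- which(!parsed)
  out
}

#' Morgan fingerprint profiles for all drugs of a graph
#'
#' @param kg a `simvec_kg` whose entity table carries SMILES.
#' @inheritParams morgan_fingerprints
#' @return `chem_profiles` of kind `morgan` covering every drug.
#' @export
morgan_profiles <- function(kg, radius = 3L, n_bits = 100L) {
  drugs <- kg$entities[kg$entities$kind == "drug", ]
  m <- morgan_fingerprints(setNames(drugs$smiles, drugs$external_id),
                           radius = radius, n_bits = n_bits)
  chem_profiles(m, "morgan")
}

# numeric descriptor panel from OpenBabel properties, atom counts, ring and
# functional-group counts
descriptor_panel <- function(smiles_vec) {
  sdf <- smiles_to_sdf(setNames(smiles_vec, paste0("m", seq_along(smiles_vec))))
  prop <- ChemmineR::propOB(sdf)
  prop <- prop[, vapply(prop, is.numeric, logical(1L)), drop = FALSE]
  atoms <- ChemmineR::atomcountMA(sdf, addH = TRUE)
  rings <- ChemmineR::rings(sdf, type = "count", arom = FALSE)
  grp <- ChemmineR::groups(sdf, groups = "fctgroup", type = "countMA")
  panel <- cbind(as.matrix(prop), as.matrix(atoms),
                 as.matrix(rings), as.matrix(grp))
  storage.mode(panel) <- "double"
  panel
}

#' Standardized molecular-descriptor profiles
#'
#' Computes the available numeric descriptor panel for every drug, ranks
#' descriptors by their number of distinct values over the drug set (ties by
#' descriptor name), keeps the top `n_keep` and standardizes each kept column
#' to zero mean and unit variance. Drugs without a parseable SMILES get the
#' column mean (zero after standardization) as fallback.
#'
#' @param kg a `simvec_kg`.
#' @param n_keep number of descriptors to keep; clamped (with a warning) to
#'   the available panel size.
#' @return `chem_profiles` of kind `descriptor`; attribute `descriptors`
#'   names the kept columns.
#' @export
descriptor_profiles <- function(kg, n_keep = 100L) {
  drugs <- kg$entities[kg$entities$kind == "drug", ]
  ok <- !is.na(drugs$smiles) & nzchar(drugs$smiles)
  assert_that(sum(ok) >= 2L, "need at least 2 drugs with valid SMILES")
  panel <- descriptor_panel(drugs$smiles[ok])
  n_unique <- apply(panel, 2L, function(col) length(unique(col)))
  if (all(n_unique <= 1L)) stop("all descriptors constant; nothing to rank")
  ord <- order(-n_unique, colnames(panel))
  if (n_keep > ncol(panel)) {
    warning(sprintf("n_keep = %d exceeds available %d descriptors; keeping all",
                    n_keep, ncol(panel)))
    n_keep <- ncol(panel)
  }
  keep <- ord[seq_len(n_keep)]
  kept <- panel[, keep, drop = FALSE]
  kept <- scale(kept)
  kept[, attr(kept, "scaled:scale") == 0] <- 0    # constant kept columns
  out <- matrix(0, nrow = nrow(drugs), ncol = ncol(kept),
                dimnames = list(drugs$external_id, colnames(kept)))
  out[ok, ] <- kept
  if (any(!ok)) {
    warning(sprintf("%d drug(s) without SMILES get descriptor fallback (0)",
                    sum(!ok)))
  }
  p <- chem_profiles(out, "descriptor")
  attr(p, "descriptors") <- colnames(kept)
  p
}

#' Read external (e.g. hyperbolic VAE) drug embeddings from a table
#'
#' Consumes a CSV/TSV with a `drug_id` column followed by numeric columns.
#' No model is trained here; the vectors are taken as-is and paired with the
#' Lorentz similarity.
#'
#' @param path file path, or a data.frame already in memory.
#' @return `chem_profiles` of kind `external_embedding`.
#' @export
external_profiles <- function(path) {
  x <- if (is.character(path)) fread(path) else as.data.table(path)
  assert_that("drug_id" %in% names(x), "embedding table needs a drug_id column")
  ids <- as.character(x$drug_id)
  m <- as.matrix(x[, setdiff(names(x), "drug_id"), with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  chem_profiles(m, "external_embedding")
}

#' Tanimoto similarity of two binary vectors
#'
#' `|X AND Y| / |X OR Y|`; defined as 1 when both vectors are all-zero
#' (two featureless objects are treated as indistinguishable, avoiding 0/0).
#'
#' @param x,y equal-length binary vectors.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(x, y) {
  assert_that(length(x) == length(y), "tanimoto: length mismatch")
  u <- sum(x | y)
  if (u == 0) return(1)
  sum(x & y) / u
}

# pairwise tanimoto for the rows of binary matrices a (n x d) and b (m x d)
tanimoto_matrix <- function(a, b = a) {
  inter <- a %*% t(b)
  uni <- outer(rowSums(a), rowSums(b), `+`) - inter
  s <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  s
}

#' Gaussian-kernel similarity of two descriptor vectors
#'
#' `exp(-||x - y||^2 / sigma^2)`.
#'
#' @param x,y equal-length numeric vectors.
#' @param sigma positive kernel width; the default `sqrt(length(x))` makes
#'   typical distances between standardized descriptor vectors order sigma.
#' @return A number in `(0, 1]`.
#' @export
gaussian_similarity <- function(x, y, sigma = sqrt(length(x))) {
  assert_that(length(x) == length(y), "gaussian_similarity: length mismatch")
  assert_that(is.numeric(sigma) && sigma > 0, "sigma must be positive")
  exp(-sum((x - y)^2) / sigma^2)
}

#' Lorentz (hyperboloid) inner-product distance
#'
#' `-x0*y0 + sum_{i>=1} xi*yi` between points of a hyperboloid-model
#' embedding.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return A real number (can be negative; -1 for a point with itself on the
#'   unit hyperboloid).
#' @export
lorentz_distance <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2L,
              "lorentz_distance needs equal lengths >= 2")
  -x[1L] * y[1L] + sum(x[-1L] * y[-1L])
}

lorentz_gram <- function(mat) {
  g <- mat %*% diag(c(-1, rep(1, ncol(mat) - 1L))) %*% t(mat)
  g
}

#' Lorentz similarity normalized over a profile set
#'
#' `(max_{i,j} lor_dist - lor_dist(x, y)) / max_{i,j} lor_dist`, the maximum
#' taken over all drug pairs in the profile set and cached on the object.
#' As printed, the self-similarity of a hyperboloid point can exceed 1; the
#' value is deliberately not clipped.
#'
#' @param x,y embedding vectors.
#' @param profiles `chem_profiles` of kind `external_embedding` defining the
#'   normalizing maximum.
#' @return A real number.
#' @export
lorentz_similarity <- function(x, y, profiles) {
  mx <- attr(profiles, "max_lorentz")
  if (is.null(mx)) mx <- max(lorentz_gram(profiles$mat))
  if (mx == 0) stop("degenerate geometry: max Lorentz distance is 0")
  (mx - lorentz_distance(x, y)) / mx
}

# pairwise similarity matrix for a profile set under its native metric
pairwise_similarity <- function(profiles, sigma = NULL) {
  m <- profiles$mat
  switch(profiles$kind,
    morgan = tanimoto_matrix(m),
    descriptor = {
      s <- sigma %||% sqrt(ncol(m))
      d2 <- as.matrix(stats::dist(m))^2
      exp(-d2 / s^2)
    },
    external_embedding = {
      g <- lorentz_gram(m)
      mx <- max(g)
      if (mx == 0) stop("degenerate geometry: max Lorentz distance is 0")
      (mx - g) / mx
    })
}

#' Nearest strong neighbor of a drug in chemical space
#'
#' The strong-set drug minimizing Euclidean distance to `drug` in the given
#' profile space (molecular descriptors in the reference configuration);
#' ties broken by ascending external id.
#'
#' @param drug a drug external id.
#' @param strong_set character vector of candidate (strong) drug ids.
#' @param profiles a `chem_profiles` covering drug and candidates.
#' @return The chosen strong drug's external id.
#' @export
nearest_strong_neighbor <- function(drug, strong_set, profiles) {
  assert_that(length(strong_set) >= 1L, "strong_set must be nonempty")
  m <- profiles$mat
  getv <- function(id) {
    if (id %in% rownames(m)) m[id, ] else {
      warning(sprintf("drug %s lacks a profile; zero fallback used", id))
      numeric(ncol(m))
    }
  }
  x <- getv(drug)
  d <- vapply(strong_set, function(s) sqrt(sum((getv(s) - x)^2)), numeric(1L))
  strong_set[order(d, strong_set)][1L]
}
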