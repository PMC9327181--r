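# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom data.table data.table as.data.table setDT setkey setnames := .N .SD %chin% rbindlist fread fwrite copy setorder
#' @importFrom withr with_seed
#' @importFrom stats rnorm runif rbinom rpois sd setNames
#' @importFrom utils head modifyList
NULL

# derive a child seed from a master seed and an integer tag; stays < 2^31
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(tag) * 97 + 13) %% 2147483629) + 1L
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log-sum-exp of x within groups; group must take every value in 1..n_groups
grouped_logsumexp <- function(x, group, n_groups) {
  g <- factor(group, levels = seq_len(n_groups))
  mx <- as.numeric(tapply(x, g, max))
  s <- as.numeric(rowsum(exp(x - mx[group]), group)[, 1L])
  log(s) + mx
}

# M[idx, ] += X with duplicate indices accumulated
index_add <- function(M, idx, X) {
  if (length(idx) == 0L) return(M)
  if (is.null(dim(X))) X <- matrix(X, nrow = length(idx))
  agg <- rowsum(X, group = idx, reorder = TRUE)
  rows <- as.integer(rownames(agg))
  M[rows, ] <- M[rows, ] + agg
  M
}

# triple key strings used for filtered negative sampling
triple_key <- function(h, r, t) paste(h, r, t, sep = "|")

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
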