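# Shared fixture builders: all test data is constructed in code.

# The 18 canonical (state, compartment, time) groups.
fixture_groups <- function() dormclass:::design_groups()

# Expand a genes x 18 matrix of group means into a replicate-level expression
# matrix plus sample keys, with optional Gaussian replicate noise.
make_design_dataset <- function(group_means, n_rep = 3, noise_sd = 0,
                                seed = NULL) {
  groups <- fixture_groups()
  stopifnot(ncol(group_means) == nrow(groups))
  colnames(group_means) <- groups$group
  if (is.null(rownames(group_means))) {
    rownames(group_means) <- sprintf("gene%03d", seq_len(nrow(group_means)))
  }
  keys <- groups[rep(seq_len(nrow(groups)), each = n_rep), , drop = FALSE]
  keys$replicate <- rep(seq_len(n_rep), times = nrow(groups))
  keys$array <- paste0(keys$group, "_r", keys$replicate)
  rownames(keys) <- NULL
  mat <- group_means[, rep(seq_len(nrow(groups)), each = n_rep), drop = FALSE]
  colnames(mat) <- keys$array
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    mat <- mat + matrix(rnorm(length(mat), 0, noise_sd), nrow = nrow(mat))
  }
  list(matrix = mat, keys = keys)
}

# A mean_matrix straight from prescribed group means (zero noise).
make_mean_matrix <- function(group_means, n_rep = 2) {
  d <- make_design_dataset(group_means, n_rep = n_rep)
  compute_sample_means(d$matrix, d$keys)
}

# Group means that are `base` everywhere, with named overrides like
# list(gene001 = c(D_MCE_24 = 9)).
flat_group_means <- function(n_genes, base = 7, overrides = list()) {
  groups <- fixture_groups()
  m <- matrix(base, nrow = n_genes, ncol = nrow(groups),
              dimnames = list(sprintf("gene%03d", seq_len(n_genes)),
                              groups$group))
  for (g in names(overrides)) m[g, names(overrides[[g]])] <- overrides[[g]]
  m
}

# Small generator config for fast end-to-end runs.
small_generator_config <- function(seed = 1, noise_sd = 0.15, ...) {
  generator_config(
    n_flat = 100L,
    n_temporal_up = c(D_only = 15L, AR_only = 25L, both = 20L),
    n_temporal_down = c(D_only = 10L, AR_only = 20L, both = 15L),
    n_state_specific = c(D = 10L, AR = 15L),
    n_compartment_specific = c(MCE = 10L, RAD = 10L),
    n_noise_floor = 40L,
    noise_sd = noise_sd, seed = seed, ...
  )
}

# Exhaustive-enumeration oracle for the upper hypergeometric tail: fraction
# of all size-n subsets of an N-universe (K marked) overlapping the marked
# set in at least k elements. Only feasible for small N.
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  combos <- utils::combn(N, n)
  overlaps <- colSums(combos <= K)
  mean(overlaps >= k)
}

# Hand evaluation of the Benjamini-Hochberg step-up formula.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
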