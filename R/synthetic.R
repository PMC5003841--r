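# Synthetic-data generator emulating the study design: 2 dormancy states x
# (dry whole seed + 2 dissected compartments x 4 imbibition times) x
# replicates, with planted gene classes and a per-gene truth table so every
# downstream stage can be tested without downloads.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions at desk scale: log2 expression with
#' a technical-noise floor near 5, three replicates, Gaussian replicate noise
#' of 0.15 log2 units, planted fourfold (delta = 2) temporal regulation
#' between 3 and 24 HAS skewed toward the after-ripened state, plus
#' state-specific, compartment-specific, flat background and noise-floor
#' genes.
#'
#' @param n_flat number of flat expressed background genes.
#' @param n_temporal_up,n_temporal_down named counts `c(D_only=, AR_only=,
#'   both=)` of planted temporally regulated genes per regulated-state
#'   pattern.
#' @param n_state_specific named counts `c(D=, AR=)` of state-specific genes
#'   (pre-noise means > 6 in one state, < 5 in the other).
#' @param n_compartment_specific named counts `c(MCE=, RAD=)` of
#'   compartment-specific genes.
#' @param n_noise_floor number of genes with all pre-noise means below 5.
#' @param delta planted log2 effect size between 3 and 24 HAS (2 = fourfold).
#' @param noise_sd replicate noise standard deviation, log2 units.
#' @param n_replicates replicate arrays per group (a t-test needs >= 2).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_flat = 1000L,
                             n_temporal_up = c(D_only = 60L, AR_only = 150L,
                                               both = 90L),
                             n_temporal_down = c(D_only = 40L, AR_only = 100L,
                                                 both = 60L),
                             n_state_specific = c(D = 20L, AR = 60L),
                             n_compartment_specific = c(MCE = 30L, RAD = 30L),
                             n_noise_floor = 500L,
                             delta = 2.0, noise_sd = 0.15,
                             n_replicates = 3L, seed = 1L) {
  norm_counts <- function(x, nms) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(as.integer(x), length(nms)), nms)
    }
    if (!all(nms %in% names(x))) {
      stop("counts must be named with: ", paste(nms, collapse = ", "))
    }
    stats::setNames(as.integer(x[nms]), nms)
  }
  cfg <- list(
    n_flat = as.integer(n_flat),
    n_temporal_up = norm_counts(n_temporal_up, c("D_only", "AR_only", "both")),
    n_temporal_down = norm_counts(n_temporal_down,
                                  c("D_only", "AR_only", "both")),
    n_state_specific = norm_counts(n_state_specific, c("D", "AR")),
    n_compartment_specific = norm_counts(n_compartment_specific,
                                         c("MCE", "RAD")),
    n_noise_floor = as.integer(n_noise_floor),
    delta = delta, noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  )
  counts <- c(cfg$n_flat, cfg$n_temporal_up, cfg$n_temporal_down,
              cfg$n_state_specific, cfg$n_compartment_specific,
              cfg$n_noise_floor)
  if (any(counts < 0L)) stop("all gene counts must be >= 0")
  if (sum(counts) == 0L) stop("generator needs at least one gene")
  if (cfg$delta < 0) stop("delta must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (cfg$n_replicates < 2L) {
    warning("n_replicates < 2: downstream t-tests will not be computable")
  }
  structure(cfg, class = "generator_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Linear temporal ramp: baseline at dry seed and 3 HAS, full effect at
# 24 HAS, interpolated in time in between.
ramp <- function(time_has, baseline, delta_signed) {
  if (time_has <= 3L) return(baseline)
  baseline + delta_signed * (time_has - 3L) / 21
}

#' Generate a synthetic expression dataset with truth labels
#'
#' Builds pre-noise group means per planted class, then expands each of the
#' 18 design groups into replicate arrays with i.i.d. Gaussian noise. Planted
#' temporal genes change by exactly `delta` (before noise) between 3 and
#' 24 HAS in their regulated state(s), linearly in time, in both dissected
#' compartments; state-specific genes sit above 6 in one state and below 5 in
#' the other; compartment-specific genes above 6 in one dissected compartment
#' (both states) and below 5 elsewhere, including the dry seed; noise-floor
#' genes stay below 5 everywhere.
#'
#' @param config a `generator_config`.
#' @return list with `matrix` (genes x arrays), `keys` (sample sheet
#'   data.frame) and `truth` (data.frame `gene_id`, `class`, `direction`,
#'   `regulated_in`, `baseline`, `level_low`, `delta`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    groups <- design_groups()
    spec_rows <- list()
    add <- function(n, class, direction = NA_character_,
                    regulated_in = NA_character_) {
      if (n > 0L) {
        spec_rows[[length(spec_rows) + 1L]] <<- data.frame(
          class = class, direction = direction, regulated_in = regulated_in,
          stringsAsFactors = FALSE
        )[rep(1L, n), , drop = FALSE]
      }
    }
    add(config$n_flat, "flat")
    for (pat in c("D_only", "AR_only", "both")) {
      add(config$n_temporal_up[[pat]], paste0("temporal_up_", pat), "up", pat)
      add(config$n_temporal_down[[pat]], paste0("temporal_down_", pat),
          "down", pat)
    }
    for (s in c("D", "AR")) {
      add(config$n_state_specific[[s]], paste0("state_specific_", s))
    }
    for (comp in c("MCE", "RAD")) {
      add(config$n_compartment_specific[[comp]],
          paste0("compartment_specific_", comp))
    }
    add(config$n_noise_floor, "noise_floor")
    truth <- do.call(rbind, spec_rows)
    n_genes <- nrow(truth)
    truth$gene_id <- sprintf("g%05d", seq_len(n_genes))
    rownames(truth) <- NULL

    # per-gene levels: expressed baselines uniform on [6, 12]; specific
    # high side uniform on [6.5, 10]; absent side uniform on [3.5, 4.5];
    # noise floor Gaussian(3.5, 0.3) resampled while >= 5
    truth$baseline <- stats::runif(n_genes, 6, 12)
    truth$level_low <- NA_real_
    truth$delta <- NA_real_
    is_spec <- grepl("_specific_", truth$class)
    truth$baseline[is_spec] <- stats::runif(sum(is_spec), 6.5, 10)
    truth$level_low[is_spec] <- stats::runif(sum(is_spec), 3.5, 4.5)
    is_nf <- truth$class == "noise_floor"
    if (any(is_nf)) {
      b <- stats::rnorm(sum(is_nf), 3.5, 0.3)
      while (any(b >= 5)) b[b >= 5] <- stats::rnorm(sum(b >= 5), 3.5, 0.3)
      truth$baseline[is_nf] <- b
    }
    is_temp <- grepl("^temporal_", truth$class)
    truth$delta[is_temp] <- ifelse(truth$direction[is_temp] == "up",
                                   config$delta, -config$delta)

    # pre-noise means, genes x 18 groups
    mu <- matrix(0, nrow = n_genes, ncol = nrow(groups),
                 dimnames = list(truth$gene_id, groups$group))
    for (j in seq_len(nrow(groups))) {
      st <- groups$state[j]; comp <- groups$compartment[j]
      t_has <- groups$time_has[j]
      m <- truth$baseline
      reg <- is_temp & (truth$regulated_in == "both" |
                          truth$regulated_in == paste0(st, "_only"))
      if (comp != "SEED") {
        m[reg] <- ramp(t_has, truth$baseline[reg], truth$delta[reg])
      }
      st_spec_other <- truth$class == paste0("state_specific_",
                                             setdiff(c("D", "AR"), st))
      m[st_spec_other] <- truth$level_low[st_spec_other]
      comp_spec <- grepl("^compartment_specific_", truth$class)
      low_here <- comp_spec & (comp == "SEED" |
                                 truth$class != paste0("compartment_specific_",
                                                       comp))
      m[low_here] <- truth$level_low[low_here]
      mu[, j] <- m
    }

    # expand to replicate arrays with i.i.d. Gaussian noise
    n_rep <- config$n_replicates
    keys <- groups[rep(seq_len(nrow(groups)), each = n_rep), , drop = FALSE]
    keys$replicate <- rep(seq_len(n_rep), times = nrow(groups))
    keys$array <- paste0(keys$group, "_r", keys$replicate)
    rownames(keys) <- NULL
    keys <- keys[, c("array", "state", "compartment", "time_has",
                     "replicate", "group")]
    mat <- mu[, rep(seq_len(nrow(groups)), each = n_rep), drop = FALSE]
    colnames(mat) <- keys$array
    if (config$noise_sd > 0) {
      mat <- mat + matrix(stats::rnorm(length(mat), 0, config$noise_sd),
                          nrow = nrow(mat))
    }
    truth <- truth[, c("gene_id", "class", "direction", "regulated_in",
                       "baseline", "level_low", "delta")]
    list(matrix = mat, keys = keys, truth = truth)
  })
}

#' Generate a synthetic annotation catalog from a truth table
#'
#' Emits one designated enriched term whose members are drawn with
#' probability mass `enrichment_fraction` from one truth class (prefix
#' matching, so `"temporal_up"` covers all up patterns) and the remainder
#' uniformly from all genes, plus `n_terms - 1` uniformly drawn background
#' terms. With `enrichment_fraction = 0` every term is uniform.
#'
#' @param truth truth table from [generate_dataset()].
#' @param n_terms total number of terms.
#' @param enrichment_fraction fraction of the enriched term drawn from the
#'   class, in [0, 1].
#' @param seed integer seed.
#' @param enriched_class truth-class label or prefix; required when
#'   `enrichment_fraction > 0`.
#' @param term_size members per term.
#' @return An `annotation_catalog`; the enriched term is named `"enriched"`,
#'   background terms `"T001"`, `"T002"`, ...
#' @export
generate_annotation_catalog <- function(truth, n_terms = 20L,
                                        enrichment_fraction = 0,
                                        seed = 1L, enriched_class = NULL,
                                        term_size = 50L) {
  if (enrichment_fraction < 0 || enrichment_fraction > 1) {
    stop("enrichment_fraction must lie in [0, 1]")
  }
  if (n_terms < 1L) stop("n_terms must be >= 1")
  all_genes <- truth$gene_id
  class_genes <- character(0)
  if (enrichment_fraction > 0) {
    if (is.null(enriched_class)) {
      stop("enriched_class is required when enrichment_fraction > 0")
    }
    class_genes <- all_genes[startsWith(truth$class, enriched_class)]
    if (length(class_genes) == 0L) {
      stop("truth class '", enriched_class, "' is empty")
    }
  }
  with_seed(seed, {
    terms <- list()
    if (enrichment_fraction > 0) {
      n_in <- min(round(enrichment_fraction * term_size), length(class_genes))
      members <- sample(class_genes, n_in)
      n_out <- term_size - n_in
      if (n_out > 0L) {
        pool <- setdiff(all_genes, members)
        members <- c(members, sample(pool, min(n_out, length(pool))))
      }
      terms[["enriched"]] <- sort(members)
      n_bg <- n_terms - 1L
    } else {
      n_bg <- n_terms
    }
    if (n_bg > 0L) {
      for (i in seq_len(n_bg)) {
        terms[[sprintf("T%03d", i)]] <-
          sort(sample(all_genes, min(term_size, length(all_genes))))
      }
    }
    descriptions <- stats::setNames(rep("synthetic term", length(terms)),
                                    names(terms))
    structure(list(terms = terms, descriptions = descriptions),
              class = "annotation_catalog")
  })
}
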