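# Two-step temporal classification of imbibition-regulated genes, the
# decomposition of state-differential expression into underlying temporal
# profiles, dual state-and-compartment enrichment sets, and mean expression
# profiles of gene sets.

#' Select strongly temporally regulated genes (step 1)
#'
#' Finds genes whose expression changes at least `fold`-fold between 3 and
#' 24 HAS in the dormant and/or after-ripened state of one compartment, using
#' the full DE call (clipped fold change + t-test) per state. A gene may carry
#' one label per direction: up in both states collapses to one `both` label,
#' while up in one state and down in the other yields two labels.
#'
#' @param matrix expression matrix (genes x arrays, log2).
#' @param keys sample keys.
#' @param compartment `"MCE"` or `"RAD"`.
#' @param fold step-1 fold cut-off.
#' @param alpha,clip,var_equal DE-caller parameters, see [de_call()].
#' @param require_significance when `FALSE` the t-test requirement is dropped
#'   and selection is by fold change alone.
#' @return data.frame of temporal labels: `gene_id`, `direction`
#'   (`up`/`down`), `regulated_in` (`D_only`/`AR_only`/`both`).
#' @export
select_temporally_regulated <- function(matrix, keys, compartment, fold = 3,
                                        alpha = 0.05, clip = 4,
                                        var_equal = TRUE,
                                        require_significance = TRUE) {
  de <- lapply(stats::setNames(STATES, STATES), function(s) {
    de_call(matrix, keys,
            group_a = group_id(s, compartment, 3L),
            group_b = group_id(s, compartment, 24L),
            alpha = alpha, clip = clip, cutoffs = fold, var_equal = var_equal)
  })
  dir_in <- function(rec) {
    passes <- abs(rec$clipped_lfc) >= log2(fold)
    if (require_significance) passes <- passes & rec$p_value < alpha
    ifelse(!passes, "none", ifelse(rec$clipped_lfc > 0, "up", "down"))
  }
  d_dir <- dir_in(de$D)
  ar_dir <- dir_in(de$AR)
  genes <- de$D$gene_id
  rows <- list()
  for (direction in c("up", "down")) {
    in_d <- d_dir == direction
    in_ar <- ar_dir == direction
    hit <- in_d | in_ar
    if (!any(hit)) next
    regulated_in <- ifelse(in_d[hit] & in_ar[hit], "both",
                           ifelse(in_d[hit], "D_only", "AR_only"))
    rows[[direction]] <- data.frame(gene_id = genes[hit],
                                    direction = direction,
                                    regulated_in = regulated_in,
                                    stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(gene_id = character(0), direction = character(0),
               regulated_in = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "compartment") <- compartment
  attr(out, "fold") <- fold
  out
}

#' Five-class D-vs-AR classification of temporal genes (step 2)
#'
#' Bins every step-1 gene by its dormant-vs-after-ripened expression
#' difference at 24 HAS: `similar` below the first band (twofold), `weak_D` /
#' `weak_AR` between the bands (side by sign; D means higher in dormant),
#' `strong_D` / `strong_AR` at or above the second band (threefold) when the
#' t-test is also significant — a large but non-significant difference
#' demotes to weak, so the five classes partition the step-1 selection.
#'
#' @param labels temporal labels from [select_temporally_regulated()].
#' @param de_24 DE records from [state_contrast()] at 24 HAS (positive lfc
#'   means higher in D).
#' @param bands fold boundaries of the similar/weak and weak/strong bands.
#' @param alpha significance level for the strong classes.
#' @return data.frame `gene_id`, `class`, `delta_24` (clipped lfc, D - AR),
#'   `p_value`, one row per distinct step-1 gene.
#' @export
classify_step2 <- function(labels, de_24, bands = c(2, 3), alpha = 0.05) {
  stopifnot(length(bands) == 2L, bands[1L] < bands[2L])
  genes <- unique(labels$gene_id)
  idx <- match(genes, de_24$gene_id)
  if (anyNA(idx)) {
    stop("labeled gene missing from the 24 HAS contrast: ",
         genes[which(is.na(idx))[1L]])
  }
  delta <- de_24$clipped_lfc[idx]
  p <- de_24$p_value[idx]
  side <- ifelse(delta > 0, "D", "AR")
  cls <- ifelse(abs(delta) < log2(bands[1L]), "similar",
         ifelse(abs(delta) >= log2(bands[2L]) & p < alpha,
                paste0("strong_", side), paste0("weak_", side)))
  data.frame(gene_id = genes, class = cls, delta_24 = delta, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Decompose state-differential expression into temporal profiles
#'
#' For every gene strongly differentially expressed between D and AR at
#' 24 HAS on the requested side, reports which temporal profile(s) underlie
#' the difference: strongly up- or down-regulated between 3 and 24 HAS in D
#' only, in both states, or in AR only — or `not_strongly_regulated` when the
#' gene shows no threefold temporal change in either state (opposing weaker
#' profiles). A gene strongly up in one state and strongly down in the other
#' carries both patterns and is counted twice.
#'
#' @param de_24 DE records from [state_contrast()] at 24 HAS.
#' @param labels temporal labels from [select_temporally_regulated()] on the
#'   same compartment.
#' @param side `"higher_in_D"` or `"higher_in_AR"`.
#' @param fold strong-DE fold cut-off at 24 HAS.
#' @param alpha significance level.
#' @return data.frame `gene_id`, `side`, `temporal_pattern` (one of
#'   `up_D_only`, `up_both`, `up_AR_only`, `down_D_only`, `down_both`,
#'   `down_AR_only`, `not_strongly_regulated`).
#' @export
decompose_differential_profiles <- function(de_24, labels, side, fold = 3,
                                            alpha = 0.05) {
  side <- match.arg(side, c("higher_in_D", "higher_in_AR"))
  sign_needed <- if (side == "higher_in_D") 1 else -1
  strong <- de_24$gene_id[sign_needed * de_24$clipped_lfc >= log2(fold) &
                            de_24$p_value < alpha]
  if (length(strong) == 0L) {
    return(data.frame(gene_id = character(0), side = character(0),
                      temporal_pattern = character(0),
                      stringsAsFactors = FALSE))
  }
  pattern_of <- function(g) {
    lab <- labels[labels$gene_id == g, , drop = FALSE]
    if (nrow(lab) == 0L) return("not_strongly_regulated")
    paste0(lab$direction, "_",
           ifelse(lab$regulated_in == "both", "both", lab$regulated_in))
  }
  rows <- lapply(strong, function(g) {
    data.frame(gene_id = g, side = side, temporal_pattern = pattern_of(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes enriched in both a state and a compartment (dual-enrichment rule)
#'
#' Selects genes at least `state_fold`-fold higher in the given state than in
#' the other state (same compartment and time) AND at least
#' `compartment_fold`-fold higher in the given compartment than in the other
#' dissected compartment (within the given state, same time). Both conditions
#' use the full DE call, including the t-test.
#'
#' @inheritParams de_call
#' @param state,compartment,time_has the target condition, e.g. D, MCE,
#'   24 HAS.
#' @param state_fold,compartment_fold fold cut-offs of the two conditions.
#' @param require_significance drop the t-test requirement when `FALSE`.
#' @return Character vector of gene ids (matrix order).
#' @export
dual_enriched_set <- function(matrix, keys, state, compartment, time_has,
                              state_fold = 3, compartment_fold = 3,
                              alpha = 0.05, clip = 4, var_equal = TRUE,
                              require_significance = TRUE) {
  state <- match.arg(state, STATES)
  compartment <- match.arg(compartment, c("MCE", "RAD"))
  other_state <- setdiff(STATES, state)
  other_comp <- setdiff(c("MCE", "RAD"), compartment)
  de_state <- de_call(matrix, keys,
                      group_a = group_id(other_state, compartment, time_has),
                      group_b = group_id(state, compartment, time_has),
                      alpha = alpha, clip = clip, cutoffs = state_fold,
                      var_equal = var_equal)
  de_comp <- de_call(matrix, keys,
                     group_a = group_id(state, other_comp, time_has),
                     group_b = group_id(state, compartment, time_has),
                     alpha = alpha, clip = clip, cutoffs = compartment_fold,
                     var_equal = var_equal)
  pass <- function(rec, fold) {
    ok <- rec$clipped_lfc >= log2(fold)
    if (require_significance) ok <- ok & rec$p_value < alpha
    ok
  }
  de_state$gene_id[pass(de_state, state_fold) & pass(de_comp, compartment_fold)]
}

#' Mean expression profile of a gene set over the time course
#'
#' Averages the log2 group means of all genes in the set at 0, 3, 7, 12 and
#' 24 HAS for one state and compartment; the 0 HAS value comes from that
#' state's undissected dry whole-seed group.
#'
#' @param genes non-empty character vector of gene ids.
#' @param means a `mean_matrix` covering the full design.
#' @param state,compartment which trajectory to average.
#' @return Named numeric vector of length 5 (names `"0"`, `"3"`, `"7"`,
#'   `"12"`, `"24"`).
#' @export
mean_profile <- function(genes, means, state, compartment) {
  if (length(genes) == 0L) stop("gene set is empty")
  missing_g <- setdiff(genes, rownames(means$values))
  if (length(missing_g) > 0L) {
    stop("gene missing from mean matrix: ", missing_g[1L])
  }
  groups <- c(group_id(state, "SEED", 0L),
              group_id(state, compartment, c(3L, 7L, 12L, 24L)))
  missing_grp <- setdiff(groups, means$groups$group)
  if (length(missing_grp) > 0L) stop("missing group: ", missing_grp[1L])
  prof <- colMeans(means$values[genes, groups, drop = FALSE])
  stats::setNames(prof, as.character(TIMES_HAS))
}
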