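# Expressed-gene and specificity calling on replicate-mean expression.
# "Expressed in a sample" means the group mean exceeds the detection
# threshold (log2 5, below which signal is indistinguishable from technical
# noise on the array); "specific" combines a high threshold (log2 6) on one
# side with absence (< 5) on the other.

row_max <- function(values, cols) {
  apply(values[, cols, drop = FALSE], 1L, max)
}

#' Call genes expressed above a threshold in at least one group
#'
#' @param means a `mean_matrix` from [compute_sample_means()].
#' @param threshold log2 detection threshold (strict `>`).
#' @param scope character vector of group ids to consider; default all groups.
#' @return Character vector of expressed gene ids (matrix order).
#' @export
call_expressed <- function(means, threshold = 5, scope = NULL) {
  if (is.null(scope)) scope <- means$groups$group
  if (length(scope) == 0L) stop("scope must name at least one group")
  unknown <- setdiff(scope, means$groups$group)
  if (length(unknown) > 0L) stop("unknown group in scope: ", unknown[1L])
  mx <- row_max(means$values, scope)
  rownames(means$values)[mx > threshold]
}

#' Expressed-gene counts per group, union and intersection
#'
#' @inheritParams call_expressed
#' @return list with `per_group` (named integer vector), `union` and
#'   `intersection` counts over all groups.
#' @export
expressed_counts <- function(means, threshold = 5) {
  expr <- means$values > threshold
  per_group <- colSums(expr)
  list(per_group = per_group,
       union = sum(rowSums(expr) > 0L),
       intersection = sum(rowSums(expr) == ncol(expr)))
}

# Shared dual-threshold specificity rule over two group families A and B.
# Uses the max of each family's group means on both sides: specific to A
# means max_A > hi while every group of B (hence max_B) is below lo.
call_specific_pair <- function(means, groups_a, groups_b, label_a, label_b,
                               hi = 6, lo = 5) {
  if (length(groups_a) == 0L || length(groups_b) == 0L) {
    stop("both group families must be non-empty for specificity calling")
  }
  max_a <- row_max(means$values, groups_a)
  max_b <- row_max(means$values, groups_b)
  call <- rep("not_expressed", length(max_a))
  call[max_a > hi & max_b > hi] <- "shared"
  call[max_a > hi & max_b < lo] <- paste0("specific_", label_a)
  call[max_b > hi & max_a < lo] <- paste0("specific_", label_b)
  amb <- (max_a > hi & max_b >= lo & max_b <= hi) |
    (max_b > hi & max_a >= lo & max_a <= hi)
  call[amb] <- "ambiguous"
  df <- data.frame(gene_id = rownames(means$values), call = call,
                   stringsAsFactors = FALSE, row.names = NULL)
  df[[paste0("max_mean_", label_a)]] <- max_a
  df[[paste0("max_mean_", label_b)]] <- max_b
  df
}

#' Dormancy-state specific expression calls
#'
#' A gene is specific to a state when its maximal group mean in that state
#' exceeds `hi` while its maximal group mean in the other state stays below
#' `lo`; `shared` when both maxima exceed `hi`; `ambiguous` when one side is
#' above `hi` but the other falls between `lo` and `hi` (expressed, but not
#' highly specific); `not_expressed` otherwise.
#'
#' @param means a `mean_matrix`.
#' @param hi high (specific-expression) threshold, log2.
#' @param lo low (technical-noise) threshold, log2.
#' @return data.frame `gene_id`, `call`, `max_mean_D`, `max_mean_AR`.
#' @export
call_state_specific <- function(means, hi = 6, lo = 5) {
  call_specific_pair(means,
                     groups_for(means, state = "D"),
                     groups_for(means, state = "AR"),
                     "D", "AR", hi = hi, lo = lo)
}

#' Seed-compartment specific expression calls
#'
#' Same dual-threshold rule between the micropylar/chalazal endosperm (MCE)
#' and the radicle (RAD); undissected dry whole-seed groups are excluded.
#'
#' @inheritParams call_state_specific
#' @return data.frame `gene_id`, `call`, `max_mean_MCE`, `max_mean_RAD`.
#' @export
call_compartment_specific <- function(means, hi = 6, lo = 5) {
  call_specific_pair(means,
                     groups_for(means, compartment = "MCE"),
                     groups_for(means, compartment = "RAD"),
                     "MCE", "RAD", hi = hi, lo = lo)
}

#' Combined state-and-compartment specific expression calls
#'
#' A gene is specific to (state s, compartment c) when its maximal mean over
#' the (s, c) groups exceeds `hi` while its maximal mean over every other
#' dissected group stays below `lo`. Dry whole-seed groups are excluded.
#'
#' @inheritParams call_state_specific
#' @return data.frame `gene_id`, `call` (`specific_<state>_<compartment>` or
#'   `not_specific`), plus the four per-combination maxima.
#' @export
call_state_compartment_specific <- function(means, hi = 6, lo = 5) {
  combos <- expand.grid(state = STATES, compartment = c("MCE", "RAD"),
                        stringsAsFactors = FALSE)
  dissected <- groups_for(means, dissected_only = TRUE)
  maxima <- lapply(seq_len(nrow(combos)), function(i) {
    g <- groups_for(means, state = combos$state[i],
                    compartment = combos$compartment[i])
    if (length(g) == 0L) {
      stop("no groups for ", combos$state[i], " ", combos$compartment[i])
    }
    row_max(means$values, g)
  })
  names(maxima) <- paste0(combos$state, "_", combos$compartment)
  call <- rep("not_specific", nrow(means$values))
  for (nm in names(maxima)) {
    others <- setdiff(dissected,
                      means$groups$group[paste0(means$groups$state, "_",
                                                means$groups$compartment) == nm])
    other_max <- row_max(means$values, others)
    hit <- maxima[[nm]] > hi & other_max < lo
    call[hit] <- paste0("specific_", nm)
  }
  df <- data.frame(gene_id = rownames(means$values), call = call,
                   stringsAsFactors = FALSE, row.names = NULL)
  for (nm in names(maxima)) df[[paste0("max_mean_", nm)]] <- maxima[[nm]]
  df
}

#' Refine a specific gene set against a reference dataset
#'
#' Retains genes that are absent (mean below `lo`) in every named group of a
#' reference mean matrix, e.g. to drop compartment-specific candidates that
#' are expressed in the corresponding tissues of another genotype. Genes
#' missing from the reference are retained with a warning, since platform or
#' annotation differences may drop genes.
#'
#' @param genes character vector of gene ids.
#' @param reference_means `mean_matrix` of the reference dataset.
#' @param reference_groups group ids within the reference to screen against.
#' @param lo log2 absence threshold.
#' @return Character vector, the retained subset of `genes`.
#' @export
refine_against_reference <- function(genes, reference_means, reference_groups,
                                     lo = 5) {
  unknown <- setdiff(reference_groups, reference_means$groups$group)
  if (length(unknown) > 0L) stop("unknown reference group: ", unknown[1L])
  if (length(genes) == 0L) return(character(0))
  present <- genes %in% rownames(reference_means$values)
  if (any(!present)) {
    warning(sum(!present), " gene(s) absent from the reference matrix were retained")
  }
  checked <- genes[present]
  if (length(checked) > 0L) {
    mx <- row_max(reference_means$values[checked, , drop = FALSE],
                  reference_groups)
    keep_checked <- checked[mx < lo]
  } else {
    keep_checked <- character(0)
  }
  genes[genes %in% keep_checked | !present]
}
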