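# Differential-expression calling: clipped mean fold change plus a two-sample
# t-test on the unclipped replicate values. Clipping suppresses fold changes
# that originate in the technical-noise region of the array.

#' Noise-clipped log2 fold change
#'
#' Group means below the clip level (default 4, log2 scale, the noise region
#' of the platform) are raised to the clip level before the difference is
#' taken, so that fold changes cannot be driven by noise-level values.
#'
#' @param mean_a,mean_b group means on the log2 scale (vectorized).
#' @param clip log2 clip level.
#' @return Signed log2 fold change, `max(mean_b, clip) - max(mean_a, clip)`.
#' @export
clipped_fold_change <- function(mean_a, mean_b, clip = 4) {
  stopifnot(is.numeric(mean_a), is.numeric(mean_b))
  if (any(!is.finite(mean_a)) || any(!is.finite(mean_b))) {
    stop("group means must be finite")
  }
  pmax(mean_b, clip) - pmax(mean_a, clip)
}

# Row-wise two-sample t-test over two replicate matrices (genes x replicates).
# Student (pooled variance) by default; Welch behind var_equal = FALSE.
# Zero-variance convention: when the standard error is exactly zero the test
# degenerates; equal means give t = 0, p = 1, unequal means give t = +/-Inf,
# p = 0. This keeps noise-free synthetic data usable.
row_t_test <- function(a, b, var_equal = TRUE) {
  n_a <- ncol(a); n_b <- ncol(b)
  if (n_a < 2L || n_b < 2L) stop("each group needs at least 2 replicate values")
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- apply(a, 1L, stats::var)
  v_b <- apply(b, 1L, stats::var)
  if (var_equal) {
    s2 <- ((n_a - 1L) * v_a + (n_b - 1L) * v_b) / (n_a + n_b - 2L)
    se <- sqrt(s2 * (1 / n_a + 1 / n_b))
    df <- rep(n_a + n_b - 2L, length(se))
  } else {
    se2 <- v_a / n_a + v_b / n_b
    se <- sqrt(se2)
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1L) + (v_b / n_b)^2 / (n_b - 1L))
  }
  diff <- m_b - m_a
  t_stat <- ifelse(se > 0, diff / se,
                   ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(diff == 0, 1, 0))
  list(t_stat = t_stat, p_value = p)
}

#' Two-sample t-test on replicate log2 values
#'
#' Two-sided; Student's pooled-variance form by default
#' (df = n_A + n_B - 2), Welch with `var_equal = FALSE`. When both groups have
#' zero variance the test degenerates and the convention p = 1 (equal means) /
#' p = 0 (unequal means) applies.
#'
#' @param values_a,values_b numeric replicate vectors, each of length >= 2.
#' @param var_equal pooled variance (`TRUE`, default) or Welch.
#' @return list with `t_stat` and `p_value` (sign of t follows B - A).
#' @export
two_group_t_test <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 replicate values")
  }
  res <- row_t_test(matrix(values_a, nrow = 1L), matrix(values_b, nrow = 1L),
                    var_equal = var_equal)
  list(t_stat = unname(res$t_stat), p_value = unname(res$p_value))
}

#' Differential-expression call between two sample groups
#'
#' Combines the clipped fold change of the group means with a t-test on the
#' unclipped replicate values; a gene is called at fold cut-off f when
#' |clipped lfc| >= log2(f) (inclusive) and p < alpha. Calls are nested across
#' cut-offs by construction.
#'
#' @param matrix expression matrix (genes x arrays, log2).
#' @param keys sample keys (see [read_sample_sheet()]).
#' @param group_a,group_b group identifiers like `"D_MCE_3"` (see
#'   [group_id()]); the fold change is signed B - A.
#' @param alpha t-test significance level.
#' @param clip log2 clip level for the fold change.
#' @param cutoffs fold-change cut-offs to flag.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame of DE records: `gene_id`, `mean_a`, `mean_b`,
#'   `clipped_lfc`, `t_stat`, `p_value`, and one logical `sig_<f>` column per
#'   cut-off.
#' @export
de_call <- function(matrix, keys, group_a, group_b, alpha = 0.05, clip = 4,
                    cutoffs = c(2, 3, 5, 10), var_equal = TRUE) {
  keys <- validate_sample_keys(keys, colnames(matrix))
  cols_a <- keys$array[keys$group == group_a]
  cols_b <- keys$array[keys$group == group_b]
  if (length(cols_a) == 0L) stop("no arrays for group: ", group_a)
  if (length(cols_b) == 0L) stop("no arrays for group: ", group_b)
  if (length(intersect(cols_a, cols_b)) > 0L) {
    stop("contrast groups overlap: ", group_a, " vs ", group_b)
  }
  a <- matrix[, cols_a, drop = FALSE]
  b <- matrix[, cols_b, drop = FALSE]
  tt <- row_t_test(a, b, var_equal = var_equal)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  lfc <- clipped_fold_change(mean_a, mean_b, clip = clip)
  rec <- data.frame(
    gene_id = rownames(matrix), mean_a = mean_a, mean_b = mean_b,
    clipped_lfc = lfc, t_stat = tt$t_stat, p_value = tt$p_value,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (f in sort(cutoffs)) {
    rec[[paste0("sig_", f)]] <- abs(lfc) >= log2(f) & tt$p_value < alpha
  }
  attr(rec, "contrast") <- c(group_a = group_a, group_b = group_b)
  attr(rec, "alpha") <- alpha
  attr(rec, "cutoffs") <- sort(cutoffs)
  rec
}

#' Count significant genes per direction and fold cut-off
#'
#' @param records DE records from [de_call()].
#' @return data.frame with one row per cut-off: `cutoff`, `n_up` (lfc > 0),
#'   `n_down`, `n_total`.
#' @export
de_counts <- function(records) {
  cutoffs <- attr(records, "cutoffs")
  if (is.null(cutoffs)) {
    cutoffs <- as.numeric(sub("^sig_", "",
                              grep("^sig_", colnames(records), value = TRUE)))
  }
  do.call(rbind, lapply(cutoffs, function(f) {
    sig <- records[[paste0("sig_", f)]]
    data.frame(cutoff = f,
               n_up = sum(sig & records$clipped_lfc > 0),
               n_down = sum(sig & records$clipped_lfc < 0),
               n_total = sum(sig))
  }))
}

#' Temporal contrast suite for one state and compartment
#'
#' Runs the DE caller between consecutive imbibition time points (3-7, 7-12,
#' 12-24 HAS) and between every later time point and the first imbibed time
#' point (7, 12, 24 vs 3 HAS). Positive fold change means up-regulated over
#' time.
#'
#' @inheritParams de_call
#' @param state,compartment the sample group the suite runs within.
#' @return list with `records` (named list of DE-record data.frames, names
#'   like `"consecutive_3_7"` / `"vs_first_24"`) and `counts` (one long
#'   data.frame of per-direction counts per cut-off).
#' @export
contrast_suite <- function(matrix, keys, state, compartment, alpha = 0.05,
                           clip = 4, cutoffs = c(2, 3, 5, 10),
                           var_equal = TRUE) {
  keys <- validate_sample_keys(keys, colnames(matrix))
  times <- c(3L, 7L, 12L, 24L)
  have <- unique(keys$time_has[keys$state == state &
                                 keys$compartment == compartment])
  missing_t <- setdiff(times, have)
  if (length(missing_t) > 0L) {
    stop("missing time point ", missing_t[1L], " HAS for ", state, " ",
         compartment)
  }
  pairs <- rbind(
    data.frame(label = sprintf("consecutive_%d_%d", times[-4L], times[-1L]),
               from = times[-4L], to = times[-1L]),
    data.frame(label = sprintf("vs_first_%d", times[-1L]),
               from = 3L, to = times[-1L])
  )
  records <- lapply(seq_len(nrow(pairs)), function(i) {
    de_call(matrix, keys,
            group_a = group_id(state, compartment, pairs$from[i]),
            group_b = group_id(state, compartment, pairs$to[i]),
            alpha = alpha, clip = clip, cutoffs = cutoffs,
            var_equal = var_equal)
  })
  names(records) <- pairs$label
  counts <- do.call(rbind, lapply(pairs$label, function(lbl) {
    cbind(contrast = lbl, state = state, compartment = compartment,
          de_counts(records[[lbl]]))
  }))
  rownames(counts) <- NULL
  list(records = records, counts = counts)
}

#' Dormant vs after-ripened contrast at one compartment and time
#'
#' Sign convention: positive clipped fold change means higher expression in
#' the dormant (D) state.
#'
#' @inheritParams de_call
#' @param compartment,time_has where the two states are compared.
#' @return DE records as from [de_call()] with B = D, A = AR.
#' @export
state_contrast <- function(matrix, keys, compartment, time_has, alpha = 0.05,
                           clip = 4, cutoffs = c(2, 3, 5, 10),
                           var_equal = TRUE) {
  de_call(matrix, keys,
          group_a = group_id("AR", compartment, time_has),
          group_b = group_id("D", compartment, time_has),
          alpha = alpha, clip = clip, cutoffs = cutoffs,
          var_equal = var_equal)
}
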