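# Count-summary helpers used by the pipeline manifest. The study's results
# are essentially a ledger of gene counts and the percentages derived from
# them, so the reporting layer is deliberately explicit about both.

#' Percentage of a count within a total, rounded for reporting
#'
#' @param k numerator count.
#' @param n denominator count, > 0.
#' @param digits decimal places of the reported percentage.
#' @return `100 * k / n`, rounded.
#' @export
fraction_pct <- function(k, n, digits = 1) {
  if (any(n <= 0)) stop("denominator must be positive")
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  round(100 * k / n, digits)
}

#' Tabulate specificity calls
#'
#' @param calls data.frame from one of the specificity callers.
#' @return data.frame `call`, `n`, sorted by call.
#' @export
specificity_counts <- function(calls) {
  tab <- table(calls$call)
  data.frame(call = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize the five-class step-2 classification
#'
#' One row per class with its count and percentage of the step-1 selection.
#'
#' @param classes data.frame from [classify_step2()].
#' @param pct_digits decimal places for the percentage column.
#' @return data.frame `class`, `n`, `pct_of_step1`.
#' @export
step2_summary <- function(classes, pct_digits = 0) {
  total <- nrow(classes)
  lvls <- c("similar", "weak_D", "weak_AR", "strong_D", "strong_AR")
  n <- vapply(lvls, function(cl) sum(classes$class == cl), 0L)
  data.frame(class = lvls, n = as.integer(n),
             pct_of_step1 = fraction_pct(n, total, pct_digits),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Directional overlap of temporal genes with a DE side
#'
#' Of the step-1 genes regulated in a given temporal direction that become
#' (weakly or strongly) differentially expressed between the states at
#' 24 HAS, the fraction that end up higher on one side — e.g. how many
#' temporally down-regulated genes end up higher in the dormant state.
#'
#' @param labels temporal labels from [select_temporally_regulated()].
#' @param classes step-2 classes from [classify_step2()].
#' @param direction `"up"` or `"down"`.
#' @param side `"D"` or `"AR"`.
#' @param pct_digits decimal places for the reported percentage.
#' @return list `k` (genes DE toward `side`), `n` (all DE genes of the
#'   direction), `pct`.
#' @export
directional_overlap <- function(labels, classes, direction, side,
                                pct_digits = 1) {
  dir_genes <- unique(labels$gene_id[labels$direction == direction])
  de_cls <- classes[classes$gene_id %in% dir_genes &
                      classes$class != "similar", , drop = FALSE]
  n <- nrow(de_cls)
  k <- sum(endsWith(de_cls$class, paste0("_", side)))
  list(k = k, n = n,
       pct = if (n > 0) fraction_pct(k, n, pct_digits) else NA_real_)
}
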