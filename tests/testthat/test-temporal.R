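# Fixtures here plant trajectories directly as group means (zero replicate
# noise), so the expected labels are forced by arithmetic.

temporal_fixture <- function() {
  gm <- flat_group_means(6, base = 7, overrides = list(
    gene001 = c(AR_MCE_24 = 9.5),                  # up in AR only
    gene002 = c(D_MCE_24 = 9.5, AR_MCE_24 = 9.5),  # up in both
    gene003 = c(D_MCE_24 = 9.5, AR_MCE_24 = 4.5),  # up in D, down in AR
    gene004 = c(D_MCE_24 = 8.3),                   # 2.5-fold: below cut-off
    gene005 = c(D_MCE_24 = 5.0, AR_MCE_24 = 5.0)   # down in both
    # gene006 flat
  ))
  make_design_dataset(gm, n_rep = 3, noise_sd = 0.05, seed = 41)
}

test_that("step-1 labels genes by direction and regulated-state pattern", {
  d <- temporal_fixture()
  labels <- select_temporally_regulated(d$matrix, d$keys, "MCE")
  key <- paste(labels$gene_id, labels$direction, labels$regulated_in)
  expect_setequal(key, c("gene001 up AR_only", "gene002 up both",
                         "gene003 up D_only", "gene003 down AR_only",
                         "gene005 down both"))
  # dual-direction gene carries two labels
  expect_identical(sum(labels$gene_id == "gene003"), 2L)
})

test_that("step-2 bins step-1 genes into the five classes by the 24 HAS
           difference", {
  d <- temporal_fixture()
  labels <- select_temporally_regulated(d$matrix, d$keys, "MCE")
  de24 <- state_contrast(d$matrix, d$keys, "MCE", 24)
  classes <- classify_step2(labels, de24)
  got <- setNames(classes$class, classes$gene_id)
  expect_identical(unname(got["gene001"]), "strong_AR")  # AR up, D flat
  expect_identical(unname(got["gene002"]), "similar")
  expect_identical(unname(got["gene003"]), "strong_D")
  expect_identical(unname(got["gene005"]), "similar")
  # one class per step-1 gene; partition identity
  expect_identical(nrow(classes), length(unique(labels$gene_id)))
  s <- step2_summary(classes)
  expect_identical(sum(s$n), nrow(classes))
})

test_that("step-2 band edges: weak between 2- and 3-fold, demotion without
           significance", {
  labels <- data.frame(gene_id = c("a", "b", "c", "d"),
                       direction = "up", regulated_in = "both")
  de24 <- data.frame(gene_id = c("a", "b", "c", "d"),
                     clipped_lfc = c(0.5, 1.2, 2.0, 2.0),
                     p_value = c(0.5, 0.01, 0.004, 0.20))
  classes <- classify_step2(labels, de24)
  expect_identical(classes$class, c("similar", "weak_D", "strong_D", "weak_D"))
  expect_error(classify_step2(rbind(labels,
                                    data.frame(gene_id = "ghost",
                                               direction = "up",
                                               regulated_in = "both")),
                              de24), "ghost")
})

test_that("step-2 partitions arbitrary inputs into exactly five classes", {
  set.seed(61)
  for (i in 1:10) {
    n <- 50L
    ids <- sprintf("g%03d", seq_len(n))
    labels <- data.frame(gene_id = ids,
                         direction = sample(c("up", "down"), n, TRUE),
                         regulated_in = sample(c("D_only", "AR_only", "both"),
                                               n, TRUE))
    de24 <- data.frame(gene_id = ids,
                       clipped_lfc = runif(n, -4, 4),
                       p_value = runif(n))
    classes <- classify_step2(labels, de24)
    expect_identical(nrow(classes), n)
    expect_true(all(classes$class %in% c("similar", "weak_D", "weak_AR",
                                         "strong_D", "strong_AR")))
    expect_identical(sum(step2_summary(classes)$n), n)
  }
})

test_that("profile decomposition assigns temporal patterns to strongly DE
           genes and covers the dual up/down case", {
  gm <- flat_group_means(4, base = 7, overrides = list(
    gene001 = c(D_MCE_24 = 5.0, AR_MCE_3 = 7, AR_MCE_24 = 3.5), # down both, AR deeper
    gene002 = c(D_MCE_24 = 9.5),                    # up D only -> higher in D
    gene003 = c(D_MCE_3 = 5, D_MCE_7 = 5, D_MCE_12 = 5, D_MCE_24 = 5,
                AR_MCE_3 = 8.4, AR_MCE_7 = 8.4, AR_MCE_12 = 8.4,
                AR_MCE_24 = 8.4),                   # state difference, no ramp
    gene004 = c(D_MCE_24 = 9.5, AR_MCE_24 = 4.4)    # up in D, down in AR
  ))
  d <- make_design_dataset(gm, n_rep = 3, noise_sd = 0.05, seed = 42)
  labels <- select_temporally_regulated(d$matrix, d$keys, "MCE")
  de24 <- state_contrast(d$matrix, d$keys, "MCE", 24)

  dec_d <- decompose_differential_profiles(de24, labels, "higher_in_D")
  pat_d <- setNames(dec_d$temporal_pattern, dec_d$gene_id)
  expect_identical(unname(pat_d["gene002"]), "up_D_only")
  # dual-direction gene appears under both patterns
  expect_setequal(dec_d$temporal_pattern[dec_d$gene_id == "gene004"],
                  c("up_D_only", "down_AR_only"))

  dec_ar <- decompose_differential_profiles(de24, labels, "higher_in_AR")
  pat_ar <- setNames(dec_ar$temporal_pattern, dec_ar$gene_id)
  expect_identical(unname(pat_ar["gene003"]), "not_strongly_regulated")

  # coverage: every strongly DE gene on a side receives >= 1 pattern
  strong_d <- de24$gene_id[de24$clipped_lfc >= log2(3) & de24$p_value < 0.05]
  expect_setequal(unique(dec_d$gene_id), strong_d)
})

test_that("dual-enrichment requires both the state and the compartment fold", {
  gm <- flat_group_means(4, base = 6, overrides = list(
    gene001 = c(D_MCE_24 = 9.0, AR_MCE_24 = 6.0, D_RAD_24 = 6.5),
    gene002 = c(D_MCE_24 = 9.0, AR_MCE_24 = 6.0, D_RAD_24 = 8.0), # comp delta 1
    gene003 = c(D_MCE_24 = 9.0, AR_MCE_24 = 8.5, D_RAD_24 = 6.0)  # state delta .5
  ))
  d <- make_design_dataset(gm, n_rep = 3, noise_sd = 0.05, seed = 43)
  set <- dual_enriched_set(d$matrix, d$keys, "D", "MCE", 24)
  expect_identical(set, "gene001")
  # dropping the significance requirement cannot shrink the set
  set_ns <- dual_enriched_set(d$matrix, d$keys, "D", "MCE", 24,
                              require_significance = FALSE)
  expect_true(all(set %in% set_ns))
})

test_that("mean profiles average gene trajectories with the dry seed first", {
  gm <- flat_group_means(2, base = 4)
  gm["gene001", c("D_SEED_0", "D_MCE_3", "D_MCE_7", "D_MCE_12", "D_MCE_24")] <-
    c(4, 5, 6, 7, 8)
  gm["gene002", c("D_SEED_0", "D_MCE_3", "D_MCE_7", "D_MCE_12", "D_MCE_24")] <-
    c(6, 7, 8, 9, 10)
  means <- make_mean_matrix(gm)
  prof <- mean_profile(c("gene001", "gene002"), means, "D", "MCE")
  expect_identical(names(prof), c("0", "3", "7", "12", "24"))
  expect_equal(unname(prof), c(5, 6, 7, 8, 9))
  # singleton set returns the gene's own profile
  solo <- mean_profile("gene001", means, "D", "MCE")
  expect_equal(unname(solo), c(4, 5, 6, 7, 8))
  expect_error(mean_profile(character(0), means, "D", "MCE"), "empty")
  expect_error(mean_profile("ghost", means, "D", "MCE"), "ghost")
})

test_that("zero-noise synthetic planted classes are recovered exactly", {
  d <- generate_dataset(small_generator_config(seed = 77, noise_sd = 0))
  labels <- select_temporally_regulated(d$matrix, d$keys, "MCE")
  planted <- d$truth[grepl("^temporal_", d$truth$class), ]
  # step-1 selection equals the planted temporal set
  expect_setequal(unique(labels$gene_id), planted$gene_id)
  # direction and pattern match the truth labels
  key <- paste(labels$gene_id, labels$direction, labels$regulated_in)
  truth_key <- paste(planted$gene_id, planted$direction,
                     ifelse(planted$regulated_in == "both", "both",
                            planted$regulated_in))
  expect_setequal(key, truth_key)
  # step-2 zero-noise mapping: both -> similar, regulated state determines side
  de24 <- state_contrast(d$matrix, d$keys, "MCE", 24)
  classes <- classify_step2(labels, de24)
  m <- merge(classes, d$truth[, c("gene_id", "class")], by = "gene_id")
  expected <- c(temporal_up_D_only = "strong_D",
                temporal_up_AR_only = "strong_AR",
                temporal_up_both = "similar",
                temporal_down_D_only = "strong_AR",
                temporal_down_AR_only = "strong_D",
                temporal_down_both = "similar")
  expect_identical(unname(expected[m$class.y]), m$class.x)
})
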