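test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_generator_config(seed = 123)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(d1$keys, d2$keys)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(small_generator_config(seed = 124))
  expect_false(identical(d1$matrix, d3$matrix))
})

test_that("dimensions, design and truth labels follow the configuration", {
  cfg <- small_generator_config(seed = 2)
  d <- generate_dataset(cfg)
  n_genes <- cfg$n_flat + sum(cfg$n_temporal_up) + sum(cfg$n_temporal_down) +
    sum(cfg$n_state_specific) + sum(cfg$n_compartment_specific) +
    cfg$n_noise_floor
  expect_identical(dim(d$matrix), c(n_genes, 18L * cfg$n_replicates))
  expect_identical(nrow(d$truth), n_genes)
  expect_identical(sum(d$truth$class == "temporal_up_AR_only"),
                   as.integer(cfg$n_temporal_up[["AR_only"]]))
  keys <- d$keys
  expect_identical(length(unique(keys$group)), 18L)
  expect_true(all(table(keys$group) == cfg$n_replicates))
  expect_true(all(keys$compartment[keys$time_has == 0] == "SEED"))
})

test_that("zero-noise planting forces exact pre-noise contrasts", {
  cfg <- generator_config(n_flat = 0L,
                          n_temporal_up = c(D_only = 0L, AR_only = 20L,
                                            both = 0L),
                          n_temporal_down = c(D_only = 0L, AR_only = 0L,
                                              both = 0L),
                          n_state_specific = c(D = 5L, AR = 0L),
                          n_compartment_specific = c(MCE = 0L, RAD = 0L),
                          n_noise_floor = 5L,
                          noise_sd = 0, seed = 31)
  d <- generate_dataset(cfg)
  expect_identical(sum(d$truth$class == "temporal_up_AR_only"), 20L)
  means <- compute_sample_means(d$matrix, d$keys)
  up <- d$truth$gene_id[d$truth$class == "temporal_up_AR_only"]
  # AR 24 HAS mean - AR 3 HAS mean = delta exactly; D side flat
  expect_equal(means$values[up, "AR_MCE_24"] - means$values[up, "AR_MCE_3"],
               setNames(rep(cfg$delta, 20), up))
  expect_equal(means$values[up, "D_MCE_24"], means$values[up, "D_MCE_3"])
  # state-specific genes: > 6 in D everywhere, < 5 in AR everywhere
  sp <- d$truth$gene_id[d$truth$class == "state_specific_D"]
  d_groups <- grep("^D_", colnames(means$values), value = TRUE)
  ar_groups <- grep("^AR_", colnames(means$values), value = TRUE)
  expect_true(all(means$values[sp, d_groups] > 6))
  expect_true(all(means$values[sp, ar_groups] < 5))
  # noise-floor genes stay below 5 everywhere
  nf <- d$truth$gene_id[d$truth$class == "noise_floor"]
  expect_true(all(means$values[nf, ] < 5))
})

test_that("fourfold planting at zero noise is recovered exactly by the DE
           caller at threefold", {
  d <- generate_dataset(small_generator_config(seed = 8, noise_sd = 0))
  for (comp in c("MCE", "RAD")) {
    labels <- select_temporally_regulated(d$matrix, d$keys, comp)
    planted <- d$truth$gene_id[grepl("^temporal_", d$truth$class)]
    expect_setequal(unique(labels$gene_id), planted)
  }
})

test_that("parameter recovery: sensitivity >= 0.95 and flat false positives
           <= 0.01 under replicate noise", {
  d <- generate_dataset(generator_config(seed = 17))  # delta 2, noise 0.15
  labels <- select_temporally_regulated(d$matrix, d$keys, "MCE")
  sel <- unique(labels$gene_id)
  planted <- d$truth$gene_id[grepl("^temporal_", d$truth$class)]
  flat <- d$truth$gene_id[d$truth$class == "flat"]
  expect_gte(mean(planted %in% sel), 0.95)
  expect_lte(mean(flat %in% sel), 0.01)
})

test_that("null simulation: flat-gene type-I error is 0.05 +/- 0.02", {
  cfg <- generator_config(n_flat = 2500L,
                          n_temporal_up = c(D_only = 0L, AR_only = 0L,
                                            both = 0L),
                          n_temporal_down = c(D_only = 0L, AR_only = 0L,
                                              both = 0L),
                          n_state_specific = c(D = 0L, AR = 0L),
                          n_compartment_specific = c(MCE = 0L, RAD = 0L),
                          n_noise_floor = 0L,
                          delta = 0, seed = 19)
  d <- generate_dataset(cfg)
  rec <- de_call(d$matrix, d$keys, "D_MCE_3", "D_MCE_24")
  frac <- mean(rec$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("state-specificity recovery >= 0.95 at noise 0.1", {
  d <- generate_dataset(small_generator_config(seed = 23, noise_sd = 0.1))
  means <- compute_sample_means(d$matrix, d$keys)
  calls <- call_state_specific(means)
  for (s in c("D", "AR")) {
    planted <- d$truth$gene_id[d$truth$class == paste0("state_specific_", s)]
    got <- calls$gene_id[calls$call == paste0("specific_", s)]
    expect_gte(mean(planted %in% got), 0.95)
  }
})

test_that("generator rejects invalid configurations", {
  expect_error(generator_config(n_flat = -1), ">= 0")
  expect_error(generator_config(noise_sd = -0.1), "noise_sd")
  expect_error(generator_config(n_flat = 0, n_noise_floor = 0,
                                n_temporal_up = 0, n_temporal_down = 0,
                                n_state_specific = 0,
                                n_compartment_specific = 0),
               "at least one gene")
  expect_warning(generator_config(n_replicates = 1), "t-test")
})

test_that("the synthetic catalog is deterministic, respects containment and
           independence", {
  d <- generate_dataset(small_generator_config(seed = 3))
  c1 <- generate_annotation_catalog(d$truth, n_terms = 10,
                                    enrichment_fraction = 1, seed = 4,
                                    enriched_class = "temporal_up",
                                    term_size = 30)
  c2 <- generate_annotation_catalog(d$truth, n_terms = 10,
                                    enrichment_fraction = 1, seed = 4,
                                    enriched_class = "temporal_up",
                                    term_size = 30)
  expect_identical(c1$terms, c2$terms)
  up_class <- d$truth$gene_id[startsWith(d$truth$class, "temporal_up")]
  expect_true(all(c1$terms$enriched %in% up_class))
  expect_error(generate_annotation_catalog(d$truth, enrichment_fraction = 0.5,
                                           seed = 1,
                                           enriched_class = "no_such_class"),
               "empty")

  # fraction 0: term membership independent of the planted class (large
  # truth table so the contingency test is well powered and well behaved)
  big_truth <- data.frame(gene_id = sprintf("g%05d", 1:2000),
                          class = rep(c("temporal_up_both", "flat"),
                                      each = 1000))
  c0 <- generate_annotation_catalog(big_truth, n_terms = 20,
                                    enrichment_fraction = 0, seed = 6,
                                    term_size = 50)
  in_term <- big_truth$gene_id %in% unique(unlist(c0$terms))
  in_class <- startsWith(big_truth$class, "temporal_up")
  expect_gt(chisq.test(table(in_term, in_class))$p.value, 0.001)
})
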