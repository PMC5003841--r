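# End-to-end orchestration: a single config drives means, expressed and
# specificity calls, the contrast suites, the two-step temporal
# classification, profile decomposition, dual-enrichment sets, ORA,
# ordination and mean profiles, with every table written as TSV and a
# machine-readable manifest of all counts.

#' Build a pipeline configuration
#'
#' Every analysis threshold is a named key with the method's default:
#' detection threshold 5, specificity thresholds 6/5, fold-change clip 4,
#' t-test alpha 0.05, fold cut-offs 2/3/5/10, step-1 fold 3, step-2 bands
#' 2 and 3 (all log2-scale fold conventions).
#'
#' @param matrix path to the expression TSV.
#' @param sample_sheet path to the sample sheet.
#' @param out_dir output directory, created if needed.
#' @param catalog optional GMT catalog path; enables the ORA stage.
#' @param reference_matrix,reference_sample_sheet optional reference dataset
#'   used to refine compartment-specific sets.
#' @param reference_groups reference group ids screened in the refinement.
#' @param expressed_threshold,hi,lo,clip,alpha,cutoffs,step1_fold,step2_bands
#'   analysis thresholds (see the callers' documentation).
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @param step1_significance require the t-test in step-1 selection.
#' @param dual_significance require the t-test in the dual-enrichment rule.
#' @param compartments compartments to run the temporal classification on.
#' @param n_components PCA components.
#' @param seed seed for any stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, sample_sheet, out_dir,
                            catalog = NULL,
                            reference_matrix = NULL,
                            reference_sample_sheet = NULL,
                            reference_groups = NULL,
                            expressed_threshold = 5, hi = 6, lo = 5,
                            clip = 4, alpha = 0.05,
                            cutoffs = c(2, 3, 5, 10),
                            step1_fold = 3, step2_bands = c(2, 3),
                            var_equal = TRUE,
                            step1_significance = TRUE,
                            dual_significance = TRUE,
                            compartments = c("MCE", "RAD"),
                            n_components = 2L, seed = 1L) {
  cfg <- list(matrix = matrix, sample_sheet = sample_sheet, out_dir = out_dir,
              catalog = catalog, reference_matrix = reference_matrix,
              reference_sample_sheet = reference_sample_sheet,
              reference_groups = reference_groups,
              expressed_threshold = expressed_threshold, hi = hi, lo = lo,
              clip = clip, alpha = alpha, cutoffs = sort(cutoffs),
              step1_fold = step1_fold, step2_bands = step2_bands,
              var_equal = isTRUE(var_equal),
              step1_significance = isTRUE(step1_significance),
              dual_significance = isTRUE(dual_significance),
              compartments = compartments,
              n_components = as.integer(n_components),
              seed = as.integer(seed))
  if (any(c(cfg$expressed_threshold, cfg$hi, cfg$lo, cfg$clip,
            cfg$step1_fold, cfg$cutoffs, cfg$step2_bands) <= 0)) {
    stop("thresholds must be positive")
  }
  if (cfg$lo > cfg$hi) stop("lo threshold must not exceed hi")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.unsorted(cfg$step2_bands, strictly = TRUE)) {
    stop("step2_bands must be strictly increasing")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) stop("unknown config key: ", unknown[1L])
  required <- c("matrix", "sample_sheet", "out_dir")
  missing_k <- setdiff(required, names(raw))
  if (length(missing_k) > 0L) stop("config is missing key: ", missing_k[1L])
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full classification pipeline
#'
#' Executes every stage in order and writes all result tables under
#' `config$out_dir`: group means, expressed counts, the three specificity
#' tables, temporal and state contrast suites with a count summary, step-1
#' labels, step-2 classes with summary, profile decompositions, the
#' dual-enrichment sets as GMT, ORA tables per classified set (when a
#' catalog is given), PCA coordinates and explained variance, mean profiles
#' of the step-2 classes, and `manifest.json` echoing the configuration with
#' all counts. Outputs are deterministic: the same config yields identical
#' files.
#'
#' @param config a `pipeline_config` or a path to a YAML config.
#' @return Invisibly, the manifest list.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # validate inputs up front so a broken config fails before any computation
  for (p in c(config$matrix, config$sample_sheet, config$catalog,
              config$reference_matrix, config$reference_sample_sheet)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), counts = list(), outputs = list())
  emit <- function(df, name) {
    path <- file.path(out, name)
    write_result_table(df, path)
    manifest$outputs[[name]] <<- path
    path
  }

  mat <- run_stage("read_matrix", read_expression_matrix(config$matrix))
  keys <- run_stage("read_sample_sheet", read_sample_sheet(config$sample_sheet, mat))
  means <- run_stage("means", compute_sample_means(mat, keys))
  emit(data.frame(gene_id = rownames(means$values), means$values,
                  check.names = FALSE), "means.tsv")

  # expressed and specificity calls
  expressed <- run_stage("expressed",
                         call_expressed(means, config$expressed_threshold))
  ec <- expressed_counts(means, config$expressed_threshold)
  emit(data.frame(group = c(names(ec$per_group), "union", "intersection"),
                  n_expressed = c(as.integer(ec$per_group), ec$union,
                                  ec$intersection)),
       "expressed_counts.tsv")
  manifest$counts$expressed_union <- ec$union
  manifest$counts$expressed_intersection <- ec$intersection

  spec_state <- run_stage("state_specific",
                          call_state_specific(means, config$hi, config$lo))
  spec_comp <- run_stage("compartment_specific",
                         call_compartment_specific(means, config$hi, config$lo))
  spec_both <- run_stage("state_compartment_specific",
                         call_state_compartment_specific(means, config$hi,
                                                         config$lo))
  emit(spec_state, "specificity_state.tsv")
  emit(spec_comp, "specificity_compartment.tsv")
  emit(spec_both, "specificity_state_compartment.tsv")
  manifest$counts$specificity_state <- specificity_counts(spec_state)
  manifest$counts$specificity_compartment <- specificity_counts(spec_comp)
  manifest$counts$specificity_state_compartment <- specificity_counts(spec_both)

  if (!is.null(config$reference_matrix)) {
    ref_mat <- run_stage("reference_matrix",
                         read_expression_matrix(config$reference_matrix))
    ref_keys <- run_stage("reference_sample_sheet",
                          read_sample_sheet(config$reference_sample_sheet,
                                            ref_mat))
    ref_means <- compute_sample_means(ref_mat, ref_keys)
    ref_groups <- config$reference_groups
    if (is.null(ref_groups)) ref_groups <- ref_means$groups$group
    for (comp in c("MCE", "RAD")) {
      set <- spec_comp$gene_id[spec_comp$call == paste0("specific_", comp)]
      refined <- run_stage("refine",
                           refine_against_reference(set, ref_means,
                                                    ref_groups, config$lo))
      emit(data.frame(gene_id = refined), paste0("refined_specific_", comp,
                                                 ".tsv"))
      manifest$counts[[paste0("refined_specific_", comp)]] <- length(refined)
    }
  }

  # contrast suites and state contrasts
  all_counts <- list()
  for (s in STATES) {
    for (comp in c("MCE", "RAD")) {
      suite <- run_stage("contrast_suite",
                         contrast_suite(mat, keys, s, comp,
                                        alpha = config$alpha,
                                        clip = config$clip,
                                        cutoffs = config$cutoffs,
                                        var_equal = config$var_equal))
      for (lbl in names(suite$records)) {
        emit(suite$records[[lbl]],
             sprintf("contrast_%s_%s_%s.tsv", s, comp, lbl))
      }
      all_counts[[paste(s, comp)]] <- suite$counts
    }
  }
  state_de <- list()
  for (comp in c("MCE", "RAD")) {
    for (t_has in c(3L, 7L, 12L, 24L)) {
      rec <- run_stage("state_contrast",
                       state_contrast(mat, keys, comp, t_has,
                                      alpha = config$alpha,
                                      clip = config$clip,
                                      cutoffs = config$cutoffs,
                                      var_equal = config$var_equal))
      emit(rec, sprintf("contrast_D_vs_AR_%s_%d.tsv", comp, t_has))
      state_de[[paste0(comp, "_", t_has)]] <- rec
      all_counts[[paste("DvsAR", comp, t_has)]] <-
        cbind(contrast = sprintf("D_vs_AR_%d", t_has), state = "D_vs_AR",
              compartment = comp, de_counts(rec))
    }
  }
  counts_summary <- do.call(rbind, all_counts)
  rownames(counts_summary) <- NULL
  emit(counts_summary, "contrast_counts.tsv")
  manifest$counts$contrasts <- counts_summary

  # two-step temporal classification + decomposition per compartment
  classified_sets <- list()
  for (comp in config$compartments) {
    labels <- run_stage("step1",
                        select_temporally_regulated(
                          mat, keys, comp, fold = config$step1_fold,
                          alpha = config$alpha, clip = config$clip,
                          var_equal = config$var_equal,
                          require_significance = config$step1_significance))
    emit(labels, paste0("step1_labels_", comp, ".tsv"))
    de24 <- state_de[[paste0(comp, "_24")]]
    classes <- run_stage("step2",
                         classify_step2(labels, de24,
                                        bands = config$step2_bands,
                                        alpha = config$alpha))
    emit(classes, paste0("step2_classes_", comp, ".tsv"))
    manifest$counts[[paste0("step1_", comp)]] <- list(
      n_selected = length(unique(labels$gene_id)),
      n_up = length(unique(labels$gene_id[labels$direction == "up"])),
      n_down = length(unique(labels$gene_id[labels$direction == "down"]))
    )
    manifest$counts[[paste0("step2_", comp)]] <- step2_summary(classes)
    for (side in c("higher_in_D", "higher_in_AR")) {
      dec <- run_stage("decomposition",
                       decompose_differential_profiles(
                         de24, labels, side, fold = config$step1_fold,
                         alpha = config$alpha))
      emit(dec, sprintf("profile_groups_%s_%s.tsv", comp, side))
      manifest$counts[[sprintf("decomposition_%s_%s", comp, side)]] <-
        nrow(dec)
    }
    for (cls in c("similar", "weak_D", "weak_AR", "strong_D", "strong_AR")) {
      g <- classes$gene_id[classes$class == cls]
      if (length(g) > 0L) {
        classified_sets[[paste0(comp, "_", cls)]] <- g
      }
    }
  }

  # dual state-and-compartment enrichment sets at 24 HAS
  dual_sets <- list()
  for (s in STATES) {
    for (comp in c("MCE", "RAD")) {
      nm <- paste0("dual_", s, "_", comp, "_24")
      dual_sets[[nm]] <- run_stage("dual_enrichment",
                                   dual_enriched_set(
                                     mat, keys, s, comp, 24L,
                                     state_fold = config$step1_fold,
                                     compartment_fold = config$step1_fold,
                                     alpha = config$alpha, clip = config$clip,
                                     var_equal = config$var_equal,
                                     require_significance = config$dual_significance))
      manifest$counts[[nm]] <- length(dual_sets[[nm]])
    }
  }
  gmt_path <- file.path(out, "dual_enriched_sets.gmt")
  write_gene_sets_gmt(dual_sets, gmt_path)
  manifest$outputs[["dual_enriched_sets.gmt"]] <- gmt_path

  # overrepresentation analysis of each classified set, universe = expressed
  if (!is.null(config$catalog)) {
    catalog <- run_stage("read_catalog", read_annotation_gmt(config$catalog))
    for (nm in names(classified_sets)) {
      q <- intersect(classified_sets[[nm]], expressed)
      if (length(q) == 0L) next
      ora <- run_stage("ora", run_ora(q, expressed, catalog))
      emit(ora, paste0("ora_", nm, ".tsv"))
    }
  }

  # ordination of replicate arrays
  ord <- run_stage("ordination", pca_project(mat, config$n_components))
  coord <- data.frame(array = rownames(ord$coordinates),
                      keys[match(rownames(ord$coordinates), keys$array),
                           c("state", "compartment", "time_has", "replicate")],
                      ord$coordinates, check.names = FALSE)
  emit(coord, "pca_coordinates.tsv")
  emit(data.frame(component = seq_along(ord$explained_variance),
                  explained_variance = ord$explained_variance),
       "pca_explained_variance.tsv")

  # mean profiles of the classified sets, both states
  prof_rows <- list()
  for (nm in names(classified_sets)) {
    comp <- sub("_.*$", "", nm)
    for (s in STATES) {
      prof <- mean_profile(classified_sets[[nm]], means, s, comp)
      prof_rows[[paste(nm, s)]] <- data.frame(set = nm, state = s,
                                              t(prof), check.names = FALSE)
    }
  }
  if (length(prof_rows) > 0L) {
    profiles <- do.call(rbind, prof_rows)
    rownames(profiles) <- NULL
    emit(profiles, "mean_profiles.tsv")
  }

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest$outputs[["manifest.json"]] <- manifest_path
  invisible(manifest)
}
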