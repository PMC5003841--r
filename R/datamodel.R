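# Core data types and readers/writers for the formats the pipeline touches:
# expression TSV (genes x arrays, log2 scale), sample sheet, GMT catalogs,
# tab-delimited result tables.

#' Allowed physiological states
#' @keywords internal
STATES <- c("D", "AR")

#' Allowed seed compartments
#'
#' `SEED` is the undissected dry whole seed; dissected compartments (`MCE`,
#' `RAD`) exist only for imbibed time points.
#' @keywords internal
COMPARTMENTS <- c("SEED", "MCE", "RAD")

#' Sampling times, hours after sowing
#' @keywords internal
TIMES_HAS <- c(0L, 3L, 7L, 12L, 24L)

#' Canonical group identifier for a (state, compartment, time) triple
#'
#' @param state `"D"` or `"AR"`.
#' @param compartment `"SEED"`, `"MCE"` or `"RAD"`.
#' @param time_has hours after sowing.
#' @return Character vector like `"D_MCE_24"`.
#' @export
group_id <- function(state, compartment, time_has) {
  paste(state, compartment, time_has, sep = "_")
}

# The 18 groups of the full design, in canonical order: D first, dry seed,
# then MCE and RAD over the imbibition time course.
design_groups <- function() {
  out <- list()
  for (s in STATES) {
    out[[length(out) + 1L]] <- data.frame(
      state = s, compartment = "SEED", time_has = 0L,
      stringsAsFactors = FALSE
    )
    for (comp in c("MCE", "RAD")) {
      out[[length(out) + 1L]] <- data.frame(
        state = s, compartment = comp, time_has = c(3L, 7L, 12L, 24L),
        stringsAsFactors = FALSE
      )
    }
  }
  g <- do.call(rbind, out)
  g$group <- group_id(g$state, g$compartment, g$time_has)
  g[, c("group", "state", "compartment", "time_has")]
}

#' Read a log2 expression matrix from tab-delimited text
#'
#' First column holds gene identifiers, header row holds array names, body is
#' numeric log2 expression. Values are taken as already log2-scale and never
#' transformed.
#'
#' @param path path to a TSV file.
#' @return Numeric matrix, genes in rows (rownames = gene ids), arrays in
#'   columns (colnames = array names), in file order.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression matrix is empty or has no array columns: ", path)
  }
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop("duplicate gene id in expression matrix: ", dup[1L])
  }
  arrays <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric or missing expression value at gene '%s', array '%s' ('%s')",
      gene_ids[bad[1L, 1L]], arrays[bad[1L, 2L]], vals[bad[1L, , drop = FALSE]][1L]
    ))
  }
  dimnames(num) <- list(gene_ids, arrays)
  num
}

#' Write an expression matrix as tab-delimited text
#'
#' @param matrix numeric matrix with gene rownames and array colnames.
#' @param path output path.
#' @param id_column header for the gene-id column.
#' @export
write_expression_matrix <- function(matrix, path, id_column = "gene_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write_result_table(df, path)
}

validate_sample_keys <- function(keys, arrays) {
  required <- c("array", "state", "compartment", "time_has", "replicate")
  missing_cols <- setdiff(required, colnames(keys))
  if (length(missing_cols) > 0L) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  keys$time_has <- as.integer(keys$time_has)
  keys$replicate <- as.integer(keys$replicate)
  bad_state <- setdiff(unique(keys$state), STATES)
  if (length(bad_state) > 0L) {
    stop("unknown state '", bad_state[1L], "' in sample sheet (allowed: ",
         paste(STATES, collapse = ", "), ")")
  }
  bad_comp <- setdiff(unique(keys$compartment), COMPARTMENTS)
  if (length(bad_comp) > 0L) {
    stop("unknown compartment '", bad_comp[1L], "' in sample sheet (allowed: ",
         paste(COMPARTMENTS, collapse = ", "), ")")
  }
  bad_time <- setdiff(unique(keys$time_has), TIMES_HAS)
  if (length(bad_time) > 0L) {
    stop("unknown time point ", bad_time[1L], " HAS in sample sheet (allowed: ",
         paste(TIMES_HAS, collapse = ", "), ")")
  }
  if (any(keys$replicate < 1L)) stop("replicate indices must be positive")
  # dry whole seed <=> 0 HAS, in both directions
  seed_bad <- keys$compartment == "SEED" & keys$time_has != 0L
  if (any(seed_bad)) {
    stop("dry whole-seed (SEED) arrays must have time 0 HAS: ",
         keys$array[seed_bad][1L])
  }
  t0_bad <- keys$time_has == 0L & keys$compartment != "SEED"
  if (any(t0_bad)) {
    stop("0 HAS arrays must be dry whole seed (SEED): ", keys$array[t0_bad][1L])
  }
  dup <- keys$array[duplicated(keys$array)]
  if (length(dup) > 0L) stop("duplicate array in sample sheet: ", dup[1L])
  if (!is.null(arrays)) {
    extra <- setdiff(keys$array, arrays)
    if (length(extra) > 0L) {
      stop("array in sample sheet absent from expression matrix: ", extra[1L])
    }
    absent <- setdiff(arrays, keys$array)
    if (length(absent) > 0L) {
      stop("matrix array missing from sample sheet: ", absent[1L])
    }
    keys <- keys[match(arrays, keys$array), , drop = FALSE]
    rownames(keys) <- NULL
  }
  keys$group <- group_id(keys$state, keys$compartment, keys$time_has)
  keys
}

#' Read a sample sheet and assign a sample key to every array
#'
#' The sheet (TSV or CSV, autodetected) must carry columns `array`, `state`
#' (`D`/`AR`), `compartment` (`SEED`/`MCE`/`RAD`), `time_has` (0, 3, 7, 12, 24)
#' and `replicate`. Dry whole-seed (`SEED`) rows must be at 0 HAS and vice
#' versa. Row order is rearranged to match the matrix column order.
#'
#' @param path path to the sample sheet.
#' @param matrix optional expression matrix; when given, the sheet and matrix
#'   must cover exactly the same arrays.
#' @return `data.frame` with columns `array`, `state`, `compartment`,
#'   `time_has`, `replicate`, `group`, one row per array.
#' @export
read_sample_sheet <- function(path, matrix = NULL) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  keys <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "")
  if (nrow(keys) == 0L) stop("sample sheet is empty: ", path)
  validate_sample_keys(keys, if (is.null(matrix)) NULL else colnames(matrix))
}

#' Collapse replicate arrays to per-group means
#'
#' One column per (state, compartment, time) group, the arithmetic mean of its
#' replicate columns on the log2 scale. Groups follow the canonical design
#' order (D before AR; dry seed, then MCE, then RAD over time).
#'
#' @param matrix expression matrix (genes x arrays).
#' @param keys sample keys as returned by [read_sample_sheet()].
#' @return A `mean_matrix`: list with `values` (genes x groups matrix) and
#'   `groups` (data.frame `group`, `state`, `compartment`, `time_has`).
#' @export
compute_sample_means <- function(matrix, keys) {
  keys <- validate_sample_keys(keys, colnames(matrix))
  canon <- design_groups()
  present <- canon[canon$group %in% unique(keys$group), , drop = FALSE]
  extra <- setdiff(unique(keys$group), canon$group)
  if (length(extra) > 0L) stop("unknown group: ", extra[1L])
  vals <- vapply(present$group, function(g) {
    cols <- keys$array[keys$group == g]
    if (length(cols) == 0L) stop("group without replicate arrays: ", g)
    rowMeans(matrix[, cols, drop = FALSE])
  }, numeric(nrow(matrix)))
  vals <- matrix(vals, nrow = nrow(matrix),
                 dimnames = list(rownames(matrix), present$group))
  structure(list(values = vals, groups = present), class = "mean_matrix")
}

#' @export
print.mean_matrix <- function(x, ...) {
  cat("mean_matrix:", nrow(x$values), "genes x", ncol(x$values), "groups\n")
  cat("groups:", paste(x$groups$group, collapse = " "), "\n")
  invisible(x)
}

# Groups of a mean matrix for one state / compartment, optionally excluding
# the undissected dry seed.
groups_for <- function(means, state = NULL, compartment = NULL,
                       dissected_only = FALSE) {
  g <- means$groups
  if (!is.null(state)) g <- g[g$state == state, , drop = FALSE]
  if (!is.null(compartment)) g <- g[g$compartment == compartment, , drop = FALSE]
  if (dissected_only) g <- g[g$compartment != "SEED", , drop = FALSE]
  g$group
}

#' Read a GMT gene-set catalog
#'
#' Standard GMT: one term per line, tab-separated fields `name`, `description`,
#' then member gene ids. Member lists are deduplicated.
#'
#' @param path path to the GMT file.
#' @return An `annotation_catalog`: list with `terms` (named list of character
#'   vectors) and `descriptions` (named character vector).
#' @export
read_annotation_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # a 2-field line is an empty set (name + description); fewer is malformed
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  }
  nms <- vapply(fields, `[[`, "", 1L)
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) stop("duplicate term name in GMT: ", dup[1L])
  terms <- lapply(fields, function(f) {
    m <- unique(f[-c(1L, 2L)])
    m[nzchar(m)]
  })
  names(terms) <- nms
  descriptions <- vapply(fields, `[[`, "", 2L)
  names(descriptions) <- nms
  structure(list(terms = terms, descriptions = descriptions),
            class = "annotation_catalog")
}

#' Write gene sets to a GMT file
#'
#' Round-trips losslessly through [read_annotation_gmt()]. Empty sets are
#' written as name + description only.
#'
#' @param sets named list of character vectors, or an `annotation_catalog`.
#' @param path output path.
#' @param descriptions optional named character vector of term descriptions;
#'   defaults to the catalog's own, or `"na"`.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "annotation_catalog")) {
    if (is.null(descriptions)) descriptions <- sets$descriptions
    sets <- sets$terms
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup) > 0L) stop("duplicate gene-set name: ", dup[1L])
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  all_fields <- c(names(sets), unlist(sets, use.names = FALSE),
                  unname(descriptions))
  if (any(grepl("[\t\n]", all_fields))) {
    stop("gene-set names, descriptions and members must not contain tabs or newlines")
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], unique(sets[[nm]])), collapse = "\t")
  }, "")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a result table as tab-delimited text with a header
#'
#' @param df data.frame; the gene-id column is conventionally first.
#' @param path output path.
#' @export
write_result_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited result table
#'
#' @param path path to a TSV written by [write_result_table()].
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}
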