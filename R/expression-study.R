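#' Construct a paired two-group expression study
#'
#' Bundles a nonnegative expression matrix (genes in rows, samples in
#' columns) with its sample metadata and validates the paired design:
#' every patient must contribute exactly one `normal` and one `tumor`
#' sample.
#'
#' @param values Numeric matrix of nonnegative expression values with
#'   unique gene identifiers as row names and unique sample identifiers
#'   as column names.  Values are taken as already normalized (e.g.
#'   RSEM-style normalized counts); no library-size correction is applied.
#' @param samples Data frame with columns `sample_id`, `patient_id` and
#'   `group` (values `"normal"` or `"tumor"`), one row per sample.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` (the matrix, columns reordered to match `samples`) and
#'   `samples` (a tibble).
#'
#' @examples
#' vals <- matrix(rpois(12, 50), nrow = 3,
#'                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    patient_id = rep(c("p1", "p2"), each = 2),
#'                    group = rep(c("normal", "tumor"), 2))
#' study <- expression_study(vals, meta)
#' n_pairs(study)
#' @export
expression_study <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "patient_id", "group")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("`samples` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$patient_id <- as.character(samples$patient_id)
  samples$group <- as.character(samples$group)

  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must have gene row names and sample column names.")
  }
  dup_genes <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_genes) > 0) {
    abort(paste0("Duplicate gene identifier(s): ",
                 paste(head(dup_genes, 5), collapse = ", ")))
  }
  dup_samples <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_samples) > 0) {
    abort(paste0("Duplicate sample identifier(s): ",
                 paste(head(dup_samples, 5), collapse = ", ")))
  }
  if (anyNA(values)) abort("Expression values must not contain NA.")
  if (any(values < 0)) abort("Expression values must be nonnegative.")

  if (anyDuplicated(samples$sample_id)) {
    abort("Duplicate sample_id in metadata.")
  }
  missing_meta <- setdiff(sample_ids, samples$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("Sample(s) in matrix missing from metadata: ",
                 paste(head(missing_meta, 5), collapse = ", ")))
  }
  extra_meta <- setdiff(samples$sample_id, sample_ids)
  if (length(extra_meta) > 0) {
    abort(paste0("Sample(s) in metadata missing from matrix: ",
                 paste(head(extra_meta, 5), collapse = ", ")))
  }
  bad_group <- setdiff(unique(samples$group), c("normal", "tumor"))
  if (length(bad_group) > 0) {
    abort(paste0("`group` must be 'normal' or 'tumor'; found: ",
                 paste(bad_group, collapse = ", ")))
  }

  ## paired design: each patient exactly once per group
  tab <- table(samples$patient_id, samples$group)
  full <- matrix(0L, nrow(tab), 2,
                 dimnames = list(rownames(tab), c("normal", "tumor")))
  full[, colnames(tab)] <- tab
  bad <- rownames(full)[full[, "normal"] != 1L | full[, "tumor"] != 1L]
  if (length(bad) > 0) {
    abort(paste0("Unpaired patient(s) (need exactly one normal and one ",
                 "tumor sample each): ", paste(head(bad, 5), collapse = ", ")))
  }

  values <- values[, samples$sample_id, drop = FALSE]
  structure(list(values = values, samples = samples),
            class = "expression_study")
}

#' Read an expression study from TSV files
#'
#' @param matrix_path Path to a tab-separated expression table: header row
#'   of sample identifiers, first column gene identifiers, nonnegative
#'   values elsewhere.
#' @param metadata_path Path to a tab-separated metadata table with
#'   columns `sample_id`, `patient_id`, `group`.
#'
#' @return A validated [expression_study()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                            progress = FALSE)
  if (ncol(mat_df) < 2) abort("Expression matrix needs >= 1 sample column.")
  gene_ids <- as.character(mat_df[[1]])
  dup_genes <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_genes) > 0) {
    abort(paste0("Duplicate gene identifier(s) in ", matrix_path, ": ",
                 paste(head(dup_genes, 5), collapse = ", ")))
  }
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  expression_study(values, meta)
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression()].
#'
#' @param study An `expression_study`.
#' @param matrix_path,metadata_path Output file paths.
#' @return `study`, invisibly.
#' @export
write_expression <- function(study, matrix_path, metadata_path) {
  stopifnot(inherits(study, "expression_study"))
  out <- bind_cols(tibble(gene = rownames(study$values)),
                   as_tibble(study$values))
  readr::write_tsv(out, matrix_path, progress = FALSE)
  readr::write_tsv(study$samples, metadata_path, progress = FALSE)
  invisible(study)
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study>\n")
  cat("  genes:  ", nrow(x$values), "\n", sep = "")
  cat("  samples:", ncol(x$values),
      sprintf(" (%d pairs)", n_pairs(x)), "\n", sep = "")
  invisible(x)
}

#' Number of patient pairs in a study
#' @param study An `expression_study`.
#' @return Integer count of patients (= samples per group).
#' @export
n_pairs <- function(study) {
  length(unique(study$samples$patient_id))
}

#' Gene identifiers of a study
#' @param study An `expression_study`.
#' @return Character vector of gene ids, in matrix row order.
#' @export
gene_ids <- function(study) rownames(study$values)

#' Extract the expression submatrix of one group
#'
#' Columns are ordered by `patient_id` so that the normal and tumor
#' submatrices of the same study are column-aligned by patient.
#'
#' @param study An `expression_study`.
#' @param group `"normal"` or `"tumor"`.
#' @param genes Optional character vector restricting the rows.
#' @return Numeric matrix (genes x patients) with patient ids as column
#'   names.
#' @export
group_matrix <- function(study, group = c("normal", "tumor"), genes = NULL) {
  group <- match.arg(group)
  meta <- study$samples[study$samples$group == group, ]
  meta <- meta[order(meta$patient_id), ]
  m <- study$values[, meta$sample_id, drop = FALSE]
  colnames(m) <- meta$patient_id
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("Gene(s) not in study: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  m
}

#' Subset a study to a set of genes
#' @param study An `expression_study`.
#' @param genes Character vector of gene ids to keep (order preserved as
#'   in the study).
#' @return An `expression_study` with the reduced gene set.
#' @export
subset_genes <- function(study, genes) {
  keep <- rownames(study$values) %in% genes
  if (!any(keep)) abort("No genes left after subsetting.")
  expression_study(study$values[keep, , drop = FALSE], study$samples)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an expression study into long format
#'
#' @param x An `expression_study`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample_id`, `patient_id`,
#'   `group`, `expression`.
#' @export
tidy.expression_study <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id",
                        values_to = "expression")
  left_join(long, x$samples, by = "sample_id") |>
    select("gene", "sample_id", "patient_id", "group", "expression")
}
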