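# Readers and writers for every file format the pipeline touches. All other
# modules operate only on the validated in-memory types constructed here.

## ---- ExpressionMatrix -------------------------------------------------------

#' Construct a validated expression matrix
#'
#' The pipeline's central bulk container: a non-negative, linear-scale
#' numeric matrix with genes as rows and samples as columns, optionally
#' carrying a per-sample condition label (e.g. control / endometriosis).
#'
#' @param values numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids).
#' @param group_labels optional character vector of per-sample condition
#'   labels, length `ncol(values)`.
#' @return an object of class `ExpressionMatrix` (a numeric matrix with a
#'   `group_labels` attribute).
#' @export
expression_matrix <- function(values, group_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_val("values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    abort_val("values must have gene rownames and sample colnames")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    abort_val("duplicate gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    abort_val("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(values)))
    abort_val("expression values must all be finite")
  if (any(values < 0))
    abort_val("expression values must be >= 0")
  if (!is.null(group_labels)) {
    if (length(group_labels) != ncol(values))
      abort_val("group_labels length must equal the number of samples")
    group_labels <- as.character(group_labels)
    names(group_labels) <- sid
  }
  structure(values, group_labels = group_labels, class = c("ExpressionMatrix", "matrix"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  gl <- attr(x, "group_labels")
  if (!is.null(gl)) {
    tb <- table(gl)
    cat("groups:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-sample group labels of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return named character vector or `NULL`.
#' @export
group_labels <- function(x) attr(x, "group_labels")

#' Read a genes-x-samples expression TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Row and column order are preserved.
#'
#' @param path file path.
#' @param group_labels optional per-sample labels to attach.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, group_labels = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) abort_val("expression TSV needs a gene-id column plus >= 1 sample: ", path)
  gid <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    abort_val(sprintf("non-numeric value at data row %d, column '%s' in %s",
                      bad[1, 1], colnames(vals)[bad[1, 2]], path))
  neg <- which(num < 0, arr.ind = TRUE)
  if (length(neg) && nrow(neg))
    abort_val(sprintf("negative value at data row %d, column '%s' in %s",
                      neg[1, 1], colnames(vals)[neg[1, 2]], path))
  dimnames(num) <- list(gid, colnames(vals))
  expression_matrix(num, group_labels = group_labels)
}

#' Write an expression matrix as TSV
#' @param x an `ExpressionMatrix` (or plain named matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- GeneAnnotation ---------------------------------------------------------

#' Construct a validated gene annotation table
#'
#' One row per gene with its subcellular localization tags, a decoy flag
#' (soluble factors such as shed cytokine-receptor isoforms, which act in
#' solution and are excluded from network nodes) and a protein-level
#' evidence flag.
#'
#' @param gene_id character vector of unique gene ids.
#' @param localizations list of character vectors; allowed tags are
#'   `plasma_membrane`, `secreted`, `other`.
#' @param is_decoy logical vector; may be TRUE only for secreted genes.
#' @param protein_evidence logical vector.
#' @return a `data.frame` of class `GeneAnnotation` with a list-column
#'   `localizations`.
#' @export
gene_annotation <- function(gene_id, localizations, is_decoy, protein_evidence) {
  gene_id <- as.character(gene_id)
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup)) abort_val("duplicate annotation gene id(s): ", paste(dup, collapse = ", "))
  if (length(localizations) != length(gene_id) ||
      length(is_decoy) != length(gene_id) ||
      length(protein_evidence) != length(gene_id))
    abort_val("annotation columns must all have one entry per gene")
  allowed <- c("plasma_membrane", "secreted", "other")
  for (i in seq_along(localizations)) {
    loc <- localizations[[i]]
    if (length(loc) == 0) abort_val("empty localization set for gene ", gene_id[i])
    bad <- setdiff(loc, allowed)
    if (length(bad)) abort_val("unknown localization tag(s) for gene ", gene_id[i],
                               ": ", paste(bad, collapse = ", "))
  }
  sec <- vapply(localizations, function(l) "secreted" %in% l, logical(1))
  if (any(is_decoy & !sec))
    abort_val("is_decoy may be TRUE only for secreted genes: ",
              paste(gene_id[is_decoy & !sec], collapse = ", "))
  out <- data.frame(gene_id = gene_id, is_decoy = as.logical(is_decoy),
                    protein_evidence = as.logical(protein_evidence),
                    stringsAsFactors = FALSE)
  out$localizations <- localizations
  class(out) <- c("GeneAnnotation", "data.frame")
  out
}

#' Read a gene annotation TSV
#'
#' Columns: `gene_id`, `localizations` (semicolon-separated tags),
#' `is_decoy`, `protein_evidence`.
#' @param path file path.
#' @return a [gene_annotation()] table.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  need <- c("gene_id", "localizations", "is_decoy", "protein_evidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_val("annotation TSV missing column(s): ", paste(miss, collapse = ", "))
  gene_annotation(df$gene_id,
                  strsplit(df$localizations, ";", fixed = TRUE),
                  as.logical(df$is_decoy),
                  as.logical(df$protein_evidence))
}

#' Write a gene annotation TSV
#' @param ann a `GeneAnnotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  df <- data.frame(gene_id = ann$gene_id,
                   localizations = vapply(ann$localizations, paste, "", collapse = ";"),
                   is_decoy = ann$is_decoy,
                   protein_evidence = ann$protein_evidence)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genes carrying a given localization tag
#' @param ann a `GeneAnnotation`.
#' @param tag one of `plasma_membrane`, `secreted`, `other`.
#' @return character vector of gene ids.
#' @export
genes_with_tag <- function(ann, tag) {
  ann$gene_id[vapply(ann$localizations, function(l) tag %in% l, logical(1))]
}

## ---- InteractionTable -------------------------------------------------------

#' Construct a validated protein-interaction table
#'
#' Candidate protein pairs with a combined confidence score in `[0, 1]`,
#' a physical-interaction flag, and a flag recording whether published
#' evidence explicitly describes a receptor-ligand relationship (the
#' manual-curation step represented as data). Pairs are order-insensitive;
#' symmetric duplicates are collapsed keeping the maximum score.
#'
#' @param protein_a,protein_b character vectors of interactor ids.
#' @param combined_score numeric in `[0, 1]` (native STRING 0-1000 integer
#'   scores are detected by a maximum above 1 and divided by 1000).
#' @param is_physical,receptor_ligand_evidence logical vectors.
#' @return a `data.frame` of class `InteractionTable`.
#' @export
interaction_table <- function(protein_a, protein_b, combined_score,
                              is_physical, receptor_ligand_evidence) {
  protein_a <- as.character(protein_a); protein_b <- as.character(protein_b)
  n <- length(protein_a)
  if (length(protein_b) != n || length(combined_score) != n ||
      length(is_physical) != n || length(receptor_ligand_evidence) != n)
    abort_val("interaction columns must have equal length")
  if (n == 0) {
    out <- data.frame(protein_a = character(), protein_b = character(),
                      combined_score = numeric(), is_physical = logical(),
                      receptor_ligand_evidence = logical())
    class(out) <- c("InteractionTable", "data.frame")
    return(out)
  }
  combined_score <- as.numeric(combined_score)
  if (any(!is.finite(combined_score))) abort_val("non-numeric combined_score")
  if (max(combined_score) > 1) combined_score <- combined_score / 1000
  if (any(combined_score < 0 | combined_score > 1))
    abort_val("combined_score outside [0, 1] after scale detection")
  self <- protein_a == protein_b
  if (any(self)) abort_val("self-pair(s) not allowed: ",
                           paste(unique(protein_a[self]), collapse = ", "))
  # canonical unordered pair key
  a <- pmin(protein_a, protein_b); b <- pmax(protein_a, protein_b)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -combined_score)
  keep <- o[!duplicated(key[o])]
  keep <- sort(keep)
  out <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    combined_score = combined_score[keep],
                    is_physical = as.logical(is_physical)[keep],
                    receptor_ligand_evidence = as.logical(receptor_ligand_evidence)[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("InteractionTable", "data.frame")
  out
}

#' Read an interaction TSV
#'
#' Columns: `protein_a`, `protein_b`, `combined_score`, `is_physical`,
#' `receptor_ligand_evidence`. Symmetric duplicates collapse to the
#' max-score record.
#' @param path file path.
#' @return an [interaction_table()].
#' @export
read_interaction_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  need <- c("protein_a", "protein_b", "combined_score", "is_physical",
            "receptor_ligand_evidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_val("interaction TSV missing column(s): ", paste(miss, collapse = ", "))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(score) & !is.na(df$combined_score)))
    abort_val("non-numeric combined_score at data row ",
              which(is.na(score) & !is.na(df$combined_score))[1], " in ", path)
  interaction_table(df$protein_a, df$protein_b, score,
                    as.logical(df$is_physical),
                    as.logical(df$receptor_ligand_evidence))
}

#' Write an interaction TSV
#' @param tab an `InteractionTable`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interaction_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- GeneSetCollection ------------------------------------------------------

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a line
#' are collapsed.
#'
#' @param path file path.
#' @return a named list of character vectors with attributes `source`
#'   (per-set source tag, from the description field) of class
#'   `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    abort_val("GMT line ", short[1], " has fewer than 3 tab-separated fields in ", path)
  nm <- vapply(parts, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) abort_val("duplicate gene-set name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "source") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param source optional per-set description/source tags.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, source = NULL) {
  src <- source %||% attr(sets, "source") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], src[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## ---- SingleCellDataset ------------------------------------------------------

#' Construct a validated single-cell dataset
#'
#' Sparse non-negative integer counts stored genes x cells (the R
#' single-cell convention), with per-cell sample ids and per-sample group
#' labels.
#'
#' @param counts a genes x cells sparse or dense non-negative integer matrix
#'   with gene rownames and cell colnames.
#' @param sample_id character vector, one per cell.
#' @param sample_groups optional named character vector mapping sample id to
#'   condition label.
#' @return list of class `SingleCellDataset` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `sample_id`, `sample_groups`.
#' @export
single_cell_dataset <- function(counts, sample_id, sample_groups = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_val("counts must carry gene rownames and cell colnames")
  if (length(sample_id) != ncol(counts))
    abort_val("cell metadata rows (", length(sample_id),
              ") do not match cell count (", ncol(counts), ")")
  v <- counts@x
  if (any(v < 0)) abort_val("counts must be >= 0")
  if (any(v != round(v))) abort_val("counts must be integers")
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 cell_ids = colnames(counts),
                 sample_id = stats::setNames(as.character(sample_id), colnames(counts)),
                 sample_groups = sample_groups),
            class = "SingleCellDataset")
}

#' @export
print.SingleCellDataset <- function(x, ...) {
  cat(sprintf("SingleCellDataset: %d genes x %d cells, %d sample(s)\n",
              length(x$gene_ids), length(x$cell_ids), length(unique(x$sample_id))))
  invisible(x)
}

#' Read a single-cell dataset from MTX + metadata TSVs
#'
#' `matrix_path` is a MatrixMarket triplet file (1-based indices, genes x
#' cells), `genes_path` a one-column-or-more TSV whose first column holds
#' gene ids, `cells_path` a TSV with columns `cell_id`, `sample_id` and
#' optionally `group`.
#'
#' @param matrix_path,cells_path,genes_path file paths.
#' @return a [single_cell_dataset()].
#' @export
read_single_cell <- function(matrix_path, cells_path, genes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(genes_path, colClasses = "character")
  cells <- utils::read.delim(cells_path, colClasses = "character")
  if (!"sample_id" %in% names(cells))
    abort_val("cell metadata must have a sample_id column: ", cells_path)
  cid <- if ("cell_id" %in% names(cells)) cells$cell_id else cells[[1]]
  if (nrow(genes) != nrow(m))
    abort_val("gene metadata rows (", nrow(genes), ") do not match matrix rows (", nrow(m), ")")
  if (nrow(cells) != ncol(m))
    abort_val("cell metadata rows (", nrow(cells),
              ") do not match cell count (", ncol(m), ")")
  dimnames(m) <- list(genes[[1]], cid)
  groups <- NULL
  if ("group" %in% names(cells)) {
    groups <- tapply(cells$group, cells$sample_id, function(g) g[1])
    groups <- stats::setNames(as.character(groups), names(groups))
  }
  single_cell_dataset(m, cells$sample_id, sample_groups = groups)
}

#' Write a single-cell dataset as MTX + metadata TSVs
#' @param ds a `SingleCellDataset`.
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
write_single_cell <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, "matrix.mtx")
  gp <- file.path(dir, "genes.tsv")
  cp <- file.path(dir, "cells.tsv")
  Matrix::writeMM(ds$counts, mp)
  utils::write.table(data.frame(gene_id = ds$gene_ids), gp,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- data.frame(cell_id = ds$cell_ids, sample_id = unname(ds$sample_id))
  if (!is.null(ds$sample_groups))
    cells$group <- unname(ds$sample_groups[cells$sample_id])
  utils::write.table(cells, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mp, genes = gp, cells = cp))
}
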