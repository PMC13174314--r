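#' Construct an expression matrix
#'
#' The central container of the package: a sparse non-negative integer count
#' matrix (genes as rows, cells or spots as columns) with optional
#' library-size log-normalized layer of identical shape.
#'
#' @param counts matrix or sparse Matrix of non-negative integer counts,
#'   genes x observations.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param obs_ids character vector of unique observation (cell/spot)
#'   identifiers, one per column.
#' @param normalized optional numeric matrix of the same shape as `counts`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `gene_ids`, `obs_ids`, `counts` (a `dgCMatrix`) and `normalized`
#'   (a `dgCMatrix` or `NULL`).
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              obs_ids = colnames(counts), normalized = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(obs_ids)) {
    stop_regenmac("gene_ids and obs_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (anyDuplicated(gene_ids)) stop_regenmac("duplicate gene identifiers")
  if (anyDuplicated(obs_ids)) stop_regenmac("duplicate observation identifiers")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(obs_ids)) {
    stop_regenmac("matrix dimensions do not match identifier lengths: ",
                  nrow(counts), "x", ncol(counts), " vs ",
                  length(gene_ids), " genes, ", length(obs_ids), " obs")
  }
  if (any(counts@x < 0)) stop_regenmac("negative count entries")
  if (any(counts@x != round(counts@x))) {
    stop_regenmac("non-integer count entries")
  }
  dimnames(counts) <- list(gene_ids, obs_ids)
  if (!is.null(normalized)) {
    normalized <- methods::as(methods::as(Matrix::Matrix(normalized, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix")
    if (!identical(dim(normalized), dim(counts))) {
      stop_regenmac("normalized layer shape does not match counts")
    }
    dimnames(normalized) <- dimnames(counts)
  }
  structure(list(gene_ids = gene_ids, obs_ids = obs_ids,
                 counts = counts, normalized = normalized),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d obs (%s normalized layer)\n",
              length(x$gene_ids), length(x$obs_ids),
              if (is.null(x$normalized)) "no" else "with"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read an expression matrix from MatrixMarket + identifier sidecars
#'
#' @param mtx_path path to a MatrixMarket coordinate file (1-based indices).
#' @param genes_path path to a TSV whose first column lists gene identifiers
#'   in matrix row order (an optional second column of symbols is ignored).
#' @param obs_path path to a TSV listing observation identifiers in matrix
#'   column order.
#' @return An [expression_matrix()] with counts only.
#' @export
read_expression <- function(mtx_path, genes_path, obs_path) {
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop_regenmac("malformed MTX file: ",
                                                  conditionMessage(e)))
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")[[1]]
  obs <- utils::read.table(obs_path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")[[1]]
  if (nrow(m) != length(genes)) {
    stop_regenmac("MTX declares ", nrow(m), " rows but gene sidecar lists ",
                  length(genes))
  }
  if (ncol(m) != length(obs)) {
    stop_regenmac("MTX declares ", ncol(m), " columns but obs sidecar lists ",
                  length(obs))
  }
  expression_matrix(m, gene_ids = genes, obs_ids = obs)
}

#' Write an expression matrix as MatrixMarket + sidecars
#'
#' Inverse of [read_expression()]; only the counts layer is written.
#'
#' @param em an `ExpressionMatrix`.
#' @param mtx_path,genes_path,obs_path output paths.
#' @export
write_expression <- function(em, mtx_path, genes_path, obs_path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  Matrix::writeMM(em$counts, mtx_path)
  writeLines(em$gene_ids, genes_path)
  writeLines(em$obs_ids, obs_path)
  invisible(c(mtx = mtx_path, genes = genes_path, obs = obs_path))
}

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene identifiers (non-empty).
#' @param description free-text description.
#' @return An object of class `GeneSet`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_regenmac("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning("gene set '", name, "': collapsing ",
            sum(duplicated(genes)), " duplicate identifiers", call. = FALSE)
    genes <- unique(genes)
  }
  structure(list(name = as.character(name),
                 description = as.character(description),
                 genes = genes),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per tab-separated line: name, description, then gene identifiers.
#'
#' @param path path to a GMT file.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    fields <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_regenmac("GMT line with fewer than 3 fields: '",
                    substr(l, 1, 60), "'")
    }
    gene_set(fields[1], fields[-(1:2)], description = fields[2])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of `GeneSet` objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Library-size log-normalize a count matrix
#'
#' Computes `log(1 + scale * counts[g, c] / total_counts[c])` per entry and
#' stores it as the `normalized` layer; the counts layer is unchanged.
#'
#' @param em an `ExpressionMatrix`.
#' @param scale scale factor (default 1e4).
#' @return The input with its `normalized` layer filled in.
#' @export
normalize_counts <- function(em, scale = 1e4) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  totals <- Matrix::colSums(em$counts)
  if (any(totals == 0)) {
    stop_regenmac("observations with zero total counts: ",
                  paste(em$obs_ids[totals == 0], collapse = ", "))
  }
  norm <- em$counts
  # scale each column by scale/total; log1p preserves sparsity
  norm@x <- norm@x * rep.int(scale / totals, diff(norm@p))
  norm@x <- log1p(norm@x)
  em$normalized <- norm
  em
}

#' Validate a per-observation annotation table
#'
#' Checks one annotation row per observation, with cluster/injury/timepoint
#' labels drawn from declared vocabularies.
#'
#' @param ann data.frame with columns `obs_id`, `cluster`, `injury`,
#'   `timepoint`.
#' @param em optional `ExpressionMatrix` whose `obs_ids` must all be
#'   annotated.
#' @param injury_levels,timepoint_levels allowed category vocabularies.
#' @return The validated annotation data.frame (character columns).
#' @export
validate_annotations <- function(ann, em = NULL,
                                 injury_levels = c("UA", "P2", "P3"),
                                 timepoint_levels = c("D0", "D7", "D10", "D14")) {
  req <- c("obs_id", "cluster", "injury", "timepoint")
  if (!all(req %in% names(ann))) {
    stop_regenmac("annotation table must have columns: ",
                  paste(req, collapse = ", "))
  }
  ann <- as.data.frame(lapply(ann[req], as.character),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(ann$obs_id)) {
    stop_regenmac("observations annotated more than once")
  }
  bad_inj <- setdiff(unique(ann$injury), injury_levels)
  if (length(bad_inj)) {
    stop_regenmac("unknown injury labels: ", paste(bad_inj, collapse = ", "))
  }
  bad_tp <- setdiff(unique(ann$timepoint), timepoint_levels)
  if (length(bad_tp)) {
    stop_regenmac("unknown timepoint labels: ", paste(bad_tp, collapse = ", "))
  }
  if (!is.null(em)) {
    missing <- setdiff(em$obs_ids, ann$obs_id)
    if (length(missing)) {
      stop_regenmac(length(missing), " observations lack annotations")
    }
  }
  ann
}

#' Read a per-observation annotation CSV
#'
#' @param path CSV with header columns `obs_id`, `cluster`, `injury`,
#'   `timepoint`.
#' @param ... passed to [validate_annotations()].
#' @export
read_annotations <- function(path, ...) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(ann, ...)
}

#' Write a dataset bundle to a directory
#'
#' Writes `matrix.mtx`, `genes.tsv`, `obs.tsv` and (when given)
#' `annotations.csv` — the on-disk form consumed by [read_bundle()] and
#' [validate_bundle()].
#'
#' @param em an `ExpressionMatrix`.
#' @param dir output directory (created if needed).
#' @param annotations optional annotation data.frame.
#' @export
write_bundle <- function(em, dir, annotations = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(em,
                   file.path(dir, "matrix.mtx"),
                   file.path(dir, "genes.tsv"),
                   file.path(dir, "obs.tsv"))
  if (!is.null(annotations)) {
    utils::write.csv(annotations, file.path(dir, "annotations.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset bundle from a directory
#'
#' @param dir directory produced by [write_bundle()].
#' @return list with `em` (ExpressionMatrix) and `annotations`
#'   (data.frame or NULL).
#' @export
read_bundle <- function(dir) {
  em <- read_expression(file.path(dir, "matrix.mtx"),
                        file.path(dir, "genes.tsv"),
                        file.path(dir, "obs.tsv"))
  ann_path <- file.path(dir, "annotations.csv")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path, em = em) else NULL
  list(em = em, annotations = ann)
}

#' Validate a dataset bundle and print a summary
#'
#' @param dir bundle directory.
#' @return Invisibly, a summary list.
#' @export
validate_bundle <- function(dir) {
  b <- read_bundle(dir)
  s <- list(genes = length(b$em$gene_ids),
            obs = length(b$em$obs_ids),
            total_counts = sum(b$em$counts),
            annotated = !is.null(b$annotations))
  cat(sprintf("bundle OK: %d genes x %d obs, %.0f total counts, %s\n",
              s$genes, s$obs, s$total_counts,
              if (s$annotated) "annotated" else "no annotations"))
  invisible(s)
}

# Intersect a gene set with a matrix; drop absent genes with a logged count.
resolve_genes <- function(gene_set, gene_ids, context = "gene set") {
  present <- intersect(gene_set$genes, gene_ids)
  n_drop <- length(gene_set$genes) - length(present)
  if (length(present) == 0L) {
    stop_regenmac(context, " '", gene_set$name,
                  "': no genes found in matrix; missing: ",
                  paste(utils::head(gene_set$genes, 10), collapse = ", "))
  }
  if (n_drop > 0L) {
    message(context, " '", gene_set$name, "': dropped ", n_drop,
            " genes absent from matrix")
  }
  list(genes = present, dropped = n_drop)
}
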