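#' Gene-set module score with bin-matched background controls
#'
#' Scores each observation as the mean normalized expression of the set
#' genes minus the mean over a pool of control genes matched on average
#' expression. Genes are ranked by their mean normalized expression across
#' observations and cut into `n_bins` equal-frequency bins; each set gene
#' contributes `n_ctrl` control genes sampled from its own bin (without
#' replacement, or with replacement when the bin is smaller than `n_ctrl`).
#' Controls are pooled (unique) across set genes, so the score is centered on
#' an expression-matched background and 0 is the null.
#'
#' @param em an `ExpressionMatrix` with a normalized layer (see
#'   [normalize_counts()]).
#' @param gene_set a [gene_set()]; genes absent from the matrix are dropped
#'   with a message.
#' @param n_bins number of equal-frequency expression bins (default 24).
#' @param n_ctrl controls sampled per set gene (default 100).
#' @param seed integer seed for control sampling.
#' @return A `ModuleScoreResult`: list with `set_name`, per-observation
#'   `scores` (named numeric), and the parameters `n_bins`, `n_ctrl`,
#'   `seed`, `dropped_genes` recorded for reproducibility.
#' @export
module_score <- function(em, gene_set, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$normalized)) {
    stop_regenmac("normalized layer required; run normalize_counts() first")
  }
  if (n_bins < 2) stop_regenmac("n_bins must be >= 2")
  res <- resolve_genes(gene_set, em$gene_ids)
  set_genes <- res$genes

  x <- em$normalized
  gene_means <- Matrix::rowMeans(x)
  n_genes <- length(gene_means)
  # equal-frequency bins on the mean-expression rank
  bin <- ceiling(n_bins * rank(gene_means, ties.method = "first") / n_genes)
  bin <- pmin(pmax(bin, 1L), n_bins)
  names(bin) <- em$gene_ids
  bin_members <- split(em$gene_ids, bin)

  ctrl <- with_seed(seed, {
    unlist(lapply(set_genes, function(g) {
      members <- bin_members[[as.character(bin[[g]])]]
      if (length(members) >= n_ctrl) {
        sample(members, n_ctrl, replace = FALSE)
      } else {
        sample(members, n_ctrl, replace = TRUE)
      }
    }), use.names = FALSE)
  })
  ctrl_pool <- unique(ctrl)

  set_mean <- Matrix::colMeans(x[set_genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(x[ctrl_pool, , drop = FALSE])
  scores <- set_mean - ctrl_mean
  names(scores) <- em$obs_ids
  structure(list(set_name = gene_set$name, scores = scores,
                 n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed), dropped_genes = res$dropped),
            class = "ModuleScoreResult")
}

#' @export
print.ModuleScoreResult <- function(x, ...) {
  cat(sprintf("ModuleScoreResult '%s': %d obs, mean %.4f (n_bins=%d, n_ctrl=%d, seed=%d)\n",
              x$set_name, length(x$scores), mean(x$scores),
              x$n_bins, x$n_ctrl, x$seed))
  invisible(x)
}

#' Rank marker genes of a cluster against all other cells
#'
#' Per-gene two-sided Wilcoxon rank-sum test of the cluster's normalized
#' values against the complement (exact distribution for small untied
#' groups, otherwise normal approximation with tie and continuity
#' correction), Benjamini-Hochberg adjustment across tested genes, and a
#' natural-log fold change of expm1-means with a 1e-9 pseudocount.
#'
#' @param em an `ExpressionMatrix` with a normalized layer.
#' @param annotations annotation data.frame (see [validate_annotations()]).
#' @param cluster cluster label to contrast against all other clusters.
#' @return A `MarkerTable` data.frame with columns `gene`,
#'   `log_fold_change`, `p_value`, `adj_p`, `frac_in`, `frac_out`, ordered
#'   as in the matrix; the contrasted cluster is kept in
#'   `attr(, "cluster")`.
#' @export
rank_markers <- function(em, annotations, cluster) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$normalized)) {
    stop_regenmac("normalized layer required; run normalize_counts() first")
  }
  annotations <- validate_annotations(annotations, em)
  if (!cluster %in% annotations$cluster) {
    stop_regenmac("cluster '", cluster, "' absent from annotations")
  }
  idx <- match(em$obs_ids, annotations$obs_id)
  in_cluster <- annotations$cluster[idx] == cluster
  if (sum(in_cluster) < 3 || sum(!in_cluster) < 3) {
    stop_regenmac("need >= 3 observations in the cluster and its complement")
  }
  x <- as.matrix(em$normalized)
  xin <- x[, in_cluster, drop = FALSE]
  xout <- x[, !in_cluster, drop = FALSE]

  pseudo <- 1e-9
  lfc <- log((rowMeans(expm1(xin)) + pseudo) / (rowMeans(expm1(xout)) + pseudo))
  p <- vapply(seq_len(nrow(x)), function(i) {
    rank_sum_test(xin[i, ], xout[i, ])$p
  }, numeric(1))
  tbl <- data.frame(gene = em$gene_ids,
                    log_fold_change = lfc,
                    p_value = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    frac_in = rowMeans(xin > 0),
                    frac_out = rowMeans(xout > 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(tbl, "cluster") <- cluster
  class(tbl) <- c("MarkerTable", "data.frame")
  tbl
}

#' Select the top-k marker signature of a cluster
#'
#' Filters to positively enriched significant markers
#' (`log_fold_change > 0`, `adj_p < 0.05`), orders by adjusted p ascending,
#' then fold change descending, then gene id, and takes the first `k`.
#'
#' @param mt a `MarkerTable` from [rank_markers()].
#' @param k signature size (default 50).
#' @param lfc_min,adj_p_max filter thresholds.
#' @return A [gene_set()] named after the contrasted cluster.
#' @export
top_signature <- function(mt, k = 50, lfc_min = 0, adj_p_max = 0.05) {
  if (k < 1) stop_regenmac("k must be >= 1")
  pass <- mt[mt$log_fold_change > lfc_min & mt$adj_p < adj_p_max, , drop = FALSE]
  if (nrow(pass) == 0L) {
    stop_regenmac("no genes pass the signature filter (lfc > ", lfc_min,
                  ", adj_p < ", adj_p_max, ")")
  }
  ord <- order(pass$adj_p, -pass$log_fold_change, pass$gene)
  top <- pass$gene[ord][seq_len(min(k, nrow(pass)))]
  gene_set(attr(mt, "cluster") %||% "signature", top,
           description = sprintf("top %d positive markers", length(top)))
}
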