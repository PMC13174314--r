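#' Per-cell metabolic pathway scores and group profiles
#'
#' Runs [module_score()] for the glycolysis, oxidative-phosphorylation and
#' fatty-acid-metabolism gene sets (one shared seed) and aggregates the
#' scores by (cluster, injury, timepoint). The group `overall_score` is the
#' signed glycolysis-minus-FAO difference: positive means
#' glycolysis-dominated, negative means FAO-dominated.
#'
#' @param em an `ExpressionMatrix` with a normalized layer.
#' @param sets named list with `GeneSet` elements `glyco`, `oxphos`, `famet`.
#' @param annotations annotation data.frame.
#' @param n_bins,n_ctrl,seed module-score parameters shared by the three
#'   calls.
#' @return A `MetabolicProfile`: list with `cells` (per-observation scores
#'   plus annotations) and `groups` (per-group means and `overall_score`).
#' @export
pathway_scores <- function(em, sets, annotations,
                           n_bins = 24, n_ctrl = 100, seed = 0) {
  need <- c("glyco", "oxphos", "famet")
  if (!all(need %in% names(sets))) {
    stop_regenmac("sets must contain elements: ", paste(need, collapse = ", "))
  }
  annotations <- validate_annotations(annotations, em)
  ms <- lapply(sets[need], function(s) module_score(em, s, n_bins, n_ctrl, seed))
  idx <- match(em$obs_ids, annotations$obs_id)
  cells <- data.frame(obs_id = em$obs_ids,
                      cluster = annotations$cluster[idx],
                      injury = annotations$injury[idx],
                      timepoint = annotations$timepoint[idx],
                      glyco_score = unname(ms$glyco$scores),
                      oxphos_score = unname(ms$oxphos$scores),
                      famet_score = unname(ms$famet$scores),
                      stringsAsFactors = FALSE)
  groups <- stats::aggregate(
    cells[c("glyco_score", "oxphos_score", "famet_score")],
    by = cells[c("cluster", "injury", "timepoint")], FUN = mean)
  groups$n <- stats::aggregate(seq_len(nrow(cells)),
                               by = cells[c("cluster", "injury", "timepoint")],
                               FUN = length)$x
  groups$overall_score <- groups$glyco_score - groups$famet_score
  groups <- groups[order(groups$cluster, groups$injury, groups$timepoint), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  structure(list(cells = cells, groups = groups,
                 params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)),
            class = "MetabolicProfile")
}

#' Glycolysis-versus-FAO overall score of a cell group
#'
#' `mean(glyco_score) - mean(famet_score)` over the cells selected by
#' `group` — a signed difference of background-centered module scores
#' (scores can be negative, so a literal quotient is ill-defined; one is
#' available via `type = "quotient"` for comparison).
#'
#' @param profile a `MetabolicProfile` from [pathway_scores()].
#' @param group named list selecting cells; any subset of `cluster`,
#'   `injury`, `timepoint` (e.g. `list(injury = "P3", timepoint = "D10")`).
#' @param type `"difference"` (default) or `"quotient"`.
#' @return A single number: positive = glycolysis-dominated, negative =
#'   FAO-dominated.
#' @export
metabolic_ratio <- function(profile, group, type = c("difference", "quotient")) {
  type <- match.arg(type)
  cells <- profile$cells
  keep <- rep(TRUE, nrow(cells))
  for (f in intersect(names(group), c("cluster", "injury", "timepoint"))) {
    keep <- keep & cells[[f]] %in% group[[f]]
  }
  if (!any(keep)) stop_regenmac("no cells match the requested group")
  g <- mean(cells$glyco_score[keep])
  f <- mean(cells$famet_score[keep])
  if (type == "difference") g - f else g / f
}

#' Per-gene variance partition across grouping factors
#'
#' For each gene and each factor separately, the one-way between-group sum
#' of squares of the normalized values and the corresponding eta-squared
#' (`ss_between / ss_total`). Genes with zero total variance are excluded
#' and counted.
#'
#' @param em an `ExpressionMatrix` with a normalized layer.
#' @param annotations annotation data.frame.
#' @param factors annotation columns to partition over (each needs >= 2
#'   levels among the selected observations).
#' @return A `VariancePartition` list: `table` (per gene: `ss_total` and
#'   one `eta_sq_<factor>` / `ss_between_<factor>` pair per factor),
#'   `n_constant` (excluded genes), `summary` (per-factor mean/median
#'   eta-squared).
#' @export
variance_partition <- function(em, annotations,
                               factors = c("injury", "cluster")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$normalized)) {
    stop_regenmac("normalized layer required; run normalize_counts() first")
  }
  annotations <- validate_annotations(annotations, em)
  idx <- match(em$obs_ids, annotations$obs_id)
  x <- as.matrix(em$normalized)
  n <- ncol(x)
  gm <- rowMeans(x)
  ss_total <- rowSums((x - gm)^2)
  constant <- ss_total <= 1e-12
  tbl <- data.frame(gene = em$gene_ids, ss_total = ss_total,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (f in factors) {
    labels <- annotations[[f]][idx]
    if (length(unique(labels)) < 2) {
      stop_regenmac("factor '", f, "' has fewer than 2 levels")
    }
    ss_between <- rep(0, nrow(x))
    for (lev in unique(labels)) {
      sel <- labels == lev
      ss_between <- ss_between + sum(sel) * (rowMeans(x[, sel, drop = FALSE]) - gm)^2
    }
    tbl[[paste0("ss_between_", f)]] <- ss_between
    tbl[[paste0("eta_sq_", f)]] <- ifelse(constant, NA_real_,
                                          pmin(1, ss_between / ss_total))
  }
  tbl <- tbl[!constant, , drop = FALSE]
  summ <- do.call(rbind, lapply(factors, function(f) {
    e <- tbl[[paste0("eta_sq_", f)]]
    data.frame(factor = f, mean_eta_sq = mean(e), median_eta_sq = stats::median(e),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tbl, n_constant = sum(constant), summary = summ),
            class = "VariancePartition")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum of the absolute difference of the two empirical
#' CDFs; the p-value uses the asymptotic Kolmogorov distribution evaluated
#' at `sqrt(n_eff) * D` with effective size `n_a * n_b / (n_a + n_b)`.
#'
#' @param sample_a,sample_b numeric vectors (each non-empty).
#' @return list with `D` (in \[0, 1\]) and `p`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a)
  b <- as.numeric(sample_b)
  if (length(a) == 0L || length(b) == 0L) stop_regenmac("empty sample")
  na <- length(a)
  nb <- length(b)
  w <- c(a, b)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= na, 1 / na, -1 / nb))
  # at tied values only the ECDF gap after the full tie group counts
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)
  d <- max(abs(z[keep]))
  n_eff <- na * nb / (na + nb)
  list(D = d, p = kolmogorov_sf(sqrt(n_eff) * d))
}

# Survival function of the Kolmogorov distribution,
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2), clipped to [0, 1].
kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  k <- seq_len(200)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}
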