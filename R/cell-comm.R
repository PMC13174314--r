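# Simplified ligand-receptor communication scoring with a permutation null.
# The score for a (pair, sender, receiver) triple is the product of the mean
# normalized ligand expression in the sender cluster and the minimum over
# receptor-complex members of the mean normalized expression in the receiver
# cluster (AND semantics), gated to zero when the expressing-cell fraction
# falls below min_frac on either side. Significance comes from cluster-label
# permutations within the condition.

#' Read a ligand-receptor pair table
#'
#' CSV with columns `pathway`, `ligand`, `receptors` (semicolon-joined
#' receptor-complex members).
#'
#' @param path CSV path; defaults to the small curated table shipped with
#'   the package (BMP and TNF pairs).
#' @return list of `LRPair` lists (`pathway`, `ligand`, `receptors`).
#' @export
read_lr_pairs <- function(path = system.file("extdata", "lr_pairs.csv",
                                             package = "regenmac")) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("pathway", "ligand", "receptors")
  if (!all(req %in% names(tbl))) {
    stop_regenmac("LR table must have columns: ", paste(req, collapse = ", "))
  }
  lapply(seq_len(nrow(tbl)), function(i) {
    receptors <- strsplit(tbl$receptors[i], ";", fixed = TRUE)[[1]]
    receptors <- trimws(receptors[nzchar(trimws(receptors))])
    if (length(receptors) == 0L) {
      stop_regenmac("pair '", tbl$ligand[i], "' has no receptors")
    }
    list(pathway = tbl$pathway[i], ligand = tbl$ligand[i],
         receptors = receptors)
  })
}

# Per-cluster mean and expressing fraction for a genes x cells matrix.
cluster_stats <- function(x, labels) {
  levs <- sort(unique(labels))
  means <- vapply(levs, function(l) {
    rowMeans(x[, labels == l, drop = FALSE])
  }, numeric(nrow(x)))
  fracs <- vapply(levs, function(l) {
    rowMeans(x[, labels == l, drop = FALSE] > 0)
  }, numeric(nrow(x)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = nrow(x), dimnames = list(rownames(x), levs))
    fracs <- matrix(fracs, nrow = nrow(x), dimnames = list(rownames(x), levs))
  }
  list(means = means, fracs = fracs, levels = levs)
}

lr_score_one <- function(pair, stats, sender, receiver, min_frac) {
  lig <- pair$ligand
  l_mean <- stats$means[lig, sender]
  l_frac <- stats$fracs[lig, sender]
  r_mean <- min(stats$means[pair$receptors, receiver])
  r_frac <- min(stats$fracs[pair$receptors, receiver])
  gated <- l_frac < min_frac || r_frac < min_frac
  list(score = if (gated) 0 else l_mean * r_mean,
       frac_ligand = l_frac, frac_receptor = r_frac)
}

#' Permutation-scored ligand-receptor communication between clusters
#'
#' @param em `ExpressionMatrix` with a normalized layer.
#' @param annotations annotation data.frame.
#' @param lr_db list of LR pairs from [read_lr_pairs()].
#' @param condition injury condition to restrict to (e.g. `"P3"`), or
#'   `NULL` for all cells.
#' @param senders,receivers cluster labels to evaluate (default: all
#'   clusters present under the condition).
#' @param min_frac minimum expressing-cell fraction (default 0.10) below
#'   which a score is gated to 0.
#' @param n_perm number of cluster-label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return A `CommResult`: list with `table` (one row per pair x sender x
#'   receiver: `pathway`, `ligand`, `receptors`, `sender`, `receiver`,
#'   `condition`, `score`, `p` with add-one correction,
#'   `expressed_frac_ligand`, `expressed_frac_receptor`) and `skipped`
#'   (pairs whose genes were absent).
#' @export
communication_score <- function(em, annotations, lr_db, condition = NULL,
                                senders = NULL, receivers = NULL,
                                min_frac = 0.10, n_perm = 1000, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$normalized)) {
    stop_regenmac("normalized layer required; run normalize_counts() first")
  }
  annotations <- validate_annotations(annotations, em)
  idx <- match(em$obs_ids, annotations$obs_id)
  keep <- if (is.null(condition)) {
    rep(TRUE, length(idx))
  } else {
    annotations$injury[idx] %in% condition
  }
  if (!any(keep)) stop_regenmac("no cells under condition ", condition)
  labels <- annotations$cluster[idx][keep]

  usable <- list()
  skipped <- character(0)
  for (pair in lr_db) {
    genes <- c(pair$ligand, pair$receptors)
    if (!all(genes %in% em$gene_ids)) {
      skipped <- c(skipped,
                   sprintf("%s->%s", pair$ligand,
                           paste(pair$receptors, collapse = "+")))
      next
    }
    usable[[length(usable) + 1L]] <- pair
  }
  if (length(skipped)) {
    message("skipped ", length(skipped), " LR pairs with absent genes: ",
            paste(skipped, collapse = ", "))
  }
  if (length(usable) == 0L) {
    stop_regenmac("no LR pair has all genes in the matrix")
  }
  genes_used <- unique(unlist(lapply(usable, function(p) {
    c(p$ligand, p$receptors)
  })))
  x <- as.matrix(em$normalized[genes_used, keep, drop = FALSE])

  obs_stats <- cluster_stats(x, labels)
  senders <- senders %||% obs_stats$levels
  receivers <- receivers %||% obs_stats$levels
  combos <- expand.grid(pair_i = seq_along(usable), sender = senders,
                        receiver = receivers, stringsAsFactors = FALSE)

  observed <- lapply(seq_len(nrow(combos)), function(i) {
    lr_score_one(usable[[combos$pair_i[i]]], obs_stats,
                 combos$sender[i], combos$receiver[i], min_frac)
  })
  obs_scores <- vapply(observed, `[[`, numeric(1), "score")

  exceed <- integer(nrow(combos))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_labels <- sample(labels)
      perm_stats <- cluster_stats(x, perm_labels)
      perm_scores <- vapply(seq_len(nrow(combos)), function(i) {
        lr_score_one(usable[[combos$pair_i[i]]], perm_stats,
                     combos$sender[i], combos$receiver[i], min_frac)$score
      }, numeric(1))
      exceed <- exceed + (perm_scores >= obs_scores)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)

  tbl <- data.frame(
    pathway = vapply(usable, `[[`, character(1), "pathway")[combos$pair_i],
    ligand = vapply(usable, `[[`, character(1), "ligand")[combos$pair_i],
    receptors = vapply(usable, function(p) {
      paste(p$receptors, collapse = ";")
    }, character(1))[combos$pair_i],
    sender = combos$sender, receiver = combos$receiver,
    condition = if (is.null(condition)) "all" else condition,
    score = obs_scores, p = p,
    expressed_frac_ligand = vapply(observed, `[[`, numeric(1), "frac_ligand"),
    expressed_frac_receptor = vapply(observed, `[[`, numeric(1),
                                     "frac_receptor"),
    stringsAsFactors = FALSE)
  structure(list(table = tbl, skipped = skipped,
                 params = list(min_frac = min_frac, n_perm = n_perm,
                               seed = seed)),
            class = "CommResult")
}

#' Rank ligands by between-condition expression difference per cluster
#'
#' For each ligand and each (macrophage) cluster: mean normalized
#' expression per condition, signed difference (second minus first
#' condition), Wilcoxon rank-sum p across cells, and BH adjustment across
#' all (ligand, cluster) rows; ranked by signed difference, so the top rows
#' are the ligands most enriched in the second condition.
#'
#' @param em `ExpressionMatrix` with a normalized layer.
#' @param annotations annotation data.frame.
#' @param conditions length-2 character vector (default `c("P2", "P3")`).
#' @param ligands ligand gene ids; absent ones are skipped with a message.
#' @param clusters clusters to evaluate (default: all).
#' @return data.frame ranked by difference descending.
#' @export
differential_ligands <- function(em, annotations, conditions = c("P2", "P3"),
                                 ligands, clusters = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$normalized)) {
    stop_regenmac("normalized layer required; run normalize_counts() first")
  }
  if (length(conditions) != 2) stop_regenmac("exactly two conditions required")
  annotations <- validate_annotations(annotations, em)
  idx <- match(em$obs_ids, annotations$obs_id)
  inj <- annotations$injury[idx]
  cl <- annotations$cluster[idx]
  if (!all(conditions %in% inj)) {
    stop_regenmac("both conditions must be present in the annotations")
  }
  absent <- setdiff(ligands, em$gene_ids)
  if (length(absent)) {
    message("skipped ", length(absent), " absent ligands: ",
            paste(absent, collapse = ", "))
    ligands <- setdiff(ligands, absent)
  }
  if (length(ligands) == 0L) stop_regenmac("no ligands found in matrix")
  clusters <- clusters %||% sort(unique(cl))
  x <- as.matrix(em$normalized[ligands, , drop = FALSE])

  rows <- list()
  for (clu in clusters) {
    for (lig in ligands) {
      v1 <- x[lig, cl == clu & inj == conditions[1]]
      v2 <- x[lig, cl == clu & inj == conditions[2]]
      if (length(v1) == 0L || length(v2) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = lig, cluster = clu,
        mean_1 = mean(v1), mean_2 = mean(v2),
        difference = mean(v2) - mean(v1),
        p_value = rank_sum_test(v2, v1)$p,
        stringsAsFactors = FALSE)
    }
  }
  tbl <- do.call(rbind, rows)
  names(tbl)[names(tbl) == "mean_1"] <- paste0("mean_", conditions[1])
  names(tbl)[names(tbl) == "mean_2"] <- paste0("mean_", conditions[2])
  tbl$adj_p <- stats::p.adjust(tbl$p_value, method = "BH")
  tbl <- tbl[order(-tbl$difference), , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}

#' Extract the significant signaling network of a pathway
#'
#' Edges (sender -> receiver) for the pathway's pairs whose BH-adjusted
#' permutation p is below `alpha`.
#'
#' @param comm a `CommResult` (or a list of them, one per condition).
#' @param pathway pathway label (e.g. `"BMP"`).
#' @param alpha significance level after BH adjustment within the pathway
#'   and condition.
#' @return data.frame of edges (possibly zero rows) with columns
#'   `condition`, `pathway`, `ligand`, `receptors`, `sender`, `receiver`,
#'   `score`, `adj_p`.
#' @export
pathway_network <- function(comm, pathway, alpha = 0.05) {
  comms <- if (inherits(comm, "CommResult")) list(comm) else comm
  edges <- do.call(rbind, lapply(comms, function(cm) {
    tbl <- cm$table[cm$table$pathway == pathway, , drop = FALSE]
    if (nrow(tbl) == 0L) return(NULL)
    tbl$adj_p <- stats::p.adjust(tbl$p, method = "BH")
    tbl[tbl$adj_p < alpha,
        c("condition", "pathway", "ligand", "receptors", "sender",
          "receiver", "score", "adj_p"), drop = FALSE]
  }))
  if (is.null(edges)) {
    edges <- data.frame(condition = character(0), pathway = character(0),
                        ligand = character(0), receptors = character(0),
                        sender = character(0), receiver = character(0),
                        score = numeric(0), adj_p = numeric(0))
  }
  rownames(edges) <- NULL
  edges
}
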