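# Shared fixtures and independently written reference implementations used
# to cross-check the package's analytical code.

# Small Poisson count fixture with a normalized layer.
make_test_em <- function(n_genes = 30, n_cells = 40, seed = 11, lambda = 2) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("c%02d", seq_len(n_cells))))
  # guarantee no all-zero columns
  counts[1, colSums(counts) == 0] <- 1
  normalize_counts(expression_matrix(counts))
}

# Brute-force module score: dense re-implementation of the documented
# algorithm (equal-frequency bins on mean expression, n_ctrl controls per
# set gene from its own bin, unique pooled controls, set mean minus control
# mean). Shares only the RNG seed with the package version.
oracle_module_score <- function(em, set_genes, n_bins, n_ctrl, seed) {
  x <- as.matrix(em$normalized)
  means <- rowMeans(x)
  bins <- ceiling(n_bins * rank(means, ties.method = "first") / nrow(x))
  bins <- pmin(pmax(bins, 1L), n_bins)
  names(bins) <- rownames(x)
  set_genes <- intersect(set_genes, rownames(x))
  set.seed(as.integer(seed))
  ctrl <- character(0)
  for (g in set_genes) {
    members <- rownames(x)[bins == bins[[g]]]
    if (length(members) >= n_ctrl) {
      ctrl <- c(ctrl, sample(members, n_ctrl, replace = FALSE))
    } else {
      ctrl <- c(ctrl, sample(members, n_ctrl, replace = TRUE))
    }
  }
  ctrl <- unique(ctrl)
  colMeans(x[set_genes, , drop = FALSE]) - colMeans(x[ctrl, , drop = FALSE])
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
oracle_ranksum_p <- function(x_in, x_out) {
  n1 <- length(x_in)
  n2 <- length(x_out)
  r <- rank(c(x_in, x_out))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
# value and take the largest absolute gap.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

# Single-component NIPALS PLS1 on a centered y: closed form for one
# response, w = X'y / ||X'y||, t = Xw, p = X't / t't.
oracle_pls1 <- function(x, y) {
  w <- drop(crossprod(x, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(x %*% w)
  p <- drop(crossprod(x, t)) / sum(t^2)
  list(weights = w, scores = t, loadings = p)
}

# Annotation table where every cell shares one injury/timepoint.
flat_annotations <- function(obs_ids, cluster) {
  data.frame(obs_id = obs_ids, cluster = cluster,
             injury = "P3", timepoint = "D10", stringsAsFactors = FALSE)
}
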