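#' Construct a metabolite abundance table
#'
#' @param abundances positive numeric matrix, metabolites x samples, with
#'   dimnames.
#' @param groups named character vector (or factor) of group labels, one
#'   per sample.
#' @return A `MetaboliteTable`.
#' @export
metabolite_table <- function(abundances, groups) {
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)) || is.null(colnames(abundances))) {
    stop_regenmac("abundances must have metabolite and sample dimnames")
  }
  if (anyDuplicated(rownames(abundances)) ||
      anyDuplicated(colnames(abundances))) {
    stop_regenmac("duplicate metabolite or sample identifiers")
  }
  if (any(abundances <= 0)) stop_regenmac("abundances must be positive")
  groups <- stats::setNames(as.character(groups),
                            names(groups) %||% colnames(abundances))
  if (!all(colnames(abundances) %in% names(groups))) {
    stop_regenmac("every sample needs a group label")
  }
  groups <- groups[colnames(abundances)]
  structure(list(metabolite_ids = rownames(abundances),
                 sample_ids = colnames(abundances),
                 abundances = abundances, groups = groups),
            class = "MetaboliteTable")
}

#' Read a metabolite table from CSV
#'
#' @param table_path CSV, metabolites x samples; header = sample ids,
#'   first column = metabolite ids.
#' @param groups_path CSV with columns `sample_id`, `group`.
#' @export
read_metabolite_table <- function(table_path, groups_path) {
  tbl <- utils::read.csv(table_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  g <- utils::read.csv(groups_path, stringsAsFactors = FALSE)
  metabolite_table(m, stats::setNames(g$group, g$sample_id))
}

#' Preprocess a metabolite table for latent-variable modeling
#'
#' Log-transform, then metabolite-wise centering with unit-variance or
#' Pareto scaling; constant metabolites are dropped with a message.
#'
#' @param mt a `MetaboliteTable`.
#' @param transform `"log"` (natural log) or `"none"`.
#' @param scaling `"uv"` (unit variance), `"pareto"` (divide by sqrt(SD)),
#'   or `"center"` (centering only).
#' @return samples x metabolites numeric matrix; dropped metabolites are
#'   recorded in `attr(, "dropped")` and the group labels in
#'   `attr(, "groups")`.
#' @export
preprocess <- function(mt, transform = c("log", "none"),
                       scaling = c("uv", "pareto", "center")) {
  stopifnot(inherits(mt, "MetaboliteTable"))
  transform <- match.arg(transform)
  scaling <- match.arg(scaling)
  x <- mt$abundances
  if (transform == "log") {
    if (any(x <= 0)) stop_regenmac("non-positive value under log transform")
    x <- log(x)
  }
  x <- t(x)  # samples x metabolites
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds <= 1e-12]
  if (length(dropped)) {
    message("dropping ", length(dropped), " constant metabolites: ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 1e-12, drop = FALSE]
    sds <- sds[sds > 1e-12]
  }
  x <- sweep(x, 2, colMeans(x))
  x <- switch(scaling,
              uv = sweep(x, 2, sds, `/`),
              pareto = sweep(x, 2, sqrt(sds), `/`),
              center = x)
  attr(x, "dropped") <- dropped
  attr(x, "groups") <- mt$groups
  x
}

#' Principal component analysis of a preprocessed matrix
#'
#' Truncated SVD of the column-centered matrix. Loadings are orthonormal;
#' signs are fixed so each loading's largest-magnitude entry is positive.
#'
#' @param x samples x variables matrix (e.g. from [preprocess()]).
#' @param k number of components, `<= min(dim(x))`.
#' @return A `LatentModel` list: `scores` (samples x k), `loadings`
#'   (variables x k), `variance_explained` (length k, non-increasing).
#' @export
pca <- function(x, k = 2) {
  x <- as.matrix(x)
  if (k < 1 || k > min(dim(x))) stop_regenmac("invalid k")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  # sign convention: largest-|entry| of each loading positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2,
                    flip[seq_len(k)], `*`)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip[seq_len(k)], `*`)
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 kind = "pca"),
            class = "LatentModel")
}

#' Orthogonal PLS discriminant analysis with VIP (binary response)
#'
#' Single-response O-PLS in the orthogonal-signal-correction formulation:
#' `n_ortho` components capturing X-variation orthogonal to the group
#' response are extracted and deflated, then one predictive PLS component
#' is fitted on the deflated matrix. With `n_ortho = 0` the predictive
#' component is the first NIPALS PLS1 component. VIP for variable j is
#' `sqrt(M * sum_c w_jc^2 SSY_c / sum_c SSY_c)` over retained components
#' (mean VIP^2 = 1). Leave-one-out Q2 and a label-permutation p-value for
#' the model are reported because the assay-scale group sizes (n = 3) make
#' parametric claims fragile.
#'
#' @param x samples x variables matrix from [preprocess()].
#' @param labels group label per sample (exactly two groups).
#' @param n_ortho number of orthogonal components (default 1).
#' @param tol,max_iter NIPALS convergence controls (single-y NIPALS
#'   converges in one pass; kept for interface stability).
#' @param n_perm permutations for the model p-value (0 to skip).
#' @param seed seed for the permutation test.
#' @return A `LatentModel` list with `scores` (predictive then orthogonal
#'   columns), `loadings`, `weights`, `vip`, `r2y`, `q2`, `perm_p`,
#'   `n_ortho`.
#' @export
oplsda <- function(x, labels, n_ortho = 1, tol = 1e-10, max_iter = 500,
                   n_perm = 200, seed = 0) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  levs <- sort(unique(labels))
  if (length(levs) != 2) stop_regenmac("exactly 2 groups required")
  if (n_ortho < 0) stop_regenmac("n_ortho must be >= 0")
  y <- ifelse(labels == levs[2], 1, -1)
  y <- y - mean(y)
  fit <- opls_core(x, y, n_ortho, tol, max_iter)

  perm_p <- NA_real_
  if (n_perm > 0) {
    with_seed(seed, {
      perm_r2 <- vapply(seq_len(n_perm), function(b) {
        yp <- sample(y)
        opls_core(x, yp, n_ortho, tol, max_iter)$r2y
      }, numeric(1))
    })
    perm_p <- (1 + sum(perm_r2 >= fit$r2y)) / (n_perm + 1)
  }
  q2 <- oplsda_q2_loo(x, y, n_ortho, tol, max_iter)

  structure(list(scores = fit$scores, loadings = fit$loadings,
                 weights = fit$weights, vip = fit$vip,
                 variance_explained = fit$variance_explained,
                 r2y = fit$r2y, q2 = q2, perm_p = perm_p,
                 n_ortho = n_ortho, group_levels = levs, kind = "oplsda"),
            class = "LatentModel")
}

# Core O-PLS (Trygg-Wold) with a single centered response.
opls_core <- function(x, y, n_ortho, tol = 1e-10, max_iter = 500) {
  xd <- x
  p <- ncol(x)
  w <- drop(crossprod(xd, y))
  w <- w / sqrt(sum(w^2))
  t_o <- list(); p_o <- list(); w_o <- list()
  for (j in seq_len(n_ortho)) {
    t_pred <- drop(xd %*% w)
    p_load <- drop(crossprod(xd, t_pred)) / sum(t_pred^2)
    wo <- p_load - drop(crossprod(w, p_load)) * w
    nrm <- sqrt(sum(wo^2))
    if (nrm < tol) break  # no orthogonal variation left
    wo <- wo / nrm
    to <- drop(xd %*% wo)
    po <- drop(crossprod(xd, to)) / sum(to^2)
    xd <- xd - tcrossprod(to, po)
    t_o[[j]] <- to; p_o[[j]] <- po; w_o[[j]] <- wo
    w <- drop(crossprod(xd, y))
    w <- w / sqrt(sum(w^2))
  }
  # predictive NIPALS PLS1 component on the deflated matrix
  it <- 0
  repeat {
    t_pred <- drop(xd %*% w)
    w_new <- drop(crossprod(xd, y)) / sum(y^2)
    w_new <- w_new / sqrt(sum(w_new^2))
    it <- it + 1
    if (sum((w_new - w)^2) < tol^2 || it >= max_iter) {
      w <- w_new
      break
    }
    w <- w_new
  }
  t_pred <- drop(xd %*% w)
  p_pred <- drop(crossprod(xd, t_pred)) / sum(t_pred^2)
  c_pred <- sum(y * t_pred) / sum(t_pred^2)
  y_hat <- c_pred * t_pred
  r2y <- 1 - sum((y - y_hat)^2) / sum(y^2)

  comps <- c(list(list(w = w, t = t_pred)),
             lapply(seq_along(t_o), function(j) {
               list(w = w_o[[j]], t = t_o[[j]])
             }))
  ssy <- vapply(comps, function(cp) {
    ch <- sum(y * cp$t) / sum(cp$t^2)
    sum((ch * cp$t)^2)
  }, numeric(1))
  if (sum(ssy) <= 0) ssy <- rep(1 / length(ssy), length(ssy))
  wmat <- vapply(comps, `[[`, numeric(p), "w")
  vip <- sqrt(p * drop(wmat^2 %*% (ssy / sum(ssy))))
  names(vip) <- colnames(x)

  scores <- cbind(predictive = t_pred,
                  if (length(t_o)) do.call(cbind, t_o))
  if (length(t_o)) {
    colnames(scores) <- c("predictive", paste0("ortho", seq_along(t_o)))
  }
  loadings <- cbind(predictive = p_pred,
                    if (length(p_o)) do.call(cbind, p_o))
  rownames(loadings) <- colnames(x)
  # SSX explained by component c: X_hat_c = t_c p_c', so ||X_hat_c||^2 =
  # sum(t_c^2) * sum(p_c^2)
  sst <- max(sum(x^2), .Machine$double.eps)
  ve <- colSums(scores^2) * colSums(loadings^2) / sst
  list(scores = scores, loadings = loadings, weights = wmat, vip = vip,
       variance_explained = ve, r2y = r2y)
}

# Leave-one-out Q2 for the O-PLS-DA model.
oplsda_q2_loo <- function(x, y, n_ortho, tol, max_iter) {
  n <- nrow(x)
  press <- 0
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    fit <- opls_core(xt, yt - mean(yt), n_ortho, tol, max_iter)
    # project the held-out sample through the orthogonal filter
    xi <- x[i, ]
    n_used <- ncol(fit$weights) - 1L
    for (j in seq_len(n_used)) {
      wo <- fit$weights[, j + 1]
      po <- fit$loadings[, j + 1]
      xi <- xi - sum(xi * wo) * po
    }
    w <- fit$weights[, 1]
    t_new <- sum(xi * w)
    ch <- sum((yt - mean(yt)) * fit$scores[, 1]) / sum(fit$scores[, 1]^2)
    y_pred <- mean(yt) + ch * t_new
    press <- press + (y[i] - y_pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Per-metabolite differential testing between two groups
#'
#' Welch two-sample t-test on log abundances per metabolite, BH adjustment,
#' and log2 fold change of group mean abundances.
#'
#' @param mt a `MetaboliteTable`.
#' @param groups the two group labels to compare (default: the two present).
#' @return data.frame with `metabolite`, `mean_<g1>`, `mean_<g2>`,
#'   `log2_fc` (second over first), `t`, `df`, `p_value`, `adj_p`.
#' @export
differential_metabolites <- function(mt, groups = NULL) {
  stopifnot(inherits(mt, "MetaboliteTable"))
  groups <- groups %||% sort(unique(mt$groups))
  if (length(groups) != 2) stop_regenmac("exactly 2 groups required")
  sel1 <- mt$groups == groups[1]
  sel2 <- mt$groups == groups[2]
  if (sum(sel1) < 2 || sum(sel2) < 2) {
    stop_regenmac("each group needs >= 2 samples")
  }
  lx <- log(mt$abundances)
  rows <- lapply(mt$metabolite_ids, function(m) {
    a <- lx[m, sel1]
    b <- lx[m, sel2]
    tt <- stats::t.test(b, a)  # Welch by default
    data.frame(metabolite = m,
               mean_1 = mean(mt$abundances[m, sel1]),
               mean_2 = mean(mt$abundances[m, sel2]),
               log2_fc = log2(mean(mt$abundances[m, sel2]) /
                                mean(mt$abundances[m, sel1])),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  names(tbl)[names(tbl) == "mean_1"] <- paste0("mean_", groups[1])
  names(tbl)[names(tbl) == "mean_2"] <- paste0("mean_", groups[2])
  tbl$adj_p <- stats::p.adjust(tbl$p_value, method = "BH")
  rownames(tbl) <- NULL
  tbl
}
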