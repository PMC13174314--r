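make_mt <- function(n_met = 12, n_per = 4, seed = 17, effect = NULL) {
  set.seed(seed)
  mets <- sprintf("M%02d", seq_len(n_met))
  samples <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  ab <- matrix(rlnorm(n_met * 2 * n_per, meanlog = 5, sdlog = 0.3),
               nrow = n_met, dimnames = list(mets, samples))
  if (!is.null(effect)) {
    ab[names(effect), seq_len(n_per) + n_per] <-
      ab[names(effect), seq_len(n_per) + n_per] * effect
  }
  metabolite_table(ab, setNames(rep(c("a", "b"), each = n_per), samples))
}

test_that("metabolite_table validates its inputs", {
  ab <- matrix(1:4, 2, dimnames = list(c("m1", "m2"), c("s1", "s2")))
  expect_error(metabolite_table(ab - 2, c(s1 = "a", s2 = "b")), "positive")
  expect_error(metabolite_table(unname(ab), c(s1 = "a", s2 = "b")),
               "dimnames")
  expect_error(metabolite_table(ab, c(s1 = "a")), "group label")
  mt <- metabolite_table(ab, c(s2 = "b", s1 = "a"))
  expect_identical(unname(mt$groups), c("a", "b"))  # reordered to samples
})

test_that("preprocess applies the documented transform and scaling", {
  mt <- make_mt(6, 3)
  x <- preprocess(mt, transform = "log", scaling = "uv")
  manual <- t(log(mt$abundances))
  manual <- sweep(manual, 2, colMeans(manual))
  manual <- sweep(manual, 2, apply(t(log(mt$abundances)), 2, sd), `/`)
  expect_equal(unclass(x), manual, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(colMeans(x)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 6), tolerance = 1e-12)

  xp <- preprocess(mt, scaling = "pareto")
  sds <- apply(t(log(mt$abundances)), 2, sd)
  expect_equal(unname(apply(xp, 2, sd)), unname(sqrt(sds)),
               tolerance = 1e-12)

  # constant metabolites are dropped with a message
  ab <- mt$abundances
  ab["M01", ] <- 7
  mt2 <- metabolite_table(ab, mt$groups)
  expect_message(x2 <- preprocess(mt2), "constant")
  expect_identical(attr(x2, "dropped"), "M01")
  expect_false("M01" %in% colnames(x2))
})

test_that("pca reconstructs the centered matrix and matches eigenvectors", {
  mt <- make_mt(8, 5, seed = 23)
  x <- preprocess(mt)
  k <- min(dim(x))
  pc <- pca(x, k)
  xc <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(pc$scores %*% t(pc$loadings) - xc)), 1e-8)
  expect_lt(max(abs(crossprod(pc$loadings) - diag(k))), 1e-10)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  # loadings span the same axes as eigen of the covariance matrix
  ev <- eigen(cov(xc), symmetric = TRUE)$vectors
  for (j in 1:2) {
    expect_equal(abs(sum(pc$loadings[, j] * ev[, j])), 1, tolerance = 1e-8)
  }
  # collinear data puts all variance on the first component
  line <- outer(1:6, c(1, -2, 3))
  pl <- pca(line, 2)
  expect_equal(pl$variance_explained[1], 1, tolerance = 1e-12)
  expect_error(pca(x, 0), "invalid k")
})

test_that("oplsda with n_ortho = 0 equals the NIPALS PLS1 oracle", {
  mt <- make_mt(10, 4, seed = 29, effect = c(M01 = 3, M02 = 0.3))
  x <- preprocess(mt)
  fit <- oplsda(x, attr(x, "groups"), n_ortho = 0, n_perm = 0)
  y <- ifelse(attr(x, "groups") == "b", 1, -1)
  y <- y - mean(y)
  or <- oracle_pls1(x, y)
  s <- sign(sum(or$weights * fit$weights[, 1]))
  expect_lt(max(abs(fit$weights[, 1] - s * or$weights)), 1e-8)
  expect_lt(max(abs(fit$scores[, 1] - s * or$scores)), 1e-8)
  expect_lt(max(abs(fit$loadings[, 1] - s * or$loadings)), 1e-8)
})

test_that("VIP normalization and ranking behave as defined", {
  mt <- make_mt(15, 5, seed = 31, effect = c(M05 = 6))
  x <- preprocess(mt)
  fit <- oplsda(x, attr(x, "groups"), n_ortho = 1, n_perm = 0)
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-6)
  # the single planted driver carries the largest VIP
  expect_identical(names(which.max(fit$vip)), "M05")
  expect_gt(fit$r2y, 0.5)
})

test_that("oplsda permutation p and Q2 respond to real versus null signal", {
  mt <- make_mt(20, 5, seed = 37, effect = c(M01 = 8, M02 = 8, M03 = 0.12))
  x <- preprocess(mt)
  fit <- oplsda(x, attr(x, "groups"), n_ortho = 1, n_perm = 100, seed = 3)
  expect_lte(fit$perm_p, 0.05)
  expect_gte(fit$perm_p, 1 / 101)
  expect_gt(fit$q2, 0.3)
  # pure noise: permutation p is not extreme
  null_mt <- make_mt(20, 5, seed = 41)
  xn <- preprocess(null_mt)
  fit0 <- oplsda(xn, attr(xn, "groups"), n_ortho = 1, n_perm = 100, seed = 3)
  expect_gt(fit0$perm_p, 0.05)
  expect_error(oplsda(x, rep("one", nrow(x))), "2 groups")
})

test_that("differential_metabolites matches the Welch closed form", {
  ab <- matrix(exp(c(1, 2, 3, 4, 5, 6,
                     2, 2, 2, 2, 2, 2.5)), nrow = 2, byrow = TRUE,
               dimnames = list(c("mA", "mB"), paste0("s", 1:6)))
  mt <- metabolite_table(ab, setNames(rep(c("g1", "g2"), each = 3),
                                      paste0("s", 1:6)))
  res <- differential_metabolites(mt)
  # log abundances are {1,2,3} vs {4,5,6}: t = -3 / sqrt(2/3), df = 4
  row <- res[res$metabolite == "mA", ]
  expect_equal(row$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(row$df, 4, tolerance = 1e-12)
  expect_equal(row$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(row$log2_fc, log2(mean(ab["mA", 4:6]) / mean(ab["mA", 1:3])),
               tolerance = 1e-12)
  expect_equal(res$adj_p, p.adjust(res$p_value, "BH"), tolerance = 1e-12)
  expect_error(differential_metabolites(mt, groups = c("g1", "zz")))
})

test_that("planted metabolomics effects surface in the VIP ranking", {
  sm <- simulate_metabolomics(seed = 2)
  x <- preprocess(sm$table)
  fit <- oplsda(x, attr(x, "groups"), n_ortho = 1, n_perm = 0)
  planted <- sm$truth$metabolite
  top <- names(sort(fit$vip, decreasing = TRUE))[seq_len(max(10,
                                                             length(planted)))]
  expect_gte(mean(planted %in% top), 0.5)
})
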