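test_that("module_score matches the brute-force oracle", {
  em <- make_test_em(30, 40, seed = 11)
  for (seed in c(0, 7, 123)) {
    set.seed(seed + 99)
    genes <- sample(em$gene_ids, 6)
    got <- module_score(em, gene_set("s", genes), n_bins = 5, n_ctrl = 20,
                        seed = seed)
    want <- oracle_module_score(em, genes, n_bins = 5, n_ctrl = 20,
                                seed = seed)
    expect_equal(unname(got$scores), unname(want), tolerance = 1e-10)
  }
  # also at near-default parameters (bins larger than the fixture supports
  # more bins than genes per bin, exercising the with-replacement branch)
  genes <- em$gene_ids[c(2, 9, 17, 25)]
  got <- module_score(em, gene_set("s", genes), n_bins = 24, n_ctrl = 100,
                      seed = 4)
  want <- oracle_module_score(em, genes, n_bins = 24, n_ctrl = 100, seed = 4)
  expect_equal(unname(got$scores), unname(want), tolerance = 1e-10)
})

test_that("module_score nulls: whole-universe set and constant matrix", {
  em <- make_test_em(30, 20, seed = 2)
  # with n_ctrl >> bin size every bin is fully covered by the control pool,
  # so the set mean equals the control mean exactly
  all_set <- gene_set("all", em$gene_ids)
  got <- module_score(em, all_set, n_bins = 5, n_ctrl = 200, seed = 1)
  expect_equal(unname(got$scores), rep(0, 20), tolerance = 1e-12)

  const <- expression_matrix(matrix(3L, 10, 6,
                                    dimnames = list(paste0("g", 1:10),
                                                    paste0("c", 1:6))))
  const <- normalize_counts(const)
  gs <- gene_set("s", paste0("g", 1:3))
  sc <- module_score(const, gs, n_bins = 2, n_ctrl = 50, seed = 0)
  expect_equal(unname(sc$scores), rep(0, 6), tolerance = 1e-12)
})

test_that("module_score is invariant to a constant shift of the layer", {
  em <- make_test_em(25, 12, seed = 8)
  shifted <- expression_matrix(em$counts, normalized = em$normalized + 5)
  gs <- gene_set("s", em$gene_ids[c(1, 5, 20)])
  a <- module_score(em, gs, n_bins = 6, n_ctrl = 30, seed = 3)$scores
  b <- module_score(shifted, gs, n_bins = 6, n_ctrl = 30, seed = 3)$scores
  expect_equal(unname(a), unname(b), tolerance = 1e-10)
})

test_that("module_score leaves the caller's RNG stream untouched", {
  em <- make_test_em(20, 10)
  set.seed(42)
  before <- .Random.seed
  module_score(em, gene_set("s", em$gene_ids[1:4]), seed = 9)
  expect_identical(.Random.seed, before)
})

test_that("rank_markers p-values are exact for small untied groups", {
  set.seed(21)
  n1 <- 4; n2 <- 5
  norm <- matrix(runif(10 * (n1 + n2)), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 sprintf("c%02d", seq_len(n1 + n2))))
  em <- expression_matrix(matrix(1L, 10, n1 + n2,
                                 dimnames = dimnames(norm)),
                          normalized = norm)
  ann <- flat_annotations(em$obs_ids, rep(c("in", "out"), c(n1, n2)))
  mt <- rank_markers(em, ann, "in")
  for (i in 1:10) {
    expect_equal(mt$p_value[i],
                 oracle_ranksum_p(norm[i, 1:n1], norm[i, n1 + 1:n2]),
                 tolerance = 1e-12)
  }
})

test_that("a completely tied gene gets p = 1", {
  norm <- matrix(runif(3 * 8), nrow = 3,
                 dimnames = list(c("flat", "g2", "g3"), paste0("c", 1:8)))
  norm["flat", ] <- 0.5
  em <- expression_matrix(matrix(1L, 3, 8, dimnames = dimnames(norm)),
                          normalized = norm)
  ann <- flat_annotations(em$obs_ids, rep(c("a", "b"), each = 4))
  mt <- rank_markers(em, ann, "a")
  expect_equal(mt$p_value[mt$gene == "flat"], 1)
})

test_that("rank_markers requires a minimum group size", {
  em <- make_test_em(6, 5)
  ann <- flat_annotations(em$obs_ids, c("a", "a", "b", "b", "b"))
  expect_error(rank_markers(em, ann, "a"), ">= 3")
  expect_error(rank_markers(em, ann, "zz"), "absent")
})

test_that("rank_markers p-values are calibrated under the null", {
  set.seed(60)
  counts <- matrix(rpois(200 * 80, 3), nrow = 200,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("c%03d", 1:80)))
  em <- normalize_counts(expression_matrix(counts))
  ann <- flat_annotations(em$obs_ids, sample(rep(c("a", "b"), 40)))
  mt <- rank_markers(em, ann, "a")
  # under exchangeable labels the p-values must not pile up near 0
  expect_lt(mean(mt$p_value < 0.05), 0.12)
  expect_gt(mean(mt$p_value), 0.4)
  expect_lt(mean(mt$p_value), 0.65)
})

test_that("top_signature filters, orders and truncates correctly", {
  mt <- data.frame(
    gene = c("up_sig1", "up_sig2", "up_weak", "down_sig", "up_tie"),
    log_fold_change = c(2, 1, 0.5, -2, 2),
    p_value = c(1e-5, 1e-4, 0.2, 1e-6, 1e-5),
    adj_p = c(1e-4, 1e-3, 0.4, 1e-5, 1e-4),
    frac_in = 1, frac_out = 0, stringsAsFactors = FALSE)
  attr(mt, "cluster") <- "k"
  class(mt) <- c("MarkerTable", "data.frame")
  sig <- top_signature(mt, k = 10)
  # down-regulated and non-significant genes excluded; ties on adj_p and
  # lfc break by gene id
  expect_identical(sig$genes, c("up_sig1", "up_tie", "up_sig2"))
  expect_identical(sig$name, "k")
  expect_identical(top_signature(mt, k = 1)$genes, "up_sig1")
  mt$adj_p <- 0.9
  expect_error(top_signature(mt), "no genes pass")
})

test_that("planted cluster markers are recovered by the signature", {
  cfg <- default_sim_config(seed = 5, n_cells_per_group = 40)
  sim <- simulate_scrna(cfg)
  sim$em <- normalize_counts(sim$em)
  mt <- rank_markers(sim$em, sim$annotations, "inflammatory_mac")
  sig <- top_signature(mt, k = 50)
  planted <- cfg$markers$inflammatory_mac
  expect_gte(mean(planted %in% sig$genes), 0.9)
})
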