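# Minimal two-cluster expression fixture for communication scoring.
make_comm_em <- function(lig_sender = 2, lig_receiver = 0,
                         rec_receiver = 2, rec_sender = 0,
                         n_per = 20, seed = 33, extra_genes = 3) {
  set.seed(seed)
  n <- 2 * n_per
  genes <- c("Lig", "RecA", "RecB", sprintf("F%02d", seq_len(extra_genes)))
  counts <- matrix(rpois(length(genes) * n, 2), nrow = length(genes),
                   dimnames = list(genes, sprintf("c%03d", seq_len(n))))
  sender <- seq_len(n_per)
  receiver <- n_per + seq_len(n_per)
  counts["Lig", sender] <- rpois(n_per, lig_sender)
  counts["Lig", receiver] <- rpois(n_per, lig_receiver)
  counts["RecA", receiver] <- rpois(n_per, rec_receiver)
  counts["RecA", sender] <- rpois(n_per, rec_sender)
  counts["RecB", ] <- rpois(n, 2)
  counts[4, colSums(counts) == 0] <- 1
  em <- normalize_counts(expression_matrix(counts))
  ann <- flat_annotations(em$obs_ids, rep(c("snd", "rcv"), each = n_per))
  list(em = em, ann = ann)
}

lr_single <- list(list(pathway = "X", ligand = "Lig", receptors = "RecA"))

test_that("absent ligand expression gives score 0 and p 1", {
  fx <- make_comm_em(lig_sender = 0, lig_receiver = 0, seed = 1)
  res <- communication_score(fx$em, fx$ann, lr_single, n_perm = 50, seed = 2)
  row <- res$table[res$table$sender == "snd" & res$table$receiver == "rcv", ]
  expect_equal(row$score, 0)
  expect_equal(row$p, 1)
})

test_that("planted directional signaling is detected at the permutation floor", {
  fx <- make_comm_em(lig_sender = 8, lig_receiver = 0,
                     rec_receiver = 8, rec_sender = 0, seed = 7)
  n_perm <- 200
  res <- communication_score(fx$em, fx$ann, lr_single, n_perm = n_perm,
                             seed = 3)
  tbl <- res$table
  fwd <- tbl[tbl$sender == "snd" & tbl$receiver == "rcv", ]
  expect_gt(fwd$score, 0)
  expect_equal(fwd$p, 1 / (n_perm + 1))
  # p-values respect the add-one permutation floor everywhere
  expect_true(all(tbl$p >= 1 / (n_perm + 1)))
  expect_true(all(tbl$p <= 1))
})

test_that("receptor complexes use AND semantics and min_frac gates", {
  fx <- make_comm_em(lig_sender = 8, rec_receiver = 8, seed = 9)
  # complex with one silent subunit scores 0 (min over members, gated)
  x <- as.matrix(fx$em$normalized)
  silent <- list(list(pathway = "X", ligand = "Lig",
                      receptors = c("RecA", "F01")))
  fx$em$normalized["F01", ] <- 0
  res <- communication_score(fx$em, fx$ann, silent, n_perm = 20, seed = 1)
  expect_true(all(res$table$score == 0))
  # a high-mean ligand expressed by too few cells is gated off
  fx2 <- make_comm_em(lig_sender = 0, rec_receiver = 8, seed = 10)
  norm <- as.matrix(fx2$em$normalized)
  norm["Lig", 1] <- 50  # one expressing sender cell: fraction 0.05 < 0.1
  fx2$em <- expression_matrix(fx2$em$counts, normalized = norm)
  res2 <- communication_score(fx2$em, fx2$ann, lr_single, min_frac = 0.1,
                              n_perm = 20, seed = 1)
  fwd <- res2$table[res2$table$sender == "snd" & res2$table$receiver == "rcv", ]
  expect_equal(fwd$score, 0)
})

test_that("pairs with absent genes are skipped with a message", {
  fx <- make_comm_em()
  db <- c(lr_single, list(list(pathway = "Y", ligand = "Nope",
                               receptors = "RecA")))
  expect_message(res <- communication_score(fx$em, fx$ann, db, n_perm = 10,
                                            seed = 1), "skipped 1")
  expect_length(res$skipped, 1)
  only_bad <- list(list(pathway = "Y", ligand = "Nope", receptors = "RecA"))
  expect_error(suppressMessages(
    communication_score(fx$em, fx$ann, only_bad, n_perm = 10, seed = 1)),
    "no LR pair")
})

test_that("permutation p-values are calibrated under the null", {
  # exchangeable labels: rejection rate at alpha = 0.05 stays near 0.05
  n_reps <- 200
  n_perm <- 99
  rejected <- 0L
  for (rep_i in seq_len(n_reps)) {
    set.seed(1000 + rep_i)
    n <- 40
    counts <- matrix(rpois(4 * n, 3), nrow = 4,
                     dimnames = list(c("Lig", "RecA", "F1", "F2"),
                                     sprintf("c%03d", 1:n)))
    counts[3, colSums(counts) == 0] <- 1
    em <- normalize_counts(expression_matrix(counts))
    ann <- flat_annotations(em$obs_ids, sample(rep(c("a", "b"), n / 2)))
    res <- communication_score(em, ann, lr_single, senders = "a",
                               receivers = "b", n_perm = n_perm,
                               seed = rep_i)
    if (res$table$p <= 0.05) rejected <- rejected + 1L
  }
  rate <- rejected / n_reps
  # binomial(200, 0.05): 3 standard deviations is about 0.046
  expect_gt(rate, 0.003)
  expect_lt(rate, 0.11)
})

test_that("differential_ligands ranks the planted condition difference", {
  cfg <- default_sim_config(seed = 4, n_cells_per_group = 25)
  sim <- simulate_scrna(cfg)
  sim$em <- normalize_counts(sim$em)
  dl <- differential_ligands(sim$em, sim$annotations,
                             ligands = c("Bmp2", "Bmp4", "Bmp5", "Tnf"),
                             clusters = "inflammatory_mac")
  bmp <- dl[dl$ligand %in% c("Bmp2", "Bmp4", "Bmp5"), ]
  tnf <- dl[dl$ligand == "Tnf", ]
  expect_true(all(bmp$difference > 0))   # higher in P3
  expect_true(all(tnf$difference < 0))   # higher in P2
  expect_true(all(bmp$adj_p < 0.05))
  expect_message(
    differential_ligands(sim$em, sim$annotations,
                         ligands = c("Bmp2", "NotAGene")), "skipped 1")
  expect_error(differential_ligands(sim$em, sim$annotations,
                                    conditions = "P3", ligands = "Bmp2"),
               "two conditions")
})

test_that("pathway_network applies BH within pathway and condition", {
  tbl <- data.frame(
    pathway = "BMP", ligand = "Bmp2", receptors = "R",
    sender = c("a", "a", "b"), receiver = c("b", "c", "c"),
    condition = "P3", score = c(5, 4, 0.1),
    p = c(0.001, 0.02, 0.9),
    expressed_frac_ligand = 1, expressed_frac_receptor = 1,
    stringsAsFactors = FALSE)
  comm <- structure(list(table = tbl, skipped = character(0)),
                    class = "CommResult")
  net <- pathway_network(comm, "BMP", alpha = 0.05)
  expect_equal(nrow(net), 2)
  expect_equal(net$adj_p, p.adjust(tbl$p, "BH")[1:2], tolerance = 1e-12)
  empty <- pathway_network(comm, "WNT")
  expect_equal(nrow(empty), 0)
  expect_true(is.character(empty$sender) && is.numeric(empty$adj_p))
})
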