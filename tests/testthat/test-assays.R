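# Deterministic mito-stress-test toy trace: baseline 100, oligomycin 60,
# FCCP phase peaking at 200, rot/AA 20.
make_stress_trace <- function() {
  inj <- data.frame(time = c(20, 40, 60),
                    agent = c("oligomycin", "FCCP", "rot/AA"))
  times <- c(5, 10, 15, 25, 30, 35, 45, 50, 55, 65, 70, 75)
  values <- c(100, 100, 100, 60, 60, 60, 190, 200, 195, 20, 20, 20)
  rate_trace("w1", "ctrl", times, values, inj)
}

test_that("rate_trace validates times and injections", {
  expect_error(rate_trace("w", "g", c(1, 2, 2), c(1, 2, 3)), "increasing")
  expect_error(rate_trace("w", "g", 1:3, 1:2), "lengths differ")
  expect_error(rate_trace("w", "g", 1:3, 1:3,
                          data.frame(time = 5, agent = "x")), "after last")
  expect_error(rate_trace("w", "g", 2:4, 1:3,
                          data.frame(time = 1, agent = "x")),
               "before first")
})

test_that("phase segmentation splits at injection times (half-open)", {
  tr <- make_stress_trace()
  seg <- phase_segment(tr)
  expect_equal(as.vector(table(seg$phase)), rep(3L, 4))
  expect_identical(levels(seg$phase),
                   c("baseline", "oligomycin", "FCCP", "rot/AA"))
  # a measurement exactly at an injection time joins the post phase
  tr2 <- rate_trace("w", "g", c(0, 10, 20, 30), c(1, 2, 3, 4),
                    data.frame(time = 10, agent = "x"))
  seg2 <- phase_segment(tr2)
  expect_identical(as.character(seg2$phase), c("baseline", "x", "x", "x"))
  # duplicate agents get unique phase labels
  tr3 <- rate_trace("w", "g", seq(0, 50, 10), rep(1, 6),
                    data.frame(time = c(15, 35), agent = c("a", "a")))
  expect_identical(levels(phase_segment(tr3)$phase),
                   c("baseline", "a", "a.1"))
})

test_that("flux metrics match hand-computed values", {
  tr <- make_stress_trace()
  basal <- basal_rate(tr)
  expect_equal(as.numeric(basal), 100 - 20)
  expect_true(attr(basal, "corrected"))
  maximal <- maximal_rate(tr)
  expect_equal(as.numeric(maximal), 200 - 20)
  expect_equal(percent_change_post_injection(tr, "oligomycin"),
               100 * (60 - 100) / 100)
  # without rot/AA the basal rate is uncorrected
  tr_nr <- rate_trace("w", "g", c(1, 2, 3, 5, 6), c(90, 100, 110, 80, 80),
                      data.frame(time = 4, agent = "etomoxir"))
  b <- basal_rate(tr_nr)
  expect_equal(as.numeric(b), 100)
  expect_false(attr(b, "corrected"))
  expect_error(maximal_rate(tr_nr), "FCCP")
  expect_error(percent_change_post_injection(tr, "saline"), "not injected")
})

test_that("percent change is invariant to rescaling the trace", {
  tr <- make_stress_trace()
  tr_scaled <- rate_trace("w1", "ctrl", tr$time, tr$value * 3.7,
                          tr$injections)
  expect_equal(percent_change_post_injection(tr, "FCCP"),
               percent_change_post_injection(tr_scaled, "FCCP"),
               tolerance = 1e-12)
})

test_that("basal_rate uses only the last baseline cycles", {
  tr <- rate_trace("w", "g", 1:6, c(500, 90, 100, 110, 30, 30),
                   data.frame(time = 4.5, agent = "rot/AA"))
  expect_equal(as.numeric(basal_rate(tr, n_baseline_cycles = 3)),
               mean(c(90, 100, 110)) - 30)
})

test_that("group_compare matches t.test and orders Dunnett sanely", {
  vals <- list(ctrl = c(10, 11, 12, 9), hi = c(20, 21, 19, 22),
               mid = c(14, 15, 16, 15))
  res <- group_compare(vals, dunnett_control = "ctrl")
  ref <- t.test(vals$ctrl, vals$hi)
  row <- res$welch[res$welch$group_1 == "ctrl" & res$welch$group_2 == "hi", ]
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(nrow(res$welch), 3)
  expect_equal(nrow(res$dunnett), 2)
  expect_true(all(res$dunnett$adj_p < 0.05))
  est <- res$dunnett$estimate[grepl("^hi", res$dunnett$comparison)]
  expect_equal(est, mean(vals$hi) - mean(vals$ctrl), tolerance = 1e-8)
  expect_error(group_compare(vals, dunnett_control = "zz"), "not found")
  expect_error(group_compare(list(a = 1, b = c(1, 2))), "n >= 2")
  # degenerate constant groups
  const <- group_compare(list(a = c(2, 2), b = c(2, 2), c = c(3, 3)))
  ab <- const$welch[const$welch$group_1 == "a" & const$welch$group_2 == "b", ]
  expect_equal(ab$p_value, 1)
  ac <- const$welch[const$welch$group_1 == "a" & const$welch$group_2 == "c", ]
  expect_equal(ac$p_value, 0)
})

test_that("ddcq matches the 2^dCq closed form and flags bad replicates", {
  cq <- data.frame(
    sample = rep(c("s1", "s2"), each = 4),
    gene = rep(c("B2M", "B2M", "Tgt", "Tgt"), 2),
    cq = c(20, 20, 20, 20,    # s1: target == housekeeping
           20, 20, 19, 19))   # s2: target one cycle earlier
  res <- ddcq(cq, housekeeping = "B2M")
  expect_equal(res$rel_expr[res$sample == "s1"], 1, tolerance = 1e-12)
  expect_equal(res$rel_expr[res$sample == "s2"], 2, tolerance = 1e-12)
  # a global Cq shift cancels out
  cq2 <- cq; cq2$cq <- cq2$cq + 3
  expect_equal(ddcq(cq2, "B2M")$rel_expr, res$rel_expr, tolerance = 1e-12)
  # replicate scatter above the CV threshold is flagged
  cq3 <- data.frame(sample = "s1", gene = c("B2M", "B2M", "Tgt", "Tgt"),
                    cq = c(20, 20, 15, 25))
  expect_true(ddcq(cq3, "B2M")$flag)
  expect_error(ddcq(data.frame(sample = "s", gene = "Tgt", cq = 50), "B2M"),
               "0, 45")
  expect_error(ddcq(cq[cq$gene != "B2M", ], "B2M"), "housekeeping")
})

test_that("trace CSVs round-trip through read_traces", {
  params <- list(g1 = list(basal = 100, mult = c(etomoxir = 0.7)))
  sim <- simulate_traces(params, n_wells = 3, seed = 8)
  dir <- withr::local_tempdir()
  rows <- do.call(rbind, lapply(sim$traces, function(tr) {
    data.frame(well = tr$well, group = tr$group, time_min = tr$time,
               value = tr$value, stringsAsFactors = FALSE)
  }))
  write.csv(rows, file.path(dir, "traces.csv"), row.names = FALSE)
  write.csv(data.frame(time_min = 14, agent = "etomoxir"),
            file.path(dir, "inj.csv"), row.names = FALSE)
  back <- read_traces(file.path(dir, "traces.csv"), file.path(dir, "inj.csv"))
  expect_length(back, 3)
  orig <- sim$traces[[1]]
  got <- back[[orig$well]]
  expect_equal(got$value, orig$value, tolerance = 1e-9)
  expect_equal(flux_metrics(back, "etomoxir")$basal,
               flux_metrics(sim$traces, "etomoxir")$basal,
               tolerance = 1e-9)
})

test_that("saline injections leave rates unchanged", {
  params <- list(a = list(basal = 100, mult = c(saline = 1)),
                 b = list(basal = 100, mult = c(saline = 1)))
  sim <- simulate_traces(params, n_wells = 10,
                         injections = data.frame(time = 14,
                                                 agent = "saline"),
                         noise_sd = 4, seed = 21)
  m <- flux_metrics(sim$traces, percent_change_agent = "saline")
  expect_lt(max(abs(tapply(m$percent_change, m$group, mean))), 5)
  cmp <- group_compare(split(m$percent_change, m$group))
  expect_gt(cmp$welch$p_value, 0.01)
})
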