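test_that("no selection means no realized gain", {
  p <- mix_params()
  d <- scheme_design(900, 3, selection_rate = 1)
  mc <- simulate_cycle(p, d, "srma", c(1, 1), n_replicates = 200, seed = 3)
  for (q in c("after_dG_total", "before_dG_total")) {
    expect_within_3se(mc$means[[q]], mc$se[[q]], 0, q)
  }
})

test_that("simulated pair criterion variance matches the closed form over
           50,000 pairs", {
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = -0.5)
  d <- scheme_design(150000, 3, 0.10)  # 50,000 pairs per replicate
  mc <- simulate_cycle(p, d, "srma", c(1, 1), n_replicates = 5, seed = 2)
  expect_within_3se(mc$means[["crit_var"]], mc$se[["crit_var"]],
                    srma_criterion_variance(p, c(1, 1), 3), "crit_var")
})

test_that("fixture tables are tidy, additive and reproducible", {
  p <- mix_params()
  d2 <- scheme_design(2, 1, 0.5)
  fx <- generate_fixture(p, d2, "srma", seed = 9)
  expect_identical(nrow(fx), 2L)
  expect_equal(fx$y, fx$x1 + fx$x2, tolerance = 1e-12)
  expect_identical(fx, generate_fixture(p, d2, "srma", seed = 9))

  d <- basic_design("sgma")
  fs <- generate_fixture(p, d, "sgma", seed = 9)
  expect_identical(nrow(fs), 2L * 150L * 3L)
  expect_setequal(unique(fs$process), c(1L, 2L))
  expect_equal(fs$y, fs$x1 + fs$x2, tolerance = 1e-12)

  pp <- mix_params(eta = 0.5, omega = 0.25, h2 = 0.6)
  fp <- generate_fixture(pp, basic_design("pure"), "pure", seed = 9)
  expect_true(all(is.na(fp$x2)))
  # family-mean variance of the pure-stand observations reflects h2 = 0.6
  ym <- tapply(fp$y[fp$process == 1], fp$candidate_1[fp$process == 1], mean)
  expect_lt(abs(stats::var(ym) - 1 / 0.6), 3 * (1 / 0.6) * sqrt(2 / 149))
})

test_that("realized parallel-scheme gains match the closed forms within
           3 SE", {
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = -0.5)
  d <- basic_design("sgma")
  mc <- simulate_cycle(p, d, "sgma", c(1, 1), n_replicates = 500, seed = 1)
  ctr <- mc_centering(mc$tested, mc$selected, d$selection_rate)
  g <- sgma_cumulated(p, d, c(1, 1))
  expect_within_3se(mc$means[["after_dG_total"]], mc$se[["after_dG_total"]],
                    ctr * g$dG_total, "cumulated total")
  expect_within_3se(mc$means[["dG_x11"]], mc$se[["dG_x11"]],
                    ctr * g$by_process$dG_x11, "process-1 own gain")
  expect_within_3se(mc$means[["dG_x21"]], mc$se[["dG_x21"]],
                    ctr * g$by_process$dG_x21, "process-1 companion gain")
})

test_that("realized pair-scheme gains and the recombination gap match the
           closed forms within 3 SE", {
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = 0)
  d <- basic_design("srma")
  mc <- simulate_cycle(p, d, "srma", c(1, 1), n_replicates = 500, seed = 1)
  ctr <- mc_centering(mc$tested, mc$selected, d$selection_rate)
  a <- srma_responses_after(p, d, c(1, 1))
  b <- srma_responses_before(p, d, c(1, 1))
  expect_within_3se(mc$means[["after_dG_x1"]], mc$se[["after_dG_x1"]],
                    ctr * a$dG_x1, "after x1")
  expect_within_3se(mc$means[["after_dG_total"]], mc$se[["after_dG_total"]],
                    ctr * a$dG_total, "after total")
  # realized (before - after) gap: the non-heritable interaction mean
  gap <- mc$replicates[, "before_dG_total"] - mc$replicates[, "after_dG_total"]
  expect_within_3se(mean(gap), stats::sd(gap) / sqrt(length(gap)),
                    ctr * (b$dG_total - a$dG_total), "recombination gap")
})

test_that("realized pure-stand gains match the closed forms within 3 SE", {
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = 0,
                  eta = 0.5, omega = 0.3, h2 = 0.6)
  d <- basic_design("pure")
  mc <- simulate_cycle(p, d, "pure", n_replicates = 500, seed = 1)
  ctr <- mc_centering(mc$tested, mc$selected, d$selection_rate)
  r <- pure_stand_responses(p, d)
  expect_within_3se(mc$means[["after_dG_total"]], mc$se[["after_dG_total"]],
                    ctr * r$dG_total, "pure total")
})

test_that("changing the seed changes the draws but not the agreement", {
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = -0.5)
  d <- basic_design("sgma")
  g <- sgma_cumulated(p, d, c(1, 1))
  mc_a <- simulate_cycle(p, d, "sgma", c(1, 1), n_replicates = 300, seed = 10)
  mc_b <- simulate_cycle(p, d, "sgma", c(1, 1), n_replicates = 300, seed = 20)
  expect_false(identical(mc_a$means, mc_b$means))
  ctr <- mc_centering(mc_a$tested, mc_a$selected, d$selection_rate)
  for (mc in list(mc_a, mc_b)) {
    expect_within_3se(mc$means[["after_dG_total"]], mc$se[["after_dG_total"]],
                      ctr * g$dG_total, "cumulated total")
  }
})

test_that("a non-realizable pure-stand correlation structure is refused", {
  p <- mix_params(rho = -0.75, eta = 0.75, omega = 0.5, h2 = 0.6)
  expect_error(simulate_cycle(p, basic_design("pure"), "pure",
                              n_replicates = 2, seed = 1),
               "positive definite")
})
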