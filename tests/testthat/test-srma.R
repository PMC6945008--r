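test_that("conservation and label symmetry hold for pair-mixture responses", {
  d <- basic_design("srma")
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = 0)
  a <- srma_responses_after(p, d, c(1, 1))
  expect_equal(a$dG_x1, a$dG_x2, tolerance = 1e-12)
  b <- srma_responses_before(p, d, c(1, 1))
  expect_equal(b$dG_x1, b$dG_x2, tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:20) {
    q <- random_params()
    w <- stats::runif(2, -1, 2)
    if (all(w == 0)) w <- c(1, 1)
    for (r in list(srma_responses_after(q, d, w),
                   srma_responses_before(q, d, w))) {
      expect_equal(r$dG_total, r$dG_x1 + r$dG_x2, tolerance = 1e-12)
    }
  }
})

test_that("responses are invariant under joint positive rescaling of the
           weights", {
  d <- basic_design("srma")
  p <- mix_params(sa1 = 0.5, sa2 = 0.1, rho = -0.5)
  a1 <- srma_responses_after(p, d, c(1, 0.7))
  a2 <- srma_responses_after(p, d, 3.2 * c(1, 0.7))
  expect_equal(a1$dG_x1, a2$dG_x1, tolerance = 1e-12)
  expect_equal(a1$dG_x2, a2$dG_x2, tolerance = 1e-12)
})

test_that("the before/after gap equals the non-heritable interaction part", {
  d <- basic_design("srma")
  i <- selection_intensity(d$selection_rate)
  set.seed(31)
  for (rep in 1:10) {
    q <- random_params()
    dq <- derive_components(q)
    sd_y <- sqrt(srma_criterion_variance(q, c(1, 1), d$replicates))
    b <- srma_responses_before(q, d, c(1, 1))
    a <- srma_responses_after(q, d, c(1, 1))
    expect_equal(b$dG_x1 - a$dG_x1,
                 i * (q$var_va_12 + dq$cov_va12_va21) / sd_y,
                 tolerance = 1e-9)
    expect_equal(b$dG_x2 - a$dG_x2,
                 i * (q$var_va_21 + dq$cov_va12_va21) / sd_y,
                 tolerance = 1e-9)
    expect_equal(b$dG_total - a$dG_total, i * dq$var_sma / sd_y,
                 tolerance = 1e-9)
  }
  # no interactions: candidate gains are fully heritable
  p0 <- mix_params(va12 = 0, va21 = 0)
  expect_equal(srma_responses_before(p0, d, c(1, 1))$dG_total,
               srma_responses_after(p0, d, c(1, 1))$dG_total,
               tolerance = 1e-12)
})

test_that("with no associate or interaction variance the pair scheme reduces
           to two-trait truncation selection", {
  d <- basic_design("srma")
  p <- mixture_params(species_params(1, 0), species_params(0.5, 0),
                      var_plot_error_mixture = 2)
  a <- srma_responses_after(p, d, c(1, 1))
  sd_I <- sqrt(1 + 0.5 + 2 / 3)
  expect_equal(a$dG_total, selection_intensity(0.1) * (1 + 0.5) / sd_I,
               tolerance = 1e-12)
})

test_that("index solving meets the target ratio before recombination", {
  d <- basic_design("srma")
  # diagonal system: no genetic covariance between the contributions
  p0 <- mixture_params(species_params(1, 0.4, 0), species_params(0.8, 0.2, 0),
                       var_va_12 = 0.1, var_va_21 = 0.2, rho_va12_va21 = 0,
                       var_plot_error_mixture = 2)
  dc0 <- derive_components(p0)
  w0 <- solve_srma_index(p0, c(2, 1))
  expect_equal(w0$alpha_1, 2 / dc0$var_Gx1, tolerance = 1e-12)
  expect_equal(w0$alpha_2, 1 / dc0$var_Gx2, tolerance = 1e-12)

  # asymmetric interaction setting: exact ratio before, near-but-not-exact
  # after recombination
  p <- mix_params(sa1 = 0.5, sa2 = 0.1, rho = -0.5)
  expect_equal(p$var_va_12, 0.05)
  expect_equal(p$var_va_21, 0.25)
  w <- solve_srma_index(p, c(1, 1))
  b <- srma_responses_before(p, d, w)
  expect_equal(b$dG_x1 / b$dG_x2, 1, tolerance = 1e-9)
  a <- srma_responses_after(p, d, w)
  ratio_after <- a$dG_x1 / a$dG_x2
  expect_false(isTRUE(all.equal(ratio_after, 1, tolerance = 1e-9)))
  expect_lt(abs(ratio_after - 1), 0.5)

  # equal interaction variances and equal contribution variances: the solved
  # weights coincide, the gap terms match, and the after ratio is exactly 1
  ps <- mix_params(sa1 = 0.6, sa2 = 0.8, rho = -0.25, va12 = 0.2, va21 = 0.2,
                   sv1 = 1, sv2 = 1.2)
  ws <- solve_srma_index(ps, c(1, 1))
  expect_equal(ws$alpha_1, ws$alpha_2, tolerance = 1e-12)
  as_ <- srma_responses_after(ps, d, ws)
  expect_equal(as_$dG_x1 / as_$dG_x2, 1, tolerance = 1e-9)

  # symmetric parameters with a symmetric target give equal weights
  psym <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = -0.5)
  wsym <- solve_srma_index(psym, c(1, 1))
  expect_equal(wsym$alpha_1, wsym$alpha_2, tolerance = 1e-12)

  set.seed(41)
  for (rep in 1:10) {
    q <- random_params()
    k <- stats::runif(2, 0.2, 2)
    wq <- suppressWarnings(solve_srma_index(q, k))
    bq <- srma_responses_before(q, d, wq)
    expect_equal(bq$dG_x1 / bq$dG_x2, k[1] / k[2], tolerance = 1e-9)
  }
})

test_that("a singular contribution covariance matrix is reported as
           unsolvable", {
  # contributions perfectly correlated: v and a swap roles exactly
  p <- mixture_params(species_params(1, 1, rho_va = 1),
                      species_params(1, 1, rho_va = 1),
                      var_plot_error_mixture = 2)
  expect_error(solve_srma_index(p, c(1, 1)), "singular|unsolvable")
})
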