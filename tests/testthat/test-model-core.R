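test_that("derived variance components follow the GMA/SMA decomposition", {
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = -0.5)
  dc <- derive_components(p)
  # g = v + a: 1 + 0.5 + 2*(-0.5)*sqrt(0.5)
  expect_equal(dc$var_gma_1, 1.5 - sqrt(0.5), tolerance = 1e-12)
  expect_equal(dc$var_gma_2, dc$var_gma_1, tolerance = 1e-12)
  # d = (va)12 + (va)21: 0.25 + 0.25 + 2*(-0.5)*0.25
  expect_equal(dc$var_sma, 0.25, tolerance = 1e-12)
  expect_equal(dc$var_Gx1, 1 + 0.5 + 0.25, tolerance = 1e-12)
  expect_lte(abs(dc$cov_Gx1_Gx2), sqrt(dc$var_Gx1 * dc$var_Gx2))
})

test_that("a zero variance silences its correlation and the covariance", {
  p <- mixture_params(species_params(1, 0, rho_va = 0.9),
                      species_params(1, 0.5),
                      var_plot_error_mixture = 1)
  dc <- derive_components(p)
  expect_identical(dc$cov_v1_a1, 0)
  expect_equal(dc$var_gma_1, 1)
})

test_that("invalid parameters are rejected with the field named", {
  expect_error(species_params(-1, 0.5), "var_direct")
  expect_error(species_params(1, 0.5, rho_va = 1.2), "rho_va")
  expect_error(species_params(1, 0.5, pure_design_h2 = 0), "pure_design_h2")
  expect_error(mixture_params(species_params(1, 0.5), species_params(1, 0.5),
                              var_va_12 = -0.1), "var_va_12")
  expect_error(
    mixture_params(species_params(1, 0.5), species_params(1, 0.5),
                   var_plot_error_mixture = 2,
                   var_e1 = 1, var_e2 = 1, rho_e1_e2 = 0.5),
    "does not recompose")
})

test_that("default error split reproduces the mixture plot-error variance", {
  p <- mix_params()
  expect_equal(p$var_e1 + p$var_e2 +
                 2 * p$rho_e1_e2 * sqrt(p$var_e1 * p$var_e2),
               p$var_plot_error_mixture, tolerance = 1e-12)
  expect_equal(p$rho_e1_e2, -0.5)
})

test_that("JSON configs round-trip and unknown keys are rejected", {
  cfg <- list(
    species1 = list(var_direct = 1, var_associate = 0.5, rho_va = -0.5),
    species2 = list(var_direct = 1, var_associate = 0.1, rho_va = -0.5),
    var_va_12 = 0.05, var_va_21 = 0.25, rho_va12_va21 = -0.5,
    var_plot_error_mixture = 2
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  p <- read_mixture_params(path)
  expect_s3_class(p, "mixture_params")
  expect_equal(p$species2$var_associate, 0.1)

  cfg$rho_va21_va12 <- 0.3
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_mixture_params(path), "rho_va21_va12")
})

test_that("pair-index variance matches the quadratic form and its unit-weight
           identity", {
  p <- mix_params()
  v <- srma_criterion_variance(p, c(1, 1), replicates = 3)
  dc <- derive_components(p)
  expect_equal(v, dc$var_gma_1 + dc$var_gma_2 + dc$var_sma + 2 / 3,
               tolerance = 1e-12)
  expect_equal(v, 1.8357864 + 2 / 3, tolerance = 1e-6)

  set.seed(11)
  for (rep in 1:20) {
    q <- random_params()
    M <- sample(1:6, 1)
    dq <- derive_components(q)
    expect_equal(srma_criterion_variance(q, c(1, 1), M),
                 dq$var_gma_1 + dq$var_gma_2 + dq$var_sma +
                   q$var_plot_error_mixture / M,
                 tolerance = 1e-12)
    # positive homogeneity of degree 2 in the weights, error terms included
    w <- stats::runif(2, -1.5, 1.5)
    if (all(w == 0)) w <- c(1, 0.2)
    cc <- stats::runif(1, 0.1, 3)
    expect_equal(srma_criterion_variance(q, cc * w, M),
                 cc^2 * srma_criterion_variance(q, w, M),
                 tolerance = 1e-9)
    expect_equal(sgma_criterion_variance(q, cc * w, M, 1),
                 cc^2 * sgma_criterion_variance(q, w, M, 1),
                 tolerance = 1e-9)
  }
})

test_that("process-index variance covers the unit, own-only and
           large-replication cases", {
  p <- mix_params()
  dc <- derive_components(p)
  expect_equal(sgma_criterion_variance(p, c(1, 1), 3, 1),
               dc$var_gma_1 + 2 / 3, tolerance = 1e-12)
  expect_equal(sgma_criterion_variance(p, c(1, 1), 3, 1), 1.45956,
               tolerance = 1e-5)
  # own-contribution index: direct variance plus its own error share
  expect_equal(sgma_criterion_variance(p, c(1, 0), 3, 1),
               1 + p$var_e1 / 3, tolerance = 1e-12)
  # error term vanishes with replication
  expect_equal(sgma_criterion_variance(p, c(1, 1), 1e9, 1),
               dc$var_gma_1, tolerance = 1e-6)
})

test_that("design heritabilities hit the worked-example values", {
  p <- mix_params(sa1 = 0.5, sa2 = 0.5, rho = -0.5)
  d <- basic_design("srma")
  expect_equal(round(design_heritability(p, d, "srma"), 2), 0.73)
  expect_equal(round(design_heritability(p, basic_design("sgma"), "sgma"), 2),
               0.54)
  # no plot error: heritability 1 under both designs
  p0 <- mix_params(var_eps = 0, rho_e = 0)
  expect_equal(design_heritability(p0, d, "srma"), 1, tolerance = 1e-12)
  expect_equal(design_heritability(p0, d, "sgma"), 1, tolerance = 1e-12)
})

test_that("a fully degenerate model is flagged before any response divides
           by the criterion sd", {
  p <- mixture_params(species_params(0, 0), species_params(0, 0),
                      var_plot_error_mixture = 0)
  expect_error(srma_criterion_variance(p, c(1, 1), 3), "degenerate")
})
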