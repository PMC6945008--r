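# standard parameter point used across the suite: unit direct variances,
# plot error 2, interaction variances half the companion associate variance,
# one shared rho for all three correlations, symmetric error split
mix_params <- function(sa1 = 0.5, sa2 = 0.5, rho = -0.5,
                       va12 = sa2 / 2, va21 = sa1 / 2,
                       var_eps = 2, rho_e = -0.5,
                       eta = NA_real_, omega = NA_real_, h2 = NA_real_,
                       sv1 = 1, sv2 = 1) {
  ve <- var_eps / (2 + 2 * rho_e)
  mixture_params(
    species1 = species_params(sv1, sa1, rho_va = rho, eta = eta,
                              omega = omega, pure_design_h2 = h2),
    species2 = species_params(sv2, sa2, rho_va = rho, eta = eta,
                              omega = omega, pure_design_h2 = h2),
    var_va_12 = va12, var_va_21 = va21, rho_va12_va21 = rho,
    var_plot_error_mixture = var_eps,
    var_e1 = ve, var_e2 = ve, rho_e1_e2 = rho_e
  )
}

# random valid parameter set for property-style loops
random_params <- function() {
  rho <- stats::runif(3, -0.9, 0.9)
  mixture_params(
    species1 = species_params(stats::runif(1, 0.2, 2),
                              stats::runif(1, 0, 1.5), rho[1]),
    species2 = species_params(stats::runif(1, 0.2, 2),
                              stats::runif(1, 0, 1.5), rho[2]),
    var_va_12 = stats::runif(1, 0, 0.6),
    var_va_21 = stats::runif(1, 0, 0.6),
    rho_va12_va21 = rho[3],
    var_plot_error_mixture = stats::runif(1, 0.5, 4)
  )
}

# centering factor for Monte-Carlo bands: the simulator truncates the top k
# of a finite candidate set, whose exact expected intensity is slightly
# below the infinite-population value used by the closed forms
mc_centering <- function(n, k, rate) {
  finite_selection_intensity(n, k) / selection_intensity(rate)
}

expect_within_3se <- function(mc_mean, mc_se, expected, label = "quantity") {
  expect_lt(abs(mc_mean - expected), 3 * mc_se,
            label = sprintf("%s: |%g - %g| vs 3*SE = %g",
                            label, mc_mean, expected, 3 * mc_se))
}
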