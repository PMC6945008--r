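#' Pure-stand selection criterion
#'
#' The criterion of pure-stand selection is the family-mean pure-stand
#' performance; its variance is the genetic variance divided by the design
#' heritability, so the criterion standard deviation is
#' `sqrt(var_genetic / design_h2)`. The design heritability absorbs the
#' pure-stand plot-error variance and the number of pure-stand replicates.
#'
#' @param var_genetic Genetic variance of the pure-stand family effect.
#' @param design_h2 Design heritability in (0, 1].
#' @return A list of class `pure_stand_criterion` with `var_genetic`,
#'   `design_h2` and `criterion_sd`.
#' @export
pure_stand_criterion <- function(var_genetic, design_h2) {
  check_var(var_genetic, "var_genetic")
  if (is.na(design_h2) || design_h2 <= 0 || design_h2 > 1) {
    stop("design_h2 must be in (0, 1]", call. = FALSE)
  }
  structure(list(var_genetic = var_genetic,
                 design_h2 = design_h2,
                 criterion_sd = sqrt(var_genetic / design_h2)),
            class = "pure_stand_criterion")
}

#' Build a design heritability from its components
#'
#' Alternate constructor deriving `design_h2` from the genetic variance, the
#' pure-stand plot-error variance and the number of pure-stand replicates:
#' `h2 = var_genetic / (var_genetic + var_plot_error / replicates)`.
#'
#' @param var_genetic Genetic variance of the pure-stand family effect.
#' @param var_plot_error Pure-stand plot-error variance.
#' @param replicates Number of pure-stand observations per family.
#' @return A [pure_stand_criterion()] object.
#' @export
pure_stand_criterion_from_trial <- function(var_genetic, var_plot_error,
                                            replicates) {
  check_var(var_plot_error, "var_plot_error")
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (var_genetic <= 0) {
    stop("var_genetic must be positive to define a heritability",
         call. = FALSE)
  }
  h2 <- var_genetic / (var_genetic + var_plot_error / replicates)
  pure_stand_criterion(var_genetic, h2)
}

#' Correlative responses in mixture expected from parallel pure-stand
#' selections
#'
#' Both species are improved by ordinary pure-stand recurrent selection; the
#' gains their next-cycle progeny families would express in mixture are
#' correlative responses driven by the covariances of the pure-stand effect
#' `p` with the mixture direct and associate effects:
#' \deqn{\Delta G_{x1,1} = \frac{\theta'_1\varphi_1 i_p}{\sigma_{y_p}}
#'   \mathrm{Cov}(p_1, v_1), \qquad
#'   \Delta G_{x2,1} = \frac{\theta'_1\varphi_1 i_p}{\sigma_{y_p}}
#'   \mathrm{Cov}(p_1, a_1)}
#' with `Cov(p, v) = eta * sigma_p * sigma_v` and
#' `Cov(p, a) = omega * sigma_p * sigma_a`; the species-2 process mirrors
#' this, and responses cumulate over the two processes as in the parallel
#' mixture-ability scheme. Since `sigma_p / sigma_yp = sqrt(design_h2)`, the
#' pure-stand genetic variance cancels and only the design heritability and
#' the correlations matter. The direct-associate correlations `rho_va` never
#' enter these covariances.
#'
#' @param params A [mixture_params()] object; both species must carry `eta`,
#'   `omega` and `pure_design_h2`.
#' @param design A [scheme_design()] object; `selection_rate` is the
#'   pure-stand rate and `theta_prime_*` the sexes coefficients.
#' @return A [response_set()] with a `by_process` breakdown (same layout as
#'   [sgma_cumulated()]).
#' @export
pure_stand_responses <- function(params, design) {
  stopifnot(inherits(params, "mixture_params"),
            inherits(design, "scheme_design"))
  for (sp in list(params$species1, params$species2)) {
    if (is.na(sp$eta) || is.na(sp$omega) || is.na(sp$pure_design_h2)) {
      stop("pure-stand responses need eta, omega and pure_design_h2 for ",
           "both species", call. = FALSE)
    }
  }
  ip <- selection_intensity(design$selection_rate)
  gains <- function(sp, theta_phi) {
    crit <- pure_stand_criterion(sp$var_pure, sp$pure_design_h2)
    cov_pv <- cov_from_cor(sp$eta, sp$var_pure, sp$var_direct)
    cov_pa <- cov_from_cor(sp$omega, sp$var_pure, sp$var_associate)
    list(own = response_kernel(ip, theta_phi, crit$criterion_sd, cov_pv),
         comp = response_kernel(ip, theta_phi, crit$criterion_sd, cov_pa))
  }
  g1 <- gains(params$species1, design$theta_prime_1 * design$phi_1)
  g2 <- gains(params$species2, design$theta_prime_2 * design$phi_2)
  response_set(
    dG_x1 = g1$own + g2$comp,
    dG_x2 = g1$comp + g2$own,
    flavor = "after_recombination",
    by_process = list(dG_x11 = g1$own, dG_x21 = g1$comp,
                      dG_x22 = g2$own, dG_x12 = g2$comp)
  )
}
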