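#' Selection-index weights on observed species contributions
#'
#' A linear selection index weights the observed contributions of the two
#' species to the performance of a tested mixture. For the pair-mixture
#' scheme there is one pair `(alpha_1, alpha_2)`; the parallel
#' general-mixture-ability scheme uses one pair per selection process.
#'
#' @param alpha_1 Weight on the observed species-1 contribution (for a
#'   process index, the weight on the focal family's own contribution).
#' @param alpha_2 Weight on the observed species-2 contribution (for a
#'   process index, the weight on the companion-bulk contribution).
#' @return An object of class `index_weights`.
#' @export
index_weights <- function(alpha_1, alpha_2) {
  if (!is.finite(alpha_1) || !is.finite(alpha_2)) {
    stop("index weights must be finite", call. = FALSE)
  }
  if (alpha_1 == 0 && alpha_2 == 0) {
    stop("index weights must not both be zero", call. = FALSE)
  }
  structure(list(alpha_1 = as.numeric(alpha_1),
                 alpha_2 = as.numeric(alpha_2)),
            class = "index_weights")
}

as_index_weights <- function(w) {
  if (inherits(w, "index_weights")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(index_weights(w[1], w[2]))
  stop("weights must be an index_weights object or a numeric pair",
       call. = FALSE)
}

#' Variance of the pair-mixture selection index
#'
#' Variance of `I = alpha_1 * x1 + alpha_2 * x2` where `x1`, `x2` are the
#' family-mean observed contributions of the two species over `replicates`
#' observations of a pair mixture:
#' \deqn{\sigma_I^2 = \alpha_1^2(\sigma_{v1}^2+\sigma_{a2}^2+\sigma_{(va)12}^2)
#'   + \alpha_2^2(\sigma_{v2}^2+\sigma_{a1}^2+\sigma_{(va)21}^2)
#'   + 2\alpha_1\alpha_2(\mathrm{Cov}(v_1,a_1)+\mathrm{Cov}(v_2,a_2)
#'   +\mathrm{Cov}((va)_{12},(va)_{21}))
#'   + \frac{1}{M}(\alpha_1^2\sigma_{e1}^2+\alpha_2^2\sigma_{e2}^2
#'   +2\alpha_1\alpha_2\mathrm{Cov}(e_1,e_2)).}
#' With unit weights this is the variance of the observed mixture
#' performance, `var_gma_1 + var_gma_2 + var_sma + var_plot_error/M`.
#'
#' @param params A [mixture_params()] object.
#' @param weights An [index_weights()] object or numeric pair.
#' @param replicates Number of observations M of each pair (>= 1).
#' @return Criterion variance (trait units squared).
#' @export
srma_criterion_variance <- function(params, weights, replicates) {
  stopifnot(inherits(params, "mixture_params"))
  weights <- as_index_weights(weights)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  dc <- derive_components(params)
  a1 <- weights$alpha_1
  a2 <- weights$alpha_2
  cov_e <- cov_from_cor(params$rho_e1_e2, params$var_e1, params$var_e2)
  v <- a1^2 * dc$var_Gx1 + a2^2 * dc$var_Gx2 +
    2 * a1 * a2 * dc$cov_Gx1_Gx2 +
    (a1^2 * params$var_e1 + a2^2 * params$var_e2 +
       2 * a1 * a2 * cov_e) / replicates
  if (v <= 0) {
    stop("criterion variance is not positive: the model is fully degenerate",
         call. = FALSE)
  }
  v
}

#' Variance of a parallel-process selection index
#'
#' Variance of the index applied in one process of the parallel
#' general-mixture-ability scheme, where the focal candidate's family is
#' tested in mixture with a bulk of all companion-species families:
#' `I = alpha_1 * x_own + alpha_2 * x_companion` with genetic components the
#' focal family's direct effect and its associate effect. With unit weights
#' this is the variance of the observed mixture performance of the tested
#' family, `var_gma + var_plot_error/M`.
#'
#' @inheritParams srma_criterion_variance
#' @param focal_species Which species' process, 1 or 2.
#' @return Criterion variance (trait units squared).
#' @export
sgma_criterion_variance <- function(params, weights, replicates,
                                    focal_species = 1) {
  stopifnot(inherits(params, "mixture_params"),
            focal_species %in% c(1, 2))
  weights <- as_index_weights(weights)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  sp <- if (focal_species == 1) params$species1 else params$species2
  cov_va <- cov_from_cor(sp$rho_va, sp$var_direct, sp$var_associate)
  a1 <- weights$alpha_1
  a2 <- weights$alpha_2
  # the error split of the observed contributions is the same in both
  # parallel processes (e_own ~ var_e1 convention kept for species 2's
  # process by symmetry of the split)
  ve_own <- params$var_e1
  ve_comp <- params$var_e2
  cov_e <- cov_from_cor(params$rho_e1_e2, ve_own, ve_comp)
  v <- a1^2 * sp$var_direct + a2^2 * sp$var_associate +
    2 * a1 * a2 * cov_va +
    (a1^2 * ve_own + a2^2 * ve_comp + 2 * a1 * a2 * cov_e) / replicates
  if (v <= 0) {
    stop("criterion variance is not positive: the model is fully degenerate",
         call. = FALSE)
  }
  v
}

#' Design heritability of the plain mixture-performance criterion
#'
#' Ratio of genetic to total variance of the selection criterion when the
#' criterion is the observed mixture performance (unit index weights). For
#' the pair-mixture scheme the genetic variance is the sum of the two GMA
#' variances and the SMA variance; for a parallel process it is the focal
#' species' GMA variance alone.
#'
#' @param params A [mixture_params()] object.
#' @param design A [scheme_design()] object (only `replicates` is used).
#' @param scheme `"srma"` or `"sgma"`.
#' @return Heritability in (0, 1].
#' @examples
#' sp <- species_params(1, 0.5, rho_va = -0.5)
#' p <- mixture_params(sp, sp, 0.25, 0.25, -0.5, 2)
#' d <- basic_design("srma")
#' round(design_heritability(p, d, "srma"), 2)  # 0.73
#' round(design_heritability(p, d, "sgma"), 2)  # 0.54
#' @export
design_heritability <- function(params, design, scheme = c("srma", "sgma")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "scheme_design"))
  dc <- derive_components(params)
  unit <- index_weights(1, 1)
  if (scheme == "srma") {
    gen <- dc$var_gma_1 + dc$var_gma_2 + dc$var_sma
    tot <- srma_criterion_variance(params, unit, design$replicates)
  } else {
    gen <- dc$var_gma_1
    tot <- sgma_criterion_variance(params, unit, design$replicates,
                                   focal_species = 1)
  }
  gen / tot
}
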