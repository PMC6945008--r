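#' Expected responses under reciprocal mixture-ability selection, after
#' recombination
#'
#' One cycle of the pair-mixture (reciprocal mixture ability) scheme: each
#' progeny family of species 1 is tested in mixture with one progeny family
#' of species 2, the best pairs are selected on the index, and the selected
#' candidates of each species are intercrossed. The gains realized in the
#' next-cycle populations involve only the heritable direct and associate
#' effects — the pair-specific direct-by-associate interactions enter the
#' criterion variance but are not transmitted, because pairs are re-drawn at
#' random each cycle. Valid for half-sib or topcross progeny families, with
#' the same selection intensity in both species:
#' \deqn{\Delta G_{x1} = \frac{\theta_1\varphi_1 i}{\sigma_I}
#'   (\alpha_1\sigma_{v1}^2 + \alpha_2\mathrm{Cov}(v_1,a_1))
#'   + \frac{\theta_2\varphi_2 i}{\sigma_I}
#'   (\alpha_1\sigma_{a2}^2 + \alpha_2\mathrm{Cov}(v_2,a_2))}
#' and symmetrically for species 2.
#'
#' @param params A [mixture_params()] object.
#' @param design A [scheme_design()] object; the selection intensity is
#'   derived from its `selection_rate`.
#' @param weights An [index_weights()] object or numeric pair.
#' @return A [response_set()] with flavor `"after_recombination"`.
#' @export
srma_responses_after <- function(params, design, weights) {
  stopifnot(inherits(design, "scheme_design"))
  weights <- as_index_weights(weights)
  dc <- derive_components(params)
  s1 <- params$species1
  s2 <- params$species2
  a1 <- weights$alpha_1
  a2 <- weights$alpha_2
  sigma_I <- sqrt(srma_criterion_variance(params, weights, design$replicates))
  i <- selection_intensity(design$selection_rate)
  dG_x1 <-
    response_kernel(i, design$theta_1 * design$phi_1, sigma_I,
                    a1 * s1$var_direct + a2 * dc$cov_v1_a1) +
    response_kernel(i, design$theta_2 * design$phi_2, sigma_I,
                    a1 * s2$var_associate + a2 * dc$cov_v2_a2)
  dG_x2 <-
    response_kernel(i, design$theta_1 * design$phi_1, sigma_I,
                    a1 * dc$cov_v1_a1 + a2 * s1$var_associate) +
    response_kernel(i, design$theta_2 * design$phi_2, sigma_I,
                    a1 * dc$cov_v2_a2 + a2 * s2$var_direct)
  response_set(dG_x1, dG_x2, flavor = "after_recombination",
               weights = weights)
}

#' Expected responses under reciprocal mixture-ability selection, before
#' recombination
#'
#' Gains of the genetic components of the species contributions measured on
#' the selected candidates themselves (before they are intercrossed), valid
#' whatever the progeny-family type and pairing design provided the same
#' selection intensity is applied in both species:
#' \deqn{\delta G_{x1} = \frac{i}{\sigma_I}
#'   (\alpha_1\sigma_{Gx1}^2 + \alpha_2\mathrm{Cov}(G_{x1},G_{x2}))}
#' where \eqn{G_{x1} = v_1 + a_2 + (va)_{12}} is the genetic component of the
#' observed species-1 contribution, interactions included. With unit weights
#' and theta*phi = 1 the gap to the after-recombination response is exactly
#' the non-heritable interaction part,
#' `i * (var_va_12 + cov_va12_va21) / sigma_y` per species.
#'
#' @inheritParams srma_responses_after
#' @return A [response_set()] with flavor `"before_recombination"`.
#' @export
srma_responses_before <- function(params, design, weights) {
  stopifnot(inherits(design, "scheme_design"))
  weights <- as_index_weights(weights)
  dc <- derive_components(params)
  a1 <- weights$alpha_1
  a2 <- weights$alpha_2
  sigma_I <- sqrt(srma_criterion_variance(params, weights, design$replicates))
  i <- selection_intensity(design$selection_rate)
  dG_x1 <- response_kernel(i, 1, sigma_I,
                           a1 * dc$var_Gx1 + a2 * dc$cov_Gx1_Gx2)
  dG_x2 <- response_kernel(i, 1, sigma_I,
                           a1 * dc$cov_Gx1_Gx2 + a2 * dc$var_Gx2)
  response_set(dG_x1, dG_x2, flavor = "before_recombination",
               weights = weights)
}

#' Tune the pair-mixture index to a target ratio of contribution responses
#'
#' Solves for index weights such that the before-recombination responses of
#' the two species contributions are proportional to `(k1, k2)`:
#' \deqn{\begin{cases}
#'   \alpha_1\sigma_{Gx1}^2 + \alpha_2\mathrm{Cov}(G_{x1},G_{x2}) = k_1\\
#'   \alpha_1\mathrm{Cov}(G_{x1},G_{x2}) + \alpha_2\sigma_{Gx2}^2 = k_2
#' \end{cases}}
#' The before-recombination ratio under the returned weights equals `k1/k2`
#' exactly; the after-recombination ratio departs from it according to the
#' magnitude of the interaction variance-covariances.
#'
#' @param params A [mixture_params()] object.
#' @param target Numeric pair `c(k1, k2)`, not both zero.
#' @return An [index_weights()] object (unnormalized solution of the linear
#'   system; responses are invariant to joint positive rescaling). A warning
#'   is issued when a solved weight is negative.
#' @export
solve_srma_index <- function(params, target) {
  if (length(target) != 2L || all(target == 0)) {
    stop("target must be a pair (k1, k2), not both zero", call. = FALSE)
  }
  dc <- derive_components(params)
  A <- matrix(c(dc$var_Gx1, dc$cov_Gx1_Gx2,
                dc$cov_Gx1_Gx2, dc$var_Gx2), 2, 2)
  if (abs(det(A)) < 1e-12 * max(abs(A))^2) {
    stop("unsolvable target: the genetic (co)variance matrix of the species ",
         "contributions is singular (perfectly correlated contributions)",
         call. = FALSE)
  }
  alpha <- solve(A, as.numeric(target))
  if (any(alpha < 0)) {
    warning("solved index weight is negative: the target ratio requires ",
            "penalizing one observed contribution", call. = FALSE)
  }
  index_weights(alpha[1], alpha[2])
}
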