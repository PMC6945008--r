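#' Expected responses of one parallel general-mixture-ability process
#'
#' In the parallel scheme each species is improved by its own recurrent
#' selection: progeny families of candidates from the focal species are
#' tested in mixture with a balanced bulk of all companion-species families,
#' so the genetic component of the observed performance of a family is its
#' general mixture ability `g = v + a`. Selecting on the index
#' `I = alpha_1 * x_own + alpha_2 * x_companion` gives, for half-sib or
#' topcross progeny families,
#' \deqn{\Delta G_{own} = \frac{\theta\varphi i}{\sigma_I}
#'   (\alpha_1\sigma_v^2 + \alpha_2\mathrm{Cov}(v,a)), \qquad
#'   \Delta G_{comp} = \frac{\theta\varphi i}{\sigma_I}
#'   (\alpha_1\mathrm{Cov}(v,a) + \alpha_2\sigma_a^2)}
#' — the gain of the focal species' own contribution (its direct effect) and
#' of the companion species' contribution (its associate effect).
#'
#' @param params A [mixture_params()] object.
#' @param design A [scheme_design()] object.
#' @param weights An [index_weights()] object or numeric pair
#'   `(own, companion)`.
#' @param focal_species Which species' process, 1 or 2.
#' @return A [response_set()]; `dG_x1`/`dG_x2` are mapped to the species,
#'   not to own/companion.
#' @export
sgma_process_responses <- function(params, design, weights,
                                   focal_species = 1) {
  stopifnot(inherits(design, "scheme_design"),
            focal_species %in% c(1, 2))
  weights <- as_index_weights(weights)
  g <- sgma_process_gains(params, design,
                          c(weights$alpha_1, weights$alpha_2),
                          focal_species)
  if (focal_species == 1) {
    response_set(g$own, g$comp, flavor = "after_recombination",
                 weights = weights)
  } else {
    response_set(g$comp, g$own, flavor = "after_recombination",
                 weights = weights)
  }
}

# vectorized core of one process: gains on the own-species and
# companion-species contributions for index weights given as two vectors
sgma_process_gains <- function(params, design, alpha, focal_species,
                               a1 = alpha[1], a2 = alpha[2]) {
  sp <- if (focal_species == 1) params$species1 else params$species2
  theta_phi <- if (focal_species == 1) {
    design$theta_1 * design$phi_1
  } else {
    design$theta_2 * design$phi_2
  }
  M <- design$replicates
  cov_va <- cov_from_cor(sp$rho_va, sp$var_direct, sp$var_associate)
  cov_e <- cov_from_cor(params$rho_e1_e2, params$var_e1, params$var_e2)
  var_I <- a1^2 * (sp$var_direct + params$var_e1 / M) +
    a2^2 * (sp$var_associate + params$var_e2 / M) +
    2 * a1 * a2 * (cov_va + cov_e / M)
  if (any(var_I <= 0)) {
    stop("criterion variance is not positive: the model is fully degenerate",
         call. = FALSE)
  }
  i <- selection_intensity(design$selection_rate)
  sd_I <- sqrt(var_I)
  list(
    own = theta_phi * i * (a1 * sp$var_direct + a2 * cov_va) / sd_I,
    comp = theta_phi * i * (a1 * cov_va + a2 * sp$var_associate) / sd_I
  )
}

#' Responses cumulated over the two parallel selection processes
#'
#' Both species run their own general-mixture-ability selection at the same
#' pace; expected responses add up. The species-1 contribution gains the
#' direct-effect response of its own process plus the associate-effect
#' response of the species-2 process, and symmetrically.
#'
#' @param params A [mixture_params()] object.
#' @param design A [scheme_design()] object (same rate in both processes).
#' @param weights_1 Index weights of the species-1 process
#'   `(own contribution, companion bulk)`.
#' @param weights_2 Index weights of the species-2 process.
#' @return A [response_set()] with a `by_process` breakdown: `dG_x11` and
#'   `dG_x21` are the species-1 and species-2 contribution gains from the
#'   species-1 process; `dG_x22` and `dG_x12` those from the species-2
#'   process.
#' @export
sgma_cumulated <- function(params, design, weights_1, weights_2 = weights_1) {
  weights_1 <- as_index_weights(weights_1)
  weights_2 <- as_index_weights(weights_2)
  g1 <- sgma_process_gains(params, design,
                           c(weights_1$alpha_1, weights_1$alpha_2), 1)
  g2 <- sgma_process_gains(params, design,
                           c(weights_2$alpha_1, weights_2$alpha_2), 2)
  response_set(
    dG_x1 = g1$own + g2$comp,
    dG_x2 = g1$comp + g2$own,
    flavor = "after_recombination",
    by_process = list(dG_x11 = g1$own, dG_x21 = g1$comp,
                      dG_x22 = g2$own, dG_x12 = g2$comp),
    weights = list(weights_1, weights_2)
  )
}

# per-process objective/constraint pieces as functions of the index angle t,
# weights (cos t, sin t); everything is invariant to positive rescaling of a
# process's weight pair, so the angle parameterization is exhaustive
# (antipodal angles flip that process's response signs and are searched too)
sgma_angle_pieces <- function(params, design, t, focal_species, target) {
  g <- sgma_process_gains(params, design, NULL, focal_species,
                          a1 = cos(t), a2 = sin(t))
  k1 <- target[1]
  k2 <- target[2]
  if (focal_species == 1) {
    # process 1: own feeds dG_x1, companion feeds dG_x2
    list(f = g$own + g$comp, c = g$own * k2 - g$comp * k1)
  } else {
    # process 2: own feeds dG_x2, companion feeds dG_x1
    list(f = g$own + g$comp, c = g$comp * k2 - g$own * k1)
  }
}

# all roots of c1 + c2(t2) = 0 on the circle, located by sign-change scan
# over the angle grid (with wraparound) and refined by uniroot
constraint_roots <- function(c1_value, c2_fun, grid, c2_grid = c2_fun(grid)) {
  h <- c1_value + c2_grid
  n <- length(h)
  roots <- grid[h == 0]
  jl <- which(h[-n] * h[-1] < 0)
  for (j in jl) {
    r <- stats::uniroot(function(t) c1_value + c2_fun(t),
                        lower = grid[j], upper = grid[j + 1],
                        tol = 1e-12)$root
    roots <- c(roots, r)
  }
  # wraparound bracket grid[n] -> grid[1] + 2*pi; c2_fun is built from
  # cos/sin so it is 2*pi-periodic and needs no wrapping to evaluate
  if (h[n] * h[1] < 0) {
    r <- stats::uniroot(function(t) c1_value + c2_fun(t),
                        lower = grid[n], upper = grid[1] + 2 * pi,
                        tol = 1e-12)$root
    roots <- c(roots, wrap_angle(r))
  }
  roots
}

wrap_angle <- function(t) {
  w <- (t + pi) %% (2 * pi) - pi
  ifelse(w <= -pi, w + 2 * pi, w)
}

#' Optimize the pair of process indices under a contribution-response target
#'
#' Finds the two index weight pairs (one per parallel process) that maximize
#' the cumulated expected response of the mixture performance subject to the
#' cumulated species-contribution responses being proportional to
#' `(k1, k2)`. The constraint is imposed in product form,
#' `dG_x1 * k2 - dG_x2 * k1 = 0`, which is well behaved near zero responses.
#'
#' Because each process's responses are invariant to positive rescaling of
#' its own weight pair, each index is parameterized by a single angle
#' `t` with weights `(cos t, sin t)`, and both the objective and the
#' constraint split into a sum of one function of `t1` and one of `t2`. The
#' search is a deterministic coarse scan at one-degree resolution over `t1`,
#' exact root-solving of the constraint in `t2` for every candidate, and a
#' derivative-free polish of `t1` around the best cell.
#'
#' @param params A [mixture_params()] object.
#' @param design A [scheme_design()] object.
#' @param target Numeric pair `c(k1, k2)` of desired proportionality
#'   constants of the cumulated contribution responses, not both zero.
#' @return A list with elements `weights_1`, `weights_2`
#'   ([index_weights()] of the two processes), `responses` (the
#'   [response_set()] at the optimum), and `constraint_residual`.
#' @export
optimize_sgma_indices <- function(params, design, target) {
  if (length(target) != 2L || all(target == 0)) {
    stop("target must be a pair (k1, k2), not both zero", call. = FALSE)
  }
  target <- as.numeric(target)
  # coarse grid: 1-degree steps over the circle
  grid <- seq(-pi, pi, length.out = 361L)[-1L]
  p1 <- sgma_angle_pieces(params, design, grid, 1, target)
  p2 <- sgma_angle_pieces(params, design, grid, 2, target)

  # feasibility: c1(t1) + c2(t2) = 0 needs -c1 to fall in the range of c2
  if (min(p1$c) + min(p2$c) > 0 || max(p1$c) + max(p2$c) < 0) {
    H <- outer(p1$c, p2$c, "+")
    j <- arrayInd(which.min(abs(H)), dim(H))
    g1 <- sgma_process_gains(params, design, NULL, 1,
                             a1 = cos(grid[j[1]]), a2 = sin(grid[j[1]]))
    g2 <- sgma_process_gains(params, design, NULL, 2,
                             a1 = cos(grid[j[2]]), a2 = sin(grid[j[2]]))
    stop(sprintf(paste0(
      "infeasible contribution-response target (%g, %g): closest achievable ",
      "cumulated responses are (%.4g, %.4g)"),
      target[1], target[2], g1$own + g2$comp, g1$comp + g2$own),
      call. = FALSE)
  }

  c2_fun <- function(t) sgma_angle_pieces(params, design, t, 2, target)$c
  f2_fun <- function(t) sgma_angle_pieces(params, design, t, 2, target)$f

  # best objective at a given t1, maximizing over all constraint roots in t2
  best_at_t1 <- function(t1) {
    pc <- sgma_angle_pieces(params, design, t1, 1, target)
    roots <- constraint_roots(pc$c, c2_fun, grid, c2_grid = p2$c)
    if (length(roots) == 0L) return(list(f = -Inf, t2 = NA_real_))
    fs <- pc$f + f2_fun(roots)
    k <- which.max(fs)
    list(f = fs[k], t2 = roots[k])
  }

  scan <- lapply(grid, best_at_t1)
  fvals <- vapply(scan, `[[`, numeric(1), "f")
  k <- which.max(fvals)
  best <- list(t1 = grid[k], t2 = scan[[k]]$t2, f = fvals[k])

  # derivative-free polish of t1 within one grid step of the best cell
  step <- grid[2] - grid[1]
  # a t1 with no feasible t2 scores a large finite penalty (optimize() does
  # not accept -Inf)
  pol <- stats::optimize(function(t1) max(best_at_t1(t1)$f, -1e12),
                         lower = best$t1 - step, upper = best$t1 + step,
                         maximum = TRUE, tol = 1e-10)
  if (is.finite(pol$objective) && pol$objective > best$f) {
    best$t1 <- wrap_angle(pol$maximum)
    b <- best_at_t1(best$t1)
    best$t2 <- b$t2
    best$f <- b$f
  }

  w1 <- index_weights(cos(best$t1), sin(best$t1))
  w2 <- index_weights(cos(best$t2), sin(best$t2))
  resp <- sgma_cumulated(params, design, w1, w2)
  residual <- resp$dG_x1 * target[2] - resp$dG_x2 * target[1]
  scale <- max(abs(resp$dG_total), .Machine$double.eps)
  if (abs(residual) > 1e-6 * scale) {
    warning("constraint residual ", signif(residual, 3),
            " exceeds 1e-6 relative to the cumulated response",
            call. = FALSE)
  }
  list(weights_1 = w1, weights_2 = w2, responses = resp,
       constraint_residual = residual)
}
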