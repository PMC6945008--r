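# per-replicate seed: simple counter-based scheme so replicate r is
# reproducible independently of execution order
replicate_seed <- function(base_seed, r) {
  (as.numeric(base_seed) + 7919 * r) %% (2^31 - 1)
}

mvn2 <- function(n, var_x, var_y, covar) {
  MASS::mvrnorm(n, mu = c(0, 0),
                Sigma = matrix(c(var_x, covar, covar, var_y), 2, 2))
}

#' Simulate one selection cycle and its realized gains
#'
#' Monte-Carlo oracle for the analytic expectations: draws candidate effects
#' from the multivariate-normal mixture model, applies truncation selection
#' on the index, and records the realized gains of the species
#' contributions. Transmission to the next cycle is represented by the
#' theta*phi coefficient applied to the mean direct/associate effects of the
#' selected parents (the expectations being validated average over Mendelian
#' sampling, which is therefore not simulated).
#'
#' For the pair-mixture scheme the realized after-recombination gain of the
#' species-1 contribution is `theta_1*phi_1 * mean(v1)` over selected pairs
#' plus `theta_2*phi_2 * mean(a2)`, and the before-recombination gain is the
#' mean selected genetic component `v1 + a2 + (va)12` (interactions
#' included, no transmission coefficient). For the parallel schemes each
#' process draws its own candidates and selects independently; gains
#' cumulate.
#'
#' @param params A [mixture_params()] object.
#' @param design A [scheme_design()] object; the number of candidates per
#'   species follows from its plot budget via [candidates_tested()].
#' @param scheme `"srma"`, `"sgma"` or `"pure"`.
#' @param weights Index weights: a pair for `"srma"`, a pair or a list of
#'   two pairs (one per process) for `"sgma"`; ignored for `"pure"`.
#' @param n_replicates Number of independent simulated cycles.
#' @param seed Base seed; replicate `r` uses a seed derived from
#'   `(seed, r)`.
#' @return A list of class `simulated_cycle` with elements `means` and `se`
#'   (named vectors over the realized quantities: `after_dG_x1`,
#'   `after_dG_x2`, `after_dG_total`, for the pair scheme also `before_*`,
#'   for the parallel schemes the per-process gains, and `crit_var`, the
#'   empirical criterion variance), `replicates` (the per-replicate matrix),
#'   `tested` and `selected` counts, and `scheme`.
#' @export
simulate_cycle <- function(params, design, scheme = c("srma", "sgma", "pure"),
                           weights = c(1, 1), n_replicates = 100, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "mixture_params"),
            inherits(design, "scheme_design"))
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  n <- candidates_tested(design, scheme)
  k <- candidates_selected(n, design$selection_rate)
  if (k > n) stop("fewer candidates than the selected count", call. = FALSE)

  one <- switch(scheme,
                srma = function() simulate_srma_once(params, design, weights,
                                                     n, k),
                sgma = function() simulate_sgma_once(params, design, weights,
                                                     n, k),
                pure = function() simulate_pure_once(params, design, n, k))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    rows[[r]] <- one()
  }
  mat <- do.call(rbind, rows)
  means <- colMeans(mat)
  se <- apply(mat, 2, stats::sd) / sqrt(n_replicates)
  structure(list(means = means, se = se, replicates = mat,
                 tested = n, selected = k, scheme = scheme,
                 n_replicates = n_replicates, seed = seed),
            class = "simulated_cycle")
}

# selection of the top k criterion values, ties broken by candidate id
select_top <- function(crit, k) {
  order(-crit, seq_along(crit))[seq_len(k)]
}

simulate_srma_once <- function(params, design, weights, n, k) {
  w <- as_index_weights(weights)
  s1 <- params$species1
  s2 <- params$species2
  M <- design$replicates
  va1 <- mvn2(n, s1$var_direct, s1$var_associate,
              cov_from_cor(s1$rho_va, s1$var_direct, s1$var_associate))
  va2 <- mvn2(n, s2$var_direct, s2$var_associate,
              cov_from_cor(s2$rho_va, s2$var_direct, s2$var_associate))
  vv <- mvn2(n, params$var_va_12, params$var_va_21,
             cov_from_cor(params$rho_va12_va21,
                          params$var_va_12, params$var_va_21))
  cov_e <- cov_from_cor(params$rho_e1_e2, params$var_e1, params$var_e2)
  # family-mean plot errors over M observations
  ee <- mvn2(n, params$var_e1 / M, params$var_e2 / M, cov_e / M)
  # draws are iid so index-wise pairing is a random pairing
  x1 <- params$mean_u1 + va1[, 1] + va2[, 2] + vv[, 1] + ee[, 1]
  x2 <- params$mean_u2 + va2[, 1] + va1[, 2] + vv[, 2] + ee[, 2]
  crit <- w$alpha_1 * x1 + w$alpha_2 * x2
  sel <- select_top(crit, k)
  tp1 <- design$theta_1 * design$phi_1
  tp2 <- design$theta_2 * design$phi_2
  after_x1 <- tp1 * mean(va1[sel, 1]) + tp2 * mean(va2[sel, 2])
  after_x2 <- tp1 * mean(va1[sel, 2]) + tp2 * mean(va2[sel, 1])
  before_x1 <- mean(va1[sel, 1] + va2[sel, 2] + vv[sel, 1])
  before_x2 <- mean(va2[sel, 1] + va1[sel, 2] + vv[sel, 2])
  c(after_dG_x1 = after_x1, after_dG_x2 = after_x2,
    after_dG_total = after_x1 + after_x2,
    before_dG_x1 = before_x1, before_dG_x2 = before_x2,
    before_dG_total = before_x1 + before_x2,
    crit_var = stats::var(crit))
}

sgma_weights_pair <- function(weights) {
  if (is.list(weights) && !inherits(weights, "index_weights")) {
    stopifnot(length(weights) == 2L)
    lapply(weights, as_index_weights)
  } else {
    w <- as_index_weights(weights)
    list(w, w)
  }
}

simulate_sgma_once <- function(params, design, weights, n, k) {
  wl <- sgma_weights_pair(weights)
  M <- design$replicates
  cov_e <- cov_from_cor(params$rho_e1_e2, params$var_e1, params$var_e2)
  run <- function(sp, w, theta_phi) {
    va <- mvn2(n, sp$var_direct, sp$var_associate,
               cov_from_cor(sp$rho_va, sp$var_direct, sp$var_associate))
    ee <- mvn2(n, params$var_e1 / M, params$var_e2 / M, cov_e / M)
    x_own <- va[, 1] + ee[, 1]
    x_comp <- va[, 2] + ee[, 2]
    crit <- w$alpha_1 * x_own + w$alpha_2 * x_comp
    sel <- select_top(crit, k)
    list(own = theta_phi * mean(va[sel, 1]),
         comp = theta_phi * mean(va[sel, 2]),
         crit_var = stats::var(crit))
  }
  g1 <- run(params$species1, wl[[1]], design$theta_1 * design$phi_1)
  g2 <- run(params$species2, wl[[2]], design$theta_2 * design$phi_2)
  c(after_dG_x1 = g1$own + g2$comp,
    after_dG_x2 = g1$comp + g2$own,
    after_dG_total = g1$own + g1$comp + g2$own + g2$comp,
    dG_x11 = g1$own, dG_x21 = g1$comp,
    dG_x22 = g2$own, dG_x12 = g2$comp,
    crit_var = g1$crit_var)
}

simulate_pure_once <- function(params, design, n, k) {
  run <- function(sp, theta_phi) {
    if (is.na(sp$eta) || is.na(sp$omega) || is.na(sp$pure_design_h2)) {
      stop("pure-stand simulation needs eta, omega and pure_design_h2",
           call. = FALSE)
    }
    S <- diag(c(sp$var_pure, sp$var_direct, sp$var_associate))
    S[1, 2] <- S[2, 1] <- cov_from_cor(sp$eta, sp$var_pure, sp$var_direct)
    S[1, 3] <- S[3, 1] <- cov_from_cor(sp$omega, sp$var_pure,
                                       sp$var_associate)
    S[2, 3] <- S[3, 2] <- cov_from_cor(sp$rho_va, sp$var_direct,
                                       sp$var_associate)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) {
      stop("the joint (pure-stand, direct, associate) covariance implied by ",
           "eta, omega and rho_va is not positive definite; these ",
           "correlations cannot be realized jointly", call. = FALSE)
    }
    pva <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = S)
    var_err <- sp$var_pure * (1 / sp$pure_design_h2 - 1)
    crit <- pva[, 1] + stats::rnorm(n, 0, sqrt(var_err))
    sel <- select_top(crit, k)
    list(own = theta_phi * mean(pva[sel, 2]),
         comp = theta_phi * mean(pva[sel, 3]),
         crit_var = stats::var(crit))
  }
  g1 <- run(params$species1, design$theta_prime_1 * design$phi_1)
  g2 <- run(params$species2, design$theta_prime_2 * design$phi_2)
  c(after_dG_x1 = g1$own + g2$comp,
    after_dG_x2 = g1$comp + g2$own,
    after_dG_total = g1$own + g1$comp + g2$own + g2$comp,
    dG_x11 = g1$own, dG_x21 = g1$comp,
    dG_x22 = g2$own, dG_x12 = g2$comp,
    crit_var = g1$crit_var)
}

#' @export
print.simulated_cycle <- function(x, ...) {
  cat(sprintf("Simulated selection cycles: scheme %s, %d replicates, %d tested, %d selected\n",
              x$scheme, x$n_replicates, x$tested, x$selected))
  out <- data.frame(mean = x$means, se = x$se)
  print(round(out, 4))
  invisible(x)
}

#' Generate a synthetic plot-level trial table
#'
#' Emits a tidy table of simulated plot observations under the given scheme:
#' one row per plot, with candidate/pair identifiers, the replicate number,
#' the observed species contributions and the observed mixture (or pure
#' stand) performance `y = x1 + x2`. Useful as command-line test input and
#' for documentation examples.
#'
#' @param params A [mixture_params()] object.
#' @param design A [scheme_design()] object.
#' @param scheme `"srma"`, `"sgma"` or `"pure"`.
#' @param seed Seed for the draws; fixed-seed reruns are identical.
#' @return A data frame with columns `scheme`, `process`, `candidate_1`,
#'   `candidate_2`, `replicate`, `x1`, `x2`, `y`. For the parallel schemes,
#'   `candidate_1`/`candidate_2` hold the focal candidate id and `NA` (the
#'   companion side is a bulk); `x1` is the focal family's observed
#'   contribution. For pure stand, `x2` is `NA` and `y` the pure-stand
#'   observation.
#' @export
generate_fixture <- function(params, design,
                             scheme = c("srma", "sgma", "pure"), seed = 1) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  n <- candidates_tested(design, scheme)
  M <- design$replicates
  s1 <- params$species1
  s2 <- params$species2
  cov_e <- cov_from_cor(params$rho_e1_e2, params$var_e1, params$var_e2)
  if (scheme == "srma") {
    va1 <- mvn2(n, s1$var_direct, s1$var_associate,
                cov_from_cor(s1$rho_va, s1$var_direct, s1$var_associate))
    va2 <- mvn2(n, s2$var_direct, s2$var_associate,
                cov_from_cor(s2$rho_va, s2$var_direct, s2$var_associate))
    vv <- mvn2(n, params$var_va_12, params$var_va_21,
               cov_from_cor(params$rho_va12_va21,
                            params$var_va_12, params$var_va_21))
    idx <- rep(seq_len(n), each = M)
    ee <- mvn2(n * M, params$var_e1, params$var_e2, cov_e)
    x1 <- params$mean_u1 + va1[idx, 1] + va2[idx, 2] + vv[idx, 1] + ee[, 1]
    x2 <- params$mean_u2 + va2[idx, 1] + va1[idx, 2] + vv[idx, 2] + ee[, 2]
    data.frame(scheme = scheme, process = NA_integer_,
               candidate_1 = idx, candidate_2 = idx,
               replicate = rep(seq_len(M), times = n),
               x1 = x1, x2 = x2, y = x1 + x2)
  } else if (scheme == "sgma") {
    run <- function(sp, proc, u_own, u_comp) {
      va <- mvn2(n, sp$var_direct, sp$var_associate,
                 cov_from_cor(sp$rho_va, sp$var_direct, sp$var_associate))
      idx <- rep(seq_len(n), each = M)
      ee <- mvn2(n * M, params$var_e1, params$var_e2, cov_e)
      x_own <- u_own + va[idx, 1] + ee[, 1]
      x_comp <- u_comp + va[idx, 2] + ee[, 2]
      data.frame(scheme = scheme, process = proc,
                 candidate_1 = idx, candidate_2 = NA_integer_,
                 replicate = rep(seq_len(M), times = n),
                 x1 = if (proc == 1L) x_own else x_comp,
                 x2 = if (proc == 1L) x_comp else x_own,
                 y = x_own + x_comp)
    }
    rbind(run(s1, 1L, params$mean_u1, params$mean_u2),
          run(s2, 2L, params$mean_u2, params$mean_u1))
  } else {
    run <- function(sp, proc, u) {
      if (is.na(sp$pure_design_h2)) {
        stop("pure-stand fixtures need pure_design_h2 for both species",
             call. = FALSE)
      }
      p <- stats::rnorm(n, 0, sqrt(sp$var_pure))
      var_err <- sp$var_pure * (1 / sp$pure_design_h2 - 1)
      idx <- rep(seq_len(n), each = M)
      yp <- u + p[idx] + stats::rnorm(n * M, 0, sqrt(var_err * M))
      data.frame(scheme = scheme, process = proc,
                 candidate_1 = idx, candidate_2 = NA_integer_,
                 replicate = rep(seq_len(M), times = n),
                 x1 = yp, x2 = NA_real_, y = yp)
    }
    rbind(run(s1, 1L, params$mean_u1_pure),
          run(s2, 2L, params$mean_u1_pure))
  }
}
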