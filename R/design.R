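#' Trial and selection design constants
#'
#' Collects the design constants shared by the response formulas: the total
#' plot budget, the number of observations (replicates) per tested family or
#' pair, the per-species selection rate, and the scheme coefficients theta
#' (1 or 2 sexes under selection) and phi (1 for half-sib progeny families,
#' 1/2 for topcross families).
#'
#' @param total_plots Total number of field plots available.
#' @param replicates Observations per tested progeny family or pair (M).
#' @param selection_rate Fraction selected per species, in (0, 1].
#' @param theta_1,theta_2 Number of sexes under selection per species (1 or 2).
#' @param phi_1,phi_2 Progeny-family coefficient per species (1 or 0.5).
#' @param theta_prime_1,theta_prime_2 Pure-stand counterparts of theta;
#'   default equal to theta.
#' @return An object of class `scheme_design`.
#' @examples
#' scheme_design(total_plots = 900, replicates = 3, selection_rate = 0.10)
#' @export
scheme_design <- function(total_plots,
                          replicates,
                          selection_rate,
                          theta_1 = 1, theta_2 = 1,
                          phi_1 = 1, phi_2 = 1,
                          theta_prime_1 = theta_1,
                          theta_prime_2 = theta_2) {
  if (replicates < 1 || replicates != round(replicates)) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  if (total_plots < replicates) {
    stop("total_plots must be at least replicates", call. = FALSE)
  }
  if (selection_rate <= 0 || selection_rate > 1) {
    stop("selection_rate must be in (0, 1]", call. = FALSE)
  }
  for (th in c(theta_1, theta_2, theta_prime_1, theta_prime_2)) {
    if (!th %in% c(1, 2)) stop("theta must be 1 or 2", call. = FALSE)
  }
  for (ph in c(phi_1, phi_2)) {
    if (!ph %in% c(1, 0.5)) stop("phi must be 1 or 0.5", call. = FALSE)
  }
  structure(list(
    total_plots = as.integer(total_plots),
    replicates = as.integer(replicates),
    selection_rate = as.numeric(selection_rate),
    theta_1 = theta_1, theta_2 = theta_2,
    phi_1 = phi_1, phi_2 = phi_2,
    theta_prime_1 = theta_prime_1,
    theta_prime_2 = theta_prime_2
  ), class = "scheme_design")
}

#' Reference trial design used throughout the worked examples
#'
#' 900 plots, 3 replicates per tested family or pair, theta = phi = 1, and a
#' selection rate of 10% for the pair-mixture (SRMA) scheme or 20% for the
#' parallel schemes. With these settings the pair-mixture scheme tests 300
#' candidates per species and the parallel schemes 150, while all schemes
#' select 30 candidates per species.
#'
#' @param scheme One of `"srma"`, `"sgma"`, `"pure"`.
#' @return A [scheme_design()] object.
#' @export
basic_design <- function(scheme = c("srma", "sgma", "pure")) {
  scheme <- match.arg(scheme)
  rate <- if (scheme == "srma") 0.10 else 0.20
  scheme_design(total_plots = 900, replicates = 3, selection_rate = rate)
}

#' Selection intensity under truncation of a Gaussian criterion
#'
#' The standardized selection differential of an infinite Gaussian population
#' truncated at its upper `rate` fraction: `i = dnorm(z) / rate` with
#' `z = qnorm(1 - rate)`.
#'
#' @param rate Selected fraction, in (0, 1].
#' @return Selection intensity in criterion standard-deviation units;
#'   0 when `rate` is 1 (no selection), monotone decreasing in `rate`.
#' @examples
#' selection_intensity(0.10)  # ~1.75
#' selection_intensity(0.20)  # ~1.40
#' @export
selection_intensity <- function(rate) {
  if (any(rate <= 0) || any(rate > 1)) {
    stop("rate must be in (0, 1]", call. = FALSE)
  }
  stats::dnorm(stats::qnorm(1 - rate)) / rate
}

#' Exact expected selection differential of the best k out of n
#'
#' Expected mean of the top `k` order statistics of `n` independent standard
#' normal draws, computed by numerical integration of
#' `(n/k) * x * dnorm(x) * P(Binom(n-1, 1-pnorm(x)) <= k-1)`. This is the
#' exact expectation of the selection intensity realized by truncation
#' selection in a finite candidate population; it approaches
#' [selection_intensity()]`(k/n)` from below as `n` grows. The Monte-Carlo
#' checks of the closed-form responses center their bands on it, since the
#' simulator necessarily selects the top k of a finite population.
#'
#' @param n Number of candidates.
#' @param k Number selected, `1 <= k <= n`.
#' @return Expected selection differential in standard-deviation units.
#' @examples
#' finite_selection_intensity(300, 30)  # slightly below 1.755
#' @export
finite_selection_intensity <- function(n, k) {
  if (k < 1 || k > n) stop("k must be in [1, n]", call. = FALSE)
  if (k == n) return(0)
  f <- function(x) {
    x * stats::dnorm(x) * stats::pbinom(k - 1, n - 1, 1 - stats::pnorm(x))
  }
  (n / k) * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Number of candidates tested per species under a given plot budget
#'
#' The pair-mixture scheme tests one candidate of each species in every plot
#' (each plot is one pair mixture), so it accommodates
#' `total_plots / replicates` candidates per species. The parallel schemes
#' split the plot budget equally between the two species' processes, halving
#' the count.
#'
#' @param design A [scheme_design()] object.
#' @param scheme One of `"srma"`, `"sgma"`, `"pure"`.
#' @return Integer count of candidates tested per species.
#' @examples
#' candidates_tested(basic_design("srma"), "srma")  # 300
#' candidates_tested(basic_design("sgma"), "sgma")  # 150
#' @export
candidates_tested <- function(design, scheme = c("srma", "sgma", "pure")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "scheme_design"))
  denom <- design$replicates * if (scheme == "srma") 1L else 2L
  if (design$total_plots %% denom != 0L) {
    stop("plot budget ", design$total_plots, " is not divisible by ",
         denom, " (replicates x processes) for scheme '", scheme, "'",
         call. = FALSE)
  }
  design$total_plots %/% denom
}

#' Number of candidates selected from those tested
#'
#' Rounds `tested * rate` half-up, with a floor of one selected candidate.
#'
#' @param tested Number of candidates tested per species.
#' @param rate Selection rate in (0, 1].
#' @return Integer count selected.
#' @examples
#' candidates_selected(300, 0.10)  # 30
#' @export
candidates_selected <- function(tested, rate) {
  if (tested < 1) stop("tested must be at least 1", call. = FALSE)
  if (rate <= 0 || rate > 1) stop("rate must be in (0, 1]", call. = FALSE)
  max(1L, as.integer(floor(tested * rate + 0.5)))
}

#' Generic truncation-selection response kernel
#'
#' All expected responses share the pattern
#' `theta * phi * i * Cov(criterion, target) / sd(criterion)`: the covariance
#' between the selection criterion and the genetic value transmitted to the
#' next cycle, scaled by the selection intensity and the criterion standard
#' deviation, times the sexes/progeny-type coefficient.
#'
#' @param intensity Selection intensity (standard-deviation units).
#' @param theta_phi Product of the theta and phi coefficients.
#' @param criterion_sd Standard deviation of the selection criterion; must be
#'   strictly positive.
#' @param covariance Covariance between criterion and transmitted value.
#' @return Expected gain in trait units; sign follows the covariance.
#' @export
response_kernel <- function(intensity, theta_phi, criterion_sd, covariance) {
  if (criterion_sd <= 0) {
    stop("criterion standard deviation must be positive; the model is ",
         "degenerate", call. = FALSE)
  }
  theta_phi * intensity * covariance / criterion_sd
}
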