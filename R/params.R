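#' Genetic parameters of one species in the mixture model
#'
#' Bundles the variance components and correlations that describe how progeny
#' families of one species behave in mixture and in pure stand: the variance
#' of the direct effect (the family's effect on its own species' contribution
#' to the mixture performance), the variance of the associate effect (its
#' effect on the companion species' contribution), the correlation between
#' the two, and the pure-stand genetic effect with its correlations to the
#' mixture effects.
#'
#' @param var_direct Variance of the direct effect v (trait units squared).
#' @param var_associate Variance of the associate effect a (trait units
#'   squared).
#' @param rho_va Correlation between direct and associate effects, in
#'   \[-1, 1\].
#' @param var_pure Variance of the pure-stand genetic effect p. Pure-stand
#'   responses only depend on it through the design heritability, so the
#'   default of 1 is a harmless scale convention.
#' @param eta Correlation between the pure-stand effect and the direct effect.
#' @param omega Correlation between the pure-stand effect and the associate
#'   effect.
#' @param pure_design_h2 Design heritability of the pure-stand selection
#'   criterion, i.e. the ratio of genetic to total variance of the
#'   family-mean performance under the pure-stand trial design; in (0, 1].
#' @return An object of class `species_params` (a validated list).
#' @examples
#' species_params(var_direct = 1, var_associate = 0.5, rho_va = -0.5)
#' @export
species_params <- function(var_direct,
                           var_associate,
                           rho_va = 0,
                           var_pure = 1,
                           eta = NA_real_,
                           omega = NA_real_,
                           pure_design_h2 = NA_real_) {
  obj <- list(
    var_direct = as.numeric(var_direct),
    var_associate = as.numeric(var_associate),
    rho_va = as.numeric(rho_va),
    var_pure = as.numeric(var_pure),
    eta = as.numeric(eta),
    omega = as.numeric(omega),
    pure_design_h2 = as.numeric(pure_design_h2)
  )
  class(obj) <- "species_params"
  validate_species_params(obj)
  obj
}

validate_species_params <- function(x) {
  check_var(x$var_direct, "var_direct")
  check_var(x$var_associate, "var_associate")
  check_var(x$var_pure, "var_pure")
  check_cor(x$rho_va, "rho_va")
  if (!is.na(x$eta)) check_cor(x$eta, "eta")
  if (!is.na(x$omega)) check_cor(x$omega, "omega")
  if (!is.na(x$pure_design_h2) &&
      (x$pure_design_h2 <= 0 || x$pure_design_h2 > 1)) {
    stop("invalid parameter 'pure_design_h2': must be in (0, 1], got ",
         x$pure_design_h2, call. = FALSE)
  }
  invisible(x)
}

check_var <- function(v, name) {
  if (length(v) != 1L || is.na(v) || v < 0) {
    stop("invalid parameter '", name, "': variance must be a single ",
         "non-negative number", call. = FALSE)
  }
  invisible(v)
}

check_cor <- function(r, name) {
  if (length(r) != 1L || is.na(r) || r < -1 || r > 1) {
    stop("invalid parameter '", name, "': correlation must be in [-1, 1]",
         call. = FALSE)
  }
  invisible(r)
}

#' Full parameter set of the two-species mixture model
#'
#' The observed contribution of species 1 to one plot of a pair mixture is
#' modelled as `x1 = u1 + v1 + a2 + (va)12 + e1`: the species baseline, the
#' direct effect of its own family, the associate effect of the partner
#' family, a pair-specific direct-by-associate interaction, and a plot error.
#' Species 2 mirrors this. The mixture performance is `y = x1 + x2`, whose
#' plot error is `eps = e1 + e2` with variance `var_plot_error_mixture`.
#'
#' All covariances are parameterized through correlations; a zero variance on
#' either side forces the corresponding covariance to zero regardless of the
#' supplied correlation.
#'
#' When only `var_plot_error_mixture` is supplied, the error components of
#' the two observed species contributions default to
#' `var_e1 = var_e2 = var_plot_error_mixture` with `rho_e1_e2 = -0.5`, which
#' reproduces the mixture plot-error variance exactly. Supplying all three
#' overrides the split (it must still recompose to
#' `var_plot_error_mixture`).
#'
#' @param species1,species2 [species_params()] objects.
#' @param var_va_12 Variance of the interaction effect (va)12 entering the
#'   species-1 contribution.
#' @param var_va_21 Variance of the interaction effect (va)21 entering the
#'   species-2 contribution.
#' @param rho_va12_va21 Correlation between the two interaction effects.
#' @param var_plot_error_mixture Plot-error variance of the observed mixture
#'   performance (the variance of `e1 + e2`).
#' @param var_e1,var_e2 Optional error variances of the observed species
#'   contributions.
#' @param rho_e1_e2 Optional correlation between the two error components.
#' @param mean_u1,mean_u2 Baseline species effects in mixture (default 0).
#' @param mean_u1_pure Baseline of species 1 in pure stand (default 0).
#' @return An object of class `mixture_params`.
#' @examples
#' sp <- species_params(1, 0.5, rho_va = -0.5)
#' mixture_params(sp, sp, var_va_12 = 0.25, var_va_21 = 0.25,
#'                rho_va12_va21 = -0.5, var_plot_error_mixture = 2)
#' @export
mixture_params <- function(species1,
                           species2,
                           var_va_12 = 0,
                           var_va_21 = 0,
                           rho_va12_va21 = 0,
                           var_plot_error_mixture = 0,
                           var_e1 = NULL,
                           var_e2 = NULL,
                           rho_e1_e2 = NULL,
                           mean_u1 = 0,
                           mean_u2 = 0,
                           mean_u1_pure = 0) {
  stopifnot(inherits(species1, "species_params"),
            inherits(species2, "species_params"))
  check_var(var_va_12, "var_va_12")
  check_var(var_va_21, "var_va_21")
  check_cor(rho_va12_va21, "rho_va12_va21")
  check_var(var_plot_error_mixture, "var_plot_error_mixture")

  supplied <- !is.null(var_e1) || !is.null(var_e2) || !is.null(rho_e1_e2)
  if (supplied) {
    if (is.null(var_e1) || is.null(var_e2) || is.null(rho_e1_e2)) {
      stop("var_e1, var_e2 and rho_e1_e2 must be supplied together",
           call. = FALSE)
    }
    check_var(var_e1, "var_e1")
    check_var(var_e2, "var_e2")
    check_cor(rho_e1_e2, "rho_e1_e2")
    recomposed <- var_e1 + var_e2 + 2 * rho_e1_e2 * sqrt(var_e1 * var_e2)
    ref <- max(var_plot_error_mixture, .Machine$double.eps)
    if (abs(recomposed - var_plot_error_mixture) > 1e-9 * ref) {
      stop("error split does not recompose: var_e1 + var_e2 + ",
           "2*rho_e1_e2*sqrt(var_e1*var_e2) = ", recomposed,
           " but var_plot_error_mixture = ", var_plot_error_mixture,
           call. = FALSE)
    }
  } else {
    # default split: each species' observed-contribution error carries the
    # full mixture plot-error variance, with correlation -1/2 so the two
    # recompose to eps = e1 + e2 exactly
    var_e1 <- var_plot_error_mixture
    var_e2 <- var_plot_error_mixture
    rho_e1_e2 <- -0.5
  }

  obj <- list(
    species1 = species1,
    species2 = species2,
    var_va_12 = as.numeric(var_va_12),
    var_va_21 = as.numeric(var_va_21),
    rho_va12_va21 = as.numeric(rho_va12_va21),
    var_plot_error_mixture = as.numeric(var_plot_error_mixture),
    var_e1 = as.numeric(var_e1),
    var_e2 = as.numeric(var_e2),
    rho_e1_e2 = as.numeric(rho_e1_e2),
    mean_u1 = as.numeric(mean_u1),
    mean_u2 = as.numeric(mean_u2),
    mean_u1_pure = as.numeric(mean_u1_pure)
  )
  class(obj) <- "mixture_params"
  obj
}

# covariance from a correlation and two variances; zero variance on either
# side forces it to 0 (the correlation is then meaningless and ignored)
cov_from_cor <- function(rho, var_x, var_y) {
  if (var_x == 0 || var_y == 0) return(0)
  rho * sqrt(var_x * var_y)
}

#' Derived variance components of the mixture model
#'
#' Computes the general-mixture-ability (GMA) variances `g = v + a`, the
#' specific-mixture-ability (SMA) variance `d = (va)12 + (va)21`, the genetic
#' variances and covariance of the two species contributions under pair
#' mixtures, and all covariances reconstructed from correlations.
#'
#' @param params A [mixture_params()] object.
#' @return A list of class `derived_components` with elements `var_gma_1`,
#'   `var_gma_2`, `var_sma`, `var_Gx1`, `var_Gx2`, `cov_Gx1_Gx2`,
#'   `cov_v1_a1`, `cov_v2_a2`, `cov_va12_va21`.
#' @examples
#' sp <- species_params(1, 0.5, rho_va = -0.5)
#' p <- mixture_params(sp, sp, 0.25, 0.25, -0.5, 2)
#' derive_components(p)$var_gma_1  # 1.5 - sqrt(0.5)
#' @export
derive_components <- function(params) {
  stopifnot(inherits(params, "mixture_params"))
  s1 <- params$species1
  s2 <- params$species2
  cov_v1_a1 <- cov_from_cor(s1$rho_va, s1$var_direct, s1$var_associate)
  cov_v2_a2 <- cov_from_cor(s2$rho_va, s2$var_direct, s2$var_associate)
  cov_va12_va21 <- cov_from_cor(params$rho_va12_va21,
                                params$var_va_12, params$var_va_21)
  out <- list(
    var_gma_1 = s1$var_direct + s1$var_associate + 2 * cov_v1_a1,
    var_gma_2 = s2$var_direct + s2$var_associate + 2 * cov_v2_a2,
    var_sma = params$var_va_12 + params$var_va_21 + 2 * cov_va12_va21,
    var_Gx1 = s1$var_direct + s2$var_associate + params$var_va_12,
    var_Gx2 = s2$var_direct + s1$var_associate + params$var_va_21,
    cov_Gx1_Gx2 = cov_v1_a1 + cov_v2_a2 + cov_va12_va21,
    cov_v1_a1 = cov_v1_a1,
    cov_v2_a2 = cov_v2_a2,
    cov_va12_va21 = cov_va12_va21
  )
  class(out) <- "derived_components"
  out
}

#' Read mixture-model parameters from a JSON configuration file
#'
#' The JSON keys mirror the argument names of [species_params()] and
#' [mixture_params()]: top-level keys `species1` and `species2` hold the
#' per-species blocks; the remaining top-level keys are passed to
#' [mixture_params()]. Unknown keys are rejected so that a typo such as
#' `"rho_va21_va12"` fails loudly instead of silently taking a default.
#'
#' @param path Path to a JSON file.
#' @return A [mixture_params()] object.
#' @export
read_mixture_params <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  species_keys <- c("var_direct", "var_associate", "rho_va", "var_pure",
                    "eta", "omega", "pure_design_h2")
  top_keys <- c("species1", "species2", "var_va_12", "var_va_21",
                "rho_va12_va21", "var_plot_error_mixture",
                "var_e1", "var_e2", "rho_e1_e2",
                "mean_u1", "mean_u2", "mean_u1_pure")
  unknown <- setdiff(names(cfg), top_keys)
  if (length(unknown) > 0) {
    stop("unknown key(s) in parameter config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sp in c("species1", "species2")) {
    if (is.null(cfg[[sp]])) stop("missing '", sp, "' block", call. = FALSE)
    unknown <- setdiff(names(cfg[[sp]]), species_keys)
    if (length(unknown) > 0) {
      stop("unknown key(s) in '", sp, "' block: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  s1 <- do.call(species_params, cfg$species1)
  s2 <- do.call(species_params, cfg$species2)
  rest <- cfg[setdiff(names(cfg), c("species1", "species2"))]
  do.call(mixture_params, c(list(species1 = s1, species2 = s2), rest))
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("Two-species mixture model parameters\n")
  cat(sprintf("  species 1: var(v) = %g, var(a) = %g, rho(v,a) = %g\n",
              x$species1$var_direct, x$species1$var_associate,
              x$species1$rho_va))
  cat(sprintf("  species 2: var(v) = %g, var(a) = %g, rho(v,a) = %g\n",
              x$species2$var_direct, x$species2$var_associate,
              x$species2$rho_va))
  cat(sprintf("  interactions: var((va)12) = %g, var((va)21) = %g, rho = %g\n",
              x$var_va_12, x$var_va_21, x$rho_va12_va21))
  cat(sprintf("  plot error: var(eps) = %g (var_e1 = %g, var_e2 = %g, rho = %g)\n",
              x$var_plot_error_mixture, x$var_e1, x$var_e2, x$rho_e1_e2))
  invisible(x)
}
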