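# symmetric error split of the mixture plot error into the two observed
# species contributions at a chosen error correlation:
# var_e1 = var_e2 = var_eps / (2 + 2*rho_e) recomposes to var_eps exactly
symmetric_error_split <- function(var_eps, rho_e) {
  if (rho_e <= -1) stop("rho_e must be > -1 for a symmetric split",
                        call. = FALSE)
  v <- var_eps / (2 + 2 * rho_e)
  list(var_e1 = v, var_e2 = v, rho_e1_e2 = rho_e)
}

# parameter point shared by all presets: unit direct-effect variances, plot
# error twice the direct variance, interaction variances half the companion
# associate variance, all three rho-va correlations equal
preset_params <- function(rho, sa1, sa2, rho_e = -0.5,
                          eta = NA_real_, omega = NA_real_,
                          pure_h2 = NA_real_) {
  var_eps <- 2
  es <- symmetric_error_split(var_eps, rho_e)
  mixture_params(
    species1 = species_params(1, sa1, rho_va = rho, eta = eta, omega = omega,
                              pure_design_h2 = pure_h2),
    species2 = species_params(1, sa2, rho_va = rho, eta = eta, omega = omega,
                              pure_design_h2 = pure_h2),
    var_va_12 = sa2 / 2,
    var_va_21 = sa1 / 2,
    rho_va12_va21 = rho,
    var_plot_error_mixture = var_eps,
    var_e1 = es$var_e1, var_e2 = es$var_e2, rho_e1_e2 = es$rho_e1_e2
  )
}

rho_axis <- function() seq(-1, 1, by = 0.125)

#' Parameter-grid specification for the numeric investigations
#'
#' A `grid_spec` names a preset scenario (or a custom one) and carries the
#' parameter axes to sweep and the fixed settings. The presets encode the
#' standard investigation settings: unit direct-effect variances, plot-error
#' variance 2, three replicates, selection rates 10% (pair scheme) / 20%
#' (parallel schemes), theta = phi = 1, interaction variances half the
#' companion associate variance, and an error-component correlation of -0.5
#' (+0.5 for the `s2`/`s3` variants).
#'
#' * `fig4` — mixture-performance responses of the pair scheme (before and
#'   after recombination) and the parallel scheme, across the rho-va
#'   correlation, at two associate-variance levels.
#' * `fig5` — ratio of the pure-stand correlative response to the parallel
#'   direct response across rho-va, associate variance, and the pure-stand
#'   correlations eta and omega (pure-stand design heritability 0.6).
#' * `fig6` — contribution responses under plain parallel selection for
#'   three asymmetric associate-variance cases.
#' * `fig7` (`s2`) — pair-scheme index tuned to equal before-recombination
#'   contribution responses; before/after responses and the plain-selection
#'   reference.
#' * `fig8` (`s3`) — parallel-scheme index pair optimized for the mixture
#'   response under equal cumulated contribution responses, with per-process
#'   breakdown and the plain-selection reference.
#'
#' @param preset One of `"fig4"`, `"fig5"`, `"fig6"`, `"fig7"`, `"fig8"`,
#'   `"s2"`, `"s3"`, `"custom"`.
#' @param axes For `"custom"`: a named list of parameter value vectors; must
#'   contain `rho` and may contain `sa1`, `sa2`, `eta`, `omega`.
#' @param fixed For `"custom"`: named list overriding fixed settings
#'   (`rho_e`, `pure_h2`, `schemes`).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(preset = c("fig4", "fig5", "fig6", "fig7", "fig8",
                                 "s2", "s3", "custom"),
                      axes = NULL, fixed = NULL) {
  preset <- match.arg(preset)
  cases3 <- list(c(0.5, 0.1), c(1, 0.1), c(1, 0.5))
  spec <- switch(preset,
    fig4 = list(axes = list(rho = rho_axis(),
                            sa = list(c(0.1, 0.1), c(0.5, 0.5))),
                fixed = list(rho_e = -0.5, task = "compare_schemes")),
    fig5 = list(axes = list(rho = rho_axis(),
                            sa = list(c(0.1, 0.1), c(0.5, 0.5)),
                            eta = c(-0.25, 0.5, 0.75),
                            omega = c(-0.5, 0, 0.5)),
                fixed = list(rho_e = -0.5, pure_h2 = 0.6,
                             task = "pure_vs_sgma")),
    fig6 = list(axes = list(rho = rho_axis(), sa = cases3),
                fixed = list(rho_e = -0.5, task = "contributions")),
    fig7 = list(axes = list(rho = rho_axis(), sa = cases3),
                fixed = list(rho_e = -0.5, task = "srma_index")),
    s2 = list(axes = list(rho = rho_axis(), sa = cases3),
              fixed = list(rho_e = 0.5, task = "srma_index")),
    fig8 = list(axes = list(rho = rho_axis(), sa = cases3),
                fixed = list(rho_e = -0.5, task = "sgma_index")),
    s3 = list(axes = list(rho = rho_axis(), sa = cases3),
              fixed = list(rho_e = 0.5, task = "sgma_index")),
    custom = {
      if (is.null(axes) || is.null(axes$rho)) {
        stop("a custom grid needs at least a 'rho' axis", call. = FALSE)
      }
      if (is.null(axes$sa)) axes$sa <- list(c(0.5, 0.5))
      list(axes = axes,
           fixed = utils::modifyList(
             list(rho_e = -0.5, task = "compare_schemes"),
             if (is.null(fixed)) list() else fixed))
    })
  structure(c(spec, list(preset = preset)), class = "grid_spec")
}

#' Evaluate a parameter grid
#'
#' Runs the scheme comparisons of a [grid_spec()] over every combination of
#' its axes and returns one row per combination. Rows where an index target
#' cannot be solved are retained with `status` set to the error message.
#'
#' @param spec A [grid_spec()] object.
#' @return A data frame; columns depend on the preset task but always
#'   include the varied parameters and a `status` column (`"ok"` or the
#'   failure message). Deterministic: re-running a preset reproduces the
#'   table exactly.
#' @export
run_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  ax <- spec$axes
  fixed <- spec$fixed
  d_srma <- basic_design("srma")
  d_par <- basic_design("sgma")
  combos <- expand.grid(
    i_rho = seq_along(ax$rho),
    i_sa = seq_along(ax$sa),
    i_eta = seq_along(if (is.null(ax$eta)) NA else ax$eta),
    i_omega = seq_along(if (is.null(ax$omega)) NA else ax$omega)
  )
  rows <- lapply(seq_len(nrow(combos)), function(j) {
    rho <- ax$rho[combos$i_rho[j]]
    sa <- ax$sa[[combos$i_sa[j]]]
    eta <- if (is.null(ax$eta)) NA_real_ else ax$eta[combos$i_eta[j]]
    omega <- if (is.null(ax$omega)) NA_real_ else ax$omega[combos$i_omega[j]]
    base <- data.frame(rho = rho, sa1 = sa[1], sa2 = sa[2],
                       eta = eta, omega = omega)
    res <- tryCatch(
      grid_row(fixed$task, rho, sa, eta, omega, fixed, d_srma, d_par),
      error = function(e) data.frame(status = conditionMessage(e)))
    if (is.null(res$status)) res$status <- "ok"
    cbind(base, res)
  })
  out <- do.call(rbind, lapply(rows, pad_columns,
                               all_names = unique(unlist(lapply(rows, names)))))
  rownames(out) <- NULL
  out
}

pad_columns <- function(df, all_names) {
  for (nm in setdiff(all_names, names(df))) df[[nm]] <- NA
  df[all_names]
}

grid_row <- function(task, rho, sa, eta, omega, fixed, d_srma, d_par) {
  p <- preset_params(rho, sa[1], sa[2], rho_e = fixed$rho_e,
                     eta = eta, omega = omega,
                     pure_h2 = if (is.null(fixed$pure_h2)) NA_real_
                               else fixed$pure_h2)
  unit <- index_weights(1, 1)
  if (task == "compare_schemes") {
    before <- srma_responses_before(p, d_srma, unit)
    after <- srma_responses_after(p, d_srma, unit)
    gma <- sgma_cumulated(p, d_par, unit)
    data.frame(dG_before_srma = before$dG_total,
               dG_after_srma = after$dG_total,
               dG_sgma = gma$dG_total)
  } else if (task == "pure_vs_sgma") {
    gma <- sgma_cumulated(p, d_par, unit)
    pure <- pure_stand_responses(p, basic_design("pure"))
    ratio <- if (gma$dG_total <= 0) NA_real_ else pure$dG_total / gma$dG_total
    out <- data.frame(dG_pure = pure$dG_total, dG_sgma = gma$dG_total,
                      ratio_pure_sgma = ratio)
    if (gma$dG_total <= 0) out$status <- "ratio undefined: dG_sgma <= 0"
    out
  } else if (task == "contributions") {
    gma <- sgma_cumulated(p, d_par, unit)
    after <- srma_responses_after(p, d_srma, unit)
    data.frame(dG_sgma = gma$dG_total, dG_x1_sgma = gma$dG_x1,
               dG_x2_sgma = gma$dG_x2,
               dG_srma = after$dG_total, dG_x1_srma = after$dG_x1,
               dG_x2_srma = after$dG_x2)
  } else if (task == "srma_index") {
    w <- withCallingHandlers(solve_srma_index(p, c(1, 1)),
                             warning = function(w) invokeRestart("muffleWarning"))
    before <- srma_responses_before(p, d_srma, w)
    after <- srma_responses_after(p, d_srma, w)
    plain_b <- srma_responses_before(p, d_srma, unit)
    plain_a <- srma_responses_after(p, d_srma, unit)
    data.frame(alpha_1 = w$alpha_1, alpha_2 = w$alpha_2,
               dG_before = before$dG_total,
               dG_x1_before = before$dG_x1, dG_x2_before = before$dG_x2,
               dG_after = after$dG_total,
               dG_x1_after = after$dG_x1, dG_x2_after = after$dG_x2,
               dG_before_plain = plain_b$dG_total,
               dG_after_plain = plain_a$dG_total)
  } else if (task == "sgma_index") {
    opt <- optimize_sgma_indices(p, d_par, c(1, 1))
    r <- opt$responses
    plain <- sgma_cumulated(p, d_par, unit)
    data.frame(alpha_11 = opt$weights_1$alpha_1,
               alpha_21 = opt$weights_1$alpha_2,
               alpha_22 = opt$weights_2$alpha_1,
               alpha_12 = opt$weights_2$alpha_2,
               dG_sgma = r$dG_total, dG_x1 = r$dG_x1, dG_x2 = r$dG_x2,
               dG_x11 = r$by_process$dG_x11, dG_x21 = r$by_process$dG_x21,
               dG_x22 = r$by_process$dG_x22, dG_x12 = r$by_process$dG_x12,
               dG_sgma_plain = plain$dG_total)
  } else {
    stop("unknown grid task '", task, "'", call. = FALSE)
  }
}

#' Plot a grid result table
#'
#' Line plots of the grid responses against the rho-va correlation,
#' panelled by the variance settings, mirroring the axes of the numeric
#' investigations. One PNG file is written per associate-variance panel
#' group; for the pure-stand preset the y axis is the response ratio.
#'
#' @param results A data frame from [run_grid()].
#' @param spec The [grid_spec()] that produced it.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the written file paths (character(0) with a warning
#'   when the table is empty).
#' @export
plot_grid <- function(results, spec, out_dir = ".") {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(results) || nrow(results) == 0) {
    warning("empty results table: no figure written", call. = FALSE)
    return(invisible(character(0)))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  task <- spec$fixed$task
  results$panel <- sprintf("var(a1) = %g, var(a2) = %g",
                           results$sa1, results$sa2)
  value_cols <- switch(task,
    compare_schemes = c("dG_before_srma", "dG_after_srma", "dG_sgma"),
    pure_vs_sgma = "ratio_pure_sgma",
    contributions = c("dG_sgma", "dG_x1_sgma", "dG_x2_sgma"),
    srma_index = c("dG_before", "dG_x1_before", "dG_x2_before",
                   "dG_after", "dG_x1_after", "dG_x2_after"),
    sgma_index = c("dG_sgma", "dG_x11", "dG_x21", "dG_x22", "dG_x12"))
  long <- do.call(rbind, lapply(value_cols, function(cl) {
    data.frame(rho = results$rho, panel = results$panel,
               eta = results$eta, omega = results$omega,
               response = cl, value = results[[cl]])
  }))
  if (task == "pure_vs_sgma") {
    long$panel <- paste0(long$panel, "; eta = ", long$eta,
                         ", omega = ", long$omega)
  }
  gg <- ggplot2::ggplot(long,
          ggplot2::aes(x = rho, y = value, colour = response)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "rho(v, a) correlation",
                  y = if (task == "pure_vs_sgma") "response ratio"
                      else "expected response",
                  colour = NULL) +
    ggplot2::theme_bw()
  path <- file.path(out_dir, paste0(spec$preset, ".png"))
  ggplot2::ggsave(path, gg, width = 9, height = 6, dpi = 120)
  invisible(path)
}
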