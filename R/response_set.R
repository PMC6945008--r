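#' Expected-response container
#'
#' Holds the expected response of the mixture performance and of each
#' species' contribution for one selection scheme, with the conservation
#' identity `dG_total = dG_x1 + dG_x2` enforced at construction.
#'
#' @param dG_x1,dG_x2 Expected responses of the species-1 and species-2
#'   contributions (trait units).
#' @param flavor `"after_recombination"` (gains realized in the intercrossed
#'   offspring of selected candidates) or `"before_recombination"` (gains
#'   measured on the selected candidates themselves, including
#'   pair-specific interaction effects that are not inherited).
#' @param by_process Optional named list with the per-process breakdown for
#'   the parallel schemes.
#' @param weights Optional [index_weights()] used to reach these responses.
#' @return An object of class `response_set` with elements `dG_total`,
#'   `dG_x1`, `dG_x2`, `flavor`, `by_process`, `weights`.
#' @export
response_set <- function(dG_x1, dG_x2,
                         flavor = c("after_recombination",
                                    "before_recombination"),
                         by_process = NULL,
                         weights = NULL) {
  flavor <- match.arg(flavor)
  structure(list(
    dG_total = dG_x1 + dG_x2,
    dG_x1 = dG_x1,
    dG_x2 = dG_x2,
    flavor = flavor,
    by_process = by_process,
    weights = weights
  ), class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat("Expected one-cycle responses (", x$flavor, ")\n", sep = "")
  cat(sprintf("  mixture performance: %+.4f\n", x$dG_total))
  cat(sprintf("  species 1 contribution: %+.4f\n", x$dG_x1))
  cat(sprintf("  species 2 contribution: %+.4f\n", x$dG_x2))
  if (!is.null(x$by_process)) {
    bp <- x$by_process
    cat(sprintf("  process 1 (species-1 selection): own %+.4f, companion %+.4f\n",
                bp$dG_x11, bp$dG_x21))
    cat(sprintf("  process 2 (species-2 selection): own %+.4f, companion %+.4f\n",
                bp$dG_x22, bp$dG_x12))
  }
  invisible(x)
}

#' Flatten a response_set to a one-row data frame
#'
#' @param x A [response_set()].
#' @param ... Unused.
#' @return A one-row data frame with columns `flavor`, `dG_total`, `dG_x1`,
#'   `dG_x2` and, when available, the index weights and per-process gains.
#' @export
as.data.frame.response_set <- function(x, ...) {
  df <- data.frame(flavor = x$flavor,
                   dG_total = x$dG_total,
                   dG_x1 = x$dG_x1,
                   dG_x2 = x$dG_x2,
                   stringsAsFactors = FALSE)
  if (!is.null(x$weights)) {
    if (inherits(x$weights, "index_weights")) {
      df$alpha_1 <- x$weights$alpha_1
      df$alpha_2 <- x$weights$alpha_2
    } else if (is.list(x$weights)) {
      df$alpha_11 <- x$weights[[1]]$alpha_1
      df$alpha_21 <- x$weights[[1]]$alpha_2
      df$alpha_22 <- x$weights[[2]]$alpha_1
      df$alpha_12 <- x$weights[[2]]$alpha_2
    }
  }
  if (!is.null(x$by_process)) {
    df$dG_x11 <- x$by_process$dG_x11
    df$dG_x21 <- x$by_process$dG_x21
    df$dG_x22 <- x$by_process$dG_x22
    df$dG_x12 <- x$by_process$dG_x12
  }
  df
}
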