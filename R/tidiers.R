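#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an interference fit
#'
#' @param x A `gamma_sprinkle_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.gamma_sprinkle_fit <- function(x, ...) {
  tibble::tibble(
    term = c("nu", "p"),
    estimate = c(x$nu, x$p),
    std.error = sqrt(c(x$var_nu, x$var_p))
  )
}

#' One-row summary of an interference fit
#'
#' @param x A `gamma_sprinkle_fit`.
#' @param ... Unused.
#' @return Tibble: `logLik`, `n_gametes`, `convergence`, `boundary`.
#' @export
glance.gamma_sprinkle_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_gametes = x$n_gametes,
    convergence = x$convergence, boundary = x$boundary
  )
}
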