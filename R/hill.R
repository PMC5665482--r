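#' Hill regulation functions
#'
#' The circuit uses three Hill forms: an activating Hill function
#' \eqn{H^+(x) = x^n / (h_0^n + x^n)} (Notch input on the Hes promoter), a
#' repressing Hill function \eqn{H^-(x) = h_0^n / (h_0^n + x^n)} (dimer
#' repression of target promoters), and a *shifted* Hill function
#' \eqn{H^S(x) = H^-(x) + f\,H^+(x)} describing partial relief of Hes
#' auto-repression: `f = 0` is complete repression at saturating repressor,
#' `f = 1` removes the repressive arm entirely, and intermediate `f` leaves a
#' residual transcription fraction `f` at high repressor concentration.
#'
#' All three are vectorised over `x`.
#'
#' @param x Concentration (molecules per cell), non-negative.
#' @param h0 Hill factor: concentration at half-maximal regulation, positive.
#' @param n Hill coefficient (cooperativity), at least 1.
#' @param f Auto-repression factor in `[0, 1]`: residual transcription
#'   fraction retained under saturating repression.
#'
#' @return Numeric vector of regulation fractions. `hill_activating()` and
#'   `hill_repressing()` lie in `[0, 1]` and sum to 1; `shifted_hill()` lies
#'   in `[min(f, 1), 1]`.
#'
#' @examples
#' hill_activating(200, h0 = 100, n = 5) # 32/33
#' hill_repressing(100, h0 = 100, n = 5) # 0.5
#' shifted_hill(1e9, h0 = 100, n = 5, f = 0.05) # ~0.05 residual
#' @export
hill_activating <- function(x, h0, n) {
  check_hill_args(x, h0, n)
  r <- (x / h0)^n
  out <- r / (1 + r)
  out[x == 0] <- 0
  out
}

#' @rdname hill_activating
#' @export
hill_repressing <- function(x, h0, n) {
  1 - hill_activating(x, h0, n)
}

#' @rdname hill_activating
#' @export
shifted_hill <- function(x, h0, n, f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    abort("`f` must be a single number in [0, 1].")
  }
  hill_repressing(x, h0, n) + f * hill_activating(x, h0, n)
}

check_hill_args <- function(x, h0, n) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and non-negative.")
  }
  if (!is.numeric(h0) || length(h0) != 1L || !is.finite(h0) || h0 <= 0) {
    abort("`h0` must be a single positive number.")
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    abort("`n` must be a single number >= 1.")
  }
  invisible(NULL)
}
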