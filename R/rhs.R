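#' Construct a circuit state
#'
#' The instantaneous state of the circuit: Hes mRNA `m`, Hes monomer `p`,
#' Hes-Hes homodimer `p2`, Hes-ID heterodimer `pid`, proneural mRNA `ma`,
#' proneural monomer `a`, proneural homodimer `a2` (the "activity level" used
#' for fate classification) and proneural-ID heterodimer `aid`. All in
#' molecules per cell, non-negative.
#'
#' @param m,p,p2,pid,ma,a,a2,aid Species copy numbers, non-negative scalars.
#' @return A named numeric vector of class `circuit_state`.
#' @export
circuit_state <- function(m = 0, p = 0, p2 = 0, pid = 0,
                          ma = 0, a = 0, a2 = 0, aid = 0) {
  s <- c(m = m, p = p, p2 = p2, pid = pid, ma = ma, a = a, a2 = a2, aid = aid)
  if (any(!is.finite(s)) || any(s < 0)) {
    abort("All state components must be finite and non-negative.")
  }
  structure(s, class = c("circuit_state", "numeric"))
}

species_names <- function() c("m", "p", "p2", "pid", "ma", "a", "a2", "aid")

check_state <- function(state) {
  state <- unclass(state)
  if (!is.numeric(state) || length(state) != 8L) {
    abort("`state` must be a circuit_state (8 species).")
  }
  if (is.null(names(state))) names(state) <- species_names()
  if (any(!is.finite(state)) || any(state < 0)) {
    abort("State components must be finite and non-negative.")
  }
  state
}

#' Right-hand side of the Hes arm of the circuit
#'
#' Time-derivatives of `(m, p, p2, pid)`. Hes transcription is activated by
#' the Notch input through `H+(I)` and auto-repressed by the *delayed*
#' homodimer through the shifted Hill `H^S(p2(t - t_i))`; translation runs at
#' `p0 * m`; monomer, homodimer and heterodimer all degrade at the shared
#' protein rate `gp`; homodimerization consumes monomers at `2 k p^2` and
#' produces dimers at `k p^2`; heterodimerization with the constant free-ID
#' pool runs at `k p ID` (the pool is not depleted).
#'
#' @param state A [circuit_state()] (only the Hes components are used).
#' @param delayed_p2 The homodimer concentration at `t - t_i`.
#' @param params A [circuit_params()] object.
#' @return Named numeric vector of derivatives `(m, p, p2, pid)`, per min.
#' @seealso [proneural_rhs()], [simulate_circuit()]
#' @export
hes_rhs <- function(state, delayed_p2, params) {
  state <- check_state(state)
  validate_params(params)
  if (!is.finite(delayed_p2) || delayed_p2 < 0) {
    abort("`delayed_p2` must be finite and non-negative.")
  }
  p <- unclass(params)
  hs <- shifted_hill(delayed_p2, p$h0, p$n, p$f)
  c(
    m = p$m0 * hill_activating(p$I, p$h0, p$n) * hs - p$gm * state[["m"]],
    p = p$p0 * state[["m"]] - p$gp * state[["p"]] -
      2 * p$k * state[["p"]]^2 - p$k * state[["p"]] * p$ID,
    p2 = p$k * state[["p"]]^2 - p$gp * state[["p2"]],
    pid = p$k * state[["p"]] * p$ID - p$gp * state[["pid"]]
  )
}

#' Right-hand side of the proneural arm of the circuit
#'
#' Time-derivatives of `(ma, a, a2, aid)`. The proneural gene is repressed by
#' Hes-Hes homodimers and, with relative efficiency `eps`, by Hes-ID
#' heterodimers, pooled as `H-(p2 + eps * pid)` (no delay on this arm).
#' Monomer/dimer balances mirror the Hes protein arm: translation `pa0 * ma`,
#' degradation of all proneural species at `ga`, homodimerization into the
#' activity-carrying dimer `a2`, and sequestration by the ID pool into the
#' inactive heterodimer `aid`.
#'
#' @inheritParams hes_rhs
#' @return Named numeric vector of derivatives `(ma, a, a2, aid)`, per min.
#' @export
proneural_rhs <- function(state, params) {
  state <- check_state(state)
  validate_params(params)
  p <- unclass(params)
  repressor <- state[["p2"]] + p$eps * state[["pid"]]
  c(
    ma = p$ma0 * hill_repressing(repressor, p$h0, p$n) - p$ga * state[["ma"]],
    a = p$pa0 * state[["ma"]] - p$ga * state[["a"]] -
      2 * p$k * state[["a"]]^2 - p$k * state[["a"]] * p$ID,
    a2 = p$k * state[["a"]]^2 - p$ga * state[["a2"]],
    aid = p$k * state[["a"]] * p$ID - p$ga * state[["aid"]]
  )
}

# full 8-species derivative, used by tests and the deSolve cross-checks
circuit_rhs <- function(state, delayed_p2, params) {
  c(hes_rhs(state, delayed_p2, params), proneural_rhs(state, params))
}

#' Equilibrium mRNA copy number of a birth-death gene
#'
#' For constitutive transcription at rate `m0` balanced by first-order decay
#' at rate `b`, the equilibrium of `dm/dt = m0 - b m` is `m = m0 / b`. Used
#' for the back-of-envelope scaling of the Hes transcription rate: with a
#' ~20 min mRNA half-life (`b ~ 0.05`/min), 2000 transcripts per cell
#' require `m0 ~ 100` mRNA/min.
#'
#' @param m0 Transcription rate, mRNA/min (>= 0).
#' @param b Degradation rate, per min (> 0).
#' @return Equilibrium copy number `m0 / b`.
#' @examples
#' steady_state_mrna(100, 0.05) # 2000
#' @export
steady_state_mrna <- function(m0, b) {
  if (!is.numeric(m0) || any(m0 < 0)) abort("`m0` must be non-negative.")
  if (!is.numeric(b) || any(b <= 0)) abort("`b` must be positive.")
  m0 / b
}

#' Convert an RPM value to an absolute transcript count
#'
#' Reads-per-million is a within-cell fraction: `rpm / 1e6` of the cell's
#' total mRNA pool. Assuming ~0.5 million mRNA molecules per cell, the
#' observed Hes ceiling of 2^12 RPM corresponds to 2^11 (~2000) transcripts,
#' which anchors the transcription-rate upper limit `m0 = 200`.
#'
#' @param rpm Reads per million (>= 0), vectorised.
#' @param total_mrna Total mRNA molecules per cell; default `5e5`.
#' @return Transcript copy number(s): `rpm / 1e6 * total_mrna`.
#' @examples
#' rpm_to_transcripts(2^12) # 2048
#' @export
rpm_to_transcripts <- function(rpm, total_mrna = 5e5) {
  if (any(rpm < 0)) abort("`rpm` must be non-negative.")
  if (total_mrna <= 0) abort("`total_mrna` must be positive.")
  rpm / 1e6 * total_mrna
}
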