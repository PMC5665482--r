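#' Summarize the oscillation of one species
#'
#' Works on the post-transient window of a trajectory (or an explicit
#' `window`). Peaks are local maxima with prominence at least 1% of the
#' windowed range and at least 10 min separation, which ignores integrator
#' ripple. The series is called oscillatory when it has at least three such
#' peaks *and* a relative amplitude `(env_max - env_min) / max(mean, tiny)`
#' above `rel_amp_tol`; the period is the median inter-peak interval.
#'
#' @param traj A `circuit_trajectory` from [simulate_circuit()].
#' @param species One of `m`, `p`, `p2`, `pid`, `ma`, `a`, `a2`, `aid`.
#' @param window Optional `c(t0, t1)` (min) analysis window; default is the
#'   trajectory's post-transient span.
#' @param rel_amp_tol Relative peak-to-trough amplitude below which the
#'   series is called non-oscillatory (sustained). Default 0.05.
#' @return A one-row tibble of class `oscillation_summary`: `species`,
#'   `oscillatory` (logical), `period` (min; `NA` when non-oscillatory),
#'   `env_max`, `env_min`, `temporal_mean` (molecules), `n_peaks`.
#' @examples
#' traj <- simulate_circuit(circuit_params(), t_end = 3000, transient = 1000,
#'                          dt = 0.1)
#' summarize_oscillation(traj, "m")
#' @export
summarize_oscillation <- function(traj, species = "m", window = NULL,
                                  rel_amp_tol = 0.05) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  if (!species %in% species_names()) {
    abort(paste0("`species` must be one of: ",
                 paste(species_names(), collapse = ", ")))
  }
  if (is.null(window)) {
    window <- c(attr(traj, "transient"), max(traj$time))
  }
  if (window[2] > max(traj$time) + 1e-9 || window[1] < min(traj$time) - 1e-9) {
    abort("`window` extends beyond the trajectory.")
  }
  keep <- traj$time >= window[1] & traj$time <= window[2]
  tt <- traj$time[keep]
  y <- traj[[species]][keep]
  summarize_series(tt, y, species, rel_amp_tol)
}

# shared by summarize_oscillation and tests on synthetic signals
summarize_series <- function(tt, y, species = "m", rel_amp_tol = 0.05) {
  env_max <- max(y)
  env_min <- min(y)
  temporal_mean <- mean(y)
  dt <- tt[2] - tt[1]
  peaks <- find_series_peaks(y, dt)
  n_peaks <- nrow(peaks)
  rel_amp <- (env_max - env_min) / max(temporal_mean, .Machine$double.eps)
  oscillatory <- n_peaks >= 3 && rel_amp > rel_amp_tol
  period <- if (oscillatory) median(diff(tt[peaks$idx])) else NA_real_
  structure(
    tibble(species = species, oscillatory = oscillatory, period = period,
           env_max = env_max, env_min = env_min,
           temporal_mean = temporal_mean, n_peaks = n_peaks),
    class = c("oscillation_summary", class(tibble())))
}

# local maxima with minimum prominence 1% of range, minimum separation 10 min
find_series_peaks <- function(y, dt, min_sep_min = 10, min_prom_frac = 0.01) {
  rng <- diff(range(y))
  n <- length(y)
  if (rng <= 0 || n < 3) return(data.frame(idx = integer(0)))
  dy <- diff(y)
  cand <- which(dy[-length(dy)] > 0 & dy[-1] <= 0) + 1L
  if (length(cand) == 0) return(data.frame(idx = integer(0)))
  # prominence against the deepest valley separating the peak from its
  # neighbouring candidates (series ends count as valleys)
  bounds <- c(1L, cand, n)
  prom <- vapply(seq_along(cand), function(i) {
    left <- min(y[bounds[i]:cand[i]])
    right <- min(y[cand[i]:bounds[i + 2L]])
    y[cand[i]] - max(left, right)
  }, numeric(1))
  cand <- cand[prom >= min_prom_frac * rng]
  if (length(cand) == 0) return(data.frame(idx = integer(0)))
  # enforce minimum separation, keeping the taller of two close peaks
  min_sep <- max(1L, as.integer(round(min_sep_min / dt)))
  keep <- integer(0)
  for (i in cand[order(y[cand], decreasing = TRUE)]) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  }
  data.frame(idx = sort(keep))
}

#' Classify NSC fate from mean proneural activity
#'
#' Fate follows the mean activity level (temporal mean of the proneural
#' homodimer `a2`) relative to a reference: below `theta_q * reference` the
#' cell is quiescent (`qNSC`), above `theta_d * reference` it differentiates
#' (`Diff`), and in between it is an active, proliferating NSC (`aNSC`). The
#' reference is the maximal activity the same base circuit reaches with
#' neither Notch input nor IDs (see [reference_activity()]).
#'
#' @param mean_activity Mean proneural activity (molecules), vectorised.
#' @param reference Positive reference activity level.
#' @param theta_q,theta_d Band edges as fractions of `reference`;
#'   `theta_q < theta_d`. Defaults 0.05 and 0.5.
#' @return Factor with levels `qNSC`, `aNSC`, `Diff`.
#' @examples
#' classify_fate(c(0, 30, 95), reference = 100)
#' @export
classify_fate <- function(mean_activity, reference,
                          theta_q = 0.05, theta_d = 0.5) {
  if (!is.numeric(reference) || reference <= 0) {
    abort("`reference` must be positive.")
  }
  if (theta_q >= theta_d) abort("`theta_q` must be smaller than `theta_d`.")
  rel <- mean_activity / reference
  labels <- ifelse(rel < theta_q, "qNSC", ifelse(rel > theta_d, "Diff", "aNSC"))
  factor(labels, levels = c("qNSC", "aNSC", "Diff"))
}

#' Reference proneural activity of a base parameter set
#'
#' Mean post-transient proneural activity (`a2`) with Notch input and the
#' ID pool both set to zero — Hes is then silent and the proneural gene runs
#' unrepressed, so this is the maximal activity the circuit can reach. Used
#' as the normalising reference for [classify_fate()].
#'
#' @param params A [circuit_params()] object.
#' @inheritParams simulate_circuit
#' @return A positive scalar (molecules).
#' @export
reference_activity <- function(params, t_end = 4000, dt = 0.05,
                               transient = 2000) {
  ref_pars <- update_params(params, I = 0, ID = 0)
  traj <- simulate_circuit(ref_pars, t_end = t_end, dt = dt,
                           transient = transient)
  mean(post_transient(traj)$a2)
}
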