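sweep_axes <- c("I", "m0", "hes_protein_half_life", "t_i", "f", "ID")

set_axis <- function(params, name, value) {
  if (!name %in% sweep_axes) {
    abort(paste0("Unsupported sweep axis `", name, "`. Supported axes: ",
                 paste(sweep_axes, collapse = ", "), "."))
  }
  args <- setNames(list(value), name)
  do.call(update_params, c(list(params), args))
}

#' Notch dose-response of the circuit
#'
#' Integrates the circuit at each Notch input level in `I_grid` and
#' summarizes the oscillation of Hes mRNA (`m`) and proneural mRNA (`ma`):
#' the max/min envelopes and temporal mean trace the dose-response curves.
#' At `I = 0` the Hes arm is silent and proneural expression sits at its
#' maximal plateau; raising Notch lowers the proneural mean monotonically
#' but never to zero — the floor set by Hes auto-repression is what the ID
#' pool, not Notch, can breach.
#'
#' @param params Base [circuit_params()]; the `I` field is overridden.
#' @param I_grid Non-negative, sorted vector of Notch inputs (molecules).
#' @inheritParams simulate_circuit
#' @param rel_amp_tol Passed to [summarize_oscillation()].
#' @return A tibble with one row per `(I, species)` pair: `I`, `species`
#'   (`"m"` or `"ma"`), `oscillatory`, `period`, `env_max`, `env_min`,
#'   `temporal_mean`, `n_peaks`.
#' @export
notch_dose_response <- function(params, I_grid, t_end = 4000, dt = 0.05,
                                transient = 2000, rel_amp_tol = 0.05) {
  if (any(I_grid < 0) || is.unsorted(I_grid)) {
    abort("`I_grid` must be non-negative and sorted increasingly.")
  }
  purrr::map_dfr(I_grid, function(I) {
    traj <- withCallingHandlers(
      simulate_circuit(set_axis(params, "I", I), t_end = t_end, dt = dt,
                       transient = transient),
      error = function(e) e)
    if (inherits(traj, "error")) {
      abort(paste0("Integration failed at I = ", I, ": ",
                   conditionMessage(traj)))
    }
    dplyr::bind_rows(
      summarize_oscillation(traj, "m", rel_amp_tol = rel_amp_tol),
      summarize_oscillation(traj, "ma", rel_amp_tol = rel_amp_tol)
    ) |>
      dplyr::mutate(I = I, .before = 1)
  })
}

#' Two-parameter phase diagram of oscillation and fate
#'
#' Full-factorial sweep over two circuit parameters. Every grid cell is
#' integrated, the Hes mRNA oscillation is summarized, the mean proneural
#' activity (temporal mean of `a2`) is recorded, and a fate label is
#' assigned by [classify_fate()] against the activity reference of the base
#' parameter set (`I = 0`, `ID = 0`). Supported axes: `I`, `m0`,
#' `hes_protein_half_life`, `t_i`, `f`, `ID`.
#'
#' @param params Base [circuit_params()].
#' @param axis_x,axis_y Axis names (fields of [circuit_params()]).
#' @param grid_x,grid_y Numeric value grids for the two axes.
#' @inheritParams simulate_circuit
#' @param rel_amp_tol Passed to [summarize_oscillation()].
#' @param theta_q,theta_d Fate thresholds, see [classify_fate()].
#' @param reference Optional precomputed reference activity; default is
#'   [reference_activity()] of `params`.
#' @return A tibble of class `phase_diagram` with one row per grid cell:
#'   the two axis columns (named after the axes), `oscillatory`, `period`,
#'   `env_max`, `env_min`, `temporal_mean` (all for Hes mRNA),
#'   `mean_proneural` (mean activity `a2`, the quantity fate is read from),
#'   `mean_proneural_mrna` (mean expression `ma`) and `fate`. Attributes
#'   `axes` and `reference`.
#' @examples
#' \donttest{
#' pd <- sweep_2d(circuit_params(), "I", "ID",
#'                grid_x = c(0, 500), grid_y = c(0, 2000),
#'                t_end = 1500, transient = 700, dt = 0.1)
#' pd
#' }
#' @export
sweep_2d <- function(params, axis_x, axis_y, grid_x, grid_y,
                     t_end = 4000, dt = 0.05, transient = 2000,
                     rel_amp_tol = 0.05, theta_q = 0.05, theta_d = 0.5,
                     reference = NULL) {
  validate_params(params)
  for (ax in c(axis_x, axis_y)) {
    if (!ax %in% sweep_axes) {
      abort(paste0("Unsupported sweep axis `", ax, "`. Supported axes: ",
                   paste(sweep_axes, collapse = ", "), "."))
    }
  }
  reference <- reference %||%
    reference_activity(params, t_end = t_end, dt = dt, transient = transient)

  cells <- tidyr::expand_grid(x = grid_x, y = grid_y)
  res <- purrr::pmap_dfr(cells, function(x, y) {
    pars <- set_axis(set_axis(params, axis_x, x), axis_y, y)
    traj <- simulate_circuit(pars, t_end = t_end, dt = dt,
                             transient = transient)
    osc <- summarize_oscillation(traj, "m", rel_amp_tol = rel_amp_tol)
    pt <- post_transient(traj)
    tibble(
      x = x, y = y,
      oscillatory = osc$oscillatory, period = osc$period,
      env_max = osc$env_max, env_min = osc$env_min,
      temporal_mean = osc$temporal_mean,
      mean_proneural = mean(pt$a2),
      mean_proneural_mrna = mean(pt$ma)
    )
  })
  res$fate <- classify_fate(res$mean_proneural, reference,
                            theta_q = theta_q, theta_d = theta_d)
  names(res)[1:2] <- c(axis_x, axis_y)
  attr(res, "axes") <- c(axis_x, axis_y)
  attr(res, "reference") <- reference
  class(res) <- c("phase_diagram", class(res))
  res
}

#' @export
print.phase_diagram <- function(x, ...) {
  ax <- attr(x, "axes")
  cat(sprintf("<phase_diagram> %s x %s, %d cells (reference activity %.4g)\n",
              ax[1], ax[2], nrow(x), attr(x, "reference")))
  NextMethod()
}

#' Summarize a phase diagram
#'
#' @param x A `phase_diagram` from [sweep_2d()].
#' @param ... Unused.
#' @return One-row tibble: grid size, fraction of oscillatory cells, median
#'   oscillation period, and cell counts per fate label.
#' @export
glance.phase_diagram <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    frac_oscillatory = mean(x$oscillatory),
    median_period = median(x$period, na.rm = TRUE),
    n_qNSC = sum(x$fate == "qNSC"),
    n_aNSC = sum(x$fate == "aNSC"),
    n_Diff = sum(x$fate == "Diff")
  )
}
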