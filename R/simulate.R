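#' Integrate the delayed circuit
#'
#' Advances the full 8-species Hes/ID/proneural system with the delayed
#' homodimer auto-repression term by fixed-step 4th-order Runge-Kutta
#' (method of steps). The delayed argument `p2(t - t_i)` is read from the
#' stored solution grid by cubic (Catmull-Rom) interpolation; history for
#' `t < 0` is constant at the initial state. Tiny negative round-off
#' excursions (> -1e-9) are clipped to zero; anything larger, or a
#' non-finite value, aborts with the time of failure.
#'
#' @param params A [circuit_params()] object.
#' @param t_end Total simulated time, min. Default 4000.
#' @param dt Step size, min; must satisfy `dt <= t_i / 10`. Default 0.05.
#' @param transient Initial span (min) flagged for downstream analyses to
#'   discard; must be `< t_end`. Default 2000 (at a ~140 min period this
#'   leaves well over 10 cycles for summaries). Stored as an attribute; the
#'   returned trajectory always covers `[0, t_end]`.
#' @param init Initial [circuit_state()]; default all-zero.
#'
#' @return A tibble of class `circuit_trajectory` with columns `time` and the
#'   eight species (`m`, `p`, `p2`, `pid`, `ma`, `a`, `a2`, `aid`), one row
#'   per grid point (`t_end / dt + 1` rows), with attributes `params`, `dt`
#'   and `transient`. Deterministic: identical inputs give identical output.
#' @seealso [summarize_oscillation()], [sweep_2d()], [delayed_lookup()]
#' @examples
#' traj <- simulate_circuit(circuit_params(I = 500), t_end = 600, dt = 0.1,
#'                          transient = 0)
#' head(traj)
#' @export
simulate_circuit <- function(params, t_end = 4000, dt = 0.05,
                             transient = 2000, init = circuit_state()) {
  validate_params(params)
  if (dt <= 0 || (params$t_i >= dt && dt > params$t_i / 10)) {
    # a resolved delay needs dt <= t_i/10; t_i < dt is the ODE limit
    abort("`dt` must be positive and at most t_i / 10.")
  }
  if (transient < 0 || transient >= t_end) {
    abort("`transient` must lie in [0, t_end).")
  }
  init <- check_state(init)
  mat <- integrate_circuit_cpp(unname(init), pars_vector(params), t_end, dt)
  colnames(mat) <- c("time", species_names())
  traj <- as_tibble(as.data.frame(mat))
  attr(traj, "params") <- params
  attr(traj, "dt") <- dt
  attr(traj, "transient") <- transient
  class(traj) <- c("circuit_trajectory", class(traj))
  traj
}

#' Look up the (possibly delayed) state along a trajectory
#'
#' Returns the interpolated state at `t_query`. Queries before time zero
#' return the constant pre-simulation history (the trajectory's first row);
#' queries on a stored grid point return that row exactly; interior queries
#' use the same Catmull-Rom cubic the integrator uses for its delayed term
#' (which reproduces linear-in-time data exactly).
#'
#' @param traj A `circuit_trajectory`.
#' @param t_query Query time, min; must not exceed the last stored time.
#' @return A named numeric vector over the eight species.
#' @export
delayed_lookup <- function(traj, t_query) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  tt <- traj$time
  if (t_query > tt[length(tt)] + 1e-12) {
    abort("`t_query` is beyond the current end of the trajectory.")
  }
  species <- as.matrix(traj[species_names()])
  if (t_query <= 0) {
    return(setNames(species[1, ], species_names()))
  }
  dt <- attr(traj, "dt")
  s <- t_query / dt
  j <- floor(s)
  theta <- s - j
  j <- as.integer(j) + 1L # 1-based row index of left neighbour
  if (theta < 1e-12) {
    return(setNames(species[j, ], species_names()))
  }
  nr <- nrow(species)
  p1 <- species[j, ]
  p2 <- species[min(j + 1L, nr), ]
  p0 <- species[max(j - 1L, 1L), ]
  p3 <- species[min(j + 2L, nr), ]
  m1 <- (p2 - p0) / 2
  m2 <- (p3 - p1) / 2
  h <- c(2 * theta^3 - 3 * theta^2 + 1, theta^3 - 2 * theta^2 + theta,
         -2 * theta^3 + 3 * theta^2, theta^3 - theta^2)
  setNames(h[1] * p1 + h[2] * m1 + h[3] * p2 + h[4] * m2, species_names())
}

#' Post-transient portion of a trajectory
#'
#' @param traj A `circuit_trajectory`.
#' @return The rows with `time >= transient`, attributes preserved.
#' @export
post_transient <- function(traj) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  keep <- traj$time >= attr(traj, "transient")
  out <- traj[keep, ]
  attr(out, "params") <- attr(traj, "params")
  attr(out, "dt") <- attr(traj, "dt")
  attr(out, "transient") <- attr(traj, "transient")
  class(out) <- class(traj)
  out
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<circuit_trajectory> %d steps, dt = %g min, t_end = %g min (I = %g, ID = %g, f = %g)\n",
    nrow(x) - 1L, attr(x, "dt"), x$time[nrow(x)], p$I, p$ID, p$f))
  NextMethod()
}

#' Tidy a trajectory into long format
#'
#' @param x A `circuit_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `value` — the long-form
#'   export format.
#' @export
tidy.circuit_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"time",
                      names_to = "species", values_to = "value")
}

#' One-row summary of a trajectory
#'
#' Post-transient temporal means of every species plus the oscillation
#' period and flag of Hes mRNA.
#'
#' @param x A `circuit_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.circuit_trajectory <- function(x, ...) {
  pt <- post_transient(x)
  means <- colMeans(as.matrix(pt[species_names()]))
  osc <- summarize_oscillation(x, species = "m")
  tibble(
    !!!setNames(as.list(means), paste0("mean_", names(means))),
    oscillatory = osc$oscillatory, period = osc$period
  )
}
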