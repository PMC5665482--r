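# Shared fixtures: the standard parameter set and a fast simulation wrapper
# (coarser grid / shorter horizon than the defaults, still >= 10 cycles).

base_params <- function(...) {
  circuit_params(...)
}

fast_sim <- function(params, t_end = 3000, dt = 0.1, transient = 1500, ...) {
  simulate_circuit(params, t_end = t_end, dt = dt, transient = transient, ...)
}

# small deterministic RPM matrix for single-cell unit tests
toy_matrix <- function() {
  m <- rbind(
    Hes1 = c(100, 0, 3, 0),
    Hes5 = c(50, 0, 4, 0),
    Id3 = c(40, 30, 0, 0),
    Slc1a3 = c(5, 10, 2, 1),
    Actb = c(7, 7, 7, 7)
  )
  colnames(m) <- paste0("c", 1:4)
  m
}
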