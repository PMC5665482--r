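#' Circuit parameters
#'
#' Constructs the full parameter set of the delayed Hes/ID/proneural circuit.
#' Rates are per minute, concentrations in molecules per cell, times in
#' minutes. Degradation rates are derived from half-lives as
#' `g = log(2) / half_life`.
#'
#' Defaults are the standard simulation values: Hes transcription capped at
#' `m0 = 200` mRNA/min (the upper limit implied by an observed ceiling of
#' 2^12 RPM, i.e. ~2000 Hes transcripts out of ~0.5e6 mRNAs per cell), mRNA
#' and protein half-lives of 24 and 22 min, an intronic maturation delay of
#' 19 min with Hill coefficient 5 (a 25 min / n = 4 pairing behaves
#' equivalently), equal homo- and heterodimerization rate `k`, Hes-ID
#' repression efficiency `eps = 0.5` relative to Hes-Hes, and complete
#' auto-repression (`f = 0`). The translation rate `p0` and the shared Hill
#' factor `h0` are calibrated so that protein levels stay in a biological
#' range and Hes mRNA oscillates with a 2-3 h period over a broad band of
#' Notch input (see the package vignette).
#'
#' @param m0 Hes transcription rate, mRNA/min.
#' @param p0 Hes translation rate, protein per mRNA per min.
#' @param hes_mrna_half_life Hes mRNA half-life, min.
#' @param hes_protein_half_life Hes protein half-life, min (shared by
#'   monomer, homodimer and heterodimer).
#' @param k Dimerization rate constant, per molecule per min, shared by
#'   Hes-Hes, Hes-ID, proneural-proneural and proneural-ID pairing.
#' @param t_i Intronic (transcriptional) delay, min.
#' @param n Hill coefficient, >= 1.
#' @param h0 Hill factor (half-maximal concentration, molecules), shared by
#'   every Hill term in the circuit.
#' @param eps Repression strength of Hes-ID heterodimer relative to Hes-Hes
#'   homodimer, in (0, 1].
#' @param f Auto-repression factor in `[0, 1]` (0 = complete repression).
#' @param ID Constant free-ID pool, molecules.
#' @param I Constant Notch signal input, molecules.
#' @param ma0 Proneural transcription rate, mRNA/min.
#' @param pa0 Proneural translation rate; defaults to `p0`.
#' @param proneural_half_life Half-life of the proneural species, min.
#'
#' @return An object of class `circuit_params`: a named list of the fields
#'   above plus derived degradation rates `gm`, `gp`, `ga` (per min).
#' @seealso [read_circuit_params()], [simulate_circuit()]
#' @examples
#' pars <- circuit_params(I = 500)
#' pars$gm # log(2)/24
#' @export
circuit_params <- function(m0 = 200,
                           p0 = 0.05,
                           hes_mrna_half_life = 24,
                           hes_protein_half_life = 22,
                           k = 0.001,
                           t_i = 19,
                           n = 5,
                           h0 = 200,
                           eps = 0.5,
                           f = 0,
                           ID = 0,
                           I = 500,
                           ma0 = 200,
                           pa0 = NULL,
                           proneural_half_life = 24) {
  pars <- list(
    m0 = m0, p0 = p0,
    hes_mrna_half_life = hes_mrna_half_life,
    hes_protein_half_life = hes_protein_half_life,
    k = k, t_i = t_i, n = n, h0 = h0, eps = eps, f = f,
    ID = ID, I = I, ma0 = ma0,
    pa0 = pa0 %||% p0,
    proneural_half_life = proneural_half_life
  )
  pars$gm <- log(2) / pars$hes_mrna_half_life
  pars$gp <- log(2) / pars$hes_protein_half_life
  pars$ga <- log(2) / pars$proneural_half_life
  validate_params(structure(pars, class = "circuit_params"))
}

#' Modify circuit parameters
#'
#' Returns a copy of `params` with the named fields replaced and derived
#' degradation rates recomputed. Unknown field names are an error.
#'
#' @param params A [circuit_params()] object.
#' @param ... Named replacements for constructor fields (e.g. `I = 0`,
#'   `hes_protein_half_life = 40`).
#' @return A validated `circuit_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "circuit_params"))
  repl <- list(...)
  fields <- setdiff(names(unclass(params)), c("gm", "gp", "ga"))
  bad <- setdiff(names(repl), fields)
  if (length(bad) > 0) {
    abort(paste0("Unknown parameter field(s): ", paste(bad, collapse = ", "),
                 ". Supported: ", paste(fields, collapse = ", "), "."))
  }
  args <- unclass(params)[fields]
  args[names(repl)] <- repl
  do.call(circuit_params, args)
}

validate_params <- function(params) {
  p <- unclass(params)
  pos <- c("m0", "p0", "hes_mrna_half_life", "hes_protein_half_life",
           "k", "t_i", "h0", "ma0", "pa0", "proneural_half_life")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      abort(paste0("`", nm, "` must be a single positive number."))
    }
  }
  if (p$n < 1) abort("`n` must be >= 1.")
  if (p$eps <= 0 || p$eps > 1) abort("`eps` must lie in (0, 1].")
  if (p$f < 0 || p$f > 1) abort("`f` must lie in [0, 1].")
  if (p$ID < 0) abort("`ID` must be non-negative.")
  if (p$I < 0) abort("`I` must be non-negative.")
  stopifnot(
    isTRUE(all.equal(p$gm, log(2) / p$hes_mrna_half_life)),
    isTRUE(all.equal(p$gp, log(2) / p$hes_protein_half_life)),
    isTRUE(all.equal(p$ga, log(2) / p$proneural_half_life))
  )
  invisible(params)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  p <- unclass(x)
  for (nm in names(p)) {
    cat(sprintf("  %-22s %g\n", nm, p[[nm]]))
  }
  invisible(x)
}

# flat named vector handed to the compiled integrator
pars_vector <- function(params) {
  p <- unclass(params)
  c(m0 = p$m0, p0 = p$p0, gm = p$gm, gp = p$gp, k = p$k, t_i = p$t_i,
    n = p$n, h0 = p$h0, eps = p$eps, f = p$f, ID = p$ID, I = p$I,
    ma0 = p$ma0, pa0 = p$pa0, ga = p$ga)
}

#' Read or write circuit parameters as a YAML key-value file
#'
#' The file holds the constructor fields of [circuit_params()] as flat
#' `name: value` pairs (derived rates are recomputed on read, so editing a
#' half-life is enough). A bundled default file mirroring the standard
#' simulation values ships at
#' `system.file("extdata", "circuit_defaults.yaml", package = "hesidyn")`.
#'
#' @param file Path to a YAML file.
#' @param params A `circuit_params` object.
#' @return `read_circuit_params()` returns a `circuit_params` object;
#'   `write_circuit_params()` returns `file` invisibly.
#' @export
read_circuit_params <- function(file) {
  vals <- yaml::read_yaml(file)
  # YAML 1.1 parses a bare `n` key as a boolean; map it back to the
  # Hill-coefficient field
  names(vals)[names(vals) %in% c("FALSE", "no")] <- "n"
  fields <- setdiff(names(formals(circuit_params)), character())
  bad <- setdiff(names(vals), fields)
  if (length(bad) > 0) {
    abort(paste0("Unknown parameter field(s) in ", file, ": ",
                 paste(bad, collapse = ", ")))
  }
  do.call(circuit_params, vals)
}

#' @rdname read_circuit_params
#' @export
write_circuit_params <- function(params, file) {
  validate_params(params)
  p <- unclass(params)
  p <- p[setdiff(names(p), c("gm", "gp", "ga"))]
  yaml::write_yaml(p, file)
  invisible(file)
}
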