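#' Synthetic population designs
#'
#' A population design fixes everything the expression-matrix generators
#' sample from: the subpopulations and their cell counts, which marker
#' panels each subpopulation expresses, the log2-scale mean/sd of expressed
#' and silent marker genes, the dropout rate, and the background gene block.
#'
#' `adult_svz_design()` emulates adult subventricular-zone progenitors:
#' three NSC subpopulations defined by Hes (Hes1, Hes5) and Id3 expression —
#' Id3+Hes+ (quiescent-leaning, default 50 cells), Id3+Hes- (10),
#' Id3-Hes+ (active, with Delta-ligand and progenitor-marker expression, 25)
#' — plus 27 transit-amplifying progenitors (TAP) with low NSC markers and
#' high active/progenitor markers. Id2 mirrors Id3 so the Id2 and pooled
#' Id1-4 panel substitutions reproduce the same structure.
#'
#' `embryonic_design()` emulates embryonic ventricular-zone cells: radial
#' glia (high Hes, high radial-glia markers, high Id4; default 100 cells)
#' versus intermediate progenitors (high IP markers, low radial-glia
#' markers; 80 cells), with Id2 moderately expressed in both so that only
#' Id4 co-varies with Hes.
#'
#' Noise model: each gene's log2(RPM+1) value is Gaussian around its
#' designed mean (sd `expressed_sd` for expressed panels, `silent_sd`
#' otherwise), truncated at 0, followed by expression-dependent technical
#' dropout to zero: `P(drop) = dropout^(mean / 2)`, a zero-inflation curve
#' that leaves near-silent genes as exact zeros most of the time (~70% at
#' the default silent level), drops genes at the detection floor at roughly
#' the nominal `dropout` rate, and essentially never removes strongly
#' expressed markers. Values return to the RPM scale as `2^x - 1`.
#'
#' @param n_id_pos_hes_pos,n_id_pos_hes_neg,n_id_neg_hes_pos,n_tap Cell
#'   counts of the adult subpopulations (defaults 50/10/25/27).
#' @param n_rg,n_ip Cell counts of the embryonic populations.
#' @param expressed_mean,expressed_sd Log2-scale mean and sd of expressed
#'   marker genes. Defaults 6 and 1.
#' @param silent_mean,silent_sd Log2-scale mean and sd of silent marker
#'   genes. Defaults 0.3 and 0.3.
#' @param dropout Baseline dropout probability for a silent gene; attenuated
#'   with designed expression (see above). Default 0.1.
#' @param n_background Number of unstructured background genes. Default 200.
#' @param background_mean,background_sd Log2-scale background parameters.
#' @param seed Integer seed; fixes the full generated output.
#' @return An object of class `population_design`.
#' @export
adult_svz_design <- function(n_id_pos_hes_pos = 50, n_id_pos_hes_neg = 10,
                             n_id_neg_hes_pos = 25, n_tap = 27,
                             expressed_mean = 6, expressed_sd = 1,
                             silent_mean = 0.3, silent_sd = 0.3,
                             dropout = 0.1, n_background = 200,
                             background_mean = 1, background_sd = 0.5,
                             seed = 1L) {
  panels <- marker_panels()
  # panels expressed per subpopulation
  regimes <- list(
    IdPos_HesPos = c("id3", "id2", "hes", "nsc"),
    IdPos_HesNeg = c("id3", "id2", "nsc"),
    IdNeg_HesPos = c("hes", "nsc", "active", "delta"),
    TAP = c("active")
  )
  counts <- c(IdPos_HesPos = n_id_pos_hes_pos, IdPos_HesNeg = n_id_pos_hes_neg,
              IdNeg_HesPos = n_id_neg_hes_pos, TAP = n_tap)
  gene_sets <- list(
    id3 = "Id3", id2 = "Id2", hes = panels$hes, nsc = panels$nsc,
    active = panels$active, delta = panels$delta
  )
  extra_genes <- c("Id1", "Id4",
                   setdiff(unique(c(panels$radial_glia, panels$ip)),
                           unlist(gene_sets)))
  new_population_design(
    kind = "adult_svz", counts = counts, regimes = regimes,
    gene_sets = gene_sets, extra_genes = extra_genes,
    expressed_mean = expressed_mean, expressed_sd = expressed_sd,
    silent_mean = silent_mean, silent_sd = silent_sd, dropout = dropout,
    n_background = n_background, background_mean = background_mean,
    background_sd = background_sd, seed = seed
  )
}

#' @rdname adult_svz_design
#' @export
embryonic_design <- function(n_rg = 100, n_ip = 80,
                             expressed_mean = 6, expressed_sd = 1,
                             silent_mean = 0.3, silent_sd = 0.3,
                             dropout = 0.1, n_background = 200,
                             background_mean = 1, background_sd = 0.5,
                             seed = 1L) {
  panels <- marker_panels()
  regimes <- list(
    RG = c("hes", "radial_glia", "id4", "id2_mid"),
    IP = c("ip", "id2_mid")
  )
  counts <- c(RG = n_rg, IP = n_ip)
  gene_sets <- list(
    hes = panels$hes, radial_glia = panels$radial_glia, ip = panels$ip,
    id4 = "Id4", id2_mid = "Id2"
  )
  extra_genes <- c("Id1", "Id3",
                   setdiff(unique(c(panels$nsc, panels$active, panels$delta)),
                           unlist(gene_sets)))
  design <- new_population_design(
    kind = "embryonic", counts = counts, regimes = regimes,
    gene_sets = gene_sets, extra_genes = extra_genes,
    expressed_mean = expressed_mean, expressed_sd = expressed_sd,
    silent_mean = silent_mean, silent_sd = silent_sd, dropout = dropout,
    n_background = n_background, background_mean = background_mean,
    background_sd = background_sd, seed = seed
  )
  # Id2 sits at an intermediate level in both populations (expressed but
  # uncorrelated with Hes), unlike the Hes-covarying Id4
  design$panel_mean_override <- c(id2_mid = min(4, expressed_mean))
  design
}

new_population_design <- function(...) {
  design <- list(...)
  design$panel_mean_override <- design$panel_mean_override %||% numeric(0)
  validate_design(structure(design, class = "population_design"))
}

validate_design <- function(design) {
  d <- unclass(design)
  if (any(d$counts < 0)) abort("Cell counts must be non-negative.")
  for (nm in c("expressed_sd", "silent_sd", "background_sd")) {
    if (d[[nm]] < 0) abort(paste0("`", nm, "` must be non-negative."))
  }
  if (d$dropout < 0 || d$dropout > 1) abort("`dropout` must lie in [0, 1].")
  if (d$n_background < 0) abort("`n_background` must be non-negative.")
  if (!all(unlist(d$regimes) %in% c(names(d$gene_sets)))) {
    abort("Every regime entry must name a gene set.")
  }
  invisible(design)
}

# designed log2 mean for every gene in every subpopulation
design_profile <- function(design) {
  d <- unclass(design)
  genes <- unique(c(unlist(d$gene_sets, use.names = FALSE), d$extra_genes))
  if (d$n_background > 0) {
    genes <- c(genes, sprintf("Bg%03d", seq_len(d$n_background)))
  }
  pops <- names(d$counts)
  mu <- matrix(d$silent_mean, nrow = length(genes), ncol = length(pops),
               dimnames = list(genes, pops))
  mu[grepl("^Bg", genes), ] <- d$background_mean
  for (pop in pops) {
    for (set in d$regimes[[pop]]) {
      lvl <- if (set %in% names(d$panel_mean_override)) {
        d$panel_mean_override[[set]]
      } else {
        d$expressed_mean
      }
      gs <- d$gene_sets[[set]]
      mu[gs, pop] <- pmax(mu[gs, pop], lvl)
    }
  }
  mu
}

generate_from_design <- function(design) {
  validate_design(design)
  d <- unclass(design)
  mu <- design_profile(design)
  genes <- rownames(mu)
  pops <- names(d$counts)
  n_cells <- sum(d$counts)
  if (n_cells == 0) {
    mat <- matrix(numeric(0), nrow = length(genes), ncol = 0,
                  dimnames = list(genes, character(0)))
    return(list(matrix = mat,
                annotation = tibble(cell = character(0),
                                    label = factor(character(0), levels = pops))))
  }
  labels <- rep(pops, d$counts)
  cells <- sprintf("cell%03d", seq_len(n_cells))

  is_bg <- grepl("^Bg", genes)
  sd_gene_pop <- function(pop) {
    m <- mu[, pop]
    s <- ifelse(m >= (d$silent_mean + d$expressed_mean) / 2,
                d$expressed_sd, d$silent_sd)
    s[is_bg] <- d$background_sd
    s
  }

  set.seed(d$seed)
  x <- matrix(0, nrow = length(genes), ncol = n_cells,
              dimnames = list(genes, cells))
  for (j in seq_len(n_cells)) {
    m <- mu[, labels[j]]
    s <- sd_gene_pop(labels[j])
    val <- pmax(0, rnorm(length(genes), mean = m, sd = s))
    # expression-dependent zero inflation: near-silent genes drop out most
    # of the time, strong markers essentially never
    p_drop <- if (d$dropout == 0) 0 else pmin(1, d$dropout^(m / 2))
    val[rbinom(length(genes), 1, p_drop) == 1] <- 0
    x[, j] <- val
  }
  rpm <- 2^x - 1
  rpm[rpm < 0] <- 0 # guard against round-off at x = 0
  list(matrix = rpm,
       annotation = tibble(cell = cells,
                           label = factor(labels, levels = pops)))
}

#' Generate a synthetic adult SVZ expression matrix
#'
#' Samples an RPM genes x cells matrix with the subpopulation and
#' marker-panel structure of adult subventricular-zone progenitors (see
#' [adult_svz_design()]), together with the ground-truth labels and a cell
#' metadata table (`cell`, `annotation` = NSC/TAP, `region`, `read_count`,
#' `condition`) in the shape the classification pipeline consumes. With the
#' noise and dropout set to zero, [classify_cells()] recovers every true
#' label and [count_subpopulations()] returns exactly the design counts.
#'
#' @param design An [adult_svz_design()] object.
#' @return A list with elements `matrix` (RPM, genes x cells), `annotation`
#'   (tibble `cell`, `label` — the ground truth) and `metadata`.
#' @examples
#' sim <- generate_adult_svz(adult_svz_design(seed = 7))
#' dim(sim$matrix)
#' @export
generate_adult_svz <- function(design = adult_svz_design()) {
  if (!identical(unclass(design)$kind, "adult_svz")) {
    abort("`design` must come from adult_svz_design().")
  }
  sim <- generate_from_design(design)
  n <- nrow(sim$annotation)
  metadata <- tibble(
    cell = sim$annotation$cell,
    annotation = ifelse(sim$annotation$label == "TAP", "TAP", "NSC"),
    region = "SVZ",
    read_count = if (n > 0) round(stats::runif(n, 1.2e6, 4e6)) else numeric(0),
    condition = "control"
  )
  list(matrix = sim$matrix, annotation = sim$annotation, metadata = metadata)
}

#' Generate a synthetic embryonic VZ expression matrix
#'
#' Two populations — radial glia (high Hes, high radial-glia markers, high
#' Id4) and intermediate progenitors (high IP markers) — whose separation
#' is recovered by PC1 of [pca_embed()] and whose Id4 expression co-varies
#' with the Hes panel across cells, while Id2 does not.
#'
#' @param design An [embryonic_design()] object.
#' @return A list with elements `matrix` (RPM) and `annotation` (tibble
#'   `cell`, `label` with levels `RG`, `IP`).
#' @export
generate_embryonic <- function(design = embryonic_design()) {
  if (!identical(unclass(design)$kind, "embryonic")) {
    abort("`design` must come from embryonic_design().")
  }
  generate_from_design(design)
}
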