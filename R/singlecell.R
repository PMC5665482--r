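#' Default marker panels
#'
#' Named gene panels used throughout the single-cell validation analyses:
#' adult NSC identity markers, active NSC/progenitor markers, the Hes panel
#' inferred to report Notch activity, the four ID genes (individually
#' selectable), Delta ligands, embryonic radial-glia markers and
#' intermediate-progenitor markers.
#'
#' @return A named list of character vectors.
#' @export
marker_panels <- function() {
  list(
    nsc = c("Slc1a3", "Nr2e1", "Sox9", "Vcam1"),
    active = c("Ascl1", "Fos", "Egr1", "Sox4", "Sox11"),
    hes = c("Hes1", "Hes5"),
    id = c("Id1", "Id2", "Id3", "Id4"),
    delta = c("Dll1", "Dll3", "Dll4"),
    radial_glia = c("Slc1a3", "Pax6", "Sox2", "Pdgfd", "Gli3"),
    ip = c("Tbr2", "Elavl4", "Neurog1", "Neurod1", "Neurod4",
           "Ppp1r17", "Penk")
  )
}

# mouse/human symbol drift; user-extensible via the `synonyms` arguments
default_synonyms <- function() {
  c(Tbr2 = "Eomes")
}

check_expression_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix (genes x cells).")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort("`matrix` must have gene rownames and cell colnames.")
  }
  if (anyDuplicated(rownames(matrix))) abort("Gene identifiers must be unique.")
  if (anyDuplicated(colnames(matrix))) abort("Cell identifiers must be unique.")
  if (any(matrix < 0)) abort("RPM values must be non-negative.")
  invisible(matrix)
}

# case-insensitive panel-to-row matching with synonym expansion; warns about
# (never silently drops) unmatched genes
match_genes <- function(matrix, genes, synonyms = default_synonyms(),
                        panel_name = "panel") {
  rows <- rownames(matrix)
  lookup <- setNames(seq_along(rows), tolower(rows))
  idx <- integer(0)
  unmatched <- character(0)
  for (g in genes) {
    cands <- tolower(c(g, synonyms[names(synonyms) == g],
                       names(synonyms)[synonyms == g]))
    hit <- lookup[cands]
    hit <- hit[!is.na(hit)]
    if (length(hit) > 0) idx <- c(idx, hit[[1]]) else unmatched <- c(unmatched, g)
  }
  if (length(unmatched) > 0) {
    warn(paste0("Panel `", panel_name, "`: gene(s) not found in matrix: ",
                paste(unmatched, collapse = ", ")))
  }
  if (length(idx) == 0) {
    abort(paste0("Panel `", panel_name,
                 "`: none of its genes are present in the matrix."))
  }
  unique(idx)
}

#' Log-transform an RPM expression matrix
#'
#' Elementwise `log2(RPM + 1)`: zero maps to zero and the transform is
#' strictly monotone, so threshold-based classification commutes with it.
#'
#' @param matrix Numeric genes x cells matrix of RPM values (>= 0) with
#'   unique gene rownames and cell colnames.
#' @return Matrix of the same shape on the log2 scale.
#' @examples
#' m <- matrix(c(0, 1, 4095, 3), 2, 2,
#'             dimnames = list(c("Hes1", "Id3"), c("c1", "c2")))
#' log_transform(m)
#' @export
log_transform <- function(matrix) {
  check_expression_matrix(matrix)
  log2(matrix + 1)
}

#' Score cells on a marker panel
#'
#' The default score pools the panel on the RPM scale before the log:
#' `log2(1 + sum(RPM))` per cell, so a single-gene panel reduces exactly to
#' [log_transform()] of that gene's row. Alternatively (`method =
#' "mean_log"`) the mean of the per-gene `log2(RPM + 1)` values.
#'
#' @param matrix Genes x cells RPM matrix.
#' @param panel Character vector of gene symbols (matched case-insensitively,
#'   with synonym support; unmatched genes produce a warning, a fully
#'   unmatched panel an error).
#' @param method `"sum_rpm"` (default) or `"mean_log"`.
#' @param synonyms Named character vector of symbol synonyms.
#' @param panel_name Label used in messages.
#' @return A tibble with columns `cell` and `score` (log2 scale).
#' @examples
#' m <- matrix(c(3, 4), 2, 1, dimnames = list(c("Hes1", "Hes5"), "c1"))
#' panel_score(m, c("Hes1", "Hes5"))$score # log2(8) = 3
#' @export
panel_score <- function(matrix, panel, method = c("sum_rpm", "mean_log"),
                        synonyms = default_synonyms(),
                        panel_name = deparse(substitute(panel))) {
  check_expression_matrix(matrix)
  method <- match.arg(method)
  idx <- match_genes(matrix, panel, synonyms, panel_name)
  sub <- matrix[idx, , drop = FALSE]
  score <- switch(method,
    sum_rpm = log2(1 + colSums(sub)),
    mean_log = colMeans(log2(sub + 1))
  )
  tibble(cell = colnames(matrix), score = unname(score))
}

#' Classify cells into Hes/Id subpopulations
#'
#' A panel counts as "expressed" in a cell when its log2-scale score exceeds
#' `expressed_threshold` (default 1, i.e. roughly 1 RPM). The 2x2 of
#' (ID expressed, Hes expressed) yields `IdPos_HesPos`, `IdPos_HesNeg`,
#' `IdNeg_HesPos` or `DoubleNeg`; cells flagged as transit-amplifying
#' progenitors in the metadata keep the `TAP` label regardless of score.
#'
#' @param id_score,hes_score Tibbles from [panel_score()] (or numeric
#'   vectors aligned to `cells`).
#' @param expressed_threshold Non-negative log2-scale cutoff. Default 1.
#' @param tap Optional character vector of cell identifiers annotated TAP.
#' @param cells Cell identifiers; taken from the score tibbles when omitted.
#' @return A tibble of class `cell_annotation`: `cell`, `id_score`,
#'   `hes_score`, `label` (factor with levels `IdPos_HesPos`,
#'   `IdPos_HesNeg`, `IdNeg_HesPos`, `DoubleNeg`, `TAP`).
#' @export
classify_cells <- function(id_score, hes_score, expressed_threshold = 1,
                           tap = NULL, cells = NULL) {
  if (expressed_threshold < 0) abort("`expressed_threshold` must be >= 0.")
  if (is.data.frame(id_score)) {
    cells <- cells %||% id_score$cell
    id_score <- id_score$score
  }
  if (is.data.frame(hes_score)) {
    cells <- cells %||% hes_score$cell
    hes_score <- hes_score$score
  }
  if (is.null(cells)) cells <- paste0("cell", seq_along(id_score))
  if (length(id_score) != length(hes_score)) {
    abort("`id_score` and `hes_score` must have the same length.")
  }
  id_pos <- id_score > expressed_threshold
  hes_pos <- hes_score > expressed_threshold
  label <- dplyr::case_when(
    id_pos & hes_pos ~ "IdPos_HesPos",
    id_pos & !hes_pos ~ "IdPos_HesNeg",
    !id_pos & hes_pos ~ "IdNeg_HesPos",
    .default = "DoubleNeg"
  )
  if (!is.null(tap)) label[cells %in% tap] <- "TAP"
  out <- tibble(
    cell = cells, id_score = id_score, hes_score = hes_score,
    label = factor(label, levels = subpopulation_levels())
  )
  class(out) <- c("cell_annotation", class(out))
  out
}

subpopulation_levels <- function() {
  c("IdPos_HesPos", "IdPos_HesNeg", "IdNeg_HesPos", "DoubleNeg", "TAP")
}

#' Filter cells by metadata rules
#'
#' Subsets the columns of an expression matrix to the cells whose metadata
#' rows satisfy every rule, dplyr-style (e.g. `read_count > 1e6`,
#' `region == "VZ"`, `condition != "ischemia"`). Rules are conjunctive, so
#' their order never changes the result. The number of cells passing each
#' rule is reported with `message()`.
#'
#' @param matrix Genes x cells RPM matrix.
#' @param metadata Data frame with a `cell` column matching the matrix
#'   columns, plus whatever fields the rules use.
#' @param ... Unquoted filter expressions over metadata fields. A rule that
#'   references a missing field is an error.
#' @return The matrix restricted to passing cells, with the filtered
#'   metadata attached as attribute `metadata`.
#' @export
filter_cells <- function(matrix, metadata, ...) {
  check_expression_matrix(matrix)
  if (!"cell" %in% names(metadata)) {
    abort("`metadata` must contain a `cell` column.")
  }
  rules <- rlang::enquos(...)
  meta <- dplyr::semi_join(as_tibble(metadata),
                           tibble(cell = colnames(matrix)), by = "cell")
  for (i in seq_along(rules)) {
    vars <- all.vars(rlang::quo_get_expr(rules[[i]]))
    missing_fields <- setdiff(vars, names(meta))
    if (length(missing_fields) > 0) {
      abort(paste0("Filter rule references missing metadata field(s): ",
                   paste(missing_fields, collapse = ", ")))
    }
    before <- nrow(meta)
    meta <- dplyr::filter(meta, !!rules[[i]])
    message(sprintf("rule %d (%s): %d -> %d cells",
                    i, rlang::as_label(rules[[i]]), before, nrow(meta)))
  }
  out <- matrix[, meta$cell, drop = FALSE]
  attr(out, "metadata") <- meta
  out
}

#' PCA embedding of cells
#'
#' Centered (unscaled) principal components of the cells from a
#' log-transformed matrix, after dropping zero-variance genes. Component
#' signs follow a deterministic convention: the loading of largest absolute
#' value on each component is positive. Explained-variance fractions are
#' attached.
#'
#' @param matrix_log Genes x cells matrix on the log2 scale (see
#'   [log_transform()]).
#' @param n_components Number of components to return (default 2); must not
#'   exceed the number of cells.
#' @return A tibble of class `cell_pca`: `cell`, `PC1`, `PC2`, ... with
#'   attributes `explained_variance` (fractions, all components) and
#'   `rotation` (gene loadings for the returned components).
#' @export
pca_embed <- function(matrix_log, n_components = 2) {
  if (!is.matrix(matrix_log) || !is.numeric(matrix_log)) {
    abort("`matrix_log` must be a numeric matrix (genes x cells).")
  }
  n_cells <- ncol(matrix_log)
  if (n_cells < n_components) {
    abort("Fewer cells than requested components.")
  }
  x <- t(matrix_log)                      # cells x genes
  keep <- apply(x, 2, stats::var) > 0
  if (sum(keep) < 1) abort("No genes with positive variance.")
  x <- x[, keep, drop = FALSE]
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  # deterministic sign: dominant loading positive
  for (j in seq_len(k)) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- dplyr::bind_cols(tibble(cell = colnames(matrix_log)),
                          as_tibble(scores))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  attr(out, "explained_variance") <- ev
  attr(out, "rotation") <- rot
  class(out) <- c("cell_pca", class(out))
  out
}

#' Count cells per subpopulation
#'
#' @param annotations A `cell_annotation` tibble from [classify_cells()]
#'   (or anything with a `label` column).
#' @return A tibble `label`, `n` covering every subpopulation level (zeros
#'   included); the counts sum to the number of cells.
#' @export
count_subpopulations <- function(annotations) {
  if (!"label" %in% names(annotations)) {
    abort("`annotations` must have a `label` column.")
  }
  lab <- factor(annotations$label, levels = subpopulation_levels())
  tibble(label = subpopulation_levels(),
         n = as.integer(table(lab)))
}
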