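test_that("log transform maps RPM to log2(RPM+1) and rejects bad input", {
  m <- toy_matrix()
  lt <- log_transform(m)
  expect_equal(lt["Hes1", "c2"], 0)
  expect_equal(log_transform(matrix(1, 1, 1, dimnames = list("g", "c")))[1, 1], 1)
  expect_equal(log_transform(matrix(4095, 1, 1,
                                    dimnames = list("Hes1", "c")))[1, 1], 12)
  expect_true(all(diff(log_transform(
    matrix(c(0, 1, 10, 100), 4, 1,
           dimnames = list(paste0("g", 1:4), "c")))[, 1]) > 0))
  bad <- m; bad[1, 1] <- -3
  expect_error(log_transform(bad), "non-negative")
  nodim <- m; rownames(nodim) <- NULL
  expect_error(log_transform(nodim), "rownames")
})

test_that("panel scores pool RPM before the log and reduce to single genes", {
  m <- toy_matrix()
  ps <- panel_score(m, c("Hes1", "Hes5"), panel_name = "hes")
  expect_named(ps, c("cell", "score"))
  # two genes with RPM 3 and 4: log2(8) = 3
  expect_equal(ps$score[ps$cell == "c3"], 3)
  # all panel genes zero: score 0
  expect_equal(ps$score[ps$cell == "c2"], 0)
  # single-gene panel == log_transform of that row
  one <- panel_score(m, "Id3", panel_name = "id")
  expect_equal(one$score, unname(log_transform(m)["Id3", ]))
  # case-insensitive matching, synonym support, unmatched reporting
  expect_equal(panel_score(m, c("HES1", "hes5"), panel_name = "hes")$score,
               ps$score)
  expect_warning(panel_score(m, c("Hes1", "Nope"), panel_name = "hes"),
                 "Nope")
  expect_error(suppressWarnings(panel_score(m, c("Nope1", "Nope2"),
                                            panel_name = "ghost")), "ghost")
  # Tbr2 resolves to Eomes
  em <- matrix(c(7), 1, 1, dimnames = list("Eomes", "c1"))
  expect_equal(panel_score(em, "Tbr2", panel_name = "ip")$score, 3)
})

test_that("cells classify into the Hes/Id 2x2 plus TAP", {
  ann <- classify_cells(id_score = c(5, 0, 0, 3, 4),
                        hes_score = c(0, 0, 6, 7, 5),
                        expressed_threshold = 1,
                        tap = "cell5",
                        cells = paste0("cell", 1:5))
  expect_equal(as.character(ann$label),
               c("IdPos_HesNeg", "DoubleNeg", "IdNeg_HesPos",
                 "IdPos_HesPos", "TAP"))
  expect_error(classify_cells(1, c(1, 2)), "same length")
  expect_error(classify_cells(1, 1, expressed_threshold = -1), ">= 0")
})

test_that("classification is invariant to monotone rescaling and monotone in threshold", {
  set.seed(42)
  id <- runif(60, 0, 8)
  hes <- runif(60, 0, 8)
  base <- classify_cells(id, hes, expressed_threshold = 1)
  # strictly monotone rescale preserving the threshold crossing at 1:
  # x -> x^3 maps (0,1) into (0,1) and (1,inf) into (1,inf)
  resc <- classify_cells(id^3, hes^3, expressed_threshold = 1)
  expect_equal(base$label, resc$label)

  n_expressed <- function(thr) {
    ann <- classify_cells(id, hes, expressed_threshold = thr)
    sum(ann$label != "DoubleNeg")
  }
  counts <- vapply(c(4, 2, 1, 0.5, 0), n_expressed, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("metadata rules filter cells conjunctively and report missing fields", {
  m <- toy_matrix()
  meta <- tibble::tibble(
    cell = colnames(m),
    read_count = c(2e6, 0.5e6, 3e6, 2e6),
    region = c("VZ", "VZ", "SVZ", "VZ"),
    condition = c("control", "control", "control", "ischemia")
  )
  expect_identical(suppressMessages(filter_cells(m, meta)), {
    out <- m[, meta$cell]; attr(out, "metadata") <- tibble::as_tibble(meta); out
  })
  kept <- suppressMessages(filter_cells(m, meta, read_count > 1e6))
  expect_equal(colnames(kept), c("c1", "c3", "c4"))
  # conjunction order does not matter
  a <- suppressMessages(filter_cells(m, meta, read_count > 1e6, region == "VZ",
                                     condition != "ischemia"))
  b <- suppressMessages(filter_cells(m, meta, condition != "ischemia",
                                     region == "VZ", read_count > 1e6))
  expect_equal(colnames(a), colnames(b))
  expect_equal(colnames(a), "c1")
  expect_error(suppressMessages(filter_cells(m, meta, nreads > 1)), "nreads")
})

test_that("PCA embedding matches a covariance eigendecomposition oracle", {
  # 5 genes x 4 cells toy matrix
  set.seed(7)
  m <- matrix(rnorm(20, mean = 4), nrow = 5, ncol = 4,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  emb <- pca_embed(m, n_components = 2)

  x <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(x))
  scores_oracle <- x %*% eig$vectors[, 1:2]
  for (j in 1:2) {
    ours <- emb[[paste0("PC", j)]]
    oracle <- scores_oracle[, j]
    # sign-free comparison
    err <- min(max(abs(ours - oracle)), max(abs(ours + oracle)))
    expect_lt(err, 1e-8)
  }
  ev <- attr(emb, "explained_variance")
  expect_equal(sum(ev), 1)
  expect_equal(ev[1:2], eig$values[1:2] / sum(eig$values), tolerance = 1e-10)
})

test_that("PCA handles degenerate inputs deterministically", {
  # two identical cells embed at the same coordinates
  m <- matrix(c(1, 2, 3, 1, 2, 3, 5, 6, 7), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  emb <- pca_embed(m, 2)
  expect_equal(unlist(emb[1, -1]), unlist(emb[2, -1]))
  # variance on exactly one gene: PC1 carries all of it
  m2 <- rbind(g1 = c(1, 5, 9), g2 = c(2, 2, 2), g3 = c(0, 0, 0))
  colnames(m2) <- paste0("c", 1:3)
  ev <- attr(pca_embed(m2, 2), "explained_variance")
  expect_equal(ev[1], 1)
  expect_error(pca_embed(m2[, 1, drop = FALSE], 2), "Fewer cells")
  # full reconstruction from all components
  set.seed(1)
  m3 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("g", 1:8),
                                                paste0("c", 1:5)))
  emb3 <- pca_embed(m3, n_components = 5)
  rot <- attr(emb3, "rotation")
  scores <- as.matrix(emb3[, -1])
  centred <- scale(t(m3), center = TRUE, scale = FALSE)
  expect_lt(max(abs(scores %*% t(rot) - centred)), 1e-8)
})

test_that("subpopulation counting conserves totals", {
  ann <- tibble::tibble(label = c("IdPos_HesPos", "IdPos_HesPos", "DoubleNeg"))
  cnt <- count_subpopulations(ann)
  expect_equal(cnt$n[cnt$label == "IdPos_HesPos"], 2L)
  expect_equal(cnt$n[cnt$label == "DoubleNeg"], 1L)
  expect_equal(sum(cnt$n), 3L)
  expect_error(count_subpopulations(tibble::tibble(x = 1)), "label")
})

test_that("expression matrices round-trip through CSV and TSV", {
  m <- toy_matrix()
  for (ext in c(".csv", ".tsv")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_expression_matrix(m, tf)
    back <- read_expression_matrix(tf)
    expect_equal(back, m)
  }
})

test_that("an MTX triple loads with its gene and barcode sidecars", {
  skip_if_not_installed("Matrix")
  m <- toy_matrix()
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  back <- read_expression_matrix(file.path(dir, "matrix.mtx"))
  expect_equal(back, m)
  file.remove(file.path(dir, "genes.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "matrix.mtx")),
               "genes.tsv")
})
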