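test_that("QC metrics follow their definitions on hand-built cells", {
  m <- make_matrix(matrix(c(3, 0, 1,
                            0, 5, 0), nrow = 3,
                          dimnames = NULL),
                   genes = c("A", "mt-B", "C"))
  # cell 1: counts [3, 0, 1] -> 2 genes, total 4, no mito
  # cell 2: counts [0, 5, 0] -> all mito
  qc <- compute_qc(m, mito = "mt-")
  expect_equal(qc$n_genes, c(2L, 1L))
  expect_equal(qc$total_counts, c(4, 5))
  expect_equal(qc$mito_frac, c(0, 1))
})

test_that("QC metrics equal a brute-force per-cell loop on random data", {
  v <- random_counts(40, 25, seed = 3, lambda = 0.8)
  genes <- c(paste0("mt-", 1:4), paste0("g", 1:36))
  m <- make_matrix(v, genes = genes)
  qc <- compute_qc(m)
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    expect_equal(qc$n_genes[j], sum(x > 0))
    expect_equal(qc$total_counts[j], sum(x))
    expect_equal(qc$mito_frac[j],
                 if (sum(x) > 0) sum(x[1:4]) / sum(x) else 0)
  }
})

test_that("a mito selector matching nothing warns and zeroes mito_frac", {
  m <- make_matrix(random_counts(5, 3, seed = 1))
  expect_warning(qc <- compute_qc(m, mito = "MT-human"), "no gene")
  expect_equal(qc$mito_frac, rep(0, 3))
})

test_that("cell filter keeps 200-2,500 genes and < 5% mito; gene filter follows", {
  set.seed(9)
  # three cells planted at n_genes 150 / 300 / 2600 with 1% mito
  n_genes <- 3000
  plant_cell <- function(k) {
    x <- numeric(n_genes)
    x[sample(5:n_genes, k - 1)] <- 1
    x[1] <- ceiling(0.01 * k / 0.99)  # mito gene, ~1% of the total
    x
  }
  v <- cbind(plant_cell(150), plant_cell(300), plant_cell(2600))
  m <- make_matrix(v, genes = c("mt-1", paste0("g", 2:n_genes)))
  qc <- compute_qc(m)
  expect_true(all(qc$mito_frac < 0.05))
  filt <- filter_cells_genes(m, qc, qc_params(min_cells_per_gene = 1))
  expect_equal(ncol(filt$values), 1L)
  expect_equal(unname(Matrix::colSums(filt$values > 0)), 300)
})

test_that("filtering matches the brute-force rule and is idempotent", {
  sim <- simulate_cells(cell_sim_config(n_clusters = 3,
                                        cells_per_cluster = 40,
                                        n_genes = 400,
                                        outlier_cells = list(
                                          n_low_genes = 4, n_high_mito = 4),
                                        seed = 12))
  m <- sim$matrix
  qc <- compute_qc(m)
  params <- qc_params(min_genes = 60, max_genes = 300,
                      max_mito_frac = 0.05, min_cells_per_gene = 3)
  filt <- filter_cells_genes(m, qc, params)
  # brute-force survivor set
  keep_cells <- which(qc$n_genes >= 60 & qc$n_genes <= 300 &
                        qc$mito_frac < 0.05)
  expect_identical(cell_ids(filt), cell_ids(m)[keep_cells])
  sub <- as.matrix(m$values)[, keep_cells]
  keep_genes <- which(rowSums(sub > 0) >= 3)
  expect_identical(gene_ids(filt), gene_ids(m)[keep_genes])
  # outlier cells were planted to fail the bounds
  expect_false(any(grepl("outlier", sim$annotations$true_cluster[keep_cells])))
  # idempotence
  qc2 <- compute_qc(filt)
  filt2 <- filter_cells_genes(filt, qc2, params)
  expect_identical(as.matrix(filt2$values), as.matrix(filt$values))
  # removing every cell is an explicit error
  expect_error(filter_cells_genes(m, qc, qc_params(min_genes = 1e5 - 1,
                                                   max_genes = 1e5)),
               "every cell")
})

test_that("median normalization scales totals [100,200,300] by [2,1,2/3]", {
  v <- matrix(0, nrow = 4, ncol = 3)
  v[, 1] <- c(50, 25, 25, 0)
  v[, 2] <- c(100, 50, 0, 50)
  v[, 3] <- c(0, 150, 75, 75)
  m <- make_matrix(v)
  norm <- normalize_to_median(m)
  expect_identical(norm$layer, "normalized")
  expect_equal(unname(Matrix::colSums(norm$values)), c(200, 200, 200))
  expect_equal(as.matrix(norm$values), as.matrix(m$values) %*%
                 diag(c(2, 1, 2 / 3)), ignore_attr = TRUE)
})

test_that("normalization fixes every total at the pre-median, keeps zeros", {
  v <- random_counts(60, 31, seed = 6, lambda = 1.5)
  v[, 5] <- 0; v[10, ] <- 0
  m <- make_matrix(v)
  expect_error(normalize_to_median(m), "all-zero cell")
  v[1, 5] <- 3
  m <- make_matrix(v)
  med <- median(colSums(v))
  norm <- normalize_to_median(m)
  post <- Matrix::colSums(norm$values)
  expect_lt(max(abs(post - med) / med), 1e-9)
  expect_identical(as.matrix(norm$values) == 0, as.matrix(m$values) == 0)
  # equal totals -> identity
  eq <- make_matrix(matrix(c(2, 3, 3, 2), 2))
  expect_equal(as.matrix(normalize_to_median(eq)$values),
               as.matrix(eq$values))
})

test_that("HVG selection matches an independent reimplementation", {
  sim <- simulate_cells(cell_sim_config(n_clusters = 4,
                                        cells_per_cluster = 50,
                                        n_genes = 500, seed = 19))
  qc <- compute_qc(sim$matrix)
  filt <- filter_cells_genes(sim$matrix, qc,
                             qc_params(min_genes = 10, max_genes = 1e4,
                                       max_mito_frac = 1))
  norm <- normalize_to_median(filt)
  params <- hvg_params(min_mean = 0.0125, max_mean = 3, min_disp = 0.5)
  got <- select_hvg(norm, params)

  # oracle: dense recomputation, bins as 20 contiguous chunks of the
  # mean-sorted gene list
  lv <- log1p(as.matrix(norm$values))
  mu <- rowMeans(lv)
  vg <- apply(lv, 1, var)
  disp <- ifelse(mu > 0, vg / mu, 0)
  n <- length(mu)
  ord <- order(mu, seq_len(n))
  bin <- integer(n)
  bin[ord] <- ceiling(20 * seq_len(n) / n)
  nd <- numeric(n)
  for (b in unique(bin)) {
    i <- bin == b
    s <- sd(disp[i])
    nd[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  want <- gene_ids(norm)[mu >= 0.0125 & mu <= 3 & nd >= 0.5]
  expect_identical(got, want)
  expect_gt(length(got), 0)
})

test_that("HVG selection is monotone in min_disp and drops constant genes", {
  v <- random_counts(100, 40, seed = 23, lambda = 1)
  v[7, ] <- 2  # constant gene
  m <- make_matrix(v, layer = "normalized")
  base <- select_hvg(m, hvg_params(min_disp = 0.1))
  stricter <- select_hvg(m, hvg_params(min_disp = 0.8))
  expect_true(all(stricter %in% base))
  expect_false("g7" %in% select_hvg(m, hvg_params(min_disp = 1e-6)))
  small <- make_matrix(random_counts(10, 5, seed = 2),
                       layer = "normalized")
  expect_warning(select_hvg(small), "single bin")
})
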