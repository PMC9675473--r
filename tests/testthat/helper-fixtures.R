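# Small builders and independent brute-force oracles used across tests.

make_matrix <- function(values, genes = NULL, cells = NULL, layer = "raw") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(values)))
  expr_matrix(values, gene_ids = genes, cell_ids = cells, layer = layer)
}

random_counts <- function(n_genes, n_cells, seed, lambda = 2) {
  withr::with_seed(seed,
    matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes))
}

# recovery-curve AUC by explicit step-curve walk (independent of the
# closed-form implementation)
oracle_aucell_cell <- function(x, in_set, top_frac,
                               normalization = "max_recovery") {
  n <- length(x)
  T <- ceiling(top_frac * n)
  ord <- order(-x, seq_along(x))
  hits <- in_set[ord]
  y <- cumsum(hits)[seq_len(T)]
  area <- sum(y)
  m <- min(sum(in_set), T)
  y_best <- pmin(seq_len(T), m)
  max_area <- if (normalization == "max_recovery") sum(y_best)
              else T * sum(in_set)
  if (max_area == 0) return(0)
  area / max_area
}

# all-pairs enumeration of k-nearest neighborhoods, ties by index
oracle_knn <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  t(sapply(seq_len(n), function(i) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2
    order(d2, seq_len(n))[seq_len(k)]
  }))
}

# Pearson r by the explicit sum formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# neighborhood colocalization scores by full enumeration
oracle_neighborhood_scores <- function(coords, a, b, k) {
  nb <- oracle_knn(coords, k)
  n <- nrow(nb)
  r <- sapply(seq_len(n), function(i) {
    ai <- a[nb[i, ]]; bi <- b[nb[i, ]]
    if (var(ai) == 0 || var(bi) == 0) return(NA_real_)
    oracle_pearson(ai, bi)
  })
  score <- sapply(seq_len(n), function(s) {
    containing <- which(apply(nb, 1, function(row) s %in% row))
    vals <- r[containing]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    mean(vals)
  })
  score[!is.na(score) & score <= 1e-12] <- NA_real_
  score
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_exact_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
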