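#' Two-sample Wilcoxon rank-sum test (vectorizable core)
#'
#' Tie-corrected normal approximation by default, matching
#' `wilcox.test(exact = FALSE, correct = FALSE)`; with `exact = TRUE` (only
#' valid without ties) the p-value comes from the exact null distribution
#' of the rank-sum statistic.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x stochastically larger)
#'   or `"less"`.
#' @param exact Use the exact distribution (requires no ties).
#' @return List with `statistic` (Mann-Whitney U of `x`), `z`, `p_value`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater",
                                                "less"),
                          exact = FALSE) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (exact) {
    if (anyDuplicated(c(x, y)))
      stop("exact rank-sum p-values require untied data", call. = FALSE)
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(list(statistic = U, z = NA_real_, p_value = p))
  }
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(statistic = U, z = z, p_value = min(1, p))
}

# tie-corrected rank-sum z for every gene (rows) of a dense matrix,
# comparing columns in `grp` against the rest
rank_sum_z_matrix <- function(v, grp) {
  n1 <- sum(grp); n2 <- sum(!grp); N <- n1 + n2
  mu <- n1 * n2 / 2
  z <- numeric(nrow(v))
  for (g in seq_len(nrow(v))) {
    r <- rank(v[g, ])
    U <- sum(r[grp]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z[g] <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  }
  z
}

#' Wilcoxon rank-sum marker genes per cluster
#'
#' Each cluster is compared against all other cells gene by gene with the
#' two-sided tie-corrected normal-approximation rank-sum test; p-values are
#' Benjamini-Hochberg adjusted across genes within each cluster comparison.
#' The returned table ranks, for every cluster, the top `n_top` genes by
#' ascending p among genes with `p_adj < 0.05` and positive enrichment
#' (higher ranks in the cluster).
#'
#' @param matrix An [expr_matrix] (normalized values recommended).
#' @param clusters Per-cell cluster labels; clusters with fewer than 2
#'   cells are excluded with a warning; at least 2 usable clusters needed.
#' @param n_top Markers reported per cluster (default 5).
#' @return List with `markers` (the significant top table: `cluster`,
#'   `gene`, `z`, `p_value`, `p_adj_bh`, `rank`) and `all` (full
#'   per-cluster test table).
#' @export
wilcoxon_markers <- function(matrix, clusters, n_top = 5) {
  stopifnot_expr(matrix)
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(matrix$values))
    stop("clusters must align with matrix cells", call. = FALSE)
  sizes <- table(clusters)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding cluster(s) with < 2 cells: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  usable <- setdiff(names(sizes), small)
  if (length(usable) < 2)
    stop("need at least 2 clusters with >= 2 cells", call. = FALSE)
  keep <- clusters %in% usable
  v <- as.matrix(matrix$values[, keep, drop = FALSE])
  cl <- clusters[keep]
  genes <- gene_ids(matrix)
  all_tabs <- lapply(sort(unique(cl)), function(target) {
    grp <- cl == target
    z <- rank_sum_z_matrix(v, grp)
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(cluster = target, gene = genes, z = z, p_value = p,
               p_adj_bh = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  all_tab <- do.call(rbind, all_tabs)
  markers <- do.call(rbind, lapply(all_tabs, function(tab) {
    hit <- tab[tab$p_adj_bh < 0.05 & tab$z > 0, , drop = FALSE]
    hit <- hit[order(hit$p_value, hit$gene), , drop = FALSE]
    hit <- utils::head(hit, n_top)
    if (nrow(hit)) hit$rank <- seq_len(nrow(hit))
    hit
  }))
  rownames(markers) <- NULL
  rownames(all_tab) <- NULL
  list(markers = markers, all = all_tab)
}

#' Pairwise rank-sum tests between groups with Bonferroni adjustment
#'
#' All unordered group pairs are compared with `stats::wilcox.test`; the
#' Bonferroni multiplier is the number of pairs tested (adjusted p capped
#' at 1).  Pairs involving a group with fewer than 2 observations are
#' skipped with a warning.
#'
#' @param scores Numeric observations (e.g. per-cell AUCell scores).
#' @param groups Group labels aligned with `scores`.
#' @return Data frame: `group_a`, `group_b`, `p_value`, `p_adj_bonferroni`.
#' @export
pairwise_group_test <- function(scores, groups) {
  groups <- as.character(groups)
  labs <- unique(groups)
  if (length(labs) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  pairs <- utils::combn(labs, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (sizes[[a]] < 2 || sizes[[b]] < 2) {
      warning(sprintf("skipping pair %s vs %s: group with < 2 observations",
                      a, b), call. = FALSE)
      next
    }
    p <- suppressWarnings(
      stats::wilcox.test(scores[groups == a], scores[groups == b]))$p.value
    rows[[length(rows) + 1]] <- data.frame(group_a = a, group_b = b,
                                           p_value = p,
                                           stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable pair", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
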