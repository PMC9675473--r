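#' Flag doublet-enriched clusters from per-cell doublet scores
#'
#' Implements cluster-level doublet flagging: the median doublet score of
#' each (sub)cluster is computed; cluster medians are robust-standardized
#' (centered on their median, scaled by 1.4826 x MAD); each cluster's
#' robust z is converted to a one-sided upper-tail p-value (Student t with
#' `n_clusters - 1` degrees of freedom by default, standard normal behind
#' `tail = "normal"`); p-values are Benjamini-Hochberg adjusted across
#' clusters and a cluster is flagged iff its adjusted p is strictly below
#' `alpha` (default 0.1).
#'
#' If every cluster median is identical the robust scale is zero; no
#' cluster is flagged and the report carries attribute
#' `degenerate_scale = TRUE`.
#'
#' @param scores Per-cell doublet scores in \[0, 1\]; no missing values.
#' @param clusters Per-cell cluster labels; at least 3 distinct clusters.
#' @param alpha Flagging threshold on the BH-adjusted p (strict `<`).
#' @param tail Reference upper-tail distribution: `"t"` (df = clusters - 1)
#'   or `"normal"`.
#' @return Data frame with one row per cluster: `cluster`, `n_cells`,
#'   `median_score`, `robust_z`, `p_value`, `p_adj_bh`, `flagged`.
#' @export
flag_doublet_clusters <- function(scores, clusters, alpha = 0.1,
                                  tail = c("t", "normal")) {
  tail <- match.arg(tail)
  if (length(scores) != length(clusters))
    stop("scores and clusters must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(clusters))
    stop("every cell needs a doublet score and a cluster label",
         call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("doublet scores must lie in [0, 1]", call. = FALSE)
  clusters <- as.character(clusters)
  labs <- unique(clusters)
  k <- length(labs)
  if (k < 3)
    stop("need at least 3 clusters to assess outlying medians",
         call. = FALSE)
  med <- vapply(labs, function(cl) stats::median(scores[clusters == cl]),
                numeric(1))
  n_cells <- as.integer(table(factor(clusters, levels = labs)))
  center <- stats::median(med)
  scale <- stats::mad(med, center = center)  # 1.4826 * MAD
  degenerate <- scale == 0
  if (degenerate) {
    z <- rep(NA_real_, k)
    p <- rep(1, k)
  } else {
    z <- (med - center) / scale
    p <- switch(tail,
                t = stats::pt(z, df = k - 1, lower.tail = FALSE),
                normal = stats::pnorm(z, lower.tail = FALSE))
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(cluster = labs, n_cells = n_cells, median_score = med,
                    robust_z = z, p_value = p, p_adj_bh = p_adj,
                    flagged = !degenerate & p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "degenerate_scale") <- degenerate
  res
}

#' Per-cell doublet flags from a cluster report
#'
#' Cells belonging to a flagged cluster are marked as potential doublets.
#'
#' @param clusters Per-cell cluster labels.
#' @param report Output of [flag_doublet_clusters()].
#' @return Logical vector aligned with `clusters`.
#' @export
cell_doublet_flags <- function(clusters, report) {
  as.character(clusters) %in% report$cluster[report$flagged]
}
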