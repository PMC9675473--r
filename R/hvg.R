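#' Highly-variable-gene selection parameters
#'
#' Bounds on the per-gene mean of log1p-normalized expression and on the
#' bin-standardized dispersion.  Defaults are the workflow's published
#' thresholds (mean in \[0.0125, 3\], normalized dispersion >= 0.5).
#'
#' @param min_mean,max_mean Inclusive bounds on the per-gene mean.
#' @param min_disp Minimum normalized dispersion.
#' @param n_bins Number of equal-frequency mean bins used to standardize
#'   the dispersion (default 20).
#' @return An `hvg_params` list.
#' @export
hvg_params <- function(min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                       n_bins = 20) {
  if (min_mean >= max_mean) stop("min_mean must be < max_mean", call. = FALSE)
  structure(list(min_mean = min_mean, max_mean = max_mean,
                 min_disp = min_disp, n_bins = n_bins),
            class = "hvg_params")
}

#' Select highly variable genes
#'
#' On natural-log `log1p` values of the normalized matrix, computes the
#' per-gene mean and the dispersion (variance / mean), assigns genes to
#' equal-frequency mean bins (by rank, ties to the lower bin), and
#' standardizes the dispersion within each bin ((disp - bin mean) / bin sd;
#' bins with undefined or zero sd give normalized dispersion 0).  Genes are
#' kept when `min_mean <= mean <= max_mean` and normalized dispersion
#' `>= min_disp`.
#'
#' @param matrix An [expr_matrix] with `layer = "normalized"`.
#' @param params An [hvg_params].
#' @return Character vector of selected gene ids, in input gene order.
#' @export
select_hvg <- function(matrix, params = hvg_params()) {
  stopifnot_expr(matrix)
  if (matrix$layer != "normalized")
    stop("select_hvg expects the normalized layer", call. = FALSE)
  v <- matrix$values
  n <- nrow(v)
  n_bins <- params$n_bins
  if (n < n_bins) {
    warning("fewer genes than bins; falling back to a single bin",
            call. = FALSE)
    n_bins <- 1L
  }
  stats <- hvg_gene_stats(v)
  bin <- ceiling(n_bins * rank(stats$mean, ties.method = "first") / n)
  norm_disp <- numeric(n)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    mu <- mean(stats$disp[idx])
    sdv <- stats::sd(stats$disp[idx])
    norm_disp[idx] <- if (is.na(sdv) || sdv == 0) 0
                      else (stats$disp[idx] - mu) / sdv
  }
  keep <- stats$mean >= params$min_mean & stats$mean <= params$max_mean &
    norm_disp >= params$min_disp
  gene_ids(matrix)[keep]
}

# per-gene mean and variance/mean dispersion of log1p values, computed from
# the sparse structure (zeros contribute log1p(0) = 0)
hvg_gene_stats <- function(v) {
  nc <- ncol(v)
  lv <- v
  lv@x <- log1p(lv@x)
  s1 <- Matrix::rowSums(lv)
  s2 <- Matrix::rowSums(lv^2)
  mean_g <- s1 / nc
  var_g <- if (nc > 1) (s2 - nc * mean_g^2) / (nc - 1) else rep(0, nrow(v))
  var_g <- pmax(var_g, 0)
  disp <- ifelse(mean_g > 0, var_g / mean_g, 0)
  list(mean = as.numeric(mean_g), disp = as.numeric(disp))
}
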