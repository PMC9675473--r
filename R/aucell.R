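#' AUCell scoring parameters
#'
#' @param top_frac Fraction of the gene universe forming the ranking window
#'   over which the recovery curve is integrated (default 0.05, the
#'   published AUCell default); the window is `T = ceiling(top_frac *
#'   n_genes)` ranks.
#' @param normalization `"max_recovery"` (default) divides the recovery-curve
#'   area by the maximum achievable area for the set size, so a fully
#'   recovered small set scores 1; `"window"` divides by the window area
#'   `T * n_set` upper bound used when treating the window itself as the
#'   reference.
#' @return An `aucell_params` list.
#' @export
aucell_params <- function(top_frac = 0.05,
                          normalization = c("max_recovery", "window")) {
  if (top_frac <= 0 || top_frac > 1)
    stop("top_frac must be in (0, 1]", call. = FALSE)
  structure(list(top_frac = top_frac,
                 normalization = match.arg(normalization)),
            class = "aucell_params")
}

#' Per-cell expression ranking
#'
#' Ranks genes within each cell by decreasing expression (rank 1 = highest);
#' ties are broken deterministically by ascending gene index.
#'
#' @param matrix An [expr_matrix] (any layer).
#' @return Integer matrix genes x cells of ranks.
#' @export
rank_genes_per_cell <- function(matrix) {
  stopifnot_expr(matrix)
  v <- as.matrix(matrix$values)
  r <- apply(v, 2, function(x) {
    ord <- order(-x, seq_along(x))
    rk <- integer(length(x))
    rk[ord] <- seq_along(x)
    rk
  })
  dimnames(r) <- dimnames(v)
  r
}

#' Gene-set recovery-AUC score per cell (AUCell)
#'
#' For each cell, genes are ranked by decreasing expression (ties by gene
#' index) and the recovery curve y(x) = number of set genes found within the
#' top x ranks is accumulated over the window x = 1..T, T =
#' `ceiling(top_frac * n_genes)`.  The score is the area under this step
#' curve divided by the maximum achievable area (all set genes at the very
#' top of the ranking, capped at the window), giving a value in \[0, 1\].
#'
#' @param matrix An [expr_matrix] (any layer; only ranks are used).
#' @param set A [gene_set]; at least one member must be present in the
#'   matrix gene universe.
#' @param params An [aucell_params].
#' @return Named numeric vector of per-cell scores in \[0, 1\].
#' @export
aucell_score <- function(matrix, set, params = aucell_params()) {
  stopifnot_expr(matrix)
  genes <- gene_ids(matrix)
  in_set <- genes %in% set$genes
  if (!any(in_set))
    stop("no gene of set '", set$name, "' is present in the matrix",
         call. = FALSE)
  n_genes <- length(genes)
  T <- as.integer(ceiling(params$top_frac * n_genes))
  m <- min(sum(in_set), T)
  max_area <- switch(params$normalization,
                     max_recovery = m * (m + 1) / 2 + m * (T - m),
                     window = as.numeric(T) * sum(in_set))
  ranks <- rank_genes_per_cell(matrix)
  scores <- apply(ranks, 2, function(rk) {
    set_ranks <- rk[in_set]
    set_ranks <- set_ranks[set_ranks <= T]
    if (length(set_ranks) == 0) return(0)
    # area of the step curve: each set gene at rank r contributes one unit
    # of height over ranks r..T
    sum(T - set_ranks + 1) / max_area
  })
  stats::setNames(as.numeric(scores), cell_ids(matrix))
}

#' Score several gene sets at once
#'
#' @param matrix An [expr_matrix].
#' @param sets List of [gene_set] objects.
#' @param params An [aucell_params].
#' @return Numeric matrix cells x sets.
#' @export
aucell_score_sets <- function(matrix, sets, params = aucell_params()) {
  out <- vapply(sets, function(s) aucell_score(matrix, s, params),
                numeric(ncol(matrix$values)))
  out <- matrix(out, ncol = length(sets),
                dimnames = list(cell_ids(matrix),
                                vapply(sets, function(s) s$name,
                                       character(1))))
  out
}

#' Group-mean enrichment table with 0-1 scaling
#'
#' Means of per-cell scores per group, then min-max scaled along the chosen
#' axis so each row (or column) spans \[0, 1\]; a constant row or column
#' carries no contrast and scales to 0.
#'
#' @param scores Numeric vector (one set) or cells x sets matrix of
#'   per-cell scores.
#' @param groups Per-cell group labels (e.g. cluster x strain).
#' @param scale_axis Scale within `"rows"` (each group, default) or
#'   `"cols"` (each gene set).
#' @return An `enrichment_table`: list with `mean` and `scaled` matrices
#'   (groups x sets).
#' @export
group_mean_enrichment <- function(scores, groups,
                                  scale_axis = c("rows", "cols")) {
  scale_axis <- match.arg(scale_axis)
  if (is.null(dim(scores)))
    scores <- matrix(scores, ncol = 1,
                     dimnames = list(names(scores), "score"))
  if (anyNA(groups)) stop("every cell must belong to a group", call. = FALSE)
  if (!is.factor(groups)) groups <- factor(groups)
  if (nrow(scores) != length(groups))
    stop("scores and groups must align", call. = FALSE)
  empty <- setdiff(levels(groups), unique(as.character(groups)))
  if (length(empty))
    warning("group(s) with 0 cells: ", paste(empty, collapse = ", "),
            call. = FALSE)
  mean_tab <- apply(scores, 2, function(s)
    tapply(s, groups, mean))
  mean_tab <- matrix(mean_tab, nrow = nlevels(groups),
                     dimnames = list(levels(groups), colnames(scores)))
  minmax <- function(x) {
    if (all(is.na(x))) return(x)
    rng <- range(x, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[1] == rng[2]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  scaled <- if (scale_axis == "rows")
    t(apply(mean_tab, 1, minmax)) else apply(mean_tab, 2, minmax)
  scaled <- matrix(scaled, nrow = nrow(mean_tab),
                   dimnames = dimnames(mean_tab))
  structure(list(mean = mean_tab, scaled = scaled,
                 scale_axis = scale_axis),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %d group(s) x %d set(s), scaled by %s\n",
              nrow(x$mean), ncol(x$mean), x$scale_axis))
  print(round(x$scaled, 3))
  invisible(x)
}
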