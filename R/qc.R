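#' QC filter parameters
#'
#' Defaults are the standard droplet scRNA-seq bounds used in the kidney
#' macrophage workflow: cells kept with 200-2,500 detected genes and
#' mitochondrial content under 5%; genes kept when expressed in at least 3
#' surviving cells.
#'
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param max_mito_frac Cells kept when `mito_frac < max_mito_frac` (strict).
#' @param min_cells_per_gene Genes kept when expressed (count > 0) in at
#'   least this many surviving cells.
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_genes = 200, max_genes = 2500,
                      max_mito_frac = 0.05, min_cells_per_gene = 3) {
  if (min_genes >= max_genes)
    stop("min_genes must be < max_genes", call. = FALSE)
  if (max_mito_frac <= 0 || max_mito_frac > 1)
    stop("max_mito_frac must be in (0, 1]", call. = FALSE)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_frac = max_mito_frac,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_params")
}

resolve_mito_genes <- function(genes, mito) {
  if (length(mito) == 1 && !mito %in% genes) {
    hit <- genes[startsWith(tolower(genes), tolower(mito))]
  } else {
    hit <- intersect(mito, genes)
  }
  hit
}

#' Per-cell QC metrics
#'
#' @param matrix An [expr_matrix] with raw counts.
#' @param mito Either a prefix matched case-insensitively against gene ids
#'   (default `"mt-"`) or an explicit vector of mitochondrial gene ids.
#' @return Data frame with `cell_id`, `n_genes` (genes with count > 0),
#'   `total_counts`, and `mito_frac` (0 for cells with zero total).
#' @export
compute_qc <- function(matrix, mito = "mt-") {
  stopifnot_expr(matrix)
  if (matrix$layer != "raw")
    stop("compute_qc expects the raw layer", call. = FALSE)
  v <- matrix$values
  mito_genes <- resolve_mito_genes(gene_ids(matrix), mito)
  if (length(mito_genes) == 0)
    warning("mito selector matched no gene; mito_frac set to 0",
            call. = FALSE)
  total <- Matrix::colSums(v)
  n_genes <- Matrix::colSums(v > 0)
  mito_counts <- if (length(mito_genes))
    Matrix::colSums(v[mito_genes, , drop = FALSE]) else rep(0, ncol(v))
  mito_frac <- ifelse(total > 0, mito_counts / total, 0)
  data.frame(cell_id = cell_ids(matrix), n_genes = as.integer(n_genes),
             total_counts = as.numeric(total),
             mito_frac = as.numeric(mito_frac),
             stringsAsFactors = FALSE)
}

#' Apply cell then gene QC filters
#'
#' Cells are kept iff `min_genes <= n_genes <= max_genes` and
#' `mito_frac < max_mito_frac`; genes are then kept iff expressed in at
#' least `min_cells_per_gene` of the surviving cells.  Order is preserved;
#' the gene filter always runs after the cell filter.
#'
#' @param matrix An [expr_matrix] (raw counts).
#' @param qc Output of [compute_qc()] on this matrix.
#' @param params A [qc_params].
#' @return The filtered [expr_matrix].
#' @export
filter_cells_genes <- function(matrix, qc, params = qc_params()) {
  stopifnot_expr(matrix)
  if (!identical(qc$cell_id, cell_ids(matrix)))
    stop("qc table does not match matrix cells", call. = FALSE)
  keep_cells <- qc$n_genes >= params$min_genes &
    qc$n_genes <= params$max_genes &
    qc$mito_frac < params$max_mito_frac
  if (!any(keep_cells))
    stop("QC filter removed every cell; relax the bounds", call. = FALSE)
  v <- matrix$values[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(v > 0) >= params$min_cells_per_gene
  v <- v[keep_genes, , drop = FALSE]
  expr_matrix(v, layer = matrix$layer)
}

#' Normalize each cell to the median pre-normalization total
#'
#' Every cell is scaled so its total count equals the median of the cell
#' totals before normalization; within-cell proportions (and the zero
#' pattern) are preserved exactly.
#'
#' @param matrix An [expr_matrix] with raw counts and no all-zero cells
#'   (run [filter_cells_genes()] first).
#' @return An [expr_matrix] with `layer = "normalized"`.
#' @export
normalize_to_median <- function(matrix) {
  stopifnot_expr(matrix)
  if (matrix$layer != "raw")
    stop("normalize_to_median expects the raw layer", call. = FALSE)
  totals <- Matrix::colSums(matrix$values)
  if (any(totals == 0))
    stop("all-zero cell present; filter cells before normalizing",
         call. = FALSE)
  med <- stats::median(totals)
  v <- matrix$values %*% Matrix::Diagonal(x = med / totals)
  v <- methods::as(v, "CsparseMatrix")
  dimnames(v) <- dimnames(matrix$values)
  expr_matrix(v, layer = "normalized")
}
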