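#' Expression matrix container
#'
#' A genes x cells nonnegative matrix (raw counts or normalized values)
#' carried as a sparse `dgCMatrix` with unique gene and cell identifiers as
#' dimnames and a `layer` tag distinguishing raw counts from normalized
#' values.
#'
#' @param values A genes x cells matrix (dense or sparse) of nonnegative
#'   values. Coerced to `dgCMatrix`.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   `colnames(values)`.
#' @param layer Either `"raw"` or `"normalized"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (dgCMatrix with dimnames), and `layer`.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        cell_ids = colnames(values),
                        layer = c("raw", "normalized")) {
  layer <- match.arg(layer)
  if (is.matrix(values)) storage.mode(values) <- "double"
  values <- methods::as(methods::as(methods::as(
    Matrix::Matrix(values, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids", call. = FALSE)
  if (length(values@x) && min(values@x) < 0)
    stop("expression values must be nonnegative", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer = %s, %d nonzero\n",
              nrow(x$values), ncol(x$values), x$layer,
              length(x$values@x)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and cell identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers, in stored order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(x$values)

is_expr_matrix <- function(x) inherits(x, "expr_matrix")

stopifnot_expr <- function(x) {
  if (!is_expr_matrix(x)) stop("expected an expr_matrix", call. = FALSE)
  invisible(x)
}

#' Gene set container
#'
#' @param name Set name.
#' @param genes Nonempty character vector of gene identifiers; duplicates
#'   are an error (collapse them upstream).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene set '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(genes))
    stop("gene set '", name, "' contains duplicate genes", call. = FALSE)
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Spatial dataset container
#'
#' Spots on an integer array grid (Visium convention) with optional
#' expression and named per-spot score channels.  Prediction-score channels
#' (label-transfer outputs) must lie in \[0, 1\]; expression-derived channels
#' need only be nonnegative.
#'
#' @param spots Data frame with columns `spot_id`, `array_row`, `array_col`,
#'   and optionally `in_tissue` (logical) and `region` (truth labels from the
#'   simulator).
#' @param channels Named list or data frame of per-spot numeric vectors,
#'   aligned with `spots` rows. `NA` encodes a missing value.
#' @param expression Optional `expr_matrix` whose cells are the spots.
#' @param score_channels Character vector naming which channels are
#'   prediction scores and must lie in \[0, 1\]; defaults to all channels.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(spots, channels = list(), expression = NULL,
                            score_channels = names(channels)) {
  req <- c("spot_id", "array_row", "array_col")
  if (!all(req %in% names(spots)))
    stop("spots must have columns spot_id, array_row, array_col",
         call. = FALSE)
  spots$spot_id <- as.character(spots$spot_id)
  if (anyDuplicated(spots$spot_id))
    stop("duplicate spot_id", call. = FALSE)
  if (anyDuplicated(spots[, c("array_row", "array_col")]))
    stop("duplicate spot coordinates", call. = FALSE)
  channels <- as.list(channels)
  for (nm in names(channels)) {
    v <- as.numeric(channels[[nm]])
    if (length(v) != nrow(spots))
      stop("channel '", nm, "' length does not match number of spots",
           call. = FALSE)
    if (nm %in% score_channels) {
      bad <- !is.na(v) & (v < 0 | v > 1)
      if (any(bad))
        stop("prediction-score channel '", nm,
             "' has values outside [0, 1]", call. = FALSE)
    } else if (any(!is.na(v) & v < 0)) {
      stop("channel '", nm, "' has negative values", call. = FALSE)
    }
    channels[[nm]] <- v
  }
  if (!is.null(expression)) {
    stopifnot_expr(expression)
    if (!identical(cell_ids(expression), spots$spot_id))
      stop("expression cell_ids must equal spot_ids in order", call. = FALSE)
  }
  structure(list(spots = spots, channels = channels,
                 expression = expression,
                 score_channels = intersect(score_channels, names(channels))),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d spots, %d channel(s)%s\n",
              nrow(x$spots), length(x$channels),
              if (is.null(x$expression)) "" else ", with expression"))
  invisible(x)
}

#' Extract a channel from a spatial dataset
#' @param dataset A `spatial_dataset`.
#' @param name Channel name.
#' @return Numeric vector aligned with `dataset$spots`.
#' @export
get_channel <- function(dataset, name) {
  if (!name %in% names(dataset$channels))
    stop("channel '", name, "' not present in dataset", call. = FALSE)
  dataset$channels[[name]]
}
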