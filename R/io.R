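#' Read a 10x-style MTX trio into an expression matrix
#'
#' Reads a Matrix Market count matrix with its features and barcodes TSVs
#' (cellranger convention).  The on-disk orientation may be genes x cells or
#' cells x genes; the result is always genes x cells.  Identifier order is
#' preserved exactly as on disk.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path Path to the features/genes TSV (first column = gene
#'   identifier).
#' @param barcodes_path Path to the barcodes TSV (one barcode per line).
#' @return An [expr_matrix] with `layer = "raw"`.
#' @export
read_counts_10x <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)
  genes <- as.character(feats[[1]])
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  ng <- length(genes); nc <- length(barcodes)
  if (nrow(m) == ng && ncol(m) == nc) {
    # already genes x cells (ambiguous square case defaults here too)
  } else if (nrow(m) == nc && ncol(m) == ng) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "matrix dimensions %d x %d do not match %d features / %d barcodes",
      nrow(m), ncol(m), ng, nc), call. = FALSE)
  }
  expr_matrix(m, gene_ids = genes, cell_ids = barcodes, layer = "raw")
}

#' Write an expression matrix as a 10x-style MTX trio
#'
#' @param x An [expr_matrix].
#' @param dir Output directory (created if absent).
#' @param prefix Optional file-name prefix.
#' @return Invisibly, the three paths written.
#' @export
write_counts_10x <- function(x, dir, prefix = "") {
  stopifnot_expr(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix,
                                 c("matrix.mtx", "features.tsv",
                                   "barcodes.tsv")))
  Matrix::writeMM(x$values, paths[1])
  utils::write.table(data.frame(gene_ids(x), gene_ids(x), "Gene Expression"),
                     paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(x), paths[3])
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description (discarded), then gene
#' identifiers.  Duplicate genes within a line are collapsed with a warning;
#' duplicate set names across lines are an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of [gene_set] objects, in file order.
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(stats::setNames(list(), character()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                   i, length(fields)), call. = FALSE)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes collapsed",
                      i, fields[1]), call. = FALSE)
      genes <- unique(genes)
    }
    sets[[i]] <- gene_set(fields[1], genes)
    nms[i] <- fields[1]
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  stats::setNames(sets, nms)
}

#' Write gene sets to a GMT file
#' @param sets List of [gene_set] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Visium-style spatial dataset
#'
#' `positions_path` follows the Visium tissue-positions convention
#' (`barcode,in_tissue,array_row,array_col,pxl_row,pxl_col`), with or
#' without a header line.  Channels are a TSV with a header whose first
#' column is the spot barcode; channel barcodes must be a subset of the
#' positions barcodes.  Missing channel values are empty fields, read as NA.
#'
#' @param positions_path Path to the tissue positions CSV.
#' @param channels_path Optional path to a per-spot channels TSV.
#' @param expression Optional [expr_matrix] over the spots.
#' @param in_tissue_only Keep only `in_tissue == 1` spots (default TRUE).
#' @param score_channels Channels validated against \[0, 1\]; default all.
#' @return A [spatial_dataset].
#' @export
read_spatial <- function(positions_path, channels_path = NULL,
                         expression = NULL, in_tissue_only = TRUE,
                         score_channels = NULL) {
  if (!file.exists(positions_path))
    stop("file not found: ", positions_path, call. = FALSE)
  first <- readLines(positions_path, n = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(positions_path, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(pos) < 4)
    stop("positions file needs at least barcode,in_tissue,array_row,array_col",
         call. = FALSE)
  names(pos)[1:4] <- c("spot_id", "in_tissue", "array_row", "array_col")
  pos$spot_id <- as.character(pos$spot_id)
  if (in_tissue_only) pos <- pos[pos$in_tissue == 1, , drop = FALSE]
  rownames(pos) <- NULL
  channels <- list()
  if (!is.null(channels_path)) {
    ch <- utils::read.delim(channels_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    bc <- as.character(ch[[1]])
    if (!all(bc %in% pos$spot_id))
      stop("channel barcodes are not a subset of positions barcodes",
           call. = FALSE)
    idx <- match(pos$spot_id, bc)
    for (nm in names(ch)[-1]) {
      channels[[nm]] <- as.numeric(ch[[nm]])[idx]
    }
  }
  if (is.null(score_channels)) score_channels <- names(channels)
  spatial_dataset(pos[, c("spot_id", "array_row", "array_col", "in_tissue")],
                  channels = channels, expression = expression,
                  score_channels = score_channels)
}

#' Write spatial channels as TSV
#'
#' Missing values are written as empty fields (the "gray spot" convention:
#' a spot with no available score).
#'
#' @param dataset A [spatial_dataset].
#' @param path Output path.
#' @param channels Channel names to write; default all.
#' @return Invisibly, `path`.
#' @export
write_spatial_channels <- function(dataset, path,
                                   channels = names(dataset$channels)) {
  df <- data.frame(barcode = dataset$spots$spot_id,
                   stringsAsFactors = FALSE)
  for (nm in channels) df[[nm]] <- get_channel(dataset, nm)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a Visium-style positions CSV (with header)
#' @param dataset A [spatial_dataset].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spatial_positions <- function(dataset, path) {
  sp <- dataset$spots
  df <- data.frame(barcode = sp$spot_id,
                   in_tissue = if ("in_tissue" %in% names(sp))
                     as.integer(sp$in_tissue) else 1L,
                   array_row = sp$array_row, array_col = sp$array_col,
                   pxl_row_in_fullres = sp$array_row * 100L,
                   pxl_col_in_fullres = sp$array_col * 100L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
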