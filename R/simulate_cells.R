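#' Configuration for the single-cell count simulator
#'
#' Defaults emulate the structure of a droplet scRNA-seq experiment on
#' sorted kidney mononuclear phagocytes: a few thousand cells in a handful
#' of clusters, negative-binomial counts with cluster-specific marker genes,
#' a small doublet subpopulation with elevated doublet scores, per-cell
#' mitochondrial fractions mostly under the 5% QC cutoff, and two strain
#' batches with one disease-enriched cluster.
#'
#' @param n_clusters Number of singlet clusters (>= 1).
#' @param cells_per_cluster Singlet cells per cluster (recycled).
#' @param n_genes Total genes, including the mitochondrial block.
#' @param n_marker_genes_per_cluster Marker genes up-shifted per cluster.
#' @param marker_fold_change Mean fold change of markers in their cluster
#'   (>= 1; 1 gives a null dataset with no differential structure).
#' @param nb_mean Mean of the per-gene baseline expression means (per-gene
#'   means are Gamma-distributed around this, mimicking the skewed mean
#'   distribution of real droplet data).
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param doublet_rate Fraction of output cells that are doublets, in \[0,1).
#' @param singlet_score_shape,doublet_score_shape Beta shape pairs for the
#'   per-cell doublet-score distributions of singlets and doublets.
#' @param mito_frac_shape Beta shape pair for the planted per-cell
#'   mitochondrial fraction.
#' @param n_mito_genes Genes in the mitochondrial block (named `mt-*`).
#' @param strain_mixing Per-cluster probability that a cell comes from the
#'   disease strain; default 0.5 everywhere except the last cluster at 0.9
#'   (a disease-enriched cluster).
#' @param outlier_cells List with counts `n_low_genes` (near-empty cells
#'   failing the minimum-genes QC bound) and `n_high_mito` (cells with ~50%
#'   mitochondrial content).
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A `cell_sim_config` list.
#' @export
cell_sim_config <- function(n_clusters = 5, cells_per_cluster = 100,
                            n_genes = 800, n_marker_genes_per_cluster = 10,
                            marker_fold_change = 4,
                            nb_mean = 0.3, nb_dispersion = 0.8,
                            doublet_rate = 0.05,
                            singlet_score_shape = c(2, 20),
                            doublet_score_shape = c(8, 4),
                            mito_frac_shape = c(2, 60),
                            n_mito_genes = 10,
                            strain_mixing = NULL,
                            outlier_cells = list(n_low_genes = 0,
                                                 n_high_mito = 0),
                            seed = 1L) {
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (marker_fold_change < 1)
    stop("marker_fold_change must be >= 1", call. = FALSE)
  if (doublet_rate < 0 || doublet_rate > 1)
    stop("doublet_rate must be in [0, 1]", call. = FALSE)
  cells_per_cluster <- rep_len(cells_per_cluster, n_clusters)
  if (doublet_rate >= 1 || (doublet_rate > 0 && sum(cells_per_cluster) < 2))
    if (doublet_rate >= 1 && all(cells_per_cluster == 1))
      stop("degenerate config: doublet_rate 1 with single-cell clusters",
           call. = FALSE)
  if (is.null(strain_mixing)) {
    strain_mixing <- rep(0.5, n_clusters)
    strain_mixing[n_clusters] <- 0.9
  }
  strain_mixing <- rep_len(strain_mixing, n_clusters)
  if (any(strain_mixing < 0 | strain_mixing > 1))
    stop("strain_mixing probabilities must be in [0, 1]", call. = FALSE)
  if (n_genes <= n_mito_genes + n_clusters * n_marker_genes_per_cluster)
    stop("n_genes too small for the mito block plus marker blocks",
         call. = FALSE)
  structure(list(n_clusters = n_clusters,
                 cells_per_cluster = cells_per_cluster, n_genes = n_genes,
                 n_marker_genes_per_cluster = n_marker_genes_per_cluster,
                 marker_fold_change = marker_fold_change, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion, doublet_rate = doublet_rate,
                 singlet_score_shape = singlet_score_shape,
                 doublet_score_shape = doublet_score_shape,
                 mito_frac_shape = mito_frac_shape,
                 n_mito_genes = n_mito_genes, strain_mixing = strain_mixing,
                 outlier_cells = outlier_cells, seed = as.integer(seed)),
            class = "cell_sim_config")
}

#' Simulate a single-cell count matrix with planted truth
#'
#' Counts are negative-binomial per gene; each cluster's marker block is
#' up-shifted by the configured fold change.  Doublets are the elementwise
#' mean of two random singlet profiles, rounded to integers (the standard
#' simulation used by doublet detectors), and draw their doublet score from
#' the doublet Beta distribution.  Mitochondrial fractions are planted by
#' generating the `mt-*` gene block as a multinomial sized to the target
#' fraction of each cell's total.
#'
#' @param config A [cell_sim_config].
#' @return List with `matrix` (an [expr_matrix], raw counts),
#'   `annotations` (data frame: `cell_id`, `strain`, `true_cluster`,
#'   `is_doublet`, `doublet_score`, `planted_mito_frac`), and
#'   `marker_genes` (data frame: `gene`, `cluster`).
#' @export
simulate_cells <- function(config = cell_sim_config()) {
  stopifnot(inherits(config, "cell_sim_config"))
  withr::with_seed(config$seed, simulate_cells_impl(config))
}

simulate_cells_impl <- function(cfg) {
  n_mito <- cfg$n_mito_genes
  n_clusters <- cfg$n_clusters
  n_genes <- cfg$n_genes
  mito_genes <- paste0("mt-Gene", seq_len(n_mito))
  body_genes <- paste0("Gene", seq_len(n_genes - n_mito))
  genes <- c(mito_genes, body_genes)
  n_body <- length(body_genes)

  # per-gene baseline means: Gamma-skewed around nb_mean
  base_mean <- stats::rgamma(n_body, shape = 0.7,
                             scale = cfg$nb_mean / 0.7)
  base_mean <- pmax(base_mean, 1e-3)

  marker_idx <- matrix(seq_len(n_clusters * cfg$n_marker_genes_per_cluster),
                       nrow = cfg$n_marker_genes_per_cluster)
  marker_tab <- data.frame(
    gene = body_genes[as.vector(marker_idx)],
    cluster = rep(paste0("c", seq_len(n_clusters)),
                  each = cfg$n_marker_genes_per_cluster),
    stringsAsFactors = FALSE)
  # markers get a floor on baseline mean so the planted fold change is
  # detectable rather than drowned in sampling zeros
  base_mean[as.vector(marker_idx)] <- pmax(base_mean[as.vector(marker_idx)],
                                           cfg$nb_mean)

  size <- 1 / cfg$nb_dispersion
  n_per <- cfg$cells_per_cluster
  n_singlets <- sum(n_per)
  counts_body <- matrix(0L, nrow = n_body, ncol = n_singlets)
  cl_of <- rep(seq_len(n_clusters), n_per)
  for (k in seq_len(n_clusters)) {
    mu <- base_mean
    mu[marker_idx[, k]] <- mu[marker_idx[, k]] * cfg$marker_fold_change
    cols <- which(cl_of == k)
    counts_body[, cols] <- stats::rnbinom(n_body * length(cols),
                                          mu = mu, size = size)
  }

  # doublets: mean of two random singlets, rounded
  n_doub <- round(cfg$doublet_rate * n_singlets / (1 - cfg$doublet_rate))
  if (cfg$doublet_rate >= 1)
    stop("degenerate config: doublet_rate must be < 1 in practice",
         call. = FALSE)
  doub_body <- NULL
  if (n_doub > 0) {
    if (n_singlets < 2)
      stop("degenerate config: need >= 2 singlets to form doublets",
           call. = FALSE)
    p1 <- sample.int(n_singlets, n_doub, replace = TRUE)
    p2 <- vapply(p1, function(i) {
      j <- sample.int(n_singlets, 1)
      while (j == i) j <- sample.int(n_singlets, 1)
      j
    }, integer(1))
    doub_body <- round((counts_body[, p1, drop = FALSE] +
                          counts_body[, p2, drop = FALSE]) / 2)
  }
  body <- cbind(counts_body, doub_body)
  n_cells <- ncol(body)
  is_doublet <- c(rep(FALSE, n_singlets), rep(TRUE, n_doub))
  true_cluster <- c(paste0("c", cl_of), rep("doublet", n_doub))

  # outlier cells violating QC bounds
  out <- cfg$outlier_cells
  n_low <- if (is.null(out$n_low_genes)) 0L else out$n_low_genes
  n_hm <- if (is.null(out$n_high_mito)) 0L else out$n_high_mito
  if (n_low > 0) {
    low <- matrix(0L, nrow = n_body, ncol = n_low)
    for (j in seq_len(n_low)) {
      pick <- sample.int(n_body, min(20L, n_body))
      low[pick, j] <- 1L
    }
    body <- cbind(body, low)
    is_doublet <- c(is_doublet, rep(FALSE, n_low))
    true_cluster <- c(true_cluster, rep("outlier_low", n_low))
  }
  if (n_hm > 0) {
    hm_cols <- seq_len(n_hm)
    hm <- counts_body[, sample.int(n_singlets, n_hm, replace = TRUE),
                      drop = FALSE]
    body <- cbind(body, hm)
    is_doublet <- c(is_doublet, rep(FALSE, n_hm))
    true_cluster <- c(true_cluster, rep("outlier_mito", n_hm))
  }
  n_cells <- ncol(body)

  # plant mitochondrial fractions via a sized multinomial on the mito block
  mito_target <- stats::rbeta(n_cells, cfg$mito_frac_shape[1],
                              cfg$mito_frac_shape[2])
  if (n_hm > 0) {
    idx_hm <- (n_cells - n_hm + 1):n_cells
    mito_target[idx_hm] <- stats::rbeta(n_hm, 30, 30)  # ~50% mito content
  }
  body_tot <- colSums(body)
  mito_tot <- round(mito_target / (1 - mito_target) * body_tot)
  mito_w <- stats::rgamma(length(mito_genes), shape = 2, scale = 1) + 0.1
  counts_mito <- vapply(seq_len(n_cells), function(j) {
    if (mito_tot[j] <= 0) return(integer(length(mito_genes)))
    as.integer(stats::rmultinom(1, mito_tot[j], prob = mito_w))
  }, integer(length(mito_genes)))

  counts <- rbind(counts_mito, body)
  cell_id <- sprintf("cell%04d", seq_len(n_cells))
  strain_p <- ifelse(is_doublet | grepl("^outlier", true_cluster), 0.5,
                     cfg$strain_mixing[match(true_cluster,
                                             paste0("c",
                                                    seq_len(n_clusters)))])
  strain_p[is.na(strain_p)] <- 0.5
  strain <- ifelse(stats::runif(n_cells) < strain_p, "disease", "control")
  score <- ifelse(is_doublet,
                  stats::rbeta(n_cells, cfg$doublet_score_shape[1],
                               cfg$doublet_score_shape[2]),
                  stats::rbeta(n_cells, cfg$singlet_score_shape[1],
                               cfg$singlet_score_shape[2]))
  ann <- data.frame(cell_id = cell_id, strain = strain,
                    true_cluster = true_cluster, is_doublet = is_doublet,
                    doublet_score = score,
                    planted_mito_frac = mito_target,
                    stringsAsFactors = FALSE)
  list(matrix = expr_matrix(counts, gene_ids = genes, cell_ids = cell_id,
                            layer = "raw"),
       annotations = ann, marker_genes = marker_tab)
}
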