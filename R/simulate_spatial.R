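#' Configuration for the spatial-grid simulator
#'
#' Builds a square spot lattice carved into anatomical regions modelled on
#' a kidney section: a cortex annulus (outer ~55% of spots), medulla (~30%),
#' pelvis (inner ~15%), and glomeruli scattered through the cortex (5% of
#' all spots).  Score channels are prediction-score-like values in \[0, 1\];
#' pairs listed in `channel_pairs` are drawn with the planted Pearson
#' correlation inside their region and independently outside.
#'
#' @param grid_rows,grid_cols Lattice dimensions.
#' @param region_map Optional character vector (length `grid_rows *
#'   grid_cols`, row-major) assigning each spot to one of `cortex`,
#'   `medulla`, `pelvis`, `glomerulus`; default is the concentric layout
#'   above.
#' @param channel_pairs List of `list(chan_a, chan_b, region, rho)` planted
#'   correlations; the default plants rho = 0.8 between channels `sigA` and
#'   `sigB` in the cortex.
#' @param noise_sd Standard deviation of the channel values around their 0.5
#'   center before clamping to \[0, 1\] (default 0.15, making clamping rare
#'   so the planted Pearson correlation survives).
#' @param glom_frac Fraction of spots converted to glomeruli (default 0.05).
#' @param podocyte_channel Name of the podocyte-signature channel that is
#'   elevated in glomeruli (`Beta(20, 4)` there vs `Beta(2, 20)` elsewhere).
#' @param seed Integer seed.
#' @return A `spatial_sim_config` list.
#' @export
spatial_sim_config <- function(grid_rows = 20, grid_cols = 20,
                               region_map = NULL,
                               channel_pairs = list(
                                 list(chan_a = "sigA", chan_b = "sigB",
                                      region = "cortex", rho = 0.8)),
                               noise_sd = 0.15, glom_frac = 0.05,
                               podocyte_channel = "podocyte",
                               seed = 1L) {
  for (p in channel_pairs) {
    if (abs(p$rho) > 1)
      stop("planted rho must be in [-1, 1]", call. = FALSE)
  }
  if (!is.null(region_map) &&
      length(region_map) != grid_rows * grid_cols)
    stop("region_map length must equal grid_rows * grid_cols", call. = FALSE)
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 region_map = region_map, channel_pairs = channel_pairs,
                 noise_sd = noise_sd, glom_frac = glom_frac,
                 podocyte_channel = podocyte_channel,
                 seed = as.integer(seed)),
            class = "spatial_sim_config")
}

default_region_map <- function(rows, cols) {
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  # normalized Chebyshev distance from grid center: concentric rings
  d <- pmax(abs(rr - (rows + 1) / 2) / (rows / 2),
            abs(cc - (cols + 1) / 2) / (cols / 2))
  region <- rep("cortex", rows * cols)
  region[d < 0.67] <- "medulla"
  region[d < 0.38] <- "pelvis"
  region
}

#' Simulate a spatial dataset with planted channel correlations
#'
#' Channel values are generated on a latent Gaussian scale (bivariate normal
#' with the planted correlation inside the target region, independent
#' standard normals elsewhere), mapped to `0.5 + noise_sd * z`, and clamped
#' to \[0, 1\]; the clamp is rare at the default noise level, so the
#' planted Pearson correlation is preserved to within sampling error.
#' Glomerulus spots carry an elevated podocyte-signature channel.
#'
#' @param config A [spatial_sim_config].
#' @return A [spatial_dataset] whose `spots` data frame carries a truth
#'   `region` column.
#' @export
simulate_spatial <- function(config = spatial_sim_config()) {
  stopifnot(inherits(config, "spatial_sim_config"))
  withr::with_seed(config$seed, simulate_spatial_impl(config))
}

simulate_spatial_impl <- function(cfg) {
  rows <- cfg$grid_rows; cols <- cfg$grid_cols
  n <- rows * cols
  region <- if (is.null(cfg$region_map)) default_region_map(rows, cols)
            else as.character(cfg$region_map)
  if (is.null(cfg$region_map) && cfg$glom_frac > 0) {
    cortex_idx <- which(region == "cortex")
    n_glom <- round(cfg$glom_frac * n)
    glom <- sample(cortex_idx, min(n_glom, length(cortex_idx)))
    region[glom] <- "glomerulus"
  }
  spots <- data.frame(
    spot_id = sprintf("spot%04d", seq_len(n)),
    array_row = rep(seq_len(rows), each = cols),
    array_col = rep(seq_len(cols), times = rows),
    in_tissue = TRUE, region = region,
    stringsAsFactors = FALSE)

  squash <- function(z) pmin(1, pmax(0, 0.5 + cfg$noise_sd * z))
  chan_names <- unique(unlist(lapply(cfg$channel_pairs,
                                     function(p) c(p$chan_a, p$chan_b))))
  latent <- stats::setNames(
    lapply(chan_names, function(nm) stats::rnorm(n)), chan_names)
  for (p in cfg$channel_pairs) {
    # glomeruli punched out of the cortex still belong to the cortical
    # tissue for correlation planting
    in_reg <- region == p$region |
      (p$region == "cortex" & region == "glomerulus")
    m <- sum(in_reg)
    if (m > 0) {
      z1 <- stats::rnorm(m)
      z2 <- p$rho * z1 + sqrt(1 - p$rho^2) * stats::rnorm(m)
      latent[[p$chan_a]][in_reg] <- z1
      latent[[p$chan_b]][in_reg] <- z2
    }
  }
  channels <- lapply(latent, squash)
  if (!is.null(cfg$podocyte_channel)) {
    pod <- stats::rbeta(n, 2, 20)
    is_glom <- region == "glomerulus"
    pod[is_glom] <- stats::rbeta(sum(is_glom), 20, 4)
    channels[[cfg$podocyte_channel]] <- pod
  }
  spatial_dataset(spots, channels = channels)
}
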