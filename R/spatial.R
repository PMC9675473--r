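#' Neighborhood parameters for the spatial colocalization statistic
#'
#' @param k Neighborhood size including the focal spot (>= 2); default 7,
#'   i.e. the focal spot plus its 6 nearest neighbors, approximating the
#'   first hexagonal ring of a Visium array.
#' @param method Correlation estimator within a neighborhood: `"pearson"`
#'   (default) or `"spearman"`.
#' @param all_containing Average a spot's score over every neighborhood that
#'   contains it (default, the overlapping-windows reading); `FALSE` uses
#'   only the spot's own neighborhood.
#' @return A `neighborhood_params` list.
#' @export
neighborhood_params <- function(k = 7, method = c("pearson", "spearman"),
                                all_containing = TRUE) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  structure(list(k = as.integer(k), method = match.arg(method),
                 all_containing = all_containing),
            class = "neighborhood_params")
}

#' k-nearest spot neighborhoods on array coordinates
#'
#' Each spot's neighborhood is itself plus its `k - 1` nearest spots by
#' Euclidean distance on `(array_row, array_col)`; distance ties are broken
#' by ascending spot index.
#'
#' @param coords Two-column matrix or data frame of unique array
#'   coordinates.
#' @param k Neighborhood size including the focal spot; must not exceed the
#'   number of spots.
#' @return Integer matrix `n x k`; row i lists the member indices of spot
#'   i's neighborhood, nearest first (the focal spot first).
#' @export
build_knn <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k > n) stop("k exceeds the number of spots", call. = FALSE)
  if (anyDuplicated(coords))
    stop("spot coordinates must be unique", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  t(vapply(seq_len(n), function(i)
    order(d[i, ], seq_len(n))[seq_len(k)], integer(k)))
}

#' Spot-neighborhood colocalization scores between two channels
#'
#' For every spot's k-nearest neighborhood the correlation of the two
#' channels over the member spots is computed; a neighborhood returns no
#' value when either channel is constant (or missing) within it.  Each
#' spot's score is the mean of the defined correlations over all
#' neighborhoods containing it (missing when none is defined), and finally
#' non-positive scores are set to missing: only positive correlation values
#' are retained, so an `NA` ("gray") spot means no available score or
#' anti-correlation, never zero signal conflated with absence.
#'
#' @param dataset A [spatial_dataset] with both channels present.
#' @param chan_a,chan_b Channel names.
#' @param params A [neighborhood_params].
#' @return Data frame `spot_id`, `score` (positive real or `NA`), aligned
#'   with the dataset spot order.
#' @export
neighborhood_correlation <- function(dataset, chan_a, chan_b,
                                     params = neighborhood_params()) {
  a <- get_channel(dataset, chan_a)
  b <- get_channel(dataset, chan_b)
  nb <- build_knn(dataset$spots[, c("array_row", "array_col")], params$k)
  n <- nrow(nb)
  r_nb <- vapply(seq_len(n), function(i) {
    ai <- a[nb[i, ]]; bi <- b[nb[i, ]]
    if (anyNA(ai) || anyNA(bi)) return(NA_real_)
    if (stats::var(ai) == 0 || stats::var(bi) == 0) return(NA_real_)
    stats::cor(ai, bi, method = params$method)
  }, numeric(1))
  score <- numeric(n)
  if (params$all_containing) {
    # accumulate each neighborhood's r onto all its member spots
    sums <- numeric(n)
    cnts <- numeric(n)
    for (i in seq_len(n)) {
      if (is.na(r_nb[i])) next
      mem <- nb[i, ]
      sums[mem] <- sums[mem] + r_nb[i]
      cnts[mem] <- cnts[mem] + 1
    }
    score <- ifelse(cnts > 0, sums / cnts, NA_real_)
  } else {
    score <- r_nb
  }
  # positive-only retention; the tiny guard keeps exact-zero averages
  # (cancellation cases) on the purged side regardless of summation order
  score[!is.na(score) & score <= 1e-12] <- NA_real_
  data.frame(spot_id = dataset$spots$spot_id, score = score,
             stringsAsFactors = FALSE)
}

#' Glomerulus-spot selection parameters
#'
#' @param channel Name of the podocyte-signature prediction-score channel.
#' @param quantile Quantile rule: select spots whose channel value strictly
#'   exceeds this quantile of the channel (default 0.95).  Ignored when
#'   `threshold` is given.
#' @param threshold Optional absolute threshold (strict `>`).
#' @return A `glom_select_params` list.
#' @export
glom_select_params <- function(channel = "podocyte", quantile = 0.95,
                               threshold = NULL) {
  if (is.null(threshold) && (quantile <= 0 || quantile >= 1))
    stop("quantile must be in (0, 1)", call. = FALSE)
  structure(list(channel = channel, quantile = quantile,
                 threshold = threshold),
            class = "glom_select_params")
}

#' Select glomerulus-containing spots by podocyte signature
#'
#' Spots whose podocyte-signature channel strictly exceeds the rule
#' threshold (the channel's `quantile` by default, or an absolute value).
#'
#' @param dataset A [spatial_dataset].
#' @param params A [glom_select_params].
#' @return Character vector of selected spot ids; an empty selection is an
#'   error.
#' @export
select_glomerular_spots <- function(dataset, params = glom_select_params()) {
  v <- get_channel(dataset, params$channel)
  thr <- if (!is.null(params$threshold)) params$threshold
         else stats::quantile(v, params$quantile, na.rm = TRUE, names = FALSE)
  sel <- !is.na(v) & v > thr
  if (!any(sel))
    stop("no spot exceeds the selection threshold (",
         signif(thr, 4), ")", call. = FALSE)
  dataset$spots$spot_id[sel]
}

#' Average subset composition within a spot set
#'
#' Within each selected spot the listed subset channels are renormalized to
#' sum to 1 (spots where all listed channels are 0 are dropped, with the
#' count recorded); the mean renormalized proportion per subset over the
#' remaining spots is returned and sums to 1.
#'
#' @param dataset A [spatial_dataset].
#' @param spot_set Nonempty character vector of spot ids (e.g. from
#'   [select_glomerular_spots()]).
#' @param subset_channels Channel names of the subset signatures.
#' @return Named numeric vector of mean proportions (sums to 1), with
#'   attribute `n_dropped` = number of all-zero spots dropped.
#' @export
composition_in_spots <- function(dataset, spot_set, subset_channels) {
  if (length(spot_set) == 0) stop("spot_set is empty", call. = FALSE)
  idx <- match(spot_set, dataset$spots$spot_id)
  if (anyNA(idx))
    stop("spot_set contains unknown spot ids", call. = FALSE)
  m <- vapply(subset_channels,
              function(nm) get_channel(dataset, nm)[idx],
              numeric(length(idx)))
  m <- matrix(m, nrow = length(idx),
              dimnames = list(spot_set, subset_channels))
  tot <- rowSums(m)
  dropped <- sum(tot == 0)
  keep <- tot > 0
  if (!any(keep))
    stop("all selected spots have zero total over the listed subsets",
         call. = FALSE)
  props <- m[keep, , drop = FALSE] / tot[keep]
  out <- colMeans(props)
  attr(out, "n_dropped") <- dropped
  out
}
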