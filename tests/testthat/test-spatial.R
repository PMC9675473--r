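test_that("k-NN neighborhoods break distance ties by spot index", {
  # 1 x 3 line: middle spot ties left/right; lower index wins
  coords <- cbind(c(1, 1, 1), c(1, 2, 3))
  nb <- build_knn(coords, 2)
  expect_equal(nb[2, ], c(2L, 1L))
  expect_equal(nb[1, ], c(1L, 2L))
  # k = n: every neighborhood covers all spots
  nb_all <- build_knn(coords, 3)
  expect_true(all(apply(nb_all, 1, sort) == 1:3))
  expect_error(build_knn(coords, 4), "exceeds")
  expect_error(build_knn(coords[c(1, 1), ], 2), "unique")
})

test_that("neighborhoods equal a brute-force all-pairs sort on random spots", {
  coords <- withr::with_seed(101, cbind(runif(50) * 10, runif(50) * 10))
  for (k in c(2, 7, 15)) {
    expect_equal(build_knn(coords, k), oracle_knn(coords, k),
                 ignore_attr = TRUE)
  }
})

grid_dataset <- function(rows, cols, channels) {
  spots <- data.frame(
    spot_id = sprintf("s%03d", seq_len(rows * cols)),
    array_row = rep(seq_len(rows), each = cols),
    array_col = rep(seq_len(cols), times = rows), in_tissue = TRUE)
  spatial_dataset(spots, channels = channels,
                  score_channels = character())
}

test_that("self-correlation gives 1 everywhere; negative maps go all-gray", {
  ch <- withr::with_seed(103, list(a = runif(25)))
  ch$b <- ch$a
  ds <- grid_dataset(5, 5, ch)
  sc <- neighborhood_correlation(ds, "a", "b",
                                 neighborhood_params(k = 4))
  expect_true(all(!is.na(sc$score)))
  expect_equal(sc$score, rep(1, 25), tolerance = 1e-12)
  # negative affine transform: all r = -1, purged by positive-only retention
  ds2 <- grid_dataset(5, 5, list(a = ch$a, b = 1 - ch$a))
  sc2 <- neighborhood_correlation(ds2, "a", "b",
                                  neighborhood_params(k = 4))
  expect_true(all(is.na(sc2$score)))
})

test_that("3x3 hand grid matches the enumeration oracle at 1e-12", {
  ch <- list(a = c(0.1, 0.5, 0.2, 0.9, 0.4, 0.3, 0.6, 0.8, 0.7),
             b = c(0.2, 0.4, 0.1, 0.8, 0.9, 0.2, 0.5, 0.6, 0.9))
  ds <- grid_dataset(3, 3, ch)
  sc <- neighborhood_correlation(ds, "a", "b", neighborhood_params(k = 3))
  coords <- as.matrix(ds$spots[, c("array_row", "array_col")])
  want <- oracle_neighborhood_scores(coords, ch$a, ch$b, 3)
  expect_equal(sc$score, want, tolerance = 1e-12)
})

test_that("constant-channel neighborhoods return no value (gray semantics)", {
  # channel a constant on the left column: its neighborhoods are undefined
  ch <- list(a = c(0.5, 0.1, 0.9, 0.5, 0.7, 0.2, 0.5, 0.3, 0.8),
             b = withr::with_seed(107, runif(9)))
  ds <- grid_dataset(3, 3, ch)
  sc <- neighborhood_correlation(ds, "a", "b", neighborhood_params(k = 3))
  coords <- as.matrix(ds$spots[, c("array_row", "array_col")])
  want <- oracle_neighborhood_scores(coords, ch$a, ch$b, 3)
  expect_equal(sc$score, want, tolerance = 1e-12)
  expect_error(neighborhood_correlation(ds, "a", "nope"), "nope")
})

test_that("scores are invariant under positive affine channel transforms", {
  ch <- withr::with_seed(109, list(a = runif(36), b = runif(36)))
  ds <- grid_dataset(6, 6, ch)
  p <- neighborhood_params(k = 5)
  base <- neighborhood_correlation(ds, "a", "b", p)$score
  ds2 <- spatial_dataset(ds$spots,
                         channels = list(a = 3 * ch$a + 0.2, b = ch$b),
                         score_channels = character())
  expect_equal(neighborhood_correlation(ds2, "a", "b", p)$score, base,
               tolerance = 1e-12)
})

test_that("own-neighborhood-only averaging and Spearman variants work", {
  ch <- withr::with_seed(113, list(a = runif(16), b = runif(16)))
  ds <- grid_dataset(4, 4, ch)
  own <- neighborhood_correlation(ds, "a", "b",
                                  neighborhood_params(k = 4,
                                                      all_containing = FALSE))
  nb <- build_knn(as.matrix(ds$spots[, c("array_row", "array_col")]), 4)
  r3 <- cor(ch$a[nb[3, ]], ch$b[nb[3, ]])
  expect_equal(own$score[3], if (r3 > 0) r3 else NA_real_)
  sp <- neighborhood_correlation(ds, "a", "b",
                                 neighborhood_params(k = 4,
                                                     method = "spearman"))
  expect_true(any(!is.na(sp$score)) || all(is.na(sp$score)))
})

test_that("planted cortex correlation lights up the map only in cortex", {
  sp <- simulate_spatial(spatial_sim_config(grid_rows = 20, grid_cols = 20,
                                            seed = 47))
  sc <- neighborhood_correlation(sp, "sigA", "sigB",
                                 neighborhood_params(k = 7))
  reg <- sp$spots$region
  cortex_like <- reg %in% c("cortex", "glomerulus")
  # interior cortex spots: all neighbors inside the cortex annulus
  nb <- build_knn(as.matrix(sp$spots[, c("array_row", "array_col")]), 7)
  interior <- which(cortex_like &
                      apply(nb, 1, function(r) all(cortex_like[r])))
  expect_gt(median(sc$score[interior], na.rm = TRUE), 0.5)
  # deep outside the cortex (neighborhoods never touching it) correlations
  # are null: they straddle zero, positive-only retention purges about
  # half, and what survives is weak
  deep_out <- which(!cortex_like &
                      apply(nb, 1, function(r) !any(cortex_like[r])))
  expect_gt(length(deep_out), 50)
  expect_equal(mean(!is.na(sc$score[deep_out])), 0.5, tolerance = 0.25)
  expect_lt(median(sc$score[deep_out], na.rm = TRUE),
            median(sc$score[interior], na.rm = TRUE) - 0.25)
})

test_that("glomerular spot selection recovers planted glomeruli", {
  sp <- simulate_spatial(spatial_sim_config(grid_rows = 20, grid_cols = 20,
                                            seed = 59))
  sel <- select_glomerular_spots(sp, glom_select_params(quantile = 0.95))
  truth <- sp$spots$spot_id[sp$spots$region == "glomerulus"]
  recovery <- length(intersect(sel, truth)) / length(truth)
  expect_gte(recovery, 0.9)
  # absolute threshold variant: {0.4, 0.6} with threshold 0.5
  ds <- spatial_dataset(data.frame(spot_id = c("x", "y"), array_row = 1:2,
                                   array_col = 1L),
                        channels = list(pod = c(0.4, 0.6)))
  expect_identical(
    select_glomerular_spots(ds, glom_select_params(channel = "pod",
                                                   threshold = 0.5)), "y")
  # all values equal: nothing strictly exceeds the quantile
  ds_eq <- spatial_dataset(data.frame(spot_id = c("x", "y"),
                                      array_row = 1:2, array_col = 1L),
                           channels = list(pod = c(0.4, 0.4)))
  expect_error(select_glomerular_spots(ds_eq,
                                       glom_select_params(channel = "pod")),
               "no spot")
})

test_that("composition renormalizes, sums to 1, and recovers planted mixes", {
  ds <- spatial_dataset(data.frame(spot_id = "s1", array_row = 1L,
                                   array_col = 1L),
                        channels = list(m1 = 0.2, m2 = 0.2))
  comp <- composition_in_spots(ds, "s1", c("m1", "m2"))
  expect_equal(unname(comp), c(0.5, 0.5), ignore_attr = TRUE)
  # planted (0.7, 0.3) with noise over 100 spots
  withr::with_seed(127, {
    m1 <- pmax(0, 0.7 + rnorm(100, sd = 0.02))
    m2 <- pmax(0, 0.3 + rnorm(100, sd = 0.02))
  })
  ds2 <- spatial_dataset(data.frame(spot_id = sprintf("s%03d", 1:100),
                                    array_row = rep(1:10, each = 10),
                                    array_col = rep(1:10, times = 10)),
                         channels = list(m1 = pmin(m1, 1),
                                         m2 = pmin(m2, 1)))
  comp2 <- composition_in_spots(ds2, ds2$spots$spot_id, c("m1", "m2"))
  expect_equal(sum(comp2), 1, tolerance = 1e-9)
  expect_equal(unname(comp2["m1"]), 0.7, tolerance = 0.05)
  # all-zero spots drop; dropping everything is an error
  ds3 <- spatial_dataset(data.frame(spot_id = c("a", "b"), array_row = 1:2,
                                    array_col = 1L),
                         channels = list(m1 = c(0, 0), m2 = c(0, 0)))
  expect_error(composition_in_spots(ds3, c("a", "b"), c("m1", "m2")),
               "zero total")
  expect_error(composition_in_spots(ds2, character(0), c("m1", "m2")),
               "empty")
})
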