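#' Configuration for cross-dataset cell-type similarity scoring
#'
#' @param n_folds Cross-validation folds (default 10).
#' @param n_iterations Number of fitting iterations averaged into the final
#'   score (default 50).  Each iteration reshuffles the CV fold partition,
#'   the only stochastic element of the procedure, and therefore its own
#'   penalty selection.
#' @param lambda_rule Penalty selection rule; only `"1se"` (largest penalty
#'   within one standard error of the CV-deviance minimum) is provided.
#' @param n_lambda Length of the log-spaced penalty path.
#' @param lambda Optional fixed penalty; when given, cross-validation is
#'   skipped and every iteration fits at this penalty.
#' @param gene_filter Optional gene-id list intersected with the reference
#'   genes before training (e.g. a tissue-specific gene list).
#' @param query_standardization `"query"` (default) standardizes the query
#'   with its own per-gene statistics, mirroring standardization performed
#'   in both the training and the test set; `"train"` reuses the training
#'   statistics.
#' @param seed Integer seed for the fold shuffles.
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(n_folds = 10, n_iterations = 50,
                              lambda_rule = "1se", n_lambda = 100,
                              lambda = NULL, gene_filter = NULL,
                              query_standardization = c("query", "train"),
                              seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (!identical(lambda_rule, "1se"))
    stop("only the 1se lambda rule is implemented", call. = FALSE)
  structure(list(n_folds = n_folds, n_iterations = n_iterations,
                 lambda_rule = lambda_rule, n_lambda = n_lambda,
                 lambda = lambda, gene_filter = gene_filter,
                 query_standardization = match.arg(query_standardization),
                 seed = as.integer(seed)),
            class = "similarity_config")
}

#' One-standard-error penalty selection
#'
#' Given a penalty path with mean cross-validated loss and its standard
#' error, returns the largest penalty whose mean loss is within one
#' standard error (taken at the minimum) of the minimum mean loss.  On a
#' flat loss curve this is the largest penalty of the path.
#'
#' @param lambda Penalty values (any order).
#' @param cvm Mean CV loss per penalty.
#' @param cvsd Standard error of the CV loss per penalty.
#' @return The selected penalty value.
#' @export
select_lambda_1se <- function(lambda, cvm, cvsd) {
  stopifnot(length(lambda) == length(cvm), length(cvm) == length(cvsd))
  i_min <- which.min(cvm)
  thr <- cvm[i_min] + cvsd[i_min]
  max(lambda[cvm <= thr])
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a cell-type similarity ensemble (ridge logistic regression)
#'
#' Trains L2-regularized (ridge, alpha = 0) logistic regression models on
#' standardized reference expression, one per iteration.  Each iteration
#' draws a fresh stratified `n_folds` partition, computes the CV binomial
#' deviance along a shared 100-value log-spaced penalty path, selects the
#' penalty by the one-standard-error rule and refits on the full reference
#' at that penalty.  Penalized fits are solved by `glmnet`; the path,
#' cross-validation, penalty selection and ensembling are the procedure
#' implemented here.
#'
#' @param reference An [expr_matrix] (normalized values recommended).
#' @param labels Binary class per reference cell: logical, 0/1, or a
#'   two-level factor/character (positive class = second sorted level).
#' @param config A [similarity_config].
#' @return A `similarity_ensemble`: gene list, training standardization
#'   mean/sd, per-iteration intercepts, coefficient matrix and selected
#'   penalties, and the positive-class prevalence.
#' @export
fit_similarity <- function(reference, labels,
                           config = similarity_config()) {
  stopifnot_expr(reference)
  y <- as_binary_labels(labels)
  if (length(y) != ncol(reference$values))
    stop("labels must align with reference cells", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present in the reference", call. = FALSE)
  genes <- gene_ids(reference)
  if (!is.null(config$gene_filter))
    genes <- intersect(genes, config$gene_filter)
  if (length(genes) < 2)
    stop("fewer than 2 genes available for training", call. = FALSE)
  X <- Matrix::t(reference$values[genes, , drop = FALSE])
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2)
    stop("fewer than 2 genes with nonzero variance", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  genes <- genes[keep]
  mu <- colMeans(X)
  sds <- sds[keep]
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
  n <- nrow(Xs)
  for (cls in 0:1)
    if (sum(y == cls) < config$n_folds)
      stop("class with fewer cells than folds; stratified CV impossible: ",
           "reduce n_folds or add cells", call. = FALSE)

  # shared penalty path, glmnet-style: lambda_max from the null-model
  # gradient, extended for the ridge case
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n / 1e-3
  path <- exp(seq(log(lmax), log(lmax * 1e-4),
                  length.out = config$n_lambda))

  fits <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_iterations), function(it) {
      lam <- config$lambda
      if (is.null(lam)) {
        foldid <- integer(n)
        for (cls in 0:1) {
          idx <- which(y == cls)
          foldid[idx] <- sample(rep_len(seq_len(config$n_folds),
                                        length(idx)))
        }
        dev <- matrix(NA_real_, config$n_folds, length(path))
        for (f in seq_len(config$n_folds)) {
          te <- foldid == f
          fit <- glmnet::glmnet(Xs[!te, , drop = FALSE], y[!te],
                                family = "binomial", alpha = 0,
                                lambda = path, standardize = FALSE)
          pr <- stats::predict(fit, Xs[te, , drop = FALSE], s = path,
                               type = "response")
          dev[f, ] <- colMeans(binomial_deviance(y[te], pr))
        }
        cvm <- colMeans(dev)
        cvsd <- apply(dev, 2, stats::sd) / sqrt(config$n_folds)
        lam <- select_lambda_1se(path, cvm, cvsd)
      }
      full_path <- sort(unique(c(path, lam)), decreasing = TRUE)
      full <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                             lambda = full_path, standardize = FALSE)
      co <- as.numeric(stats::coef(full, s = lam, exact = FALSE))
      list(lambda = lam, intercept = co[1], beta = co[-1])
    })
  })
  structure(list(genes = genes, train_mean = stats::setNames(mu, genes),
                 train_sd = stats::setNames(sds, genes),
                 intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
                 betas = vapply(fits, `[[`, numeric(length(genes)), "beta"),
                 lambdas = vapply(fits, `[[`, numeric(1), "lambda"),
                 prevalence = mean(y),
                 query_standardization = config$query_standardization),
            class = "similarity_ensemble")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  f <- factor(labels)
  if (nlevels(f) != 2)
    stop("labels must have exactly 2 levels", call. = FALSE)
  as.integer(f) - 1L
}

#' @export
print.similarity_ensemble <- function(x, ...) {
  cat(sprintf(
    "<similarity_ensemble> %d iteration(s), %d genes, lambda in [%.3g, %.3g]\n",
    length(x$intercepts), length(x$genes), min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' Score query cells against a similarity ensemble
#'
#' The query is standardized per gene (query-side statistics by default),
#' ensemble genes absent from the query enter as 0 after standardization,
#' and the final score is the mean over iterations of the logistic
#' positive-class probability.
#'
#' @param ensemble A `similarity_ensemble` from [fit_similarity()].
#' @param query An [expr_matrix].
#' @param average Return the iteration mean (default); `FALSE` returns the
#'   cells x iterations probability matrix.
#' @return Named numeric vector of per-cell similarity scores in \[0, 1\]
#'   (or a matrix when `average = FALSE`).
#' @export
score_query <- function(ensemble, query, average = TRUE) {
  stopifnot_expr(query)
  common <- intersect(ensemble$genes, gene_ids(query))
  if (length(common) == 0)
    stop("no overlap between ensemble genes and query genes", call. = FALSE)
  n_cells <- ncol(query$values)
  Xq <- matrix(0, nrow = n_cells, ncol = length(ensemble$genes),
               dimnames = list(cell_ids(query), ensemble$genes))
  Q <- as.matrix(Matrix::t(query$values[common, , drop = FALSE]))
  if (ensemble$query_standardization == "query") {
    mu <- colMeans(Q)
    sds <- apply(Q, 2, stats::sd)
  } else {
    mu <- ensemble$train_mean[common]
    sds <- ensemble$train_sd[common]
  }
  sds[sds == 0] <- 1  # constant query genes carry no information
  Xq[, common] <- sweep(sweep(Q, 2, mu, "-"), 2, sds, "/")
  eta <- Xq %*% ensemble$betas
  eta <- sweep(eta, 2, ensemble$intercepts, "+")
  probs <- stats::plogis(eta)
  if (!average) return(probs)
  stats::setNames(rowMeans(probs), cell_ids(query))
}
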