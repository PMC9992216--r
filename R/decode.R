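#' Classifier specification
#'
#' @param kind `"LDA"`, `"KNN"` or `"RF"`.
#' @param k Neighbours for KNN (default 5, Euclidean distance).
#' @param n_trees Trees for the random forest (default 100).
#' @param seed Seed controlling any classifier-internal randomness (RF
#'   bootstrap, KNN tie breaks).
#' @param scaling `"zscore"` or `"none"`. Default: z-score standardization
#'   (fit on training rows only) for LDA and KNN, none for RF, which is
#'   invariant to monotone per-feature transforms.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("LDA", "KNN", "RF"), k = 5L,
                            n_trees = 100L, seed = 1L, scaling = NULL) {
  kind <- match.arg(kind)
  if (is.null(scaling)) scaling <- if (kind == "RF") "none" else "zscore"
  scaling <- match.arg(scaling, c("zscore", "none"))
  if (kind == "KNN" && k < 1) stop("KNN needs k >= 1")
  if (kind == "RF" && n_trees < 1) stop("RF needs n_trees >= 1")
  structure(list(kind = kind, k = as.integer(k), n_trees = as.integer(n_trees),
                 seed = as.integer(seed), scaling = scaling),
            class = "classifier_spec")
}

.fit_scaler <- function(x, scaling) {
  if (scaling == "none") return(NULL)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

.apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$mu, `-`), 2, scaler$sd, `/`)
}

# Shrinkage-regularized Gaussian LDA used when the within-class scatter is
# singular (e.g. a feature constant within groups): pooled covariance shrunk
# toward a scaled identity until invertible.
.fit_rlda <- function(x, y) {
  classes <- levels(y)
  p <- ncol(x)
  mu <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                 numeric(p)))
  centered <- x - mu[as.integer(y), , drop = FALSE]
  S <- crossprod(centered) / max(1, nrow(x) - length(classes))
  tr <- sum(diag(S)) / p
  if (tr <= 0) tr <- 1
  lambda <- 1e-4
  repeat {
    Sr <- (1 - lambda) * S + lambda * tr * diag(p)
    Si <- tryCatch(solve(Sr), error = function(e) NULL)
    if (!is.null(Si) || lambda >= 1) break
    lambda <- lambda * 10
  }
  if (is.null(Si)) Si <- diag(p) / tr
  prior <- as.numeric(table(y)[classes]) / length(y)
  list(mu = mu, Si = Si, prior = prior, classes = classes)
}

.predict_rlda <- function(fit, x) {
  # linear discriminant scores d_j(x) = x Si mu_j' - mu_j Si mu_j'/2 + log pi_j
  G <- x %*% fit$Si %*% t(fit$mu)
  off <- 0.5 * rowSums((fit$mu %*% fit$Si) * fit$mu) - log(fit$prior)
  scores <- sweep(G, 2, off, `-`)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Train a gesture classifier on a feature matrix
#'
#' Any scaling is fitted on the training rows only and stored in the model,
#' so test data are standardized with training statistics (no leakage).
#' LDA falls back to a shrinkage-regularized discriminant when the
#' within-class scatter is singular (recorded in the model as
#' `regularized = TRUE`).
#'
#' @param fm A `feature_matrix` (training data).
#' @param spec A [classifier_spec()].
#' @return A `trained_model`.
#' @export
train_model <- function(fm, spec = classifier_spec()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "classifier_spec"))
  y <- factor(fm$labels)
  if (nlevels(y) < 2) stop("training data must contain >= 2 classes")
  scaler <- .fit_scaler(fm$values, spec$scaling)
  x <- .apply_scaler(fm$values, scaler)
  regularized <- FALSE
  fit <- switch(spec$kind,
    LDA = {
      f <- tryCatch(suppressWarnings(MASS::lda(x, grouping = y)),
                    error = function(e) NULL)
      if (is.null(f)) {
        regularized <- TRUE
        message("LDA within-class scatter singular; using shrinkage-regularized variant")
        .fit_rlda(x, y)
      } else f
    },
    KNN = list(x = x, y = y),   # lazy learner: store the training set
    RF = .with_seed(spec$seed, function()
      randomForest::randomForest(x = x, y = y, ntree = spec$n_trees)))
  structure(list(spec = spec, scaler = scaler, fit = fit,
                 regularized = regularized, classes = levels(y),
                 n_features = ncol(fm$values)),
            class = "trained_model")
}

#' Predict gesture labels for a feature matrix
#'
#' @param model A [train_model()] result.
#' @param fm A `feature_matrix` with the same column count as the training
#'   data.
#' @return Character vector of predicted class codes, one per row (length 0
#'   for an empty matrix).
#' @export
predict_model <- function(model, fm) {
  stopifnot(inherits(model, "trained_model"), inherits(fm, "feature_matrix"))
  if (ncol(fm$values) != model$n_features)
    stop("feature column count differs from training data")
  if (nrow(fm$values) == 0) return(character(0))
  x <- .apply_scaler(fm$values, model$scaler)
  spec <- model$spec
  out <- switch(spec$kind,
    LDA = if (model$regularized) .predict_rlda(model$fit, x)
          else .with_seed(spec$seed, function()  # max.col ties draw from RNG
            as.character(stats::predict(model$fit, x)$class)),
    KNN = .with_seed(spec$seed, function()
      as.character(class::knn(model$fit$x, x, model$fit$y, k = spec$k))),
    RF = .with_seed(spec$seed, function()     # vote ties break via the RNG
      as.character(stats::predict(model$fit, x))))
  unname(out)
}

#' Save a trained model to a single-file container
#'
#' @param model A `trained_model`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Model file.
#' @return The `trained_model`; predictions equal those of the original.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_model"))
  model
}
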