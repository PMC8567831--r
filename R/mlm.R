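#' Iterative multilinear model of behavior
#'
#' Fits nested ordinary-least-squares models of a behavioral score on
#' configural-breadth descriptors, adding predictors one at a time in the
#' supplied order (descending subject sensitivity from [rank_descriptors()]).
#' Predictors and response are z-scored before fitting, so coefficients are
#' standardized betas; the intercept is retained. The selected model is the
#' one with the smallest overall (F-test) p-value.
#'
#' @param X Numeric matrix/data frame, rows = subjects, columns = descriptors
#'   already ordered by the caller.
#' @param y Numeric response (one value per subject).
#' @param max_terms Largest model size; defaults to `ncol(X)` capped at
#'   `nrow(X) - 2` so every nested fit keeps residual degrees of freedom.
#' @return An `iterative_mlm` object: `models` (per-size data frames of
#'   standardized betas, coefficient p-values, model p, R2), `selected`
#'   (index = number of predictors of the best model), `fit` (the selected
#'   `lm`), scaling parameters for prediction.
#' @export
iterative_mlm <- function(X, y, max_terms = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (nrow(X) != length(y)) .stopf("fnmorph_validation_error", "nrow(X) != length(y)")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    .stopf("fnmorph_validation_error", "missing values in predictors or response")
  }
  max_terms <- min(max_terms %||% ncol(X), ncol(X), nrow(X) - 2L)
  if (max_terms < 1) .stopf("fnmorph_validation_error", "too few subjects to fit")
  Xq <- X[, seq_len(max_terms), drop = FALSE]
  qrk <- qr(cbind(1, scale(Xq)))
  if (qrk$rank < max_terms + 1) {
    bad <- colnames(Xq)[qrk$pivot[seq(qrk$rank + 1, max_terms + 1)] - 1L]
    .stopf("fnmorph_collinear_error", "rank-deficient design; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  zx <- apply(X, 2, function(col) .zscore(col)$z)
  zy <- .zscore(y)
  models <- vector("list", max_terms)
  fits <- vector("list", max_terms)
  for (q in seq_len(max_terms)) {
    dat <- data.frame(.y = zy$z, zx[, seq_len(q), drop = FALSE])
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    p_model <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    models[[q]] <- list(
      q = q,
      predictors = colnames(X)[seq_len(q)],
      beta = stats::coef(fit)[-1],
      p_coef = sm$coefficients[-1, 4],
      p_model = unname(p_model),
      r2 = sm$r.squared)
    fits[[q]] <- fit
  }
  p_models <- vapply(models, `[[`, numeric(1), "p_model")
  selected <- which.min(p_models)
  structure(list(models = models, selected = selected, fit = fits[[selected]],
                 predictor_order = colnames(X),
                 x_center = colMeans(X), x_scale = apply(X, 2, stats::sd),
                 y_center = zy$center, y_scale = zy$scale),
            class = "iterative_mlm")
}

#' @export
print.iterative_mlm <- function(x, ...) {
  sel <- x$models[[x$selected]]
  cat(sprintf("Iterative multilinear model: %d nested fits; selected q = %d (model p = %.3g, R2 = %.3f)\n",
              length(x$models), x$selected, sel$p_model, sel$r2))
  cat("  standardized betas:\n")
  for (i in seq_along(sel$beta)) {
    cat(sprintf("    %-12s % .4f  (p = %.3g)\n", sel$predictors[i],
                sel$beta[i], sel$p_coef[i]))
  }
  invisible(x)
}

#' @export
summary.iterative_mlm <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$models, function(m) {
    data.frame(q = m$q, last_predictor = m$predictors[m$q],
               p_model = m$p_model, r2 = m$r2)
  }))
  tab$selected <- seq_len(nrow(tab)) == object$selected
  tab
}

#' @export
coef.iterative_mlm <- function(object, ...) {
  object$models[[object$selected]]$beta
}

#' @export
predict.iterative_mlm <- function(object, newdata, rescale = TRUE, ...) {
  sel <- object$models[[object$selected]]
  newdata <- as.matrix(newdata)[, sel$predictors, drop = FALSE]
  z <- sweep(sweep(newdata, 2, object$x_center[sel$predictors]), 2,
             object$x_scale[sel$predictors], "/")
  zy_hat <- drop(cbind(1, z) %*% stats::coef(object$fit))
  if (rescale) zy_hat * object$y_scale + object$y_center else zy_hat
}

#' Cross-validated model specificity
#'
#' Repeated k-fold cross-validation of a fixed predictor set: in each
#' simulation the subjects are split into k random folds; per fold, the model
#' is fit on the training folds and the held-out scores are Pearson-correlated
#' with the predictions; the simulation's statistic is the mean of the k fold
#' correlations. The null repeats the procedure with the response replaced by
#' a fresh standard-normal vector per simulation, showing what the same
#' descriptors predict about noise.
#'
#' @param X Predictor matrix (subjects x descriptors).
#' @param y Behavioral response.
#' @param predictors Columns to use (default all — pass the selected model's
#'   predictor set).
#' @param n_sim Number of simulations.
#' @param k Folds.
#' @param seed RNG seed.
#' @param null_type `"gaussian"` (fresh normal response per simulation) or
#'   `"permutation"` (permuted y).
#' @return A `specificity` object: list with `observed` and `null` (length
#'   `n_sim` vectors of mean fold correlations), `n_sim`, `k`.
#' @export
model_specificity <- function(X, y, predictors = colnames(X),
                              n_sim = 2000L, k = 5L, seed = 1L,
                              null_type = c("gaussian", "permutation")) {
  null_type <- match.arg(null_type)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  X <- X[, predictors, drop = FALSE]
  n <- nrow(X)
  if (k > n) .stopf("fnmorph_validation_error", "k = %d folds exceed n = %d", k, n)
  set.seed(seed)
  cv_mean <- function(resp) {
    folds <- sample(rep_len(seq_len(k), n))    # sizes floor(n/k), remainder spread
    cors <- numeric(k)
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- stats::lm.fit(cbind(1, X[!test, , drop = FALSE]), resp[!test])
      pred <- drop(cbind(1, X[test, , drop = FALSE]) %*% fit$coefficients)
      cors[f] <- stats::cor(resp[test], pred)
    }
    mean(cors)
  }
  observed <- vapply(seq_len(n_sim), function(i) cv_mean(y), numeric(1))
  null <- vapply(seq_len(n_sim), function(i) {
    resp <- if (null_type == "gaussian") stats::rnorm(n) else sample(y)
    cv_mean(resp)
  }, numeric(1))
  structure(list(observed = observed, null = null, n_sim = n_sim, k = k,
                 null_type = null_type),
            class = "specificity")
}

#' @export
print.specificity <- function(x, ...) {
  cat(sprintf("Model specificity: %d simulations of %d-fold CV\n", x$n_sim, x$k))
  cat(sprintf("  observed mean fold correlation: %.4f (sd %.4f)\n",
              mean(x$observed), stats::sd(x$observed)))
  cat(sprintf("  %s null:                        %.4f (sd %.4f)\n",
              x$null_type, mean(x$null), stats::sd(x$null)))
  invisible(x)
}

#' @export
plot.specificity <- function(x, ...) {
  d_obs <- stats::density(x$observed)
  d_null <- stats::density(x$null)
  graphics::plot(d_obs, xlim = range(d_obs$x, d_null$x),
                 ylim = range(0, d_obs$y, d_null$y),
                 main = "Cross-validated model specificity",
                 xlab = "Mean fold correlation", ...)
  graphics::lines(d_null, lty = 2)
  graphics::legend("topleft", legend = c("observed", "null"), lty = c(1, 2))
  invisible(x)
}
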