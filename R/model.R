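#' Ordinary least squares on the energy features
#'
#' Plain OLS of observed log2 fold change on the 14 features plus an
#' intercept. A rank-deficient design is fit through the singular-value
#' pseudoinverse (minimum-norm solution) with a warning naming the aliased
#' features.
#'
#' @param features numeric matrix or data.frame of the 14 features (rows =
#'   miRNA-gene pairs).
#' @param observed numeric vector of observed log2 fold changes.
#' @return a `"energy_lm"` list: `intercept`, `coefficients` (named),
#'   `n_train`, `rank`.
#' @export
fit_ols <- function(features, observed) {
  X <- as.matrix(features[, intersect(colnames(features), FEATURE_NAMES),
                          drop = FALSE])
  if (ncol(X) == 0L) X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!all(is.finite(observed))) stop("observed values must be finite")
  if (nrow(X) <= ncol(X)) stop("need more training rows than features")
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  aliased <- character(0)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    warning("rank-deficient design; fitting via pseudoinverse. Aliased: ",
            paste(aliased, collapse = ", "))
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% observed) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrd, observed)
  }
  names(beta) <- colnames(design)
  structure(list(intercept = unname(beta[1L]),
                 coefficients = beta[-1L],
                 n_train = nrow(X),
                 rank = qrd$rank,
                 aliased = aliased),
            class = "energy_lm")
}

#' Predict from a single linear model
#' @param object an `"energy_lm"` from [fit_ols()].
#' @param newdata feature data.frame/matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.energy_lm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  storage.mode(X) <- "double"
  drop(object$intercept + X %*% object$coefficients)
}

#' Restrict training rows by observed expression change
#'
#' Keeps miRNA-gene pairs whose observed log2 fold change is at or below
#' the cutoff. The default cutoff 0 trains on down-regulated pairs only;
#' a cutoff of -0.1 drops weakly changed genes that are more likely noise.
#'
#' @param features feature data.frame.
#' @param observed numeric vector aligned with `features` rows.
#' @param cutoff log2 fold-change threshold.
#' @return a list `(features, observed)` with the retained rows.
#' @export
filter_training_rows <- function(features, observed, cutoff = 0) {
  keep <- observed <= cutoff
  if (!any(keep)) stop("no training rows at or below cutoff ", cutoff)
  list(features = features[keep, , drop = FALSE], observed = observed[keep])
}

#' K-fold cross-validation of the linear energy model
#'
#' Folds are disjoint at the gene/transcript level (pooled across miRNAs):
#' all rows of one gene land in the same fold. Each fold's held-out
#' predictions are scored by Spearman rank correlation against the
#' observed values.
#'
#' @param features feature data.frame including a `gene_id` column.
#' @param observed numeric vector aligned with rows.
#' @param k number of folds.
#' @param rng_seed integer seed for the fold assignment; NULL uses the
#'   current RNG state.
#' @return a list: `models` (k [fit_ols()] fits), `fold` (per-row fold
#'   id), `cv` (data.frame fold, n_test, spearman_rho, p_value).
#' @export
cross_validate <- function(features, observed, k = 5L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genes <- if ("gene_id" %in% names(features)) features$gene_id
           else seq_len(nrow(features))
  ug <- unique(genes)
  if (k > length(ug)) stop("k exceeds the number of distinct genes")
  gfold <- stats::setNames(sample(rep_len(seq_len(k), length(ug))), ug)
  fold <- unname(gfold[as.character(genes)])
  models <- vector("list", k)
  cv <- data.frame(fold = seq_len(k), n_test = NA_integer_,
                   spearman_rho = NA_real_, p_value = NA_real_)
  for (f in seq_len(k)) {
    train <- fold != f
    models[[f]] <- fit_ols(features[train, , drop = FALSE], observed[train])
    pred <- predict(models[[f]], features[!train, , drop = FALSE])
    obs <- observed[!train]
    cv$n_test[f] <- length(obs)
    ct <- suppressWarnings(stats::cor.test(pred, obs, method = "spearman"))
    cv$spearman_rho[f] <- unname(ct$estimate)
    cv$p_value[f] <- ct$p.value
  }
  list(models = models, fold = fold, cv = cv)
}

#' Median-of-models prediction
#'
#' Applies each cross-validation model to the features and returns the
#' per-row median of the k predictions, usable for all genes including
#' those with positive observed expression change.
#'
#' @param models list of `"energy_lm"` fits sharing one feature schema.
#' @param features feature data.frame.
#' @return numeric vector of median predicted scores (log2 fold-change
#'   scale; more negative = stronger predicted down-regulation).
#' @export
predict_median <- function(models, features) {
  schemas <- vapply(models, function(m) paste(names(m$coefficients),
                                              collapse = ","), character(1))
  if (length(unique(schemas)) != 1L) stop("models disagree on feature schema")
  preds <- vapply(models, predict, numeric(nrow(features)),
                  newdata = features)
  if (nrow(features) == 1L) preds <- matrix(preds, nrow = 1L)
  apply(preds, 1L, stats::median)
}

#' Fit the cross-validated linear model of miRNA-induced expression change
#'
#' The package's central fitter: restricts training rows to observed log2
#' fold change at or below `cutoff`, fits ordinary least squares on the 14
#' energy/length features in a k-fold cross-validation with folds disjoint
#' at the gene level, and keeps all k fold models. Predictions from the
#' fitted object are the per-gene median over the k models.
#'
#' @param features feature data.frame from [feature_table()] (columns
#'   `mirna_id`, `gene_id`, the 14 features).
#' @param observed numeric vector of observed log2 fold changes, aligned
#'   with `features` rows.
#' @param cutoff training cutoff on observed log2 fold change (default 0:
#'   train on down-regulated pairs).
#' @param k number of cross-validation folds.
#' @param rng_seed integer seed for the fold split.
#' @return an object of class `"energy_model"` with `models`, `cv`,
#'   `fold`, `cutoff`, `k`, `rng_seed`, `feature_names`, `training`
#'   (the retained rows), and `call`.
#' @seealso [predict.energy_model()], [coef.energy_model()],
#'   [write_energy_model()]
#' @export
energy_model <- function(features, observed, cutoff = 0, k = 5L,
                         rng_seed = NULL) {
  stopifnot(nrow(features) == length(observed))
  tr <- filter_training_rows(features, observed, cutoff)
  cvres <- cross_validate(tr$features, tr$observed, k = k,
                          rng_seed = rng_seed)
  structure(list(models = cvres$models, cv = cvres$cv, fold = cvres$fold,
                 cutoff = cutoff, k = k, rng_seed = rng_seed,
                 feature_names = names(cvres$models[[1L]]$coefficients),
                 training = list(features = tr$features,
                                 observed = tr$observed),
                 call = match.call()),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Cross-validated linear energy model of expression change\n")
  cat(sprintf("  training rows: %d (observed log2FC <= %g), folds: %d\n",
              length(x$training$observed), x$cutoff, x$k))
  cat(sprintf("  mean held-out Spearman rho: %.3f\n",
              mean(x$cv$spearman_rho)))
  invisible(x)
}

#' Coefficients of the fitted energy model
#'
#' The per-fold coefficient vectors summarized by their median (the same
#' robust combination used for prediction).
#'
#' @param object an `"energy_model"`.
#' @param ... unused.
#' @return named numeric vector (intercept first).
#' @export
coef.energy_model <- function(object, ...) {
  m <- coef_matrix(object)
  apply(m, 2L, stats::median)
}

coef_matrix <- function(object) {
  t(vapply(object$models,
           function(m) c(`(Intercept)` = m$intercept, m$coefficients),
           numeric(length(object$feature_names) + 1L)))
}

#' @export
summary.energy_model <- function(object, ...) {
  out <- list(coefficients = coef_matrix(object), cv = object$cv,
              cutoff = object$cutoff, k = object$k,
              n_train = length(object$training$observed))
  class(out) <- "summary.energy_model"
  out
}

#' @export
print.summary.energy_model <- function(x, ...) {
  cat(sprintf("Linear energy model: %d folds, %d training rows, cutoff %g\n",
              x$k, x$n_train, x$cutoff))
  cat("\nPer-fold held-out Spearman correlation:\n")
  print(x$cv, row.names = FALSE)
  cat("\nPer-fold coefficients (rows = folds):\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict expression change from a fitted energy model
#'
#' @param object an `"energy_model"`.
#' @param newdata feature data.frame; defaults to the training features.
#' @param ... unused.
#' @return per-row median of the k fold-model predictions.
#' @export
predict.energy_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$training$features
  predict_median(object$models, newdata)
}

#' @export
residuals.energy_model <- function(object, ...) {
  object$training$observed - predict(object)
}

#' @export
fitted.energy_model <- function(object, ...) predict(object)

#' Observed-versus-predicted plot of the fitted model
#' @param x an `"energy_model"`.
#' @param ... passed to [plot()].
#' @export
plot.energy_model <- function(x, ...) {
  p <- predict(x)
  graphics::plot(p, x$training$observed,
                 xlab = "median predicted log2 fold change",
                 ylab = "observed log2 fold change", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate expression responses from the fitted model
#'
#' Draws `nsim` response vectors as median prediction plus Gaussian noise
#' with the residual standard deviation.
#'
#' @param object an `"energy_model"`.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data.frame with `nsim` columns.
#' @export
simulate.energy_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  s <- stats::sd(residuals(object))
  out <- replicate(nsim, p + stats::rnorm(length(p), 0, s))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Serialize an energy model to JSON
#'
#' The JSON holds feature names, per-fold intercepts and coefficients at
#' full precision, the training cutoff, fold count and RNG seed; a
#' round-trip through [read_energy_model()] leaves predictions
#' bit-identical.
#'
#' @param object an `"energy_model"`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_energy_model <- function(object, path) {
  payload <- list(
    type = "mirddg_energy_model",
    feature_names = object$feature_names,
    cutoff = object$cutoff, k = object$k,
    rng_seed = object$rng_seed,
    cv = object$cv,
    models = lapply(object$models, function(m) {
      list(intercept = m$intercept, coefficients = as.list(m$coefficients),
           n_train = m$n_train, rank = m$rank)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load an energy model written by [write_energy_model()]
#'
#' @param path path to the model JSON.
#' @return an `"energy_model"` (without the training data, which is not
#'   serialized).
#' @export
read_energy_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  if (!identical(payload$type, "mirddg_energy_model")) {
    stop("not a mirddg energy model: ", path)
  }
  models <- lapply(seq_along(payload$models$intercept), function(i) {
    structure(list(intercept = payload$models$intercept[i],
                   coefficients = unlist(payload$models$coefficients[i, ]),
                   n_train = payload$models$n_train[i],
                   rank = payload$models$rank[i]),
              class = "energy_lm")
  })
  structure(list(models = models, cv = payload$cv, fold = NULL,
                 cutoff = payload$cutoff, k = payload$k,
                 rng_seed = payload$rng_seed,
                 feature_names = payload$feature_names,
                 training = NULL, call = NULL),
            class = "energy_model")
}
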