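# Leakage-aware evaluation machinery: stratified k-fold cross-validation
# with fold-wise fitting of the delta-degree transform, raw-genotype
# baselines, per-component models, an 80/20 holdout protocol, and
# resampling-based feature importance.

#' Specify a predictive model
#'
#' @param kind `"logistic_regression"` (L2-penalised, fitted with glmnet)
#'   or `"random_forest"`.
#' @param lambda Ridge penalty for logistic regression; `NULL` (default)
#'   uses 1/n at fit time, a mild penalty on the scale of scikit-learn's
#'   default C = 1.
#' @param ntree Number of trees for the random forest (default 500).
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("logistic_regression", "random_forest"),
                       lambda = NULL, ntree = 500L) {
  kind <- match.arg(kind)
  if (!is.null(lambda) && lambda < 0) stop("lambda must be non-negative")
  if (ntree < 1) stop("ntree must be positive")
  structure(list(kind = kind, lambda = lambda, ntree = as.integer(ntree)),
            class = "model_spec")
}

fit_model <- function(spec, x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (spec$kind == "logistic_regression") {
    lambda <- if (is.null(spec$lambda)) 1 / nrow(x) else spec$lambda
    padded <- ncol(x) < 2L
    if (padded) x <- cbind(x, `.pad.` = 0)
    fit <- glmnet::glmnet(x, factor(y, levels = 0:1), family = "binomial",
                          alpha = 0, lambda = lambda, standardize = FALSE)
    structure(list(kind = spec$kind, fit = fit, padded = padded,
                   lambda = lambda), class = "epi_model")
  } else {
    fit <- randomForest::randomForest(x, factor(y, levels = 0:1),
                                      ntree = spec$ntree)
    structure(list(kind = spec$kind, fit = fit, padded = FALSE),
              class = "epi_model")
  }
}

predict_model <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (model$kind == "logistic_regression") {
    if (model$padded) x <- cbind(x, `.pad.` = 0)
    p <- predict(model$fit, newx = x, type = "response")[, 1]
    as.integer(p >= 0.5)
  } else {
    as.integer(as.character(predict(model$fit, x)))
  }
}

model_coefficients <- function(model) {
  stopifnot(model$kind == "logistic_regression")
  co <- as.matrix(coef(model$fit))[, 1]
  co <- co[setdiff(names(co), c("(Intercept)", ".pad."))]
  co
}

#' Stratified fold assignment
#'
#' @param labels 0/1 phenotype vector.
#' @param k Number of folds.
#' @param seed Integer seed; the assignment is a deterministic function of
#'   `(labels, k, seed)`.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  if (min(table(factor(labels, levels = 0:1))) < k)
    stop("both classes need at least k subjects for stratified ", k,
         "-fold CV")
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    idx <- idx[rng$sample(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Seeded RNG scoped to an object so library calls elsewhere cannot disturb
# reproducibility mid-pipeline.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample = function(n, size = n) with_state(function() sample.int(n, size)),
    runif = function(n) with_state(function() stats::runif(n)),
    with_state = with_state
  )
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fn <- sum(truth == 1L & pred == 0L)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  data.frame(
    precision_case = safe_div(tp, tp + fp),
    recall_case = safe_div(tp, tp + fn),
    f1_case = safe_div(2 * tp, 2 * tp + fp + fn),
    precision_control = safe_div(tn, tn + fn),
    recall_control = safe_div(tn, tn + fp),
    f1_control = safe_div(2 * tn, 2 * tn + fn + fp),
    accuracy = (tp + tn) / length(truth))
}

aggregate_fold_metrics <- function(per_fold, truth, pred) {
  pooled <- confusion_metrics(truth, pred)
  means <- colMeans(do.call(rbind, per_fold), na.rm = TRUE)
  out <- rbind(pooled, means)
  out <- cbind(summary = c("pooled", "fold_mean"), out)
  rownames(out) <- NULL
  out
}

#' Cross-validated evaluation of the delta-degree transform
#'
#' Stratified k-fold cross-validation in which, for each fold, the
#' per-edge class proportions are fitted on the k-1 training folds only;
#' both the training and the test fold are then transformed with those
#' statistics, the model is fitted on the transformed training data and
#' evaluated on the transformed test fold. Per-class precision/recall/F1
#' and accuracy are reported pooled over folds and as fold means.
#'
#' @param dataset A [geno_dataset].
#' @param network An `epi_network` (typically built beforehand; see
#'   [holdout_protocol()] for the variant that builds it on a training
#'   split only).
#' @param model A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment and any model
#'   randomness.
#' @param zero_evidence Sign rule for unseen genotype-pair cells; see
#'   [edge_sign()].
#' @return A list with `metrics` (data.frame, rows `pooled` and
#'   `fold_mean`), `fold_metrics`, `folds` and `predictions`.
#' @export
cv_transform_evaluate <- function(dataset, network, model = model_spec(),
                                  k = 5L, seed = 1L,
                                  zero_evidence = c("absent", "positive")) {
  zero_evidence <- match.arg(zero_evidence)
  cv_engine(dataset, network, model, k, seed, transform = TRUE,
            variants = network$nodes, zero_evidence = zero_evidence)
}

#' Cross-validated baseline on raw genotype codes
#'
#' Identical fold layout to [cv_transform_evaluate()] for the same seed,
#' but the model is fitted on the untransformed 0/1/2 codes of the chosen
#' variants — the no-transformation comparator.
#'
#' @param dataset A [geno_dataset].
#' @param variant_subset Character vector of variant ids to use as
#'   features.
#' @param model A [model_spec()] (`logistic_regression` or
#'   `random_forest`).
#' @inheritParams cv_transform_evaluate
#' @return As [cv_transform_evaluate()].
#' @export
baseline_evaluate <- function(dataset, variant_subset, model = model_spec(),
                              k = 5L, seed = 1L) {
  cv_engine(dataset, network = NULL, model, k, seed, transform = FALSE,
            variants = variant_subset)
}

cv_engine <- function(dataset, network, model, k, seed, transform,
                      variants, zero_evidence = "absent") {
  y <- dataset$phenotype
  folds <- make_folds(y, k, seed)
  rng <- local_rng(seed + 1L)
  per_fold <- vector("list", k)
  pred_all <- integer(length(y))
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
      stop("fold ", f, " has a single class; use stratified folds or more data")
    if (transform) {
      train_ds <- subset_dataset(dataset, subjects = tr)
      stats <- fit_pair_statistics(train_ds, network)
      x_tr <- delta_degree_transform(train_ds, network, stats,
                                     zero_evidence)
      x_te <- delta_degree_transform(subset_dataset(dataset, subjects = te),
                                     network, stats, zero_evidence)
    } else {
      x_tr <- impute_training_mode(dataset$genotypes[tr, variants,
                                                     drop = FALSE])
      x_te <- impute_training_mode(dataset$genotypes[te, variants,
                                                     drop = FALSE],
                                   ref = x_tr)
    }
    fit <- rng$with_state(function() fit_model(model, x_tr, y[tr]))
    pred <- predict_model(fit, x_te)
    pred_all[te] <- pred
    per_fold[[f]] <- confusion_metrics(y[te], pred)
  }
  metrics <- aggregate_fold_metrics(per_fold, y, pred_all)
  list(metrics = metrics, fold_metrics = do.call(rbind, per_fold),
       folds = folds, predictions = pred_all)
}

# Mode imputation for raw-code baselines; the training matrix defines the
# fill value for its own and the test matrix's missing cells.
impute_training_mode <- function(x, ref = x) {
  if (!anyNA(x)) return(x)
  for (j in seq_len(ncol(x))) {
    if (anyNA(x[, j])) {
      vals <- ref[, j][!is.na(ref[, j])]
      fill <- if (length(vals)) as.integer(names(which.max(table(vals)))) else 0L
      x[is.na(x[, j]), j] <- fill
    }
  }
  x
}

#' Per-component cross-validated evaluation
#'
#' Runs [cv_transform_evaluate()] restricted to each component's induced
#' subnetwork (and [baseline_evaluate()] on its raw variants when
#' `baseline = TRUE`), mirroring the component-wise performance tables.
#'
#' @param dataset A [geno_dataset].
#' @param network An `epi_network`.
#' @param components List of node vectors (from [select_components()]).
#' @param model A [model_spec()].
#' @inheritParams cv_transform_evaluate
#' @param baseline Also evaluate the raw-code baseline per component.
#' @return data.frame with one row per component (pooled metrics), plus
#'   baseline columns when requested; attribute `"details"` keeps the full
#'   per-component results.
#' @export
per_component_evaluate <- function(dataset, network, components,
                                   model = model_spec(), k = 5L, seed = 1L,
                                   baseline = FALSE) {
  details <- vector("list", length(components))
  rows <- vector("list", length(components))
  for (i in seq_along(components)) {
    nodes <- components[[i]]
    if (!length(nodes)) {
      warning("component ", i, " is empty; skipped")
      next
    }
    sub <- induced_subnetwork(network, nodes)
    res <- cv_transform_evaluate(dataset, sub, model, k, seed)
    row <- cbind(component = i, n_variants = length(nodes),
                 res$metrics[res$metrics$summary == "pooled",
                             -1, drop = FALSE])
    if (baseline) {
      base <- baseline_evaluate(dataset, nodes, model, k, seed)
      row$baseline_accuracy <-
        base$metrics$accuracy[base$metrics$summary == "pooled"]
      details[[i]] <- list(transform = res, baseline = base)
    } else details[[i]] <- list(transform = res)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' 80/20 holdout protocol with training-only network construction
#'
#' Splits the data (stratified) into a working set and a held-out
#' validation set. Pair scores, the network at `tau` and the component
#' selection are computed on the working set only; k-fold CV (with
#' fold-wise transform fitting) runs inside the working set; finally the
#' transform statistics and the model are refitted on the whole working
#' set and evaluated once on the untouched validation subjects. Reporting
#' all three surfaces (training resubstitution, CV test, validation)
#' exposes overfitting.
#'
#' @param dataset A [geno_dataset].
#' @param holdout_fraction Fraction held out for validation (default 0.2).
#' @param tau Information-gain threshold for the network.
#' @param min_component_size Strict component-size cutoff for feature
#'   selection (set 0 to keep the whole network).
#' @param model A [model_spec()].
#' @inheritParams cv_transform_evaluate
#' @return A list with `train_metrics` (resubstitution on the working
#'   set), `test_metrics` (pooled CV), `validation_metrics`, the fitted
#'   `network`, selected `components`, and the subject-id split
#'   (`working_subjects`, `validation_subjects`).
#' @export
holdout_protocol <- function(dataset, holdout_fraction = 0.2, tau,
                             min_component_size = 0L, model = model_spec(),
                             k = 5L, seed = 1L,
                             zero_evidence = c("absent", "positive")) {
  zero_evidence <- match.arg(zero_evidence)
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  y <- dataset$phenotype
  rng <- local_rng(seed)
  val_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_val <- floor(holdout_fraction * length(idx))
    if (n_val < 1L || n_val >= length(idx))
      stop("degenerate holdout split for class ", cls)
    val_idx <- c(val_idx, idx[rng$sample(length(idx), n_val)])
  }
  val_idx <- sort(val_idx)
  work_idx <- setdiff(seq_along(y), val_idx)
  working <- subset_dataset(dataset, subjects = work_idx)
  validation <- subset_dataset(dataset, subjects = val_idx)

  scores <- all_pairs_information_gain(working)
  network <- build_network(scores, tau)
  if (!length(network$nodes))
    stop("no edges above tau = ", tau, " on the working set")
  sel <- select_components(network, min_component_size)
  nodes <- unlist(sel$components)
  if (!length(nodes)) stop("no component exceeds min_component_size")
  network_sel <- induced_subnetwork(network, nodes)

  cv <- cv_transform_evaluate(working, network_sel, model, k, seed + 1L,
                              zero_evidence)
  stats <- fit_pair_statistics(working, network_sel)
  x_work <- delta_degree_transform(working, network_sel, stats,
                                   zero_evidence)
  x_val <- delta_degree_transform(validation, network_sel, stats,
                                  zero_evidence)
  fit <- local_rng(seed + 2L)$with_state(
    function() fit_model(model, x_work, working$phenotype))
  train_metrics <- confusion_metrics(working$phenotype,
                                     predict_model(fit, x_work))
  validation_metrics <- confusion_metrics(validation$phenotype,
                                          predict_model(fit, x_val))
  list(train_metrics = train_metrics,
       test_metrics = cv$metrics[cv$metrics$summary == "pooled", -1],
       validation_metrics = validation_metrics,
       network = network_sel, components = sel$components,
       scores = scores,
       working_subjects = rownames(working$genotypes),
       validation_subjects = rownames(validation$genotypes))
}

#' Resampling-based feature importance
#'
#' Repeatedly draws a stratified subsample of subjects without
#' replacement, refits the per-edge class proportions and the
#' delta-degree transform on the draw, fits an L2 logistic regression,
#' and records the coefficient of every network variant. Importance is
#' summarised as the signed mean and the mean absolute coefficient over
#' replicates.
#'
#' @param dataset A [geno_dataset].
#' @param network An `epi_network`.
#' @param replicates Number of resampling replicates (default 100).
#' @param fraction Subsample fraction drawn without replacement
#'   (default 0.8).
#' @param model A [model_spec()] of kind `logistic_regression`.
#' @param seed Integer seed.
#' @param zero_evidence See [edge_sign()].
#' @return data.frame with `variant_id`, `mean_coefficient`,
#'   `mean_abs_coefficient`, `n_replicates`, sorted by decreasing
#'   `mean_abs_coefficient`; attribute `"coefficients"` holds the
#'   replicates x variants coefficient matrix.
#' @export
resampling_importance <- function(dataset, network, replicates = 100L,
                                  fraction = 0.8, model = model_spec(),
                                  seed = 1L,
                                  zero_evidence = c("absent", "positive")) {
  zero_evidence <- match.arg(zero_evidence)
  stopifnot(model$kind == "logistic_regression",
            fraction > 0, fraction < 1, replicates >= 1)
  replicates <- as.integer(replicates)
  y <- dataset$phenotype
  rng <- local_rng(seed)
  coefs <- matrix(NA_real_, replicates, length(network$nodes),
                  dimnames = list(NULL, network$nodes))
  for (r in seq_len(replicates)) {
    draw <- integer(0)
    for (cls in c(0L, 1L)) {     # stratified draw: no single-class replicate
      idx <- which(y == cls)
      n_draw <- max(1L, floor(fraction * length(idx)))
      draw <- c(draw, idx[rng$sample(length(idx), n_draw)])
    }
    draw <- sort(draw)
    sub <- subset_dataset(dataset, subjects = draw)
    stats <- fit_pair_statistics(sub, network)
    x <- delta_degree_transform(sub, network, stats, zero_evidence)
    fit <- rng$with_state(function() fit_model(model, x, sub$phenotype))
    co <- model_coefficients(fit)
    coefs[r, names(co)] <- co
  }
  out <- data.frame(variant_id = colnames(coefs),
                    mean_coefficient = colMeans(coefs),
                    mean_abs_coefficient = colMeans(abs(coefs)),
                    n_replicates = replicates,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_coefficient), ]
  rownames(out) <- NULL
  attr(out, "coefficients") <- coefs
  out
}
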