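#' Cascade SVM configuration
#'
#' Divide-and-conquer SVM training: the data are split into `n_subsets`
#' random stratified subsets, one SVM is fit per subset and only its support
#' vectors survive; adjacent support-vector sets are merged pairwise up a
#' binary tree until a single SVM remains, whose support set is fed back
#' into every level-0 subset; the whole pass repeats until the global
#' support-index set stabilizes or `max_global_passes` is reached.
#'
#' @param n_subsets Number of level-0 subsets; must be a power of two
#'   (default 8).
#' @param max_global_passes Cap on feedback passes (default 5).
#' @param C Soft-margin regularization constant (> 0).
#' @param kernel Kernel reference: a `wd_kernel_params` (string instances) or
#'   `rbf_kernel_params` (numeric instances).
#' @param seed Integer seed controlling the level-0 split.
#' @param tol Per-node solver tolerance (default 1e-3; recorded in the model).
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(n_subsets = 8L, max_global_passes = 5L, C = 1,
                           kernel = wd_kernel_params(), seed = 1L, tol = 1e-3) {
  n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1L || bitwAnd(n_subsets, n_subsets - 1L) != 0L) {
    stop("n_subsets must be a power of two", call. = FALSE)
  }
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (max_global_passes < 1L) stop("max_global_passes must be at least 1", call. = FALSE)
  structure(list(n_subsets = n_subsets,
                 max_global_passes = as.integer(max_global_passes),
                 C = C, kernel = kernel, seed = as.integer(seed), tol = tol),
            class = "cascade_config")
}

kernel_type <- function(kernel) {
  if (inherits(kernel, "wd_kernel_params")) "wd"
  else if (inherits(kernel, "rbf_kernel_params")) "rbf"
  else stop("kernel must be wd_kernel_params or rbf_kernel_params", call. = FALSE)
}

# Full training gram for either kernel family. WD expects a character vector
# of equal-length sequences; RBF a numeric matrix (rows = instances).
training_gram <- function(instances, kernel) {
  switch(kernel_type(kernel),
         wd = wd_gram(instances, params = kernel),
         rbf = rbf_gram(as.matrix(instances), params = kernel))
}

cross_gram <- function(new_instances, train_instances, kernel) {
  switch(kernel_type(kernel),
         wd = wd_gram(new_instances, train_instances, params = kernel),
         rbf = rbf_gram(as.matrix(new_instances), as.matrix(train_instances),
                        params = kernel))
}

n_instances_of <- function(instances) {
  if (is.character(instances)) length(instances) else nrow(instances)
}

# Fit one soft-margin SVM node on a precomputed kernel block. Labels are
# passed as factor(levels = c("negative","positive")) so kernlab's decision
# value is positive for the positive class; the decision function is
# K[, sv] %*% alpha - b (verified exactly against predict(type="decision")).
fit_svm_node <- function(K_block, y01, C, tol) {
  y <- factor(ifelse(y01 == 1L, "positive", "negative"),
              levels = c("negative", "positive"))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K_block), y, type = "C-svc",
                       C = C, tol = tol)
  list(sv_local = kernlab::SVindex(fit),
       alpha = as.numeric(unlist(kernlab::coef(fit))),
       b = kernlab::b(fit))
}

# Stratified split of indices into n_subsets random parts; every part gets
# members of both classes whenever the class has at least n_subsets members.
stratified_subsets <- function(y01, n_subsets) {
  parts <- rep(list(integer(0)), n_subsets)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y01 == cls))
    grp <- rep(seq_len(n_subsets), length.out = length(idx))
    for (g in seq_len(n_subsets)) parts[[g]] <- c(parts[[g]], idx[grp == g])
  }
  lapply(parts, sort)
}

#' Train a cascade SVM
#'
#' @param train_instances Character vector of equal-length sequences (WD
#'   kernel) or numeric matrix (RBF kernel).
#' @param labels Binary labels (1/"positive" = positive class); both classes
#'   must be present.
#' @param config A [cascade_config()].
#' @return An object of class `cascade_model`: `support_indices` (into the
#'   training set), `dual_coefficients` (signed, `|alpha| <= C`), `bias`,
#'   `kernel`, `config`, `n_passes`, `converged`, and `history` (candidate
#'   and support counts per level and pass). Training instances are retained
#'   for scoring.
#' @export
train_cascade <- function(train_instances, labels, config) {
  stopifnot(inherits(config, "cascade_config"))
  y01 <- as_binary_labels(labels)
  n <- n_instances_of(train_instances)
  if (length(y01) != n) stop("labels and instances differ in length", call. = FALSE)
  if (length(unique(y01)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  if (config$n_subsets > n) stop("n_subsets exceeds the number of instances", call. = FALSE)
  set.seed(config$seed)
  K <- training_gram(train_instances, config$kernel)
  level0 <- stratified_subsets(y01, config$n_subsets)

  history <- list()
  global_sv <- integer(0)
  final_fit <- NULL
  final_set <- NULL
  n_passes <- 0L
  converged <- FALSE
  for (pass in seq_len(config$max_global_passes)) {
    n_passes <- pass
    sets <- lapply(level0, function(s) sort(union(s, global_sv)))
    level <- 0L
    repeat {
      fitted <- lapply(sets, function(idx) {
        node <- fit_svm_node(K[idx, idx, drop = FALSE], y01[idx], config$C, config$tol)
        list(idx = idx, sv = idx[node$sv_local], fit = node)
      })
      history[[length(history) + 1L]] <- data.frame(
        pass = pass, level = level,
        n_sets = length(fitted),
        n_candidates = sum(lengths(lapply(fitted, `[[`, "idx"))),
        n_support = sum(lengths(lapply(fitted, `[[`, "sv")))
      )
      if (length(fitted) == 1L) {
        final_fit <- fitted[[1L]]$fit
        final_set <- fitted[[1L]]$idx
        new_global <- sort(fitted[[1L]]$sv)
        break
      }
      pairs <- split(seq_along(fitted), ceiling(seq_along(fitted) / 2))
      sets <- lapply(pairs, function(p) sort(unique(unlist(lapply(fitted[p], `[[`, "sv")))))
      level <- level + 1L
    }
    if (identical(new_global, global_sv)) {
      converged <- TRUE
      global_sv <- new_global
      break
    }
    global_sv <- new_global
  }

  structure(list(
    support_indices = final_set[final_fit$sv_local],
    dual_coefficients = final_fit$alpha,
    bias = final_fit$b,
    kernel = config$kernel,
    config = config,
    support_instances = if (is.character(train_instances)) {
      train_instances[final_set[final_fit$sv_local]]
    } else {
      as.matrix(train_instances)[final_set[final_fit$sv_local], , drop = FALSE]
    },
    n_training = n,
    n_passes = n_passes,
    converged = converged,
    history = do.call(rbind, history),
    calibration = NULL
  ), class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("cascade_model: %s kernel, %d support vectors of %d training instances, %d pass(es)%s\n",
              kernel_type(x$kernel), length(x$support_indices), x$n_training,
              x$n_passes, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' SVM decision scores
#'
#' `f(x) = sum_s alpha_s K(x_s, x) + b`; the predicted label is the sign at
#' zero (positive score = positive class).
#'
#' @param model A `cascade_model`.
#' @param instances New instances, same representation as the training set.
#' @return Numeric vector of decision values (empty input gives an empty
#'   vector).
#' @export
decision_function <- function(model, instances) {
  stopifnot(inherits(model, "cascade_model"))
  if (n_instances_of(instances) == 0L) return(numeric(0))
  Kx <- cross_gram(instances, model$support_instances, model$kernel)
  as.numeric(Kx %*% model$dual_coefficients - model$bias)
}

#' Fit a sigmoid probability calibration on held-out data
#'
#' Maps decision scores to probabilities with a logistic regression
#' (Platt-style) fit on a validation set, enabling binary cross-entropy for
#' SVM models. Probabilities are clipped to `[1e-15, 1 - 1e-15]` downstream.
#'
#' @param model A `cascade_model`.
#' @param instances Validation instances.
#' @param labels Validation labels.
#' @return The model with a `calibration` component (intercept and slope).
#' @export
calibrate_cascade <- function(model, instances, labels) {
  y <- as_binary_labels(labels)
  f <- decision_function(model, instances)
  fit <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
  model$calibration <- stats::coef(fit)
  model
}

#' Predicted probabilities from a cascade SVM
#'
#' Uses the sigmoid calibration when present, otherwise a plain logistic
#' squashing of the decision value (monotone in the score either way, so
#' AUC is unaffected by the choice).
#'
#' @param model A `cascade_model`.
#' @param instances New instances.
#' @return Probabilities of the positive class.
#' @export
predict_cascade_proba <- function(model, instances) {
  f <- decision_function(model, instances)
  if (length(f) == 0L) return(numeric(0))
  if (!is.null(model$calibration)) {
    eta <- model$calibration[1L] + model$calibration[2L] * f
  } else {
    eta <- f
  }
  stats::plogis(eta)
}

#' Grid search over SVM hyper-parameters
#'
#' Trains one cascade per grid cell on the training set and evaluates it on
#' the validation set; the cell with the highest validation AUC-ROC wins
#' (ties broken by smaller C, then smaller d or gamma).
#'
#' @param train_instances,train_labels Training data.
#' @param val_instances,val_labels Validation data.
#' @param grid Data frame of cells; columns `C` and either `d` (WD kernel)
#'   or `gamma` (RBF kernel).
#' @param kernel_type `"wd"` or `"rbf"`.
#' @param n_subsets,seed Passed to [cascade_config()].
#' @return A list with `best` (the winning row), `report` (per-cell data
#'   frame with validation AUC) and `best_model`.
#' @export
grid_search <- function(train_instances, train_labels, val_instances, val_labels,
                        grid, kernel_type = c("wd", "rbf"), n_subsets = 1L,
                        seed = 1L) {
  kernel_type <- match.arg(kernel_type)
  if (is.null(grid) || nrow(grid) == 0L) stop("parameter grid is empty", call. = FALSE)
  hyper <- if (kernel_type == "wd") "d" else "gamma"
  if (!all(c("C", hyper) %in% names(grid))) {
    stop(sprintf("grid must have columns 'C' and '%s'", hyper), call. = FALSE)
  }
  report <- grid
  report$val_auc <- NA_real_
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    kern <- if (kernel_type == "wd") wd_kernel_params(grid$d[i]) else rbf_kernel_params(grid$gamma[i])
    cfg <- cascade_config(n_subsets = n_subsets, C = grid$C[i], kernel = kern,
                          seed = seed)
    models[[i]] <- train_cascade(train_instances, train_labels, cfg)
    scores <- decision_function(models[[i]], val_instances)
    report$val_auc[i] <- auc_roc(val_labels, scores)
  }
  ord <- order(-report$val_auc, report$C, report[[hyper]])
  best_i <- ord[1L]
  list(best = report[best_i, , drop = FALSE], report = report,
       best_model = models[[best_i]])
}

#' Serialize a cascade model header to JSON
#'
#' Writes config, support indices, coefficients and bias (plus the training
#' set hash for WD models) so a model can be audited or reloaded against the
#' same dataset.
#'
#' @param model A `cascade_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_model <- function(model, path) {
  hdr <- list(
    kernel = kernel_type(model$kernel),
    kernel_params = unclass(model$kernel)[setdiff(names(unclass(model$kernel)), "beta")],
    C = model$config$C, n_subsets = model$config$n_subsets,
    tol = model$config$tol, seed = model$config$seed,
    n_training = model$n_training,
    support_indices = model$support_indices,
    dual_coefficients = model$dual_coefficients,
    bias = model$bias,
    converged = model$converged, n_passes = model$n_passes,
    training_hash = if (is.character(model$support_instances))
      sequence_list_hash(model$support_instances) else NULL
  )
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
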