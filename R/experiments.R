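#' Define a classifier for the experiment harnesses
#'
#' A classifier is a named pair of closures: `fit(train, validation, seed)`
#' returning an opaque model, and `predict(model, dataset)` returning
#' probabilities of the positive class. The harnesses are agnostic to what
#' is inside.
#'
#' @param name Display name used in reports.
#' @param fit Function `(train_dataset, validation_dataset, seed) -> model`.
#' @param predict Function `(model, dataset) -> probabilities`.
#' @return A list of class `tss_classifier`.
#' @export
classifier_spec <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "tss_classifier")
}

#' Cascade-SVM classifier for the harnesses
#'
#' Wraps [train_cascade()] (with sigmoid calibration on the validation
#' split) as a [classifier_spec()]. The WD kernel consumes raw sequences;
#' the RBF kernel one-hot encodes them.
#'
#' @param kernel `"wd"` or `"rbf"`.
#' @param C Regularization constant.
#' @param d WD kernel degree.
#' @param gamma RBF bandwidth.
#' @param n_subsets Level-0 subsets of the cascade.
#' @return A `tss_classifier`.
#' @export
svm_classifier <- function(kernel = c("wd", "rbf"), C = 1, d = 10L,
                           gamma = 0.01, n_subsets = 4L) {
  kernel <- match.arg(kernel)
  kern <- if (kernel == "wd") wd_kernel_params(d) else rbf_kernel_params(gamma)
  rep_fn <- if (kernel == "wd") {
    function(ds) ds$instances$sequence
  } else {
    function(ds) one_hot_matrix(ds$instances$sequence)
  }
  classifier_spec(
    name = paste0("cascade_svm_", kernel),
    fit = function(train, validation, seed) {
      cfg <- cascade_config(n_subsets = n_subsets, C = C, kernel = kern,
                            seed = seed)
      m <- train_cascade(rep_fn(train), dataset_labels(train), cfg)
      if (nrow(validation$instances) > 0L) {
        m <- calibrate_cascade(m, rep_fn(validation), dataset_labels(validation))
      }
      m
    },
    predict = function(model, dataset) {
      predict_cascade_proba(model, rep_fn(dataset))
    }
  )
}

#' Neural-network classifier for the harnesses
#'
#' @param arch Architecture name (see [build_architecture()]).
#' @param input_length Window length.
#' @param max_epochs,patience,batch_size,learning_rate Training protocol
#'   overrides (defaults follow [training_config()]).
#' @return A `tss_classifier`.
#' @export
nn_classifier <- function(arch = "lstm", input_length = 1003L,
                          max_epochs = 100L, patience = 10L,
                          batch_size = 32L, learning_rate = 0.001) {
  classifier_spec(
    name = arch,
    fit = function(train, validation, seed) {
      model <- build_architecture(arch, input_length = input_length)
      cfg <- training_config(batch_size = batch_size,
                             learning_rate = learning_rate,
                             max_epochs = max_epochs, patience = patience,
                             seed = seed)
      split <- structure(list(train = train, validation = validation),
                         class = "tss_split")
      train_network(model, split, cfg)$model
    },
    predict = function(model, dataset) predict_proba(model, dataset)
  )
}

eval_row <- function(classifier, cell, repeat_i, seed, partition, report) {
  data.frame(classifier = classifier, cell = cell, rep = repeat_i, seed = seed,
             partition = partition,
             accuracy = report$accuracy, bc = report$binary_cross_entropy,
             f1 = report$f1, auc_roc = report$auc_roc,
             sensitivity = report$sensitivity, specificity = report$specificity,
             n = report$n_instances, n_positive = report$n_positive,
             stringsAsFactors = FALSE)
}

new_experiment_report <- function(rows, kind) {
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  structure(list(rows = rows, kind = kind), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report (%s): %d rows\n", x$kind, nrow(x$rows)))
  print(aggregate_report(x))
  invisible(x)
}

#' Aggregate an experiment report over repeats
#'
#' Mean (and standard deviation of AUC) per classifier, cell and partition;
#' recomputable from the per-repeat rows.
#'
#' @param report An `experiment_report`.
#' @return Data frame of aggregates.
#' @export
aggregate_report <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  rows <- report$rows
  agg <- stats::aggregate(rows[, c("accuracy", "bc", "f1", "auc_roc")],
                          by = rows[, c("classifier", "cell", "partition")],
                          FUN = mean)
  sd_auc <- stats::aggregate(list(auc_sd = rows$auc_roc),
                             by = rows[, c("classifier", "cell", "partition")],
                             FUN = stats::sd)
  merge(agg, sd_auc, by = c("classifier", "cell", "partition"))
}

run_one_cell <- function(classifier, train_ds, validation_ds, test_ds,
                         cell, repeat_i, seed) {
  model <- classifier$fit(train_ds, validation_ds, seed)
  p_train <- classifier$predict(model, train_ds)
  p_test <- classifier$predict(model, test_ds)
  list(
    eval_row(classifier$name, cell, repeat_i, seed, "train",
             evaluate(dataset_labels(train_ds), p_train)),
    eval_row(classifier$name, cell, repeat_i, seed, "test",
             evaluate(dataset_labels(test_ds), p_test))
  )
}

#' Class-ratio experiment
#'
#' Two training arms from a split built at 1:10 — arm `1:10` trains on the
#' train partition as is; arm `1:1` trains on
#' `undersample_majority(train, 1.0)` — and both are evaluated on the
#' untouched 1:10 test partition (the ratio found in real data is kept at
#' test time). Repeated `n_repeats` times with seeds `base_seed + 0, 1, ...`.
#'
#' @param split A `tss_split` whose train partition is at 1:10.
#' @param classifiers List of `tss_classifier`s.
#' @param n_repeats Number of seeded repetitions (default 5).
#' @param base_seed First seed.
#' @return An `experiment_report`; one train and one test row per
#'   (classifier, arm, repeat).
#' @export
run_ratio_experiment <- function(split, classifiers, n_repeats = 5L,
                                 base_seed = 1L) {
  stopifnot(inherits(split, "tss_split"))
  if (nrow(split$train$instances) == 0L || nrow(split$test$instances) == 0L) {
    stop("split must have non-empty train and test partitions", call. = FALSE)
  }
  rows <- list()
  for (clf in classifiers) {
    for (i in seq_len(n_repeats)) {
      seed <- base_seed + i - 1L
      arms <- list(
        "1:10" = split$train,
        "1:1" = undersample_majority(split$train, 1.0, seed = seed)
      )
      for (arm in names(arms)) {
        rows <- c(rows, run_one_cell(clf, arms[[arm]], split$validation,
                                     split$test, arm, i, seed))
      }
    }
  }
  new_experiment_report(rows, "ratio")
}

#' Stratified training fraction (nested across fractions)
#'
#' Draws a class-stratified subset of size `floor(f * n)` per class. The
#' per-class permutation depends only on the seed, so for a fixed seed the
#' 10% subset is contained in the 50% subset, which is contained in the
#' full set.
#'
#' @param dataset A `tss_dataset`.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return A `tss_dataset`.
#' @export
stratified_fraction <- function(dataset, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]", call. = FALSE)
  if (fraction == 1) return(dataset)
  set.seed(seed)
  keep <- integer(0)
  for (cls in c("positive", "negative")) {
    idx <- which(dataset$instances$label == cls)
    if (length(idx) == 0L) next
    perm <- sample(idx)
    n_keep <- floor(fraction * length(idx))
    if (n_keep < 1L) {
      stop(sprintf("fraction %.3f leaves no '%s' instances", fraction, cls),
           call. = FALSE)
    }
    keep <- c(keep, perm[seq_len(n_keep)])
  }
  inst <- dataset$instances[sort(keep), , drop = FALSE]
  rownames(inst) <- NULL
  prov <- dataset$provenance
  prov$fraction <- fraction
  prov$fraction_seed <- seed
  new_tss_dataset(inst, dataset$params, prov)
}

#' Training-fraction experiment
#'
#' For each fraction f, trains on a stratified subset of the train partition
#' of size floor(f * n) per class; validation and test partitions are left
#' untouched. Seeded per repeat.
#'
#' @param split A `tss_split`.
#' @param classifiers List of `tss_classifier`s.
#' @param fractions Numeric vector in (0, 1], e.g. `c(0.1, 0.5, 1)`.
#' @param n_repeats,base_seed As in [run_ratio_experiment()].
#' @return An `experiment_report` with cells named by fraction.
#' @export
run_fraction_experiment <- function(split, classifiers, fractions = c(0.1, 0.5, 1),
                                    n_repeats = 5L, base_seed = 1L) {
  stopifnot(inherits(split, "tss_split"))
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  rows <- list()
  for (clf in classifiers) {
    for (i in seq_len(n_repeats)) {
      seed <- base_seed + i - 1L
      for (f in fractions) {
        sub <- stratified_fraction(split$train, f, seed = seed)
        if (length(unique(sub$instances$label)) < 2L) {
          stop(sprintf("fraction %.3f leaves a single class", f), call. = FALSE)
        }
        rows <- c(rows, run_one_cell(clf, sub, split$validation, split$test,
                                     sprintf("%d%%", round(100 * f)), i, seed))
      }
    }
  }
  new_experiment_report(rows, "fraction")
}

#' Cross-species evaluation without retraining
#'
#' Scores a model trained on one species' split against the full labeled
#' dataset of another species; window lengths must match.
#'
#' @param classifier The `tss_classifier` the model came from.
#' @param model A model returned by `classifier$fit`.
#' @param dataset_b A `tss_dataset` from the other species.
#' @param reference_params Optional [window_params()] of the training data;
#'   when given, a window-length mismatch is an error.
#' @return An `eval_report` over all of `dataset_b`.
#' @export
run_cross_species <- function(classifier, model, dataset_b,
                              reference_params = NULL) {
  stopifnot(inherits(classifier, "tss_classifier"),
            inherits(dataset_b, "tss_dataset"))
  if (!is.null(reference_params) &&
      reference_params$window_length != dataset_b$params$window_length) {
    stop(sprintf("window length mismatch: model expects %d, dataset has %d",
                 reference_params$window_length,
                 dataset_b$params$window_length), call. = FALSE)
  }
  p <- classifier$predict(model, dataset_b)
  evaluate(dataset_labels(dataset_b), p)
}

#' Run a task under several seeds
#'
#' Executes `task(seed)` for seeds `base_seed + 0 .. n_repeats - 1` — the
#' repeated-seed protocol standing in for cross-validation when partitions
#' are fixed by chromosome (networks re-initialize; cascades re-randomize
#' their level-0 split).
#'
#' @param task Function of one argument (the seed).
#' @param n_repeats Number of repetitions (default 5).
#' @param base_seed First seed.
#' @return List of class `seed_repeats`: `results` (in seed order) and
#'   `seeds`.
#' @export
repeat_with_seeds <- function(task, n_repeats = 5L, base_seed = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be at least 1", call. = FALSE)
  seeds <- base_seed + seq_len(n_repeats) - 1L
  structure(list(results = lapply(seeds, task), seeds = seeds),
            class = "seed_repeats")
}

#' Mean and standard deviation over seeded repeats
#'
#' @param repeats A `seed_repeats` object whose results are numeric scalars,
#'   or from which `extract` pulls one.
#' @param extract Optional function applied to each result first.
#' @return List with `values`, `mean`, `sd`.
#' @export
summarize_repeats <- function(repeats, extract = identity) {
  stopifnot(inherits(repeats, "seed_repeats"))
  vals <- vapply(repeats$results, function(r) as.numeric(extract(r)), numeric(1))
  list(values = vals, mean = mean(vals), sd = stats::sd(vals))
}
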