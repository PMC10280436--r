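# Separable two-cluster toy problem in the plane (one-hot-like scale).
toy_separable <- function(n = 200, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, 2, 0.5), n / 2, 2),
             matrix(rnorm(n, -2, 0.5), n / 2, 2))
  list(X = X, y = rep(c(1L, 0L), each = n / 2))
}

# Independent full-SVM oracle: kernlab on the complete precomputed gram.
full_svm_scores <- function(X, y, kernel, C, grid) {
  K <- rbf_gram(X, params = kernel)
  yf <- factor(ifelse(y == 1, "positive", "negative"),
               levels = c("negative", "positive"))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc", C = C)
  Kg <- rbf_gram(grid, X, params = kernel)
  as.numeric(Kg[, kernlab::SVindex(fit), drop = FALSE] %*%
               unlist(kernlab::coef(fit)) - kernlab::b(fit))
}

test_that("cascade configuration enforces its invariants", {
  expect_error(cascade_config(n_subsets = 3), "power of two")
  expect_error(cascade_config(C = 0), "positive")
  expect_silent(cascade_config(n_subsets = 1))
  expect_silent(cascade_config(n_subsets = 16))
})

test_that("cascade predictions match a single full SVM on separable data", {
  toy <- toy_separable()
  kern <- rbf_kernel_params(0.5)
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))

  casc <- train_cascade(toy$X, toy$y,
                        cascade_config(n_subsets = 4, C = 1, kernel = kern,
                                       seed = 9))
  sc_cascade <- decision_function(casc, grid)
  sc_full <- full_svm_scores(toy$X, toy$y, kern, C = 1, grid)
  expect_identical(sign(sc_cascade), sign(sc_full))

  # the cascade converged within the pass budget
  expect_true(casc$converged)
  expect_lte(casc$n_passes, 5)
})

test_that("degenerate single-subset cascade equals one SVM fit", {
  toy <- toy_separable(n = 80, seed = 2)
  kern <- rbf_kernel_params(0.5)
  casc <- train_cascade(toy$X, toy$y,
                        cascade_config(n_subsets = 1, C = 1, kernel = kern,
                                       seed = 4))
  grid <- as.matrix(expand.grid(seq(-3, 3, 1), seq(-3, 3, 1)))
  sc <- decision_function(casc, grid)
  sc_full <- full_svm_scores(toy$X, toy$y, kern, C = 1, grid)
  expect_equal(sc, sc_full, tolerance = 1e-8)
})

test_that("support vectors come from the training set with bounded coefficients", {
  toy <- toy_separable()
  casc <- train_cascade(toy$X, toy$y,
                        cascade_config(n_subsets = 4, C = 2,
                                       kernel = rbf_kernel_params(0.5), seed = 9))
  expect_true(all(casc$support_indices %in% seq_len(200)))
  expect_length(casc$dual_coefficients, length(casc$support_indices))
  expect_true(all(abs(casc$dual_coefficients) <= 2 + 1e-9))

  # scoring the support vectors of a separable model recovers their labels
  sv_scores <- decision_function(casc, toy$X[casc$support_indices, , drop = FALSE])
  expect_identical(sign(sv_scores) > 0, toy$y[casc$support_indices] == 1)

  # empty instance list -> empty scores
  expect_length(decision_function(casc, toy$X[0, , drop = FALSE]), 0)
})

test_that("support-set size never grows from level to level within a pass", {
  toy <- toy_separable()
  casc <- train_cascade(toy$X, toy$y,
                        cascade_config(n_subsets = 8, C = 1,
                                       kernel = rbf_kernel_params(0.5), seed = 1))
  h <- casc$history
  for (p in unique(h$pass)) {
    hp <- h[h$pass == p, ]
    expect_true(all(hp$n_support <= hp$n_candidates))
    # candidates at the next level are the supports of the previous one
    if (nrow(hp) > 1) {
      expect_true(all(diff(hp$n_candidates) <= 0))
    }
  }
})

test_that("cascade training is deterministic given the seed", {
  toy <- toy_separable(n = 120, seed = 3)
  cfg <- cascade_config(n_subsets = 4, C = 1, kernel = rbf_kernel_params(0.5),
                        seed = 77)
  m1 <- train_cascade(toy$X, toy$y, cfg)
  m2 <- train_cascade(toy$X, toy$y, cfg)
  expect_identical(m1$support_indices, m2$support_indices)
  expect_equal(m1$dual_coefficients, m2$dual_coefficients)
  expect_equal(m1$bias, m2$bias)
})

test_that("single-class input and oversized subset counts are rejected", {
  toy <- toy_separable(n = 40, seed = 5)
  cfg <- cascade_config(n_subsets = 4, C = 1, kernel = rbf_kernel_params(0.5))
  expect_error(train_cascade(toy$X, rep(1, 40), cfg), "single class")
  expect_error(train_cascade(toy$X[1:3, ], toy$y[c(1, 2, 21)],
                             cascade_config(n_subsets = 4, C = 1,
                                            kernel = rbf_kernel_params(0.5))),
               "exceeds")
})

test_that("the cascade trains on string instances with the WD kernel", {
  ds <- small_dataset()
  seqs <- ds$instances$sequence
  y <- dataset_labels(ds)
  cfg <- cascade_config(n_subsets = 2, C = 1, kernel = wd_kernel_params(5),
                        seed = 10)
  m <- train_cascade(seqs, y, cfg)
  sc <- decision_function(m, seqs)
  expect_gt(auc_roc(y, sc), 0.95)  # planted positional motif is easy for WD

  # calibrated probabilities preserve the ranking
  m <- calibrate_cascade(m, seqs, y)
  pr <- predict_cascade_proba(m, seqs)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(auc_roc(y, pr), auc_roc(y, sc))

  # kernel incompatibility: sequence length mismatch
  expect_error(decision_function(m, c("ACGT")), "equal length")
})

test_that("grid search selects the best validation-AUC cell with full reporting", {
  ds <- small_dataset()
  sp <- split_by_chromosome(ds, validation_chromosomes = "2",
                            test_chromosomes = character(0))
  tr <- sp$train; va <- sp$validation
  grid <- expand.grid(C = c(0.1, 1, 10), d = c(3))
  gs <- grid_search(tr$instances$sequence, dataset_labels(tr),
                    va$instances$sequence, dataset_labels(va),
                    grid, kernel_type = "wd", n_subsets = 1, seed = 2)
  expect_equal(nrow(gs$report), nrow(grid))
  expect_true(all(gs$best$val_auc >= gs$report$val_auc))

  # one-cell grid selects that cell
  gs1 <- grid_search(tr$instances$sequence, dataset_labels(tr),
                     va$instances$sequence, dataset_labels(va),
                     data.frame(C = 1, d = 2), kernel_type = "wd",
                     n_subsets = 1, seed = 2)
  expect_equal(gs1$best$C, 1)
  expect_error(grid_search(tr$instances$sequence, dataset_labels(tr),
                           va$instances$sequence, dataset_labels(va),
                           data.frame(), kernel_type = "wd"), "empty")
})

test_that("model headers serialize with config, coefficients and data hash", {
  ds <- small_dataset()
  m <- train_cascade(ds$instances$sequence[1:44], dataset_labels(ds)[1:44],
                     cascade_config(n_subsets = 1, C = 1,
                                    kernel = wd_kernel_params(3), seed = 1))
  path <- tempfile(fileext = ".json")
  write_cascade_model(m, path)
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(hdr$kernel, "wd")
  expect_equal(hdr$kernel_params$d, 3)
  expect_equal(hdr$support_indices, m$support_indices)
  expect_equal(hdr$bias, m$bias)
  expect_equal(hdr$tol, 1e-3)
})
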