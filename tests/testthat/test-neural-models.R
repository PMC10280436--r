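test_that("architecture layer lists match their definitions exactly", {
  spec <- architecture_spec(build_architecture("cnn", 1003))
  conv <- spec[spec$kind == "conv1d", ]
  expect_equal(nrow(conv), 3)
  expect_true(all(conv$filters == 32 & conv$width == 5))
  pools <- spec[spec$kind == "maxpool", ]
  expect_equal(nrow(pools), 3)
  expect_true(all(pools$pool == 4))
  dense <- spec[spec$kind == "dense", ]
  expect_equal(dense$units, c(1024, 512, 128, 1))
  expect_equal(dense$activation, c("relu", "relu", "relu", "sigmoid"))
  drops <- spec[spec$kind == "dropout", ]
  expect_equal(drops$rate, rep(0.2, 3))
  # convolutions precede the dense stack
  expect_lt(max(which(spec$kind == "conv1d")), min(which(spec$kind == "dense")))

  spec_l <- architecture_spec(build_architecture("lstm", 1003))
  expect_equal(spec_l$kind, c("lstm", "dense", "dropout", "dense"))
  expect_equal(spec_l$units[1], 128)
  expect_false(spec_l$bidirectional[1])
  expect_equal(spec_l$units[2], 64)
  expect_equal(spec_l$rate[3], 0.5)

  spec_b <- architecture_spec(build_architecture("blstm", 1003))
  expect_true(spec_b$bidirectional[1])
  expect_equal(spec_b$units[1], 128)  # per direction

  spec_cl <- architecture_spec(build_architecture("cnn_lstm", 1003))
  expect_equal(spec_cl$kind,
               c("conv1d", "maxpool", "dropout", "lstm", "dropout", "dense"))
  expect_equal(spec_cl$filters[1], 64)
  expect_equal(spec_cl$width[1], 3)
  expect_equal(spec_cl$pool[2], 3)
  expect_equal(spec_cl$rate[c(3, 5)], c(0.25, 0.80))
  expect_equal(spec_cl$units[4], 64)

  spec_cb <- architecture_spec(build_architecture("cnn_blstm", 1003))
  expect_true(spec_cb$bidirectional[4])
  expect_equal(spec_cb$rate[c(3, 5)], c(0.25, 0.80))

  # every architecture ends in a single sigmoid unit
  for (nm in c("cnn", "lstm", "blstm", "cnn_lstm", "cnn_blstm")) {
    sp <- architecture_spec(build_architecture(nm, 1003))
    last <- sp[nrow(sp), ]
    expect_equal(last$kind, "dense")
    expect_equal(last$units, 1)
    expect_equal(last$activation, "sigmoid")
  }
  expect_error(build_architecture("transformer"), "unknown architecture")
})

test_that("forward passes produce probabilities of the right shape", {
  set.seed(1)
  X <- array(stats::rbinom(2 * 1003 * 4, 1, 0.25), c(2, 1003, 4))
  for (nm in c("cnn", "lstm", "blstm", "cnn_lstm", "cnn_blstm")) {
    model <- build_architecture(nm, 1003)
    p <- predict_proba(model, X)
    expect_length(p, 2)
    expect_true(all(p > 0 & p < 1))
  }
  # empty input -> empty output, order preserved otherwise
  model <- build_architecture("lstm", 10)
  expect_length(predict_proba(model, character(0)), 0)
  p2 <- predict_proba(model, c("ACGTACGTAC", "TTTTTTTTTT"))
  expect_length(p2, 2)
  expect_error(predict_proba(model, "ACGT"), "does not match")
})

test_that("analytic gradients agree with finite differences for every layer kind", {
  grad_check <- function(arch, T_, n_checks = 5, eps = 1e-5) {
    model <- build_architecture(arch, input_length = T_, seed = 5)
    set.seed(5)
    B <- 3
    X <- array(stats::runif(B * T_ * 4), c(B, T_, 4))
    y <- c(1, 0, 1)
    loss_of <- function(m) {
      p <- pmin(pmax(tsspredict:::nn_forward(m, X, train = FALSE)$p, 1e-12),
                1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    fwd <- tsspredict:::nn_forward(model, X, train = FALSE)
    dZ <- matrix((fwd$p - y) / length(y), ncol = 1)
    grads <- tsspredict:::nn_backward(model, fwd$caches, dZ)
    worst <- 0
    set.seed(99)
    for (li in seq_along(model$layers)) {
      g <- grads[[li]]
      if (is.null(g)) next
      for (nm in names(g)) {
        for (k in sample(length(g[[nm]]), min(n_checks, length(g[[nm]])))) {
          m2 <- model
          m2$layers[[li]]$params[[nm]][k] <- m2$layers[[li]]$params[[nm]][k] + eps
          m3 <- model
          m3$layers[[li]]$params[[nm]][k] <- m3$layers[[li]]$params[[nm]][k] - eps
          num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
          ana <- g[[nm]][k]
          worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
        }
      }
    }
    worst
  }
  expect_lt(grad_check("cnn", 180), 1e-4)
  expect_lt(grad_check("lstm", 12), 1e-4)
  expect_lt(grad_check("blstm", 12), 1e-4)
  expect_lt(grad_check("cnn_lstm", 20), 1e-4)
  expect_lt(grad_check("cnn_blstm", 20), 1e-4)
})

test_that("early stopping obeys the patience arithmetic on synthetic traces", {
  # improvements at epochs 1..3, plateau afterwards -> stop at 3 + 10
  trace <- c(0.9, 0.8, 0.7, rep(0.7, 20))
  r <- early_stop_trace(trace, patience = 10)
  expect_equal(r$stopped_epoch, 13)
  expect_equal(r$best_epoch, 3)

  # monotone improvement never stops early
  r2 <- early_stop_trace(seq(1, 0.1, length.out = 30), patience = 10)
  expect_equal(r2$stopped_epoch, 30)
  expect_equal(r2$best_epoch, 30)

  # late best epoch resets the counter
  r3 <- early_stop_trace(c(0.9, rep(0.85, 9), 0.5, rep(0.85, 10)), patience = 10)
  expect_equal(r3$stopped_epoch, 21)
  expect_equal(r3$best_epoch, 11)
})

test_that("training configs validate the protocol constraints", {
  cfg <- training_config()
  expect_equal(cfg$batch_size, 32)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$max_epochs, 100)
  expect_equal(cfg$patience, 10)
  expect_equal(cfg$loss, "binary_cross_entropy")
  expect_error(training_config(patience = 100, max_epochs = 100), "patience")
  expect_error(training_config(batch_size = 0), "positive")
})

test_that("training is seeded and reduces loss below the uninformative baseline", {
  # tiny balanced motif task: short windows keep the check fast
  set.seed(3)
  mk <- function(n, seed) {
    set.seed(seed)
    pos <- replicate(n, paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                              collapse = ""))
    for (i in seq_len(n)) substr(pos[i], 8, 17) <- "TATAAAGGCC"
    neg <- replicate(n, paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                              collapse = ""))
    list(x = one_hot_array(c(pos, neg)), y = rep(c(1L, 0L), each = n))
  }
  tr <- mk(60, 31)
  va <- mk(20, 32)
  data <- list(x_train = tr$x, y_train = tr$y, x_val = va$x, y_val = va$y)
  model <- build_architecture("lstm", input_length = 25)
  cfg <- training_config(max_epochs = 12, patience = 10, seed = 7)
  fit1 <- train_network(model, data, cfg)

  # final train loss beats the all-0.5 baseline ln 2
  expect_lt(utils::tail(fit1$history$train_loss, 1), log(2))
  expect_lte(fit1$history$best_epoch, fit1$history$stopped_epoch)
  expect_lte(fit1$history$stopped_epoch, cfg$max_epochs)

  # same seed -> identical first-epoch loss; different seed -> different
  fit2 <- train_network(model, data, cfg)
  expect_identical(fit1$history$train_loss[1], fit2$history$train_loss[1])
  fit3 <- train_network(model, data, training_config(max_epochs = 2,
                                                     patience = 1, seed = 8))
  expect_false(identical(fit1$history$train_loss[1], fit3$history$train_loss[1]))

  # the learned model separates the classes it was trained on
  p <- predict_proba(fit1$model, va$x)
  expect_gt(mean(p[va$y == 1]), mean(p[va$y == 0]))
})

test_that("empty partitions are rejected", {
  model <- build_architecture("lstm", 10)
  expect_error(train_network(model, list(x_train = array(0, c(0, 10, 4)),
                                         y_train = integer(0),
                                         x_val = array(0, c(1, 10, 4)),
                                         y_val = 0L)),
               "non-empty")
})
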