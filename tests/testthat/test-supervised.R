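test_that("metric suite matches hand formulas on a fixed confusion matrix", {
  # TP = 90, FP = 10, TN = 80, FN = 20 at threshold 0.5
  probs <- c(rep(0.9, 90), rep(0.1, 20), rep(0.9, 10), rep(0.1, 80))
  labels <- c(rep(1, 110), rep(0, 90))
  m <- evaluate_metrics(probs, labels)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.90)
  expect_equal(m$sensitivity, 90 / 110, tolerance = 1e-4)  # 0.8182
  expect_equal(m$specificity, 80 / 90, tolerance = 1e-4)   # 0.8889
})

test_that("ROC-AUC equals the pairwise concordance oracle", {
  expect_equal(evaluate_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$roc_auc, 1.0)
  for (rep in 1:100) {
    set.seed(2000 + rep)
    n <- sample(8:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    # coarse scores induce ties, exercising the half-tie convention
    scores <- round(runif(n), 1)
    expect_equal(evaluate_metrics(scores, labels)$roc_auc,
                 oracle_auc(scores, labels))
  }
  expect_error(evaluate_metrics(c(0.1, 0.9), c(1, 1)), "single class")
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(evaluate_metrics(scores, labels)$roc_auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("stratified splits preserve class proportions within one sample", {
  set.seed(4)
  labels <- rbinom(200, 1, 0.35)
  plan <- split_plan(seed = 7L)
  a <- make_splits(labels, plan)
  expect_setequal(unique(a), c("calibration", "validation", "test"))
  expect_equal(sum(a == "calibration"), 140, tolerance = 2)
  for (s in unique(a)) {
    for (cls in 0:1) {
      got <- sum(labels == cls & a == s)
      want <- sum(labels == cls) * c(calibration = 0.70, validation = 0.15,
                                     test = 0.15)[[s]]
      expect_lte(abs(got - want), 1)
    }
  }
  # deterministic under the plan seed
  expect_identical(a, make_splits(labels, plan))
})

test_that("cross-validation folds partition the data with stratification", {
  labels <- rbinom(83, 1, 0.4)
  set.seed(1)
  fold <- make_cv_folds(labels, folds = 5L, seed = 3L)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 83L)
  for (k in 1:5) {
    for (cls in 0:1) {
      frac <- sum(labels == cls & fold == k) / sum(fold == k)
      expect_lt(abs(frac - mean(labels == cls)), 0.15)
    }
  }
  expect_identical(fold, make_cv_folds(labels, 5L, seed = 3L))
  expect_error(make_cv_folds(c(1, 1, 1, 0, 0, 0), folds = 5L), "stratify")
})

test_that("an untrained model with a zeroed final layer predicts 0.5", {
  fx <- get_fixture(200L)
  fit <- train_model(fx[1:24, ], config = model_config(batch_size = 8L,
                                                       ecfp_bits = 128L),
                     encoder_cfg = encoder_config(hidden_dim = 8L, n_heads = 2L),
                     split = rep("calibration", 24), epochs = 1L, seed = 1L)
  m <- fit$model
  last <- length(m$params$ffn)
  m$params$ffn[[last]]$W <- m$params$ffn[[last]]$W * 0
  m$params$ffn[[last]]$b <- m$params$ffn[[last]]$b * 0
  p <- build_and_predict(m, "CCO")
  expect_equal(p$probability, 0.5)
  expect_equal(p$label, 1L)  # threshold convention: >= 0.5 is positive
})

test_that("prediction is deterministic and robust to bad records", {
  fx <- get_fixture(200L)
  fit <- train_model(fx[1:30, ], config = model_config(batch_size = 8L,
                                                       ecfp_bits = 128L),
                     encoder_cfg = encoder_config(hidden_dim = 8L, n_heads = 2L),
                     split = rep("calibration", 30), epochs = 2L, seed = 1L)
  p1 <- build_and_predict(fit$model, "c1ccncc1C")
  p2 <- build_and_predict(fit$model, "c1ccncc1C")
  expect_identical(p1$probability, p2$probability)
  batch <- predict_molecules(fit$model, c("CCO", "##bad##", "c1ccccc1"))
  expect_true(is.na(batch$probability[2]))
  expect_match(batch$error[2], "bad")
  expect_false(anyNA(batch$probability[c(1, 3)]))
})

test_that("training descends the loss, reports all metrics and reproduces", {
  fx <- get_fixture(200L)
  data <- fx[1:120, ]
  cfg <- model_config(batch_size = 16L, ecfp_bits = 256L)
  ec <- encoder_config(hidden_dim = 16L, n_heads = 2L, message_iterations = 2L)
  fit <- train_model(data, config = cfg, encoder_cfg = ec, epochs = 10L,
                     split = split_plan(seed = 2L), seed = 3L)
  h <- fit$history
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
  for (nm in c("roc_auc", "accuracy", "precision", "sensitivity", "specificity")) {
    expect_true(is.finite(fit$metrics$test[[nm]]))
  }
  # reproducibility under a fixed seed
  fit2 <- train_model(data, config = cfg, encoder_cfg = ec, epochs = 10L,
                      split = split_plan(seed = 2L), seed = 3L)
  expect_identical(fit$history, fit2$history)
  expect_equal(fit$metrics$test$roc_auc, fit2$metrics$test$roc_auc)
  # single-class data is rejected
  expect_error(train_model(data[data$label == 1, ], config = cfg),
               "both classes")
})

test_that("pretrained initialization is accepted and fine-tunes end to end", {
  fx <- get_fixture(200L)
  ec <- encoder_config(hidden_dim = 16L, message_iterations = 2L, n_heads = 2L)
  pt <- pretrain(fx$smiles[1:40], ec,
                 contrastive_config(batch_size = 8L, epochs = 1L, seed = 2L))
  for (pre in list(NULL, pt$encoder)) {
    fit <- train_model(fx[41:100, ],
                       config = model_config(batch_size = 16L, ecfp_bits = 128L),
                       encoder_cfg = ec, epochs = 3L,
                       split = split_plan(seed = 5L), pretrained = pre, seed = 4L)
    expect_s3_class(fit$model, "aampnn_model")
    expect_true(is.finite(fit$metrics$test$roc_auc))
  }
  # frozen encoder leaves encoder parameters untouched
  fit_frozen <- train_model(fx[41:100, ],
                            config = model_config(batch_size = 16L,
                                                  ecfp_bits = 128L),
                            encoder_cfg = ec, epochs = 2L,
                            split = split_plan(seed = 5L),
                            pretrained = pt$encoder, freeze_encoder = TRUE,
                            seed = 4L)
  expect_equal(fit_frozen$model$params$encoder$Wi, pt$encoder$params$Wi)
})

test_that("cross-validation reports mean and spread over a partition", {
  fx <- get_fixture(200L)
  data <- fx[1:60, ]
  cv <- cross_validate(data, config = model_config(batch_size = 16L,
                                                   ecfp_bits = 128L),
                       encoder_cfg = encoder_config(hidden_dim = 8L,
                                                    n_heads = 2L,
                                                    message_iterations = 2L),
                       folds = 3L, epochs = 3L, seed = 6L)
  expect_equal(nrow(cv$per_fold), 3L)
  expect_true(all(table(cv$fold) >= 1))
  expect_equal(length(cv$fold), 60L)
  expect_true(is.finite(cv$mean[["roc_auc"]]))
  expect_true(all(cv$sd >= 0, na.rm = TRUE))
})

test_that("Bayesian optimization respects the grid and finds a mock argmax", {
  # deterministic mock objective over a 2-point space returns the argmax
  space <- list(ffn_layers = list(type = "discrete", values = c(2L, 3L)))
  res <- bayes_optimize(objective = function(cfg) {
    if (cfg$ffn_layers == 3L) 1.0 else 0.0
  }, search_space = space, n_iterations = 8L, seed = 3L)
  expect_equal(res$best_config$ffn_layers, 3L)
  expect_equal(res$best_score, 1.0)

  # every trial of a full search lies inside the published grid
  grid <- default_search_space()
  scorer <- function(cfg) {
    # smooth deterministic surrogate: prefers T = 4, dropout 0.1, lr 5e-4
    -abs(cfg$message_iterations - 4) - abs(cfg$dropout - 0.1) -
      abs(log(cfg$learning_rate) - log(5e-4))
  }
  res <- bayes_optimize(objective = scorer, search_space = grid,
                        n_iterations = 20L, seed = 11L)
  tr <- res$trials
  expect_equal(nrow(tr), 20L)
  expect_true(all(tr$message_iterations %in% 2:6))
  expect_true(all(tr$batch_size %in% c(128L, 256L, 512L)))
  expect_true(all(vapply(tr$dropout, function(d) {
    any(abs(d - seq(0, 0.4, 0.05)) < 1e-9)
  }, TRUE)))
  expect_true(all(tr$ffn_layers %in% c(2L, 3L)))
  expect_true(all(tr$learning_rate >= 1e-4 & tr$learning_rate <= 1e-3))

  # reproducible trial sequence under the seed
  res2 <- bayes_optimize(objective = scorer, search_space = grid,
                         n_iterations = 20L, seed = 11L)
  expect_identical(res$trials, res2$trials)
  expect_error(bayes_optimize(objective = scorer, search_space = list()),
               "empty")
})

test_that("configuration objects validate their ranges", {
  expect_error(model_config(dropout = 0.6), "dropout")
  expect_error(model_config(ffn_layers = 4L), "ffn_layers")
  expect_error(model_config(learning_rate = 5e-3), "learning_rate")
  expect_error(encoder_config(hidden_dim = 10L, n_heads = 4L), "divisible")
  expect_error(contrastive_config(mask_ratio = 1.5), "mask_ratio")
  expect_error(contrastive_config(temperature = -0.1), "temperature")
  expect_error(split_plan(test_fraction = 0.5), "sum to 1")
})
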