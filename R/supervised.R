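# Supervised fine-tuning and evaluation: stratified splitting, Adam/BCE
# training of the full model (encoder + optional ECFP + FFN head),
# prediction, the metric suite, and cross-validation.

#' Model (fine-tuning) configuration
#'
#' Hyperparameters of the downstream classifier. `dropout`,
#' `learning_rate` and `ffn_layers` are validated against the tuning
#' grid (dropout 0-0.4, learning rate 1e-4 to 1e-3, 2 or 3 FFN layers);
#' `message_iterations` and `batch_size` accept any positive value so
#' scaled-down experiments remain expressible (the Bayesian search space
#' itself is restricted to the published grid, see
#' [default_search_space()]).
#'
#' @param message_iterations Bond message-passing steps T.
#' @param batch_size Minibatch size.
#' @param dropout Dropout probability in \[0, 0.4\].
#' @param ffn_layers Number of linear layers in the output FFN (2 or 3).
#' @param learning_rate Adam step size in \[1e-4, 1e-3\].
#' @param use_ecfp Concatenate the ECFP to the molecule vector before the
#'   FFN (the published model; `FALSE` gives the fingerprint-free ablation).
#' @param use_pretrained Declarative flag recorded in the config; the
#'   actual pretrained parameters are passed to [train_model()].
#' @param ecfp_radius,ecfp_bits Fingerprint settings when `use_ecfp`.
#' @return A `model_config` object.
#' @export
model_config <- function(message_iterations = 3L, batch_size = 32L,
                         dropout = 0.0, ffn_layers = 2L,
                         learning_rate = 1e-3, use_ecfp = TRUE,
                         use_pretrained = FALSE,
                         ecfp_radius = 2L, ecfp_bits = 2048L) {
  if (message_iterations < 1) stop_config("message_iterations must be >= 1")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  if (dropout < 0 || dropout > 0.4) {
    stop_config("dropout must be in [0, 0.4], got %s", dropout)
  }
  if (!ffn_layers %in% c(2L, 3L)) stop_config("ffn_layers must be 2 or 3")
  if (learning_rate < 1e-4 || learning_rate > 1e-3) {
    stop_config("learning_rate must be in [1e-4, 1e-3], got %s", learning_rate)
  }
  structure(list(message_iterations = as.integer(message_iterations),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 ffn_layers = as.integer(ffn_layers),
                 learning_rate = learning_rate,
                 use_ecfp = isTRUE(use_ecfp),
                 use_pretrained = isTRUE(use_pretrained),
                 ecfp_radius = as.integer(ecfp_radius),
                 ecfp_bits = as.integer(ecfp_bits)),
            class = "model_config")
}

#' Data split plan
#'
#' 85% train / 15% test, with the training portion further divided so
#' that calibration and validation are 70% and 15% of the FULL dataset
#' (the "70:15" ratio is interpreted as fractions of the whole, consistent
#' with 85 = 70 + 15). Stratified by class within +-1 sample.
#'
#' @param test_fraction,calibration_fraction,validation_fraction
#'   Fractions of the full dataset; must sum to 1.
#' @param cv_folds Folds used by [cross_validate()].
#' @param seed Seed for the stratified shuffles.
#' @return A `split_plan` object.
#' @export
split_plan <- function(test_fraction = 0.15, calibration_fraction = 0.70,
                       validation_fraction = 0.15, cv_folds = 5L, seed = 1L) {
  total <- test_fraction + calibration_fraction + validation_fraction
  if (abs(total - 1) > 1e-8) stop_config("split fractions must sum to 1")
  structure(list(test_fraction = test_fraction,
                 calibration_fraction = calibration_fraction,
                 validation_fraction = validation_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "split_plan")
}

# Largest-remainder apportionment of n items into the given fractions.
apportion <- function(n, fractions) {
  target <- n * fractions
  base <- floor(target)
  extra <- round(n - sum(base))
  if (extra > 0) {
    order_rem <- order(target - base, decreasing = TRUE)
    base[order_rem[seq_len(extra)]] <- base[order_rem[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Assign records to calibration/validation/test splits
#'
#' Stratified by label: within each class the records are shuffled and
#' apportioned by largest remainder, keeping every split's class
#' proportions within one sample of the global proportions.
#'
#' @param labels Binary (0/1) label vector.
#' @param plan A [split_plan()].
#' @return Character vector (`"calibration"`, `"validation"`, `"test"`)
#'   aligned with `labels`.
#' @export
make_splits <- function(labels, plan = split_plan()) {
  stopifnot(is_binary01(labels))
  assignment <- character(length(labels))
  fr <- c(calibration = plan$calibration_fraction,
          validation = plan$validation_fraction,
          test = plan$test_fraction)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- with_seed(derive_seed(plan$seed, 10L + cls), sample(idx))
    counts <- apportion(length(idx), fr)
    assignment[idx] <- rep(names(fr), counts)
  }
  assignment
}

#' Stratified cross-validation folds
#'
#' @param labels Binary label vector.
#' @param folds Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @return Integer fold id per record; each class is spread across folds
#'   as evenly as possible.
#' @export
make_cv_folds <- function(labels, folds = 5L, seed = 1L) {
  stopifnot(is_binary01(labels))
  if (folds < 2L) stop_config("folds must be >= 2")
  if (min(table(labels)) < folds) {
    stop_config("cannot stratify: a class has fewer records (%d) than folds (%d)",
                min(table(labels)), folds)
  }
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- with_seed(derive_seed(seed, 20L + cls), sample(idx))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Classification metric suite
#'
#' ROC-AUC is the probability that a uniformly chosen positive outranks a
#' uniformly chosen negative, with ties counted one half (rank /
#' Mann-Whitney formulation); the remaining metrics come from the
#' confusion matrix at the decision threshold.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param labels Binary 0/1 labels (both classes required for ROC-AUC).
#' @param threshold Decision threshold (default 0.5; predictions at the
#'   threshold count as positive).
#' @return Named list: `roc_auc`, `accuracy`, `precision`, `sensitivity`,
#'   `specificity`. Precision is `NA` when nothing is predicted positive.
#' @export
evaluate_metrics <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  if (!is_binary01(labels)) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC-AUC undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(probabilities)  # average ranks give the half-tie convention
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  list(
    roc_auc = auc,
    accuracy = (tp + tn) / length(labels),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

# ---------------------------------------------------------------------------
# Full-model forward/backward

ffn_dims <- function(d, n_extra, ffn_layers) {
  input <- d + n_extra
  if (ffn_layers == 2L) c(input, d, 1L) else c(input, d, d, 1L)
}

model_forward <- function(model, graph, fp_bits = NULL, training = FALSE) {
  enc <- encode_forward(graph, model$params$encoder, model$encoder_config,
                        drop_p = if (training) model$model_config$dropout else 0,
                        training = training)
  x <- if (model$model_config$use_ecfp) c(enc$h, fp_bits) else enc$h
  ff <- mlp_forward(model$params$ffn, matrix(x, 1L),
                    drop_p = if (training) model$model_config$dropout else 0,
                    training = training)
  list(prob = sigmoid(ff$out[1L, 1L]), logit = ff$out[1L, 1L],
       enc = enc, ff = ff, attention = enc$attention)
}

model_backward <- function(model, fw, dlogit) {
  d <- model$encoder_config$hidden_dim
  fb <- mlp_backward(model$params$ffn, fw$ff, matrix(dlogit, 1L, 1L))
  dh <- fb$dx[1L, seq_len(d)]
  eg <- encode_backward(fw$enc$cache, dh, model$params$encoder)
  list(encoder = eg, ffn = fb$grads)
}

new_model <- function(encoder_config, mconfig, eparams, ffn_params,
                      atom_width, bond_width) {
  structure(list(encoder_config = encoder_config, model_config = mconfig,
                 params = list(encoder = eparams, ffn = ffn_params),
                 atom_width = atom_width, bond_width = bond_width,
                 threshold = 0.5),
            class = "aampnn_model")
}

#' @export
print.aampnn_model <- function(x, ...) {
  cat(sprintf(
    "aampnn_model: d=%d, T=%d, heads=%d, ffn_layers=%d, ecfp=%s\n",
    x$encoder_config$hidden_dim, x$encoder_config$message_iterations,
    x$encoder_config$n_heads, x$model_config$ffn_layers,
    x$model_config$use_ecfp))
  invisible(x)
}

#' Predict permeability for a single molecule
#'
#' @param model A trained `aampnn_model`.
#' @param smiles A single SMILES string.
#' @return List with `probability` (sigmoid output), `label`
#'   (1 when probability >= 0.5) and `attention_weights`.
#' @export
build_and_predict <- function(model, smiles) {
  graph <- featurize_molecule(smiles)
  fp <- if (model$model_config$use_ecfp) {
    compute_ecfp(smiles, model$model_config$ecfp_radius,
                 model$model_config$ecfp_bits)$bits
  }
  fw <- model_forward(model, graph, fp)
  list(probability = fw$prob,
       label = as.integer(fw$prob >= model$threshold),
       attention_weights = fw$attention)
}

#' Batch prediction
#'
#' Unparseable SMILES are skipped and reported per record rather than
#' aborting the batch.
#'
#' @param model A trained `aampnn_model`.
#' @param smiles Character vector of SMILES.
#' @return data.frame with columns `smiles`, `probability`, `label`,
#'   `error` (NA on success).
#' @export
predict_molecules <- function(model, smiles) {
  out <- data.frame(smiles = smiles, probability = NA_real_,
                    label = NA_integer_, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(smiles)) {
    res <- tryCatch(build_and_predict(model, smiles[i]), error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$probability[i] <- res$probability
      out$label[i] <- res$label
    }
  }
  out
}

#' @export
predict.aampnn_model <- function(object, newdata, ...) {
  predict_molecules(object, newdata)
}

#' Fine-tune (or train from scratch) the permeability classifier
#'
#' Minimizes binary cross-entropy with Adam over the calibration split,
#' monitoring the validation split each epoch, and reports the metric
#' suite on every split. When `pretrained` is supplied (a [pretrain()]
#' encoder payload or a checkpoint path), the encoder starts from the
#' pretrained parameters and is fully fine-tuned unless
#' `freeze_encoder = TRUE`.
#'
#' @param data data.frame with columns `smiles` and `label` (0/1).
#' @param config A [model_config()].
#' @param encoder_cfg An [encoder_config()]; ignored (with a message) when
#'   `pretrained` fixes the architecture.
#' @param split A [split_plan()], or a precomputed character vector of
#'   assignments (`"calibration"`/`"validation"`/`"test"`).
#' @param epochs Training epochs.
#' @param pretrained Optional pretrained encoder payload or checkpoint path.
#' @param freeze_encoder Keep encoder parameters fixed during fine-tuning.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return List of class `aampnn_fit`: `model`, `history` (per-epoch
#'   train/validation losses and validation AUC), `metrics` (per split),
#'   `split` (assignment vector), `failed_smiles`.
#' @export
train_model <- function(data, config = model_config(),
                        encoder_cfg = encoder_config(), split = split_plan(),
                        epochs = 30L, pretrained = NULL,
                        freeze_encoder = FALSE, seed = 1L, verbose = FALSE) {
  stopifnot(all(c("smiles", "label") %in% names(data)))
  labels <- as.integer(data$label)
  if (!is_binary01(labels)) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (inherits(split, "split_plan")) {
    assignment <- make_splits(labels, split)
  } else {
    assignment <- as.character(split)
    stopifnot(length(assignment) == nrow(data))
  }

  graphs <- featurize_molecules(data$smiles, on_error = "skip")
  failed <- attr(graphs, "failed")
  keep <- !vapply(graphs, is.null, TRUE)
  if (!any(keep)) stop("no parseable molecules in training data", call. = FALSE)
  graphs <- graphs[keep]
  labels <- labels[keep]
  assignment <- assignment[keep]
  smiles <- data$smiles[keep]

  aw <- graphs[[1L]]$atom_width
  bw <- graphs[[1L]]$bond_width
  fps <- NULL
  if (config$use_ecfp) {
    uniq <- unique(smiles)
    fpu <- lapply(uniq, function(s) {
      compute_ecfp(s, config$ecfp_radius, config$ecfp_bits)$bits
    })
    names(fpu) <- uniq
    fps <- fpu[smiles]
  }

  if (!is.null(pretrained)) {
    if (is.character(pretrained)) pretrained <- load_checkpoint(pretrained)
    if (!identical(pretrained$type, "encoder")) {
      stop_config("pretrained payload must have type 'encoder'")
    }
    if (pretrained$atom_width != aw || pretrained$bond_width != bw) {
      stop_config("pretrained encoder feature widths do not match the data")
    }
    encoder_cfg <- pretrained$encoder_config
    eparams <- pretrained$params
    config$use_pretrained <- TRUE
  } else {
    encoder_cfg$message_iterations <- config$message_iterations
    eparams <- init_encoder_params(encoder_cfg, aw, bw,
                                   seed = derive_seed(seed, 31L))
  }
  d <- encoder_cfg$hidden_dim
  n_extra <- if (config$use_ecfp) config$ecfp_bits else 0L
  ffn <- with_seed(derive_seed(seed, 32L),
                   mlp_init(ffn_dims(d, n_extra, config$ffn_layers)))
  model <- new_model(encoder_cfg, config, eparams, ffn, aw, bw)

  cal_idx <- which(assignment == "calibration")
  val_idx <- which(assignment == "validation")
  if (length(cal_idx) == 0L) stop("empty calibration split", call. = FALSE)

  opt <- adam_init(model$params)
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  predict_idx <- function(idx) {
    vapply(idx, function(i) {
      model_forward(model, graphs[[i]], fps[[i]])$prob
    }, numeric(1))
  }

  history <- NULL
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 500L + epoch), sample(cal_idx))
    nb <- max(1L, ceiling(length(ord) / config$batch_size))
    ep_loss <- 0
    with_seed(derive_seed(seed, 900L + epoch), {
      for (b in seq_len(nb)) {
        take <- ord[(((b - 1L) * config$batch_size) + 1L):
                      min(b * config$batch_size, length(ord))]
        grads <- NULL
        for (i in take) {
          fw <- model_forward(model, graphs[[i]], fps[[i]], training = TRUE)
          ep_loss <- ep_loss + bce(fw$prob, labels[i])
          gi <- model_backward(model, fw, fw$prob - labels[i])
          grads <- if (is.null(grads)) gi else walk_add(grads, gi)
        }
        grads <- walk_scale(grads, 1 / length(take))
        if (freeze_encoder) grads$encoder <- walk_zero(grads$encoder)
        step <- adam_step(model$params, grads, opt, config$learning_rate)
        model$params <- step$params
        opt <- step$state
      }
    })
    train_loss <- ep_loss / length(ord)
    val_loss <- NA_real_; val_auc <- NA_real_
    if (length(val_idx) > 0L) {
      pv <- predict_idx(val_idx)
      val_loss <- mean(bce(pv, labels[val_idx]))
      if (length(unique(labels[val_idx])) == 2L) {
        val_auc <- evaluate_metrics(pv, labels[val_idx])$roc_auc
      }
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss,
                                         val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %d: train BCE %.4f, val BCE %.4f, val AUC %s",
                      epoch, train_loss, val_loss,
                      ifelse(is.na(val_auc), "NA", sprintf("%.3f", val_auc))))
    }
  }

  metrics <- lapply(c(calibration = "calibration", validation = "validation",
                      test = "test"), function(s) {
    idx <- which(assignment == s)
    if (length(idx) == 0L || length(unique(labels[idx])) < 2L) return(NULL)
    evaluate_metrics(predict_idx(idx), labels[idx])
  })

  structure(list(model = model, history = history, metrics = metrics,
                 split = assignment, failed_smiles = failed),
            class = "aampnn_fit")
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold on the remaining folds and evaluates the
#' metric suite on the held-out fold; reports per-fold values and their
#' mean and sample standard deviation.
#'
#' @param data data.frame with `smiles` and `label`.
#' @param config,encoder_cfg,epochs,pretrained,seed As in [train_model()].
#' @param folds Number of folds (default 5).
#' @return List of class `aampnn_cv`: `fold` (assignment), `per_fold`
#'   (data.frame of metrics per fold), `mean`, `sd`.
#' @export
cross_validate <- function(data, config = model_config(),
                           encoder_cfg = encoder_config(), folds = 5L,
                           epochs = 10L, pretrained = NULL, seed = 1L) {
  labels <- as.integer(data$label)
  if (nrow(data) < folds) stop_config("dataset smaller than fold count")
  fold <- make_cv_folds(labels, folds, seed)
  rows <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- data[fold != k, , drop = FALSE]
    te <- data[fold == k, , drop = FALSE]
    assignment <- rep("calibration", nrow(tr))
    fit <- train_model(tr, config = config, encoder_cfg = encoder_cfg,
                       split = assignment, epochs = epochs,
                       pretrained = pretrained,
                       seed = derive_seed(seed, 40L + k))
    pr <- predict_molecules(fit$model, te$smiles)
    ok <- !is.na(pr$probability)
    m <- evaluate_metrics(pr$probability[ok], as.integer(te$label)[ok])
    rows[[k]] <- data.frame(fold = k, as.data.frame(m))
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(list(fold = fold, per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2, stats::sd)),
            class = "aampnn_cv")
}
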