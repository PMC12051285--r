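# Bayesian hyperparameter optimization with a compact tree-structured
# Parzen estimator (TPE) over the published mixed discrete/continuous
# grid: after a warm-up of random draws, trials are split at a quantile
# of the objective into "good" and "bad" sets; candidates are sampled
# from the good-set density and scored by the Parzen density ratio
# l(x)/g(x), independently per parameter (the "tree" factorization).

#' The published hyperparameter search space
#'
#' Message-passing iterations 2-6, batch size {128, 256, 512}, dropout
#' 0-0.4 in steps of 0.05, FFN layers {2, 3}, and a log-uniform Adam
#' learning rate between 1e-4 and 1e-3.
#'
#' @return Named list of parameter definitions (`discrete` values or
#'   `loguniform` bounds).
#' @export
default_search_space <- function() {
  list(
    message_iterations = list(type = "discrete", values = 2:6),
    batch_size = list(type = "discrete", values = c(128L, 256L, 512L)),
    dropout = list(type = "discrete", values = seq(0, 0.4, by = 0.05)),
    ffn_layers = list(type = "discrete", values = c(2L, 3L)),
    learning_rate = list(type = "loguniform", lower = 1e-4, upper = 1e-3)
  )
}

sample_config <- function(space) {
  out <- lapply(space, function(p) {
    if (p$type == "discrete") {
      p$values[sample.int(length(p$values), 1L)]
    } else {
      exp(stats::runif(1, log(p$lower), log(p$upper)))
    }
  })
  names(out) <- names(space)
  out
}

# Smoothed categorical density of `value` under observations `obs`.
parzen_discrete <- function(value, obs, values) {
  counts <- table(factor(obs, levels = as.character(values)))
  (counts[[as.character(value)]] + 1) / (length(obs) + length(values))
}

# Log-space Gaussian kernel density with a fixed bandwidth fraction.
parzen_logkde <- function(value, obs, lower, upper) {
  bw <- max((log(upper) - log(lower)) / 5, 1e-3)
  mean(stats::dnorm(log(value), mean = log(obs), sd = bw)) + 1e-12
}

#' Bayesian hyperparameter optimization (TPE)
#'
#' Maximizes validation ROC-AUC over the search space. Each trial trains
#' a model with the candidate configuration and records the score; the
#' best configuration and the full trial log are returned. A custom
#' `objective(config)` can replace the training objective (used for
#' testing and for cheap surrogate searches).
#'
#' @param data data.frame with `smiles`/`label`; ignored when `objective`
#'   is supplied.
#' @param search_space Parameter definitions, by default
#'   [default_search_space()].
#' @param n_epochs Training epochs per trial (default 20).
#' @param n_iterations Number of trials (default 20).
#' @param objective Optional function(config_list) -> numeric score to
#'   maximize.
#' @param n_startup Random trials before the TPE model kicks in.
#' @param gamma Quantile splitting good from bad trials.
#' @param n_candidates Candidates scored per TPE iteration.
#' @param encoder_cfg,pretrained Passed to [train_model()] for the default
#'   objective.
#' @param seed Seed for the whole search.
#' @return List of class `aampnn_tune`: `best_config`, `best_score`,
#'   `trials` (data.frame log with one row per trial).
#' @export
bayes_optimize <- function(data = NULL, search_space = default_search_space(),
                           n_epochs = 20L, n_iterations = 20L,
                           objective = NULL, n_startup = 8L, gamma = 0.3,
                           n_candidates = 24L,
                           encoder_cfg = encoder_config(), pretrained = NULL,
                           seed = 1L) {
  if (length(search_space) == 0L) stop_config("empty search space")
  for (p in search_space) {
    if (p$type == "discrete" && length(p$values) == 0L) {
      stop_config("degenerate search space: empty discrete value set")
    }
  }
  if (is.null(objective)) {
    if (is.null(data)) stop_config("either data or objective must be supplied")
    objective <- function(cfg) {
      mc <- model_config(message_iterations = cfg$message_iterations,
                         batch_size = cfg$batch_size, dropout = cfg$dropout,
                         ffn_layers = cfg$ffn_layers,
                         learning_rate = cfg$learning_rate)
      fit <- train_model(data, config = mc, encoder_cfg = encoder_cfg,
                         epochs = n_epochs, pretrained = pretrained,
                         seed = derive_seed(seed, 77L))
      m <- fit$metrics$validation
      if (is.null(m)) stop("no validation split available for tuning", call. = FALSE)
      m$roc_auc
    }
  }

  trials <- list()
  scores <- numeric(0)
  with_seed(derive_seed(seed, 55L), {
    for (it in seq_len(n_iterations)) {
      if (it <= n_startup || length(scores) < 4L) {
        cfg <- sample_config(search_space)
      } else {
        cut <- stats::quantile(scores, probs = 1 - gamma, names = FALSE)
        good <- which(scores >= cut)
        bad <- which(scores < cut)
        if (length(bad) == 0L) bad <- seq_along(scores)
        cands <- vector("list", n_candidates)
        ratio <- numeric(n_candidates)
        for (ci in seq_len(n_candidates)) {
          cand <- lapply(names(search_space), function(nm) {
            p <- search_space[[nm]]
            gvals <- vapply(trials[good], function(tr) as.numeric(tr[[nm]]), 1)
            if (p$type == "discrete") {
              w <- vapply(p$values, function(v) {
                parzen_discrete(v, as.character(gvals), p$values)
              }, 1)
              p$values[sample.int(length(p$values), 1L, prob = w)]
            } else {
              base <- gvals[sample.int(length(gvals), 1L)]
              bw <- max((log(p$upper) - log(p$lower)) / 5, 1e-3)
              min(max(exp(stats::rnorm(1, log(base), bw)), p$lower), p$upper)
            }
          })
          names(cand) <- names(search_space)
          lr_ratio <- 0
          for (nm in names(search_space)) {
            p <- search_space[[nm]]
            gvals <- vapply(trials[good], function(tr) as.numeric(tr[[nm]]), 1)
            bvals <- vapply(trials[bad], function(tr) as.numeric(tr[[nm]]), 1)
            if (p$type == "discrete") {
              l <- parzen_discrete(cand[[nm]], as.character(gvals), p$values)
              g <- parzen_discrete(cand[[nm]], as.character(bvals), p$values)
            } else {
              l <- parzen_logkde(cand[[nm]], gvals, p$lower, p$upper)
              g <- parzen_logkde(cand[[nm]], bvals, p$lower, p$upper)
            }
            lr_ratio <- lr_ratio + log(l) - log(g)
          }
          cands[[ci]] <- cand
          ratio[ci] <- lr_ratio
        }
        cfg <- cands[[which.max(ratio)]]
      }
      trials[[it]] <- cfg
      scores[it] <- objective(cfg)
    }
  })

  log_df <- do.call(rbind, lapply(seq_along(trials), function(i) {
    data.frame(trial = i, as.data.frame(trials[[i]]), score = scores[i])
  }))
  best <- which.max(scores)
  structure(list(best_config = trials[[best]], best_score = scores[best],
                 trials = log_df),
            class = "aampnn_tune")
}
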