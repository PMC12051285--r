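# Self-supervised contrastive pretraining of the encoder: positive pairs
# are (original molecule, atom-masked copy); both are encoded, projected
# through a small MLP head, and pulled together under the NT-Xent loss.
# The projection head is discarded after pretraining - only the encoder
# parameters transfer to fine-tuning.

#' Contrastive pretraining configuration
#'
#' @param mask_ratio Fraction of atoms replaced by the mask token in the
#'   positive view (default 0.25).
#' @param temperature NT-Xent temperature tau (default 0.1).
#' @param projection_dims Hidden and output widths of the projection head
#'   appended to the encoder's d-dimensional output; default
#'   `c(hidden_dim, 128)` is resolved at pretraining time when `NULL`.
#' @param batch_size Number N of molecules per contrastive batch (each
#'   contributes an original and a masked view, i.e. 2N samples).
#' @param epochs Number of passes over the training split.
#' @param learning_rate Adam step size.
#' @param validation_fraction Held-out fraction of the corpus (default
#'   0.1, i.e. a 90:10 train/validation split).
#' @param seed Integer seed controlling the split, masking and batching.
#' @return A `contrastive_config` object.
#' @export
contrastive_config <- function(mask_ratio = 0.25, temperature = 0.1,
                               projection_dims = NULL, batch_size = 16L,
                               epochs = 3L, learning_rate = 1e-3,
                               validation_fraction = 0.1, seed = 1L) {
  if (mask_ratio <= 0 || mask_ratio >= 1) {
    stop_config("mask_ratio must be in (0, 1), got %s", mask_ratio)
  }
  if (temperature <= 0) stop_config("temperature must be positive")
  if (batch_size < 2) stop_config("batch_size must be >= 2 for informative negatives")
  structure(list(mask_ratio = mask_ratio, temperature = temperature,
                 projection_dims = projection_dims,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "contrastive_config")
}

#' Mask atoms of a molecular graph
#'
#' Replaces `max(1, floor(mask_ratio * M))` uniformly chosen atom feature
#' rows with the mask token: an all-zero vector whose dedicated indicator
#' column (the last atom-feature column) is 1, which no valid one-hot
#' encoding can produce. Bond features are untouched.
#'
#' @param graph A `mol_graph`.
#' @param mask_ratio Fraction of atoms to mask, in (0, 1).
#' @param rng_seed Integer seed making the draw reproducible.
#' @return List of class `masked_view`: `graph` (masked copy),
#'   `masked_atom_indices`, `mask_token`.
#' @export
mask_atoms <- function(graph, mask_ratio = 0.25, rng_seed = 1L) {
  if (mask_ratio <= 0 || mask_ratio >= 1) {
    stop_config("mask_ratio must be in (0, 1), got %s", mask_ratio)
  }
  M <- graph$n_atoms
  n_mask <- max(1L, floor(mask_ratio * M))
  idx <- with_seed(rng_seed, sample.int(M, n_mask))
  token <- numeric(graph$atom_width)
  token[graph$atom_width] <- 1
  g2 <- graph
  for (i in idx) g2$atom_features[i, ] <- token
  structure(list(graph = g2, masked_atom_indices = sort(idx),
                 mask_token = token),
            class = "masked_view")
}

#' Cosine similarity
#'
#' @param z1,z2 Nonzero numeric vectors of equal length.
#' @return `z1'z2 / (|z1| |z2|)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(z1, z2) {
  stopifnot(length(z1) == length(z2))
  n1 <- sqrt(sum(z1^2)); n2 <- sqrt(sum(z2^2))
  if (n1 == 0 || n2 == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(z1 * z2) / (n1 * n2)
}

# Row-normalize a matrix; errors on zero rows.
unit_rows <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0)) stop("cosine similarity undefined for a zero vector", call. = FALSE)
  Z / nrm
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross-entropy over N positive pairs
#' (z_i, z_i'). The per-pair loss is
#' `-log( exp(sim(z_i, z_i')/tau) / sum_j (exp(sim(z_i, z_j')/tau) +
#' exp(sim(z_i', z_j)/tau)) )`, with the denominator exactly as printed
#' (the positive pair is included; there are no within-set negatives),
#' and the batch loss is the mean over i. At N = 1 the loss is exactly
#' log 2 regardless of the embeddings.
#'
#' @param Z Matrix N x p of projected originals (rows z_i).
#' @param Zp Matrix N x p of projected positive views (rows z_i').
#' @param temperature Positive temperature tau.
#' @param with_grad If `TRUE`, also return gradients with respect to `Z`
#'   and `Zp`.
#' @return The scalar loss, or (with `with_grad`) a list
#'   `loss, dZ, dZp`.
#' @export
nt_xent_loss <- function(Z, Zp, temperature = 0.1, with_grad = FALSE) {
  if (temperature <= 0) stop_config("temperature must be positive")
  Z <- as.matrix(Z); Zp <- as.matrix(Zp)
  stopifnot(nrow(Z) == nrow(Zp), ncol(Z) == ncol(Zp))
  N <- nrow(Z)
  U <- unit_rows(Z)
  V <- unit_rows(Zp)
  S <- U %*% t(V)                       # S[i, j] = sim(z_i, z_j')
  E <- exp(S / temperature)
  D <- rowSums(E) + colSums(E)          # denominator of pair i
  loss <- mean(-S[cbind(1:N, 1:N)] / temperature + log(D))
  if (!with_grad) return(loss)

  G <- E / temperature * (1 / D + rep(1 / D, each = N))  # via D_i and D_j
  G <- G / N
  diag(G) <- diag(G) - 1 / (N * temperature)
  # chain through cosine normalization
  rowdot <- rowSums(G * S)
  coldot <- colSums(G * S)
  nZ <- sqrt(rowSums(Z^2)); nZp <- sqrt(rowSums(Zp^2))
  dZ <- (G %*% V - U * rowdot) / nZ
  dZp <- (t(G) %*% U - V * coldot) / nZp
  list(loss = loss, dZ = dZ, dZp = dZp)
}

#' Contrastive pretraining of the encoder
#'
#' Featurizes the corpus, splits it 90:10 into train/validation, and for
#' each training batch builds positive pairs (original, atom-masked view),
#' encodes both, projects them through a two-layer MLP head, and descends
#' the NT-Xent loss with Adam. The final incomplete batch of each epoch is
#' dropped (contrastive losses are batch-size sensitive). The returned
#' artifact carries the encoder parameters only; the projection head is
#' discarded.
#'
#' @param corpus Character vector of SMILES (unparseable entries are
#'   skipped and reported; an all-invalid corpus is an error).
#' @param encoder_config An [encoder_config()].
#' @param contrastive_config A [contrastive_config()].
#' @param verbose Print per-epoch losses.
#' @return List of class `pretrain_result`: `encoder` (checkpointable
#'   payload with `type = "encoder"`, `params`, `encoder_config`, feature
#'   widths), `history` (data.frame epoch/train_loss/val_loss, epoch 0 =
#'   losses at random initialization), `n_train`, `n_val`, `failed_smiles`.
#' @export
pretrain <- function(corpus, encoder_config = aampnn::encoder_config(),
                     contrastive_config = aampnn::contrastive_config(),
                     verbose = FALSE) {
  cc <- contrastive_config
  graphs <- featurize_molecules(corpus, on_error = "skip")
  failed <- attr(graphs, "failed")
  graphs <- Filter(Negate(is.null), graphs)
  if (length(graphs) < 2L) {
    stop("pretraining corpus has fewer than two parseable molecules",
         call. = FALSE)
  }
  n <- length(graphs)
  aw <- graphs[[1L]]$atom_width
  bw <- graphs[[1L]]$bond_width
  d <- encoder_config$hidden_dim
  proj_dims <- cc$projection_dims %||% c(d, min(128L, d))

  idx <- with_seed(derive_seed(cc$seed, 1L), sample.int(n))
  n_val <- max(1L, floor(cc$validation_fraction * n))
  val_idx <- idx[seq_len(n_val)]
  train_idx <- idx[-seq_len(n_val)]

  eparams <- init_encoder_params(encoder_config, aw, bw,
                                 seed = derive_seed(cc$seed, 2L))
  pparams <- with_seed(derive_seed(cc$seed, 3L), mlp_init(c(d, proj_dims)))
  all_params <- list(encoder = eparams, proj = pparams)
  opt <- adam_init(all_params)

  batch_loss <- function(params, graphs_batch, mask_seeds, grad = TRUE) {
    N <- length(graphs_batch)
    fw1 <- vector("list", N); fw2 <- vector("list", N)
    H1 <- matrix(0, N, d); H2 <- matrix(0, N, d)
    for (i in seq_len(N)) {
      mv <- mask_atoms(graphs_batch[[i]], cc$mask_ratio, mask_seeds[i])
      fw1[[i]] <- encode_forward(graphs_batch[[i]], params$encoder,
                                 encoder_config)
      fw2[[i]] <- encode_forward(mv$graph, params$encoder, encoder_config)
      H1[i, ] <- fw1[[i]]$h
      H2[i, ] <- fw2[[i]]$h
    }
    p1 <- mlp_forward(params$proj, H1)
    p2 <- mlp_forward(params$proj, H2)
    nx <- nt_xent_loss(p1$out, p2$out, cc$temperature, with_grad = grad)
    if (!grad) return(list(loss = nx))
    b1 <- mlp_backward(params$proj, p1, nx$dZ)
    b2 <- mlp_backward(params$proj, p2, nx$dZp)
    pgrad <- walk_add(b1$grads, b2$grads)
    egrad <- NULL
    for (i in seq_len(N)) {
      g1 <- encode_backward(fw1[[i]]$cache, b1$dx[i, ], params$encoder)
      g2 <- encode_backward(fw2[[i]]$cache, b2$dx[i, ], params$encoder)
      gi <- walk_add(g1, g2)
      egrad <- if (is.null(egrad)) gi else walk_add(egrad, gi)
    }
    list(loss = nx$loss, grads = list(encoder = egrad, proj = pgrad))
  }

  eval_split <- function(params, split_idx, seed_base) {
    # fixed batching and masks so validation losses are comparable
    N <- cc$batch_size
    nb <- length(split_idx) %/% N
    if (nb == 0L) { nb <- 1L; N <- length(split_idx) }
    losses <- numeric(nb)
    for (b in seq_len(nb)) {
      take <- split_idx[((b - 1L) * N + 1L):(b * N)]
      losses[b] <- batch_loss(params, graphs[take],
                              derive_seed(seed_base, b) + seq_along(take),
                              grad = FALSE)$loss
    }
    mean(losses)
  }

  history <- data.frame(epoch = 0L,
                        train_loss = eval_split(all_params, train_idx, 7001L),
                        val_loss = eval_split(all_params, val_idx, 9001L))
  for (epoch in seq_len(cc$epochs)) {
    ord <- with_seed(derive_seed(cc$seed, 100L + epoch),
                     sample(train_idx))
    N <- cc$batch_size
    n_batches <- length(ord) %/% N       # last incomplete batch dropped
    if (n_batches == 0L) { n_batches <- 1L; N <- length(ord) }
    ep_losses <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      take <- ord[((b - 1L) * N + 1L):(b * N)]
      res <- batch_loss(all_params, graphs[take],
                        derive_seed(cc$seed, 1000L * epoch + b) + seq_along(take))
      ep_losses[b] <- res$loss
      step <- adam_step(all_params, res$grads, opt, cc$learning_rate)
      all_params <- step$params
      opt <- step$state
    }
    val <- eval_split(all_params, val_idx, 9001L)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(ep_losses),
                                         val_loss = val))
    if (verbose) {
      message(sprintf("epoch %d: train NT-Xent %.4f, val NT-Xent %.4f",
                      epoch, mean(ep_losses), val))
    }
  }

  structure(
    list(encoder = list(type = "encoder", params = all_params$encoder,
                        encoder_config = encoder_config,
                        atom_width = aw, bond_width = bw),
         history = history, n_train = length(train_idx), n_val = n_val,
         failed_smiles = failed),
    class = "pretrain_result"
  )
}
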