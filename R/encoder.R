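# Directed message-passing encoder with multi-head atom-attention readout.
#
# Forward pass (per molecule; x_v atom features, e_vw bond features):
#   h_vw^0 = ReLU(Concat(x_v, e_vw) W_i)
#   for t in 1..T:
#     m_vw^t = sum_{k in N(v)} h_kv^{t-1}  -  h_wv^{t-1}
#     h_vw^t = ReLU(h_vw^0 + m_vw^t W_h)
#   m_v    = ReLU(Concat(x_v, sum_{w in N(v)} h_vw^T) W_0)
#   h_v    = MultiHeadAttention(m_v) + m_v        (residual after W_o)
#   h      = sum_v h_v
# The reverse-bond subtraction stops messages echoing straight back along
# the bond they arrived on. All weight matrices are bias-free; attention
# logits are scaled by sqrt(d / n_heads) (the per-head width).

#' Encoder configuration
#'
#' @param hidden_dim Hidden dimension d of bond/atom states (default 300).
#' @param message_iterations Number T of bond message-passing steps
#'   (default 3; the tuning grid spans 2-6).
#' @param n_heads Number of attention heads (default 4); must divide
#'   `hidden_dim`.
#' @param activation Nonlinearity name; only `"relu"` is supported.
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(hidden_dim = 300L, message_iterations = 3L,
                           n_heads = 4L, activation = "relu") {
  if (hidden_dim <= 0) stop_config("hidden_dim must be positive")
  if (message_iterations < 1) stop_config("message_iterations must be >= 1")
  if (hidden_dim %% n_heads != 0) {
    stop_config("hidden_dim (%d) must be divisible by n_heads (%d)",
                hidden_dim, n_heads)
  }
  if (!identical(activation, "relu")) stop_config("only 'relu' is supported")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 message_iterations = as.integer(message_iterations),
                 n_heads = as.integer(n_heads),
                 activation = activation),
            class = "encoder_config")
}

#' Initialize encoder parameters
#'
#' Glorot-uniform initialization of all weight matrices: `Wi`
#' ((atom_width + bond_width) x d), `Wh` (d x d), `W0`
#' ((atom_width + d) x d), and the attention maps `Wq`, `Wk`, `Wv`, `Wo`
#' (each d x d; heads are column blocks of width d / n_heads).
#'
#' @param config An `encoder_config`.
#' @param atom_width,bond_width Feature widths from the schemas.
#' @param seed Integer seed for reproducible initialization.
#' @return Named list of parameter matrices with attribute `dims`.
#' @export
init_encoder_params <- function(config, atom_width, bond_width, seed = 1L) {
  d <- config$hidden_dim
  with_seed(seed, {
    p <- list(
      Wi = glorot(atom_width + bond_width, d),
      Wh = glorot(d, d),
      W0 = glorot(atom_width + d, d),
      Wq = glorot(d, d),
      Wk = glorot(d, d),
      Wv = glorot(d, d),
      Wo = glorot(d, d)
    )
    attr(p, "dims") <- c(atom_width = atom_width, bond_width = bond_width,
                         hidden_dim = d)
    p
  })
}

check_encoder_shapes <- function(graph, params) {
  if (nrow(params$Wi) != graph$atom_width + graph$bond_width) {
    stop_config(
      "encoder/graph shape mismatch: Wi expects input width %d, graph provides %d",
      nrow(params$Wi), graph$atom_width + graph$bond_width)
  }
}

#' Initial directed-bond hidden states
#'
#' `h_vw^0 = ReLU(Concat(x_v, e_vw) Wi)` for every directed bond v->w.
#'
#' @param graph A `mol_graph`.
#' @param params Encoder parameters.
#' @return Matrix (n directed bonds) x d; all entries nonnegative.
#' @export
init_bond_states <- function(graph, params) {
  check_encoder_shapes(graph, params)
  if (nrow(graph$bonds) == 0L) {
    return(matrix(0, 0L, ncol(params$Wi)))
  }
  inp <- cbind(graph$atom_features[graph$bonds[, "src"], , drop = FALSE],
               graph$bond_features)
  relu(inp %*% params$Wi)
}

#' One bond message-passing step
#'
#' Aggregates incoming bond states at each source atom, subtracts the
#' reverse bond's state, applies `Wh` and rectifies against the initial
#' state: `h_vw^t = ReLU(h_vw^0 + m_vw^t Wh)` with
#' `m_vw^t = sum_{k in N(v)} h_kv^{t-1} - h_wv^{t-1}`.
#'
#' @param graph A `mol_graph`.
#' @param bond_hidden Previous step's bond states.
#' @param h0 Initial bond states from [init_bond_states()].
#' @param params Encoder parameters.
#' @return Updated bond-state matrix.
#' @export
bond_message_step <- function(graph, bond_hidden, h0, params) {
  nb <- nrow(graph$bonds)
  if (nb == 0L) return(bond_hidden)
  incoming_sum <- rowsum_into(bond_hidden, graph$bonds[, "dst"], graph$n_atoms)
  m <- incoming_sum[graph$bonds[, "src"], , drop = FALSE] -
    bond_hidden[graph$reverse_index, , drop = FALSE]
  relu(h0 + m %*% params$Wh)
}

#' Aggregate bond states into atom messages
#'
#' `m_v = ReLU(Concat(x_v, sum_{w in N(v)} h_vw^T) W0)`; the sum runs over
#' directed bonds leaving v, and is the zero vector for isolated atoms.
#'
#' @param graph A `mol_graph`.
#' @param bond_hidden Final bond states after T steps.
#' @param params Encoder parameters.
#' @return Matrix n_atoms x d of nonnegative atom messages.
#' @export
atom_aggregate <- function(graph, bond_hidden, params) {
  d <- ncol(params$Wh)
  S <- if (nrow(graph$bonds) > 0L) {
    rowsum_into(bond_hidden, graph$bonds[, "src"], graph$n_atoms)
  } else {
    matrix(0, graph$n_atoms, d)
  }
  relu(cbind(graph$atom_features, S) %*% params$W0)
}

#' Multi-head scaled dot-product atom attention with residual
#'
#' Computes, per head, `softmax(Q K' / sqrt(d_head)) V` over the atoms of
#' one molecule, concatenates heads, applies `Wo`, and adds the residual
#' input.
#'
#' @param atom_messages Matrix M x d of atom messages.
#' @param params Encoder parameters.
#' @param n_heads Number of heads; must divide d.
#' @return List with `atom_hidden` (M x d, residual added), `attention`
#'   (list of per-head row-stochastic M x M matrices) and `output`
#'   (attention output before the residual).
#' @export
atom_attention <- function(atom_messages, params, n_heads) {
  M <- nrow(atom_messages)
  if (is.null(M) || M < 1L) stop("attention requires at least one atom", call. = FALSE)
  d <- ncol(atom_messages)
  if (d %% n_heads != 0) stop_config("d (%d) not divisible by n_heads (%d)", d, n_heads)
  dh <- d %/% n_heads
  scale <- sqrt(dh)
  heads <- vector("list", n_heads)
  Ocat <- matrix(0, M, d)
  cache <- vector("list", n_heads)
  for (k in seq_len(n_heads)) {
    idx <- ((k - 1L) * dh + 1L):(k * dh)
    Q <- atom_messages %*% params$Wq[, idx, drop = FALSE]
    K <- atom_messages %*% params$Wk[, idx, drop = FALSE]
    V <- atom_messages %*% params$Wv[, idx, drop = FALSE]
    A <- softmax_rows(Q %*% t(K) / scale)
    Ocat[, idx] <- A %*% V
    heads[[k]] <- A
    cache[[k]] <- list(Q = Q, K = K, V = V, A = A)
  }
  out <- Ocat %*% params$Wo
  list(atom_hidden = out + atom_messages, attention = heads, output = out,
       .cache = list(heads = cache, Ocat = Ocat))
}

# Full forward pass with cache for backprop. `drop_p` applies inverted
# dropout to the atom messages before the attention block when training.
encode_forward <- function(graph, params, config, drop_p = 0,
                           training = FALSE) {
  T_steps <- config$message_iterations
  h0 <- init_bond_states(graph, params)
  h_list <- vector("list", T_steps + 1L)
  h_list[[1L]] <- h0
  ht <- h0
  for (t in seq_len(T_steps)) {
    ht <- bond_message_step(graph, ht, h0, params)
    h_list[[t + 1L]] <- ht
  }
  Ma <- atom_aggregate(graph, ht, params)
  dmask <- NULL
  Ma_d <- Ma
  if (training && drop_p > 0) {
    dmask <- matrix(stats::rbinom(length(Ma), 1, 1 - drop_p) / (1 - drop_p),
                    nrow(Ma), ncol(Ma))
    Ma_d <- Ma * dmask
  }
  att <- atom_attention(Ma_d, params, config$n_heads)
  Hv <- att$atom_hidden
  h <- colSums(Hv)
  list(h = h, attention = att$attention, atom_hidden = Hv,
       cache = list(graph = graph, config = config, h_list = h_list,
                    Ma = Ma, Ma_d = Ma_d, dmask = dmask,
                    att = att$.cache))
}

#' Encode a molecule into a fixed-length vector
#'
#' Runs the full encoder (no dropout) and returns the molecule vector
#' `h = sum_v h_v` together with the per-head attention matrices.
#'
#' @param graph A `mol_graph`, or a SMILES string (featurized on the fly).
#' @param params Encoder parameters.
#' @param config The `encoder_config` used to shape `params`.
#' @return List with `molecule_vector` (length d), `attention_weights`
#'   (list of M x M row-stochastic matrices, one per head), `atom_hidden`
#'   and `atom_messages`.
#' @export
encode_molecule <- function(graph, params, config) {
  if (is.character(graph)) graph <- featurize_molecule(graph)
  fw <- encode_forward(graph, params, config)
  list(molecule_vector = fw$h, attention_weights = fw$attention,
       atom_hidden = fw$atom_hidden, atom_messages = fw$cache$Ma)
}

# Backward pass: dh is the gradient at the molecule vector (length d).
# Returns gradients for every encoder parameter matrix.
encode_backward <- function(cache, dh, params) {
  graph <- cache$graph
  config <- cache$config
  M <- graph$n_atoms
  d <- config$hidden_dim
  nb <- nrow(graph$bonds)
  grads <- list(Wi = params$Wi * 0, Wh = params$Wh * 0, W0 = params$W0 * 0,
                Wq = params$Wq * 0, Wk = params$Wk * 0, Wv = params$Wv * 0,
                Wo = params$Wo * 0)

  dHv <- matrix(dh, M, d, byrow = TRUE)

  # attention block (residual: Hv = Ocat %*% Wo + Ma_d)
  dMa_d <- dHv
  grads$Wo <- t(cache$att$Ocat) %*% dHv
  dOcat <- dHv %*% t(params$Wo)
  n_heads <- config$n_heads
  dhd <- d %/% n_heads
  scale <- sqrt(dhd)
  for (k in seq_len(n_heads)) {
    idx <- ((k - 1L) * dhd + 1L):(k * dhd)
    hc <- cache$att$heads[[k]]
    dOk <- dOcat[, idx, drop = FALSE]
    dA <- dOk %*% t(hc$V)
    dV <- t(hc$A) %*% dOk
    dL <- hc$A * (dA - rowSums(dA * hc$A))
    dQ <- dL %*% hc$K / scale
    dK <- t(dL) %*% hc$Q / scale
    grads$Wq[, idx] <- t(cache$Ma_d) %*% dQ
    grads$Wk[, idx] <- t(cache$Ma_d) %*% dK
    grads$Wv[, idx] <- t(cache$Ma_d) %*% dV
    dMa_d <- dMa_d + dQ %*% t(params$Wq[, idx, drop = FALSE]) +
      dK %*% t(params$Wk[, idx, drop = FALSE]) +
      dV %*% t(params$Wv[, idx, drop = FALSE])
  }
  dMa <- if (is.null(cache$dmask)) dMa_d else dMa_d * cache$dmask

  # atom aggregation: Ma = relu(cbind(X, S) %*% W0)
  dZ0 <- dMa * (cache$Ma > 0)
  aw <- graph$atom_width
  S <- if (nb > 0L) {
    rowsum_into(cache$h_list[[length(cache$h_list)]],
                graph$bonds[, "src"], M)
  } else {
    matrix(0, M, d)
  }
  grads$W0 <- t(cbind(graph$atom_features, S)) %*% dZ0
  dS <- (dZ0 %*% t(params$W0))[, (aw + 1L):(aw + d), drop = FALSE]

  if (nb > 0L) {
    T_steps <- config$message_iterations
    dht <- dS[graph$bonds[, "src"], , drop = FALSE]  # grad at h^T
    dh0_total <- matrix(0, nb, d)
    for (t in seq(T_steps, 1L)) {
      ht <- cache$h_list[[t + 1L]]
      h_prev <- cache$h_list[[t]]
      dP <- dht * (ht > 0)
      dh0_total <- dh0_total + dP
      # m_t recomputed for the Wh gradient
      incoming_sum <- rowsum_into(h_prev, graph$bonds[, "dst"], M)
      m_t <- incoming_sum[graph$bonds[, "src"], , drop = FALSE] -
        h_prev[graph$reverse_index, , drop = FALSE]
      grads$Wh <- grads$Wh + t(m_t) %*% dP
      dm <- dP %*% t(params$Wh)
      dA_atom <- rowsum_into(dm, graph$bonds[, "src"], M)
      dht <- dA_atom[graph$bonds[, "dst"], , drop = FALSE] -
        dm[graph$reverse_index, , drop = FALSE]
    }
    dh0_total <- dh0_total + dht
    h0 <- cache$h_list[[1L]]
    dZi <- dh0_total * (h0 > 0)
    inp <- cbind(graph$atom_features[graph$bonds[, "src"], , drop = FALSE],
                 graph$bond_features)
    grads$Wi <- t(inp) %*% dZi
  }
  grads
}

# ---------------------------------------------------------------------------
# Checkpoints

#' Save a checkpoint
#'
#' Writes an RDS container with a schema tag and version so pretrained
#' encoders can be transferred into fine-tuning runs.
#'
#' @param object A payload list; typically `type = "encoder"` artifacts
#'   from [pretrain()] or `type = "model"` artifacts from [train_model()].
#' @param path Output file path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(schema = "aampnn_checkpoint", version = 1L, payload = object),
          path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return The stored payload.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "aampnn_checkpoint")) {
    stop_config("not an aampnn checkpoint: %s", path)
  }
  if (!identical(x$version, 1L)) {
    stop_config("unsupported checkpoint version: %s", x$version)
  }
  x$payload
}
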