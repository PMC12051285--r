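# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's index structures (reverse_index, incoming lists,
# rowsum aggregation) and recompute everything with plain loops.

oracle_relu <- function(x) pmax(x, 0)

# Find the reverse of directed bond b by matching endpoints.
oracle_reverse <- function(bonds, b) {
  which(bonds[, 1] == bonds[b, 2] & bonds[, 2] == bonds[b, 1])
}

# Full encoder forward pass, loop-by-loop.
oracle_encode <- function(graph, params, T_steps, n_heads) {
  X <- graph$atom_features
  B <- graph$bond_features
  bonds <- graph$bonds
  nb <- nrow(bonds)
  d <- ncol(params$Wh)
  M <- graph$n_atoms

  h0 <- matrix(0, nb, d)
  for (b in seq_len(nb)) {
    h0[b, ] <- oracle_relu(c(X[bonds[b, 1], ], B[b, ]) %*% params$Wi)
  }
  h <- h0
  for (t in seq_len(T_steps)) {
    hn <- matrix(0, nb, d)
    for (b in seq_len(nb)) {
      v <- bonds[b, 1]
      rev_b <- oracle_reverse(bonds, b)
      m <- numeric(d)
      for (c in seq_len(nb)) {
        if (bonds[c, 2] == v && c != rev_b) m <- m + h[c, ]
      }
      hn[b, ] <- oracle_relu(h0[b, ] + m %*% params$Wh)
    }
    h <- hn
  }
  Ma <- matrix(0, M, d)
  for (v in seq_len(M)) {
    s <- numeric(d)
    for (b in seq_len(nb)) if (bonds[b, 1] == v) s <- s + h[b, ]
    Ma[v, ] <- oracle_relu(c(X[v, ], s) %*% params$W0)
  }
  dh <- d %/% n_heads
  Ocat <- matrix(0, M, d)
  att <- vector("list", n_heads)
  for (k in seq_len(n_heads)) {
    idx <- ((k - 1) * dh + 1):(k * dh)
    Q <- Ma %*% params$Wq[, idx, drop = FALSE]
    K <- Ma %*% params$Wk[, idx, drop = FALSE]
    V <- Ma %*% params$Wv[, idx, drop = FALSE]
    A <- matrix(0, M, M)
    for (i in seq_len(M)) {
      logits <- numeric(M)
      for (j in seq_len(M)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dh)
      e <- exp(logits - max(logits))
      A[i, ] <- e / sum(e)
    }
    Ocat[, idx] <- A %*% V
    att[[k]] <- A
  }
  Hv <- Ocat %*% params$Wo + Ma
  list(h = colSums(Hv), attention = att, atom_hidden = Hv)
}

# NT-Xent via the printed formula, double loop.
oracle_nt_xent <- function(Z, Zp, tau) {
  N <- nrow(Z)
  cs <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  losses <- numeric(N)
  for (i in seq_len(N)) {
    num <- exp(cs(Z[i, ], Zp[i, ]) / tau)
    den <- 0
    for (j in seq_len(N)) {
      den <- den + exp(cs(Z[i, ], Zp[j, ]) / tau) +
        exp(cs(Zp[i, ], Z[j, ]) / tau)
    }
    losses[i] <- -log(num / den)
  }
  mean(losses)
}

# ROC-AUC as explicit pairwise concordance with half ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Apply an atom permutation to a mol_graph: perm[i] is the new index of
# old atom i. Rebuilds bonds, reverse index and incoming lists from
# scratch.
permute_graph <- function(graph, perm) {
  g <- graph
  inv <- order(perm)
  g$atom_features <- graph$atom_features[inv, , drop = FALSE]
  g$elements <- graph$elements[inv]
  g$aromatic <- graph$aromatic[inv]
  g$in_ring <- graph$in_ring[inv]
  g$bonds <- cbind(src = perm[graph$bonds[, 1]], dst = perm[graph$bonds[, 2]])
  g$incoming <- lapply(seq_len(g$n_atoms), function(v) which(g$bonds[, "dst"] == v))
  g
}

# Small cached fixture shared across test files.
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(n = 200L, seed = 101L) {
  key <- sprintf("fx_%d_%d", n, seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- generate_fixture(n, seed = seed)
  }
  fixture_cache[[key]]
}
get_graphs <- function(smiles) {
  key <- paste0("g_", substr(digest_chr(paste(smiles, collapse = "|")), 1, 16))
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- featurize_molecules(smiles)
  }
  fixture_cache[[key]]
}
digest_chr <- function(x) {
  # cheap stable hash for cache keys
  paste(as.integer(utf8ToInt(substr(x, 1, 64))), collapse = "")
}

small_encoder <- function(graph, d = 12L, T_steps = 3L, heads = 3L, seed = 5L) {
  cfg <- encoder_config(hidden_dim = d, message_iterations = T_steps,
                        n_heads = heads)
  list(cfg = cfg,
       params = init_encoder_params(cfg, graph$atom_width, graph$bond_width,
                                    seed = seed))
}
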