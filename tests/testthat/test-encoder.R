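test_that("bond state initialization follows the concat-transform-rectify rule", {
  g <- featurize_molecule("CCO")
  se <- small_encoder(g)
  p <- se$params

  p0 <- p
  p0$Wi <- p$Wi * 0
  expect_true(all(init_bond_states(g, p0) == 0))

  # padded identity on one-hot inputs returns the concatenated features
  pid <- p
  d_full <- g$atom_width + g$bond_width
  cfg_id <- encoder_config(hidden_dim = d_full, message_iterations = 1L,
                           n_heads = 1L)
  pid <- init_encoder_params(cfg_id, g$atom_width, g$bond_width, seed = 2L)
  pid$Wi <- diag(d_full)
  h0 <- init_bond_states(g, pid)
  expected <- cbind(g$atom_features[g$bonds[, "src"], ], g$bond_features)
  expect_equal(h0, unname(expected))

  # random weights match a per-bond dense recomputation
  h0 <- init_bond_states(g, p)
  for (b in seq_len(nrow(g$bonds))) {
    expect_equal(h0[b, ],
                 oracle_relu(as.numeric(
                   c(g$atom_features[g$bonds[b, 1], ], g$bond_features[b, ]) %*% p$Wi)),
                 tolerance = 1e-12)
  }
  expect_true(all(h0 >= 0))

  # shape mismatch is a configuration error
  g2 <- featurize_molecule("CC")
  bad <- p
  bad$Wi <- p$Wi[-1, , drop = FALSE]
  expect_error(init_bond_states(g2, bad), "mismatch")
})

test_that("message passing excludes the reverse bond exactly", {
  # terminal atom: its only incoming state is the reverse bond, so the
  # message is zero and the state is a fixed point of the update
  g <- featurize_molecule("CC")
  se <- small_encoder(g)
  h0 <- init_bond_states(g, se$params)
  h1 <- bond_message_step(g, h0, h0, se$params)
  expect_equal(h1, h0)

  # linear chain A-B-C: the message into bond B->C at t=1 is h0[A->B]
  g <- featurize_molecule("CCO")
  se <- small_encoder(g)
  p <- se$params
  h0 <- init_bond_states(g, p)
  h1 <- bond_message_step(g, h0, h0, p)
  b_BC <- which(g$bonds[, 1] == 2 & g$bonds[, 2] == 3)
  b_AB <- which(g$bonds[, 1] == 1 & g$bonds[, 2] == 2)
  expect_equal(h1[b_BC, ],
               oracle_relu(h0[b_BC, ] + as.numeric(h0[b_AB, ] %*% p$Wh)),
               tolerance = 1e-12)

  # cyclopropane against the loop-over-bonds oracle
  g <- featurize_molecule("C1CC1")
  se <- small_encoder(g, d = 9L, T_steps = 2L, heads = 3L)
  ours <- encode_molecule(g, se$params, se$cfg)
  orc <- oracle_encode(g, se$params, 2L, 3L)
  expect_equal(ours$molecule_vector, orc$h, tolerance = 1e-10)
})

test_that("atom aggregation handles empty neighbourhoods and symmetry", {
  g <- featurize_molecule("C")  # no bonds: empty sum is the zero vector
  se <- small_encoder(g)
  h0 <- init_bond_states(g, se$params)
  m <- atom_aggregate(g, h0, se$params)
  expect_equal(m[1, ],
               oracle_relu(as.numeric(
                 c(g$atom_features[1, ], numeric(12)) %*% se$params$W0)),
               tolerance = 1e-12)
  expect_true(all(m >= 0))

  # ethane: the two carbons are equivalent and get identical messages
  g <- featurize_molecule("CC")
  se <- small_encoder(g)
  hT <- init_bond_states(g, se$params)
  for (t in 1:3) hT <- bond_message_step(g, hT, hT, se$params)
  m <- atom_aggregate(g, hT, se$params)
  expect_equal(m[1, ], m[2, ], tolerance = 1e-12)
})

test_that("attention is row-stochastic with the documented edge cases", {
  g <- featurize_molecule("CCOC")
  se <- small_encoder(g, d = 8L, heads = 2L)
  p <- se$params
  hT <- init_bond_states(g, p)
  Ma <- atom_aggregate(g, hT, p)

  # zero query/key weights: exactly uniform rows, output = mean of values
  p0 <- p
  p0$Wq <- p$Wq * 0
  p0$Wk <- p$Wk * 0
  att <- atom_attention(Ma, p0, 2L)
  M <- nrow(Ma)
  for (A in att$attention) {
    expect_equal(A, matrix(1 / M, M, M), tolerance = 1e-12)
  }
  V1 <- Ma %*% p0$Wv[, 1:4]
  expect_equal(att$.cache$heads[[1]]$A %*% V1,
               matrix(colMeans(V1), M, 4, byrow = TRUE), tolerance = 1e-12)

  # single atom: weight exactly one, residual added
  g1 <- featurize_molecule("C")
  se1 <- small_encoder(g1, d = 8L, heads = 2L)
  m1 <- atom_aggregate(g1, init_bond_states(g1, se1$params), se1$params)
  att1 <- atom_attention(m1, se1$params, 2L)
  expect_equal(att1$attention[[1]], matrix(1, 1, 1))
  expect_equal(att1$atom_hidden, att1$output + m1, tolerance = 1e-12)

  # random case against the explicit softmax/matmul oracle
  att <- atom_attention(Ma, p, 2L)
  orc <- oracle_encode(g, p, 0L, 2L)
  expect_true(all(abs(sapply(att$attention, rowSums) - 1) < 1e-6))
  expect_error(atom_attention(Ma[0, , drop = FALSE], p, 2L), "at least one atom")
})

test_that("the full encoder matches the index-free oracle on small molecules", {
  smis <- c("C", "CC", "CCO", "C1CC1", "CC(C)=O", "c1ccoc1", "C1CCOC1", "NCC(=O)O")
  for (s in smis) {
    g <- featurize_molecule(s)
    se <- small_encoder(g, d = 12L, T_steps = 3L, heads = 3L,
                        seed = nchar(s))
    ours <- encode_molecule(g, se$params, se$cfg)
    orc <- oracle_encode(g, se$params, 3L, 3L)
    expect_equal(ours$molecule_vector, orc$h, tolerance = 1e-8,
                 label = sprintf("molecule vector for %s", s))
    for (k in seq_along(ours$attention_weights)) {
      expect_equal(ours$attention_weights[[k]], orc$attention[[k]],
                   tolerance = 1e-8)
    }
  }
})

test_that("molecule vectors are invariant to atom reordering", {
  fx <- get_fixture(400L)
  graphs <- get_graphs(fx$smiles)
  pick <- which(!duplicated(fx$smiles))[1:40]
  g0 <- graphs[[pick[1]]]
  se <- small_encoder(g0, d = 16L, heads = 4L)
  for (i in pick) {
    g <- graphs[[i]]
    h_ref <- encode_molecule(g, se$params, se$cfg)$molecule_vector
    for (r in 1:3) {
      perm <- sample(g$n_atoms)
      hp <- encode_molecule(permute_graph(g, perm), se$params, se$cfg)$molecule_vector
      expect_equal(hp, h_ref, tolerance = 1e-8)
    }
  }
  # and via genuinely different SMILES orderings
  h1 <- encode_molecule("CCO", se$params, se$cfg)$molecule_vector
  h2 <- encode_molecule("OCC", se$params, se$cfg)$molecule_vector
  expect_equal(h1, h2, tolerance = 1e-10)
})

test_that("all-zero parameters give a zero molecule vector", {
  g <- featurize_molecule("CCO")
  se <- small_encoder(g)
  pz <- lapply(se$params, function(w) w * 0)
  attr(pz, "dims") <- attr(se$params, "dims")
  expect_equal(encode_molecule(g, pz, se$cfg)$molecule_vector, numeric(12))
})

test_that("the analytic backward pass matches numerical gradients", {
  g <- featurize_molecule("c1cc[nH]c1C")
  cfg <- encoder_config(hidden_dim = 6L, message_iterations = 2L, n_heads = 2L)
  p <- init_encoder_params(cfg, g$atom_width, g$bond_width, seed = 13L)
  set.seed(77)
  dh <- rnorm(6)
  fw <- aampnn:::encode_forward(g, p, cfg)
  gr <- aampnn:::encode_backward(fw$cache, dh, p)
  lossf <- function(pp) sum(aampnn:::encode_forward(g, pp, cfg)$h * dh)
  eps <- 1e-6
  for (nm in names(gr)) {
    idx <- sample(length(p[[nm]]), 5)
    for (k in idx) {
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- p; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (lossf(p2) - lossf(p3)) / (2 * eps)
      expect_equal(gr[[nm]][k], num, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", nm, k))
    }
  }
})

test_that("checkpoints roundtrip encoder payloads with schema validation", {
  g <- featurize_molecule("CCO")
  se <- small_encoder(g)
  path <- withr::local_tempfile(fileext = ".ckpt")
  payload <- list(type = "encoder", params = se$params,
                  encoder_config = se$cfg,
                  atom_width = g$atom_width, bond_width = g$bond_width)
  save_checkpoint(payload, path)
  back <- load_checkpoint(path)
  expect_equal(back$params$Wi, se$params$Wi)
  expect_identical(back$type, "encoder")
  saveRDS(list(schema = "other"), path)
  expect_error(load_checkpoint(path), "not an aampnn checkpoint")
})
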