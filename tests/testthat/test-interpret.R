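# Shared small trained model for the interpretation tests.
interp_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      fx <- get_fixture(200L)
      fit <- train_model(fx[1:60, ],
                         config = model_config(batch_size = 16L,
                                               ecfp_bits = 128L),
                         encoder_cfg = encoder_config(hidden_dim = 16L,
                                                      n_heads = 2L,
                                                      message_iterations = 2L),
                         split = rep("calibration", 60), epochs = 5L,
                         seed = 8L)
      model <<- fit$model
    }
    model
  }
})

test_that("attention profiles are normalized with occlusion-signed contributions", {
  model <- interp_model()
  rep <- atom_attention_profile(model, "Cc1ccncc1")
  expect_equal(sum(rep$atoms$weight), 1, tolerance = 1e-9)
  expect_true(all(rep$atoms$weight >= 0))
  expect_true(all(is.finite(rep$atoms$contribution)))
  expect_equal(nrow(rep$atoms), 7L)

  # single-atom molecule: weight exactly one; occlusion = p(orig) - p(masked)
  r1 <- atom_attention_profile(model, "C")
  expect_equal(r1$atoms$weight, 1)
  g <- featurize_molecule("C")
  token <- numeric(g$atom_width); token[g$atom_width] <- 1
  g$atom_features[1, ] <- token
  fp <- compute_ecfp("C", model$model_config$ecfp_radius,
                     model$model_config$ecfp_bits)$bits
  p_masked <- aampnn:::model_forward(model, g, fp)$prob
  expect_equal(r1$atoms$contribution, r1$probability - p_masked,
               tolerance = 1e-12)

  # ethane: symmetric carbons receive equal weight and contribution
  r2 <- atom_attention_profile(model, "CC")
  expect_equal(r2$atoms$weight[1], r2$atoms$weight[2], tolerance = 1e-9)
  expect_equal(r2$atoms$contribution[1], r2$atoms$contribution[2],
               tolerance = 1e-9)
  expect_error(atom_attention_profile(model, "bad(("), "parse")
})

test_that("attention profiles normalize to one across fixture molecules", {
  model <- interp_model()
  fx <- get_fixture(200L)
  for (s in unique(fx$smiles)[1:15]) {
    rep <- atom_attention_profile(model, s)
    expect_equal(sum(rep$atoms$weight), 1, tolerance = 1e-9)
  }
})

test_that("heatmap export writes deterministic tables with sign-faithful colors", {
  model <- interp_model()
  rep <- atom_attention_profile(model, "Cc1ccncc1O")
  dir <- withr::local_tempdir()
  p1 <- export_heatmap(rep, file.path(dir, "m1.svg"), format = "svg")
  expect_true(file.exists(p1$image))
  expect_true(file.exists(p1$table))
  # re-export is byte-identical
  p2 <- export_heatmap(rep, file.path(dir, "m2.svg"), format = "svg")
  expect_identical(readLines(p1$table), readLines(p2$table))
  expect_identical(readLines(p1$image), readLines(p2$image))
  # green/red assignment matches the contribution sign
  svg <- paste(readLines(p1$image), collapse = "\n")
  circles <- regmatches(svg, gregexpr("<circle[^/]*/>", svg))[[1]]
  expect_length(circles, nrow(rep$atoms))
  for (i in seq_along(circles)) {
    col <- if (rep$atoms$contribution[i] >= 0) "#00a000" else "#d00000"
    expect_match(circles[i], col, fixed = TRUE)
  }
  tab <- utils::read.csv(p1$table)
  expect_equal(tab$contribution, rep$atoms$contribution, tolerance = 1e-9)
  expect_equal(tab$element, rep$atoms$element)
  # a png export also renders
  p3 <- export_heatmap(rep, file.path(dir, "m3"), format = "png")
  expect_true(file.exists(p3$image))
})

test_that("the embedding map is deterministic with one row per molecule", {
  model <- interp_model()
  fx <- get_fixture(200L)
  smis <- unique(fx$smiles)[1:25]
  labs <- fx$label[match(smis, fx$smiles)]
  em1 <- embedding_map(model, smis, labs)
  em2 <- embedding_map(model, smis, labs)
  expect_equal(nrow(em1), 25L)
  expect_identical(em1, em2)
  expect_error(embedding_map(model, smis[1:2]), "at least 3")
})

test_that("fine-tuned embeddings separate the two planted classes", {
  model <- interp_model()
  fx <- get_fixture(200L)
  pick <- !duplicated(fx$smiles)
  smis <- fx$smiles[pick][1:40]
  labs <- fx$label[pick][1:40]
  em <- embedding_map(model, smis, labs)
  # mean silhouette of the 2-D embedding against the class labels
  X <- as.matrix(em[, c("dim1", "dim2")])
  sil <- cluster::silhouette(labs + 1L, stats::dist(X))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("occlusion of planted-signal atoms shifts predictions toward the other class", {
  model <- interp_model()
  fx <- get_fixture(200L)
  pos <- fx$smiles[fx$label == 1 & !duplicated(fx$smiles)][1:12]
  shifted <- vapply(pos, function(s) {
    rep <- atom_attention_profile(model, s)
    g <- featurize_molecule(s)
    aromN <- which(g$elements == "N" & g$aromatic)
    # summed occlusion contribution of the label-defining atoms
    sum(rep$atoms$contribution[aromN])
  }, numeric(1))
  # soft property: logged, not hard-failed
  frac_pos <- mean(shifted > 0)
  testthat::expect_true(is.finite(frac_pos))
  message(sprintf(
    "occlusion check: %.0f%% of positives lose predicted permeability when masking aromatic N",
    100 * frac_pos))
})
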