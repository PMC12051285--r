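# Interpretation: per-atom attention profiles, occlusion-based signed
# contributions, heatmap export, and 2-D embedding maps of molecule
# vectors.
#
# Attention weights from a row-stochastic softmax are nonnegative, so
# they cannot by themselves say whether an atom pushes the prediction up
# or down. The signed contribution is therefore defined by single-atom
# occlusion: probability(original) - probability(atom replaced by the
# pretraining mask token). A positive value means the atom's presence
# raises the predicted permeability. This is this package's
# interpretation definition, documented as such.

#' Per-atom attention and contribution profile
#'
#' Aggregated attention weight of atom j = mean (or max) over heads of
#' the attention received by j (column means of the row-stochastic
#' per-head matrices), renormalized to sum to one over the molecule.
#' Signed contribution of atom j = p(original) - p(j masked).
#'
#' @param model A trained `aampnn_model`.
#' @param smiles A single SMILES string.
#' @param head_aggregation `"mean"` (default) or `"max"` over heads.
#' @return Object of class `attention_report`: data.frame `atoms` (atom
#'   index, element, weight, contribution), `smiles`,
#'   `smiles_canonical`, `probability`, `label`.
#' @export
atom_attention_profile <- function(model, smiles,
                                   head_aggregation = c("mean", "max")) {
  head_aggregation <- match.arg(head_aggregation)
  graph <- featurize_molecule(smiles)
  fp <- if (model$model_config$use_ecfp) {
    compute_ecfp(smiles, model$model_config$ecfp_radius,
                 model$model_config$ecfp_bits)$bits
  }
  fw <- model_forward(model, graph, fp)
  received <- sapply(fw$attention, colMeans)  # M x n_heads
  if (is.null(dim(received))) received <- matrix(received, nrow = 1L)
  w <- if (head_aggregation == "mean") {
    rowMeans(received)
  } else {
    apply(received, 1L, max)
  }
  w <- w / sum(w)

  token <- numeric(graph$atom_width)
  token[graph$atom_width] <- 1
  contribution <- vapply(seq_len(graph$n_atoms), function(i) {
    g2 <- graph
    g2$atom_features[i, ] <- token
    fw$prob - model_forward(model, g2, fp)$prob
  }, numeric(1))

  structure(
    list(atoms = data.frame(atom = seq_len(graph$n_atoms),
                            element = graph$elements,
                            weight = w, contribution = contribution,
                            stringsAsFactors = FALSE),
         smiles = smiles, smiles_canonical = graph$smiles_canonical,
         probability = fw$prob,
         label = as.integer(fw$prob >= model$threshold)),
    class = "attention_report"
  )
}

#' @export
print.attention_report <- function(x, ...) {
  cat(sprintf("attention_report: %s (p = %.3f, label %d)\n",
              x$smiles_canonical, x$probability, x$label))
  print(x$atoms)
  invisible(x)
}

# Fixed-format numeric printing so exported tables are byte-identical
# across runs.
fmt_num <- function(x) sprintf("%.10g", x)

#' Export an attention heatmap depiction and per-atom table
#'
#' Draws the molecule in 2-D (OpenBabel-generated coordinates) with atoms
#' colored on a diverging scale - green for positive occlusion
#' contribution, red for negative, intensity proportional to
#' |contribution| - and writes a machine-readable per-atom CSV table
#' next to the depiction.
#'
#' @param report An [atom_attention_profile()] result.
#' @param out_path Output path for the depiction (`.svg` or `.png`
#'   appended if missing).
#' @param format `"svg"` (hand-written vector output, deterministic) or
#'   `"png"`.
#' @return Invisibly, a list with `image` and `table` paths.
#' @export
export_heatmap <- function(report, out_path, format = c("svg", "png")) {
  format <- match.arg(format)
  mb <- parse_molblock(smiles_to_molblock(report$smiles, gen2d = TRUE))
  heavy <- which(mb$symbol != "H")
  if (length(heavy) != nrow(report$atoms)) {
    stop("depiction atom count does not match the report", call. = FALSE)
  }
  x <- mb$x[heavy]; y <- mb$y[heavy]
  hmap <- integer(mb$n_atoms); hmap[heavy] <- seq_along(heavy)
  contr <- report$atoms$contribution
  cmax <- max(abs(contr), 1e-12)
  intensity <- abs(contr) / cmax
  pos <- contr >= 0

  base <- sub("\\.(svg|png)$", "", out_path)
  img_path <- paste0(base, ".", format)
  tbl_path <- paste0(base, "_atoms.csv")

  # per-atom table, fixed formatting for byte-identical re-export
  hdr <- "atom,element,weight,contribution"
  rows <- sprintf("%d,%s,%s,%s", report$atoms$atom, report$atoms$element,
                  fmt_num(report$atoms$weight), fmt_num(contr))
  writeLines(c(hdr, rows), tbl_path)

  # bonds between heavy atoms (one line per chemical bond)
  seg <- NULL
  for (i in seq_along(mb$bond_a)) {
    a <- mb$bond_a[i]; b <- mb$bond_b[i]
    if (mb$symbol[a] != "H" && mb$symbol[b] != "H") {
      seg <- rbind(seg, c(x[hmap[a]], y[hmap[a]], x[hmap[b]], y[hmap[b]]))
    }
  }
  rng_x <- range(x); rng_y <- range(y)
  pad <- 1
  if (format == "svg") {
    sc <- 40
    px <- function(v) fmt_num((v - rng_x[1] + pad) * sc)
    py <- function(v) fmt_num((rng_y[2] - v + pad) * sc)
    w <- (diff(rng_x) + 2 * pad) * sc
    h <- (diff(rng_y) + 2 * pad) * sc
    out <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
      fmt_num(w), fmt_num(h), fmt_num(w), fmt_num(h)),
      '<rect width="100%" height="100%" fill="white"/>')
    for (i in seq_len(NROW(seg))) {
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="2"/>',
        px(seg[i, 1]), py(seg[i, 2]), px(seg[i, 3]), py(seg[i, 4])))
    }
    for (i in seq_along(x)) {
      col <- if (pos[i]) "#00a000" else "#d00000"
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="12" fill="%s" fill-opacity="%s"/>',
        px(x[i]), py(y[i]), col, fmt_num(intensity[i])))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="10" text-anchor="middle" dy="3">%s</text>',
        px(x[i]), py(y[i]), report$atoms$element[i]))
    }
    out <- c(out, "</svg>")
    writeLines(out, img_path)
  } else {
    grDevices::png(img_path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
    graphics::plot(NA, xlim = rng_x + c(-pad, pad), ylim = rng_y + c(-pad, pad),
                   asp = 1, axes = FALSE, xlab = "", ylab = "",
                   main = report$smiles_canonical)
    if (!is.null(seg)) {
      graphics::segments(seg[, 1], seg[, 2], seg[, 3], seg[, 4],
                         col = "grey40", lwd = 2)
    }
    cols <- ifelse(pos, grDevices::rgb(0, 0.63, 0, intensity),
                   grDevices::rgb(0.82, 0, 0, intensity))
    graphics::points(x, y, pch = 19, cex = 3, col = cols)
    graphics::text(x, y, report$atoms$element)
  }
  invisible(list(image = img_path, table = tbl_path))
}

#' 2-D embedding map of molecule vectors
#'
#' Encodes every molecule with the model's encoder and projects the
#' d-dimensional molecule vectors to two dimensions by principal
#' component analysis, for plotting pretrained-versus-scratch
#' representation comparisons. Deterministic for a fixed model and input
#' set.
#'
#' @param model An `aampnn_model`, or a pretrained encoder payload from
#'   [pretrain()].
#' @param smiles Character vector (>= 3 molecules).
#' @param labels Optional labels carried through to the output.
#' @return data.frame with `smiles`, `dim1`, `dim2` and optionally
#'   `label`.
#' @export
embedding_map <- function(model, smiles, labels = NULL) {
  if (length(smiles) < 3L) {
    stop_config("embedding map requires at least 3 molecules")
  }
  if (inherits(model, "aampnn_model")) {
    eparams <- model$params$encoder
    ecfg <- model$encoder_config
  } else if (identical(model$type, "encoder")) {
    eparams <- model$params
    ecfg <- model$encoder_config
  } else {
    stop_config("model must be an aampnn_model or a pretrained encoder payload")
  }
  graphs <- featurize_molecules(smiles)
  H <- t(vapply(graphs, function(g) {
    encode_forward(g, eparams, ecfg)$h
  }, numeric(ecfg$hidden_dim)))
  pc <- stats::prcomp(H, center = TRUE, scale. = FALSE, rank. = 2L)
  out <- data.frame(smiles = smiles, dim1 = pc$x[, 1L], dim2 = pc$x[, 2L],
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- labels
  out
}
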