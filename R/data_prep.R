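# Dataset curation and diversity diagnostics: Caco-2 logPapp labeling via
# 1-D two-cluster k-means, Murcko scaffold statistics, and the Tanimoto
# leakage screen between datasets.

# Keep the largest organic fragment of a dot-separated SMILES (salt and
# solvent stripping); fragment size = heavy-atom count of the parse.
largest_fragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(smiles)
  sizes <- vapply(parts, function(p) {
    g <- tryCatch(featurize_molecule(p), error = function(e) NULL)
    if (is.null(g)) -1L else g$n_atoms
  }, integer(1))
  if (all(sizes < 0L)) stop(sprintf("cannot parse SMILES: '%s'", smiles),
                            call. = FALSE)
  parts[which.max(sizes)]
}

# OpenBabel charge neutralization + canonicalization.
standardize_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"),
                              options = ob_options("neutralize")),
    error = function(e) ""
  )
  out <- trimws(out)
  if (!nzchar(out)) stop(sprintf("cannot parse SMILES: '%s'", smiles),
                         call. = FALSE)
  strsplit(out, "[ \t\n]")[[1]][1]
}

#' Curate a Caco-2 permeability dataset
#'
#' Pipeline: parse -> keep the largest organic fragment (salt/solvent
#' stripping) -> neutralize and canonicalize -> drop records with logPapp
#' outside \[-8, -3.5\] (log10 cm/s; values outside are considered
#' unreliable) -> two-cluster k-means on the retained logPapp values ->
#' binary labels (higher-permeability cluster = permeable, label 1). The
#' reported threshold is the midpoint between the maximum of the lower
#' cluster and the minimum of the upper cluster.
#'
#' @param records data.frame with columns `smiles` and `log_papp`
#'   (log10 apparent permeability in cm/s); an optional `source_id`
#'   column is carried through.
#' @param range Retention range for logPapp (default `c(-8, -3.5)`).
#' @param kmeans_restarts Restarts for [stats::kmeans()] (default 10).
#' @param seed Seed for k-means initialization.
#' @return List of class `curation_result`: `records` (curated
#'   data.frame with `smiles` standardized, `log_papp`, `label`), and
#'   `report` (class `curation_report`: `n_input`, `n_removed_parse`,
#'   `n_removed_range`, `n_after_standardization`, `threshold`,
#'   `class_counts`).
#' @export
curate_caco2 <- function(records, range = c(-8, -3.5), kmeans_restarts = 10L,
                         seed = 1L) {
  stopifnot(all(c("smiles", "log_papp") %in% names(records)))
  n_input <- nrow(records)
  std <- character(n_input)
  parse_ok <- logical(n_input)
  for (i in seq_len(n_input)) {
    s <- tryCatch(standardize_smiles(largest_fragment(records$smiles[i])),
                  error = function(e) NA_character_)
    parse_ok[i] <- !is.na(s)
    std[i] <- if (parse_ok[i]) s else NA_character_
  }
  n_removed_parse <- sum(!parse_ok)
  kept <- records[parse_ok, , drop = FALSE]
  kept$smiles <- std[parse_ok]
  in_range <- kept$log_papp >= range[1] & kept$log_papp <= range[2]
  n_removed_range <- sum(!in_range)
  kept <- kept[in_range, , drop = FALSE]
  if (length(unique(kept$log_papp)) < 2L) {
    stop("clustering requires at least two distinct logPapp values",
         call. = FALSE)
  }
  if (nrow(kept) == 2L) {
    # k-means degenerates to one point per cluster
    label <- as.integer(kept$log_papp == max(kept$log_papp))
  } else {
    km <- with_seed(seed,
                    stats::kmeans(kept$log_papp, centers = 2L,
                                  nstart = kmeans_restarts))
    upper_cluster <- which.max(km$centers)
    label <- as.integer(km$cluster == upper_cluster)
  }
  threshold <- (max(kept$log_papp[label == 0]) +
                  min(kept$log_papp[label == 1])) / 2
  kept$label <- label
  report <- structure(
    list(n_input = n_input, n_removed_parse = n_removed_parse,
         n_removed_range = n_removed_range,
         n_after_standardization = nrow(kept), threshold = threshold,
         class_counts = c(non_permeable = sum(label == 0),
                          permeable = sum(label == 1))),
    class = "curation_report")
  structure(list(records = kept, report = report), class = "curation_result")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(
    "curation: %d in, %d unparseable, %d out of range, %d retained\n",
    x$n_input, x$n_removed_parse, x$n_removed_range,
    x$n_after_standardization))
  cat(sprintf("k-means threshold: logPapp = %.3f (%d non-permeable, %d permeable)\n",
              x$threshold, x$class_counts[1], x$class_counts[2]))
  invisible(x)
}

# Murcko scaffold of one molecule: iteratively prune terminal (degree-1)
# heavy atoms from the package's graph until only rings and linkers
# remain, then canonicalize the induced subgraph via a generated
# molblock. Acyclic molecules prune to nothing and map to the empty
# scaffold "".
murcko_scaffold <- function(smiles) {
  g <- featurize_molecule(smiles)
  M <- g$n_atoms
  if (M == 1L || nrow(g$bonds) == 0L) return("")
  undirected <- g$bonds[g$bonds[, "src"] < g$bonds[, "dst"], , drop = FALSE]
  # recover bond orders from one-hot bond features (single/double/triple/arom)
  bf <- g$bond_features[g$bonds[, "src"] < g$bonds[, "dst"], , drop = FALSE]
  # V2000 bond orders: 1 single, 2 double, 3 triple, 4 aromatic -
  # matches the one-hot block order directly
  order <- apply(bf[, 1:4, drop = FALSE], 1L, which.max)
  alive <- rep(TRUE, M)
  repeat {
    deg <- integer(M)
    for (i in seq_len(nrow(undirected))) {
      a <- undirected[i, 1L]; b <- undirected[i, 2L]
      if (alive[a] && alive[b]) {
        deg[a] <- deg[a] + 1L
        deg[b] <- deg[b] + 1L
      }
    }
    prune <- alive & deg <= 1L
    if (!any(prune)) break
    alive[prune] <- FALSE
    if (!any(alive)) break
  }
  if (!any(alive)) return("")
  keep_bond <- alive[undirected[, 1L]] & alive[undirected[, 2L]]
  sub_atoms <- which(alive)
  remap <- integer(M); remap[sub_atoms] <- seq_along(sub_atoms)
  na <- length(sub_atoms); nbnd <- sum(keep_bond)
  lines <- c("", " aampnn scaffold", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nbnd))
  for (v in sub_atoms) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$elements[v]))
  }
  for (i in which(keep_bond)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              remap[undirected[i, 1L]],
                              remap[undirected[i, 2L]], order[i]))
  }
  lines <- c(lines, "M  END", "$$$$")
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", paste0(paste(lines, collapse = "\n"), "\n")),
    error = function(e) ""
  )
  out <- trimws(strsplit(trimws(out), "[ \t\n]")[[1]][1])
  if (is.na(out) || !nzchar(out)) "" else out
}

#' Murcko scaffold statistics of a dataset
#'
#' Computes the Murcko scaffold (ring systems plus linkers after removing
#' all substituents) for every molecule; acyclic molecules fall into the
#' empty-scaffold bucket.
#'
#' @param smiles Character vector (invalid entries are skipped and
#'   reported).
#' @return List of class `scaffold_stats`: `scaffolds` (per-molecule
#'   scaffold SMILES, NA where the input failed to parse), `n_unique`
#'   (unique scaffolds including the empty bucket when present),
#'   `counts` (named per-scaffold molecule counts),
#'   `singleton_doubleton_fraction` (fraction of scaffolds backed by only
#'   one or two molecules), `failed`.
#' @export
murcko_scaffold_stats <- function(smiles) {
  sc <- vapply(smiles, function(s) {
    tryCatch(murcko_scaffold(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  failed <- smiles[is.na(sc)]
  ok <- sc[!is.na(sc)]
  counts <- table(ok)
  frac <- if (length(counts)) mean(counts <= 2) else NA_real_
  structure(list(scaffolds = sc, n_unique = length(counts),
                 counts = counts,
                 singleton_doubleton_fraction = frac, failed = failed),
            class = "scaffold_stats")
}

#' Tanimoto leakage screen between two datasets
#'
#' For every molecule in `set_a`, computes its maximum ECFP Tanimoto
#' similarity over `set_b` and flags pairs at or above the threshold
#' (the leakage criterion between a labeled dataset and a pretraining
#' corpus).
#'
#' @param set_a,set_b Character vectors of SMILES (non-empty).
#' @param threshold Flagging threshold (default 0.85).
#' @param radius,n_bits Fingerprint settings.
#' @return List: `max_similarity` (per `set_a` molecule), `flagged`
#'   (data.frame `smiles_a`, `smiles_b`, `similarity` of all pairs >=
#'   threshold).
#' @export
tanimoto_leakage_screen <- function(set_a, set_b, threshold = 0.85,
                                    radius = 2L, n_bits = 2048L) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both SMILES sets must be non-empty", call. = FALSE)
  }
  fa <- lapply(set_a, compute_ecfp, radius = radius, n_bits = n_bits)
  fb <- lapply(set_b, compute_ecfp, radius = radius, n_bits = n_bits)
  Ma <- do.call(rbind, lapply(fa, `[[`, "bits"))
  Mb <- do.call(rbind, lapply(fb, `[[`, "bits"))
  inter <- Ma %*% t(Mb)
  ca <- rowSums(Ma); cb <- rowSums(Mb)
  uni <- outer(ca, cb, `+`) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  hits <- which(sim >= threshold, arr.ind = TRUE)
  flagged <- data.frame(
    smiles_a = set_a[hits[, 1L]], smiles_b = set_b[hits[, 2L]],
    similarity = sim[hits], stringsAsFactors = FALSE)
  list(max_similarity = apply(sim, 1L, max), flagged = flagged)
}
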