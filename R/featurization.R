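# Molecular featurization: SMILES -> directed molecular graph + ECFP.
#
# The one-hot category lists below are the package's documented schema
# (a widely used D-MPNN convention). Each block is either exact one-hot
# or one-hot with a trailing "unknown" bucket; the atom schema carries one
# extra indicator column reserved for the contrastive mask token, so a
# masked atom (all-zero one-hots, indicator = 1) can never collide with a
# valid encoding.

# Element symbols for atomic numbers 1..100.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm"
)

#' Atom feature schema
#'
#' Ordered one-hot blocks encoding an atom: atomic number (1-100 plus an
#' unknown bucket), heavy-atom degree (0-5 plus unknown), formal charge
#' (-2..+2 plus unknown), chirality tag (none / clockwise /
#' counterclockwise / either), bonded-hydrogen count (0-4 plus unknown)
#' and hybridization (SP, SP2, SP3, SP3D, SP3D2 plus unknown), followed by
#' a single mask-indicator column used only by the contrastive mask token.
#'
#' @return An object of class `atom_feature_schema` with elements `blocks`
#'   (named list of category vectors), `has_unknown` (logical per block)
#'   and `total_width` (includes the mask-indicator column).
#' @export
atom_feature_schema <- function() {
  blocks <- list(
    element      = .ELEMENTS,
    degree       = as.character(0:5),
    formal_charge = as.character(-2:2),
    chirality    = c("none", "cw", "ccw", "either"),
    n_hydrogens  = as.character(0:4),
    hybridization = c("SP", "SP2", "SP3", "SP3D", "SP3D2")
  )
  has_unknown <- c(element = TRUE, degree = TRUE, formal_charge = TRUE,
                   chirality = FALSE, n_hydrogens = TRUE, hybridization = TRUE)
  widths <- vapply(blocks, length, 1L) + as.integer(has_unknown)
  structure(
    list(blocks = blocks, has_unknown = has_unknown, widths = widths,
         total_width = sum(widths) + 1L),  # +1 mask indicator
    class = "atom_feature_schema"
  )
}

#' Bond feature schema
#'
#' One-hot blocks for a bond: bond type (single, double, triple,
#' aromatic), a single in-ring flag, and stereo annotation
#' (none / up / down / either).
#'
#' @return An object of class `bond_feature_schema` with `blocks`,
#'   `has_unknown` and `total_width`.
#' @export
bond_feature_schema <- function() {
  blocks <- list(
    bond_type = c("single", "double", "triple", "aromatic"),
    in_ring   = "in_ring",
    stereo    = c("none", "up", "down", "either")
  )
  has_unknown <- c(bond_type = FALSE, in_ring = FALSE, stereo = FALSE)
  widths <- vapply(blocks, length, 1L)
  structure(
    list(blocks = blocks, has_unknown = has_unknown, widths = widths,
         total_width = sum(widths)),
    class = "bond_feature_schema"
  )
}

# Encode one categorical value against a block (one-hot, optionally with
# trailing unknown bucket). Values outside the list land in the unknown
# bucket when present, otherwise in the first category.
one_hot <- function(value, categories, unknown) {
  v <- numeric(length(categories) + as.integer(unknown))
  i <- match(as.character(value), categories)
  if (is.na(i)) {
    if (unknown) v[length(v)] <- 1 else v[1L] <- 1
  } else {
    v[i] <- 1
  }
  v
}

encode_atom_row <- function(schema, element, degree, charge, chirality,
                            n_h, hybridization) {
  vals <- list(element, degree, charge, chirality, n_h, hybridization)
  parts <- mapply(function(val, cats, unk) one_hot(val, cats, unk),
                  vals, schema$blocks, schema$has_unknown, SIMPLIFY = FALSE)
  c(unlist(parts, use.names = FALSE), 0)  # mask indicator off
}

encode_bond_row <- function(schema, type, in_ring, stereo) {
  c(one_hot(type, schema$blocks$bond_type, FALSE),
    as.numeric(in_ring),
    one_hot(stereo, schema$blocks$stereo, FALSE))
}

# ---------------------------------------------------------------------------
# OpenBabel plumbing

ob_options <- function(...) {
  nm <- c(...)
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

# Convert one SMILES to an explicit-hydrogen V2000 molblock. OpenBabel
# signals parse failure by returning (near-)empty output.
smiles_to_molblock <- function(smiles, gen2d = FALSE) {
  opts <- if (gen2d) ob_options("h", "gen2D") else ob_options("h")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"), options = opts),
    error = function(e) ""
  )
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE)) {
    stop(sprintf("cannot parse SMILES: '%s'", smiles), call. = FALSE)
  }
  out
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
      error = function(e) ""
    )
    out <- trimws(out)
    if (!nzchar(out)) stop(sprintf("cannot parse SMILES: '%s'", s), call. = FALSE)
    strsplit(out, "[ \t\n]")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

# MDL charge codes in the atom block: 0 none, 1 +3, 2 +2, 3 +1,
# 4 doublet radical, 5 -1, 6 -2, 7 -3.
.MDL_CHARGE <- c(0, 3, 2, 1, 0, -1, -2, -3)

parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + n_atoms)]
  symbol <- trimws(substr(atom_lines, 32, 34))
  charge_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge_code[is.na(charge_code)] <- 0L
  charge <- .MDL_CHARGE[charge_code + 1L]
  parity <- suppressWarnings(as.integer(substr(atom_lines, 40, 42)))
  parity[is.na(parity)] <- 0L
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  if (n_bonds > 0L) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    b1 <- as.integer(substr(bond_lines, 1, 3))
    b2 <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
    stereo <- suppressWarnings(as.integer(substr(bond_lines, 10, 12)))
    stereo[is.na(stereo)] <- 0L
  } else {
    b1 <- b2 <- order <- stereo <- integer(0)
  }
  # "M  CHG" property lines override atom-block charge codes
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    f <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "[ ]+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) {
      charge[f[2 * i]] <- f[2 * i + 1]
    }
  }
  list(n_atoms = n_atoms, symbol = symbol, charge = charge, parity = parity,
       x = x, y = y, bond_a = b1, bond_b = b2, order = order,
       bond_stereo = stereo)
}

# Ring and aromaticity perception, delegated to ChemmineR's ring finder
# on the same molblock. Returns, per full-molblock atom index pair, the
# set of ring edges and aromatic ring edges (as "u-v" keys with u < v).
perceive_rings <- function(molblock_text) {
  sdf <- suppressWarnings(ChemmineR::read.SDFset(
    ChemmineR::read.SDFstr(strsplit(molblock_text, "\n", fixed = TRUE)[[1]])
  ))[[1]]
  r <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
  ring_keys <- character(0)
  arom_keys <- character(0)
  arom_atoms <- integer(0)
  for (k in seq_along(r$RINGS)) {
    idx <- as.integer(sub("^[^_]+_", "", r$RINGS[[k]]))
    nxt <- c(idx[-1L], idx[1L])
    keys <- paste(pmin(idx, nxt), pmax(idx, nxt), sep = "-")
    ring_keys <- c(ring_keys, keys)
    if (isTRUE(r$AROMATIC[[k]])) {
      arom_keys <- c(arom_keys, keys)
      arom_atoms <- c(arom_atoms, idx)
    }
  }
  list(ring = unique(ring_keys), aromatic = unique(arom_keys),
       aromatic_atoms = unique(arom_atoms))
}

#' Convert a SMILES string to a directed molecular graph
#'
#' Parses the molecule with OpenBabel (hydrogens made explicit for
#' counting, then folded back into the H-count feature), perceives rings
#' and aromaticity, and encodes every heavy atom and every directed bond
#' against the feature schemas. Each chemical bond contributes two
#' directed bonds (v->w and w->v) with identical bond features.
#'
#' @param smiles A single SMILES string.
#' @param atom_schema,bond_schema Feature schemas; defaults are the
#'   package schemas.
#' @return An object of class `mol_graph`: `n_atoms`, `atom_features`
#'   (matrix n_atoms x atom width), `bonds` (2-column matrix of directed
#'   source/target indices), `bond_features`, `reverse_index` (index of
#'   the opposite directed bond), `incoming` (per atom, indices of
#'   directed bonds pointing at it), `elements`, `aromatic`, `in_ring`
#'   (per-atom logicals), `smiles` and `smiles_canonical`.
#' @export
featurize_molecule <- function(smiles,
                               atom_schema = atom_feature_schema(),
                               bond_schema = bond_feature_schema()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mb_text <- smiles_to_molblock(smiles)
  mb <- parse_molblock(mb_text)
  ring_info <- if (length(mb$bond_a) >= 3L) {
    perceive_rings(mb_text)
  } else {
    list(ring = character(0), aromatic = character(0),
         aromatic_atoms = integer(0))
  }
  heavy <- which(mb$symbol != "H")
  if (length(heavy) == 0L) {
    stop(sprintf("molecule has no heavy atoms: '%s'", smiles), call. = FALSE)
  }
  hmap <- integer(mb$n_atoms)          # old index -> heavy index (0 if H)
  hmap[heavy] <- seq_along(heavy)
  M <- length(heavy)

  # Per-heavy-atom tallies from the full (explicit-H) bond list
  n_h <- integer(M)
  degree <- integer(M)
  n_double <- integer(M)
  n_triple <- integer(M)
  hb_a <- integer(0); hb_b <- integer(0); hb_order <- integer(0)
  hb_stereo <- integer(0); hb_key <- character(0)
  for (i in seq_along(mb$bond_a)) {
    u <- mb$bond_a[i]; v <- mb$bond_b[i]
    uh <- mb$symbol[u] != "H"; vh <- mb$symbol[v] != "H"
    if (uh && vh) {
      hb_a <- c(hb_a, hmap[u]); hb_b <- c(hb_b, hmap[v])
      hb_order <- c(hb_order, mb$order[i])
      hb_stereo <- c(hb_stereo, mb$bond_stereo[i])
      hb_key <- c(hb_key, paste(min(u, v), max(u, v), sep = "-"))
      degree[hmap[u]] <- degree[hmap[u]] + 1L
      degree[hmap[v]] <- degree[hmap[v]] + 1L
      if (mb$order[i] == 2L) {
        n_double[hmap[u]] <- n_double[hmap[u]] + 1L
        n_double[hmap[v]] <- n_double[hmap[v]] + 1L
      } else if (mb$order[i] == 3L) {
        n_triple[hmap[u]] <- n_triple[hmap[u]] + 1L
        n_triple[hmap[v]] <- n_triple[hmap[v]] + 1L
      }
    } else if (uh && !vh) {
      n_h[hmap[u]] <- n_h[hmap[u]] + 1L
    } else if (vh && !uh) {
      n_h[hmap[v]] <- n_h[hmap[v]] + 1L
    }
  }

  ring_edge <- hb_key %in% ring_info$ring
  aromatic_edge <- hb_key %in% ring_info$aromatic
  atom_in_ring <- logical(M)
  atom_in_ring[c(hb_a[ring_edge], hb_b[ring_edge])] <- TRUE
  aromatic_atom <- logical(M)
  arom_heavy <- hmap[ring_info$aromatic_atoms]
  aromatic_atom[arom_heavy[arom_heavy > 0L]] <- TRUE

  hybrid <- ifelse(n_triple > 0L | n_double >= 2L, "SP",
            ifelse(n_double == 1L | aromatic_atom, "SP2",
            ifelse(degree + n_h >= 6L, "SP3D2",
            ifelse(degree + n_h == 5L, "SP3D", "SP3"))))
  chirality <- c("none", "cw", "ccw", "either")[
    pmin(mb$parity[heavy], 3L) + 1L]

  X <- matrix(0, M, atom_schema$total_width)
  sym <- mb$symbol[heavy]
  for (v in seq_len(M)) {
    X[v, ] <- encode_atom_row(atom_schema, sym[v], degree[v],
                              mb$charge[heavy][v], chirality[v],
                              min(n_h[v], 4L), hybrid[v])
  }

  nb <- 2L * length(hb_a)
  bonds <- matrix(0L, nb, 2L, dimnames = list(NULL, c("src", "dst")))
  BF <- matrix(0, nb, bond_schema$total_width)
  rev_index <- integer(nb)
  stereo_cat <- ifelse(hb_stereo == 1L, "up",
                ifelse(hb_stereo == 6L, "down",
                ifelse(hb_stereo == 4L, "either", "none")))
  type_cat <- ifelse(aromatic_edge, "aromatic",
              c("single", "double", "triple")[pmin(hb_order, 3L)])
  for (i in seq_along(hb_a)) {
    f <- encode_bond_row(bond_schema, type_cat[i], ring_edge[i], stereo_cat[i])
    j1 <- 2L * i - 1L; j2 <- 2L * i
    bonds[j1, ] <- c(hb_a[i], hb_b[i])
    bonds[j2, ] <- c(hb_b[i], hb_a[i])
    BF[j1, ] <- f; BF[j2, ] <- f
    rev_index[j1] <- j2; rev_index[j2] <- j1
  }
  incoming <- lapply(seq_len(M), function(v) which(bonds[, "dst"] == v))

  structure(
    list(n_atoms = M, atom_features = X, bonds = bonds, bond_features = BF,
         reverse_index = rev_index, incoming = incoming,
         elements = sym, aromatic = aromatic_atom, in_ring = atom_in_ring,
         n_hydrogens = n_h, smiles = smiles,
         smiles_canonical = canonical_smiles(smiles),
         atom_width = atom_schema$total_width,
         bond_width = bond_schema$total_width),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph: %s (%d atoms, %d directed bonds)\n",
              x$smiles_canonical, x$n_atoms, nrow(x$bonds)))
  invisible(x)
}

#' Featurize a batch of SMILES
#'
#' Featurizes each unique SMILES once; unparseable inputs either raise an
#' error or are reported, depending on `on_error`.
#'
#' @param smiles Character vector.
#' @param on_error `"stop"` or `"skip"` (skipped inputs are returned in
#'   the `failed` attribute).
#' @inheritParams featurize_molecule
#' @return A list of `mol_graph` objects, aligned with `smiles`; failed
#'   entries are `NULL` when `on_error = "skip"`.
#' @export
featurize_molecules <- function(smiles, on_error = c("stop", "skip"),
                                atom_schema = atom_feature_schema(),
                                bond_schema = bond_feature_schema()) {
  on_error <- match.arg(on_error)
  uniq <- unique(smiles)
  cache <- vector("list", length(uniq))
  names(cache) <- uniq
  failed <- character(0)
  for (s in uniq) {
    g <- tryCatch(featurize_molecule(s, atom_schema, bond_schema),
                  error = function(e) e)
    if (inherits(g, "error")) {
      if (on_error == "stop") stop(g)
      failed <- c(failed, s)
      cache[[s]] <- list(NULL)  # placeholder, flattened below
    } else {
      cache[[s]] <- g
    }
  }
  out <- lapply(smiles, function(s) {
    g <- cache[[s]]
    if (inherits(g, "mol_graph")) g else NULL
  })
  attr(out, "failed") <- failed
  out
}

# ---------------------------------------------------------------------------
# Fingerprints

#' Extended-connectivity fingerprint (ECFP)
#'
#' Computes OpenBabel's circular ECFP of the requested radius and folds it
#' to `n_bits` by modular OR. Identical molecules (any SMILES ordering)
#' produce identical bit vectors.
#'
#' @param smiles A single SMILES string.
#' @param radius Circular radius (0-5); the default 2 corresponds to ECFP4.
#' @param n_bits Folded fingerprint length (default 2048).
#' @return Object of class `ecfp_fingerprint` with `bits` (0/1 numeric of
#'   length `n_bits`), `radius`, `n_bits`.
#' @export
compute_ecfp <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(length(smiles) == 1L)
  if (!radius %in% 0:5) stop_config("ECFP radius must be in 0..5, got %s", radius)
  if (n_bits < 1L) stop_config("n_bits must be positive")
  can <- canonical_smiles(smiles)  # also validates the input
  mol <- ChemmineOB::forEachMol("SMILES", can, identity)
  raw <- ChemmineOB::fingerprint_OB(mol, sprintf("ECFP%d", 2L * radius))
  raw <- as.numeric(raw)
  bits <- numeric(n_bits)
  on_idx <- which(raw != 0) - 1L
  bits[(on_idx %% n_bits) + 1L] <- 1
  structure(list(bits = bits, radius = as.integer(radius),
                 n_bits = as.integer(n_bits)),
            class = "ecfp_fingerprint")
}

#' Tanimoto similarity between two fingerprints
#'
#' @param fp1,fp2 `ecfp_fingerprint` objects or 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\]; 0 when both fingerprints are empty.
#' @export
tanimoto_similarity <- function(fp1, fp2) {
  b1 <- if (inherits(fp1, "ecfp_fingerprint")) fp1$bits else as.numeric(fp1)
  b2 <- if (inherits(fp2, "ecfp_fingerprint")) fp2$bits else as.numeric(fp2)
  stopifnot(length(b1) == length(b2))
  inter <- sum(b1 > 0 & b2 > 0)
  union <- sum(b1 > 0 | b2 > 0)
  if (union == 0) 0 else inter / union
}
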