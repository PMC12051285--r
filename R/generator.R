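# Synthetic drug-like fixture generator. Molecules are assembled from a
# curated fragment grammar (ring cores with optional substitution sites
# plus a vocabulary of common substituents), so every emitted SMILES is
# valid by construction. The classification task plants a structural
# signal - by default the presence of an aromatic nitrogen, carried by
# the choice of core - so labels are perfectly recoverable by
# substructure matching when label noise is zero. The permeability task
# draws logPapp from a two-component Gaussian mixture emulating the
# bimodal permeable/non-permeable populations seen in Caco-2 data.

# Cores: "{R}" marks an optional substitution site (removed when unused).
.CORES_PLAIN <- c(
  "c1ccc({R})cc1",        # benzene
  "C1CCC({R})CC1",        # cyclohexane
  "C1CC({R})OC1",         # tetrahydrofuran
  "c1cc({R})sc1",         # thiophene
  "c1cc({R})oc1",         # furan
  "C1CC({R})C1",          # cyclobutane
  "c1ccc2cc({R})ccc2c1"   # naphthalene
)
.CORES_AROMATIC_N <- c(
  "c1cc({R})ncc1",        # pyridine
  "c1cnc({R})nc1",        # pyrimidine
  "c1cc({R})[nH]c1",      # pyrrole
  "c1ccc2nc({R})ccc2c1"   # quinoline
)
.SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "CO", "CCO", "OC", "O", "F", "Cl", "Br",
  "C(=O)O", "C(=O)N", "C(F)(F)F", "C#N", "CN(C)C", "OCC", "CC(=O)O",
  "S(=O)(=O)C", "CCN"
)

# Substituents attach through their first atom at the core's bracketed
# site; an unused site is deleted, leaving the bare core.
assemble_smiles <- function(core, substituent) {
  if (is.na(substituent)) {
    sub("\\(\\{R\\}\\)", "", core)
  } else {
    sub("{R}", substituent, core, fixed = TRUE)
  }
}

#' Does a molecule contain an aromatic nitrogen?
#'
#' The default planted substructure of the classification fixture.
#'
#' @param smiles A single SMILES string.
#' @return Logical.
#' @export
has_aromatic_nitrogen <- function(smiles) {
  g <- featurize_molecule(smiles)
  any(g$elements == "N" & g$aromatic)
}

#' Generate a synthetic labeled SMILES fixture
#'
#' Emits valid drug-like SMILES assembled from a fragment grammar.
#' For `task = "classification"` labels mark the presence of the planted
#' substructure (default: an aromatic nitrogen, planted through the
#' choice of ring core), optionally corrupted by label noise. For
#' `task = "permeability"` each molecule receives a logPapp value drawn
#' from a two-component Gaussian mixture.
#'
#' @param n Number of molecules (>= 10).
#' @param seed Integer seed; output is identical run to run.
#' @param task `"classification"` or `"permeability"`.
#' @param label_noise Probability of flipping a classification label
#'   (default 0).
#' @param modes Mixture component means for the permeability task
#'   (default `c(-6.5, -4.5)` log10 cm/s).
#' @param mode_sd Component standard deviation (default 0.3).
#' @param mode_weights Component weights (default equal).
#' @return data.frame with `smiles` plus, depending on task, `label`
#'   (and `true_label` before noise) or `log_papp` (and `component`).
#' @export
generate_fixture <- function(n, seed = 1L,
                             task = c("classification", "permeability"),
                             label_noise = 0, modes = c(-6.5, -4.5),
                             mode_sd = 0.3, mode_weights = c(0.5, 0.5)) {
  task <- match.arg(task)
  if (n < 10L) stop_config("n must be >= 10, got %s", n)
  with_seed(seed, {
    if (task == "classification") {
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      smiles <- character(n)
      for (i in seq_len(n)) {
        core <- if (pos[i]) {
          sample(.CORES_AROMATIC_N, 1L)
        } else {
          sample(.CORES_PLAIN, 1L)
        }
        sub_s <- if (stats::runif(1) < 0.8) sample(.SUBSTITUENTS, 1L) else NA
        smiles[i] <- assemble_smiles(core, sub_s)
      }
      true_label <- as.integer(pos)
      label <- true_label
      if (label_noise > 0) {
        flip <- stats::runif(n) < label_noise
        label[flip] <- 1L - label[flip]
      }
      data.frame(smiles = smiles, label = label, true_label = true_label,
                 stringsAsFactors = FALSE)
    } else {
      comp <- sample(seq_along(modes), n, replace = TRUE,
                     prob = mode_weights)
      smiles <- character(n)
      for (i in seq_len(n)) {
        core <- sample(c(.CORES_PLAIN, .CORES_AROMATIC_N), 1L)
        sub_s <- if (stats::runif(1) < 0.8) sample(.SUBSTITUENTS, 1L) else NA
        smiles[i] <- assemble_smiles(core, sub_s)
      }
      data.frame(smiles = smiles,
                 log_papp = stats::rnorm(n, modes[comp], mode_sd),
                 component = comp, stringsAsFactors = FALSE)
    }
  })
}
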