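# Synthetic interaction datasets with a planted structure-activity signal.
#
# The generator emulates the shape of a ChEMBL-style IC50 interaction
# table: short valid SMILES, protein sequences over the 20 standard amino
# acids, and approximately normal pIC50 labels (mean ~6, sd ~1.3) whose
# signal is a linear function of graph- and sequence-derived descriptors
# plus one graph x sequence interaction term, plus Gaussian noise.

.hydrophobic_residues <- c("A", "V", "L", "I", "M", "F", "W", "Y")
.standard_residues <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Synthetic dataset configuration
#'
#' @param n_records Number of interaction records.
#' @param n_targets Number of distinct protein targets.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @param noise_sd Standard deviation of the Gaussian label noise, on the
#'   scale of the standardized planted signal (before the final shift and
#'   scale to pIC50 range).
#' @param seq_len_range Length-2 integer vector; target sequence lengths
#'   are uniform in this range (minimum 10).
#' @param signal_weights Length-6 coefficient vector `(w0, w1..w5)` of the
#'   planted mechanism: intercept, z(heavy atoms), z(aromatic fraction),
#'   z(heteroatom count), z(target hydrophobic fraction), and the
#'   z(heavy atoms) x z(hydrophobic fraction) interaction.
#' @param label_mean,label_sd Location and scale of the final pIC50 labels.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_records = 2000L, n_targets = 25L, seed = 1L,
                         noise_sd = 0.5,
                         seq_len_range = c(100L, 2500L),
                         signal_weights = c(0, 0.8, 0.5, 0.5, 0.6, 0.4),
                         label_mean = 6, label_sd = 1.3) {
  stopifnot(
    n_records >= 1, n_targets >= 1, noise_sd >= 0,
    length(seq_len_range) == 2, seq_len_range[1] >= 10,
    seq_len_range[2] >= seq_len_range[1],
    length(signal_weights) == 6
  )
  structure(
    list(
      n_records = as.integer(n_records), n_targets = as.integer(n_targets),
      seed = as.integer(seed), noise_sd = noise_sd,
      seq_len_range = as.integer(seq_len_range),
      signal_weights = as.numeric(signal_weights),
      label_mean = label_mean, label_sd = label_sd
    ),
    class = "synth_config"
  )
}

#' Draw one random valid SMILES string
#'
#' Samples from a restricted generative grammar: a linear or branched
#' carbon chain with substituents from {N, O, F, Cl} and an optional
#' single benzene ring, guaranteeing 2-40 heavy atoms and parseability by
#' [smiles_to_graph()].  Consumes the current RNG state.
#'
#' @return A single SMILES string.
#' @export
generate_smiles <- function() {
  chain_len <- sample(2:8, 1)
  subs <- c("N", "O", "F", "Cl")
  atoms <- rep("C", chain_len)
  out <- character(0)
  has_ring <- stats::runif(1) < 0.4
  ring_pos <- if (has_ring) sample(chain_len, 1) else 0L
  for (i in seq_len(chain_len)) {
    out <- c(out, atoms[i])
    branches <- character(0)
    if (i == ring_pos) branches <- c(branches, "c1ccccc1")
    n_sub <- stats::rbinom(1, 2, 0.25)
    # interior chain carbons have 2 chain bonds; cap substituents at
    # free valence
    free <- 4L - (if (i == 1 || i == chain_len) 1L else 2L) - length(branches)
    n_sub <- min(n_sub, max(0L, free))
    if (n_sub > 0) branches <- c(branches, sample(subs, n_sub, replace = TRUE))
    if (length(branches) > 0) {
      out <- c(out, paste0("(", branches, ")"))
    }
  }
  paste(out, collapse = "")
}

# Count heavy atoms / aromatic atoms / heteroatoms directly from a grammar
# SMILES (the grammar has no hydrogens, charges, or multi-letter organic
# subset elements other than Cl).
.grammar_descriptors <- function(smiles) {
  tokens <- gregexpr("Cl|c|C|N|O|F", smiles)[[1]]
  syms <- regmatches(smiles, gregexpr("Cl|c|C|N|O|F", smiles))[[1]]
  heavy <- length(syms)
  aromatic <- sum(syms == "c")
  hetero <- sum(syms %in% c("N", "O", "F", "Cl"))
  c(heavy_atoms = heavy, aromatic_fraction = aromatic / heavy, heteroatoms = hetero)
}

.random_sequence <- function(len, hydrophobic_prop) {
  other <- setdiff(.standard_residues, .hydrophobic_residues)
  w <- ifelse(.standard_residues %in% .hydrophobic_residues,
    hydrophobic_prop / length(.hydrophobic_residues),
    (1 - hydrophobic_prop) / length(other)
  )
  paste(sample(.standard_residues, len, replace = TRUE, prob = w), collapse = "")
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

# Shared deterministic core: descriptors, standardized signal, and record
# table (without labels), all under cfg$seed.
.synth_core <- function(cfg) {
  with_seed(cfg$seed, {
    # targets differ in hydrophobic-residue propensity so that sequence
    # composition carries learnable between-target signal
    target_prop <- stats::runif(cfg$n_targets, 0.25, 0.55)
    target_len <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2],
      cfg$n_targets,
      replace = TRUE
    )
    target_seq <- vapply(
      seq_len(cfg$n_targets),
      function(t) .random_sequence(target_len[t], target_prop[t]),
      character(1)
    )
    smiles <- vapply(seq_len(cfg$n_records), function(i) generate_smiles(), character(1))
    target_of <- sample.int(cfg$n_targets, cfg$n_records, replace = TRUE)

    desc <- t(vapply(smiles, .grammar_descriptors, numeric(3)))
    hyd_frac <- vapply(
      target_seq,
      function(s) {
        ch <- strsplit(s, "")[[1]]
        mean(ch %in% .hydrophobic_residues)
      },
      numeric(1)
    )[target_of]

    z1 <- .zscore(desc[, "heavy_atoms"])
    z2 <- .zscore(desc[, "aromatic_fraction"])
    z3 <- .zscore(desc[, "heteroatoms"])
    z4 <- .zscore(hyd_frac)
    w <- cfg$signal_weights
    signal <- w[1] + w[2] * z1 + w[3] * z2 + w[4] * z3 + w[5] * z4 +
      w[6] * z1 * z4
    noise <- stats::rnorm(cfg$n_records, 0, cfg$noise_sd)
    list(
      smiles = smiles, target_of = target_of, target_seq = target_seq,
      descriptors = cbind(desc, hydrophobic_fraction = hyd_frac),
      signal = signal, noise = noise
    )
  })
}

#' Generate a synthetic interaction dataset
#'
#' @param cfg A [synth_config()].
#' @return A tibble with columns `smiles`, `target_id`, `sequence`,
#'   `pic50`, carrying the generating `synth_config` as attribute
#'   `"config"` and the descriptor matrix as attribute `"descriptors"`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  core <- .synth_core(cfg)
  raw <- core$signal + core$noise
  s <- stats::sd(raw)
  labels <- if (cfg$n_records > 1 && s > 0) {
    cfg$label_mean + cfg$label_sd * (raw - mean(raw)) / s
  } else {
    rep(cfg$label_mean, cfg$n_records)
  }
  out <- tibble::tibble(
    smiles = unname(core$smiles),
    target_id = sprintf("T%03d", core$target_of),
    sequence = unname(core$target_seq[core$target_of]),
    pic50 = unname(labels)
  )
  attr(out, "config") <- cfg
  attr(out, "descriptors") <- core$descriptors
  out
}

#' Best achievable R-squared of a synthetic configuration
#'
#' The planted labels are an affine transform of `signal + noise`, and
#' affine transforms leave R-squared invariant, so the ceiling for any
#' predictor is `var(signal) / (var(signal) + noise_sd^2)`, evaluated on
#' the dataset the configuration generates.
#'
#' @param cfg A [synth_config()].
#' @return The oracle R-squared in `[0, 1]`.
#' @export
oracle_r2 <- function(cfg = synth_config()) {
  if (cfg$noise_sd == 0) return(1)
  core <- .synth_core(cfg)
  v <- stats::var(core$signal)
  v / (v + cfg$noise_sd^2)
}

#' Noise level that yields a requested oracle R-squared
#'
#' Inverts [oracle_r2()]: returns the `noise_sd` for which the
#' configuration's planted-signal variance gives the requested ceiling.
#'
#' @param cfg A [synth_config()] (its `noise_sd` is ignored).
#' @param r2 Target oracle R-squared in (0, 1).
#' @return The required `noise_sd`.
#' @export
noise_for_oracle_r2 <- function(cfg, r2) {
  stopifnot(r2 > 0, r2 < 1)
  core <- .synth_core(cfg)
  sqrt(stats::var(core$signal) * (1 - r2) / r2)
}
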