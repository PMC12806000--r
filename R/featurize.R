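# Featurization: SMILES -> molecular graph, amino-acid sequence -> integer
# tokens.  The cheminformatics backend is OpenBabel via ChemmineOB; its MOL
# and molreport outputs are read directly so that single-heavy-atom
# molecules (e.g. methane) are handled.

# Default 44-symbol element vocabulary used by graph-based DTA models;
# the final entry is the catch-all bucket for unlisted elements.
.default_elements <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "Unknown"
)

#' Atom feature encoding scheme
#'
#' Describes the per-atom feature vector used by [smiles_to_graph()]: an
#' element one-hot block, a degree one-hot block, a hydrogen-count one-hot
#' block, an implicit-valence one-hot block, and a single aromaticity flag.
#' Values beyond a block's maximum map to the block's final bucket, so each
#' one-hot block always sums to exactly 1.
#'
#' @param element_vocabulary Ordered character vector of element symbols;
#'   atoms whose element is not listed map to the final entry.
#' @param max_degree,max_hydrogens,max_implicit_valence Upper bound of the
#'   corresponding one-hot block (each block has `max + 1` buckets).
#' @return An object of class `atom_feature_scheme` with a `$n_features`
#'   field giving the encoded length
#'   `|elements| + (max_degree+1) + (max_hydrogens+1) + (max_implicit_valence+1) + 1`.
#'   The default scheme is 78-dimensional.
#' @examples
#' scheme <- atom_feature_scheme()
#' scheme$n_features
#' @export
atom_feature_scheme <- function(element_vocabulary = .default_elements,
                                max_degree = 10L,
                                max_hydrogens = 10L,
                                max_implicit_valence = 10L) {
  stopifnot(length(element_vocabulary) >= 1, !anyDuplicated(element_vocabulary))
  scheme <- list(
    element_vocabulary = as.character(element_vocabulary),
    max_degree = as.integer(max_degree),
    max_hydrogens = as.integer(max_hydrogens),
    max_implicit_valence = as.integer(max_implicit_valence)
  )
  scheme$n_features <- length(scheme$element_vocabulary) +
    (scheme$max_degree + 1L) + (scheme$max_hydrogens + 1L) +
    (scheme$max_implicit_valence + 1L) + 1L
  structure(scheme, class = "atom_feature_scheme")
}

# Usual valences used to infer implicit hydrogen counts from kekulized
# bond orders; elements not listed get no implicit hydrogens.
.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, As = 3, Se = 2, Br = 1, I = 1
)

# Parse the V2000 MOL block emitted by OpenBabel: atoms (element symbol,
# formal charge) and bonds (1-based endpoints, kekulized order).
.parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1) return(NULL)
  atom_lines <- lines[4 + seq_len(n_atoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(n_atoms)
  bonds <- NULL
  if (!is.na(n_bonds) && n_bonds > 0) {
    bond_lines <- lines[4 + n_atoms + seq_len(n_bonds)]
    bonds <- cbind(
      from = as.integer(substr(bond_lines, 1, 3)),
      to = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)), " +")[[1]])
    if (length(f) >= 2) {
      idx <- f[seq(1, length(f), by = 2)]
      chg <- f[seq(2, length(f), by = 2)]
      charge[idx] <- chg
    }
  }
  list(element = element, charge = charge, bonds = bonds)
}

# Aromatic-atom flags from OpenBabel's molreport atom types (Car, Nar, ...).
.aromatic_flags <- function(report, n_atoms) {
  lines <- strsplit(report, "\n", fixed = TRUE)[[1]]
  atom_lines <- grep("^ATOM:", lines, value = TRUE)
  types <- sub(".*TYPE: *([^ ]+).*", "\\1", atom_lines)
  flags <- endsWith(types, "ar")
  if (length(flags) < n_atoms) flags <- c(flags, rep(FALSE, n_atoms - length(flags)))
  flags[seq_len(n_atoms)]
}

.one_hot <- function(value, n_buckets) {
  v <- numeric(n_buckets)
  v[min(value, n_buckets - 1L) + 1L] <- 1
  v
}

#' Convert a SMILES string to a molecular graph
#'
#' Parses the SMILES with the OpenBabel backend and returns one node per
#' heavy atom (hydrogens are implicit) with a symmetric 0-based edge pair
#' per chemical bond.  Node features follow `scheme`: element one-hot,
#' heavy-atom degree one-hot, total hydrogen count one-hot, implicit
#' valence one-hot, aromaticity flag.
#'
#' @param smiles A single SMILES string.
#' @param scheme An [atom_feature_scheme()].
#' @return An object of class `molecular_graph` with fields
#'   `node_features` (N x C matrix), `edges` (m x 2 integer matrix of
#'   0-based directed pairs; both directions of every bond are present),
#'   `n_nodes`, and `smiles`.
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$n_nodes          # 6
#' nrow(g$edges)      # 12
#' @export
smiles_to_graph <- function(smiles, scheme = atom_feature_scheme()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- tryCatch(
    .parse_molblock(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) NULL
  )
  if (is.null(mol)) {
    stop_invalid(sprintf("unparseable SMILES: '%s'", smiles), smiles = smiles)
  }
  report <- tryCatch(
    ChemmineOB::convertFormat("SMI", "molreport", smiles),
    error = function(e) ""
  )
  aromatic <- .aromatic_flags(report, length(mol$element))

  heavy <- which(mol$element != "H")
  if (length(heavy) == 0) {
    stop_invalid(sprintf("SMILES has no heavy atoms: '%s'", smiles),
      smiles = smiles
    )
  }
  n_all <- length(mol$element)
  new_index <- rep(NA_integer_, n_all)
  new_index[heavy] <- seq_along(heavy)

  order_sum <- numeric(n_all)
  explicit_h <- integer(n_all)
  degree <- integer(n_all)
  edges <- matrix(integer(0), ncol = 2)
  if (!is.null(mol$bonds)) {
    b <- mol$bonds
    for (r in seq_len(nrow(b))) {
      i <- b[r, "from"]; j <- b[r, "to"]; o <- b[r, "order"]
      order_sum[i] <- order_sum[i] + o
      order_sum[j] <- order_sum[j] + o
      if (mol$element[i] == "H") explicit_h[j] <- explicit_h[j] + 1L
      if (mol$element[j] == "H") explicit_h[i] <- explicit_h[i] + 1L
    }
    hb <- b[mol$element[b[, "from"]] != "H" & mol$element[b[, "to"]] != "H", ,
      drop = FALSE
    ]
    if (nrow(hb) > 0) {
      i0 <- new_index[hb[, "from"]] - 1L
      j0 <- new_index[hb[, "to"]] - 1L
      edges <- cbind(c(i0, j0), c(j0, i0))
      degree_tab <- table(factor(c(i0, j0), levels = 0:(length(heavy) - 1L)))
      degree[heavy] <- as.integer(degree_tab)
    }
  }

  nf <- matrix(0, nrow = length(heavy), ncol = scheme$n_features)
  vocab <- scheme$element_vocabulary
  for (k in seq_along(heavy)) {
    a <- heavy[k]
    el <- mol$element[a]
    el_idx <- match(el, vocab)
    if (is.na(el_idx)) el_idx <- length(vocab)
    dv <- .default_valence[el]
    if (is.na(dv)) dv <- order_sum[a]
    implicit_h <- max(0, dv + mol$charge[a] - order_sum[a])
    total_h <- implicit_h + explicit_h[a]
    row <- c(
      .one_hot(el_idx - 1L, length(vocab)),
      .one_hot(degree[a], scheme$max_degree + 1L),
      .one_hot(total_h, scheme$max_hydrogens + 1L),
      .one_hot(implicit_h, scheme$max_implicit_valence + 1L),
      as.numeric(aromatic[a])
    )
    nf[k, ] <- row
  }
  structure(
    list(
      node_features = nf,
      edges = edges,
      n_nodes = length(heavy),
      smiles = smiles
    ),
    class = "molecular_graph"
  )
}

#' Protein sequence vocabulary
#'
#' Maps amino-acid one-letter codes to integer indices `1..V`; index 0 is
#' reserved for padding.  The default vocabulary is the 25-letter extended
#' amino-acid alphabet (standard residues plus ambiguity codes, no 'J').
#'
#' @param symbols String of allowed characters, in index order.
#' @param unknown_policy `"map_to_X"` substitutes unknown characters by the
#'   index of `'X'`; `"error"` raises an invalid-input error naming the
#'   character and its position.
#' @return An object of class `protein_vocabulary`.
#' @export
protein_vocabulary <- function(symbols = "ABCDEFGHIKLMNOPQRSTUVWXYZ",
                               unknown_policy = c("map_to_X", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  chars <- strsplit(symbols, "")[[1]]
  stopifnot(!anyDuplicated(chars))
  if (unknown_policy == "map_to_X" && !("X" %in% chars)) {
    stop_config("unknown_policy 'map_to_X' requires 'X' in the vocabulary")
  }
  structure(
    list(symbols = chars, size = length(chars), unknown_policy = unknown_policy),
    class = "protein_vocabulary"
  )
}

#' Encode a protein sequence as fixed-length integer tokens
#'
#' Uppercases the sequence, maps each character to its 1-based vocabulary
#' index, truncates to the first `L` characters, and pads with trailing
#' zeros up to length `L`.
#'
#' @param sequence A single non-empty amino-acid string.
#' @param vocab A [protein_vocabulary()].
#' @param L Fixed output length (default 1000, the model input size).
#' @return Object of class `protein_tokens`: fields `tokens` (integer
#'   vector of length `L`) and `original_length`.
#' @examples
#' encode_protein("ACD", L = 6)$tokens # 1 3 4 0 0 0
#' @export
encode_protein <- function(sequence, vocab = protein_vocabulary(), L = 1000L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1) stop_invalid("protein sequence must be non-empty")
  if (L < 1) stop_invalid("L must be >= 1")
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, vocab$symbols)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    if (vocab$unknown_policy == "error") {
      stop_invalid(sprintf(
        "character '%s' at position %d is not in the protein vocabulary",
        chars[bad[1]], bad[1]
      ))
    }
    idx[bad] <- match("X", vocab$symbols)
  }
  tokens <- integer(L)
  keep <- seq_len(min(length(idx), L))
  tokens[keep] <- idx[keep]
  structure(
    list(tokens = tokens, original_length = length(chars)),
    class = "protein_tokens"
  )
}

#' Featurize a table of interaction records
#'
#' Converts every record's SMILES to a molecular graph and its sequence to
#' protein tokens, preserving order.  If any record fails, an aggregated
#' invalid-input error lists every failing record index.
#'
#' @param records A data frame with columns `smiles`, `sequence`, `pic50`
#'   (as produced by [load_interactions()] or [generate_dataset()]).
#' @param scheme An [atom_feature_scheme()].
#' @param vocab A [protein_vocabulary()].
#' @param L Protein token length.
#' @param smiles_tokens Also encode each SMILES as character tokens (the
#'   input format of the convolutional two-branch model).
#' @param smiles_len SMILES token length.
#' @param smiles_vocab A [smiles_vocabulary()]; default is built from the
#'   records' own SMILES.
#' @return A list with elements `graphs` (list of `molecular_graph`),
#'   `tokens` (integer matrix, one row per record), `labels` (numeric),
#'   `scheme`, `vocab`, `L`, and — when requested — `smiles_tokens` and
#'   `smiles_vocab`.
#' @export
featurize_dataset <- function(records, scheme = atom_feature_scheme(),
                              vocab = protein_vocabulary(), L = 1000L,
                              smiles_tokens = FALSE, smiles_len = 100L,
                              smiles_vocab = NULL) {
  n <- nrow(records)
  graphs <- vector("list", n)
  tokens <- matrix(0L, nrow = n, ncol = L)
  failed <- integer(0)
  graph_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    smi <- records$smiles[i]
    g <- if (!is.null(graph_cache[[smi]])) {
      graph_cache[[smi]]
    } else {
      gi <- tryCatch(smiles_to_graph(smi, scheme), dta_invalid_input = function(e) NULL)
      if (!is.null(gi)) graph_cache[[smi]] <- gi
      gi
    }
    tk <- tryCatch(encode_protein(records$sequence[i], vocab, L),
      dta_invalid_input = function(e) NULL
    )
    if (is.null(g) || is.null(tk)) {
      failed <- c(failed, i)
    } else {
      graphs[[i]] <- g
      tokens[i, ] <- tk$tokens
    }
  }
  if (length(failed) > 0) {
    stop_invalid(
      sprintf(
        "featurization failed for %d record(s) at indices: %s",
        length(failed), paste(failed, collapse = ", ")
      ),
      indices = failed
    )
  }
  out <- list(
    graphs = graphs, tokens = tokens,
    labels = as.numeric(records$pic50 %||% rep(NA_real_, n)),
    scheme = scheme, vocab = vocab, L = as.integer(L)
  )
  if (smiles_tokens) {
    out$smiles_vocab <- smiles_vocab %||% smiles_vocabulary(records$smiles)
    out$smiles_tokens <- encode_smiles_matrix(
      records$smiles, out$smiles_vocab, smiles_len
    )
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' Target identifiers are the first whitespace-delimited token of each
#' header; wrapped sequence lines are concatenated.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `target_id` and `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    target_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}
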