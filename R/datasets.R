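# Interaction tables, the pIC50 transform, and seeded splitting.

#' Convert IC50 to pIC50
#'
#' `pIC50 = -log10(IC50)` with the concentration expressed in molar units.
#' With `units = "raw"` the value is transformed verbatim (no unit
#' conversion), which is the literal form of the transform; ChEMBL exports
#' are typically nanomolar.
#'
#' @param ic50 Positive numeric vector of IC50 values.
#' @param units One of `"molar"`, `"micromolar"`, `"nanomolar"`, `"raw"`.
#' @return Numeric vector of pIC50 values.
#' @examples
#' to_pic50(1000, "nanomolar") # 6
#' to_pic50(1, "raw") # 0
#' @export
to_pic50 <- function(ic50, units = c("molar", "micromolar", "nanomolar", "raw")) {
  units <- match.arg(units)
  if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop_invalid("ic50 must be finite and > 0")
  }
  factor <- switch(units,
    molar = 1, micromolar = 1e-6, nanomolar = 1e-9, raw = 1
  )
  -log10(ic50 * factor)
}

#' Load an interaction table from CSV
#'
#' Reads a CSV of interaction records, maps columns to the canonical names,
#' applies the pIC50 transform where needed, and drops rows that carry
#' neither a usable IC50 nor a pIC50.  A load report (rows kept / dropped
#' and the reasons) is emitted as a message.
#'
#' @param path CSV file with a header row.
#' @param column_map Named list mapping canonical names (`smiles`,
#'   `target_id`, `sequence`, `ic50`, `pic50`) to the file's column names;
#'   `target_id`, and either `ic50` or `pic50`, may be absent.
#' @param units IC50 units passed to [to_pic50()]; required when an `ic50`
#'   column is mapped.
#' @param fasta Optional FASTA file supplying sequences joined on
#'   `target_id` when the CSV has no sequence column.
#' @return A tibble with columns `smiles`, `target_id`, `sequence`, `pic50`.
#' @export
load_interactions <- function(path,
                              column_map = list(
                                smiles = "smiles", target_id = "target_id",
                                sequence = "sequence", ic50 = "ic50",
                                pic50 = "pic50"
                              ),
                              units = "nanomolar",
                              fasta = NULL) {
  if (!file.exists(path)) stop_config(sprintf("input CSV not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  get_col <- function(name) {
    col <- column_map[[name]]
    if (is.null(col) || !(col %in% names(df))) NULL else df[[col]]
  }
  smiles <- get_col("smiles")
  if (is.null(smiles)) {
    stop_config(sprintf(
      "mapped smiles column '%s' not present in %s",
      column_map$smiles %||% "smiles", path
    ))
  }
  n <- length(smiles)
  target_id <- get_col("target_id") %||% rep(NA_character_, n)
  sequence <- get_col("sequence")
  if (is.null(sequence)) {
    if (is.null(fasta)) {
      stop_config("CSV has no sequence column and no FASTA file was given")
    }
    fa <- read_fasta_sequences(fasta)
    sequence <- fa$sequence[match(target_id, fa$target_id)]
  }
  ic50 <- suppressWarnings(as.numeric(get_col("ic50") %||% rep(NA_real_, n)))
  pic50 <- suppressWarnings(as.numeric(get_col("pic50") %||% rep(NA_real_, n)))
  if (all(is.na(ic50)) && all(is.na(pic50))) {
    stop_config("neither an ic50 nor a pic50 column could be mapped")
  }

  need_transform <- is.na(pic50) & !is.na(ic50) & ic50 > 0
  pic50[need_transform] <- to_pic50(ic50[need_transform], units)
  bad_affinity <- is.na(pic50)
  bad_sequence <- is.na(sequence) | !nzchar(sequence)
  keep <- !bad_affinity & !bad_sequence
  message(sprintf(
    "loaded %d rows: kept %d, dropped %d (missing/non-positive affinity: %d, missing sequence: %d)",
    n, sum(keep), sum(!keep), sum(bad_affinity), sum(bad_sequence & !bad_affinity)
  ))
  if (n == 0) warning("input CSV has a header but no data rows")
  tibble::tibble(
    smiles = smiles[keep],
    target_id = as.character(target_id)[keep],
    sequence = as.character(sequence)[keep],
    pic50 = pic50[keep]
  )
}

#' Write an interaction table to canonical CSV
#'
#' @param records Tibble with columns `smiles`, `target_id`, `sequence`, `pic50`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  utils::write.csv(
    records[, c("smiles", "target_id", "sequence", "pic50")],
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Seeded train/test split
#'
#' Draws a uniform random permutation under `seed` and assigns the first
#' `floor(ratio * n)` (at least 1) indices to the training set.
#'
#' @param n Number of records (>= 2).
#' @param ratio Training fraction in (0, 1); default 0.8 for an 80:20 split.
#' @param seed Integer seed; the split is deterministic given `(n, ratio, seed)`.
#' @return Object of class `dataset_split` with `train_indices`,
#'   `test_indices` (1-based), `seed`, `ratio`.
#' @export
split_dataset <- function(n, ratio = 0.8, seed = 1L) {
  if (!is.numeric(n) || n < 2) stop_invalid("n must be >= 2")
  if (ratio <= 0 || ratio >= 1) stop_invalid("ratio must be in (0, 1)")
  perm <- with_seed(seed, sample.int(n))
  n_train <- max(1L, floor(ratio * n))
  structure(
    list(
      train_indices = sort(perm[seq_len(n_train)]),
      test_indices = sort(perm[(n_train + 1L):n]),
      seed = as.integer(seed), ratio = ratio
    ),
    class = "dataset_split"
  )
}

#' Seeded balanced k-fold assignment
#'
#' Assigns each training index to one of `k` folds of near-equal size
#' (sizes differ by at most 1), deterministically under `seed`.
#'
#' @param train_indices Integer vector of indices to fold.
#' @param k Number of folds (>= 2); default 10.
#' @param seed Integer seed.
#' @return Object of class `fold_assignment` with `k`, `fold_of` (integer
#'   vector in `0:(k-1)` aligned with `train_indices`), `train_indices`,
#'   `seed`.
#' @export
kfold <- function(train_indices, k = 10L, seed = 1L) {
  m <- length(train_indices)
  if (k < 2) stop_invalid("k must be >= 2")
  if (m < k) stop_invalid("need at least k training indices")
  perm <- with_seed(seed, sample.int(m))
  fold_of <- integer(m)
  fold_of[perm] <- rep_len(0:(k - 1L), m)
  structure(
    list(
      k = as.integer(k), fold_of = fold_of,
      train_indices = train_indices, seed = as.integer(seed)
    ),
    class = "fold_assignment"
  )
}

#' Iterate the (fit, held-out) partitions of a fold assignment
#'
#' @param folds A [kfold()] result.
#' @return List of `k` lists with elements `fit` and `held_out`, each a
#'   vector of original record indices.
#' @export
fold_partitions <- function(folds) {
  lapply(0:(folds$k - 1L), function(f) {
    list(
      fit = folds$train_indices[folds$fold_of != f],
      held_out = folds$train_indices[folds$fold_of == f]
    )
  })
}
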