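# Synthetic fixtures: geometrically plausible pockets (helix-like backbone
# trace) and a small conditioned SMILES corpus with computable properties and
# pseudo docking scores.  Everything is bit-reproducible per seed; nothing
# external is required to build or test the package.

#' Generate a synthetic pocket
#'
#' Residues lie on a helix-like backbone trace (rise ~1.5 A, ~100 degrees of
#' turn per residue, radius 2.3 A); each residue gets 4-8 atoms within 1.5 A
#' of its backbone point, the first four flagged as backbone (N, CA, C, O
#' elements N/C/C/O), side-chain elements drawn from C/N/O/S with
#' protein-like frequencies.
#'
#' @param seed integer seed (deterministic output).
#' @param n_residues number of residues (>= 2).
#' @return a `PocketStructure`.
#' @export
make_pocket_fixture <- function(seed, n_residues = 12L) {
  stopifnot(n_residues >= 2L)
  with_local_seed(seed, {
    residues <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      theta <- (i - 1L) * 100 * pi / 180
      base <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1L))
      n_atoms <- sample(4:8, 1L)
      el <- c("N", "C", "C", "O",
              sample(c("C", "N", "O", "S"), n_atoms - 4L, replace = TRUE,
                     prob = c(0.70, 0.12, 0.14, 0.04)))
      offs <- matrix(stats::runif(n_atoms * 3L, -1, 1), n_atoms, 3L)
      nrm <- sqrt(rowSums(offs^2))
      offs <- offs / nrm * stats::runif(n_atoms, 0.3, 1.5)
      coords <- sweep(offs, 2L, base, `+`)
      residues[[i]] <- list(
        residue_type = sample(AA3, 1L),
        atoms = data.frame(
          element = el,
          x = coords[, 1], y = coords[, 2], z = coords[, 3],
          mass = unname(ATOMIC_MASS[el]),
          is_backbone = c(rep(TRUE, 4L), rep(FALSE, n_atoms - 4L)),
          stringsAsFactors = FALSE))
    }
    pocket_structure(residues)
  })
}

# One synthetic linear-chain SMILES: C/O/N backbone, first and last atoms
# carbon, no adjacent heteroatoms; `with_nitrogen` forces >= 1 N.
random_chain_smiles <- function(len, with_nitrogen) {
  stopifnot(len >= 3L)
  atoms <- rep("C", len)
  # interior positions eligible for heteroatoms, keeping them non-adjacent
  slots <- seq(2L, len - 1L, by = 2L)
  n_het <- sample(0:min(length(slots), 3L), 1L)
  het_pos <- if (n_het > 0L) sample(slots, n_het) else integer(0)
  if (length(het_pos) > 0L)
    atoms[het_pos] <- sample(c("O", "N"), length(het_pos), replace = TRUE)
  if (with_nitrogen && !"N" %in% atoms) {
    pos <- if (length(het_pos) > 0L) het_pos[sample.int(length(het_pos), 1L)]
    else slots[sample.int(length(slots), 1L)]
    atoms[pos] <- "N"
  } else if (!with_nitrogen) {
    atoms[atoms == "N"] <- "O"
  }
  paste(atoms, collapse = "")
}

#' Generate a conditioned training corpus
#'
#' Emits `n_records` valid linear alkane/alcohol/amine/ether SMILES (3-12
#' heavy atoms).  The hard affinity bit is made learnable: molecules
#' containing nitrogen receive pseudo docking scores around -8 kcal/mol,
#' others around -5 (sd 0.2), so binarization at -7.5 recovers the
#' nitrogen rule for ~99% of records.  The conditioning vector is
#' (affinity bit, heavy-atom count).  Records are assigned round-robin to a
#' pool of fixture pockets sized at about one pocket per 34 records,
#' mirroring a realistic pair:pocket ratio.
#'
#' @param seed integer seed.
#' @param n_records number of records (>= 20).
#' @param n_pockets pocket pool size (default scales with `n_records`).
#' @return list: `records` ([molecule_record()]s with `y`), `pocket_ids`,
#'   `pockets` (list of `PocketStructure`s), `schema`, `vocab`
#'   (built from the emitted SMILES), `smiles`.
#' @export
make_conditioned_corpus <- function(seed, n_records = 200L,
                                    n_pockets = NULL) {
  stopifnot(n_records >= 20L)
  n_pockets <- n_pockets %||% max(2L, round(n_records / 34))
  schema <- property_schema(hard_property("affinity", -7.5, "le"),
                            soft_property("heavy_atoms"))
  with_local_seed(seed, {
    pockets <- lapply(seq_len(n_pockets), function(i)
      make_pocket_fixture((seed %% 1000000L) * 1000L + i,
                          n_residues = sample(8:14, 1L)))
    smiles <- character(n_records)
    scores <- numeric(n_records)
    has_n <- stats::rbinom(n_records, 1L, 0.5) == 1L
    for (i in seq_len(n_records)) {
      smiles[i] <- random_chain_smiles(sample(3:12, 1L), has_n[i])
      h <- as.numeric(grepl("N", smiles[i], fixed = TRUE))
      scores[i] <- -5 - 3 * h + stats::rnorm(1L, 0, 0.2)
    }
    vocab <- build_vocabulary(smiles, target_size = 110L)
    records <- lapply(seq_len(n_records), function(i) {
      y <- c(binarize_property(scores[i], schema[[1]]), nchar(smiles[i]))
      molecule_record(smiles[i], tokenize(smiles[i], vocab), y,
                      docking_score = scores[i])
    })
    list(records = records,
         pocket_ids = rep_len(seq_len(n_pockets), n_records),
         pockets = pockets,
         schema = schema, vocab = vocab, smiles = smiles)
  })
}

#' SMILES / property-sidecar file IO
#'
#' SMILES files hold one molecule per line; the sidecar is a TSV with header
#' `smiles`, one column per schema property (raw values) and
#' `docking_score`.
#'
#' @param smiles character vector.
#' @param path file path.
#' @export
write_smiles <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}

#' @rdname write_smiles
#' @export
read_smiles <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Assemble a training corpus from SMILES + sidecar files and pockets
#'
#' The on-disk counterpart of [make_conditioned_corpus()]: reads a SMILES
#' file, its TSV property sidecar (columns: `smiles`, one per schema
#' property, `docking_score`) and a list of pocket PDB paths, builds (or
#' reuses) the vocabulary, and returns a corpus list accepted by [train()].
#' Records are assigned to pockets round-robin unless the sidecar has a
#' `pocket` column of 1-based indices.
#'
#' @param smiles_path SMILES file, one molecule per line.
#' @param sidecar_path property TSV.
#' @param pocket_paths character vector of pocket PDB files.
#' @param schema a `PropertySchema` naming the sidecar columns to use.
#' @param vocab optional prebuilt `Vocabulary` (built from the corpus when
#'   omitted).
#' @return a corpus list (`records`, `pocket_ids`, `pockets`, `schema`,
#'   `vocab`, `smiles`).
#' @export
read_conditioned_corpus <- function(smiles_path, sidecar_path, pocket_paths,
                                    schema, vocab = NULL) {
  smiles <- read_smiles(smiles_path)
  side <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
  stopifnot(nrow(side) == length(smiles), length(pocket_paths) >= 1L)
  if (is.null(vocab)) vocab <- build_vocabulary(smiles)
  pockets <- lapply(pocket_paths, function(p) parse_pocket(readLines(p)))
  records <- lapply(seq_along(smiles), function(i) {
    vals <- as.list(side[i, , drop = FALSE])
    y <- schema_vector(vals, schema)
    molecule_record(smiles[i], tokenize(smiles[i], vocab), y,
                    docking_score = vals$docking_score %||% NA_real_)
  })
  pocket_ids <- if ("pocket" %in% names(side)) as.integer(side$pocket)
  else rep_len(seq_along(pockets), length(smiles))
  stopifnot(all(pocket_ids >= 1L & pocket_ids <= length(pockets)))
  list(records = records, pocket_ids = pocket_ids, pockets = pockets,
       schema = schema, vocab = vocab, smiles = smiles)
}

#' @rdname write_smiles
#' @param corpus a [make_conditioned_corpus()] result.
#' @export
write_property_sidecar <- function(corpus, path) {
  y <- do.call(rbind, lapply(corpus$records, `[[`, "y"))
  colnames(y) <- names(corpus$schema)
  df <- data.frame(smiles = corpus$smiles, y,
                   docking_score = vapply(corpus$records, `[[`,
                                          numeric(1), "docking_score"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
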