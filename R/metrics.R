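# Evaluation metrics: RDKit-backed descriptors (via the shipped Python
# helper), Tanimoto diversity, high-affinity ratio, property compliance, and
# the pluggable affinity-scorer seam.

python_binary <- function() {
  Sys.getenv("POCKETMOLGEN_PYTHON", unset = Sys.which("python"))
}

descriptor_script <- function() {
  p <- system.file("python", "mol_descriptors.py", package = "pocketmolgen")
  if (p == "") stop("mol_descriptors.py not found in installed package")
  p
}

#' Molecular descriptors for a set of SMILES
#'
#' Delegates QED, synthetic-accessibility (fragment-based SA score), logP,
#' TPSA, molecular weight, validity and 2048-bit Morgan (radius 2)
#' fingerprints to RDKit through a batch subprocess.  Unparseable SMILES are
#' flagged invalid with NA descriptors.
#'
#' @param smiles character vector.
#' @return data.frame with columns `smiles`, `valid`, `qed`, `sa`, `logp`,
#'   `tpsa`, `mw` and attribute `fingerprints` (list of raw vectors, NULL
#'   for invalid entries).
#' @export
mol_properties <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  inp <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(inp, out)), add = TRUE)
  writeLines(smiles, inp)
  py <- python_binary()
  if (!nzchar(py)) stop("mol_properties: no python interpreter found ",
                        "(set POCKETMOLGEN_PYTHON)")
  status <- system2(py, c(descriptor_script(), inp, out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out))
    stop("mol_properties: descriptor helper failed (status ", status, ")")
  df <- utils::read.delim(out, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", rep("numeric", 5),
                                         "character"),
                          na.strings = "")
  fps <- lapply(df$fp, function(h)
    if (is.na(h) || !nzchar(h)) NULL else hex_to_raw(h))
  df$fp <- NULL
  df$valid <- df$valid == 1L
  attr(df, "fingerprints") <- fps
  df
}

hex_to_raw <- function(h) {
  n <- nchar(h) / 2
  as.raw(strtoi(substring(h, 2 * seq_len(n) - 1, 2 * seq_len(n)), 16L))
}

# Tanimoto similarity of two bit fingerprints stored as raw vectors.
tanimoto <- function(a, b) {
  ab <- sum(bit_count(a & b))
  un <- sum(bit_count(a | b))
  if (un == 0) return(1)
  ab / un
}

BITS_PER_BYTE <- vapply(0:255, function(x) sum(bitwAnd(x, 2^(0:7)) > 0),
                        numeric(1))

bit_count <- function(r) BITS_PER_BYTE[as.integer(r) + 1L]

#' Tanimoto diversity of a generated set
#'
#' `1 - (1/N^2) * sum over all ordered pairs (including self-pairs) of the
#' Tanimoto similarity` between 2048-bit Morgan fingerprints; a set of N
#' identical molecules scores exactly 0.
#'
#' @param smiles character vector of valid SMILES (N >= 1).
#' @param fingerprints optional precomputed list of raw fingerprints
#'   (from [mol_properties()]); computed when omitted.
#' @return diversity in `[0, 1]`, or `NA` for an empty set.
#' @export
diversity <- function(smiles, fingerprints = NULL) {
  if (length(smiles) == 0L) return(NA_real_)
  if (is.null(fingerprints)) {
    props <- mol_properties(smiles)
    fingerprints <- attr(props, "fingerprints")
    if (any(!props$valid))
      stop("diversity: input contains invalid SMILES; filter first")
  }
  N <- length(fingerprints)
  M <- do.call(rbind, lapply(fingerprints, function(r)
    as.integer(rawToBits(r))))
  inter <- M %*% t(M)
  ones <- rowSums(M)
  uni <- outer(ones, ones, `+`) - inter
  Tm <- ifelse(uni == 0, 1, inter / uni)
  1 - sum(Tm) / N^2
}

#' High-affinity ratio (HAR)
#'
#' Percentage of generated molecules whose docking score is at least as good
#' (i.e. less than or equal, scores negative-better) as the reference
#' ligand's.
#'
#' @param generated_scores numeric vector (kcal/mol).
#' @param reference_score reference ligand score (kcal/mol).
#' @param better `"le"` (default: lower is better) or `"ge"` for score
#'   conventions where higher is better.
#' @return percentage in `[0, 100]`, `NA` for an empty set.
#' @export
high_affinity_ratio <- function(generated_scores, reference_score,
                                better = c("le", "ge")) {
  better <- match.arg(better)
  if (length(generated_scores) == 0L) return(NA_real_)
  hit <- if (better == "le") generated_scores <= reference_score
  else generated_scores >= reference_score
  100 * mean(hit)
}

#' Compliance fractions against requested property thresholds
#'
#' @param properties data.frame from [mol_properties()] (valid rows only).
#' @param conditions named list of [hard_property()] rules keyed by the
#'   descriptor column they test (e.g. `qed`, `sa`).
#' @return named numeric vector of fractions (empty request gives an empty
#'   vector).
#' @export
compliance <- function(properties, conditions) {
  if (length(conditions) == 0L) return(stats::setNames(numeric(0), character(0)))
  out <- vapply(names(conditions), function(col) {
    rule <- conditions[[col]]
    v <- properties[[col]]
    if (is.null(v)) stop("compliance: unknown property column ", col)
    mean(vapply(v, binarize_property, numeric(1), rule = rule))
  }, numeric(1))
  out
}

# ---- affinity scorers -------------------------------------------------------

#' Affinity scorer seam
#'
#' `mock_scorer()` is a deterministic stand-in used by tests: a fixed
#' additive model over atom counts (each nitrogen contributes -1.5, each
#' oxygen -0.5, each heavy atom -0.25 kcal/mol from a -3 baseline).
#' `external_scorer()` wraps an external docking command (never
#' re-implemented here); it is declared unavailable when the binary is
#' absent.
#'
#' @param pocket a `PocketStructure` (unused by the mock backend).
#' @return a scorer: list(name, available, score(pocket, smiles)).
#' @export
mock_scorer <- function() {
  list(name = "mock", available = TRUE,
       score = function(pocket, smiles) {
         nN <- lengths(regmatches(smiles, gregexpr("N", smiles, fixed = TRUE)))
         nO <- lengths(regmatches(smiles, gregexpr("O", smiles, fixed = TRUE)))
         heavy <- nchar(gsub("[^A-Za-z]", "", smiles))
         -3 - 1.5 * nN - 0.5 * nO - 0.25 * heavy
       })
}

#' @rdname mock_scorer
#' @param command external docking binary (e.g. a docking wrapper script
#'   taking a pocket PDB and a SMILES and printing a score).
#' @export
external_scorer <- function(command) {
  avail <- nzchar(Sys.which(command))
  list(name = command, available = avail,
       score = function(pocket, smiles) {
         if (!avail) stop("external scorer '", command, "' unavailable")
         pdb <- tempfile(fileext = ".pdb")
         on.exit(unlink(pdb), add = TRUE)
         writeLines(write_pocket_pdb(pocket), pdb)
         vapply(smiles, function(s)
           as.numeric(system2(command, c(pdb, s), stdout = TRUE)[1]),
           numeric(1), USE.NAMES = FALSE)
       })
}

#' Evaluate a generated molecule set
#'
#' Pipeline: validity filter, descriptor aggregation (mean/sd of QED, SA,
#' logP, TPSA, MW), Tanimoto diversity, compliance against requested
#' thresholds, and the high-affinity ratio when a scorer is available.
#'
#' @param generated character vector of generated SMILES.
#' @param reference reference ligand SMILES (scored for HAR) or a numeric
#'   reference score.
#' @param pocket optional `PocketStructure` passed to the scorer.
#' @param scorer optional scorer from [mock_scorer()] / [external_scorer()];
#'   HAR is omitted (with a notice) when absent or unavailable.
#' @param conditions compliance rules as in [compliance()].
#' @return a `MetricsReport` list: `n`, `validity_rate`, `diversity`,
#'   `property_summary` (mean/sd data.frame), `compliance`, `har`,
#'   `per_molecule` (data.frame).
#' @export
evaluate <- function(generated, reference = NULL, pocket = NULL,
                     scorer = NULL, conditions = list()) {
  stopifnot(length(generated) >= 1L)
  props <- mol_properties(generated)
  fps <- attr(props, "fingerprints")
  valid <- props$valid
  report <- list(n = length(generated), validity_rate = mean(valid))
  per_mol <- props
  if (!any(valid)) {
    report$diversity <- NA_real_
    report$property_summary <- NULL
    report$compliance <- NULL
    report$har <- NA_real_
    report$per_molecule <- per_mol
    class(report) <- "MetricsReport"
    return(report)
  }
  vp <- props[valid, , drop = FALSE]
  report$diversity <- diversity(vp$smiles, fps[valid])
  cols <- c("qed", "sa", "logp", "tpsa", "mw")
  report$property_summary <- data.frame(
    property = cols,
    mean = vapply(cols, function(c) mean(vp[[c]]), numeric(1)),
    sd = vapply(cols, function(c) stats::sd(vp[[c]]), numeric(1)),
    row.names = NULL)
  report$compliance <- compliance(vp, conditions)
  report$har <- NA_real_
  if (!is.null(scorer) && isTRUE(scorer$available)) {
    sc <- scorer$score(pocket, vp$smiles)
    per_mol$score <- NA_real_
    per_mol$score[valid] <- sc
    ref_score <- if (is.numeric(reference)) reference
    else if (is.character(reference)) scorer$score(pocket, reference)
    else NA_real_
    if (is.finite(ref_score))
      report$har <- high_affinity_ratio(sc, ref_score)
  } else if (!is.null(scorer)) {
    message("evaluate: scorer unavailable; HAR omitted")
  }
  report$per_molecule <- per_mol
  class(report) <- "MetricsReport"
  report
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: n=%d validity=%.3f diversity=%s har=%s\n",
              x$n, x$validity_rate,
              format(x$diversity, digits = 4),
              format(x$har, digits = 4)))
  if (!is.null(x$property_summary)) print(x$property_summary)
  if (length(x$compliance)) {
    cat("compliance:\n")
    print(x$compliance)
  }
  invisible(x)
}

#' Write the evaluation TSVs (one metrics row + per-molecule table)
#' @param report a `MetricsReport`.
#' @param metrics_path,per_molecule_path output TSV paths.
#' @export
write_metrics_report <- function(report, metrics_path, per_molecule_path) {
  row <- data.frame(n = report$n, validity_rate = report$validity_rate,
                    diversity = report$diversity, har = report$har)
  if (!is.null(report$property_summary))
    for (i in seq_len(nrow(report$property_summary))) {
      row[[paste0("mean_", report$property_summary$property[i])]] <-
        report$property_summary$mean[i]
      row[[paste0("sd_", report$property_summary$property[i])]] <-
        report$property_summary$sd[i]
    }
  for (nm in names(report$compliance))
    row[[paste0("compliance_", nm)]] <- report$compliance[[nm]]
  utils::write.table(row, metrics_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(report$per_molecule, per_molecule_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(metrics_path)
}
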