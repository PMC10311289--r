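# Joint molecule embedding: property row, token one-hots, token-type vectors
# and sinusoidal positions; plus property binarization rules.

#' Property schema
#'
#' An ordered list of conditioning properties.  Hard properties carry an
#' inclusive threshold and direction and are binarized; soft properties are
#' fed as raw continuous values.  The order is fixed at training time.
#'
#' @param ... property definitions created by [hard_property()] /
#'   [soft_property()].
#' @return a `PropertySchema` (list).
#' @export
property_schema <- function(...) {
  props <- list(...)
  stopifnot(length(props) >= 1L)
  nm <- vapply(props, `[[`, character(1), "name")
  stopifnot(!anyDuplicated(nm))
  structure(props, class = "PropertySchema", names = nm)
}

#' @rdname property_schema
#' @param name property name.
#' @param threshold inclusive threshold.
#' @param direction `"le"` (value <= threshold gives 1) or `"ge"`.
#' @export
hard_property <- function(name, threshold, direction = c("le", "ge")) {
  list(name = name, kind = "hard", threshold = threshold,
       direction = match.arg(direction))
}

#' @rdname property_schema
#' @param standardize standardize the raw value as `(v - mean) / sd`?
#'   Off by default; `mean`/`sd` are typically taken from the training
#'   corpus.
#' @param mean,sd standardization constants (used when `standardize`).
#' @export
soft_property <- function(name, standardize = FALSE, mean = 0, sd = 1) {
  stopifnot(sd > 0)
  list(name = name, kind = "soft", standardize = standardize,
       mean = mean, sd = sd)
}

#' Default conditioning schema: binding-affinity bit at -7.5 kcal/mol,
#' QED bit at 0.6, SA bit at 4.0 (all inclusive).
#' @export
default_property_schema <- function() {
  property_schema(hard_property("affinity", -7.5, "le"),
                  hard_property("QED", 0.6, "ge"),
                  hard_property("SA", 4.0, "le"))
}

#' Binarize a property value
#'
#' Inclusive thresholding: e.g. a docking score of -7.5 kcal/mol against the
#' rule "<= -7.5" gives 1.
#'
#' @param value finite numeric value.
#' @param rule a [hard_property()].
#' @return 0 or 1.
#' @export
binarize_property <- function(value, rule) {
  stopifnot(is.finite(value), rule$kind == "hard")
  if (rule$direction == "le") as.numeric(value <= rule$threshold)
  else as.numeric(value >= rule$threshold)
}

# Assemble the conditioning vector y for raw property values named per schema.
schema_vector <- function(values, schema) {
  y <- numeric(length(schema))
  for (i in seq_along(schema)) {
    p <- schema[[i]]
    v <- values[[p$name]]
    if (is.null(v)) stop("schema_vector: missing property ", p$name)
    y[i] <- if (p$kind == "hard" && (v < 0 || v > 1 || v != round(v)))
      binarize_property(v, p)
    else if (p$kind == "soft" && isTRUE(p$standardize))
      (v - p$mean) / p$sd
    else v
  }
  y
}

#' Sinusoidal positional encodings
#'
#' Position i (0-based), pair j: odd 1-based dimension 2j-1 holds
#' `cos(i / r^(2(j-1)/d))`, even dimension 2j holds the matching sine, so
#' wavelengths form a geometric progression from 2*pi to r*2*pi.
#'
#' @param length number of positions (>= 1).
#' @param d embedding width (>= 2).
#' @param r wavelength base (10000 as is conventional).
#' @return `length` x `d` matrix.
#' @export
sinusoidal_positions <- function(length, d, r = 10000) {
  stopifnot(length >= 1L, d >= 2L)
  pos <- 0:(length - 1L)
  npair <- ceiling(d / 2)
  j <- seq_len(npair)
  freq <- r^(-2 * (j - 1) / d)
  ang <- outer(pos, freq)
  out <- matrix(0, length, d)
  out[, 2L * j - 1L] <- cos(ang)
  sin_cols <- 2L * j
  sin_cols <- sin_cols[sin_cols <= d]
  out[, sin_cols] <- sin(ang[, seq_along(sin_cols), drop = FALSE])
  out
}

#' Molecule record
#'
#' @param smiles SMILES string.
#' @param token_ids integer ids from [tokenize()].
#' @param y numeric conditioning vector ordered per schema (hard entries
#'   already binarized).
#' @param docking_score kcal/mol, negative = better; `NA` if unknown.
#' @return a `MoleculeRecord` list.
#' @export
molecule_record <- function(smiles, token_ids, y, docking_score = NA_real_) {
  structure(list(smiles = smiles, token_ids = as.integer(token_ids),
                 y = as.numeric(y), docking_score = docking_score),
            class = "MoleculeRecord")
}

#' Joint molecule embedding h0
#'
#' Row 1 is the property row `y Wp` (+ token type t1); rows 2..n+2 are the
#' one-hot token embeddings of the begin tag and the n sub-tokens (+ t0);
#' sinusoidal positions are added over all n+2 rows.
#'
#' @param record a [molecule_record()] (only `token_ids` and `y` are used).
#' @param vocab the `Vocabulary`.
#' @param schema the `PropertySchema` (length must match `record$y`).
#' @param params list with `Wp` (m x d), `Ws` (|V| x d), `t1`, `t0`
#'   (length-d vectors).
#' @param max_len maximum sub-token count (200 by default).
#' @return (n+2) x d matrix.
#' @export
embed_molecule <- function(record, vocab, schema, params, max_len = 200L) {
  ids <- record$token_ids
  n <- length(ids)
  if (n + 2L > max_len + 2L)
    stop(sprintf("embed_molecule: sequence length %d exceeds max_len %d",
                 n, max_len))
  stopifnot(length(record$y) == length(schema),
            length(record$y) == nrow(params$Wp),
            vocab$size == nrow(params$Ws))
  d <- ncol(params$Wp)
  rows <- c(vocab$bos_id, ids)
  hm <- rbind(matrix(record$y, 1L) %*% params$Wp,
              params$Ws[rows, , drop = FALSE])
  htok <- rbind(matrix(params$t1, 1L),
                matrix(params$t0, n + 1L, d, byrow = TRUE))
  hm + htok + sinusoidal_positions(n + 2L, d)
}

# Gradient of a loss wrt (Wp, Ws, t1, t0) given d_h0 for one molecule.
embed_molecule_bwd <- function(dh0, record, vocab, params) {
  rows <- c(vocab$bos_id, record$token_ids)
  dWs <- matrix(0, nrow(params$Ws), ncol(params$Ws))
  body <- dh0[-1L, , drop = FALSE]
  s <- rowsum(body, rows)
  dWs[as.integer(rownames(s)), ] <- s
  list(Wp = outer(record$y, dh0[1L, ]),
       Ws = dWs,
       t1 = dh0[1L, ],
       t0 = colSums(body))
}
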