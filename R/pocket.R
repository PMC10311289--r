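# Pocket structures: typed residues/atoms with 3D coordinates.
# Coordinates are Angstrom throughout; PDB numbering is kept only as metadata.

#' Standard amino acids (three-letter codes, fixed order)
#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# The six supported elements, fixed order; last feature bit flags backbone.
POCKET_ELEMENTS <- c("H", "C", "N", "O", "S", "P")

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                 S = 32.06, P = 30.974)

#' Construct a pocket structure
#'
#' A `PocketStructure` is an ordered list of residues; each residue carries a
#' type (one of the 20 standard amino acids), and atoms with element symbol,
#' coordinates (Angstrom), atomic mass (Dalton) and a backbone flag.
#'
#' @param residues list of residues, each a list with `residue_type` (3-letter
#'   code), and `atoms`: a data.frame with columns `element`, `x`, `y`, `z`,
#'   `mass`, `is_backbone`.
#' @param metadata optional list (e.g. original chain/sequence numbers).
#' @return an object of class `PocketStructure`.
#' @export
pocket_structure <- function(residues, metadata = list()) {
  stopifnot(length(residues) >= 1L)
  for (r in residues) {
    if (!r$residue_type %in% AA3)
      stop("unknown residue type: ", r$residue_type)
    a <- r$atoms
    stopifnot(nrow(a) >= 1L,
              all(is.finite(as.matrix(a[, c("x", "y", "z")]))),
              all(a$mass > 0),
              all(a$element %in% POCKET_ELEMENTS))
  }
  structure(list(residues = residues, metadata = metadata),
            class = "PocketStructure")
}

#' @export
print.PocketStructure <- function(x, ...) {
  na <- sum(vapply(x$residues, function(r) nrow(r$atoms), integer(1)))
  cat(sprintf("PocketStructure: %d residues, %d atoms\n",
              length(x$residues), na))
  invisible(x)
}

n_pocket_atoms <- function(pocket) {
  sum(vapply(pocket$residues, function(r) nrow(r$atoms), integer(1)))
}

#' Parse a pocket from PDB text
#'
#' Reads ATOM/HETATM coordinate records.  Residues are ordered by
#' chain/sequence number; backbone flags are set for atoms named N, CA, C, O;
#' atoms whose element is outside H/C/N/O/S/P are dropped with a warning, as
#' are residues with non-standard names (waters, ligands, ions).
#'
#' @param pdb_text a character scalar or vector of PDB lines.
#' @return a [pocket_structure()].
#' @export
parse_pocket <- function(pdb_text) {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n",
                           fixed = TRUE))
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0L)
    stop("parse_pocket: no parsable ATOM/HETATM records", call. = FALSE)
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  rec <- vapply(rec, pad, character(1), n = 80L, USE.NAMES = FALSE)
  fld <- function(a, b) trimws(substr(rec, a, b))

  atom_name <- fld(13, 16)
  res_name  <- fld(18, 20)
  chain     <- fld(22, 22)
  res_seq   <- fld(23, 26)
  icode     <- fld(27, 27)
  x <- as.numeric(fld(31, 38))
  y <- as.numeric(fld(39, 46))
  z <- as.numeric(fld(47, 54))
  element <- fld(77, 78)
  # Fall back to the atom-name column when the element field is blank.
  blank <- element == ""
  if (any(blank)) {
    guess <- toupper(gsub("[^A-Za-z].*$", "", atom_name[blank]))
    two <- substr(guess, 1, 2)
    one <- substr(guess, 1, 1)
    element[blank] <- ifelse(two %in% toupper(POCKET_ELEMENTS), two, one)
  }
  element <- toupper(element)

  keep_res <- res_name %in% AA3
  if (any(!keep_res))
    warning(sprintf("parse_pocket: dropped %d non-standard-residue atoms (%s)",
                    sum(!keep_res),
                    paste(unique(res_name[!keep_res]), collapse = ",")))
  keep_el <- element %in% POCKET_ELEMENTS
  if (any(!keep_el & keep_res))
    warning(sprintf("parse_pocket: dropped %d atoms with unsupported elements (%s)",
                    sum(!keep_el & keep_res),
                    paste(unique(element[!keep_el & keep_res]), collapse = ",")))
  keep <- keep_res & keep_el & is.finite(x) & is.finite(y) & is.finite(z)
  if (!any(keep))
    stop("parse_pocket: no parsable atom records after filtering",
         call. = FALSE)

  key <- paste(chain, res_seq, icode, sep = "|")[keep]
  ord_first <- !duplicated(key)
  res_keys <- key[ord_first]
  df <- data.frame(key = key,
                   residue_type = res_name[keep],
                   element = element[keep],
                   x = x[keep], y = y[keep], z = z[keep],
                   atom_name = atom_name[keep],
                   stringsAsFactors = FALSE)
  residues <- lapply(res_keys, function(k) {
    sub <- df[df$key == k, , drop = FALSE]
    list(residue_type = sub$residue_type[1],
         atoms = data.frame(
           element = sub$element,
           x = sub$x, y = sub$y, z = sub$z,
           mass = unname(ATOMIC_MASS[sub$element]),
           is_backbone = sub$atom_name %in% c("N", "CA", "C", "O"),
           stringsAsFactors = FALSE))
  })
  meta <- lapply(seq_along(res_keys), function(i) {
    p <- strsplit(res_keys[i], "|", fixed = TRUE)[[1]]
    list(chain = p[1], res_seq = p[2])
  })
  pocket_structure(residues, metadata = list(residue_ids = meta))
}

#' Serialize a pocket structure to PDB text
#'
#' Inverse of [parse_pocket()] for fixture round-trips; writes minimal
#' ATOM records with generic atom names (backbone atoms are named N/CA/C/O
#' in order so that re-parsing restores backbone flags).
#'
#' @param pocket a `PocketStructure`.
#' @return character vector of PDB lines.
#' @export
write_pocket_pdb <- function(pocket) {
  lines <- character(0)
  serial <- 0L
  bb_names <- c("N", "CA", "C", "O")
  for (ri in seq_along(pocket$residues)) {
    r <- pocket$residues[[ri]]
    nb <- 0L
    counts <- integer(length(POCKET_ELEMENTS))
    names(counts) <- POCKET_ELEMENTS
    for (ai in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      a <- r$atoms[ai, ]
      if (isTRUE(a$is_backbone) && nb < 4L) {
        nb <- nb + 1L
        nm <- bb_names[nb]
      } else {
        counts[a$element] <- counts[a$element] + 1L
        nm <- paste0(a$element, "X", counts[a$element])
      }
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, substr(nm, 1, 4), r$residue_type, ri,
        a$x, a$y, a$z, a$element))
    }
  }
  c(lines, "END")
}

#' Pocket JSON round-trip (internal fixture format)
#' @param pocket a `PocketStructure`.
#' @param path file path.
#' @return `pocket_to_json` returns the path invisibly; `pocket_from_json`
#'   returns a `PocketStructure`.
#' @export
pocket_to_json <- function(pocket, path) {
  obj <- list(residues = lapply(pocket$residues, function(r)
    list(residue_type = r$residue_type, atoms = r$atoms)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pocket_to_json
#' @export
pocket_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  residues <- lapply(seq_len(nrow_or_len(obj$residues)), function(i) {
    r <- if (is.data.frame(obj$residues)) {
      list(residue_type = obj$residues$residue_type[i],
           atoms = obj$residues$atoms[[i]])
    } else obj$residues[[i]]
    r$atoms <- as.data.frame(r$atoms, stringsAsFactors = FALSE)
    r
  })
  pocket_structure(residues)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Mass-weighted residue centroid
#'
#' c_i = sum_k r_ik * m_ik / sum_k m_ik over the residue's atoms.
#'
#' @param residue one element of `PocketStructure$residues`.
#' @return numeric length-3 vector (Angstrom).
#' @export
residue_centroid <- function(residue) {
  a <- residue$atoms
  stopifnot(nrow(a) >= 1L)
  total <- sum(a$mass)
  if (total <= 0) stop("residue_centroid: zero total mass")
  as.numeric(crossprod(a$mass, as.matrix(a[, c("x", "y", "z")])) / total)
}

#' 7-dimensional atom feature vector
#'
#' One-hot over the six supported elements (H, C, N, O, S, P in that order)
#' concatenated with a backbone-membership bit.
#'
#' @param element element symbol.
#' @param is_backbone logical flag.
#' @return numeric length-7 binary vector.
#' @export
atom_feature_vector <- function(element, is_backbone) {
  i <- match(element, POCKET_ELEMENTS)
  if (is.na(i))
    stop("atom_feature_vector: unsupported element ", element)
  v <- numeric(7L)
  v[i] <- 1
  v[7L] <- as.numeric(isTRUE(is_backbone))
  v
}
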