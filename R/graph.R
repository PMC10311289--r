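# Spatial KNN graphs over pocket representative points, Gaussian RBF edge
# embeddings, and Laplacian-eigenvector positional features.

#' Graph-construction configuration for one view
#'
#' Defaults follow the reported runs: residue view k = 30, RBF centers on
#' 0-25 A, sigma = 30 A; atom view k = 48, RBF centers on 0-15 A,
#' sigma = 15 A; 64 RBF centers and 8 retained eigenvectors in both views.
#'
#' @param view `"residue"` or `"atom"`.
#' @param k_neighbors neighbors per node (clamped to n-1).
#' @param rbf_count number of Gaussian RBF centers.
#' @param rbf_min,rbf_max center range in Angstrom.
#' @param laplacian_sigma edge-weight bandwidth sigma (Angstrom).
#' @param n_eigenvectors retained low-frequency eigenvectors.
#' @param include_trivial keep the trivial (lambda = 0) eigenvector? Default
#'   drops it: it is proportional to D^(1/2)*1 and carries no positional
#'   signal.
#' @return a `GraphConfig` list.
#' @export
graph_config <- function(view = c("residue", "atom"),
                         k_neighbors = NULL,
                         rbf_count = 64L,
                         rbf_min = NULL, rbf_max = NULL,
                         laplacian_sigma = NULL,
                         n_eigenvectors = 8L,
                         include_trivial = FALSE) {
  view <- match.arg(view)
  if (view == "residue") {
    k_neighbors <- k_neighbors %||% 30L
    rbf_min <- rbf_min %||% 0
    rbf_max <- rbf_max %||% 25
    laplacian_sigma <- laplacian_sigma %||% 30
  } else {
    k_neighbors <- k_neighbors %||% 48L
    rbf_min <- rbf_min %||% 0
    rbf_max <- rbf_max %||% 15
    laplacian_sigma <- laplacian_sigma %||% 15
  }
  stopifnot(rbf_min < rbf_max, k_neighbors >= 1L, n_eigenvectors >= 1L,
            rbf_count >= 1L, laplacian_sigma > 0)
  structure(list(view = view, k_neighbors = as.integer(k_neighbors),
                 rbf_count = as.integer(rbf_count),
                 rbf_min = rbf_min, rbf_max = rbf_max,
                 laplacian_sigma = laplacian_sigma,
                 n_eigenvectors = as.integer(n_eigenvectors),
                 include_trivial = include_trivial),
            class = "GraphConfig")
}

#' Build a directed KNN spatial graph
#'
#' Each node's neighborhood holds the `min(k, n-1)` nearest other points by
#' Euclidean distance, ties broken by ascending index; per-edge distances are
#' stored alongside.
#'
#' @param points n x 3 coordinate matrix (Angstrom).
#' @param node_features n x d_v feature matrix.
#' @param k_neighbors requested neighborhood size.
#' @return a `SpatialGraph`: list with `node_features`, `coords`,
#'   `neighborhoods` (n x k index matrix, row i = N_i in distance order) and
#'   `edge_distances` (n x k, same layout).
#' @export
build_graph <- function(points, node_features, k_neighbors) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("build_graph: need at least 2 points")
  stopifnot(all(is.finite(points)), ncol(points) == 3L,
            nrow(node_features) == n, k_neighbors >= 1L)
  k <- min(as.integer(k_neighbors), n - 1L)
  dmat <- as.matrix(stats::dist(points))
  nbr <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- dmat[i, ]
    d[i] <- Inf
    # order() is stable: ties resolve to the lower index.
    ord <- order(d)[seq_len(k)]
    nbr[i, ] <- ord
    dst[i, ] <- d[ord]
  }
  structure(list(node_features = as.matrix(node_features),
                 coords = points,
                 neighborhoods = nbr,
                 edge_distances = dst,
                 k = k),
            class = "SpatialGraph")
}

#' Gaussian RBF encoding of an edge distance
#'
#' Component t is `exp(-(d - mu_t)^2 / (2 w^2))` with centers mu_t equally
#' spaced on `[rbf_min, rbf_max]` and width w equal to the interval size
#' `(rbf_max - rbf_min) / rbf_count`.
#'
#' @param d distance(s), Angstrom, >= 0; vectorized.
#' @param config a [graph_config()].
#' @return matrix `length(d)` x `rbf_count`.
#' @export
rbf_encode <- function(d, config) {
  stopifnot(all(d >= 0))
  centers <- seq(config$rbf_min, config$rbf_max,
                 length.out = config$rbf_count)
  w <- (config$rbf_max - config$rbf_min) / config$rbf_count
  exp(-(outer(d, centers, "-"))^2 / (2 * w^2))
}

# RBF-embed every directed edge of a graph -> (n*k) x rbf_count matrix,
# edge e = (i-1)*k + s is neighbor slot s of node i.
edge_embeddings <- function(graph, config) {
  rbf_encode(as.numeric(t(graph$edge_distances)), config)
}

#' Serialize a spatial graph to a named-array JSON container
#'
#' Arrays: `node_features`, `coords`, `neighbor_index`, `edge_distance`,
#' and (when positional features are attached) `eigvecs`.
#'
#' @param graph a `SpatialGraph` (optionally with `$positional`).
#' @param path file path.
#' @export
write_graph_json <- function(graph, path) {
  obj <- list(node_features = graph$node_features,
              coords = graph$coords,
              neighbor_index = graph$neighborhoods,
              edge_distance = graph$edge_distances)
  if (!is.null(graph$positional))
    obj$eigvecs <- graph$positional$vectors
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- structure(list(node_features = obj$node_features,
                      coords = obj$coords,
                      neighborhoods = matrix(as.integer(obj$neighbor_index),
                                             nrow(obj$neighbor_index)),
                      edge_distances = obj$edge_distance,
                      k = ncol(obj$neighbor_index)),
                 class = "SpatialGraph")
  if (!is.null(obj$eigvecs))
    g$positional <- list(vectors = obj$eigvecs, eigenvalues = NULL)
  g
}

#' Extract a pocket from a full structure around a ligand
#'
#' Convenience path for un-cut structures: keeps residues with any atom
#' within `radius` Angstrom of any ligand atom.
#'
#' @param pocket a `PocketStructure` holding the full protein.
#' @param ligand_coords n x 3 matrix of ligand atom coordinates.
#' @param radius cutoff in Angstrom (default 10).
#' @return the trimmed `PocketStructure`.
#' @export
extract_pocket <- function(pocket, ligand_coords, radius = 10) {
  ligand_coords <- as.matrix(ligand_coords)
  keep <- vapply(pocket$residues, function(r) {
    xyz <- as.matrix(r$atoms[, c("x", "y", "z")])
    d2 <- outer(rowSums(xyz^2), rowSums(ligand_coords^2), `+`) -
      2 * xyz %*% t(ligand_coords)
    any(d2 <= radius^2 + 1e-9)
  }, logical(1))
  if (!any(keep)) stop("extract_pocket: no residues within ", radius, " A")
  pocket_structure(pocket$residues[keep])
}

#' Laplacian-eigenvector positional features
#'
#' Edge weights `w_ij = exp(-d_ij^2 / (2 sigma^2))` on the symmetrized edge
#' set (an undirected edge exists if either direction is a KNN edge); the
#' symmetric normalized Laplacian `L = I - D^(-1/2) A D^(-1/2)` is
#' eigendecomposed, eigenvalues ascending.  The `n_eigenvectors` smallest
#' non-trivial eigenvectors are retained (unit norm, deterministic sign:
#' largest-magnitude component positive; degenerate eigenvalues ordered by
#' eigenvalue then lexicographically); missing columns are zero-padded when
#' the graph is smaller than requested.
#'
#' @param graph a [build_graph()] result.
#' @param config a [graph_config()].
#' @param random_sign_flip when TRUE, independently flips each retained
#'   eigenvector's sign with probability 1/2 (training augmentation; off by
#'   default and never used in evaluation).
#' @return list with `vectors` (n x n_eigenvectors) and `eigenvalues`
#'   (ascending, full spectrum, clamped to `[0, 2]`).
#' @export
laplacian_positional_features <- function(graph, config,
                                          random_sign_flip = FALSE) {
  n <- nrow(graph$coords)
  stopifnot(n >= 2L)
  sigma <- config$laplacian_sigma
  A <- matrix(0, n, n)
  k <- graph$k
  for (i in seq_len(n)) {
    j <- graph$neighborhoods[i, ]
    w <- exp(-graph$edge_distances[i, ]^2 / (2 * sigma^2))
    A[i, j] <- pmax(A[i, j], w)
    A[j, i] <- pmax(A[j, i], w)
  }
  deg <- rowSums(A)
  if (any(deg <= 0))
    stop("laplacian_positional_features: isolated node (zero degree)")
  dis <- 1 / sqrt(deg)
  L <- diag(n) - (dis * A) %*% diag(dis)
  L <- (L + t(L)) / 2
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- pmin(pmax(eig$values[ord], 0), 2)
  vecs <- eig$vectors[, ord, drop = FALSE]

  start <- if (isTRUE(config$include_trivial)) 1L else 2L
  avail <- if (n >= start) start:n else integer(0)
  take <- avail[seq_len(min(length(avail), config$n_eigenvectors))]
  V <- vecs[, take, drop = FALSE]
  # unit norm + deterministic sign
  for (cix in seq_len(ncol(V))) {
    v <- V[, cix]
    v <- v / sqrt(sum(v^2))
    m <- which.max(abs(v))
    if (v[m] < 0) v <- -v
    V[, cix] <- v
  }
  # order degenerate eigenvalue groups lexicographically for determinism
  tv <- vals[take]
  if (length(take) > 1L) {
    grp <- cumsum(c(TRUE, diff(tv) > 1e-9))
    for (g in unique(grp)) {
      cols <- which(grp == g)
      if (length(cols) > 1L) {
        key <- apply(round(V[, cols, drop = FALSE], 9), 2,
                     paste, collapse = ",")
        V[, cols] <- V[, cols[order(key)], drop = FALSE]
      }
    }
  }
  if (isTRUE(random_sign_flip) && ncol(V) > 0L) {
    flip <- sample(c(-1, 1), ncol(V), replace = TRUE)
    V <- sweep(V, 2L, flip, `*`)
  }
  if (ncol(V) < config$n_eigenvectors)
    V <- cbind(V, matrix(0, n, config$n_eigenvectors - ncol(V)))
  list(vectors = V, eigenvalues = vals)
}

#' Initial node embedding with positional adapter
#'
#' Row i is `x_i W0 + U(i, 1:k) Wpos`: the node-feature projection plus the
#' Laplacian positional encoding mapped into model space.
#'
#' @param graph a `SpatialGraph`.
#' @param positional a [laplacian_positional_features()] result.
#' @param W0 d_v x d matrix.
#' @param Wpos n_eigenvectors x d matrix.
#' @return n x d matrix.
#' @export
embed_graph_nodes <- function(graph, positional, W0, Wpos) {
  X <- graph$node_features
  U <- positional$vectors
  if (ncol(X) != nrow(W0))
    stop("embed_graph_nodes: W0 shape mismatch")
  if (ncol(U) != nrow(Wpos))
    stop("embed_graph_nodes: Wpos shape mismatch")
  X %*% W0 + U %*% Wpos
}

#' Build both pocket views
#'
#' Residue view: nodes are residues at their mass-weighted centroids with
#' 20-way one-hot types.  Atom view: nodes are atoms with 7-dim element +
#' backbone features.
#'
#' @param pocket a `PocketStructure`.
#' @param residue_config,atom_config [graph_config()]s for each view.
#' @return list with `residue` and `atom` `SpatialGraph`s (each also carrying
#'   its `positional` features and RBF `edge_emb`).
#' @export
pocket_graphs <- function(pocket,
                          residue_config = graph_config("residue"),
                          atom_config = graph_config("atom")) {
  nres <- length(pocket$residues)
  cent <- t(vapply(pocket$residues, residue_centroid, numeric(3)))
  rx <- matrix(0, nres, 20L)
  for (i in seq_len(nres))
    rx[i, match(pocket$residues[[i]]$residue_type, AA3)] <- 1

  atoms <- do.call(rbind, lapply(pocket$residues, function(r)
    r$atoms[, c("element", "x", "y", "z", "is_backbone")]))
  ax <- t(mapply(atom_feature_vector, atoms$element, atoms$is_backbone))
  rownames(ax) <- NULL
  acoord <- as.matrix(atoms[, c("x", "y", "z")])

  g_res <- build_graph(cent, rx, residue_config$k_neighbors)
  g_atom <- build_graph(acoord, ax, atom_config$k_neighbors)
  g_res$positional <- laplacian_positional_features(g_res, residue_config)
  g_atom$positional <- laplacian_positional_features(g_atom, atom_config)
  g_res$edge_emb <- edge_embeddings(g_res, residue_config)
  g_atom$edge_emb <- edge_embeddings(g_atom, atom_config)
  list(residue = g_res, atom = g_atom)
}
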