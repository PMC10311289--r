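test_that("parse_pocket reads coordinate records and round-trips", {
  p <- parse_pocket(PDB_FRAGMENT)
  expect_s3_class(p, "PocketStructure")
  expect_length(p$residues, 1L)
  expect_equal(nrow(p$residues[[1]]$atoms), 4L)
  expect_equal(p$residues[[1]]$residue_type, "GLY")
  expect_true(all(p$residues[[1]]$atoms$is_backbone))
  expect_equal(p$residues[[1]]$atoms$element, c("N", "C", "C", "O"))

  # unsupported element (Se) is dropped with a warning
  se_line <- paste0("ATOM      5 SE   MET A   2      1.000   2.000   3.000",
                    "  1.00  0.00          SE")
  ca_line <- paste0("ATOM      6  CA  MET A   2      1.500   2.000   3.000",
                    "  1.00  0.00           C")
  expect_warning(p2 <- parse_pocket(c(PDB_FRAGMENT[1:4], se_line, ca_line)),
                 "unsupported elements")
  expect_equal(nrow(p2$residues[[2]]$atoms), 1L)

  # no records at all -> structured error
  expect_error(parse_pocket("REMARK nothing here"), "no parsable")

  # fixture pocket serialized then re-parsed is identical
  fx <- make_pocket_fixture(99, n_residues = 6L)
  re <- parse_pocket(write_pocket_pdb(fx))
  expect_equal(length(re$residues), length(fx$residues))
  for (i in seq_along(fx$residues)) {
    expect_equal(re$residues[[i]]$residue_type, fx$residues[[i]]$residue_type)
    expect_equal(re$residues[[i]]$atoms$element, fx$residues[[i]]$atoms$element)
    expect_equal(re$residues[[i]]$atoms$is_backbone,
                 fx$residues[[i]]$atoms$is_backbone)
    # PDB stores 3 decimals
    expect_equal(re$residues[[i]]$atoms$x, fx$residues[[i]]$atoms$x,
                 tolerance = 1e-3)
  }

  # JSON round-trip is exact
  tmp <- tempfile(fileext = ".json")
  pocket_to_json(fx, tmp)
  fx2 <- pocket_from_json(tmp)
  expect_equal(fx2$residues[[3]]$atoms$x, fx$residues[[3]]$atoms$x)
  expect_equal(fx2$residues[[3]]$residue_type, fx$residues[[3]]$residue_type)
})

test_that("residue_centroid is the mass-weighted mean", {
  res <- function(mass, coords) list(
    residue_type = "ALA",
    atoms = data.frame(element = rep("C", length(mass)),
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       mass = mass, is_backbone = FALSE))
  expect_equal(residue_centroid(res(c(1, 1), rbind(c(0, 0, 0), c(2, 0, 0)))),
               c(1, 0, 0))
  expect_equal(residue_centroid(res(c(12, 1), rbind(c(0, 0, 0), c(13, 0, 0)))),
               c(1, 0, 0))
  expect_equal(residue_centroid(res(5, rbind(c(5, 5, 5)))), c(5, 5, 5))
  bad <- res(c(0, 0), rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(residue_centroid(bad), "zero total mass")
})

test_that("build_graph matches inspection cases and the brute-force oracle", {
  pts <- cbind(c(0, 1, 3), 0, 0)
  g <- build_graph(pts, matrix(0, 3, 1), 1L)
  expect_equal(as.integer(g$neighborhoods), c(2L, 1L, 2L))
  expect_equal(as.numeric(g$edge_distances), c(1, 1, 2))

  # k clamps to n - 1
  g2 <- build_graph(matrix(rnorm(6), 2, 3), matrix(0, 2, 1), 48L)
  expect_equal(ncol(g2$neighborhoods), 1L)
  expect_error(build_graph(matrix(0, 1, 3), matrix(0, 1, 1), 1L),
               "at least 2")

  # property: neighborhoods equal an exhaustive sort oracle
  set.seed(314)
  for (rep in 1:50) {
    n <- sample(5:100, 1)
    k <- sample(1:8, 1)
    pts <- matrix(rnorm(n * 3, sd = 10), n, 3)
    g <- build_graph(pts, matrix(0, n, 1), k)
    expect_identical(g$neighborhoods, oracle_knn(pts, k))
  }
})

test_that("atom_feature_vector is a one-hot plus backbone bit", {
  expect_equal(atom_feature_vector("C", TRUE), c(0, 1, 0, 0, 0, 0, 1))
  expect_equal(atom_feature_vector("O", FALSE), c(0, 0, 0, 1, 0, 0, 0))
  for (el in c("H", "C", "N", "O", "S", "P"))
    expect_equal(sum(atom_feature_vector(el, FALSE)[1:6]), 1)
  expect_error(atom_feature_vector("Se", FALSE), "unsupported element")
})

test_that("rbf_encode has the Gaussian closed form and 64-dim default", {
  cfg <- graph_config("residue")
  centers <- seq(cfg$rbf_min, cfg$rbf_max, length.out = cfg$rbf_count)
  w <- (cfg$rbf_max - cfg$rbf_min) / cfg$rbf_count
  e <- rbf_encode(centers[10], cfg)
  expect_length(as.numeric(e), 64L)
  expect_equal(e[1, 10], 1)
  e2 <- rbf_encode(centers[10] + w, cfg)
  expect_equal(e2[1, 10], exp(-1 / 2), tolerance = 1e-12)
  # mathematically (0, 1]; distant components underflow to exactly 0
  expect_true(all(e >= 0 & e <= 1))
  expect_gt(e[1, 10], 0)

  # per component, strictly decreasing away from the center
  d <- centers[20] + c(0, 0.5, 1, 2, 5) * w
  vals <- rbf_encode(d, cfg)[, 20]
  expect_true(all(diff(vals) < 0))
  # maximized at the nearest center
  row <- rbf_encode(centers[33] + 0.1 * w, cfg)
  expect_equal(which.max(row), 33L)
})

test_that("Laplacian positional features satisfy spectral bounds and forms", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    fx <- random_graph_fixture(n, k = sample(2:3, 1))
    lp <- laplacian_positional_features(fx$graph, fx$config)
    expect_true(all(lp$eigenvalues >= -1e-9 & lp$eigenvalues <= 2 + 1e-9))
    expect_lt(abs(lp$eigenvalues[1]), 1e-8)
  }

  # complete unit-weight graph on 4 nodes: regular tetrahedron with sigma
  # huge so all weights are equal -> nonzero eigenvalues all n/(n-1)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  g <- build_graph(tet, matrix(0, 4, 1), 3L)
  cfg <- graph_config("residue", k_neighbors = 3L, laplacian_sigma = 1e6,
                      n_eigenvectors = 3L)
  lp <- laplacian_positional_features(g, cfg)
  expect_equal(lp$eigenvalues, c(0, 4 / 3, 4 / 3, 4 / 3), tolerance = 1e-9)

  # two-node graph: eigenvalues {0, 2}
  g2 <- build_graph(rbind(c(0, 0, 0), c(3, 0, 0)), matrix(0, 2, 1), 1L)
  lp2 <- laplacian_positional_features(g2, graph_config("residue",
                                                        k_neighbors = 1L))
  expect_equal(lp2$eigenvalues, c(0, 2), tolerance = 1e-12)

  # retained eigenvectors are orthonormal; zero-padding when n is small
  fx <- random_graph_fixture(6, k = 2)
  cfg6 <- fx$config
  cfg6$n_eigenvectors <- 8L
  lp3 <- laplacian_positional_features(fx$graph, cfg6)
  V <- lp3$vectors[, 1:5]
  expect_equal(crossprod(V), diag(5), tolerance = 1e-8)
  expect_equal(lp3$vectors[, 6:8], matrix(0, 6, 3))
})

test_that("positional features are equivariant to node relabeling", {
  set.seed(7)
  fx <- random_graph_fixture(12, k = 3)
  lp <- laplacian_positional_features(fx$graph, fx$config)
  perm <- sample(12)
  gperm <- build_graph(fx$graph$coords[perm, ],
                       fx$graph$node_features[perm, , drop = FALSE], 3L)
  gperm$edge_emb <- rbf_encode(as.numeric(t(gperm$edge_distances)),
                               fx$config)
  lpp <- laplacian_positional_features(gperm, fx$config)
  # eigenvalues identical; eigenvector rows permuted consistently
  expect_equal(lpp$eigenvalues, lp$eigenvalues, tolerance = 1e-9)
  expect_equal(lpp$vectors, lp$vectors[perm, ], tolerance = 1e-6)
})

test_that("graph JSON round-trips and pocket extraction trims by radius", {
  set.seed(41)
  fx <- random_graph_fixture(8, k = 3)
  fx$graph$positional <- laplacian_positional_features(fx$graph, fx$config)
  tmp <- tempfile(fileext = ".json")
  write_graph_json(fx$graph, tmp)
  back <- read_graph_json(tmp)
  expect_identical(back$neighborhoods, fx$graph$neighborhoods)
  expect_equal(back$edge_distances, fx$graph$edge_distances)
  expect_equal(back$positional$vectors, fx$graph$positional$vectors)
  expect_equal(back$coords, fx$graph$coords)

  # extract_pocket keeps residues within 10 A of the ligand
  fxp <- make_pocket_fixture(17, n_residues = 12L)
  lig <- matrix(residue_centroid(fxp$residues[[1]]), 1)
  sub <- extract_pocket(fxp, lig, radius = 6)
  expect_lt(length(sub$residues), 12L)
  expect_gte(length(sub$residues), 1L)
  keep_manual <- sapply(fxp$residues, function(r)
    any(sqrt((r$atoms$x - lig[1])^2 + (r$atoms$y - lig[2])^2 +
               (r$atoms$z - lig[3])^2) <= 6))
  expect_equal(length(sub$residues), sum(keep_manual))
  expect_error(extract_pocket(fxp, lig + 1e4, radius = 6), "no residues")

  # optional random sign flip only changes signs, and only when requested
  lp <- laplacian_positional_features(fx$graph, fx$config)
  set.seed(1)
  lpf <- laplacian_positional_features(fx$graph, fx$config,
                                       random_sign_flip = TRUE)
  for (j in seq_len(ncol(lp$vectors))) {
    a <- lp$vectors[, j]
    b <- lpf$vectors[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-12)
  }
})

test_that("embed_graph_nodes is the two-term linear map", {
  set.seed(21)
  fx <- random_graph_fixture(10, k = 3)
  lp <- laplacian_positional_features(fx$graph, fx$config)
  d <- 6L
  W0 <- matrix(rnorm(4 * d), 4, d)
  Wpos <- matrix(rnorm(fx$config$n_eigenvectors * d),
                 fx$config$n_eigenvectors, d)
  out <- embed_graph_nodes(fx$graph, lp, W0, Wpos)
  expect_equal(embed_graph_nodes(fx$graph, lp, W0, 0 * Wpos),
               fx$graph$node_features %*% W0)
  expect_equal(embed_graph_nodes(fx$graph, lp, 0 * W0, Wpos),
               lp$vectors %*% Wpos)
  # two-term matrix-product oracle + superposition
  manual <- matrix(0, 10, d)
  for (i in 1:10)
    manual[i, ] <- as.numeric(fx$graph$node_features[i, ] %*% W0) +
      as.numeric(lp$vectors[i, ] %*% Wpos)
  expect_equal(out, manual, tolerance = 1e-6)
  expect_error(embed_graph_nodes(fx$graph, lp, W0[1:2, ], Wpos), "W0 shape")
})
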