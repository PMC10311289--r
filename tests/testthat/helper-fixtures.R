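# Shared tiny fixtures for the unit tests.  Everything is built in code at
# test time; nothing is read from disk.

# Cache expensive shared fixtures across test files within one run.
.fixture_env <- new.env(parent = emptyenv())

tiny_corpus <- function() {
  if (is.null(.fixture_env$corpus))
    .fixture_env$corpus <- suppressWarnings(
      make_conditioned_corpus(424, n_records = 60, n_pockets = 2))
  .fixture_env$corpus
}

# A very small model (d = 16) over the tiny corpus, with its first pocket's
# graphs precomputed.
tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    corpus <- tiny_corpus()
    model <- small_model(corpus, model_dim = 16L, n_units = 2L,
                         n_blocks = 2L, n_heads = 2L, ffn_dim = 24L,
                         residue_k = 3L, atom_k = 5L, max_len = 30L,
                         seed = 11)
    graphs <- pocket_graphs(corpus$pockets[[1]],
                            model$configs$residue_graph,
                            model$configs$atom_graph)
    .fixture_env$model <- list(model = model, graphs = graphs)
  }
  .fixture_env$model
}

# Random dense-attention parameters in the package's layout.
random_mha <- function(d_q, d_kv, d, H, dk, dv) {
  list(heads = replicate(H, list(
    Wq = matrix(rnorm(d_q * dk), d_q, dk),
    Wk = matrix(rnorm(d_kv * dk), d_kv, dk),
    Wv = matrix(rnorm(d_kv * dv), d_kv, dv)), simplify = FALSE),
    Wo = matrix(rnorm(H * dv * d), H * dv, d))
}

# Seeded full encoder parameter store for given configs.
with_seed_params <- function(seed, cfg, res_cfg, atom_cfg) {
  set.seed(seed)
  list(res = pocketmolgen:::init_encoder_view(cfg, 20L,
                                              res_cfg$n_eigenvectors,
                                              res_cfg$rbf_count),
       atom = pocketmolgen:::init_encoder_view(cfg, 7L,
                                               atom_cfg$n_eigenvectors,
                                               atom_cfg$rbf_count),
       fusion = pocketmolgen:::init_fusion_blocks(cfg))
}

# A random spatial graph over n points with k neighbors and de-dim edges.
random_graph_fixture <- function(n, k, d_feat = 4L, de = 8L) {
  pts <- matrix(rnorm(n * 3, sd = 5), n, 3)
  g <- build_graph(pts, matrix(rnorm(n * d_feat), n, d_feat), k)
  cfg <- graph_config("atom", k_neighbors = k, rbf_count = de,
                      n_eigenvectors = 4L)
  g$edge_emb <- rbf_encode(as.numeric(t(g$edge_distances)), cfg)
  list(graph = g, config = cfg)
}

# A 1-residue, 4-atom PDB fragment (glycine backbone).
PDB_FRAGMENT <- c(
  "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   GLY A   1      10.729   6.768  -4.123  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       9.580   7.111  -4.411  1.00  0.00           O",
  "END")
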