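# Model container: all learnable parameters plus configuration, with a
# single-record loss/gradient entry point used by training, and a versioned
# checkpoint round-trip.

CHECKPOINT_VERSION <- 1L

#' Initialize a generation model
#'
#' Creates the full `ParameterStore`: per-view encoder stacks (including the
#' node-feature and positional adapters W0/Wpos), cross-fusion blocks, the
#' decoder, and the molecule embedding parameters (Wp, Ws, token-type
#' vectors).  Xavier initialization, fully seeded.
#'
#' @param vocab a `Vocabulary`.
#' @param schema a `PropertySchema`.
#' @param enc_cfg an [encoder_config()].
#' @param dec_cfg a [decoder_config()].
#' @param res_cfg,atom_cfg [graph_config()]s for the two views.
#' @param seed integer RNG seed.
#' @return a `GenModel` list: `params`, `configs`, `vocab`, `schema`.
#' @export
init_model <- function(vocab, schema,
                       enc_cfg = encoder_config(),
                       dec_cfg = decoder_config(),
                       res_cfg = graph_config("residue"),
                       atom_cfg = graph_config("atom"),
                       seed = 1L) {
  stopifnot(enc_cfg$model_dim == dec_cfg$model_dim)
  d <- enc_cfg$model_dim
  with_local_seed(seed, {
    params <- list(
      enc = list(
        res = init_encoder_view(enc_cfg, 20L, res_cfg$n_eigenvectors,
                                res_cfg$rbf_count),
        atom = init_encoder_view(enc_cfg, 7L, atom_cfg$n_eigenvectors,
                                 atom_cfg$rbf_count),
        fusion = init_fusion_blocks(enc_cfg)),
      dec = init_decoder(dec_cfg, vocab$size),
      emb = list(Wp = xavier(length(schema), d),
                 Ws = xavier(vocab$size, d),
                 t1 = stats::rnorm(d, sd = 0.02),
                 t0 = stats::rnorm(d, sd = 0.02)))
    structure(list(params = params,
                   configs = list(encoder = enc_cfg, decoder = dec_cfg,
                                  residue_graph = res_cfg,
                                  atom_graph = atom_cfg),
                   vocab = vocab, schema = schema),
              class = "GenModel")
  })
}

# Loss and full parameter gradient for one (pocket graphs, record) pair.
model_loss_grad <- function(model, graphs, record, dropout = 0,
                            want_grad = TRUE) {
  p <- model$params
  cfg <- model$configs
  rep <- encode_pocket(graphs, p$enc, cfg$encoder, dropout)
  h0 <- embed_molecule(record, model$vocab, model$schema, p$emb,
                       cfg$decoder$max_len)
  fwd <- decoder_forward(h0, rep, p$dec, cfg$decoder, dropout)
  targets <- shifted_targets(record$token_ids, model$vocab)
  ls <- nll_loss(fwd$logits, targets)
  if (!want_grad) return(list(loss = ls$loss))
  bdec <- decoder_bwd(ls$dlogits, fwd$cache, p$dec, cfg$decoder)
  gemb <- embed_molecule_bwd(bdec$dh0, record, model$vocab, p$emb)
  genc <- encode_pocket_bwd(bdec$dHp, rep, p$enc, cfg$encoder)
  list(loss = ls$loss,
       grads = list(enc = genc, dec = bdec$grads, emb = gemb))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the parameter values, configs, vocabulary, schema
#' and a format version; the round-trip is exact.
#'
#' @param model a `GenModel`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(version = CHECKPOINT_VERSION, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("load_checkpoint: unsupported checkpoint version ", obj$version)
  obj$model
}
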