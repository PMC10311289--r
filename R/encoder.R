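# Dual-view pocket encoder: per-view stacks of edge-augmented self-attention
# units, with one-way residue<-atom cross-fusion at selected depths, and the
# final stacked pocket representation H_P = [H(t); Z(t)].

#' Encoder configuration
#'
#' Defaults are the reported architecture: 6 tandem units of 4 heads,
#' model dim 256, key dim 32, value dim 64 (4 x 64 = 256 so concatenated
#' heads return to model dim), FFN width 1024, cross-fusion after units 3
#' and 6.
#'
#' @param n_units tandem encoding units per view.
#' @param n_heads attention heads.
#' @param model_dim node state width d.
#' @param key_dim,value_dim per-head Query/Key and Value widths.
#' @param ffn_dim feed-forward hidden width.
#' @param fusion_units integer vector: apply residue<-atom fusion after the
#'   attention+FFN block of these units.
#' @param fusion_heads heads in the fusion block.
#' @param dropout dropout rate on attention weights and FFN hidden layer
#'   during training (0 disables; generation/evaluation never uses it).
#' @return an `EncoderConfig` list.
#' @export
encoder_config <- function(n_units = 6L, n_heads = 4L, model_dim = 256L,
                           key_dim = 32L, value_dim = 64L, ffn_dim = 1024L,
                           fusion_units = c(3L, 6L), fusion_heads = 4L,
                           dropout = 0.1) {
  stopifnot(n_heads * value_dim == model_dim,
            all(fusion_units >= 1L & fusion_units <= n_units))
  structure(list(n_units = as.integer(n_units), n_heads = as.integer(n_heads),
                 model_dim = as.integer(model_dim),
                 key_dim = as.integer(key_dim),
                 value_dim = as.integer(value_dim),
                 ffn_dim = as.integer(ffn_dim),
                 fusion_units = sort(unique(as.integer(fusion_units))),
                 fusion_heads = as.integer(fusion_heads),
                 dropout = dropout),
            class = "EncoderConfig")
}

init_encoder_view <- function(cfg, d_feat, n_eig, de = 64L) {
  d <- cfg$model_dim
  units <- replicate(cfg$n_units, list(
    attn = init_mha_edges(d, de, cfg$n_heads, cfg$key_dim, cfg$value_dim),
    ln1 = init_ln(d),
    ffn = init_ffn(d, cfg$ffn_dim),
    ln2 = init_ln(d)), simplify = FALSE)
  list(W0 = xavier(d_feat, d), Wpos = xavier(n_eig, d), units = units)
}

init_fusion_blocks <- function(cfg) {
  d <- cfg$model_dim
  lapply(cfg$fusion_units, function(u) list(
    mha = init_mha_dense(d, d, d, cfg$fusion_heads, cfg$key_dim,
                         cfg$value_dim),
    ln = init_ln(d)))
}

#' One encoding unit (edge-augmented attention + FFN, post-norm residuals)
#'
#' h <- LayerNorm(MHA(h) Wo + h); h <- LayerNorm(FFN(h) + h).
#'
#' @param Hn n x d node states.
#' @param graph `SpatialGraph` for this view.
#' @param edge_emb RBF edge embeddings, (n*k) x de.
#' @param unit_params one element of the view's `units` parameter list.
#' @param dropout training-time dropout rate.
#' @return list(out, cache).
#' @export
encoder_unit <- function(Hn, graph, edge_emb, unit_params, dropout = 0) {
  a <- mha_edges_fwd(Hn, graph, edge_emb, unit_params$attn, dropout)
  l1 <- ln_fwd(a$out + Hn, unit_params$ln1)
  f <- ffn_fwd(l1$out, unit_params$ffn, dropout)
  l2 <- ln_fwd(f$out + l1$out, unit_params$ln2)
  list(out = l2$out,
       cache = list(a = a$cache, l1 = l1$cache, f = f$cache, l2 = l2$cache,
                    attn = a$attn))
}

encoder_unit_bwd <- function(dOut, cache, unit_params) {
  b2 <- ln_bwd(dOut, cache$l2, unit_params$ln2)
  bf <- ffn_bwd(b2$dX, cache$f, unit_params$ffn)
  dl1 <- b2$dX + bf$dX
  b1 <- ln_bwd(dl1, cache$l1, unit_params$ln1)
  ba <- mha_edges_bwd(b1$dX, cache$a, unit_params$attn)
  dH <- b1$dX + ba$dX
  list(dX = dH,
       grads = list(attn = ba$grads, ln1 = b1$grads, ffn = bf$grads,
                    ln2 = b2$grads))
}

#' One-way cross-view fusion (residues attend over all atoms)
#'
#' Residue states are Queries; atom states supply Keys and Values; the
#' concatenated heads are mapped and added residually, then normalized.
#' Atom states are not modified.
#'
#' @param h_residue n_res x d residue states.
#' @param z_atom n_atom x d atom states.
#' @param block_params list(mha, ln) fusion parameters.
#' @param dropout training-time dropout rate.
#' @return list(out, cache).
#' @export
cross_fusion <- function(h_residue, z_atom, block_params, dropout = 0) {
  if (nrow(z_atom) < 1L) stop("cross_fusion: empty atom view")
  m <- mha_dense_fwd(h_residue, z_atom, block_params$mha, dropout = dropout)
  l <- ln_fwd(h_residue + m$out, block_params$ln)
  list(out = l$out, cache = list(m = m$cache, l = l$cache, attn = m$attn))
}

cross_fusion_bwd <- function(dOut, cache, block_params) {
  bl <- ln_bwd(dOut, cache$l, block_params$ln)
  bm <- mha_dense_bwd(bl$dX, cache$m, block_params$mha)
  list(dH = bl$dX + bm$dXq, dZ = bm$dXkv,
       grads = list(mha = bm$grads, ln = bl$grads))
}

#' Encode a pocket into its stacked representation
#'
#' Runs the residue and atom encoders in lockstep, applying cross-fusion
#' after the attention+FFN block of each unit listed in
#' `config$fusion_units`, and vertically stacks the final states:
#' H_P = rbind(H(t), Z(t)) with a row-validity mask.
#'
#' @param graphs a [pocket_graphs()] result.
#' @param params encoder `ParameterStore` (see [init_model()]).
#' @param config an [encoder_config()].
#' @param dropout training-time dropout rate.
#' @return a `PocketRepresentation`: list(H, mask, n_res, n_atom, cache).
#' @export
encode_pocket <- function(graphs, params, config, dropout = 0) {
  gr <- graphs$residue
  ga <- graphs$atom
  Hn <- embed_graph_nodes(gr, gr$positional, params$res$W0, params$res$Wpos)
  Zn <- embed_graph_nodes(ga, ga$positional, params$atom$W0, params$atom$Wpos)
  caches <- vector("list", config$n_units)
  for (l in seq_len(config$n_units)) {
    uh <- encoder_unit(Hn, gr, gr$edge_emb, params$res$units[[l]], dropout)
    uz <- encoder_unit(Zn, ga, ga$edge_emb, params$atom$units[[l]], dropout)
    Hn <- uh$out
    Zn <- uz$out
    cf <- NULL
    fi <- match(l, config$fusion_units)
    if (!is.na(fi)) {
      cf <- cross_fusion(Hn, Zn, params$fusion[[fi]], dropout)
      Hn <- cf$out
    }
    caches[[l]] <- list(h = uh$cache, z = uz$cache,
                        fusion = if (is.null(cf)) NULL else cf$cache)
  }
  structure(list(H = rbind(Hn, Zn),
                 mask = rep(TRUE, nrow(Hn) + nrow(Zn)),
                 n_res = nrow(Hn), n_atom = nrow(Zn),
                 cache = list(units = caches, graphs = graphs)),
            class = "PocketRepresentation")
}

# Backward through the full dual-view encoder.  dH_P: (n_res+n_atom) x d.
encode_pocket_bwd <- function(dHP, rep, params, config) {
  nr <- rep$n_res
  dH <- dHP[seq_len(nr), , drop = FALSE]
  dZ <- dHP[(nr + 1L):nrow(dHP), , drop = FALSE]
  g <- list(res = list(units = vector("list", config$n_units)),
            atom = list(units = vector("list", config$n_units)),
            fusion = vector("list", length(config$fusion_units)))
  for (l in rev(seq_len(config$n_units))) {
    cl <- rep$cache$units[[l]]
    if (!is.null(cl$fusion)) {
      fi <- match(l, config$fusion_units)
      bf <- cross_fusion_bwd(dH, cl$fusion, params$fusion[[fi]])
      g$fusion[[fi]] <- bf$grads
      dH <- bf$dH
      dZ <- dZ + bf$dZ
    }
    bh <- encoder_unit_bwd(dH, cl$h, params$res$units[[l]])
    bz <- encoder_unit_bwd(dZ, cl$z, params$atom$units[[l]])
    g$res$units[[l]] <- bh$grads
    g$atom$units[[l]] <- bz$grads
    dH <- bh$dX
    dZ <- bz$dX
  }
  gr <- rep$cache$graphs$residue
  ga <- rep$cache$graphs$atom
  g$res$W0 <- crossprod(gr$node_features, dH)
  g$res$Wpos <- crossprod(gr$positional$vectors, dH)
  g$atom$W0 <- crossprod(ga$node_features, dZ)
  g$atom$Wpos <- crossprod(ga$positional$vectors, dZ)
  # reorder so the structure matches params exactly (W0, Wpos, units)
  g$res <- g$res[c("W0", "Wpos", "units")]
  g$atom <- g$atom[c("W0", "Wpos", "units")]
  g
}
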