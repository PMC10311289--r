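# Conditional transformer decoder: masked (causal) self-attention,
# protein-interactive cross-attention over the stacked pocket representation,
# FFN; post-norm residuals throughout; NLL training loss.

#' Decoder configuration
#'
#' The attention dimensions mirror the encoder's (same model/key/value/FFN
#' widths, 6 blocks of 4 heads by default); `max_len` bounds the sub-token
#' sequence length at 200.
#'
#' @param n_blocks tandem decoding units.
#' @param n_heads attention heads.
#' @param model_dim,key_dim,value_dim,ffn_dim as in [encoder_config()].
#' @param max_len maximum sub-token sequence length.
#' @param dropout training-time dropout rate.
#' @return a `DecoderConfig` list.
#' @export
decoder_config <- function(n_blocks = 6L, n_heads = 4L, model_dim = 256L,
                           key_dim = 32L, value_dim = 64L, ffn_dim = 1024L,
                           max_len = 200L, dropout = 0.1) {
  stopifnot(n_heads * value_dim == model_dim)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 model_dim = as.integer(model_dim),
                 key_dim = as.integer(key_dim),
                 value_dim = as.integer(value_dim),
                 ffn_dim = as.integer(ffn_dim),
                 max_len = as.integer(max_len),
                 dropout = dropout),
            class = "DecoderConfig")
}

init_decoder <- function(cfg, vocab_size) {
  d <- cfg$model_dim
  blocks <- replicate(cfg$n_blocks, list(
    self = init_mha_dense(d, d, d, cfg$n_heads, cfg$key_dim, cfg$value_dim),
    ln1 = init_ln(d),
    cross = init_mha_dense(d, d, d, cfg$n_heads, cfg$key_dim, cfg$value_dim),
    ln2 = init_ln(d),
    ffn = init_ffn(d, cfg$ffn_dim),
    ln3 = init_ln(d)), simplify = FALSE)
  list(blocks = blocks, Wout = xavier(d, vocab_size),
       bout = rep(0, vocab_size))
}

#' Decoder forward pass
#'
#' Causal self-attention (position i attends only to positions <= i),
#' cross-attention with molecule rows as Queries and the pocket rows as
#' Keys/Values (masked rows excluded), and an FFN, all with post-norm
#' residual connections; final linear map to per-position vocabulary logits.
#'
#' @param h0 (n+2) x d molecule embedding from [embed_molecule()].
#' @param pocket_rep a `PocketRepresentation` (or any list with `H`, `mask`).
#' @param params decoder `ParameterStore` (see [init_model()]).
#' @param config a [decoder_config()].
#' @param dropout training-time dropout rate.
#' @return list: `logits` ((n+2) x |V|), `cache`.
#' @export
decoder_forward <- function(h0, pocket_rep, params, config, dropout = 0) {
  T_ <- nrow(h0)
  if (!any(pocket_rep$mask)) stop("decoder_forward: fully masked pocket")
  causal <- lower.tri(matrix(TRUE, T_, T_), diag = TRUE)
  cmask <- matrix(pocket_rep$mask, T_, length(pocket_rep$mask), byrow = TRUE)
  X <- h0
  caches <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    bp <- params$blocks[[b]]
    sa <- mha_dense_fwd(X, X, bp$self, mask = causal, dropout = dropout)
    l1 <- ln_fwd(sa$out + X, bp$ln1)
    ca <- mha_dense_fwd(l1$out, pocket_rep$H, bp$cross, mask = cmask,
                        dropout = dropout)
    l2 <- ln_fwd(ca$out + l1$out, bp$ln2)
    ff <- ffn_fwd(l2$out, bp$ffn, dropout)
    l3 <- ln_fwd(ff$out + l2$out, bp$ln3)
    caches[[b]] <- list(sa = sa$cache, l1 = l1$cache, ca = ca$cache,
                        l2 = l2$cache, ff = ff$cache, l3 = l3$cache,
                        X = X, attn_self = sa$attn, attn_cross = ca$attn)
    X <- l3$out
  }
  logits <- sweep(X %*% params$Wout, 2L, params$bout, `+`)
  list(logits = logits,
       cache = list(blocks = caches, Xfinal = X, pocket_H = pocket_rep$H))
}

decoder_bwd <- function(dlogits, cache, params, config) {
  dX <- dlogits %*% t(params$Wout)
  gWout <- crossprod(cache$Xfinal, dlogits)
  gbout <- colSums(dlogits)
  gblocks <- vector("list", config$n_blocks)
  dHp <- matrix(0, nrow(cache$pocket_H), ncol(cache$pocket_H))
  for (b in rev(seq_len(config$n_blocks))) {
    bc <- cache$blocks[[b]]
    bp <- params$blocks[[b]]
    b3 <- ln_bwd(dX, bc$l3, bp$ln3)
    bff <- ffn_bwd(b3$dX, bc$ff, bp$ffn)
    dl2 <- b3$dX + bff$dX
    b2 <- ln_bwd(dl2, bc$l2, bp$ln2)
    bca <- mha_dense_bwd(b2$dX, bc$ca, bp$cross)
    dHp <- dHp + bca$dXkv
    dl1 <- b2$dX + bca$dXq
    b1 <- ln_bwd(dl1, bc$l1, bp$ln1)
    bsa <- mha_dense_bwd(b1$dX, bc$sa, bp$self)
    dX <- b1$dX + bsa$dXq + bsa$dXkv
    gblocks[[b]] <- list(self = bsa$grads, ln1 = b1$grads,
                         cross = bca$grads, ln2 = b2$grads,
                         ffn = bff$grads, ln3 = b3$grads)
  }
  list(dh0 = dX, dHp = dHp,
       grads = list(blocks = gblocks, Wout = gWout, bout = gbout))
}

#' Negative log-likelihood over target tokens
#'
#' Targets are the input sequence shifted left: the logits at the row holding
#' token x_{i-1} predict x_i, and the final body row predicts the end tag.
#' Rows whose target id is 0 (padding / the conditioning rows) are excluded.
#'
#' @param logits T x |V| matrix.
#' @param target_ids length-T integer vector; 0 marks excluded positions.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return list: `loss` (scalar) and `dlogits` (gradient wrt logits under
#'   the chosen reduction).
#' @export
nll_loss <- function(logits, target_ids, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  keep <- which(target_ids > 0L)
  if (length(keep) == 0L) stop("nll_loss: all positions are padded")
  P <- softmax_rows(logits[keep, , drop = FALSE])
  tid <- target_ids[keep]
  picked <- P[cbind(seq_along(keep), tid)]
  loss <- -sum(log(picked))
  dP <- P
  dP[cbind(seq_along(keep), tid)] <- dP[cbind(seq_along(keep), tid)] - 1
  denom <- if (reduction == "mean") length(keep) else 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[keep, ] <- dP / denom
  list(loss = loss / denom, dlogits = dlogits)
}

# Targets for teacher forcing: row 1 (property) predicts nothing; rows
# 2..n+2 (the rows holding b, a_1..a_n) predict a_1..a_n, e.
shifted_targets <- function(token_ids, vocab) {
  c(0L, token_ids, vocab$eos_id)
}
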