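# Independent naive-loop reference implementations ("oracles").  These are
# deliberately written element-by-element, sharing no code with the package
# internals they check.

oracle_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

oracle_layernorm <- function(X, g, b, eps = 1e-5) {
  out <- X
  for (i in seq_len(nrow(X))) {
    r <- X[i, ]
    mu <- mean(r)
    v <- mean((r - mu)^2)
    out[i, ] <- ((r - mu) / sqrt(v + eps)) * g + b
  }
  out
}

oracle_ffn <- function(X, p) {
  out <- matrix(0, nrow(X), length(p$b2))
  for (i in seq_len(nrow(X))) {
    h <- pmax(as.numeric(X[i, ] %*% p$W1) + p$b1, 0)
    out[i, ] <- as.numeric(h %*% p$W2) + p$b2
  }
  out
}

# Naive KNN: exhaustive distance sort per node.
oracle_knn <- function(points, k) {
  n <- nrow(points)
  kk <- min(k, n - 1)
  nbr <- matrix(0L, n, kk)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j)
      sqrt(sum((points[i, ] - points[j, ])^2)))
    cand <- setdiff(order(d), i)
    nbr[i, ] <- cand[seq_len(kk)]
  }
  nbr
}

# Naive edge-augmented multi-head neighborhood attention (one unit's
# attention sub-block, before the output residual/normalization).
oracle_mha_edges <- function(Hn, graph, E, p) {
  n <- nrow(Hn)
  k <- graph$k
  H <- length(p$heads)
  per_head <- list()
  for (r in seq_len(H)) {
    hp <- p$heads[[r]]
    dk <- ncol(hp$Wq)
    O <- matrix(0, n, ncol(hp$Wv))
    for (i in seq_len(n)) {
      qi <- as.numeric(Hn[i, ] %*% hp$Wq)
      logits <- numeric(k)
      vals <- matrix(0, k, ncol(hp$Wv))
      for (s in seq_len(k)) {
        j <- graph$neighborhoods[i, s]
        e <- E[(i - 1) * k + s, ]
        qij <- qi * as.numeric(e %*% hp$WeQ)
        kij <- as.numeric(Hn[j, ] %*% hp$Wk) * as.numeric(e %*% hp$WeK)
        vals[s, ] <- as.numeric(Hn[j, ] %*% hp$Wv) * as.numeric(e %*% hp$WeV)
        logits[s] <- sum(qij * kij) / sqrt(dk)
      }
      w <- oracle_softmax(logits)
      for (s in seq_len(k)) O[i, ] <- O[i, ] + w[s] * vals[s, ]
    }
    per_head[[r]] <- O
  }
  do.call(cbind, per_head) %*% p$Wo
}

# Naive dense multi-head attention (queries X1 over keys/values X2).
oracle_mha_dense <- function(X1, X2, p, mask = NULL) {
  H <- length(p$heads)
  per_head <- list()
  for (r in seq_len(H)) {
    hp <- p$heads[[r]]
    dk <- ncol(hp$Wq)
    O <- matrix(0, nrow(X1), ncol(hp$Wv))
    for (i in seq_len(nrow(X1))) {
      qi <- as.numeric(X1[i, ] %*% hp$Wq)
      logits <- rep(-Inf, nrow(X2))
      for (j in seq_len(nrow(X2))) {
        if (!is.null(mask) && !mask[i, j]) next
        kj <- as.numeric(X2[j, ] %*% hp$Wk)
        logits[j] <- sum(qi * kj) / sqrt(dk)
      }
      ok <- is.finite(logits)
      w <- numeric(length(logits))
      w[ok] <- oracle_softmax(logits[ok])
      for (j in which(w > 0))
        O[i, ] <- O[i, ] + w[j] * as.numeric(X2[j, ] %*% hp$Wv)
    }
    per_head[[r]] <- O
  }
  do.call(cbind, per_head) %*% p$Wo
}

oracle_encoder_unit <- function(Hn, graph, E, up) {
  a <- oracle_mha_edges(Hn, graph, E, up$attn)
  h1 <- oracle_layernorm(a + Hn, up$ln1$g, up$ln1$b)
  h2 <- oracle_layernorm(oracle_ffn(h1, up$ffn) + h1, up$ln2$g, up$ln2$b)
  h2
}

oracle_encode_pocket <- function(graphs, params, config) {
  gr <- graphs$residue
  ga <- graphs$atom
  Hn <- gr$node_features %*% params$res$W0 +
    gr$positional$vectors %*% params$res$Wpos
  Zn <- ga$node_features %*% params$atom$W0 +
    ga$positional$vectors %*% params$atom$Wpos
  for (l in seq_len(config$n_units)) {
    Hn <- oracle_encoder_unit(Hn, gr, gr$edge_emb, params$res$units[[l]])
    Zn <- oracle_encoder_unit(Zn, ga, ga$edge_emb, params$atom$units[[l]])
    fi <- match(l, config$fusion_units)
    if (!is.na(fi)) {
      fp <- params$fusion[[fi]]
      upd <- oracle_mha_dense(Hn, Zn, fp$mha)
      Hn <- oracle_layernorm(Hn + upd, fp$ln$g, fp$ln$b)
    }
  }
  rbind(Hn, Zn)
}

oracle_decoder_forward <- function(h0, Hp, pmask, params, config) {
  T_ <- nrow(h0)
  causal <- outer(seq_len(T_), seq_len(T_), `>=`)
  cmask <- matrix(pmask, T_, length(pmask), byrow = TRUE)
  X <- h0
  for (b in seq_len(config$n_blocks)) {
    bp <- params$blocks[[b]]
    X1 <- oracle_layernorm(oracle_mha_dense(X, X, bp$self, causal) + X,
                           bp$ln1$g, bp$ln1$b)
    X2 <- oracle_layernorm(oracle_mha_dense(X1, Hp, bp$cross, cmask) + X1,
                           bp$ln2$g, bp$ln2$b)
    X <- oracle_layernorm(oracle_ffn(X2, bp$ffn) + X2, bp$ln3$g, bp$ln3$b)
  }
  out <- X %*% params$Wout
  sweep(out, 2L, params$bout, `+`)
}
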