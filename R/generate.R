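# Conditional autoregressive generation with top-k sampling.

#' Generation request
#'
#' @param y_desired named list/vector of desired property values in schema
#'   order (hard bits as 0/1, soft values raw), or a plain numeric vector.
#' @param n_samples molecules to sample.
#' @param top_k restrict each step to the k most probable tokens
#'   (1 = greedy).
#' @param temperature softmax temperature (> 0).
#' @param seed RNG seed.
#' @param max_len maximum sub-token count per molecule.
#' @return a `GenerationRequest` list.
#' @export
generation_request <- function(y_desired, n_samples = 10L, top_k = 5L,
                               temperature = 1, seed = 1L, max_len = 200L) {
  stopifnot(top_k >= 1L, temperature > 0, n_samples >= 1L, max_len >= 1L)
  structure(list(y_desired = y_desired, n_samples = as.integer(n_samples),
                 top_k = as.integer(top_k), temperature = temperature,
                 seed = as.integer(seed), max_len = as.integer(max_len)),
            class = "GenerationRequest")
}

#' Generate molecules for a pocket under property conditions
#'
#' Each sample starts from the (property row, begin tag) pair; at every step
#' the next-token distribution is tempered, restricted to the `top_k`
#' highest-probability tokens and renormalized, and one token is drawn
#' (greedy when `top_k = 1`).  Decoding stops at the end tag or `max_len`.
#' Returned SMILES are the detokenized bodies (tags stripped); syntactic
#' validity is checked downstream by the evaluation module.
#'
#' @param model a trained `GenModel`.
#' @param pocket a `PocketStructure` or a precomputed [pocket_graphs()] list.
#' @param request a [generation_request()].
#' @return a `GeneratedSet`: data.frame with `smiles`, `log_prob`,
#'   `termination` (`"end_tag"` or `"max_len"`), and attribute `token_ids`
#'   (list of integer vectors).
#' @export
generate <- function(model, pocket, request) {
  cfg <- model$configs
  stopifnot(request$max_len <= cfg$decoder$max_len)
  graphs <- if (inherits(pocket, "PocketStructure"))
    pocket_graphs(pocket, cfg$residue_graph, cfg$atom_graph) else pocket
  rep <- encode_pocket(graphs, model$params$enc, cfg$encoder, dropout = 0)
  y <- if (is.list(request$y_desired))
    schema_vector(request$y_desired, model$schema)
  else as.numeric(request$y_desired)
  stopifnot(length(y) == length(model$schema))

  V <- model$vocab$size
  k <- min(request$top_k, V)
  out_smiles <- character(request$n_samples)
  out_lp <- numeric(request$n_samples)
  out_term <- character(request$n_samples)
  out_ids <- vector("list", request$n_samples)

  with_local_seed(request$seed, {
    for (s in seq_len(request$n_samples)) {
      ids <- integer(0)
      lp <- 0
      term <- "max_len"
      repeat {
        rec <- molecule_record("", ids, y)
        h0 <- embed_molecule(rec, model$vocab, model$schema,
                             model$params$emb, cfg$decoder$max_len)
        fwd <- decoder_forward(h0, rep, model$params$dec, cfg$decoder,
                               dropout = 0)
        logit <- fwd$logits[nrow(fwd$logits), ]
        probs <- as.numeric(softmax_rows(logit / request$temperature))
        full_log <- as.numeric(softmax_rows(logit))
        if (k == 1L) {
          nxt <- which.max(probs)
        } else {
          topi <- order(probs, decreasing = TRUE)[seq_len(k)]
          pk <- probs[topi] / sum(probs[topi])
          nxt <- topi[sample.int(k, 1L, prob = pk)]
        }
        lp <- lp + log(full_log[nxt])
        if (nxt == model$vocab$eos_id) { term <- "end_tag"; break }
        ids <- c(ids, nxt)
        if (length(ids) >= request$max_len) break
      }
      out_ids[[s]] <- ids
      out_smiles[s] <- detokenize(ids, model$vocab)
      out_lp[s] <- lp
      out_term[s] <- term
    }
  })
  res <- data.frame(smiles = out_smiles, log_prob = out_lp,
                    termination = out_term, stringsAsFactors = FALSE)
  attr(res, "token_ids") <- out_ids
  class(res) <- c("GeneratedSet", class(res))
  res
}
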