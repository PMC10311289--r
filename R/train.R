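# Training: Adam with validation-driven learning-rate decay and early
# stopping.  Schedule semantics: validate every `validate_every` iterations;
# after `decay_patience` consecutive non-improving validations multiply the
# learning rate by `lr_decay_factor` (floored at `lr_floor`); stop after
# `stop_patience` validations without improvement; keep the best-validation
# parameters.

#' Training configuration
#'
#' Defaults follow the reported regime: batch size 4, Adam at 1e-4, decay
#' factor 0.6 with patience 5 validations, floor 1e-5, validation every 1000
#' iterations, early stop after 20 stagnant validations.
#'
#' @param batch_size records per optimizer step.
#' @param lr_init initial learning rate.
#' @param lr_decay_factor multiplicative decay (0 < f < 1).
#' @param lr_floor lowest learning rate.
#' @param decay_patience stagnant validations before a decay.
#' @param validate_every training iterations between validations.
#' @param stop_patience stagnant validations before stopping.
#' @param max_iterations hard cap on training iterations (Inf = schedule
#'   only); scaled-down runs set this explicitly.
#' @param val_fraction fraction of the corpus held out for validation.
#' @param improve_tol required decrease to count as an improvement (0 =
#'   any strict decrease).
#' @param grad_clip global-norm gradient clip (documented addition for
#'   stability; NULL disables).
#' @param seed RNG seed for the split, batching and dropout.
#' @return a `TrainingConfig` list.
#' @export
training_config <- function(batch_size = 4L, lr_init = 1e-4,
                            lr_decay_factor = 0.6, lr_floor = 1e-5,
                            decay_patience = 5L, validate_every = 1000L,
                            stop_patience = 20L, max_iterations = Inf,
                            val_fraction = 0.01, improve_tol = 0,
                            grad_clip = 1.0, seed = 1L) {
  stopifnot(lr_decay_factor > 0, lr_decay_factor < 1, lr_floor < lr_init,
            batch_size >= 1L, validate_every >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_decay_factor = lr_decay_factor, lr_floor = lr_floor,
                 decay_patience = as.integer(decay_patience),
                 validate_every = as.integer(validate_every),
                 stop_patience = as.integer(stop_patience),
                 max_iterations = max_iterations,
                 val_fraction = val_fraction, improve_tol = improve_tol,
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Learning-rate schedule state machine
#'
#' `lr_schedule_init` starts the state at `lr_init`; `lr_schedule_update`
#' consumes one validation loss and returns the updated state, applying the
#' decay/floor/early-stop rules.  Exposed separately so the schedule can be
#' driven by a scripted loss trace.
#'
#' @param config a [training_config()].
#' @return a schedule state list with `lr`, `best`, `stagnant`,
#'   `since_decay`, `stop`, `improved`.
#' @export
lr_schedule_init <- function(config) {
  list(lr = config$lr_init, best = Inf, stagnant = 0L, since_decay = 0L,
       stop = FALSE, improved = FALSE)
}

#' @rdname lr_schedule_init
#' @param state current schedule state.
#' @param val_loss validation loss just measured.
#' @export
lr_schedule_update <- function(state, val_loss, config) {
  if (val_loss < state$best - config$improve_tol) {
    state$best <- val_loss
    state$stagnant <- 0L
    state$since_decay <- 0L
    state$improved <- TRUE
  } else {
    state$stagnant <- state$stagnant + 1L
    state$since_decay <- state$since_decay + 1L
    state$improved <- FALSE
    if (state$since_decay >= config$decay_patience) {
      state$lr <- max(state$lr * config$lr_decay_factor, config$lr_floor)
      state$since_decay <- 0L
    }
    if (state$stagnant >= config$stop_patience) state$stop <- TRUE
  }
  state
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = param_map2(params, upd, `-`), state = state)
}

clip_global_norm <- function(grads, max_norm) {
  if (is.null(max_norm)) return(grads)
  nrm <- sqrt(param_reduce(grads, function(x) sum(x^2)))
  if (nrm <= max_norm || nrm == 0) return(grads)
  param_map(grads, function(x) x * (max_norm / nrm))
}

#' Train a generation model on a conditioned corpus
#'
#' @param model a fresh or resumed `GenModel`.
#' @param corpus a list with `records` (list of [molecule_record()]s),
#'   `pocket_ids` (integer per record) and `pockets` (list of
#'   `PocketStructure`s or precomputed [pocket_graphs()]); see
#'   [make_conditioned_corpus()].
#' @param config a [training_config()].
#' @param log_path optional TSV path for the training log.
#' @param verbose print validation lines?
#' @return list: `model` (best-validation parameters), `log` (data.frame
#'   with iteration, lr, train_loss, val_loss), `schedule` (final state).
#' @export
train <- function(model, corpus, config = training_config(),
                  log_path = NULL, verbose = FALSE) {
  n <- length(corpus$records)
  if (n < 2L) stop("train: corpus too small")
  enc_drop <- model$configs$encoder$dropout
  dec_drop <- model$configs$decoder$dropout
  dropout <- max(enc_drop, dec_drop)

  # graphs depend only on geometry: build once per pocket
  graphs <- lapply(corpus$pockets, function(p) {
    if (inherits(p, "PocketStructure"))
      pocket_graphs(p, model$configs$residue_graph, model$configs$atom_graph)
    else p
  })

  log_rows <- list()
  res <- with_local_seed(config$seed, {
    n_val <- max(1L, round(n * config$val_fraction))
    idx <- sample.int(n)
    val_idx <- idx[seq_len(n_val)]
    train_idx <- idx[-seq_len(n_val)]
    if (length(train_idx) == 0L) stop("train: empty training split")

    sched <- lr_schedule_init(config)
    opt <- adam_init(model$params)
    best_params <- model$params
    it <- 0L
    running <- NULL
    repeat {
      it <- it + 1L
      batch <- sample(train_idx, min(config$batch_size, length(train_idx)))
      acc <- NULL
      bloss <- 0
      for (i in batch) {
        r <- model_loss_grad(model, graphs[[corpus$pocket_ids[i]]],
                             corpus$records[[i]], dropout = dropout)
        bloss <- bloss + r$loss
        acc <- if (is.null(acc)) r$grads
        else param_map2(acc, r$grads, `+`)
      }
      g <- param_map(acc, function(x) x / length(batch))
      g <- clip_global_norm(g, config$grad_clip)
      st <- adam_step(model$params, g, opt, sched$lr)
      model$params <- st$params
      opt <- st$state
      bloss <- bloss / length(batch)
      running <- if (is.null(running)) bloss else 0.95 * running + 0.05 * bloss

      if (it %% config$validate_every == 0L || it >= config$max_iterations) {
        val_loss <- mean(vapply(val_idx, function(i)
          model_loss_grad(model, graphs[[corpus$pocket_ids[i]]],
                          corpus$records[[i]], dropout = 0,
                          want_grad = FALSE)$loss, numeric(1)))
        sched <- lr_schedule_update(sched, val_loss, config)
        if (sched$improved) best_params <- model$params
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(iteration = it, lr = sched$lr, train_loss = running,
                     val_loss = val_loss)
        if (verbose)
          message(sprintf("iter %d  lr %.2e  train %.4f  val %.4f",
                          it, sched$lr, running, val_loss))
        if (sched$stop || it >= config$max_iterations) break
      }
    }
    model$params <- best_params
    list(model = model, sched = sched)
  })
  log <- do.call(rbind, log_rows)
  if (!is.null(log_path))
    utils::write.table(log, log_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(model = res$model, log = log, schedule = res$sched)
}
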