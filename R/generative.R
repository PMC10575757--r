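#' Configuration for the per-cluster generative sequence model
#'
#' The architecture defaults are the study conditions for repertoire
#' modelling: a two-layer LSTM with 64 hidden units per layer, 0.2 dropout
#' between layers, up to 200 training epochs with the reported epoch chosen
#' by five-fold cross-validation, and 10,000 samples drawn per cluster at
#' temperature 1. Optimiser settings (Adam, learning rate, batch size,
#' gradient clipping) are numerical choices of this implementation.
#'
#' @param num_layers Number of stacked LSTM layers.
#' @param hidden_units Hidden units per layer.
#' @param dropout Dropout rate applied to each layer's output during
#'   training (inverted dropout; recurrent connections are not dropped).
#' @param max_epochs Maximum training epochs (cross-validation explores
#'   epochs `1..max_epochs`).
#' @param cv_folds Cross-validation folds over unique sequences; `1`
#'   disables cross-validation and trains for `max_epochs`.
#' @param sample_n Default number of sequences to sample per cluster.
#' @param temperature Softmax sampling temperature.
#' @param seed Integer seed controlling initialisation, fold assignment,
#'   shuffling, dropout masks and sampling.
#' @param count_weighting Train on redundant reads: each unique sequence
#'   appears `min(count, replication_cap)` times per epoch, carrying a
#'   residual loss weight of `count / replications` so the objective
#'   equals training on every redundant read while bounding epoch size.
#' @param replication_cap Maximum in-epoch replications per sequence.
#' @param learning_rate,batch_size,weight_decay,ema_decay,clip,init_scale
#'   Adam learning rate, minibatch size, decoupled weight decay on the
#'   weight matrices, exponential moving-average (Polyak) decay for the
#'   reported weights (0 disables), global gradient-norm clip and uniform
#'   init half-width.
#' @param lr_cosine Cosine-decay the learning rate to zero across epochs.
#' @return A `generative_config` list.
#' @export
generative_config <- function(num_layers = 2L, hidden_units = 64L,
                              dropout = 0.2, max_epochs = 200L,
                              cv_folds = 5L, sample_n = 10000L,
                              temperature = 1.0, seed = 1L,
                              count_weighting = TRUE,
                              replication_cap = 100L,
                              learning_rate = 0.03, batch_size = 4L,
                              weight_decay = 0, ema_decay = 0.997,
                              lr_cosine = FALSE, clip = 5, init_scale = 0.08) {
  stopifnot(num_layers >= 1, hidden_units >= 1, dropout >= 0, dropout < 1,
            max_epochs >= 1, cv_folds >= 1, temperature > 0,
            learning_rate > 0, batch_size >= 1)
  structure(list(
    num_layers = as.integer(num_layers),
    hidden_units = as.integer(hidden_units), dropout = dropout,
    max_epochs = as.integer(max_epochs), cv_folds = as.integer(cv_folds),
    sample_n = as.integer(sample_n), temperature = temperature,
    seed = as.integer(seed), count_weighting = isTRUE(count_weighting),
    replication_cap = as.integer(replication_cap),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    weight_decay = weight_decay, ema_decay = ema_decay,
    lr_cosine = isTRUE(lr_cosine), clip = clip, init_scale = init_scale
  ), class = "generative_config")
}

#' Encode CDR triplets as padded token arrays
#'
#' Each sequence becomes `<start>` + concatenated CDR1-3 residue tokens +
#' `<end>`, right-padded with the pad token to the batch maximum. The
#' encoding is invertible on non-pad positions; the original CDR boundary
#' lengths are carried so [decode_sequences()] restores the full triplet.
#'
#' @param x Data frame with `cdr1`, `cdr2`, `cdr3` columns.
#' @return A `vhh_encoding`: list with `tokens` (T x n integer matrix,
#'   columns are sequences, 0 = pad), `lengths` (token count per sequence
#'   incl. start/end), `cdr1_len`, `cdr2_len`, `vocabulary`.
#' @export
encode_sequences <- function(x) {
  x <- as_tibble(x)
  for (region in c("cdr1", "cdr2", "cdr3")) check_aa(x[[region]], region)
  toks <- triplet_tokens(x$cdr1, x$cdr2, x$cdr3)
  lens <- lengths(toks)
  tmax <- if (length(lens) > 0) max(lens) else 0L
  m <- matrix(0L, nrow = tmax, ncol = length(toks))
  for (j in seq_along(toks)) m[seq_len(lens[j]), j] <- toks[[j]]
  structure(list(tokens = m, lengths = as.integer(lens),
                 cdr1_len = nchar(x$cdr1), cdr2_len = nchar(x$cdr2),
                 vocabulary = model_vocabulary()),
            class = "vhh_encoding")
}

#' Invert [encode_sequences()]
#'
#' @param enc A `vhh_encoding`.
#' @return Tibble with `cdr1`, `cdr2`, `cdr3`.
#' @export
decode_sequences <- function(enc) {
  stopifnot(inherits(enc, "vhh_encoding"))
  inv <- names(enc$vocabulary)
  n <- ncol(enc$tokens)
  out <- character(n)
  for (j in seq_len(n)) {
    ids <- enc$tokens[seq_len(enc$lengths[j]), j]
    ids <- ids[ids <= 20]  # strip control tokens
    out[j] <- paste(inv[ids], collapse = "")
  }
  tibble(
    cdr1 = substr(out, 1, enc$cdr1_len),
    cdr2 = substr(out, enc$cdr1_len + 1, enc$cdr1_len + enc$cdr2_len),
    cdr3 = substr(out, enc$cdr1_len + enc$cdr2_len + 1, nchar(out))
  )
}

#' One-hot view of an encoding
#'
#' @param enc A `vhh_encoding`.
#' @return Numeric array `n x T x vocab`; pad positions are all-zero rows.
#' @export
as_one_hot <- function(enc) {
  stopifnot(inherits(enc, "vhh_encoding"))
  V <- length(enc$vocabulary)
  n <- ncol(enc$tokens); tmax <- nrow(enc$tokens)
  arr <- array(0, dim = c(n, tmax, V),
               dimnames = list(NULL, NULL, names(enc$vocabulary)))
  for (j in seq_len(n)) {
    for (t in seq_len(enc$lengths[j])) arr[j, t, enc$tokens[t, j]] <- 1
  }
  arr
}

# count-weighted modal value
modal_weighted <- function(v, w) {
  tab <- tapply(w, v, sum)
  as.integer(names(tab)[which.max(tab)])
}

#' Train a per-cluster generative model on concatenated CDR1-3 sequences
#'
#' Fits the character-level LSTM of [generative_config()] to the unique
#' sequences of a (typically single-cluster) repertoire, weighting each
#' sequence's loss by its read count in the training round so that the
#' model sees the redundancy structure of the sorted pool. When
#' `cv_folds > 1`, folds are split over unique sequences with a seeded
#' shuffle, the mean validation loss across folds selects the reported
#' epoch, and the returned model is refit on all data for that many
#' epochs. Fully deterministic given (data, config).
#'
#' @param x Repertoire tibble.
#' @param config A [generative_config()].
#' @param round Round whose counts weight (and gate) training; sequences
#'   with zero reads in this round are not used.
#' @return A `vhh_lstm` bundle: model parameters, vocabulary, config,
#'   `selected_epoch`, `fold_validation_losses` (folds x epochs),
#'   `training_length_set`, fixed `cdr1_len`/`cdr2_len`, `n_train`.
#' @export
train_generative_model <- function(x, config = generative_config(),
                                   round = 2) {
  x <- as_repertoire(x)
  cc <- sprintf("count_r%d", round)
  if (!cc %in% names(x)) abort(sprintf("unknown round %d", round))
  counts <- as.numeric(x[[cc]])
  if (config$count_weighting) {
    keep <- counts > 0
    x <- x[keep, , drop = FALSE]
    counts <- counts[keep]
    reps <- pmin(pmax(round(counts), 1), config$replication_cap)
  } else {
    counts <- rep(1, nrow(x))
    reps <- rep(1L, nrow(x))
  }
  n <- nrow(x)
  if (n < config$cv_folds) {
    abort(sprintf("need at least %d unique sequences for %d-fold CV, got %d",
                  config$cv_folds, config$cv_folds, n))
  }
  # per-column residual weight: replications x weight == read count
  w <- counts / reps
  expand <- function(idx) rep(idx, times = reps[idx])
  enc <- encode_sequences(x)
  vocab_size <- length(enc$vocabulary)

  set.seed(config$seed)
  folds <- config$cv_folds
  fold_losses <- NULL
  if (folds > 1) {
    assignment <- rep_len(seq_len(folds), n)[sample.int(n)]
    fold_losses <- matrix(NA_real_, nrow = folds, ncol = config$max_epochs)
    for (f in seq_len(folds)) {
      tr <- which(assignment != f)
      va <- which(assignment == f)
      params <- cpp_lstm_init(config$num_layers, config$hidden_units,
                              vocab_size, config$init_scale)
      fit <- cpp_lstm_train(params, enc$tokens, enc$lengths, w, expand(tr), va,
                            config$max_epochs, config$batch_size,
                            config$learning_rate, config$dropout, config$clip,
                            config$weight_decay, config$ema_decay,
                            config$lr_cosine)
      fold_losses[f, ] <- fit$val_loss
    }
    selected_epoch <- which.min(colMeans(fold_losses))
  } else {
    selected_epoch <- config$max_epochs
  }
  params <- cpp_lstm_init(config$num_layers, config$hidden_units,
                          vocab_size, config$init_scale)
  fit <- cpp_lstm_train(params, enc$tokens, enc$lengths, w, expand(seq_len(n)),
                        integer(0), selected_epoch, config$batch_size,
                        config$learning_rate, config$dropout, config$clip,
                        config$weight_decay, config$ema_decay,
                        config$lr_cosine)
  concat_len <- nchar(x$cdr1) + nchar(x$cdr2) + nchar(x$cdr3)
  structure(list(
    params = fit$params,
    vocabulary = enc$vocabulary,
    config = config,
    selected_epoch = as.integer(selected_epoch),
    fold_validation_losses = fold_losses,
    train_loss = fit$train_loss,
    training_length_set = sort(unique(concat_len)),
    cdr1_len = modal_weighted(nchar(x$cdr1), w),
    cdr2_len = modal_weighted(nchar(x$cdr2), w),
    n_train = n
  ), class = "vhh_lstm")
}

#' @export
print.vhh_lstm <- function(x, ...) {
  cat(sprintf(
    "<vhh_lstm> %d layers x %d units, %d unique training sequences, epoch %d\n",
    x$config$num_layers, x$config$hidden_units, x$n_train, x$selected_epoch))
  invisible(x)
}

#' Sample new CDR triplets from a trained model
#'
#' Autoregressive sampling from the start token with softmax temperature;
#' generation stops at the end token or at the maximum training length.
#' Sampled sequences whose total length is not among the training lengths
#' are discarded and redrawn (up to `max_retry_factor * n` total draws;
#' if the budget is exhausted a warning reports the shortfall and a
#' partial result is returned). CDR boundaries are re-imposed from the
#' cluster's fixed CDR1/CDR2 lengths. `temperature` near zero reduces to
#' greedy argmax decoding.
#'
#' @param model A `vhh_lstm`.
#' @param n Number of sequences to return.
#' @param temperature Softmax temperature; defaults to the config value.
#' @param max_retry_factor Total-draw budget as a multiple of `n`.
#' @return Tibble with `cdr1`, `cdr2`, `cdr3`, `source = "sampled"`.
#' @export
sample_sequences <- function(model, n = model$config$sample_n,
                             temperature = model$config$temperature,
                             max_retry_factor = 20) {
  stopifnot(inherits(model, "vhh_lstm"))
  n <- as.integer(n)
  empty <- tibble(cdr1 = character(0), cdr2 = character(0),
                  cdr3 = character(0), source = character(0))
  if (n <= 0) return(empty)
  max_len <- max(model$training_length_set)
  min_body <- model$cdr1_len + model$cdr2_len
  inv <- names(model$vocabulary)
  kept <- character(0)
  drawn <- 0L
  budget <- max_retry_factor * n
  while (length(kept) < n && drawn < budget) {
    batch <- min(n - length(kept), budget - drawn)
    toks <- cpp_lstm_sample(model$params, batch, temperature, max_len)
    drawn <- drawn + batch
    seqs <- apply(toks, 1, function(row) {
      row <- row[row > 0 & row <= 20]
      paste(inv[row], collapse = "")
    })
    ok <- nchar(seqs) %in% model$training_length_set & nchar(seqs) > min_body
    kept <- c(kept, seqs[ok])
  }
  if (length(kept) < n) {
    warning(sprintf("retry budget exhausted: %d of %d sequences sampled",
                    length(kept), n))
  }
  kept <- kept[seq_len(min(n, length(kept)))]
  tibble(
    cdr1 = substr(kept, 1, model$cdr1_len),
    cdr2 = substr(kept, model$cdr1_len + 1, min_body),
    cdr3 = substr(kept, min_body + 1, nchar(kept)),
    source = rep("sampled", length(kept))
  )
}

#' Negative log-likelihood of sequences under a trained model
#'
#' `NLL = -sum_k ln p(x_k)`: the sum over sequence positions of the
#' model's stepwise probability of each observed token, by default
#' including the end token. Probabilities are floored at 1e-12 before the
#' logarithm, so the score is always finite and non-negative; lower means
#' more typical of the sorted training pool.
#'
#' @param model A `vhh_lstm`.
#' @param x Data frame with `cdr1`, `cdr2`, `cdr3` columns.
#' @param include_end Include the end-of-sequence token's term.
#' @return Numeric vector of NLL scores (>= 0).
#' @export
sequence_nll <- function(model, x, include_end = TRUE) {
  stopifnot(inherits(model, "vhh_lstm"))
  enc <- encode_sequences(x)
  as.numeric(cpp_lstm_nll(model$params, enc$tokens, enc$lengths, include_end))
}

#' Combine training and sampled sequences and rank by NLL
#'
#' The union is deduplicated on the CDR triplet (a sequence present in
#' both keeps `source = "ngs"`), scored with [sequence_nll()] and sorted
#' ascending; ties break lexicographically on (cdr1, cdr2, cdr3).
#'
#' @param training Repertoire tibble (NGS sequences).
#' @param sampled Tibble from [sample_sequences()].
#' @param model A `vhh_lstm`.
#' @return Tibble `cdr1`, `cdr2`, `cdr3`, `source`, `nll`, `rank`.
#' @export
rank_pool <- function(training, sampled, model) {
  tr <- as_tibble(training)[, c("cdr1", "cdr2", "cdr3")]
  tr$source <- "ngs"
  sa <- as_tibble(sampled)[, c("cdr1", "cdr2", "cdr3")]
  if (nrow(sa) > 0) sa$source <- "sampled"
  pool <- bind_rows(tr, sa) %>%
    group_by(.data$cdr1, .data$cdr2, .data$cdr3) %>%
    summarise(source = if (any(.data$source == "ngs")) "ngs" else "sampled",
              .groups = "drop")
  pool$nll <- sequence_nll(model, pool)
  pool <- pool %>% arrange(.data$nll, .data$cdr1, .data$cdr2, .data$cdr3)
  pool$rank <- seq_len(nrow(pool))
  pool
}

#' @describeIn train_generative_model Cross-validation losses in long form
#'   (`fold`, `epoch`, `val_loss`).
#' @param x,... Method arguments.
#' @export
tidy.vhh_lstm <- function(x, ...) {
  if (is.null(x$fold_validation_losses)) {
    return(tibble(fold = integer(0), epoch = integer(0),
                  val_loss = numeric(0)))
  }
  m <- x$fold_validation_losses
  tibble(
    fold = rep(seq_len(nrow(m)), times = ncol(m)),
    epoch = rep(seq_len(ncol(m)), each = nrow(m)),
    val_loss = as.vector(m)
  )
}

#' @describeIn train_generative_model One-row model summary.
#' @export
glance.vhh_lstm <- function(x, ...) {
  tibble(
    layers = x$config$num_layers,
    hidden_units = x$config$hidden_units,
    dropout = x$config$dropout,
    cv_folds = x$config$cv_folds,
    selected_epoch = x$selected_epoch,
    n_train = x$n_train,
    vocab_size = length(x$vocabulary),
    final_train_loss = x$train_loss[length(x$train_loss)]
  )
}

#' @describeIn train_generative_model Cross-validation loss curves.
#' @param object A `vhh_lstm`.
#' @export
autoplot.vhh_lstm <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) abort("model was trained without cross-validation")
  mean_df <- df %>% group_by(.data$epoch) %>%
    summarise(val_loss = mean(.data$val_loss), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$val_loss,
                                   group = .data$fold)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$selected_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "validation loss (per token)") +
    ggplot2::theme_minimal()
}

#' Save / load a trained model bundle
#'
#' @param model A `vhh_lstm`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `vhh_lstm` (load).
#' @export
save_generative_model <- function(model, path) {
  stopifnot(inherits(model, "vhh_lstm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_generative_model
#' @export
load_generative_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vhh_lstm"))
  model
}
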