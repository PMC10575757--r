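# construct a weight bundle by hand: zero recurrence, output bias only
manual_model <- function(logit_bias) {
  vocab <- model_vocabulary()
  D <- length(vocab); H <- 4L; L <- 2L
  zeros <- function(r, c) matrix(0, r, c)
  params <- list(layers = L, hidden = H, vocab = D,
                 W = list(zeros(4 * H, D), zeros(4 * H, H)),
                 U = list(zeros(4 * H, H), zeros(4 * H, H)),
                 b = list(rep(0, 4 * H), rep(0, 4 * H)),
                 V = zeros(D, H), c = logit_bias)
  structure(list(params = params, vocabulary = vocab,
                 config = generative_config(sample_n = 10L),
                 selected_epoch = 1L, fold_validation_losses = NULL,
                 train_loss = 0, training_length_set = 36L,
                 cdr1_len = 10L, cdr2_len = 8L, n_train = 1L),
            class = "vhh_lstm")
}

test_that("encoding is invertible and pads to the batch maximum", {
  set.seed(31)
  df <- tibble::tibble(cdr1 = random_aa(10, 10), cdr2 = random_aa(10, 8),
                       cdr3 = random_aa(10, 18))
  enc <- encode_sequences(df)
  expect_equal(dim(enc$tokens), c(38, 10))  # 36 residues + start/end
  expect_equal(as.data.frame(decode_sequences(enc)), as.data.frame(df))

  jag <- tibble::tibble(cdr1 = c("GFTFSSYAIS", "GFTFSSYAIS"),
                        cdr2 = c("SSGSNTAA", "SSGSNTAA"),
                        cdr3 = c("VFTPTDTVVFTNKEPY", "VFTPTDTVVFTNKEPYNY"))
  enc2 <- encode_sequences(jag)
  expect_equal(nrow(enc2$tokens), 36 + 2)   # padded to longest + specials
  expect_equal(enc2$lengths, c(36L, 38L))
  expect_equal(sum(enc2$tokens[, 1] == 0), 2)  # pad positions

  empty <- encode_sequences(tibble::tibble(cdr1 = character(0),
                                           cdr2 = character(0),
                                           cdr3 = character(0)))
  expect_equal(ncol(empty$tokens), 0)

  oh <- as_one_hot(enc2)
  expect_equal(dim(oh), c(2, 38, 23))
  expect_equal(sum(oh[1, , ]), 36)  # one-hot rows only on non-pad positions
})

test_that("a probability-one model has zero NLL and the uniform model K*ln(20)", {
  vocab <- model_vocabulary()
  fav <- manual_model({b <- rep(-200, 23); b[vocab["A"]] <- 200; b})
  seq_a <- tibble::tibble(cdr1 = strrep("A", 10), cdr2 = strrep("A", 8),
                          cdr3 = strrep("A", 18))
  expect_equal(sequence_nll(fav, seq_a, include_end = FALSE), 0,
               tolerance = 1e-8)

  unif <- manual_model({b <- rep(-1e9, 23); b[1:20] <- 0; b})
  set.seed(5)
  seq36 <- tibble::tibble(cdr1 = random_aa(1, 10), cdr2 = random_aa(1, 8),
                          cdr3 = random_aa(1, 18))
  expect_equal(sequence_nll(unif, seq36, include_end = FALSE), 36 * log(20),
               tolerance = 1e-8)
})

test_that("NLL is finite, non-negative and non-decreasing in sequence length", {
  m <- train_generative_model(tiny_cluster(), generative_config(
    hidden_units = 8L, max_epochs = 3L, cv_folds = 2L, seed = 2L))
  full <- "AGGMGSTTVVVSTIPYKY"
  prev <- 0
  for (k in 1:nchar(full)) {
    nll <- sequence_nll(m, tibble::tibble(cdr1 = "", cdr2 = "",
                                          cdr3 = substr(full, 1, k)),
                        include_end = FALSE)
    expect_gte(nll, prev)
    expect_true(is.finite(nll))
    prev <- nll
  }
})

test_that("temperature -> 0 sampling equals an independent greedy decode", {
  m <- train_generative_model(tiny_cluster(), generative_config(
    hidden_units = 8L, max_epochs = 4L, cv_folds = 2L, seed = 13L))
  # R-side forward pass, written against the weight-bundle contract
  r_greedy <- function(params, max_steps) {
    L <- params$layers; H <- params$hidden; D <- params$vocab
    sig <- function(x) 1 / (1 + exp(-x))
    h <- replicate(L, rep(0, H), simplify = FALSE); cs <- h
    tok <- D - 2L
    out <- integer(0)
    for (step in seq_len(max_steps)) {
      x <- rep(0, D); x[tok] <- 1
      inp <- x
      for (l in seq_len(L)) {
        z <- params$W[[l]] %*% inp + params$U[[l]] %*% h[[l]] + params$b[[l]]
        i <- sig(z[1:H]); f <- sig(z[(H + 1):(2 * H)])
        g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sig(z[(3 * H + 1):(4 * H)])
        cs[[l]] <- f * cs[[l]] + i * g
        h[[l]] <- o * tanh(cs[[l]])
        inp <- h[[l]]
      }
      logits <- as.vector(params$V %*% inp + params$c)
      logits[c(D - 2L, D)] <- -Inf
      nxt <- which.max(logits)
      if (nxt == D - 1L) break
      out <- c(out, nxt)
      tok <- nxt
    }
    paste(names(model_vocabulary())[out], collapse = "")
  }
  expected <- r_greedy(m$params, max(m$training_length_set))
  set.seed(1)
  got <- suppressWarnings(
    sample_sequences(m, 3, temperature = 1e-12, max_retry_factor = 100))
  if (nrow(got) > 0) {
    expect_true(all(paste0(got$cdr1, got$cdr2, got$cdr3) == expected))
  } else {
    # greedy decode of this model leaves the training length set entirely
    expect_false(nchar(expected) %in% m$training_length_set)
  }
})

test_that("sampling respects the training length contract and n = 0", {
  m <- train_generative_model(tiny_cluster(), generative_config(
    hidden_units = 8L, max_epochs = 4L, cv_folds = 2L, seed = 13L))
  expect_equal(nrow(sample_sequences(m, 0)), 0)
  set.seed(3)
  s <- sample_sequences(m, 50)
  expect_true(all(nchar(paste0(s$cdr1, s$cdr2, s$cdr3)) %in%
                    m$training_length_set))
  expect_true(all(s$source == "sampled"))
  expect_true(all(nchar(s$cdr1) == m$cdr1_len & nchar(s$cdr2) == m$cdr2_len))
})

test_that("training, sampling and scoring are deterministic under a fixed seed", {
  cfg <- generative_config(hidden_units = 8L, max_epochs = 3L, cv_folds = 2L,
                           seed = 17L)
  m1 <- train_generative_model(tiny_cluster(), cfg)
  m2 <- train_generative_model(tiny_cluster(), cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$selected_epoch, m2$selected_epoch)
  set.seed(9); s1 <- sample_sequences(m1, 25)
  set.seed(9); s2 <- sample_sequences(m2, 25)
  expect_identical(s1, s2)
  q <- tiny_cluster()[1:5, ]
  expect_identical(sequence_nll(m1, q), sequence_nll(m2, q))
})

test_that("cross-validated epoch beats the first epoch on validation loss", {
  m <- train_generative_model(tiny_cluster(60), generative_config(
    hidden_units = 8L, max_epochs = 6L, cv_folds = 3L, seed = 23L))
  means <- colMeans(m$fold_validation_losses)
  expect_equal(m$selected_epoch, which.min(means))
  expect_lte(means[m$selected_epoch], means[1])
})

test_that("training refuses fewer unique sequences than folds", {
  few <- tiny_cluster()[1:3, ]
  expect_error(train_generative_model(few, generative_config(cv_folds = 5L)),
               "at least 5")
})

test_that("rank_pool deduplicates on the triplet and keeps the NGS label", {
  m <- train_generative_model(tiny_cluster(), generative_config(
    hidden_units = 8L, max_epochs = 3L, cv_folds = 2L, seed = 2L))
  train <- tiny_cluster()[1:10, ]
  dup <- train[1, c("cdr1", "cdr2", "cdr3")]
  dup$source <- "sampled"
  sampled <- dplyr::bind_rows(dup, tibble::tibble(
    cdr1 = "GGTFGSYAIS", cdr2 = "RSGGSTAA",
    cdr3 = "AGGMGSTTVVVSTIPYKA", source = "sampled"))
  pool <- rank_pool(train, sampled, m)
  expect_equal(nrow(pool), 11)  # 10 unique NGS + 1 new sampled
  hit <- pool[pool$cdr3 == train$cdr3[1] & pool$cdr1 == train$cdr1[1], ]
  expect_equal(hit$source, "ngs")
  expect_false(is.unsorted(pool$nll))
  expect_equal(pool$rank, seq_len(nrow(pool)))
})

test_that("model bundles survive a save/load round trip", {
  m <- train_generative_model(tiny_cluster(), generative_config(
    hidden_units = 8L, max_epochs = 2L, cv_folds = 2L, seed = 4L))
  p <- withr::local_tempfile(fileext = ".rds")
  save_generative_model(m, p)
  m2 <- load_generative_model(p)
  q <- tiny_cluster()[1:4, ]
  expect_identical(sequence_nll(m, q), sequence_nll(m2, q))
  expect_identical(m$vocabulary, m2$vocabulary)
})
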