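# Hierarchical biRNN tagger: forward contracts, gradients, training.

toy_params <- function(vocab_size = 6, d_e = 3, h = 4, seed = 2) {
  init_tagger(vocab_size, d_e = d_e, h = h, seed = seed, scale = 0.3)
}

test_that("zero weights give exactly 0.5 probabilities", {
  p <- toy_params()
  zero <- rapply(p[c("E", "fwd", "bwd", "upper", "head_emotion",
                     "head_fact")],
                 function(x) x * 0, how = "replace")
  p[names(zero)] <- zero
  out <- forward_tagger(c(2, 3, 4), p)
  expect_equal(out$p_emotional, rep(0.5, 3))
  expect_equal(out$p_factual, rep(0.5, 3))
})

test_that("single-token states equal one hand-rolled cell step", {
  p <- toy_params()
  out <- forward_tagger(3L, p)
  x <- p$E[3, ]
  hf <- tanh(p$fwd$Wx %*% x + p$fwd$b)
  hb <- tanh(p$bwd$Wx %*% x + p$bwd$b)
  expect_equal(out$H[1, ], c(hf, hb), tolerance = 1e-12)
  z <- p$head_emotion$W %*% out$H[1, ] + p$head_emotion$b
  expect_equal(out$p_emotional, exp(z[1]) / sum(exp(z)), tolerance = 1e-12)
})

test_that("probabilities are normalized and markers pass through", {
  p <- toy_params()
  ids <- c(2, 5, 3, 3, 6)
  mk <- c(0.4, 1.1, 2.0, 2.3, 3.1)
  out <- forward_tagger(ids, p, markers = mk)
  expect_true(all(out$p_emotional > 0 & out$p_emotional < 1))
  expect_identical(out$markers, mk)
  expect_equal(length(out$p_factual), 5)
  expect_error(forward_tagger(integer(0), p), "empty")
  expect_error(forward_tagger(99L, p), "out of range")
})

test_that("reversing input and swapping direction cells reverses output", {
  p <- toy_params()
  ids <- c(2, 3, 4, 5)
  fwd <- forward_tagger(ids, p)
  ps <- p
  ps$fwd <- p$bwd; ps$bwd <- p$fwd
  rev_out <- forward_tagger(rev(ids), ps)
  # hidden states swap blocks and reverse in time
  h <- p$h
  expect_equal(rev_out$H[, c(h + 1:h, 1:h)], fwd$H[rev(seq_along(ids)), ],
               tolerance = 1e-12)
})

test_that("document encoding follows the sentence hierarchy contract", {
  p <- toy_params()
  s1 <- c(2, 3); s2 <- c(4, 5, 6)
  enc <- encode_document(list(s1, s2), p)
  expect_equal(dim(enc$sentence_mat), c(2, 2 * p$h))
  # identical sentences give identical vectors
  enc2 <- encode_document(list(s1, s1, s1), p)
  expect_equal(enc2$sentence_mat[1, ], enc2$sentence_mat[2, ])
  # one sentence: document vector is a single upper-cell step
  enc1 <- encode_document(list(s1), p)
  u <- tanh(p$upper$Wx %*% enc1$sentence_mat[1, ] + p$upper$b)
  expect_equal(enc1$document, as.numeric(u), tolerance = 1e-12)
  expect_error(encode_document(list(), p), "empty")
})

test_that("analytic gradients match central finite differences", {
  p <- toy_params(vocab_size = 5, d_e = 2, h = 3, seed = 4)
  corpus <- list(list(tokens = c(2L, 4L, 3L), emotional = c(1, 0, 1),
                      factual = c(0, 1, 1)))
  lg <- narrafnirs:::.tagger_loss_grad(p, corpus)
  eps <- 1e-6
  leaves <- list(c("E"), c("fwd", "Wx"), c("fwd", "Wh"), c("fwd", "b"),
                 c("bwd", "Wx"), c("bwd", "Wh"), c("bwd", "b"),
                 c("head_emotion", "W"), c("head_emotion", "b"),
                 c("head_fact", "W"), c("head_fact", "b"))
  for (leaf in leaves) {
    arr <- if (length(leaf) == 1) p[[leaf]] else p[[leaf[1]]][[leaf[2]]]
    g <- if (length(leaf) == 1) lg$grads[[leaf]] else
      lg$grads[[leaf[1]]][[leaf[2]]]
    idx <- sample(length(arr), min(4, length(arr)))
    for (i in idx) {
      pp <- p; pm <- p
      if (length(leaf) == 1) {
        pp[[leaf]][i] <- pp[[leaf]][i] + eps
        pm[[leaf]][i] <- pm[[leaf]][i] - eps
      } else {
        pp[[leaf[1]]][[leaf[2]]][i] <- pp[[leaf[1]]][[leaf[2]]][i] + eps
        pm[[leaf[1]]][[leaf[2]]][i] <- pm[[leaf[1]]][[leaf[2]]][i] - eps
      }
      num <- (narrafnirs:::.tagger_loss_grad(pp, corpus)$loss -
                narrafnirs:::.tagger_loss_grad(pm, corpus)$loss) / (2 * eps)
      expect_lt(abs(num - g[i]), 1e-5)
    }
  }
})

test_that("training is deterministic and its loss non-increasing", {
  set.seed(6)
  corpus <- lapply(1:6, function(i) {
    ids <- sample(2:5, 8, replace = TRUE)
    list(tokens = ids, emotional = as.numeric(ids %in% c(2, 3)),
         factual = as.numeric(ids %in% c(3, 4)))
  })
  fit1 <- train_tagger(corpus, vocab_size = 5, d_e = 4, h = 4,
                       epochs = 30, lr = 0.5, seed = 7)
  fit2 <- train_tagger(corpus, vocab_size = 5, d_e = 4, h = 4,
                       epochs = 30, lr = 0.5, seed = 7)
  expect_identical(fit1$loss, fit2$loss)
  expect_true(all(diff(fit1$loss) <= 1e-8))
  bad <- list(list(tokens = c(2L, 3L), emotional = c(1, 1),
                   factual = c(0, 1)))
  expect_error(train_tagger(bad, 5), "both classes")
})

test_that("a lexically separable corpus is learned perfectly", {
  # two-word vocabulary: word 2 emotional, word 3 factual
  mk <- function(n) lapply(1:n, function(i) {
    ids <- sample(c(2L, 3L), 6, replace = TRUE)
    list(tokens = ids, emotional = as.numeric(ids == 2),
         factual = as.numeric(ids == 3))
  })
  set.seed(8)
  fit <- train_tagger(mk(8), vocab_size = 3, d_e = 4, h = 4,
                      epochs = 150, lr = 1, seed = 9)
  set.seed(99)
  held <- mk(4)
  for (sq in held) {
    out <- forward_tagger(sq$tokens, fit$params)
    expect_equal(as.numeric(out$p_emotional > 0.5), sq$emotional)
    expect_equal(as.numeric(out$p_factual > 0.5), sq$factual)
  }
})

test_that("trained tagger agrees with the lexicon on synthetic narratives", {
  spec <- cohort_spec(n_ptsd = 3, n_tec = 3, seed = 30)
  coh <- generate_cohort(spec)
  lex <- default_lexicon()
  trs <- lapply(seq_len(nrow(coh)), function(i)
    generate_transcript(coh[i, ], spec))
  vocab <- tagger_vocab(unique(unlist(lapply(trs[1:5], `[[`, "token"))))
  corp <- lapply(trs, function(tr) {
    cat <- unname(lex[tr$token])
    list(tokens = tokens_to_ids(tr$token, vocab),
         emotional = as.numeric(cat %in% c("negative", "positive")),
         factual = as.numeric(cat == "factual"))
  })
  fit <- train_tagger(corp[1:5], vocab_size = max(vocab) ,
                      d_e = 8, h = 8, epochs = 120, lr = 2, seed = 10)
  held <- corp[[6]]
  out <- forward_tagger(held$tokens, fit$params)
  # agreement scored over in-vocabulary tokens: the many hapax words of
  # an unseen narrative cannot be classified lexically by any tagger
  seen <- held$tokens != 1L
  acc_e <- mean((out$p_emotional > 0.5)[seen] == (held$emotional[seen] == 1))
  acc_f <- mean((out$p_factual > 0.5)[seen] == (held$factual[seen] == 1))
  expect_gte(acc_e, 0.95)
  expect_gte(acc_f, 0.95)
})

test_that("tagger parameters survive a JSON round trip", {
  p <- toy_params()
  vocab <- tagger_vocab(c("alpha", "beta", "gamma", "delta", "eps"))
  tmp <- tempfile(fileext = ".json")
  save_tagger(p, vocab, tmp)
  back <- load_tagger(tmp)
  ids <- c(2, 4, 3)
  expect_equal(forward_tagger(ids, back$params)$p_emotional,
               forward_tagger(ids, p)$p_emotional, tolerance = 1e-12)
  expect_identical(unname(back$vocab["beta"]), unname(vocab["beta"]))
})
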