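# Hierarchical bidirectional-RNN token tagger with two parallel softmax
# heads (emotional-vs-not, factual-vs-not). Elman (tanh) cells; per-token
# heads applied to the concatenated forward/backward states so each
# token keeps its onset marker. Trained by full-batch gradient descent
# with analytically derived gradients (verified against finite
# differences in the test suite).

#' Build a tagger vocabulary
#'
#' @param words Character vector of known surface forms.
#' @return Named integer index; index 1 is the out-of-vocabulary slot.
#' @export
tagger_vocab <- function(words) {
  words <- unique(words)
  structure(seq_along(words) + 1L, names = words, oov = 1L,
            class = "tagger_vocab")
}

#' Map tokens to vocabulary indices
#' @param tokens Character vector.
#' @param vocab A [tagger_vocab()].
#' @return Integer vector (out-of-vocabulary tokens map to index 1).
#' @export
tokens_to_ids <- function(tokens, vocab) {
  i <- unname(vocab[tokens])
  i[is.na(i)] <- 1L
  i
}

.cell_init <- function(h, d, scale) {
  list(Wx = matrix(runif(h * d, -scale, scale), h, d),
       Wh = matrix(runif(h * h, -scale, scale), h, h),
       b = numeric(h))
}

#' Initialize tagger parameters
#'
#' @param vocab_size Number of embedding rows (vocabulary incl. OOV).
#' @param d_e Embedding dimension (default 16).
#' @param h Hidden size of each direction (default 32); token states are
#'   `2h`-dimensional after concatenation.
#' @param seed RNG seed for the initialization.
#' @param scale Uniform initialization half-width.
#' @return List of class `tagger_params` with embedding `E`, forward and
#'   backward cells, an upper document-level cell, and the two heads.
#' @export
init_tagger <- function(vocab_size, d_e = 16, h = 32, seed = 1,
                        scale = 0.1) {
  with_local_seed(seed, {
    p <- list(
      E = matrix(runif(vocab_size * d_e, -scale, scale), vocab_size, d_e),
      fwd = .cell_init(h, d_e, scale),
      bwd = .cell_init(h, d_e, scale),
      upper = .cell_init(2L * h, 2L * h, scale),
      head_emotion = list(W = matrix(runif(4 * h, -scale, scale), 2, 2 * h),
                          b = numeric(2)),
      head_fact = list(W = matrix(runif(4 * h, -scale, scale), 2, 2 * h),
                       b = numeric(2)),
      d_e = d_e, h = h, vocab_size = vocab_size)
    class(p) <- "tagger_params"
    p
  })
}

# biRNN pass over one index sequence; returns hidden matrices.
.birnn_states <- function(ids, params) {
  X <- params$E[ids, , drop = FALSE]
  T_ <- length(ids); h <- params$h
  HF <- matrix(0, T_, h); HB <- matrix(0, T_, h)
  hf <- numeric(h)
  for (t in seq_len(T_)) {
    hf <- tanh(params$fwd$Wx %*% X[t, ] + params$fwd$Wh %*% hf + params$fwd$b)
    HF[t, ] <- hf
  }
  hb <- numeric(h)
  for (t in rev(seq_len(T_))) {
    hb <- tanh(params$bwd$Wx %*% X[t, ] + params$bwd$Wh %*% hb + params$bwd$b)
    HB[t, ] <- hb
  }
  list(X = X, HF = HF, HB = HB, H = cbind(HF, HB))
}

.softmax2 <- function(Z) {
  m <- pmax(Z[, 1], Z[, 2])
  e1 <- exp(Z[, 1] - m); e2 <- exp(Z[, 2] - m)
  cbind(e1 / (e1 + e2), e2 / (e1 + e2))
}

#' Forward pass of the token tagger
#'
#' Computes the biRNN state sequence H (forward and backward states
#' concatenated per token) and applies both softmax heads per token.
#' Onset markers, if supplied, are passed through unchanged.
#'
#' @param ids Integer token indices (OOV already mapped to 1).
#' @param params A `tagger_params` object.
#' @param markers Optional per-token marker vector (e.g. onset seconds).
#' @return List with `p_emotional`, `p_factual` (per-token probabilities
#'   of the positive class), `H`, and `markers`.
#' @export
forward_tagger <- function(ids, params, markers = NULL) {
  if (length(ids) == 0) stop("empty token sequence")
  if (any(ids < 1 | ids > params$vocab_size)) stop("token index out of range")
  if (!is.null(markers) && length(markers) != length(ids))
    stop("markers must match the token sequence")
  st <- .birnn_states(ids, params)
  Pe <- .softmax2(st$H %*% t(params$head_emotion$W) +
                    matrix(params$head_emotion$b, length(ids), 2, byrow = TRUE))
  Pf <- .softmax2(st$H %*% t(params$head_fact$W) +
                    matrix(params$head_fact$b, length(ids), 2, byrow = TRUE))
  list(p_emotional = Pe[, 1], p_factual = Pf[, 1], H = st$H,
       markers = markers)
}

#' Encode a document through the sentence hierarchy
#'
#' Each sentence is encoded by the shared biRNN; its vector `s_j` is the
#' concatenation of the final forward and final backward states. An
#' upper-level Elman cell consumes `s_1..s_J` and its final state is the
#' document representation.
#'
#' @param sentences List of integer index vectors (one per sentence).
#' @param params A `tagger_params` object.
#' @return List with `document` (the `2h` upper state) and `sentence_mat`
#'   (J x 2h matrix of sentence vectors).
#' @export
encode_document <- function(sentences, params) {
  if (length(sentences) == 0) stop("empty sentence list")
  h <- params$h
  S <- t(vapply(sentences, function(ids) {
    if (length(ids) == 0) stop("empty sentence")
    st <- .birnn_states(ids, params)
    c(st$HF[length(ids), ], st$HB[1, ])
  }, numeric(2 * h)))
  u <- numeric(2 * h)
  for (j in seq_len(nrow(S))) {
    u <- tanh(params$upper$Wx %*% S[j, ] + params$upper$Wh %*% u +
                params$upper$b)
  }
  list(document = as.numeric(u), sentence_mat = S)
}

# Loss and analytic gradients of the summed two-head cross-entropy over
# a labelled corpus. Returns list(loss, grads) where grads mirrors the
# trainable parameter structure.
.tagger_loss_grad <- function(params, corpus) {
  h <- params$h; d_e <- params$d_e
  g <- list(E = matrix(0, params$vocab_size, d_e),
            fwd = list(Wx = matrix(0, h, d_e), Wh = matrix(0, h, h),
                       b = numeric(h)),
            bwd = list(Wx = matrix(0, h, d_e), Wh = matrix(0, h, h),
                       b = numeric(h)),
            head_emotion = list(W = matrix(0, 2, 2 * h), b = numeric(2)),
            head_fact = list(W = matrix(0, 2, 2 * h), b = numeric(2)))
  loss <- 0
  for (seqd in corpus) {
    ids <- seqd$tokens
    T_ <- length(ids)
    st <- .birnn_states(ids, params)
    dH <- matrix(0, T_, 2 * h)
    for (head in c("head_emotion", "head_fact")) {
      y <- if (head == "head_emotion") seqd$emotional else seqd$factual
      W <- params[[head]]$W; b <- params[[head]]$b
      P <- .softmax2(st$H %*% t(W) + matrix(b, T_, 2, byrow = TRUE))
      tgt <- ifelse(y == 1, 1L, 2L)
      loss <- loss - sum(log(pmax(P[cbind(seq_len(T_), tgt)], 1e-300)))
      dZ <- P
      dZ[cbind(seq_len(T_), tgt)] <- dZ[cbind(seq_len(T_), tgt)] - 1
      g[[head]]$W <- g[[head]]$W + t(dZ) %*% st$H
      g[[head]]$b <- g[[head]]$b + colSums(dZ)
      dH <- dH + dZ %*% W
    }
    dX <- matrix(0, T_, d_e)
    # forward cell BPTT
    carry <- numeric(h)
    for (t in rev(seq_len(T_))) {
      dh <- dH[t, seq_len(h)] + carry
      da <- dh * (1 - st$HF[t, ]^2)
      hprev <- if (t > 1) st$HF[t - 1, ] else numeric(h)
      g$fwd$Wx <- g$fwd$Wx + outer(da, st$X[t, ])
      g$fwd$Wh <- g$fwd$Wh + outer(da, hprev)
      g$fwd$b <- g$fwd$b + da
      dX[t, ] <- dX[t, ] + as.numeric(crossprod(params$fwd$Wx, da))
      carry <- as.numeric(crossprod(params$fwd$Wh, da))
    }
    # backward cell BPTT (recursion runs T..1, so unroll 1..T)
    carry <- numeric(h)
    for (t in seq_len(T_)) {
      dh <- dH[t, h + seq_len(h)] + carry
      da <- dh * (1 - st$HB[t, ]^2)
      hnext <- if (t < T_) st$HB[t + 1, ] else numeric(h)
      g$bwd$Wx <- g$bwd$Wx + outer(da, st$X[t, ])
      g$bwd$Wh <- g$bwd$Wh + outer(da, hnext)
      g$bwd$b <- g$bwd$b + da
      dX[t, ] <- dX[t, ] + as.numeric(crossprod(params$bwd$Wx, da))
      carry <- as.numeric(crossprod(params$bwd$Wh, da))
    }
    for (t in seq_len(T_)) g$E[ids[t], ] <- g$E[ids[t], ] + dX[t, ]
  }
  list(loss = loss, grads = g)
}

.tagger_apply_grads <- function(params, grads, lr) {
  params$E <- params$E - lr * grads$E
  for (cell in c("fwd", "bwd")) {
    params[[cell]]$Wx <- params[[cell]]$Wx - lr * grads[[cell]]$Wx
    params[[cell]]$Wh <- params[[cell]]$Wh - lr * grads[[cell]]$Wh
    params[[cell]]$b <- params[[cell]]$b - lr * grads[[cell]]$b
  }
  for (head in c("head_emotion", "head_fact")) {
    params[[head]]$W <- params[[head]]$W - lr * grads[[head]]$W
    params[[head]]$b <- params[[head]]$b - lr * grads[[head]]$b
  }
  params
}

#' Train the tagger on a labelled corpus
#'
#' Full-batch gradient descent on the summed per-token cross-entropy of
#' both heads. Deterministic for a given seed.
#'
#' @param corpus List of sequences; each is a list with integer `tokens`
#'   and 0/1 vectors `emotional` and `factual` of the same length.
#' @param vocab_size Vocabulary size (incl. OOV slot).
#' @param d_e,h Network dimensions (see [init_tagger()]).
#' @param epochs Number of full-batch steps.
#' @param lr Learning rate.
#' @param seed Initialization seed.
#' @return List with trained `params` and the per-epoch `loss` log.
#' @export
train_tagger <- function(corpus, vocab_size, d_e = 16, h = 32,
                         epochs = 50, lr = 0.05, seed = 1) {
  ye <- unlist(lapply(corpus, `[[`, "emotional"))
  yf <- unlist(lapply(corpus, `[[`, "factual"))
  if (length(unique(ye)) < 2 || length(unique(yf)) < 2)
    stop("corpus must contain both classes for both heads")
  ntok <- length(ye)
  params <- init_tagger(vocab_size, d_e = d_e, h = h, seed = seed)
  log <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lg <- .tagger_loss_grad(params, corpus)
    log[e] <- lg$loss
    params <- .tagger_apply_grads(params, lapply_grads_scale(lg$grads, 1 / ntok),
                                  lr)
  }
  list(params = params, loss = log)
}

# scale every gradient leaf by s (per-token normalization)
lapply_grads_scale <- function(g, s) {
  rapply(g, function(x) x * s, classes = "ANY", how = "replace")
}

#' Tag a transcript with a trained tagger
#'
#' @param transcript Transcript data.frame (column `token`).
#' @param params Trained `tagger_params`.
#' @param vocab The [tagger_vocab()] used in training.
#' @param threshold Decision threshold (default 0.5).
#' @return The transcript with logical columns `emotional`, `factual`;
#'   onsets untouched.
#' @export
tag_with_tagger <- function(transcript, params, vocab, threshold = 0.5) {
  ids <- tokens_to_ids(transcript$token, vocab)
  out <- forward_tagger(ids, params, markers = transcript$onset_s)
  transcript$emotional <- out$p_emotional > threshold
  transcript$factual <- out$p_factual > threshold
  transcript
}

#' Serialize / restore tagger parameters as JSON
#'
#' @param params A `tagger_params` object.
#' @param vocab The associated [tagger_vocab()].
#' @param path File path.
#' @return `load_tagger` returns `list(params, vocab)`.
#' @export
save_tagger <- function(params, vocab, path) {
  obj <- list(d_e = params$d_e, h = params$h,
              vocab_size = params$vocab_size,
              vocab = as.list(unclass(vocab)),
              E = params$E,
              fwd = params$fwd, bwd = params$bwd, upper = params$upper,
              head_emotion = params$head_emotion,
              head_fact = params$head_fact)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else as.matrix(x)
  cell <- function(cl) list(Wx = as_mat(cl$Wx), Wh = as_mat(cl$Wh),
                            b = as.numeric(cl$b))
  params <- list(E = as_mat(obj$E), fwd = cell(obj$fwd), bwd = cell(obj$bwd),
                 upper = cell(obj$upper),
                 head_emotion = list(W = as_mat(obj$head_emotion$W),
                                     b = as.numeric(obj$head_emotion$b)),
                 head_fact = list(W = as_mat(obj$head_fact$W),
                                  b = as.numeric(obj$head_fact$b)),
                 d_e = obj$d_e, h = obj$h, vocab_size = obj$vocab_size)
  class(params) <- "tagger_params"
  vocab <- structure(as.integer(unlist(obj$vocab)),
                     names = names(obj$vocab), class = "tagger_vocab")
  list(params = params, vocab = vocab)
}
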