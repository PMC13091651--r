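# Multiscale lncRNA encoder: overlapping k-mer segmentation at several
# scales, one PV-DM document-embedding model per scale, and scaled
# dot-product self-attention to fuse the per-scale vectors into a single
# sequence embedding.

#' Segment a sequence into overlapping k-mers
#'
#' A sliding window of size k over a sequence of length L yields exactly
#' L - k + 1 tokens, consecutive tokens overlapping by k - 1 characters.
#'
#' @param seq a length-1 character RNA sequence, or a single-row [rna_set]
#' @param k window size
#' @param id identifier recorded in the document (taken from the rna_set if
#'   one is supplied)
#' @return list of class `kmer_document` with fields `rna_id`, `k`, `tokens`
#' @export
segment_kmers <- function(seq, k, id = "seq") {
  if (inherits(seq, "rna_set")) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- as.integer(k)
  L <- nchar(seq)
  if (L < k) {
    stop_fmt("sequence '%s' (length %d) is shorter than k = %d", id, L, k)
  }
  starts <- seq_len(L - k + 1L)
  tokens <- substring(seq, starts, starts + k - 1L)
  structure(list(rna_id = id, k = k, tokens = tokens),
            class = "kmer_document")
}

#' PV-DM hidden representation of a context window
#'
#' The hidden vector at a position is the arithmetic mean of the document
#' vector and the surrounding word vectors: `(doc + sum(context)) / (m + 1)`
#' where m is the number of context vectors. With a full window m = 2c; at
#' sequence edges the window contains fewer words and the mean divides by
#' the actual count.
#'
#' @param doc_vec document embedding (d-vector)
#' @param context_vecs matrix with one context word vector per row (may have
#'   fewer than 2c rows at sequence edges)
#' @return d-vector
#' @export
pvdm_hidden <- function(doc_vec, context_vecs) {
  context_vecs <- rbind(context_vecs)
  if (ncol(context_vecs) != length(doc_vec)) {
    stop_fmt("context vector width %d != document vector width %d",
             ncol(context_vecs), length(doc_vec))
  }
  (doc_vec + colSums(context_vecs)) / (nrow(context_vecs) + 1)
}

# k-mer corpus helpers --------------------------------------------------

pvdm_vocab <- function(corpus) {
  unique(unlist(lapply(corpus, `[[`, "tokens"), use.names = FALSE))
}

# integer token ids (0-based for C++; -1 for out-of-vocabulary)
tokens_to_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- 0L
  ids - 1L
}

# cumulative noise distribution: unigram frequency ^ 0.75
noise_cdf <- function(corpus, vocab) {
  counts <- table(factor(unlist(lapply(corpus, `[[`, "tokens"),
                                use.names = FALSE), levels = vocab))
  w <- as.numeric(counts)^0.75
  cumsum(w / sum(w))
}

#' Train a PV-DM model on a k-mer corpus
#'
#' Learns one document vector per k-mer document jointly with word and
#' context-prediction tables by stochastic gradient descent on the
#' negative-sampling objective (noise distribution: unigram^0.75).
#' Deterministic under the seed.
#'
#' @param corpus list of [segment_kmers] documents sharing the same k
#' @param config a [run_config] (uses embed_dim, window, n_negative,
#'   pvdm_epochs, seed)
#' @param lr SGD learning rate for pretraining
#' @return list of class `pvdm_model`: `k`, `vocab`, `word` and `context`
#'   tables (|V| x d), `doc` table (n_docs x d, rows named by rna_id),
#'   `window`, `n_negative`, `noise_cdf`, `loss_trace`, `seed`
#' @export
train_pvdm <- function(corpus, config = run_config(), lr = 0.025) {
  if (length(corpus) == 0L) stop_fmt("empty corpus")
  ks <- vapply(corpus, `[[`, 0L, "k")
  if (length(unique(ks)) != 1L) stop_fmt("documents mix different k values")
  vocab <- pvdm_vocab(corpus)
  if (length(vocab) == 0L) stop_fmt("empty vocabulary")
  docs <- lapply(corpus, function(doc) tokens_to_ids(doc$tokens, vocab))
  cdf <- noise_cdf(corpus, vocab)
  seed <- derive_seed(config$seed, paste0("pvdm_k", ks[1L]))
  fit <- .pvdm_train_cpp(docs, length(vocab), config$embed_dim,
                         config$window, config$n_negative,
                         config$pvdm_epochs, lr, cdf, seed)
  rownames(fit$doc) <- vapply(corpus, `[[`, "", "rna_id")
  structure(list(k = ks[1L], vocab = vocab, word = fit$word,
                 context = fit$context, doc = fit$doc,
                 window = config$window, n_negative = config$n_negative,
                 noise_cdf = cdf, loss_trace = as.numeric(fit$loss_trace),
                 seed = seed),
            class = "pvdm_model")
}

#' Full-softmax target probability under a PV-DM model
#'
#' Probability of a target k-mer given a hidden vector, normalized over the
#' whole vocabulary: `exp(v_target . h) / sum_w exp(v_w . h)`. Training uses
#' negative sampling; the full softmax is exposed for verification.
#'
#' @param model a [train_pvdm] model
#' @param hidden d-vector (see [pvdm_hidden])
#' @param target a k-mer in the model vocabulary
#' @return probability in (0, 1)
#' @export
pvdm_predict_prob <- function(model, hidden, target) {
  idx <- match(target, model$vocab)
  if (is.na(idx)) stop_fmt("token '%s' is not in the model vocabulary", target)
  scores <- drop(model$context %*% hidden)
  scores <- scores - max(scores)
  exp(scores[idx]) / sum(exp(scores))
}

#' Infer a document vector for an unseen sequence
#'
#' Optimizes a fresh document vector against the frozen word/context tables
#' with the same negative-sampling objective, for `steps` passes over the
#' document. Out-of-vocabulary tokens are skipped. `steps = 0` returns the
#' seeded random initialization. Used to embed sequences that were not in
#' the training corpus (blind / independent evaluation).
#'
#' @param model a [train_pvdm] model
#' @param doc a [segment_kmers] document with matching k
#' @param steps optimization passes
#' @param lr SGD learning rate
#' @param seed integer seed (defaults to one derived from the model seed and
#'   the document id)
#' @return d-vector
#' @export
infer_doc_vector <- function(model, doc, steps = 20L, lr = 0.025,
                             seed = NULL) {
  stopifnot(inherits(model, "pvdm_model"), inherits(doc, "kmer_document"))
  if (doc$k != model$k) {
    stop_fmt("document k = %d but model k = %d", doc$k, model$k)
  }
  ids <- tokens_to_ids(doc$tokens, model$vocab)
  if (all(ids < 0L)) {
    stop_fmt("document '%s' has no in-vocabulary token", doc$rna_id)
  }
  if (is.null(seed)) seed <- derive_seed(model$seed, paste0("infer::", doc$rna_id))
  .pvdm_infer_cpp(ids, model$word, model$context, model$window,
                  model$n_negative, as.integer(steps), lr, model$noise_cdf,
                  as.integer(seed))
}

# Embed a possibly-unseen sequence under one PV-DM model. Documents whose
# tokens are entirely out-of-vocabulary (common for large k on unrelated
# sequences) carry no usable information; they get the seeded random
# initialization a zero-step inference would produce.
infer_or_init <- function(model, seq, id) {
  doc <- segment_kmers(seq, model$k, id = id)
  if (any(doc$tokens %in% model$vocab)) {
    infer_doc_vector(model, doc)
  } else {
    seed <- derive_seed(model$seed, paste0("infer::", id))
    .pvdm_infer_cpp(rep(-1L, length(doc$tokens)), model$word, model$context,
                    model$window, model$n_negative, 0L, 0.025,
                    model$noise_cdf, as.integer(seed))
  }
}

# attention fusion ------------------------------------------------------

#' Initialize self-attention fusion parameters
#'
#' Square query/key/value projections of width d, Glorot-initialized.
#'
#' @param d hidden size
#' @param seed integer seed
#' @return list of class `attention_fusion` with `W_Q`, `W_K`, `W_V`, `d`
#' @export
attention_fusion <- function(d, seed = 1L) {
  set.seed(seed)
  lim <- sqrt(6 / (d + d))
  init <- function() matrix(stats::runif(d * d, -lim, lim), d, d)
  structure(list(W_Q = init(), W_K = init(), W_V = init(), d = as.integer(d)),
            class = "attention_fusion")
}

# forward pass returning intermediates needed for backprop
fuse_multiscale_forward <- function(H, att) {
  if (ncol(H) != att$d) {
    stop_fmt("stack width %d != attention width %d", ncol(H), att$d)
  }
  Q <- H %*% att$W_Q
  K <- H %*% att$W_K
  V <- H %*% att$W_V
  A <- row_softmax(Q %*% t(K) / sqrt(att$d))
  Z <- A %*% V
  list(out = colMeans(Z), Q = Q, K = K, V = V, A = A, H = H)
}

#' Fuse a multiscale embedding stack by scaled dot-product self-attention
#'
#' Rows of `H` are the per-scale embeddings of one sequence (one row per
#' k-mer scale). Attention weights are `softmax(Q K' / sqrt(d))` applied
#' row-wise; the fused embedding is the mean over rows of the attended value
#' matrix. Because the scales carry no order, no positional encoding is
#' used and the output is invariant to row permutations of `H`.
#'
#' @param H S x d matrix (a multiscale stack)
#' @param att an [attention_fusion]
#' @return fused d-vector
#' @export
fuse_multiscale <- function(H, att) {
  fuse_multiscale_forward(rbind(H), att)$out
}

# gradient of fuse_multiscale w.r.t. H and the three projections;
# g_out is the d-vector of upstream gradients
fuse_multiscale_backward <- function(cache, att, g_out) {
  S <- nrow(cache$H); d <- att$d
  gZ <- matrix(rep(g_out / S, each = S), S, d)   # colMeans backprop
  gA <- gZ %*% t(cache$V)
  gV <- t(cache$A) %*% gZ
  # softmax rows: dL/dscore = A * (gA - rowSums(gA * A))
  gS <- cache$A * (gA - rowSums(gA * cache$A))
  gS <- gS / sqrt(d)
  gQ <- gS %*% cache$K
  gK <- t(gS) %*% cache$Q
  list(W_Q = t(cache$H) %*% gQ,
       W_K = t(cache$H) %*% gK,
       W_V = t(cache$H) %*% gV,
       H = gQ %*% t(att$W_Q) + gK %*% t(att$W_K) + gV %*% t(att$W_V))
}

#' Build the multiscale embedding stack for a set of lncRNAs
#'
#' Trains (or reuses) one PV-DM model per k and stacks the per-scale
#' document vectors of each sequence into an S x d matrix. Sequences absent
#' from a model's training corpus are embedded by [infer_doc_vector].
#'
#' @param seqs an [rna_set] of lncRNAs
#' @param models named list of `pvdm_model`s keyed by k (as character)
#' @param config a [run_config]
#' @return named list of S x d matrices, one per sequence id; attribute
#'   `scales` records the k values (row order)
#' @export
multiscale_stack <- function(seqs, models, config = run_config()) {
  scales <- as.integer(names(models))
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    H <- t(vapply(as.character(scales), function(kc) {
      m <- models[[kc]]
      if (id %in% rownames(m$doc)) {
        m$doc[id, ]
      } else {
        infer_or_init(m, seqs$seq[i], id)
      }
    }, numeric(config$embed_dim)))
    rownames(H) <- as.character(scales)
    H
  })
  names(out) <- seqs$id
  attr(out, "scales") <- scales
  out
}

#' Pretrain all per-scale PV-DM models for a lncRNA corpus
#'
#' @param seqs an [rna_set] of lncRNAs
#' @param config a [run_config] (k_values, embed_dim, window, ...)
#' @return named list of `pvdm_model`s keyed by k
#' @export
pretrain_lncrna <- function(seqs, config = run_config()) {
  stopifnot(inherits(seqs, "rna_set"))
  models <- lapply(config$k_values, function(k) {
    ok <- seqs$length >= k
    if (!any(ok)) {
      stop_fmt("no sequence is long enough for k = %d", k)
    }
    corpus <- lapply(which(ok), function(i) {
      segment_kmers(seqs$seq[i], k, id = seqs$id[i])
    })
    train_pvdm(corpus, config)
  })
  names(models) <- as.character(config$k_values)
  models
}
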