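test_that("segment_kmers returns L - k + 1 overlapping tokens in order", {
  doc <- segment_kmers("ACGU", 3L, id = "t")
  expect_equal(doc$tokens, c("ACG", "CGU"))
  one <- segment_kmers("ACGUA", 5L)
  expect_equal(one$tokens, "ACGUA")
  expect_error(segment_kmers("ACG", 5L, id = "short"), "short.*k = 5")
  set.seed(3)
  for (i in 1:100) {
    L <- sample(15:300, 1L)
    k <- sample(c(3L, 9L, 15L), 1L)
    d <- segment_kmers(random_rna(L), k)
    expect_length(d$tokens, L - k + 1L)
    expect_true(all(nchar(d$tokens) == k))
  }
})

test_that("pvdm_hidden is the mean of document and context vectors", {
  x <- c(1, -2, 3)
  ctx <- matrix(rep(x, 4), 4, 3, byrow = TRUE)
  expect_equal(pvdm_hidden(x, ctx), x)
  e <- c(5, 0, -1)
  zeros <- matrix(0, 4, 3)
  expect_equal(pvdm_hidden(e, zeros), e / 5)
  set.seed(8)
  for (i in 1:20) {
    d <- sample(2:6, 1L); m <- sample(1:8, 1L)
    doc <- rnorm(d); ctx <- matrix(rnorm(m * d), m, d)
    ref <- numeric(d)  # brute-force elementwise averaging
    for (a in seq_len(d)) {
      s <- doc[a]
      for (r in seq_len(m)) s <- s + ctx[r, a]
      ref[a] <- s / (m + 1)
    }
    expect_lt(max(abs(pvdm_hidden(doc, ctx) - ref)), 1e-12)
    # linearity: doubling all inputs doubles the output
    expect_equal(pvdm_hidden(2 * doc, 2 * ctx), 2 * pvdm_hidden(doc, ctx))
  }
})

make_toy_pvdm <- function(n_docs = 10L, len = c(20L, 30L),
                          cfg = tiny_config(), lr = 0.025) {
  set.seed(cfg$seed)
  corpus <- lapply(seq_len(n_docs), function(i) {
    segment_kmers(random_rna(sample(len[1]:len[2], 1L)), 3L,
                  id = sprintf("doc%02d", i))
  })
  list(corpus = corpus, model = train_pvdm(corpus, cfg, lr = lr))
}

# a setup with enough capacity/updates to actually fit a 10-doc corpus
fitting_pvdm_config <- function(epochs = 20L) {
  tiny_config(k_values = 3L, embed_dim = 16L, window = 3L, n_negative = 5L,
              pvdm_epochs = epochs)
}

test_that("pvdm_predict_prob is a proper softmax over the vocabulary", {
  toy <- make_toy_pvdm(4L)
  m <- toy$model
  h <- rnorm(ncol(m$context))
  probs <- vapply(m$vocab, function(w) pvdm_predict_prob(m, h, w), 0)
  expect_lt(abs(sum(probs) - 1), 1e-9)
  expect_true(all(probs > 0 & probs < 1))
  # identical output vectors -> uniform distribution
  mu <- m
  mu$context <- matrix(1, nrow(m$context), ncol(m$context))
  pu <- pvdm_predict_prob(mu, h, m$vocab[1L])
  expect_equal(pu, 1 / length(m$vocab))
  # brute-force softmax on a hand-set 3-token model
  mh <- m
  mh$vocab <- c("AAA", "CCC", "GGG")
  mh$context <- rbind(c(1, 0), c(0, 2), c(-1, 1))
  h2 <- c(0.3, -0.7)
  ref <- exp(sum(c(0, 2) * h2)) /
    (exp(sum(c(1, 0) * h2)) + exp(sum(c(0, 2) * h2)) + exp(sum(c(-1, 1) * h2)))
  expect_equal(pvdm_predict_prob(mh, h2, "CCC"), ref, tolerance = 1e-12)
  expect_error(pvdm_predict_prob(m, h, "ZZZ"), "vocabulary")
})

test_that("train_pvdm honors shapes, determinism, and reduces loss", {
  cfg <- tiny_config()
  set.seed(1)
  corpus <- lapply(1:2, function(i) {
    segment_kmers(random_rna(25L), 3L, id = paste0("d", i))
  })
  m <- train_pvdm(corpus, cfg)
  expect_equal(dim(m$doc), c(2L, cfg$embed_dim))
  expect_equal(length(m$vocab),
               length(unique(unlist(lapply(corpus, `[[`, "tokens")))))
  m2 <- train_pvdm(corpus, cfg)
  expect_identical(m$doc, m2$doc)
  expect_error(train_pvdm(list(), cfg), "empty corpus")
  # loss decreases from epoch 1 to epoch 20 on a 10-doc corpus
  toy <- make_toy_pvdm(10L, len = c(70L, 90L), cfg = fitting_pvdm_config(),
                       lr = 0.05)
  expect_lt(toy$model$loss_trace[20L], toy$model$loss_trace[1L])
})

test_that("infer_doc_vector recovers the nearest trained document", {
  toy <- make_toy_pvdm(10L, len = c(70L, 90L),
                       cfg = fitting_pvdm_config(40L), lr = 0.05)
  m <- toy$model
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  target <- 3L
  v <- infer_doc_vector(m, toy$corpus[[target]], steps = 100L, lr = 0.05)
  sims <- apply(m$doc, 1L, cosine, a = v)
  expect_equal(unname(which.max(sims)), target)
  # determinism and the steps = 0 contract
  expect_identical(v, infer_doc_vector(m, toy$corpus[[target]],
                                       steps = 100L, lr = 0.05))
  init <- infer_doc_vector(m, toy$corpus[[1L]], steps = 0L)
  expect_identical(init, infer_doc_vector(m, toy$corpus[[1L]], steps = 0L))
  expect_false(identical(init, infer_doc_vector(m, toy$corpus[[1L]],
                                                steps = 5L)))
  oov <- segment_kmers("ACGU", 3L, id = "nope")
  oov$tokens <- c("ZZZ")  # force out-of-vocabulary
  expect_error(infer_doc_vector(m, oov), "no in-vocabulary")
})

test_that("fuse_multiscale: identical rows, softmax rows, scale-order invariance", {
  d <- 6L
  att <- attention_fusion(d, seed = 5L)
  x <- rnorm(d)
  H <- matrix(rep(x, 3), 3, d, byrow = TRUE)
  expect_equal(fuse_multiscale(H, att), drop(x %*% att$W_V),
               tolerance = 1e-12)
  set.seed(9)
  H2 <- matrix(rnorm(3 * d), 3, d)
  cache <- lncmir:::fuse_multiscale_forward(H2, att)
  expect_true(all(abs(rowSums(cache$A) - 1) < 1e-9))
  # permutation invariance over all 3! row orders
  base <- fuse_multiscale(H2, att)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    expect_lt(max(abs(fuse_multiscale(H2[p, ], att) - base)), 1e-6)
  }
  expect_error(fuse_multiscale(matrix(0, 2, d + 1L), att), "width")
})

test_that("multiscale stacks cover trained and unseen sequences", {
  cfg <- tiny_config()
  lnc <- gen_sequences(5L, c(15L, 20L), "lncRNA", seed = 2L)
  models <- pretrain_lncrna(lnc[1:3, ], cfg)
  stacks <- multiscale_stack(lnc, models, cfg)
  expect_length(stacks, 5L)
  for (H in stacks) {
    expect_equal(dim(H), c(length(cfg$k_values), cfg$embed_dim))
    expect_true(all(is.finite(H)))
  }
})
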