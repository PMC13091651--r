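test_that("fuse_pair averages per side and concatenates", {
  x <- c(1, 2, 3)
  expect_equal(fuse_pair(x, x, x, x), c(x, x))
  expect_equal(fuse_pair(x, -x, x, x)[1:3], c(0, 0, 0))
  set.seed(2)
  a <- rnorm(5); b <- rnorm(5); c_ <- rnorm(5); d_ <- rnorm(5)
  out <- fuse_pair(a, b, c_, d_)
  expect_length(out, 10L)
  expect_equal(out, c((a + b) / 2, (c_ + d_) / 2))
  expect_error(fuse_pair(a, b, c_, rnorm(4)), "width")
})

test_that("score_pair: zero network gives logit 0, matches unrolled MLP", {
  d <- 4L
  head <- predictor_head(d, seed = 3L)
  zero <- head
  zero$W1 <- zero$W1 * 0; zero$W2 <- zero$W2 * 0
  fused <- rnorm(2 * d)
  expect_equal(score_pair(zero, fused), 0)
  expect_equal(sigmoid(score_pair(zero, fused)), 0.5)
  # deterministic on repeat
  expect_identical(score_pair(head, fused), score_pair(head, fused))
  # hand-unrolled two-layer computation
  h <- pmax(drop(fused %*% head$W1) + head$b1, 0)
  ref <- sum(h * head$W2) + head$b2
  expect_equal(score_pair(head, fused), ref, tolerance = 1e-12)
})

test_that("sample_negatives: counts, disjointness, determinism", {
  tab <- random_table(10L, 10L, 0.1, seed = 3L)
  P <- sum(tab$pairs$label == 1L)
  neg <- sample_negatives(tab, ratio = 1.0, seed = 4L)
  expect_equal(nrow(neg), P)
  expect_true(all(neg$label == 0L))
  key <- function(df) paste(df$lnc_id, df$mi_id)
  expect_length(intersect(key(neg), key(tab$pairs)), 0L)
  expect_false(anyDuplicated(key(neg)) > 0)
  expect_identical(sample_negatives(tab, 1.0, seed = 4L), neg)
  # different seeds differ (50 x 50 grid makes collision vanishingly rare)
  big <- random_table(50L, 50L, 0.02, seed = 5L)
  n1 <- sample_negatives(big, 1.0, seed = 1L)
  n2 <- sample_negatives(big, 1.0, seed = 2L)
  expect_false(identical(n1, n2))
  expect_equal(nrow(sample_negatives(tab, 0, seed = 1L)), 0L)
  expect_error(sample_negatives(tab, ratio = 1e6, seed = 1L), "candidate")
  # forbidden pairs are excluded
  forb <- sample_negatives(tab, 1.0, seed = 9L)
  neg2 <- sample_negatives(tab, 1.0, seed = 10L, forbidden = forb)
  expect_length(intersect(key(neg2), key(forb)), 0L)
})

test_that("analytic gradients match finite differences in every mode", {
  prob <- tiny_problem()
  modes <- list(c("ge_gcn", "pretrained"), c("vanilla_gcn", "pretrained"),
                c("none", "pretrained"), c("only", "pretrained"),
                c("ge_gcn", "onehot"))
  for (mv in modes) {
    cfg <- tiny_config(embed_dim = 5L, interaction_mode = mv[1L],
                       feature_mode = mv[2L])
    feats <- prepare_features(prob$lnc_seqs, prob$mi_seqs, prob$cmaps, cfg)
    pos <- prob$pairs[prob$pairs$label == 1L, ]
    gtab <- interaction_table(pos$lnc_id, pos$mi_id,
                              lnc_ids = prob$lnc_seqs$id,
                              mi_ids = prob$mi_seqs$id)
    graph <- build_bipartite_graph(gtab)
    An <- lncmir:::normalize_adjacency(lncmir:::block_adjacency(graph))
    params <- lncmir:::init_params(feats, graph, cfg)
    # jitter away from exact ReLU kinks (zero-initialized biases meet
    # exactly-zero embeddings there, where one-sided finite differences
    # disagree with the subgradient convention)
    set.seed(99)
    params <- lapply(params, function(p) p + stats::rnorm(length(p), 0, 0.02))
    idx <- lncmir:::resolve_pair_indices(prob$pairs, feats, graph, cfg)
    y <- as.numeric(prob$pairs$label)
    bp <- lncmir:::lmi_backprop(params, feats, graph, An, cfg,
                                idx$li, idx$mi, y, NULL)
    lossfun <- function(p) {
      lncmir:::lmi_backprop(p, feats, graph, An, cfg, idx$li, idx$mi, y,
                            NULL)$loss
    }
    eps <- 1e-6
    set.seed(13)
    for (nm in names(bp$grads)) {
      g <- bp$grads[[nm]]
      probe <- if (length(g) <= 3L) seq_along(g) else sample(length(g), 3L)
      for (i in probe) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
        num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
        expect_lt(abs(num - g[i]), 1e-6 + 1e-3 * (abs(num) + abs(g[i])),
                  label = sprintf("grad %s[%d] mode %s/%s", nm, i,
                                  mv[1L], mv[2L]))
      }
    }
  }
})

test_that("training reduces loss and is deterministic under a fixed seed", {
  prob <- tiny_problem()
  cfg <- tiny_config(max_epochs = 30L)
  sel <- lncmir:::carve_selection_split(prob$pairs, 1L)
  data <- list(lnc_seqs = prob$lnc_seqs, mi_seqs = prob$mi_seqs,
               cmaps = prob$cmaps, train = sel$train, val = sel$val)
  m1 <- train_model(cfg, data)
  m2 <- train_model(cfg, data)
  expect_identical(m1$state$loss_trace, m2$state$loss_trace)
  expect_lt(min(m1$state$loss_trace), m1$state$loss_trace[1L])
  expect_true(all(is.finite(m1$state$loss_trace)))
  expect_error(train_model(cfg, list(train = NULL)), "empty training")
})

test_that("none-mode scores ignore the graph; only-mode ignores sequences", {
  prob <- tiny_problem()
  cfg_none <- tiny_config(embed_dim = 5L, interaction_mode = "none")
  feats <- prepare_features(prob$lnc_seqs, prob$mi_seqs, prob$cmaps,
                            cfg_none)
  pos <- prob$pairs[prob$pairs$label == 1L, ]
  mk_graph <- function(p) {
    build_bipartite_graph(interaction_table(p$lnc_id, p$mi_id,
                                            lnc_ids = prob$lnc_seqs$id,
                                            mi_ids = prob$mi_seqs$id))
  }
  g_full <- mk_graph(pos)
  g_half <- mk_graph(pos[1:2, ])
  params <- lncmir:::init_params(feats, g_full, cfg_none)
  score_with <- function(graph, cfg, f = feats, p = params) {
    An <- lncmir:::normalize_adjacency(lncmir:::block_adjacency(graph))
    ent <- lncmir:::entity_forward(p, f, graph, An, cfg)
    idx <- lncmir:::resolve_pair_indices(prob$pairs, f, graph, cfg)
    Z <- lncmir:::pair_matrix(p, ent, idx$li, idx$mi, cfg)
    lncmir:::mlp_forward(p, Z)$logit
  }
  expect_equal(score_with(g_full, cfg_none), score_with(g_half, cfg_none),
               tolerance = 1e-12)
  # only-mode: swapping in completely different sequence features changes
  # nothing
  cfg_only <- tiny_config(embed_dim = 5L, interaction_mode = "only")
  feats2 <- feats
  feats2$stacks <- lapply(feats$stacks, function(H) H + 100)
  expect_equal(score_with(g_full, cfg_only),
               score_with(g_full, cfg_only, f = feats2),
               tolerance = 1e-12)
})

test_that("predict_ranked orders by probability with lexicographic ties", {
  prob <- tiny_problem()
  cfg <- tiny_config(max_epochs = 5L)
  sel <- lncmir:::carve_selection_split(prob$pairs, 1L)
  m <- train_model(cfg, list(lnc_seqs = prob$lnc_seqs,
                             mi_seqs = prob$mi_seqs, cmaps = prob$cmaps,
                             train = sel$train, val = sel$val))
  cand <- expand.grid(lnc_id = prob$lnc_seqs$id, mi_id = prob$mi_seqs$id,
                      stringsAsFactors = FALSE)
  ranked <- predict_ranked(m, cand)
  expect_equal(ranked$rank, seq_len(nrow(cand)))
  expect_true(all(diff(ranked$probability) <= 1e-15))
  # top-k agrees with a brute-force full sort of predict_pairs output
  probs <- predict_pairs(m, cand)
  ord <- order(-probs, cand$lnc_id, cand$mi_id, method = "radix")
  expect_equal(ranked$probability[1:10], probs[ord][1:10])
  expect_equal(ranked$lnc_id[1:10], cand$lnc_id[ord][1:10])
  # unknown entity with no fallback data errors with the id
  expect_error(predict_pairs(m, data.frame(lnc_id = "ghost",
                                           mi_id = prob$mi_seqs$id[1])),
               "ghost")
})

test_that("unseen entities are scored through sequence and hub fallbacks", {
  prob <- tiny_problem()
  cfg <- tiny_config(max_epochs = 5L)
  # hold the last lncRNA and miRNA out of training entirely
  keep_lnc <- prob$lnc_seqs$id[1:5]
  keep_mi <- prob$mi_seqs$id[1:7]
  tr <- prob$pairs[prob$pairs$lnc_id %in% keep_lnc &
                     prob$pairs$mi_id %in% keep_mi, ]
  lnc_tr <- prob$lnc_seqs[prob$lnc_seqs$id %in% keep_lnc, ]
  mi_tr <- prob$mi_seqs[prob$mi_seqs$id %in% keep_mi, ]
  m <- train_model(cfg, list(lnc_seqs = lnc_tr, mi_seqs = mi_tr,
                             cmaps = prob$cmaps[keep_mi], train = tr,
                             val = NULL))
  novel <- data.frame(lnc_id = prob$lnc_seqs$id[6],
                      mi_id = prob$mi_seqs$id[8])
  p <- predict_pairs(m, novel, data = list(lnc_seqs = prob$lnc_seqs,
                                           mi_seqs = prob$mi_seqs,
                                           cmaps = prob$cmaps))
  expect_true(is.finite(p) && p > 0 && p < 1)
})
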