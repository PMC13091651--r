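test_that("build_bipartite_graph places edges and tolerates edgeless entities", {
  tab <- interaction_table(c("l0", "l1"), c("m1", "m2"),
                           lnc_ids = c("l0", "l1"),
                           mi_ids = c("m0", "m1", "m2"))
  g <- build_bipartite_graph(tab)
  expect_equal(dim(g$A_I), c(2L, 3L))
  expect_equal(sum(g$A_I), 2)
  expect_equal(g$A_I["l0", "m1"], 1)
  expect_equal(g$A_I["l1", "m2"], 1)
  # no positives at all is still a valid graph
  tab0 <- interaction_table("l0", "m0", label = 0L)
  g0 <- build_bipartite_graph(tab0)
  expect_equal(sum(g0$A_I), 0)
  expect_error(interaction_table("x", "y", lnc_ids = c("x", "z"),
                                 mi_ids = c("y", "z")), "both sides")
})

test_that("edge count equals unique positive pairs for random tables", {
  for (s in 1:10) {
    tab <- random_table(sample(4:9, 1), sample(4:9, 1), 0.3, seed = s)
    g <- build_bipartite_graph(tab)
    expect_equal(sum(g$A_I), sum(tab$pairs$label == 1L))
  }
})

test_that("local_propagate matches the shared GCN kernel and its closed forms", {
  set.seed(5)
  tab <- random_table(4L, 5L, 0.3, seed = 2L)
  g <- build_bipartite_graph(tab)
  H <- matrix(rnorm(9 * 3), 9, 3)
  W <- matrix(rnorm(9), 3, 3)
  A_block <- lncmir:::block_adjacency(g)
  expect_lt(max(abs(local_propagate(H, g, W) - gcn_layer(H, A_block, W))),
            1e-8)
  # zero-edge graph: sigma(HW)
  g0 <- build_bipartite_graph(interaction_table("l", "m", label = 0L))
  H0 <- matrix(rnorm(6), 2, 3)
  expect_equal(local_propagate(H0, g0, W), relu(H0 %*% W), tolerance = 1e-12)
  # single edge, identity weights/activation: joined rows average
  g1 <- build_bipartite_graph(interaction_table("l0", "m0"))
  H1 <- matrix(rnorm(6), 2, 3)
  out <- local_propagate(H1, g1, diag(3), act = identity)
  avg <- 0.5 * (H1[1, ] + H1[2, ])
  expect_equal(out[1, ], avg, tolerance = 1e-12)
  expect_equal(out[2, ], avg, tolerance = 1e-12)
})

test_that("global_gather is the exact per-type mean", {
  H <- rbind(c(1, 2), c(3, 4), c(10, 20), c(30, 40), c(50, 60))
  hubs <- global_gather(H, 2L, 3L)
  expect_equal(hubs$h_g_lnc, c(2, 3))
  expect_equal(hubs$h_g_mi, c(30, 40))
  x <- c(7, -1)
  Hx <- matrix(rep(x, 5), 5, 2, byrow = TRUE)
  hx <- global_gather(Hx, 2L, 3L)
  expect_equal(hx$h_g_lnc, x)
  expect_equal(hx$h_g_mi, x)
  set.seed(12)
  for (i in 1:20) {
    N <- sample(1:6, 1); M <- sample(1:6, 1); d <- sample(2:5, 1)
    Hr <- matrix(rnorm((N + M) * d), N + M, d)
    hubs <- global_gather(Hr, N, M)
    ref_l <- numeric(d); ref_m <- numeric(d)  # loop-accumulated means
    for (u in seq_len(N)) ref_l <- ref_l + Hr[u, ]
    for (v in seq_len(M)) ref_m <- ref_m + Hr[N + v, ]
    expect_lt(max(abs(hubs$h_g_lnc - ref_l / N)), 1e-12)
    expect_lt(max(abs(hubs$h_g_mi - ref_m / M)), 1e-12)
  }
  expect_error(global_gather(H, 0L, 5L), "non-empty")
})

test_that("broadcast_update adds a shared per-type term", {
  set.seed(6)
  N <- 3L; M <- 4L; d <- 5L
  H <- matrix(rnorm((N + M) * d), N + M, d)
  hubs <- global_gather(H, N, M)
  Bz <- matrix(0, d, d)
  expect_equal(broadcast_update(H, hubs, N, M, Bz, Bz), H)
  B1 <- matrix(rnorm(d * d), d); B2 <- matrix(rnorm(d * d), d)
  out <- broadcast_update(H, hubs, N, M, B1, B2)
  # all lncRNA rows receive the identical added term
  add_l <- out[1:N, ] - H[1:N, ]
  expect_lt(max(abs(sweep(add_l, 2L, add_l[1, ]))), 1e-12)
  # pairwise differences within a type are invariant
  expect_equal(out[1, ] - out[2, ], H[1, ] - H[2, ], tolerance = 1e-12)
  expect_equal(out[N + 1, ] - out[N + 2, ], H[N + 1, ] - H[N + 2, ],
               tolerance = 1e-12)
})

test_that("a full GE-GCN layer matches a hand-unrolled dense computation", {
  set.seed(31)
  tab <- interaction_table(c("a", "b"), c("x", "y"),
                           lnc_ids = c("a", "b", "c"),
                           mi_ids = c("x", "y", "z"))
  g <- build_bipartite_graph(tab)
  d <- 4L
  params <- ge_gcn_params(g, d, layers = 1L, seed = 8L)
  H0 <- matrix(rnorm(6 * d), 6, d)
  got <- run_ge_gcn(g, params, init = H0, layers = 1L)

  # unrolled: normalize block adjacency, propagate, gather, broadcast
  A <- rbind(cbind(matrix(0, 3, 3), g$A_I), cbind(t(g$A_I), matrix(0, 3, 3)))
  Ah <- A + diag(6)
  Dm <- diag(1 / sqrt(rowSums(Ah)))
  Hl <- pmax(Dm %*% Ah %*% Dm %*% H0 %*% params$weights[[1]], 0)
  hub_l <- colMeans(Hl[1:3, ]); hub_m <- colMeans(Hl[4:6, ])
  exp_lnc <- Hl[1:3, ] + matrix(pmax(hub_l %*% params$B_lnc, 0), 3, d,
                                byrow = TRUE)
  exp_mi <- Hl[4:6, ] + matrix(pmax(hub_m %*% params$B_mi, 0), 3, d,
                               byrow = TRUE)
  expect_equal(unname(got$E_lnc), unname(exp_lnc), tolerance = 1e-10)
  expect_equal(unname(got$E_mi), unname(exp_mi), tolerance = 1e-10)
})

test_that("run_ge_gcn: identity at 0 layers, global reach, determinism", {
  tab <- interaction_table(c("l1", "l2"), c("m1", "m2"),
                           lnc_ids = c("l0", "l1", "l2"),
                           mi_ids = c("m1", "m2"))
  g <- build_bipartite_graph(tab)  # l0 is isolated
  d <- 3L
  params <- ge_gcn_params(g, d, layers = 2L, seed = 2L)
  H0 <- matrix(rnorm(5 * d), 5, d)
  e0 <- run_ge_gcn(g, params, init = H0, layers = 0L)
  expect_equal(unname(e0$E_lnc), H0[1:3, ])
  expect_equal(unname(e0$E_mi), H0[4:5, ])
  # isolated node changes when a distant node's features change
  base <- run_ge_gcn(g, params, init = H0, layers = 1L)
  H0b <- H0
  H0b[5, ] <- H0[5, ] + 5  # perturb a miRNA the isolated l0 never touches
  pert <- run_ge_gcn(g, params, init = H0b, layers = 1L)
  expect_gt(max(abs(pert$E_lnc["l0", ] - base$E_lnc["l0", ])), 0)
  # with broadcast off, the isolated node is unreachable
  basev <- run_ge_gcn(g, params, init = H0, layers = 1L, broadcast = FALSE)
  pertv <- run_ge_gcn(g, params, init = H0b, layers = 1L, broadcast = FALSE)
  expect_equal(pertv$E_lnc["l0", ], basev$E_lnc["l0", ], tolerance = 1e-12)
  expect_identical(run_ge_gcn(g, params, init = H0),
                   run_ge_gcn(g, params, init = H0))
})

test_that("GE-GCN is equivariant under within-type relabeling", {
  set.seed(44)
  tab <- random_table(5L, 6L, 0.3, seed = 9L)
  g <- build_bipartite_graph(tab)
  d <- 4L
  params <- ge_gcn_params(g, d, layers = 2L, seed = 3L)
  H0 <- matrix(rnorm(11 * d), 11, d)
  base <- run_ge_gcn(g, params, init = H0)
  p <- sample(5L)
  g2 <- g
  g2$A_I <- g$A_I[p, , drop = FALSE]
  g2$lnc_ids <- g$lnc_ids[p]
  H0p <- rbind(H0[1:5, ][p, ], H0[6:11, ])
  perm <- run_ge_gcn(g2, params, init = H0p)
  expect_lt(max(abs(unname(perm$E_lnc) - unname(base$E_lnc[p, ]))), 1e-10)
  expect_lt(max(abs(unname(perm$E_mi) - unname(base$E_mi))), 1e-10)
})
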