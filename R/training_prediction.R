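# End-to-end training and prediction. The sequence/structure embeddings
# (self-attention fusion, miRNA contact-graph GCN), the interaction-graph
# GE-GCN (including its free node embeddings), the four projection heads
# and the scoring MLP are trained jointly by full-batch gradient descent
# (Adam) on binary cross-entropy with logits. Gradients are derived by
# hand per component and verified against finite differences in the test
# suite.

#' Fuse projected embeddings of one candidate pair
#'
#' Each side's sequence/structure embedding and interaction-topology
#' embedding (already projected to common width d) are averaged; the two
#' halves are concatenated into a 2d-vector.
#'
#' @param e_m_lnc,e_i_lnc,e_m_mi,e_i_mi projected d-vectors
#' @return 2d-vector
#' @export
fuse_pair <- function(e_m_lnc, e_i_lnc, e_m_mi, e_i_mi) {
  d <- length(e_m_lnc)
  if (length(e_i_lnc) != d || length(e_m_mi) != d || length(e_i_mi) != d) {
    stop_fmt("all four embeddings must share width %d", d)
  }
  c((e_m_lnc + e_i_lnc) / 2, (e_m_mi + e_i_mi) / 2)
}

#' Initialize the prediction head
#'
#' Four linear projections to shared width d plus a `[2d, d, 1]` MLP with
#' ReLU and dropout.
#'
#' @param d shared width
#' @param d_lnc_m,d_lnc_i,d_mi_m,d_mi_i input widths of the projections
#' @param dropout dropout rate on the MLP hidden layer (training only)
#' @param seed integer seed
#' @return list of class `predictor_head`
#' @export
predictor_head <- function(d, d_lnc_m = d, d_lnc_i = d, d_mi_m = d,
                           d_mi_i = d, dropout = 0.2, seed = 1L) {
  set.seed(seed)
  glorot <- function(a, b) {
    matrix(stats::runif(a * b, -sqrt(6 / (a + b)), sqrt(6 / (a + b))), a, b)
  }
  structure(list(proj_lnc_M = glorot(d_lnc_m, d), proj_lnc_I = glorot(d_lnc_i, d),
                 proj_mi_M = glorot(d_mi_m, d), proj_mi_I = glorot(d_mi_i, d),
                 W1 = glorot(2L * d, d), b1 = numeric(d),
                 W2 = glorot(d, 1L), b2 = numeric(1L),
                 dropout = dropout, d = as.integer(d)),
            class = "predictor_head")
}

#' Score a fused pair vector (evaluation mode)
#'
#' Deterministic logit from the head's MLP (dropout disabled); the
#' interaction probability is `sigmoid(logit)`.
#'
#' @param head a [predictor_head]
#' @param fused 2d-vector from [fuse_pair]
#' @return scalar logit
#' @export
score_pair <- function(head, fused) {
  if (is.null(head$W1)) stop_fmt("predictor head is not initialized")
  h <- relu(drop(fused %*% head$W1) + head$b1)
  drop(h %*% head$W2) + head$b2
}

#' Sample non-interacting candidate pairs
#'
#' Uniformly samples `floor(ratio * P)` distinct (lncRNA, miRNA) pairs that
#' are neither known positives (anywhere in the table) nor in `forbidden`
#' (e.g. held-out test pairs). Deterministic under the seed.
#'
#' @param table an [interaction_table] (defines the id universe and the
#'   positive set)
#' @param ratio negatives per positive
#' @param seed integer seed
#' @param forbidden optional data.frame (lnc_id, mi_id) of additional pairs
#'   to exclude
#' @param n_positive positive count P the ratio refers to (defaults to the
#'   number of label-1 pairs in `table`)
#' @return data.frame (lnc_id, mi_id, label = 0)
#' @export
sample_negatives <- function(table, ratio = 1.0, seed = 1L,
                             forbidden = NULL, n_positive = NULL) {
  stopifnot(inherits(table, "interaction_table"))
  P <- n_positive %||% sum(table$pairs$label == 1L)
  want <- floor(ratio * P)
  if (want == 0L) {
    return(data.frame(lnc_id = character(), mi_id = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  excl <- paste(table$pairs$lnc_id, table$pairs$mi_id, sep = "\r")
  if (!is.null(forbidden) && nrow(forbidden)) {
    excl <- c(excl, paste(forbidden$lnc_id, forbidden$mi_id, sep = "\r"))
  }
  total <- table$N * table$M
  avail <- total - length(unique(excl))
  if (want > avail) {
    stop_fmt("requested %d negatives but only %d candidate pairs exist",
             want, avail)
  }
  set.seed(as.integer(seed))
  # rejection sampling over the N x M grid; deterministic under seed
  chosen <- character(0)
  excl_set <- unique(excl)
  while (length(chosen) < want) {
    need <- want - length(chosen)
    cand <- sample.int(total, min(total, max(2L * need, 16L)), replace = TRUE)
    li <- ((cand - 1L) %% table$N) + 1L
    mj <- ((cand - 1L) %/% table$N) + 1L
    key <- paste(table$lnc_ids[li], table$mi_ids[mj], sep = "\r")
    key <- key[!key %in% excl_set & !key %in% chosen]
    key <- key[!duplicated(key)]
    chosen <- c(chosen, utils::head(key, need))
  }
  parts <- strsplit(chosen, "\r", fixed = TRUE)
  data.frame(lnc_id = vapply(parts, `[[`, "", 1L),
             mi_id = vapply(parts, `[[`, "", 2L),
             label = 0L, stringsAsFactors = FALSE)
}

# feature preparation ---------------------------------------------------

# per-sequence base-composition vector (one-hot ablation for lncRNAs)
composition_features <- function(seqs) {
  t(vapply(seqs$seq, function(s) {
    colMeans(onehot_features(s))
  }, numeric(4L)))
}

#' Prepare fixed input features for training
#'
#' Runs PV-DM pretraining (leak-free by default: only on lncRNAs appearing
#' in training pairs) and assembles miRNA node features and normalized
#' contact adjacencies. The result is treated as fixed input by
#' [train_model].
#'
#' @param lnc_seqs,mi_seqs [rna_set]s covering every entity that will be
#'   scored
#' @param cmaps named list of [contact_map]s keyed by miRNA id
#' @param config a [run_config]
#' @param mi_embeddings optional named list of L x d0 external
#'   per-nucleotide embedding matrices keyed by miRNA id
#' @param train_lnc_ids lncRNA ids allowed into the PV-DM corpus (defaults
#'   to all; pass the training-split ids for leak-free blind evaluation)
#' @return list of class `lmi_features`
#' @export
prepare_features <- function(lnc_seqs, mi_seqs, cmaps, config = run_config(),
                             mi_embeddings = NULL, train_lnc_ids = NULL) {
  stopifnot(inherits(lnc_seqs, "rna_set"), inherits(mi_seqs, "rna_set"))
  missing_cm <- setdiff(mi_seqs$id, names(cmaps))
  if (length(missing_cm)) {
    stop_fmt("missing contact map(s) for miRNA id(s): %s",
             paste(utils::head(missing_cm, 3L), collapse = ", "))
  }
  lnc_onehot <- config$feature_mode %in% c("onehot", "onehot_lnc")
  mi_onehot <- config$feature_mode %in% c("onehot", "onehot_mi") ||
    is.null(mi_embeddings)

  if (lnc_onehot) {
    pvdm_models <- NULL
    stacks <- NULL
    lnc_comp <- composition_features(lnc_seqs)
    rownames(lnc_comp) <- lnc_seqs$id
    d_lnc_m <- 4L
  } else {
    corpus_seqs <- lnc_seqs
    if (config$leak_free_pvdm && !is.null(train_lnc_ids)) {
      corpus_seqs <- lnc_seqs[lnc_seqs$id %in% train_lnc_ids, , drop = FALSE]
      class(corpus_seqs) <- c("rna_set", "data.frame")
      if (nrow(corpus_seqs) == 0L) stop_fmt("no training lncRNA sequences")
    }
    pvdm_models <- pretrain_lncrna(corpus_seqs, config)
    stacks <- multiscale_stack(lnc_seqs, pvdm_models, config)
    lnc_comp <- NULL
    d_lnc_m <- config$embed_dim
  }

  mi_H0 <- lapply(seq_len(nrow(mi_seqs)), function(i) {
    id <- mi_seqs$id[i]
    if (!mi_onehot && !is.null(mi_embeddings[[id]])) {
      emb <- rbind(mi_embeddings[[id]])
      if (nrow(emb) != cmaps[[id]]$L) {
        stop_fmt("external embedding for '%s' has %d rows, expected %d",
                 id, nrow(emb), cmaps[[id]]$L)
      }
      emb
    } else {
      onehot_features(mi_seqs$seq[i])
    }
  })
  names(mi_H0) <- mi_seqs$id
  d0 <- unique(vapply(mi_H0, ncol, 0L))
  if (length(d0) != 1L) stop_fmt("miRNA node features differ in width")
  mi_An <- lapply(mi_seqs$id, function(id) normalize_adjacency(cmaps[[id]]$A))
  names(mi_An) <- mi_seqs$id

  structure(list(lnc_ids = lnc_seqs$id, mi_ids = mi_seqs$id,
                 lnc_onehot = lnc_onehot, pvdm_models = pvdm_models,
                 stacks = stacks, lnc_comp = lnc_comp, d_lnc_m = d_lnc_m,
                 mi_H0 = mi_H0, mi_An = mi_An, d0_mi = d0,
                 lnc_seqs = lnc_seqs, mi_seqs = mi_seqs, cmaps = cmaps),
            class = "lmi_features")
}

# parameter initialization; every block is always initialized (in a fixed
# RNG order) so ablation modes consume identical random streams
init_params <- function(feats, graph, config) {
  d <- config$embed_dim
  set.seed(derive_seed(config$seed, "model_init"))
  glorot <- function(a, b) {
    matrix(stats::runif(a * b, -sqrt(6 / (a + b)), sqrt(6 / (a + b))), a, b)
  }
  p <- list()
  p$att_WQ <- glorot(d, d); p$att_WK <- glorot(d, d); p$att_WV <- glorot(d, d)
  gdims <- c(feats$d0_mi, rep(d, config$gcn_layers))
  for (l in seq_len(config$gcn_layers)) {
    p[[paste0("gcn_W", l)]] <- glorot(gdims[l], gdims[l + 1L])
  }
  p$ge_X <- matrix(stats::rnorm((graph$N + graph$M) * d, sd = 0.1),
                   graph$N + graph$M, d)
  for (l in seq_len(config$ge_layers)) {
    p[[paste0("ge_W", l)]] <- glorot(d, d)
  }
  p$ge_Blnc <- glorot(d, d); p$ge_Bmi <- glorot(d, d)
  p$proj_lnc_M <- glorot(feats$d_lnc_m, d); p$proj_lnc_I <- glorot(d, d)
  p$proj_mi_M <- glorot(d, d); p$proj_mi_I <- glorot(d, d)
  p$head_W1 <- glorot(2L * d, d); p$head_b1 <- numeric(d)
  p$head_W2 <- glorot(d, 1L); p$head_b2 <- numeric(1L)
  p
}

# forward over all entities; returns embedding matrices and caches
entity_forward <- function(params, feats, graph, An_block, config) {
  d <- config$embed_dim
  use_seq <- config$interaction_mode != "only"
  use_int <- config$interaction_mode != "none"

  att_caches <- NULL
  if (use_seq) {
    if (feats$lnc_onehot) {
      Em_lnc <- feats$lnc_comp
    } else {
      att <- structure(list(W_Q = params$att_WQ, W_K = params$att_WK,
                            W_V = params$att_WV, d = d),
                       class = "attention_fusion")
      att_caches <- lapply(feats$stacks, fuse_multiscale_forward, att = att)
      Em_lnc <- t(vapply(att_caches, `[[`, numeric(d), "out"))
    }
    gcn_w <- lapply(seq_len(config$gcn_layers),
                    function(l) params[[paste0("gcn_W", l)]])
    mi_caches <- lapply(feats$mi_ids, function(id) {
      mirna_gcn_forward(feats$mi_H0[[id]], feats$mi_An[[id]], gcn_w)
    })
    names(mi_caches) <- feats$mi_ids
    Em_mi <- t(vapply(mi_caches, `[[`, numeric(d), "out"))
    rownames(Em_lnc) <- feats$lnc_ids
    rownames(Em_mi) <- feats$mi_ids
  } else {
    Em_lnc <- Em_mi <- mi_caches <- NULL
  }

  ge <- NULL
  if (use_int) {
    ge_w <- lapply(seq_len(config$ge_layers),
                   function(l) params[[paste0("ge_W", l)]])
    broadcast_on <- config$interaction_mode == "ge_gcn"
    ge <- ge_gcn_forward(params$ge_X, An_block, ge_w, params$ge_Blnc,
                         params$ge_Bmi, graph$N, graph$M,
                         broadcast_on = broadcast_on)
    Ei_lnc <- ge$H[seq_len(graph$N), , drop = FALSE]
    Ei_mi <- ge$H[graph$N + seq_len(graph$M), , drop = FALSE]
    rownames(Ei_lnc) <- graph$lnc_ids
    rownames(Ei_mi) <- graph$mi_ids
  } else {
    Ei_lnc <- Ei_mi <- NULL
  }
  list(Em_lnc = Em_lnc, Em_mi = Em_mi, Ei_lnc = Ei_lnc, Ei_mi = Ei_mi,
       att_caches = att_caches, mi_caches = mi_caches, ge = ge)
}

# assemble the B x 2d pair matrix from entity embeddings
pair_matrix <- function(params, ent, li, mi_idx, config) {
  mode <- config$interaction_mode
  if (mode == "none") {
    Zl <- ent$Em_lnc %*% params$proj_lnc_M
    Zm <- ent$Em_mi %*% params$proj_mi_M
  } else if (mode == "only") {
    Zl <- ent$Ei_lnc %*% params$proj_lnc_I
    Zm <- ent$Ei_mi %*% params$proj_mi_I
  } else {
    Zl <- (ent$Em_lnc %*% params$proj_lnc_M +
             ent$Ei_lnc %*% params$proj_lnc_I) / 2
    Zm <- (ent$Em_mi %*% params$proj_mi_M +
             ent$Ei_mi %*% params$proj_mi_I) / 2
  }
  cbind(Zl[li, , drop = FALSE], Zm[mi_idx, , drop = FALSE])
}

mlp_forward <- function(params, Z, mask = NULL) {
  A1 <- sweep(Z %*% params$head_W1, 2L, params$head_b1, "+")
  H1 <- relu(A1)
  D1 <- if (is.null(mask)) H1 else H1 * mask
  logit <- drop(D1 %*% params$head_W2) + params$head_b2
  list(logit = logit, A1 = A1, H1 = H1, D1 = D1)
}

# full forward + backward for one batch; returns loss, grads, probs
lmi_backprop <- function(params, feats, graph, An_block, config, li, mi_idx,
                         y, mask) {
  ent <- entity_forward(params, feats, graph, An_block, config)
  Z <- pair_matrix(params, ent, li, mi_idx, config)
  fw <- mlp_forward(params, Z, mask)
  p <- sigmoid(fw$logit)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))

  B <- length(y); d <- config$embed_dim
  g <- list()
  dlogit <- matrix((p - y) / B, B, 1L)
  g$head_W2 <- t(fw$D1) %*% dlogit
  g$head_b2 <- sum(dlogit)
  gD1 <- dlogit %*% t(params$head_W2)
  gH1 <- if (is.null(mask)) gD1 else gD1 * mask
  gA1 <- gH1 * relu_grad(fw$A1)
  g$head_W1 <- t(Z) %*% gA1
  g$head_b1 <- colSums(gA1)
  gZ <- gA1 %*% t(params$head_W1)
  gZl_pair <- gZ[, seq_len(d), drop = FALSE]
  gZm_pair <- gZ[, d + seq_len(d), drop = FALSE]

  mode <- config$interaction_mode
  use_seq <- mode != "only"
  use_int <- mode != "none"
  half <- if (use_seq && use_int) 0.5 else 1

  # scatter pair gradients back to entity rows
  scatter <- function(gp, idx, n) {
    out <- matrix(0, n, ncol(gp))
    acc <- rowsum(gp, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    out
  }
  if (mode == "only") {
    gZl <- scatter(gZl_pair, li, graph$N)
    gZm <- scatter(gZm_pair, mi_idx, graph$M)
  } else {
    gZl <- scatter(gZl_pair, li, length(feats$lnc_ids))
    gZm <- scatter(gZm_pair, mi_idx, length(feats$mi_ids))
  }

  if (use_seq) {
    g$proj_lnc_M <- t(ent$Em_lnc) %*% (gZl * half)
    g$proj_mi_M <- t(ent$Em_mi) %*% (gZm * half)
    gEm_lnc <- (gZl * half) %*% t(params$proj_lnc_M)
    gEm_mi <- (gZm * half) %*% t(params$proj_mi_M)
    if (!feats$lnc_onehot) {
      att <- structure(list(W_Q = params$att_WQ, W_K = params$att_WK,
                            W_V = params$att_WV, d = d),
                       class = "attention_fusion")
      g$att_WQ <- matrix(0, d, d); g$att_WK <- matrix(0, d, d)
      g$att_WV <- matrix(0, d, d)
      for (i in seq_along(feats$lnc_ids)) {
        gv <- gEm_lnc[i, ]
        if (all(gv == 0)) next
        gb <- fuse_multiscale_backward(ent$att_caches[[i]], att, gv)
        g$att_WQ <- g$att_WQ + gb$W_Q
        g$att_WK <- g$att_WK + gb$W_K
        g$att_WV <- g$att_WV + gb$W_V
      }
    }
    gcn_w <- lapply(seq_len(config$gcn_layers),
                    function(l) params[[paste0("gcn_W", l)]])
    gw_tot <- lapply(gcn_w, function(w) matrix(0, nrow(w), ncol(w)))
    for (j in seq_along(feats$mi_ids)) {
      gv <- gEm_mi[j, ]
      if (all(gv == 0)) next
      id <- feats$mi_ids[j]
      gw <- mirna_gcn_backward(feats$mi_H0[[id]], feats$mi_An[[id]], gcn_w,
                               ent$mi_caches[[id]]$caches, gv)
      for (l in seq_along(gw_tot)) gw_tot[[l]] <- gw_tot[[l]] + gw[[l]]
    }
    for (l in seq_along(gw_tot)) g[[paste0("gcn_W", l)]] <- gw_tot[[l]]
  }

  if (use_int) {
    if (mode == "only") {
      gEi <- rbind(gZl %*% t(params$proj_lnc_I),
                   gZm %*% t(params$proj_mi_I))
      g$proj_lnc_I <- t(ent$Ei_lnc) %*% gZl
      g$proj_mi_I <- t(ent$Ei_mi) %*% gZm
    } else {
      gl <- gZl[match(graph$lnc_ids, feats$lnc_ids), , drop = FALSE] * half
      gm <- gZm[match(graph$mi_ids, feats$mi_ids), , drop = FALSE] * half
      g$proj_lnc_I <- t(ent$Ei_lnc) %*% gl
      g$proj_mi_I <- t(ent$Ei_mi) %*% gm
      gEi <- rbind(gl %*% t(params$proj_lnc_I),
                   gm %*% t(params$proj_mi_I))
    }
    ge_w <- lapply(seq_len(config$ge_layers),
                   function(l) params[[paste0("ge_W", l)]])
    gge <- ge_gcn_backward(An_block, ge_w, params$ge_Blnc, params$ge_Bmi,
                           graph$N, graph$M, ent$ge$caches, gEi,
                           broadcast_on = config$interaction_mode == "ge_gcn")
    g$ge_X <- gge$X
    for (l in seq_along(gge$weights)) g[[paste0("ge_W", l)]] <- gge$weights[[l]]
    if (config$interaction_mode == "ge_gcn" && !config$freeze_broadcast) {
      g$ge_Blnc <- gge$B_lnc
      g$ge_Bmi <- gge$B_mi
    }
  }
  list(loss = loss, grads = g, probs = p, ent = ent)
}

# Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    gnm <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gnm
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# training --------------------------------------------------------------

resolve_pair_indices <- function(pairs, feats, graph, config) {
  if (config$interaction_mode == "only") {
    li <- match(pairs$lnc_id, graph$lnc_ids)
    mi <- match(pairs$mi_id, graph$mi_ids)
  } else {
    li <- match(pairs$lnc_id, feats$lnc_ids)
    mi <- match(pairs$mi_id, feats$mi_ids)
  }
  if (anyNA(li)) {
    stop_fmt("unknown lncRNA id '%s' in pair list",
             pairs$lnc_id[which(is.na(li))[1L]])
  }
  if (anyNA(mi)) {
    stop_fmt("unknown miRNA id '%s' in pair list",
             pairs$mi_id[which(is.na(mi))[1L]])
  }
  list(li = li, mi = mi)
}

#' Train the full interaction model
#'
#' Full-batch Adam on binary cross-entropy with logits for up to
#' `config$max_epochs` epochs; the parameter snapshot with the best
#' validation AUC is returned. The interaction graph is built from the
#' training positives only. All four ablation variants are honored through
#' `config$interaction_mode` and `config$feature_mode`.
#'
#' @param config a [run_config]
#' @param data list with elements `lnc_seqs`, `mi_seqs`, `cmaps`
#'   (see [prepare_features]), `train` and `val` (data.frames with columns
#'   lnc_id, mi_id, label), and optionally `mi_embeddings`, `feats` (a
#'   precomputed [prepare_features] result, reused across folds) and
#'   `init_params` (explicit initial parameter list, for structural-identity
#'   checks)
#' @param verbose print a line every 20 epochs
#' @return list of class `lmi_model`: trained `params`, `config`, `graph`,
#'   `feats`, hub fallback vectors for unseen entities, and `state` (loss
#'   trace, validation AUC trace, best epoch)
#' @export
train_model <- function(config, data, verbose = FALSE) {
  train <- data$train
  if (is.null(train) || nrow(train) == 0L) stop_fmt("empty training split")
  train_pos <- train[train$label == 1L, , drop = FALSE]
  # graph nodes span the full entity universe; entities without training
  # edges sit isolated and are reached only through the hub broadcasts
  graph_tab <- interaction_table(train_pos$lnc_id, train_pos$mi_id,
                                 lnc_ids = data$lnc_seqs$id,
                                 mi_ids = data$mi_seqs$id)
  graph <- build_bipartite_graph(graph_tab)
  An_block <- normalize_adjacency(block_adjacency(graph))

  feats <- data$feats %||% prepare_features(
    data$lnc_seqs, data$mi_seqs, data$cmaps, config,
    mi_embeddings = data$mi_embeddings,
    train_lnc_ids = unique(train_pos$lnc_id))

  params <- init_params(feats, graph, config)
  if (!is.null(data$init_params)) params <- data$init_params
  idx <- resolve_pair_indices(train, feats, graph, config)
  y <- as.numeric(train$label)
  val <- data$val
  vidx <- if (!is.null(val) && nrow(val)) {
    resolve_pair_indices(val, feats, graph, config)
  }

  st <- adam_state(params)
  B <- nrow(train); d <- config$embed_dim
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  set.seed(derive_seed(config$seed, "train_loop"))
  for (epoch in seq_len(config$max_epochs)) {
    mask <- NULL
    if (config$dropout > 0) {
      keep <- (matrix(stats::runif(B * d), B, d) >= config$dropout) * 1
      mask <- keep / (1 - config$dropout)
    }
    bp <- lmi_backprop(params, feats, graph, An_block, config,
                       idx$li, idx$mi, y, mask)
    if (!is.finite(bp$loss)) {
      stop_fmt("training aborted: non-finite loss at epoch %d (lr = %g)",
               epoch, config$lr)
    }
    loss_trace <- c(loss_trace, bp$loss)
    upd <- adam_step(params, bp$grads, st, config$lr)
    params <- upd$params; st <- upd$state

    if (!is.null(vidx)) {
      Zv <- pair_matrix(params,
                        entity_forward(params, feats, graph, An_block, config),
                        vidx$li, vidx$mi, config)
      pv <- sigmoid(mlp_forward(params, Zv)$logit)
      auc <- auc_rank(pv, val$label)
      val_trace <- c(val_trace, auc)
      if (!is.na(auc) && auc > best$auc) {
        best <- list(auc = auc, params = params, epoch = epoch)
      }
    } else {
      best <- list(auc = NA_real_, params = params, epoch = epoch)
    }
    if (verbose && epoch %% 20L == 0L) {
      message(sprintf("epoch %3d  loss %.4f  val AUC %s", epoch, bp$loss,
                      if (length(val_trace)) sprintf("%.3f", val_trace[epoch])
                      else "-"))
    }
  }
  params <- best$params
  ent <- entity_forward(params, feats, graph, An_block, config)
  hub_lnc <- if (!is.null(ent$Ei_lnc)) colMeans(ent$Ei_lnc)
  hub_mi <- if (!is.null(ent$Ei_mi)) colMeans(ent$Ei_mi)
  structure(list(params = params, config = config, graph = graph,
                 An_block = An_block, feats = feats,
                 hub_lnc = hub_lnc, hub_mi = hub_mi,
                 state = list(loss_trace = loss_trace,
                              val_auc_trace = val_trace,
                              best_epoch = best$epoch,
                              best_val_auc = best$auc,
                              seed = config$seed)),
            class = "lmi_model")
}

# entity embeddings at prediction time, with fallbacks for entities unseen
# during training: interaction-topology side falls back to the trained
# per-type hub (mean) embedding; sequence side is computed from sequence
# and structure directly (PV-DM inference / contact-graph GCN).
predict_embeddings <- function(model, lnc_ids, mi_ids, data = NULL) {
  config <- model$config; feats <- model$feats; d <- config$embed_dim
  ent <- entity_forward(model$params, feats, model$graph, model$An_block,
                        config)
  use_seq <- config$interaction_mode != "only"
  use_int <- config$interaction_mode != "none"

  get_seq_lnc <- function(id) {
    if (use_seq && id %in% rownames(ent$Em_lnc)) return(ent$Em_lnc[id, ])
    if (!use_seq) return(NULL)
    seqs <- data$lnc_seqs
    if (is.null(seqs) || !id %in% seqs$id) {
      stop_fmt("unknown lncRNA '%s' and no sequence supplied to embed it", id)
    }
    row <- seqs[seqs$id == id, , drop = FALSE]
    if (feats$lnc_onehot) return(drop(composition_features(row)))
    H <- t(vapply(names(feats$pvdm_models), function(kc) {
      infer_or_init(feats$pvdm_models[[kc]], row$seq, id)
    }, numeric(d)))
    att <- structure(list(W_Q = model$params$att_WQ,
                          W_K = model$params$att_WK,
                          W_V = model$params$att_WV, d = d),
                     class = "attention_fusion")
    fuse_multiscale(H, att)
  }
  get_seq_mi <- function(id) {
    if (use_seq && id %in% rownames(ent$Em_mi)) return(ent$Em_mi[id, ])
    if (!use_seq) return(NULL)
    if (is.null(data$cmaps[[id]]) || is.null(data$mi_seqs) ||
        !id %in% data$mi_seqs$id) {
      stop_fmt("unknown miRNA '%s' and no sequence/contact map supplied", id)
    }
    H0 <- onehot_features(data$mi_seqs$seq[data$mi_seqs$id == id])
    if (!is.null(data$mi_embeddings[[id]])) H0 <- data$mi_embeddings[[id]]
    gcn_w <- lapply(seq_len(config$gcn_layers),
                    function(l) model$params[[paste0("gcn_W", l)]])
    mirna_gcn_forward(H0, normalize_adjacency(data$cmaps[[id]]$A), gcn_w)$out
  }
  get_int <- function(id, E, hub) {
    if (!use_int) return(NULL)
    if (id %in% rownames(E)) E[id, ] else hub
  }
  list(
    Em_lnc = if (use_seq) t(vapply(lnc_ids, get_seq_lnc, numeric(d))),
    Em_mi = if (use_seq) t(vapply(mi_ids, get_seq_mi, numeric(d))),
    Ei_lnc = if (use_int) t(vapply(lnc_ids, get_int, numeric(d),
                                   E = ent$Ei_lnc, hub = model$hub_lnc)),
    Ei_mi = if (use_int) t(vapply(mi_ids, get_int, numeric(d),
                                  E = ent$Ei_mi, hub = model$hub_mi)))
}

#' Predict interaction probabilities for candidate pairs
#'
#' @param model a trained [train_model] result
#' @param pairs data.frame with columns lnc_id, mi_id
#' @param data optional list (`lnc_seqs`, `mi_seqs`, `cmaps`,
#'   `mi_embeddings`) supplying sequences/structures for entities unseen at
#'   training time
#' @return numeric vector of probabilities (same order as `pairs`)
#' @export
predict_pairs <- function(model, pairs, data = NULL) {
  lnc_ids <- unique(pairs$lnc_id); mi_ids <- unique(pairs$mi_id)
  emb <- predict_embeddings(model, lnc_ids, mi_ids, data)
  li <- match(pairs$lnc_id, lnc_ids); mj <- match(pairs$mi_id, mi_ids)
  config <- model$config; params <- model$params
  mode <- config$interaction_mode
  if (mode == "none") {
    Zl <- emb$Em_lnc %*% params$proj_lnc_M
    Zm <- emb$Em_mi %*% params$proj_mi_M
  } else if (mode == "only") {
    Zl <- emb$Ei_lnc %*% params$proj_lnc_I
    Zm <- emb$Ei_mi %*% params$proj_mi_I
  } else {
    Zl <- (emb$Em_lnc %*% params$proj_lnc_M +
             emb$Ei_lnc %*% params$proj_lnc_I) / 2
    Zm <- (emb$Em_mi %*% params$proj_mi_M +
             emb$Ei_mi %*% params$proj_mi_I) / 2
  }
  Z <- cbind(Zl[li, , drop = FALSE], Zm[mj, , drop = FALSE])
  unname(sigmoid(mlp_forward(params, Z)$logit))
}

#' Rank candidate pairs by predicted interaction probability
#'
#' Descending probability; exact ties are broken lexicographically by
#' (lnc_id, mi_id) for reproducibility.
#'
#' @inheritParams predict_pairs
#' @return data.frame (lnc_id, mi_id, probability, rank)
#' @export
predict_ranked <- function(model, pairs, data = NULL) {
  prob <- predict_pairs(model, pairs, data)
  ord <- order(-prob, pairs$lnc_id, pairs$mi_id, method = "radix")
  out <- data.frame(lnc_id = pairs$lnc_id[ord], mi_id = pairs$mi_id[ord],
                    probability = prob[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
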