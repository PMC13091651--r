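# Synthetic inputs for every pipeline stage: random RNA sequences,
# hairpin-like contact maps, and a planted low-rank bipartite interaction
# graph with known latent structure. The planted model draws latent factors
# u_i, v_j ~ N(0, I_r) and connects pairs with probability
# sigmoid(a * u_i'v_j + b + noise), the intercept b calibrated by bisection
# so the expected density matches the target. Sequence content and planted
# topology are intentionally independent: topology recovery tests must not
# be solvable from sequence.

#' Generate random RNA sequences
#'
#' Uniform i.i.d. letters over {A, C, G, U}; lengths uniform in
#' `length_range`. Deterministic under the seed.
#'
#' @param n number of sequences
#' @param length_range integer vector `c(min, max)`
#' @param rna_type "lncRNA" or "miRNA"
#' @param seed integer seed
#' @param prefix id prefix (defaults to "lnc"/"mi" by type)
#' @return an [rna_set]
#' @export
gen_sequences <- function(n, length_range, rna_type = c("lncRNA", "miRNA"),
                          seed = 1L, prefix = NULL) {
  rna_type <- match.arg(rna_type)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] < 1L ||
      length_range[2L] < length_range[1L]) {
    stop_fmt("length_range must be c(min, max) with 1 <= min <= max")
  }
  prefix <- prefix %||% if (rna_type == "lncRNA") "lnc" else "mi"
  set.seed(as.integer(seed))
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, "")
  rna_set(sprintf("%s%03d", prefix, seq_len(n)), seqs, rna_type = rna_type)
}

#' Generate a hairpin-like contact map
#'
#' Pairs position i with position L - 1 - i (0-based) for the first `stem`
#' positions, mimicking a single-stem hairpin. Deliberately simplistic:
#' what matters for the GCN tests is topology variety, not thermodynamic
#' realism.
#'
#' @param L sequence length
#' @param stem number of stem pairs (requires `2 * stem < L`)
#' @param rna_id identifier
#' @return a [contact_map]
#' @export
gen_hairpin_contact <- function(L, stem, rna_id = "mi") {
  if (2L * stem >= L) {
    stop_fmt("infeasible stem: need 2 * stem < L (stem = %d, L = %d)",
             stem, L)
  }
  A <- matrix(0, L, L)
  if (stem > 0L) {
    for (i in seq_len(stem)) {
      A[i, L + 1L - i] <- A[L + 1L - i, i] <- 1
    }
  }
  contact_map(A, rna_id)
}

#' Specification of a planted low-rank interaction graph
#'
#' @param N,M entity counts
#' @param latent_dim latent factor rank r
#' @param density target edge fraction in (0, 1)
#' @param noise_sd logit-scale Gaussian noise standard deviation
#' @param seed integer seed
#' @param gain slope a applied to the factor inner products (fixed design
#'   value: 3 / sqrt(r))
#' @param factor_model "archetype" (default): entity factors cluster around
#'   r orthogonal archetypes with per-entity scale and isotropic spread,
#'   giving the modular many-to-many structure of ceRNA networks and a
#'   benchmark that is recoverable by a rank-r factorization at the default
#'   sparsity; "gaussian": plain standard-normal factors (harder to recover
#'   from very sparse graphs)
#' @param spread within-archetype factor dispersion (archetype model only)
#' @return list of class `planted_graph_spec`
#' @export
planted_graph_spec <- function(N = 60L, M = 80L, latent_dim = 4L,
                               density = 0.05, noise_sd = 0.5, seed = 1L,
                               gain = 3 / sqrt(latent_dim),
                               factor_model = c("archetype", "gaussian"),
                               spread = 0.35) {
  factor_model <- match.arg(factor_model)
  if (density <= 0 || density >= 1) stop_fmt("density must be in (0, 1)")
  if (latent_dim < 1L) stop_fmt("latent_dim must be >= 1")
  structure(list(N = as.integer(N), M = as.integer(M),
                 latent_dim = as.integer(latent_dim), density = density,
                 noise_sd = noise_sd, seed = as.integer(seed), gain = gain,
                 factor_model = factor_model, spread = spread),
            class = "planted_graph_spec")
}

# draw latent factors for one side under the configured factor model
draw_factors <- function(n, r, factor_model, spread) {
  if (factor_model == "gaussian") {
    return(matrix(stats::rnorm(n * r), n))
  }
  arch <- diag(r) * sqrt(r)
  cl <- sample.int(r, n, replace = TRUE)
  arch[cl, , drop = FALSE] * abs(stats::rnorm(n, 1, 0.3)) +
    matrix(stats::rnorm(n * r, 0, spread), n)
}

#' Sample a planted low-rank bipartite interaction graph
#'
#' Draws standard-normal latent factors, calibrates the intercept by
#' bisection so that the mean connection probability matches
#' `spec$density` within 0.005, and samples the adjacency. Entities with no
#' sampled edge remain in the id universe.
#'
#' @param spec a [planted_graph_spec]
#' @return list with `table` (an [interaction_table] of the sampled
#'   positive pairs over the full id universe), `U`, `V` (latent factors),
#'   `prob` (N x M connection probabilities), `intercept`
#' @export
gen_planted_interactions <- function(spec) {
  stopifnot(inherits(spec, "planted_graph_spec"))
  set.seed(spec$seed)
  U <- draw_factors(spec$N, spec$latent_dim, spec$factor_model, spec$spread)
  V <- draw_factors(spec$M, spec$latent_dim, spec$factor_model, spec$spread)
  noise <- if (spec$noise_sd > 0) {
    matrix(stats::rnorm(spec$N * spec$M, sd = spec$noise_sd), spec$N)
  } else 0
  logits <- spec$gain * (U %*% t(V)) + noise
  dens <- function(b) mean(sigmoid(logits + b))
  lo <- -80; hi <- 80
  b <- NA_real_
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    dmid <- dens(mid)
    if (abs(dmid - spec$density) < 5e-4) {
      b <- mid
      break
    }
    if (dmid < spec$density) lo <- mid else hi <- mid
  }
  if (is.na(b)) b <- (lo + hi) / 2
  if (abs(dens(b) - spec$density) > 0.005) {
    stop_fmt("intercept calibration failed (reached density %.4f, target %.4f)",
             dens(b), spec$density)
  }
  prob <- sigmoid(logits + b)
  A <- matrix(stats::runif(spec$N * spec$M) < prob, spec$N) * 1
  lnc_ids <- sprintf("lnc%03d", seq_len(spec$N))
  mi_ids <- sprintf("mi%03d", seq_len(spec$M))
  idx <- which(A == 1, arr.ind = TRUE)
  table <- interaction_table(lnc_ids[idx[, 1L]], mi_ids[idx[, 2L]],
                             lnc_ids = lnc_ids, mi_ids = mi_ids)
  rownames(U) <- lnc_ids; rownames(V) <- mi_ids
  list(table = table, U = U, V = V, prob = prob, intercept = b)
}

#' Rank-r factorization recoverability oracle (alternating least squares)
#'
#' Fits latent factors to the observed training pairs on a pseudo-logit
#' scale (+2 for positives, -2 for negatives; unobserved cells are pulled
#' toward logit 0 with a small weight `w0`, the standard implicit-feedback
#' weighting for very sparse graphs) by ridge-regularized alternating least
#' squares with a spectral (truncated-SVD) initialization, then scores
#' arbitrary pairs by the factor inner product. This establishes that a
#' planted benchmark is learnable (held-out AUC) before the full neural
#' model is blamed for failing on it. Deterministic: no random
#' initialization is involved.
#'
#' @param train data.frame (lnc_id, mi_id, label) of observed pairs
#' @param lnc_ids,mi_ids id universes
#' @param rank latent dimension
#' @param lambda ridge penalty
#' @param w0 weight of unobserved cells (observed cells have weight 1)
#' @param iters ALS sweeps
#' @return list with `U`, `V` and `score(pairs)` returning inner products
#' @export
als_link_oracle <- function(train, lnc_ids, mi_ids, rank = 4L,
                            lambda = 0.5, w0 = 0.1, iters = 30L) {
  N <- length(lnc_ids); M <- length(mi_ids)
  li <- match(train$lnc_id, lnc_ids); mj <- match(train$mi_id, mi_ids)
  if (anyNA(li) || anyNA(mj)) stop_fmt("train pairs outside the id universe")
  Y <- matrix(0, N, M)
  W <- matrix(w0, N, M)
  Y[cbind(li, mj)] <- ifelse(train$label == 1L, 2, -2)
  W[cbind(li, mj)] <- 1
  sv <- svd(Y, nu = rank, nv = rank)
  U <- sv$u %*% diag(sqrt(sv$d[seq_len(rank)]), rank)
  V <- sv$v %*% diag(sqrt(sv$d[seq_len(rank)]), rank)
  ridge <- lambda * diag(rank)
  for (it in seq_len(iters)) {
    for (i in seq_len(N)) {
      w <- W[i, ]
      U[i, ] <- solve(crossprod(V, V * w) + ridge, crossprod(V, w * Y[i, ]))
    }
    for (j in seq_len(M)) {
      w <- W[, j]
      V[j, ] <- solve(crossprod(U, U * w) + ridge, crossprod(U, w * Y[, j]))
    }
  }
  rownames(U) <- lnc_ids; rownames(V) <- mi_ids
  list(U = U, V = V,
       score = function(pairs) {
         rowSums(U[match(pairs$lnc_id, lnc_ids), , drop = FALSE] *
                   V[match(pairs$mi_id, mi_ids), , drop = FALSE])
       })
}

#' Write a self-describing synthetic fixture bundle
#'
#' Generates lncRNA and miRNA FASTA files, per-miRNA contact-map matrix
#' files, a planted interaction TSV, a flat YAML config and a JSON
#' manifest, forming a runnable end-to-end example. `tiny` is 8 lncRNAs x
#' 12 miRNAs; `small` is 60 x 80 (the scale of the recoverability tests).
#' Two bundles with the same seed are byte-identical.
#'
#' @param dir output directory (created if needed)
#' @param scale "tiny" or "small"
#' @param seed integer seed
#' @return invisible list describing the generated objects
#' @export
make_fixture_bundle <- function(dir, scale = c("tiny", "small"), seed = 1L) {
  scale <- match.arg(scale)
  dims <- switch(scale,
                 tiny = list(N = 8L, M = 12L, r = 2L, density = 0.15,
                             lnc_len = c(60L, 120L)),
                 small = list(N = 60L, M = 80L, r = 4L, density = 0.05,
                              lnc_len = c(100L, 200L)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm_dir <- file.path(dir, "contact_maps")
  dir.create(cm_dir, showWarnings = FALSE)

  lnc <- gen_sequences(dims$N, dims$lnc_len, "lncRNA",
                       seed = derive_seed(seed, "bundle_lnc"))
  mi <- gen_sequences(dims$M, c(20L, 25L), "miRNA",
                      seed = derive_seed(seed, "bundle_mi"))
  set.seed(derive_seed(seed, "bundle_stems"))
  stems <- sample(3L:7L, dims$M, replace = TRUE)
  stems <- pmin(stems, (mi$length - 1L) %/% 2L)
  cmaps <- lapply(seq_len(dims$M), function(j) {
    gen_hairpin_contact(mi$length[j], stems[j], rna_id = mi$id[j])
  })
  names(cmaps) <- mi$id

  planted <- gen_planted_interactions(planted_graph_spec(
    N = dims$N, M = dims$M, latent_dim = dims$r, density = dims$density,
    seed = derive_seed(seed, "bundle_graph")))

  write_fasta(lnc, file.path(dir, "lncRNA.fasta"))
  write_fasta(mi, file.path(dir, "miRNA.fasta"))
  for (j in seq_len(dims$M)) {
    con <- file(file.path(cm_dir, paste0(mi$id[j], ".txt")), open = "wb")
    writeLines(apply(cmaps[[j]]$A, 1L, paste, collapse = " "), con)
    close(con)
  }
  write_interactions(planted$table, file.path(dir, "interactions.tsv"))
  cfg <- run_config(seed = seed)
  write_config(cfg, file.path(dir, "config.yaml"))
  manifest <- list(scale = scale, seed = seed,
                   n_lncRNA = dims$N, n_miRNA = dims$M,
                   latent_dim = dims$r, density = dims$density,
                   n_interactions = nrow(planted$table$pairs),
                   files = list(lncRNA = "lncRNA.fasta",
                                miRNA = "miRNA.fasta",
                                interactions = "interactions.tsv",
                                contact_maps = "contact_maps/",
                                config = "config.yaml"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(lnc_seqs = lnc, mi_seqs = mi, cmaps = cmaps,
                 table = planted$table, planted = planted))
}
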