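# Experimental settings: standard 5-fold cross-validation over interaction
# pairs, cold-start ("blind") splits over entities, the independent
# train/external-test setting, and the label-noise robustness protocol.

#' Build standard cross-validation folds over interaction pairs
#'
#' Positive pairs are shuffled and partitioned into k near-equal folds
#' (sizes differ by at most one). Negatives are sampled per fold at
#' `neg_ratio` negatives per positive, disjoint across folds, excluding all
#' known positives.
#'
#' @param table an [interaction_table]
#' @param k number of folds
#' @param seed integer seed
#' @param neg_ratio negatives per positive
#' @return list of class `split_spec` with `mode = "standard"`, `folds`,
#'   `assignment` (data.frame lnc_id, mi_id, label, fold) and `seed`
#' @export
make_cv_folds <- function(table, k = 5L, seed = 1L, neg_ratio = 1.0) {
  stopifnot(inherits(table, "interaction_table"))
  pos <- table$pairs[table$pairs$label == 1L, , drop = FALSE]
  if (nrow(pos) < k) {
    stop_fmt("cannot make %d folds from %d positive pairs", k, nrow(pos))
  }
  set.seed(derive_seed(seed, "cv_shuffle"))
  pos <- pos[sample.int(nrow(pos)), , drop = FALSE]
  pos$fold <- rep(seq_len(k), length.out = nrow(pos))
  drawn <- NULL
  negs <- lapply(seq_len(k), function(f) {
    nf <- sum(pos$fold == f)
    neg <- sample_negatives(table, ratio = neg_ratio,
                            seed = derive_seed(seed, paste0("cv_neg_fold", f)),
                            forbidden = drawn, n_positive = nf)
    if (nrow(neg)) neg$fold <- f
    drawn <<- rbind(drawn, neg[, c("lnc_id", "mi_id")])
    neg
  })
  assignment <- rbind(pos[, c("lnc_id", "mi_id", "label", "fold")],
                      do.call(rbind, negs))
  rownames(assignment) <- NULL
  structure(list(mode = "standard", folds = as.integer(k),
                 assignment = assignment, seed = as.integer(seed)),
            class = "split_spec")
}

#' Build blind (cold-start) splits over entities
#'
#' Entities of the blinded type are partitioned into k folds. For each
#' fold, validation pairs are the interactions whose blinded entity belongs
#' to the fold; all remaining interactions train. In `blind_both` mode both
#' entity types are partitioned; a fold's validation pairs need BOTH
#' entities in that fold's partitions, and mixed pairs (exactly one blinded
#' entity in the fold) are dropped from that fold entirely, enforcing a
#' strict cold start.
#'
#' @param table an [interaction_table]
#' @param mode "blind_lnc", "blind_mi" or "blind_both"
#' @param k number of folds
#' @param seed integer seed
#' @return list of class `split_spec` with entity fold assignments
#'   (`lnc_folds` and/or `mi_folds`, named integer vectors)
#' @export
make_blind_split <- function(table, mode = c("blind_lnc", "blind_mi",
                                             "blind_both"),
                             k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "interaction_table"))
  part <- function(ids, label) {
    if (length(ids) < k) {
      stop_fmt("cannot blind %d folds from %d %s entities", k, length(ids),
               label)
    }
    set.seed(derive_seed(seed, paste0("blind_", label)))
    ids <- ids[sample.int(length(ids))]
    stats::setNames(rep(seq_len(k), length.out = length(ids)), ids)
  }
  lnc_folds <- if (mode %in% c("blind_lnc", "blind_both")) {
    part(table$lnc_ids, "lnc")
  }
  mi_folds <- if (mode %in% c("blind_mi", "blind_both")) {
    part(table$mi_ids, "mi")
  }
  structure(list(mode = mode, folds = as.integer(k),
                 lnc_folds = lnc_folds, mi_folds = mi_folds,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Materialize one fold of a split into train/validation pair sets
#'
#' For standard splits, returns training/validation positive and negative
#' pairs by fold membership. For blind splits, partitions the positive
#' pairs of `table` by the fold's blinded entities (see
#' [make_blind_split]); the `dropped` element is non-empty only for
#' `blind_both`.
#'
#' @param spec a `split_spec`
#' @param table the [interaction_table] the split was built from
#' @param fold fold number in `1..spec$folds`
#' @return list with data.frames `train`, `val`, `dropped` (positives only
#'   for blind modes; positives + sampled negatives for standard mode)
#' @export
split_fold_pairs <- function(spec, table, fold) {
  stopifnot(inherits(spec, "split_spec"), fold >= 1L, fold <= spec$folds)
  if (spec$mode == "standard") {
    a <- spec$assignment
    return(list(train = a[a$fold != fold, c("lnc_id", "mi_id", "label")],
                val = a[a$fold == fold, c("lnc_id", "mi_id", "label")],
                dropped = a[0L, c("lnc_id", "mi_id", "label")]))
  }
  pos <- table$pairs[table$pairs$label == 1L, , drop = FALSE]
  lnc_in <- if (!is.null(spec$lnc_folds)) {
    spec$lnc_folds[pos$lnc_id] == fold
  } else rep(FALSE, nrow(pos))
  mi_in <- if (!is.null(spec$mi_folds)) {
    spec$mi_folds[pos$mi_id] == fold
  } else rep(FALSE, nrow(pos))
  if (spec$mode == "blind_both") {
    val <- lnc_in & mi_in
    dropped <- xor(lnc_in, mi_in)
  } else {
    val <- lnc_in | mi_in
    dropped <- rep(FALSE, nrow(pos))
  }
  cols <- c("lnc_id", "mi_id", "label")
  list(train = pos[!val & !dropped, cols],
       val = pos[val, cols],
       dropped = pos[dropped, cols])
}

#' Persist a split specification as TSV
#'
#' Standard mode writes one row per pair (lnc_id, mi_id, label, fold);
#' blind modes write one row per blinded entity (entity id, type, fold).
#' Written in binary mode so identical specs are byte-identical files.
#'
#' @param spec a `split_spec`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_split <- function(spec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (spec$mode == "standard") {
    a <- spec$assignment
    writeLines(paste(a$lnc_id, a$mi_id, a$label, a$fold, sep = "\t"), con)
  } else {
    lines <- character(0)
    if (!is.null(spec$lnc_folds)) {
      lines <- c(lines, paste(names(spec$lnc_folds), "lncRNA",
                              spec$lnc_folds, sep = "\t"))
    }
    if (!is.null(spec$mi_folds)) {
      lines <- c(lines, paste(names(spec$mi_folds), "miRNA",
                              spec$mi_folds, sep = "\t"))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Swap labels of randomly chosen positive and negative training pairs
#'
#' Selects `floor(r * min(P, Q))` positives and the same number of
#' negatives uniformly at random and exchanges their labels, so class
#' counts are conserved. A ratio of zero returns the input unchanged.
#'
#' @param pairs data.frame (lnc_id, mi_id, label)
#' @param r noise ratio in `[0, 1]`
#' @param seed integer seed
#' @return data.frame with the same rows, some labels flipped
#' @export
inject_label_noise <- function(pairs, r, seed = 1L) {
  if (r < 0 || r > 1) stop_fmt("noise ratio must be in [0, 1], got %g", r)
  if (r == 0) return(pairs)
  ip <- which(pairs$label == 1L); iq <- which(pairs$label == 0L)
  n_flip <- floor(r * min(length(ip), length(iq)))
  if (n_flip == 0L) return(pairs)
  set.seed(derive_seed(seed, "label_noise"))
  flip_p <- sample(ip, n_flip)
  flip_q <- sample(iq, n_flip)
  pairs$label[flip_p] <- 0L
  pairs$label[flip_q] <- 1L
  pairs
}

# carve an internal model-selection subset (10%) out of the training pairs
carve_selection_split <- function(train, seed) {
  n <- nrow(train)
  n_val <- max(2L, floor(0.1 * n))
  set.seed(derive_seed(seed, "selection_split"))
  vi <- sample.int(n, min(n_val, n - 1L))
  list(train = train[-vi, , drop = FALSE], val = train[vi, , drop = FALSE])
}

# train/evaluate one fold given explicit train/eval pair sets
run_one_fold <- function(config, data, train_pairs, eval_pairs,
                         fold_seed, noise_ratio = 0, verbose = FALSE) {
  if (noise_ratio > 0) {
    train_pairs <- inject_label_noise(train_pairs, noise_ratio,
                                      seed = fold_seed)
  }
  sel <- carve_selection_split(train_pairs, fold_seed)
  fold_cfg <- config
  fold_cfg$seed <- fold_seed
  model <- train_model(fold_cfg, c(data, list(train = sel$train,
                                              val = sel$val)),
                       verbose = verbose)
  probs <- predict_pairs(model, eval_pairs, data = data)
  list(model = model,
       metrics = compute_metrics(probs, eval_pairs$label,
                                 threshold = config$threshold))
}

# sample evaluation negatives for a positive-only pair set
with_negatives <- function(pos_pairs, table, ratio, seed, forbidden = NULL) {
  neg <- sample_negatives(table, ratio = ratio, seed = seed,
                          forbidden = forbidden,
                          n_positive = nrow(pos_pairs))
  rbind(pos_pairs[, c("lnc_id", "mi_id", "label")],
        neg[, c("lnc_id", "mi_id", "label")])
}

#' Run a full experimental setting
#'
#' Runs train/evaluate over all folds of the requested setting and reports
#' per-fold metrics plus their mean and standard deviation. For blind
#' modes, negatives are sampled per fold for both the training and
#' validation sides (disjoint, never overlapping a known positive). For
#' `independent` mode the model is trained on `data$table` and evaluated on
#' `data$ext_table` (half validation, half test; metrics reported on the
#' test half).
#'
#' @param config a [run_config]
#' @param data list with `lnc_seqs`, `mi_seqs`, `cmaps`, `table` (an
#'   [interaction_table] of known positives) and, for independent mode,
#'   `ext_table`, `ext_lnc_seqs`, `ext_mi_seqs`, `ext_cmaps`
#' @param mode one of standard, blind_lnc, blind_mi, blind_both, independent
#' @param folds number of folds (ignored for independent mode)
#' @param noise_ratio label-noise ratio applied to each fold's training
#'   pairs (robustness protocol)
#' @param verbose print training progress
#' @return list of class `setting_report` with `mode`, `per_fold` (list of
#'   `metrics_report`), `aggregate` (mean and sd per metric), `config_hash`
#' @export
run_setting <- function(config, data,
                        mode = c("standard", "blind_lnc", "blind_mi",
                                 "blind_both", "independent"),
                        folds = 5L, noise_ratio = 0, verbose = FALSE) {
  mode <- match.arg(mode)
  table <- data$table
  stopifnot(inherits(table, "interaction_table"))
  base <- data[c("lnc_seqs", "mi_seqs", "cmaps", "mi_embeddings")]

  if (mode == "independent") {
    ext <- data$ext_table
    stopifnot(inherits(ext, "interaction_table"))
    ext_pos <- ext$pairs[ext$pairs$label == 1L, , drop = FALSE]
    set.seed(derive_seed(config$seed, "independent_halves"))
    half <- sample.int(nrow(ext_pos), floor(nrow(ext_pos) / 2))
    train_pairs <- with_negatives(
      table$pairs[table$pairs$label == 1L, , drop = FALSE], table,
      config$neg_ratio, derive_seed(config$seed, "indep_train_neg"))
    ext_data <- list(lnc_seqs = data$ext_lnc_seqs %||% data$lnc_seqs,
                     mi_seqs = data$ext_mi_seqs %||% data$mi_seqs,
                     cmaps = data$ext_cmaps %||% data$cmaps,
                     mi_embeddings = data$mi_embeddings)
    test_pairs <- with_negatives(
      ext_pos[-half, , drop = FALSE], ext, config$neg_ratio,
      derive_seed(config$seed, "indep_test_neg"))
    res <- run_one_fold(config, base, train_pairs, test_pairs,
                        fold_seed = derive_seed(config$seed, "indep_fold"),
                        noise_ratio = noise_ratio, verbose = verbose)
    # re-score with external sequence data available for unseen entities
    probs <- predict_pairs(res$model, test_pairs, data = ext_data)
    per_fold <- list(compute_metrics(probs, test_pairs$label,
                                     threshold = config$threshold))
  } else if (mode == "standard") {
    spec <- make_cv_folds(table, k = folds, seed = config$seed,
                          neg_ratio = config$neg_ratio)
    per_fold <- lapply(seq_len(folds), function(f) {
      fp <- split_fold_pairs(spec, table, f)
      run_one_fold(config, base, fp$train, fp$val,
                   fold_seed = derive_seed(config$seed, paste0("fold", f)),
                   noise_ratio = noise_ratio, verbose = verbose)$metrics
    })
  } else {
    spec <- make_blind_split(table, mode = mode, k = folds,
                             seed = config$seed)
    per_fold <- lapply(seq_len(folds), function(f) {
      fp <- split_fold_pairs(spec, table, f)
      tr <- with_negatives(fp$train, table, config$neg_ratio,
                           derive_seed(config$seed, paste0("blind_tr_neg", f)))
      va <- with_negatives(fp$val, table, config$neg_ratio,
                           derive_seed(config$seed, paste0("blind_va_neg", f)),
                           forbidden = tr[tr$label == 0L,
                                          c("lnc_id", "mi_id")])
      run_one_fold(config, base, tr, va,
                   fold_seed = derive_seed(config$seed, paste0("fold", f)),
                   noise_ratio = noise_ratio, verbose = verbose)$metrics
    })
  }

  metric_names <- c("F1", "AUC", "AUPR", "NDCG", "Pre", "Rec")
  vals <- sapply(metric_names, function(m) {
    vapply(per_fold, function(r) r[[m]], 0)
  })
  vals <- rbind(vals)  # 1-fold case stays a matrix
  aggregate <- list(mean = as.list(colMeans(vals)),
                    sd = as.list(apply(vals, 2L, stats::sd)))
  structure(list(mode = mode, per_fold = per_fold, aggregate = aggregate,
                 noise_ratio = noise_ratio, seed = config$seed,
                 config_hash = config_hash(unclass(config))),
            class = "setting_report")
}

#' Serialize a setting report to JSON
#' @param report a `setting_report`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  obj <- list(mode = report$mode, seed = report$seed,
              noise_ratio = report$noise_ratio,
              config_hash = report$config_hash,
              per_fold = lapply(report$per_fold, unclass),
              aggregate = report$aggregate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
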