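# Small in-code fixtures shared across test files.

# fast config for desk-scale training tests
tiny_config <- function(...) {
  defaults <- list(k_values = c(2L, 3L), embed_dim = 8L, window = 2L,
                   n_negative = 2L, pvdm_epochs = 3L, max_epochs = 10L,
                   lr = 1e-2, dropout = 0, seed = 7L)
  do.call(run_config, utils::modifyList(defaults, list(...)))
}

# a miniature but complete training problem: 6 lncRNAs x 8 miRNAs
tiny_problem <- function(seed = 7L) {
  lnc <- gen_sequences(6L, c(15L, 25L), "lncRNA", seed = seed)
  mi <- gen_sequences(8L, c(10L, 14L), "miRNA",
                      seed = derive_seed(seed, "mi"))
  cmaps <- lapply(seq_len(8L), function(j) {
    gen_hairpin_contact(mi$length[j], 3L, mi$id[j])
  })
  names(cmaps) <- mi$id
  set.seed(derive_seed(seed, "edges"))
  idx <- which(matrix(stats::runif(48) < 0.3, 6L), arr.ind = TRUE)
  tab <- interaction_table(lnc$id[idx[, 1L]], mi$id[idx[, 2L]],
                           lnc_ids = lnc$id, mi_ids = mi$id)
  neg <- sample_negatives(tab, ratio = 1.0, seed = derive_seed(seed, "neg"))
  pairs <- rbind(tab$pairs, neg)
  list(lnc_seqs = lnc, mi_seqs = mi, cmaps = cmaps, table = tab,
       pairs = pairs)
}

# random interaction table over arbitrary universes (for split tests)
random_table <- function(n_lnc, n_mi, density = 0.2, seed = 1L) {
  set.seed(seed)
  lnc_ids <- sprintf("L%02d", seq_len(n_lnc))
  mi_ids <- sprintf("m%02d", seq_len(n_mi))
  idx <- which(matrix(stats::runif(n_lnc * n_mi) < density, n_lnc),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) idx <- cbind(1L, 1L)
  interaction_table(lnc_ids[idx[, 1L]], mi_ids[idx[, 2L]],
                    lnc_ids = lnc_ids, mi_ids = mi_ids)
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
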