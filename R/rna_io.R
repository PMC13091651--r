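# Readers/writers for external formats, sequence containers, and the run
# configuration. FASTA parsing is delegated to Biostrings; validation and
# normalization (T -> U, case folding, ambiguity rejection) happen here
# because k-mer vocabularies and one-hot features are defined only over
# {A, C, G, U}.

#' Construct a set of RNA sequences
#'
#' The basic sequence container used by every encoder: a data.frame with
#' columns `id`, `seq`, `rna_type` and `length`, validated so that all
#' sequences are uppercase over the {A,C,G,U} alphabet and ids are unique.
#'
#' @param id character vector of identifiers (non-empty, unique)
#' @param seq character vector of sequences (normalized internally)
#' @param rna_type "lncRNA" or "miRNA" (recycled to length of `id`)
#' @return a data.frame of class `rna_set`
#' @export
rna_set <- function(id, seq, rna_type = c("lncRNA", "miRNA")) {
  rna_type <- match.arg(rna_type)
  if (length(id) != length(seq)) {
    stop_fmt("id and seq must have the same length (%d vs %d)",
             length(id), length(seq))
  }
  id <- as.character(id)
  if (any(is.na(id)) || any(!nzchar(id))) {
    stop_fmt("sequence ids must be non-empty strings")
  }
  if (anyDuplicated(id)) {
    stop_fmt("duplicate sequence id(s): %s",
             paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- normalize_rna(seq, id)
  out <- data.frame(id = id, seq = seq, rna_type = rna_type,
                    length = nchar(seq), stringsAsFactors = FALSE)
  class(out) <- c("rna_set", "data.frame")
  out
}

# uppercase, T -> U, reject anything outside {A,C,G,U} (incl. N)
normalize_rna <- function(seq, id) {
  seq <- chartr("t", "u", toupper(as.character(seq)))
  seq <- chartr("T", "U", seq)
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    offender <- id[which(bad)[1L]]
    ch <- regmatches(seq[bad][1L], regexpr("[^ACGU]", seq[bad][1L]))
    if (ch == "N") {
      stop_fmt(paste0("sequence '%s' contains ambiguity code N; ",
                      "ambiguous bases are rejected, not imputed"), offender)
    }
    stop_fmt("sequence '%s' contains invalid character '%s'", offender, ch)
  }
  if (any(!nzchar(seq))) {
    stop_fmt("sequence '%s' is empty", id[which(!nzchar(seq))[1L]])
  }
  seq
}

#' Read RNA sequences from a FASTA file
#'
#' Sequences are normalized to uppercase RNA (T becomes U). Records whose
#' sequences contain characters outside {A,C,G,U,T, case variants} are
#' rejected with an error naming the offending record; so are records
#' containing the ambiguity code N. Record order is preserved and the id is
#' the first whitespace-delimited token of the header.
#'
#' @param path FASTA file path
#' @param rna_type "lncRNA" or "miRNA" tag applied to all records
#' @return an [rna_set]
#' @export
read_fasta <- function(path, rna_type = c("lncRNA", "miRNA")) {
  rna_type <- match.arg(rna_type)
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop_fmt("malformed FASTA '%s': %s",
                                              path, conditionMessage(e)))
  if (length(ss) == 0L) stop_fmt("FASTA file '%s' contains no records", path)
  headers <- names(ss)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    stop_fmt("FASTA file '%s' has an empty record header", path)
  }
  ids <- vapply(strsplit(trimws(headers), "\\s+"), `[[`, "", 1L)
  rna_set(ids, as.character(ss), rna_type = rna_type)
}

#' Write RNA sequences to a FASTA file
#'
#' @param x an [rna_set]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "rna_set"))
  con <- file(path, open = "wb")  # binary mode: byte-identical across runs
  on.exit(close(con))
  writeLines(paste0(">", x$id, "\n", x$seq), con, sep = "\n")
  invisible(path)
}

#' Construct an interaction table
#'
#' Holds the known lncRNA-miRNA pairs as an edge list plus the ordered
#' (first-appearance) unique id lists of each side. `N` is the number of
#' distinct lncRNAs and `M` the number of distinct miRNAs.
#'
#' @param lnc_id,mi_id character vectors of equal length
#' @param label binary labels (default all 1: verified positives)
#' @param lnc_ids,mi_ids optional explicit id universes (superset of the ids
#'   in pairs); useful when some entities have no known interaction
#' @return list of class `interaction_table` with elements `pairs`
#'   (data.frame lnc_id, mi_id, label), `lnc_ids`, `mi_ids`, `N`, `M`
#' @export
interaction_table <- function(lnc_id, mi_id, label = NULL,
                              lnc_ids = NULL, mi_ids = NULL) {
  lnc_id <- as.character(lnc_id); mi_id <- as.character(mi_id)
  if (length(lnc_id) != length(mi_id)) stop_fmt("id columns differ in length")
  if (is.null(label)) label <- rep(1L, length(lnc_id))
  label <- as.integer(label)
  if (any(!label %in% c(0L, 1L))) stop_fmt("labels must be 0 or 1")
  if (any(lnc_id == mi_id)) {
    stop_fmt("self-pair with identical id on both sides: '%s'",
             lnc_id[which(lnc_id == mi_id)[1L]])
  }
  key <- paste(lnc_id, mi_id, sep = "\r")
  keep <- !duplicated(key)
  pairs <- data.frame(lnc_id = lnc_id[keep], mi_id = mi_id[keep],
                      label = label[keep], stringsAsFactors = FALSE)
  lnc_ids <- unique(c(as.character(lnc_ids %||% character()), pairs$lnc_id))
  mi_ids <- unique(c(as.character(mi_ids %||% character()), pairs$mi_id))
  if (length(intersect(lnc_ids, mi_ids))) {
    stop_fmt("id(s) appear on both sides of the bipartite graph: %s",
             paste(utils::head(intersect(lnc_ids, mi_ids), 3), collapse = ", "))
  }
  structure(list(pairs = pairs, lnc_ids = lnc_ids, mi_ids = mi_ids,
                 N = length(lnc_ids), M = length(mi_ids)),
            class = "interaction_table")
}

#' Read an interaction edge list (TSV)
#'
#' Expects 2-3 tab-separated columns: lncRNA id, miRNA id, and an optional
#' binary label defaulting to 1 (curated interaction lists contain verified
#' positives only). Duplicate pairs are dropped; ids keep first-appearance
#' order.
#'
#' @param path TSV file path
#' @return an [interaction_table]
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop_fmt("interaction file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fmt("interaction file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop_fmt("malformed row at line %d of '%s' (need >= 2 tab-separated columns)",
             which(nf < 2L)[1L], path)
  }
  lnc <- vapply(fields, `[[`, "", 1L)
  mi <- vapply(fields, `[[`, "", 2L)
  lab <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 3L) fields[[i]][[3L]] else "1"
  }, "")
  labn <- suppressWarnings(as.integer(lab))
  if (any(is.na(labn) | !labn %in% c(0L, 1L))) {
    stop_fmt("malformed label at line %d of '%s' (must be 0 or 1)",
             which(is.na(labn) | !labn %in% c(0L, 1L))[1L], path)
  }
  interaction_table(lnc, mi, labn)
}

#' Write an interaction table as TSV
#' @param table an [interaction_table]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_interactions <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(table$pairs$lnc_id, table$pairs$mi_id, table$pairs$label,
                   sep = "\t"), con)
  invisible(path)
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline with validated defaults. The four
#' ablation variants are selected through `interaction_mode` and
#' `feature_mode`:
#' \itemize{
#'   \item `interaction_mode`: `ge_gcn` (full model), `vanilla_gcn` (no
#'     global hub exchange), `none` (interaction-topology embeddings
#'     omitted), `only` (sequence/structure embeddings omitted).
#'   \item `feature_mode`: `pretrained` (PV-DM lncRNA vectors, external or
#'     one-hot miRNA node features), `onehot` (one-hot on both sides),
#'     `onehot_lnc`, `onehot_mi` (one side swapped).
#' }
#'
#' @param k_values k-mer sizes for the multiscale lncRNA encoder
#' @param embed_dim shared embedding width d
#' @param window PV-DM context half-window c
#' @param n_negative negative samples per PV-DM target
#' @param pvdm_epochs PV-DM pretraining epochs
#' @param gcn_layers depth of the miRNA contact-graph GCN
#' @param ge_layers depth of the globally enhanced interaction GCN
#' @param lr Adam learning rate
#' @param max_epochs training epoch budget (best validation checkpoint kept)
#' @param neg_ratio negatives sampled per positive
#' @param dropout dropout rate in the prediction MLP
#' @param threshold classification threshold on predicted probability
#' @param seed global seed; all component seeds derive from it
#' @param feature_mode see Details
#' @param interaction_mode see Details
#' @param leak_free_pvdm if TRUE (default) PV-DM is trained on training-split
#'   sequences only and unseen sequences are embedded by frozen-table
#'   inference, avoiding leakage in blind/independent settings
#' @param freeze_broadcast if TRUE the GE-GCN broadcast weights are excluded
#'   from optimization (used to verify that the globally enhanced layer with
#'   zero broadcast weights reproduces a vanilla GCN exactly)
#' @return list of class `run_config`
#' @export
run_config <- function(k_values = c(3L, 9L, 15L),
                       embed_dim = 64L,
                       window = 5L,
                       n_negative = 5L,
                       pvdm_epochs = 30L,
                       gcn_layers = 2L,
                       ge_layers = 2L,
                       lr = 1e-4,
                       max_epochs = 200L,
                       neg_ratio = 1.0,
                       dropout = 0.2,
                       threshold = 0.5,
                       seed = 1L,
                       feature_mode = c("pretrained", "onehot",
                                        "onehot_lnc", "onehot_mi"),
                       interaction_mode = c("ge_gcn", "vanilla_gcn",
                                            "none", "only"),
                       leak_free_pvdm = TRUE,
                       freeze_broadcast = FALSE) {
  feature_mode <- match.arg(feature_mode)
  interaction_mode <- match.arg(interaction_mode)
  k_values <- as.integer(k_values)
  if (length(k_values) < 1L || any(k_values < 1L)) {
    stop_fmt("k_values must be positive integers")
  }
  if (lr <= 0) stop_fmt("lr must be > 0")
  if (max_epochs < 1L) stop_fmt("max_epochs must be >= 1")
  if (neg_ratio < 0) stop_fmt("neg_ratio must be >= 0")
  if (dropout < 0 || dropout >= 1) stop_fmt("dropout must be in [0, 1)")
  cfg <- list(k_values = k_values, embed_dim = as.integer(embed_dim),
              window = as.integer(window), n_negative = as.integer(n_negative),
              pvdm_epochs = as.integer(pvdm_epochs),
              gcn_layers = as.integer(gcn_layers),
              ge_layers = as.integer(ge_layers),
              lr = lr, max_epochs = as.integer(max_epochs),
              neg_ratio = neg_ratio, dropout = dropout, threshold = threshold,
              seed = as.integer(seed), feature_mode = feature_mode,
              interaction_mode = interaction_mode,
              leak_free_pvdm = isTRUE(leak_free_pvdm),
              freeze_broadcast = isTRUE(freeze_broadcast))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat YAML file
#'
#' Supports the flat scalar/list subset of YAML that run configs need:
#' `key: value`, `key: [a, b, c]`, comments with `#`, blank lines. Keys must
#' match [run_config] argument names; unknown keys are an error.
#'
#' @param path YAML file path
#' @param ... overrides applied after the file is read
#' @return a [run_config]
#' @export
read_config <- function(path, ...) {
  vals <- if (is.null(path)) list() else parse_flat_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

parse_flat_yaml <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1L]]
    if (length(m) != 3L) stop_fmt("cannot parse config line: '%s'", ln)
    key <- m[2L]; val <- m[3L]
    if (grepl("^\\[.*\\]$", val)) {
      items <- trimws(strsplit(substr(val, 2L, nchar(val) - 1L), ",")[[1L]])
      out[[key]] <- yaml_scalar(items)
    } else {
      out[[key]] <- yaml_scalar(val)
    }
  }
  out
}

yaml_scalar <- function(v) {
  v <- gsub("^['\"]|['\"]$", "", v)
  low <- tolower(v)
  if (all(low %in% c("true", "false"))) return(low == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!any(is.na(num))) return(num)
  v
}

#' Write a run configuration as flat YAML
#' @param config a [run_config]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt_val <- function(v) {
    if (length(v) > 1L) paste0("[", paste(v, collapse = ", "), "]")
    else if (is.logical(v)) tolower(as.character(v))
    else as.character(v)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(names(config), function(k) {
    paste0(k, ": ", fmt_val(config[[k]]))
  }, ""), con)
  invisible(path)
}
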