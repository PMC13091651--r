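# Independent reference implementations used as oracles. These are written
# against the metric/parser definitions directly (quadratic loops, full
# enumerations) and share no code with the package internals they check.

# AUC as the fraction of positive/negative pairs ranked correctly,
# ties counting one half (O(n^2) Mann-Whitney)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# AUPR by explicit evaluation of precision/recall at every unique score
# threshold (descending), step integration
oracle_aupr <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# NDCG with binary gains over the full ranked list (stable descending sort)
oracle_ndcg <- function(scores, labels) {
  ord <- order(-scores)
  dcg <- 0
  for (i in seq_along(ord)) {
    dcg <- dcg + labels[ord[i]] / log2(i + 1)
  }
  idcg <- 0
  for (i in seq_len(sum(labels == 1))) {
    idcg <- idcg + 1 / log2(i + 1)
  }
  dcg / idcg
}

# dot-bracket pairing by iterated innermost-pair reduction (no stack):
# repeatedly find a "(" directly followed (ignoring consumed positions and
# dots) by a ")" and record the pair
oracle_dotbracket_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1L]]
  open_char <- chars == "("
  close_char <- chars == ")"
  active <- open_char | close_char
  pairs <- NULL
  repeat {
    idx <- which(active)
    if (length(idx) == 0L) break
    hit <- FALSE
    for (t in seq_len(length(idx) - 1L)) {
      i <- idx[t]; j <- idx[t + 1L]
      if (open_char[i] && close_char[j]) {
        pairs <- rbind(pairs, c(i, j))
        active[c(i, j)] <- FALSE
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("unbalanced structure")
  }
  pairs
}

# random balanced dot-bracket string (possibly nested/serial stems)
random_dotbracket <- function(L) {
  chars <- rep(".", L)
  depth <- 0
  opens <- integer(0)
  for (i in seq_len(L)) {
    remaining <- L - i
    r <- stats::runif(1)
    if (depth > 0 && (r < 0.3 || remaining <= depth)) {
      chars[i] <- ")"
      depth <- depth - 1
    } else if (r < 0.6 && remaining > depth + 1) {
      chars[i] <- "("
      depth <- depth + 1
    }
  }
  # close any dangling opens by converting from the right
  s <- paste(chars, collapse = "")
  while (TRUE) {
    bal <- cumsum((strsplit(s, "")[[1]] == "(") -
                    (strsplit(s, "")[[1]] == ")"))
    if (utils::tail(bal, 1) == 0 && all(bal >= 0)) break
    ch <- strsplit(s, "")[[1]]
    if (utils::tail(bal, 1) > 0) {
      ch[max(which(ch == "("))] <- "."
    } else {
      ch[max(which(bal < 0))] <- "."
    }
    s <- paste(ch, collapse = "")
  }
  s
}

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}
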