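# miRNA encoder: nucleotide contact graphs from secondary structure, a
# degree-normalized GCN over them, and mean pooling to one vector per
# miRNA. Initial node features are either one-hot nucleotides (bundled
# fallback) or externally supplied per-nucleotide embedding matrices
# (standing in for an RNA language model; no such model is bundled).

#' Construct a contact map
#'
#' Symmetric binary nucleotide-nucleotide adjacency with zero diagonal.
#'
#' @param A square 0/1 matrix
#' @param rna_id identifier
#' @return list of class `contact_map` with `rna_id`, `A`, `L`
#' @export
contact_map <- function(A, rna_id = "mi") {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_fmt("contact matrix must be square")
  if (any(!A %in% c(0, 1))) stop_fmt("contact matrix entries must be 0/1")
  if (any(A != t(A))) stop_fmt("contact matrix must be symmetric")
  if (any(diag(A) != 0)) stop_fmt("contact matrix diagonal must be zero")
  dimnames(A) <- NULL
  structure(list(rna_id = rna_id, A = A, L = nrow(A)), class = "contact_map")
}

#' Contact map from a dot-bracket secondary structure
#'
#' Each matched `(`/`)` pair (i, j) sets A[i, j] = A[j, i] = 1. Only one
#' bracket family is supported; pseudoknot notations are rejected.
#'
#' @param structure dot-bracket string over `.`, `(`, `)`
#' @param rna_id identifier
#' @return a [contact_map]
#' @export
dotbracket_to_contact <- function(structure, rna_id = "mi") {
  chars <- strsplit(structure, "")[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) {
    stop_fmt("unsupported character '%s' at position %d of dot-bracket string",
             chars[bad[1L]], bad[1L])
  }
  L <- length(chars)
  A <- matrix(0, L, L)
  stack <- integer(0)
  for (i in seq_len(L)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop_fmt("unbalanced ')' at position %d", i)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      A[i, j] <- A[j, i] <- 1
    }
  }
  if (length(stack)) {
    stop_fmt("unbalanced '(' at position %d", stack[length(stack)])
  }
  contact_map(A, rna_id)
}

#' Contact map from a numeric matrix file
#'
#' Reads a whitespace-delimited square matrix (e.g. contact probabilities
#' from a structure predictor), thresholds entries at `threshold`,
#' symmetrizes by `max(A, t(A))` and zeroes the diagonal.
#'
#' @param path matrix file
#' @param threshold probability cutoff (entries >= threshold become contacts)
#' @param rna_id identifier
#' @return a [contact_map]
#' @export
load_contact_matrix <- function(path, threshold = 0.5, rna_id = "mi") {
  raw <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(raw) != ncol(raw)) {
    stop_fmt("contact matrix in '%s' is not square (%d x %d)",
             path, nrow(raw), ncol(raw))
  }
  A <- (raw >= threshold) * 1
  A <- pmax(A, t(A))
  diag(A) <- 0
  contact_map(A, rna_id)
}

#' Read dot-bracket structures from a 2-column TSV (id, structure)
#' @param path TSV file path
#' @return named list of [contact_map]s
#' @export
read_structures <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_fmt("structure TSV needs 2 columns (id, structure)")
  maps <- lapply(seq_len(nrow(tab)), function(i) {
    dotbracket_to_contact(tab[i, 2L], rna_id = tab[i, 1L])
  })
  names(maps) <- tab[[1L]]
  maps
}

#' One-hot nucleotide node features
#'
#' L x 4 matrix with columns A, C, G, U; the bundled fallback for the
#' external per-nucleotide embeddings.
#'
#' @param seq RNA sequence string
#' @return L x 4 matrix
#' @export
onehot_features <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  lv <- c("A", "C", "G", "U")
  idx <- match(chars, lv)
  if (anyNA(idx)) stop_fmt("sequence contains non-ACGU characters")
  H <- matrix(0, length(chars), 4L, dimnames = list(NULL, lv))
  H[cbind(seq_along(idx), idx)] <- 1
  H
}

# symmetric normalization of A with self-loops: D^-1/2 (A + I) D^-1/2.
# Every node has degree >= 1 via its self-loop, so no zero division.
normalize_adjacency <- function(A) {
  Ah <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ah))
  Ah * outer(dinv, dinv)
}

#' One graph-convolution layer
#'
#' Computes `act(D^-1/2 (A + I) D^-1/2 H W)`: degree-normalized propagation
#' with self-loops, a linear transform, and an elementwise nonlinearity.
#'
#' @param H L x d_in node feature matrix
#' @param A a [contact_map] (or plain symmetric 0/1 matrix)
#' @param W d_in x d_out weight matrix
#' @param act activation function (default [relu]; use `identity` for none)
#' @return L x d_out node matrix
#' @export
gcn_layer <- function(H, A, W, act = relu) {
  if (inherits(A, "contact_map")) A <- A$A
  H <- rbind(H)
  if (nrow(H) != nrow(A)) {
    stop_fmt("feature rows (%d) != graph nodes (%d)", nrow(H), nrow(A))
  }
  if (ncol(H) != nrow(W)) {
    stop_fmt("feature width (%d) != weight rows (%d)", ncol(H), nrow(W))
  }
  act(normalize_adjacency(A) %*% H %*% W)
}

#' Initialize a GCN weight stack
#'
#' @param dims integer vector of layer widths `c(d0, d1, ..., dp)`
#' @param seed integer seed
#' @return list of class `gcn_stack` with `weights` (list of matrices) and
#'   `activation` ("relu")
#' @export
gcn_stack <- function(dims, seed = 1L) {
  stopifnot(length(dims) >= 2L)
  set.seed(seed)
  weights <- lapply(seq_len(length(dims) - 1L), function(l) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
           dims[l], dims[l + 1L])
  })
  structure(list(weights = weights, activation = "relu"), class = "gcn_stack")
}

# forward with caches for backprop: per layer the normalized input (MHW
# pre-activation) and the layer input
mirna_gcn_forward <- function(H0, An, weights) {
  caches <- vector("list", length(weights))
  H <- H0
  for (l in seq_along(weights)) {
    MH <- An %*% H
    pre <- MH %*% weights[[l]]
    caches[[l]] <- list(MH = MH, pre = pre)
    H <- relu(pre)
  }
  list(out = colMeans(rbind(H)), H = H, caches = caches)
}

# backprop a d-vector gradient of the pooled output through the stack;
# returns per-layer weight gradients (list) — input features are fixed
mirna_gcn_backward <- function(H0, An, weights, caches, g_out) {
  L <- nrow(rbind(H0))
  gH <- matrix(rep(g_out / L, each = L), L, length(g_out))
  gW <- vector("list", length(weights))
  for (l in rev(seq_along(weights))) {
    gPre <- gH * relu_grad(caches[[l]]$pre)
    gW[[l]] <- t(caches[[l]]$MH) %*% gPre
    if (l > 1L) {
      gH <- (t(An) %*% gPre) %*% t(weights[[l]])
    }
  }
  gW
}

#' Encode one miRNA from contact graph and node features
#'
#' Applies the GCN stack over the contact graph and mean-pools the final
#' node embeddings into a single vector.
#'
#' @param features L x d0 initial node feature matrix (one-hot or external)
#' @param cmap a [contact_map]
#' @param stack a [gcn_stack]
#' @return pooled d-vector
#' @export
encode_mirna <- function(features, cmap, stack) {
  features <- rbind(features)
  if (nrow(features) != cmap$L) {
    stop_fmt("feature rows (%d) != contact map length (%d)",
             nrow(features), cmap$L)
  }
  An <- normalize_adjacency(cmap$A)
  mirna_gcn_forward(features, An, stack$weights)$out
}
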