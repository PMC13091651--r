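# Internal utilities: deterministic seed derivation, lightweight hashing,
# activations shared by the neural modules.

#' 32-bit FNV-1a hash of a character string
#'
#' Used for config hashes in run manifests and for deriving per-component
#' child seeds from the single global seed. Returns a non-negative integer
#' below 2^31 so it is always a valid R random seed.
#'
#' @param x a length-1 character string
#' @return integer in `[0, 2^31 - 1]`
#' @keywords internal
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  # 32-bit FNV-1a in double arithmetic (exact: intermediate products are
  # reduced modulo 2^32 via byte-wise multiplication to stay < 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    # h * 16777619 mod 2^32, split to avoid exceeding 2^53
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  as.integer(h %% 2147483648)
}

# xor of two non-negative doubles < 2^32, implemented on 16-bit halves
# because bitwXor() only takes 32-bit signed integers
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo + hi * 65536
}

#' Derive a deterministic child seed
#'
#' All stochastic components draw their seed from the single global run seed
#' plus a component label, so that end-to-end runs are reproducible while
#' components remain decoupled.
#'
#' @param seed integer global seed
#' @param label character component label (e.g. "pvdm_k3", "fold2_negatives")
#' @return integer seed in `[0, 2^31 - 1]`
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  fnv1a32(paste0(format(as.integer(seed)), "::", label))
}

#' Hash an R object (via its JSON serialization)
#' @keywords internal
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("%08x", fnv1a32(as.character(js)))
}

#' Fingerprint a file (md5 of contents)
#' @keywords internal
file_fingerprint <- function(path) {
  unname(tools::md5sum(path))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_grad <- function(pre) {
  (pre > 0) * 1
}

sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

# numerically stable row-wise softmax of a matrix
row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
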