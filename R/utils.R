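# internal helpers shared across modules

# polynomial hash of a serialized R object; provenance stamp only, not crypto
obj_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# orthonormal basis of the column span of m (drops null directions)
orth_basis <- function(m, tol = 1e-10) {
  s <- svd(m)
  r <- sum(s$d > tol * max(s$d, tol))
  if (r == 0L) return(matrix(0, nrow(m), 0L))
  s$u[, seq_len(r), drop = FALSE]
}
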