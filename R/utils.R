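# Internal helpers: scoped RNG and content fingerprinting.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream.  All stochastic entry points funnel through this.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Fingerprint an R object
#'
#' MD5 digest of the object's serialized form.  Used to tie a ranked feature
#' list to the exact training data, secondary source and parameters it was
#' computed from, and to derive reproducible, input-order-independent fold
#' seeds.
#'
#' @param x Any serializable R object.
#' @return A 32-character hexadecimal string.
#' @export
fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  # version = 2 keeps the digest stable across R releases
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Deterministic 31-bit integer seed derived from a fingerprint.
seed_from_fingerprint <- function(fp, offset = 0L) {
  (strtoi(substr(fp, 1L, 7L), 16L) + as.integer(offset)) %% .Machine$integer.max
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
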