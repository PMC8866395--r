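#' @keywords internal
"_PACKAGE"

# Deterministic integer substream derivation. A master seed fans out into
# named/indexed substreams (per subject, per feature, per stage) so that the
# draw for stream i does not depend on how many other streams are consumed.
# Uses a 32-bit mixing of (seed, index); result is a valid set.seed() value.
substream_seed <- function(seed, index, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # splitmix-style mix on doubles kept below 2^31
  x <- (as.double(seed) %% 2147483647) + 1
  y <- (as.double(index) %% 2147483647) + 1
  z <- (as.double(salt) %% 2147483647) + 1
  h <- (x * 2654435761 + y * 40503 + z * 69069) %% 2147483647
  h <- (h * 48271 + 11) %% 2147483647
  as.integer(h)
}

# Run expr with a local RNG state seeded from `seed`; the caller's RNG state
# is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Checksum of an arbitrary R object
#'
#' MD5 of the canonical serialization, used to assert that frozen artifacts
#' (split plans, tangent references, scalers) are bit-identical across
#' pipeline stages.
#'
#' @param x any R object
#' @return a character MD5 digest
#' @export
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 for stability across R versions; ascii for platform freedom
  saveRDS(x, f, version = 2, ascii = TRUE)
  unname(tools::md5sum(f))
}

# Upper-triangle (strict, row-major) index pairs for an R x R matrix.
upper_pairs <- function(R) {
  i <- rep(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(a) (a + 1L):R))
  cbind(i = i, j = j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
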