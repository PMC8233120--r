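# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a deterministic sub-seed from a base seed and context labels
#'
#' Used to give every randomized stage (cohort simulation, permutation
#' draws per modality/hemisphere/bin, ICA runs) its own reproducible RNG
#' stream from one user-facing seed. The result is always a positive
#' 32-bit integer.
#'
#' @param seed Integer base seed.
#' @param ... Context labels (coerced to character).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "|")
  h <- 17
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# Near-equal contiguous chunk sizes: n items into k chunks, earlier chunks
# receive the extra item when sizes differ.
chunk_sizes <- function(n, k) {
  if (k > n) stop("more bins than eligible edges")
  base <- n %/% k
  extra <- n %% k
  rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
}
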