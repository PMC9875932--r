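#' Derive a reproducible substream seed
#'
#' Folds one or more integer indices into a master seed with a
#' linear-congruential step, yielding independent substream seeds for
#' per-subject or per-replicate random draws. Adding subjects or replicates
#' never perturbs the streams of existing ones, because each stream depends
#' only on its own indices.
#'
#' @param seed master seed (integer-valued scalar).
#' @param ... integer indices identifying the substream (e.g. subject index,
#'   model index, replicate number).
#' @return A single integer in \code{[0, 2^31 - 2]} suitable for
#'   \code{\link{set.seed}}.
#' @examples
#' splitSeed(1, 5, 2)
#' @export
splitSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  if (length(idx)) {
    for (k in as.double(idx)) {
      # multiplier kept small enough that s * 69069 stays below 2^53
      s <- (s * 69069 + k + 1) %% 2147483647
    }
  } else {
    s <- (s * 69069 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Assert a scalar condition with a message naming the offending field.
checkField <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop("invalid configuration field '", field, "': ", msg,
                        call. = FALSE)
  invisible(TRUE)
}
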