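`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a labelled sub-stream seed
#'
#' Maps a user seed and a generator label to a deterministic 32-bit seed, so
#' each simulator draws from its own pseudo-random stream and adding a new
#' generator never perturbs the output of an existing one.
#'
#' @param seed Integer-valued base seed.
#' @param label Character label naming the stream (e.g. `"screen"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "screen")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  h <- abs(as.double(seed)) %% 2147483647
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a given seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
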