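#' Derive a reproducible child seed from a master seed and a label
#'
#' Every source of randomness in the package draws its seed through this
#' function, so that stages (and individual simulated samples) get
#' independent, stable streams: adding a stage or a sample never perturbs
#' the draws of existing ones.
#'
#' @param seed master integer seed.
#' @param label character tag naming the stream (stage name, sample id, ...).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  # 32-bit FNV-1a over the label bytes, folded with the master seed.
  # Done in double precision (exact below 2^53), reduced mod 2^31 - 1.
  h <- 2166136261
  for (b in utf8ToInt(label)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((h + abs(seed) * 2654435761) %% (2^31 - 1))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop()/warning() with sprintf formatting and no call in the condition
vi_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
vi_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# upper-triangle values of a square symmetric matrix
upper_vals <- function(m) m[upper.tri(m)]
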