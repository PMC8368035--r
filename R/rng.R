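#' Derive a child seed from a run seed
#'
#' All stochastic operations in the package draw their randomness from one
#' explicit integer run seed. Sub-tasks (wells, fields, cells, stages) get
#' deterministic child seeds derived by hashing the run seed together with a
#' stream label, so that adding wells or reordering stages never perturbs the
#' random stream of unrelated components.
#'
#' @param seed integer run seed.
#' @param ... character or integer stream labels (e.g. well id, stage name).
#' @return an integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @examples
#' derive_seed(1L, "plate", "A01")
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  labels <- paste(c(format(seed, scientific = FALSE), vapply(list(...), function(x)
    paste(as.character(x), collapse = "/"), character(1))), collapse = "|")
  # FNV-1a over the label bytes, folded into a positive 31-bit integer
  h <- 2166136261 %% 2147483647
  for (b in as.integer(charToRaw(labels))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
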