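#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline receives its own seed, derived
#' deterministically from the master seed and a stage label, so that a single
#' integer reproduces a whole run while stages remain independent.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
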