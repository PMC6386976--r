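# Internal helpers: seeding, validation.

#' Derive a child seed from a master seed
#'
#' Linear-congruential mixing of a master seed with a stream index. Every
#' randomised routine in the package draws its own seed through this map, so
#' any single iteration, sequence or group is reproducible in isolation from
#' the master seed alone. Results stay below 2^31 - 1.
#'
#' @param master integer-valued master seed.
#' @param index integer stream index (iteration, sequence counter, ...).
#' @return A numeric scalar usable with [set.seed()].
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(index), length(index) == 1L, is.finite(index))
  ((abs(master) %% 2147483647) * 48271 + (abs(index) %% 2147483647) * 9973 + 1) %%
    2147483647
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_in <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
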