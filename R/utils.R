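# Shared internal helpers and physical constants.

# Boltzmann constant, J/K (CODATA 2018 exact value)
.kB <- 1.380649e-23

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state, so seeded simulation helpers do
#' not disturb the caller's random stream. With `seed = NULL` the code is
#' run against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# stop() with a classed condition so pipeline callers can catch selectively
pk_stop <- function(msg, class = "platekd_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# log-spaced sequence
lseq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}
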