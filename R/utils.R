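# Internal helpers: seeded evaluation, deterministic stage seeds, small
# numerical utilities shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream as-is.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a per-stage seed from a global seed
#'
#' Mixes the stage name into the global seed so that adding a pipeline stage
#' never perturbs the random stream of earlier stages. Result is a positive
#' integer below 2^31.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
#' @examples
#' stage_seed(1, "nti")
stage_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(as.numeric(global_seed)) %% 2147483629 * 48271 + h) %%
               2147483629 + 1)
}

# Row-wise minima of a numeric matrix; empty matrix -> Inf per row.
row_mins <- function(m) {
  if (ncol(m) == 0L) return(rep(Inf, nrow(m)))
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmin(out, m[, j])
  out
}

# Stop with a classed error so callers/tests can distinguish failure modes.
ma_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "microassembly_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# All unordered sample pairs of a character vector, as a 2-column matrix.
sample_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2L) return(matrix(character(), ncol = 2L,
                            dimnames = list(NULL, c("a", "b"))))
  idx <- utils::combn(n, 2L)
  cbind(a = ids[idx[1L, ]], b = ids[idx[2L, ]])
}
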