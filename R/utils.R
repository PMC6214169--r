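#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so seeded generators do not disturb the global stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

#' Clock-time arithmetic on a 24 h cycle
#' @param t hours (any real).
#' @return hours in `[0, 24)`.
#' @keywords internal
clock24 <- function(t) t %% 24

## Neighbor convention shared by the simulator, design builder and likelihood:
## fixed slot order E, W, N, S with unit vectors toward each neighbor.
## Rows are 0-based with row 0 at the bottom (y increases with row index),
## columns 0-based increasing with x.
NEIGHBOR_SLOTS <- c("E", "W", "N", "S")
NEIGHBOR_DROW <- c(E = 0L, W = 0L, N = 1L, S = -1L)
NEIGHBOR_DCOL <- c(E = 1L, W = -1L, N = 0L, S = 0L)
NEIGHBOR_UX <- c(E = 1, W = -1, N = 0, S = 0)
NEIGHBOR_UY <- c(E = 0, W = 0, N = 1, S = -1)
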