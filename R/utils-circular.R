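#' Signed angular difference on the 180-degree orientation circle
#'
#' Orientations are 180-degree periodic (a grating at 170 degrees is 10
#' degrees away from one at 0 degrees). All angular arithmetic in the
#' package goes through these helpers.
#'
#' @param a,b orientations in degrees.
#' @return `circ_diff180`: signed shortest-arc difference `a - b` in
#'   `[-90, 90)`. `circ_dist180`: absolute shortest-arc distance in
#'   `[0, 90]`.
#' @export
circ_diff180 <- function(a, b) {
  ((a - b + 90) %% 180) - 90
}

#' @rdname circ_diff180
#' @export
circ_dist180 <- function(a, b) {
  abs(circ_diff180(a, b))
}

#' Derive a deterministic stream of child seeds
#'
#' Expands one user-facing seed into `n` independent child seeds (all
#' valid 32-bit integers) without disturbing the caller's random-number
#' state. Used so that every stage of a pipeline has its own seed while
#' the whole run stays reproducible from a single number.
#'
#' @param seed master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.Random.seed_set <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
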