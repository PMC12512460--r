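#' @keywords internal
"_PACKAGE"

#' Derive reproducible child seeds
#'
#' Expands one integer seed into \code{k} child seeds (below 2^31) for
#' independent simulation replicates, without disturbing the caller's RNG
#' state.
#'
#' @param seed Single integer master seed.
#' @param k Number of child seeds.
#' @return Integer vector of length \code{k}.
#' @export
seed_streams <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, k)
}

# Linear-interpolation quantiles (type 7) used everywhere a quantile
# convention matters: the variability filter and the delta-beta GA range.
lin_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Huber weight function, psi(u)/u, tuning constant k.
huber_weight <- function(u, k = 1.345) {
  au <- abs(u)
  w <- rep(1, length(u))
  big <- au > k & is.finite(au)
  w[big] <- k / au[big]
  w[!is.finite(au)] <- 0
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
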