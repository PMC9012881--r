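#' Derive a per-stage random seed from a global seed
#'
#' Pipeline stages draw their own seeds from the global seed through a fixed
#' counter scheme, `(seed mod 1000003) * 1009 + stage`, so that any stage can be
#' re-run in isolation and reproduce the full-pipeline result. The derived seed
#' is always a valid 32-bit integer.
#'
#' @param seed integer global seed.
#' @param stage integer stage counter (>= 0).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(seed) %% 1000003L) * 1009L + as.integer(stage))
}

## internal: sample from the elements of x even when length(x) == 1
## (avoids base sample()'s 1:x expansion of scalars)
.resample <- function(x, ...) x[sample.int(length(x), ...)]

## internal: stop with a consistent prefix
.nf_stop <- function(...) stop(..., call. = FALSE)

## internal: check a single non-negative count
.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    .nf_stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

## internal: fraction in [0, 1]
.check_frac <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    .nf_stop(sprintf("'%s' must be a single number in [0, 1]", name))
  as.numeric(x)
}
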