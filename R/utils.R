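#' @keywords internal
"_PACKAGE"

GROUPS <- c("NEVKP", "SCS")
TIMEPOINTS <- c("BL", "R30", "POD3")

#' Derive a reproducible child seed
#'
#' Deterministic per-replicate/stage seed from `(master_seed, index)`:
#' Lehmer-style mixing mod 2^31 - 1, exact in double precision, so derived
#' seeds are platform-independent and independent of execution order.
#'
#' @param master_seed,index Single integers.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483647
  s <- ((as.double(master_seed) %% m) * 48271 + as.double(index) * 16807 + 1) %% m
  as.integer(s)
}

# Smallest p admitted before log-pooling; avoids -Inf from underflow.
P_FLOOR <- 1e-300

# session cache (studentized-range tail splines, keyed by nmeans/df)
.miprot_cache <- new.env(parent = emptyenv())

assert_probability <- function(p, what = "p-values") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}
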