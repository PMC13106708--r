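#' Internal assertion helper
#'
#' @param ok logical scalar
#' @param msg error message
#' @noRd
.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a reproducible sub-stream seed from a root seed
#'
#' One root seed drives several independent random draws (natural frequencies,
#' initial phases, dynamic noise, measurement noise). Each draw gets its own
#' 32-bit seed derived deterministically from the root so that changing one
#' stream's consumption never perturbs another.
#'
#' @param seed integer root seed.
#' @param stream small integer stream index.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
sub_seed <- function(seed, stream) {
  .assert(.is_number(seed), "seed must be a single finite number")
  .assert(.is_number(stream), "stream must be a single finite number")
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  # 48271: MINSTD multiplier; products stay below 2^53 so doubles are exact
  as.integer(((s * 48271 + as.numeric(stream) * 104729) %% 2147483646) + 1)
}
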