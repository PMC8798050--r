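# Internal helpers shared across modules.

DNA_STATES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; diversity-table ratios are
#' conventionally reported with halves rounded up, so that rule is applied
#' everywhere a ratio is printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derivation so every simulation stage is
# individually reproducible from one master seed. Offsets keep results
# well below .Machine$integer.max for small master seeds.
derive_seed <- function(seed, stage) {
  offsets <- c(
    tree = 11L, populations = 23L, sequences = 37L,
    geography = 53L, missingness = 71L, quartets = 89L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.integer(seed) * 101L + offsets[[stage]]) %% 2147483647L)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
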