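#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export tidy
#' @export glance
#' @export autoplot
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage substream seed derived from one root seed.
# Kept strictly below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, stage, index = 0L) {
  offsets <- c(simulate = 11L, prepare = 23L, absences = 37L, fit = 53L,
               cv = 67L, importance = 79L, ensemble = 97L, stack = 113L,
               diversity = 131L, clusters = 151L, sample = 173L)
  off <- offsets[[stage]] %||% 199L
  as.integer((as.double(seed) * 2654435.0 + off * 97003.0 + index * 101.0) %% 2147483629)
}

utils::globalVariables(c("taxon", "cell", "n_species", "group", "share",
                         "rank", ".row"))
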