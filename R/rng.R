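#' Derive a reproducible RNG substream seed
#'
#' A master seed is hashed together with a component label and an index to
#' give an independent-looking seed for each component of a run. Per-trial
#' and per-permutation seeds are derived this way, so results do not depend
#' on the order in which trials are executed or on how work is chunked.
#'
#' @param master integer master seed.
#' @param component character label of the consuming component
#'   (e.g. `"trial"`, `"perm"`).
#' @param index nonnegative integer index within the component.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' rng_substream(1, "trial", 7)
#' @export
rng_substream <- function(master, component, index = 0L) {
  if (!is.numeric(master) || length(master) != 1L || !is.finite(master)) {
    stop("`master` must be a single finite number", call. = FALSE)
  }
  h <- (abs(as.double(master)) %% 2147483647) + 1
  key <- c(utf8ToInt(as.character(component)), as.double(index) + 1)
  for (k in key) {
    h <- (h * 69069 + k) %% 2147483629
  }
  as.integer((h %% 2147483645) + 1)
}
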