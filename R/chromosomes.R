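#' Default rice pseudo-chromosome lengths
#'
#' A built-in table of physical lengths for the 12 rice pseudo-chromosomes,
#' used wherever a chromosome-length map is not supplied. Chromosome 1 is
#' 45 Mb so that all Saltol-region marker coordinates fall inside it; the
#' total (375.5 Mb) and per-chromosome values are rice-like round numbers,
#' not an assembly release.
#'
#' @return Named numeric vector of lengths in base pairs; names are the
#'   chromosome identifiers `"1"` to `"12"`.
#' @examples
#' rice_chromosome_lengths()[["1"]]
#' @export
rice_chromosome_lengths <- function() {
  c(`1` = 45.0e6, `2` = 36.0e6, `3` = 37.0e6, `4` = 35.0e6,
    `5` = 30.0e6, `6` = 32.0e6, `7` = 30.0e6, `8` = 28.0e6,
    `9` = 23.0e6, `10` = 23.0e6, `11` = 29.0e6, `12` = 27.5e6)
}
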