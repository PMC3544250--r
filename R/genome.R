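#' @name plant_genome
#' @title Diploid ancestry-segment genomes
#'
#' @description A simulated plant is represented by its ancestry mosaic: for
#' each chromosome, two haplotypes, each an ordered run of maximal segments
#' of `"recipient"` or `"donor"` origin. Internally a haplotype is a pair of
#' parallel vectors — `end` (segment right endpoints on the 0-based
#' half-open scale, the last equal to the chromosome length) and `origin`
#' (`0` recipient, `1` donor). Segments tile the chromosome exactly and
#' adjacent segments differ in origin.
NULL

.ORIGIN_RECIPIENT <- 0L
.ORIGIN_DONOR <- 1L

.hap <- function(end, origin) list(end = end, origin = origin)

.hap_normalize <- function(h) {
  w <- diff(c(0, h$end)) > 0
  end <- h$end[w]; origin <- h$origin[w]
  n <- length(end)
  if (n > 1L) {
    keep <- c(origin[-1L] != origin[-n], TRUE)
    end <- end[keep]; origin <- origin[keep]
  }
  .hap(end, origin)
}

.hap_valid <- function(h, L) {
  n <- length(h$end)
  n >= 1L && length(h$origin) == n &&
    !is.unsorted(h$end, strictly = TRUE) &&
    h$end[n] == L && all(diff(c(0, h$end)) > 0) &&
    all(h$origin %in% c(.ORIGIN_RECIPIENT, .ORIGIN_DONOR)) &&
    (n == 1L || all(h$origin[-1L] != h$origin[-n]))
}

#' Construct a genetic map
#'
#' A linear physical-to-genetic map: each chromosome's length in Morgans is
#' `length_bp * cm_per_mb / 1e8`. The conversion rate can be global or per
#' chromosome; genetic position is monotone non-decreasing in physical
#' position by construction.
#'
#' @param chromosome_lengths Named numeric vector of chromosome lengths (bp).
#' @param cm_per_mb Centimorgans per megabase, a single value (default 4.0,
#'   a rice-like genome-wide average) or one value per chromosome.
#' @return Object of class `genetic_map` with elements `lengths_bp` and
#'   `cm_per_mb` (both named by chromosome).
#' @export
genetic_map <- function(chromosome_lengths = rice_chromosome_lengths(),
                        cm_per_mb = 4.0) {
  stopifnot(all(chromosome_lengths > 0), all(cm_per_mb >= 0))
  if (length(cm_per_mb) == 1L) {
    cm_per_mb <- stats::setNames(rep(cm_per_mb, length(chromosome_lengths)),
                                 names(chromosome_lengths))
  }
  stopifnot(identical(names(cm_per_mb), names(chromosome_lengths)))
  structure(list(lengths_bp = chromosome_lengths, cm_per_mb = cm_per_mb),
            class = "genetic_map")
}

#' Map length of each chromosome in Morgans
#'
#' @param map A `genetic_map`.
#' @return Named numeric vector of Morgans per chromosome.
#' @export
chromosome_morgans <- function(map) {
  map$lengths_bp * map$cm_per_mb / 1e8
}

#' Founder and F1 genomes
#'
#' `founder_genome()` builds a fully homozygous plant of the given parental
#' origin; `f1_genome()` builds the donor x recipient F1, heterozygous over
#' the whole genome (one recipient and one donor haplotype per chromosome).
#'
#' @param map A `genetic_map`.
#' @param origin `"recipient"` or `"donor"`.
#' @param plant_id Identifier string.
#' @return A `plant_genome`.
#' @export
founder_genome <- function(map, origin = c("recipient", "donor"),
                           plant_id = match.arg(origin)) {
  origin <- match.arg(origin)
  code <- if (origin == "recipient") .ORIGIN_RECIPIENT else .ORIGIN_DONOR
  chrs <- lapply(map$lengths_bp, function(L)
    list(.hap(L, code), .hap(L, code)))
  structure(list(plant_id = plant_id, chromosomes = chrs),
            class = "plant_genome")
}

#' @rdname founder_genome
#' @export
f1_genome <- function(map, plant_id = "F1") {
  chrs <- lapply(map$lengths_bp, function(L)
    list(.hap(L, .ORIGIN_RECIPIENT), .hap(L, .ORIGIN_DONOR)))
  structure(list(plant_id = plant_id, chromosomes = chrs),
            class = "plant_genome")
}

#' Check the segment-tiling invariants of a plant genome
#'
#' @param plant A `plant_genome`.
#' @param map The `genetic_map` it was simulated on.
#' @return `TRUE` if every haplotype of every chromosome tiles
#'   `[0, length)` with maximal alternating-origin segments, else `FALSE`.
#' @export
validate_plant_genome <- function(plant, map) {
  all(vapply(names(map$lengths_bp), function(ch) {
    L <- map$lengths_bp[[ch]]
    pair <- plant$chromosomes[[ch]]
    !is.null(pair) && .hap_valid(pair[[1L]], L) && .hap_valid(pair[[2L]], L)
  }, logical(1L)))
}

#' @export
print.plant_genome <- function(x, ...) {
  n_seg <- sum(vapply(x$chromosomes, function(p)
    length(p[[1L]]$end) + length(p[[2L]]$end), 0L))
  cat(sprintf("plant_genome '%s': %d chromosomes, %d ancestry segments, true RPG %.2f%%\n",
              x$plant_id, length(x$chromosomes), n_seg, true_rpg(x)))
  invisible(x)
}

#' True (bp-weighted) recurrent-parent genome fraction
#'
#' Ground-truth counterpart of the marker-based %R statistic: the
#' percentage of the diploid genome (base-pair weighted, both haplotypes,
#' so heterozygous intervals count half) that is of recipient origin.
#'
#' @param plant A `plant_genome`.
#' @return Percentage in \[0, 100\].
#' @export
true_rpg <- function(plant) {
  tot <- 0; rec <- 0
  for (pair in plant$chromosomes) {
    for (h in pair) {
      w <- diff(c(0, h$end))
      tot <- tot + sum(w)
      rec <- rec + sum(w[h$origin == .ORIGIN_RECIPIENT])
    }
  }
  100 * rec / tot
}
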