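#' Haldane map function
#'
#' Converts a genetic distance in Morgans to a recombination fraction under
#' the no-interference (Haldane) model, `r = 0.5 * (1 - exp(-2 d))`:
#' strictly increasing in `d`, 0 at `d = 0`, approaching 0.5 as `d` grows.
#'
#' @param distance_morgans Non-negative genetic distance(s) in Morgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_recomb_fraction(0.10)
#' @export
haldane_recomb_fraction <- function(distance_morgans) {
  if (any(is.na(distance_morgans)) || any(distance_morgans < 0)) {
    stop("distance_morgans must be non-negative", call. = FALSE)
  }
  0.5 * (1 - exp(-2 * distance_morgans))
}

.sim_gamete_chr <- function(h1, h2, L, morgans) {
  n_xo <- stats::rpois(1L, morgans)
  first <- sample.int(2L, 1L)
  if (n_xo == 0L) {
    h <- if (first == 1L) h1 else h2
    return(.hap(h$end, h$origin))
  }
  xo <- sort(stats::runif(n_xo, 0, L))
  bounds <- c(0, xo, L)
  src <- if (first == 1L) list(h1, h2) else list(h2, h1)
  end <- numeric(0); origin <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    if (a >= b) next
    h <- src[[((i - 1L) %% 2L) + 1L]]
    seg_start <- c(0, h$end[-length(h$end)])
    keep <- which(h$end > a & seg_start < b)
    end <- c(end, pmin(h$end[keep], b))
    origin <- c(origin, h$origin[keep])
  }
  .hap_normalize(.hap(end, origin))
}

#' Simulate one meiotic gamete
#'
#' Per chromosome, the crossover count is Poisson with mean equal to the
#' chromosome's map length in Morgans (no interference, consistent with the
#' Haldane map function), crossover positions are uniform in physical
#' coordinates, and the gamete alternates between the two parental
#' haplotypes at crossovers starting from a fair random haplotype. Output
#' segments are re-normalized to a maximal tiling.
#'
#' @param parent A valid `plant_genome`.
#' @param map A `genetic_map`.
#' @return Named list (by chromosome) of haplotypes.
#' @export
simulate_gamete <- function(parent, map) {
  if (!validate_plant_genome(parent, map)) {
    stop("integrity error: parent genome violates segment-tiling invariants",
         call. = FALSE)
  }
  morgans <- chromosome_morgans(map)
  out <- lapply(names(map$lengths_bp), function(ch) {
    pair <- parent$chromosomes[[ch]]
    .sim_gamete_chr(pair[[1L]], pair[[2L]], map$lengths_bp[[ch]], morgans[[ch]])
  })
  names(out) <- names(map$lengths_bp)
  out
}

#' Cross two plants
#'
#' Each progeny receives one independently simulated gamete from each
#' parent. Progeny identifiers are `"<id_prefix>_<i>"`, deterministic given
#' the RNG seed.
#'
#' @param mother,father Valid `plant_genome` objects.
#' @param n_progeny Number of progeny (>= 1).
#' @param map A `genetic_map`.
#' @param id_prefix Prefix for progeny identifiers.
#' @return List of `plant_genome` objects.
#' @export
cross <- function(mother, father, n_progeny, map, id_prefix = "progeny") {
  if (length(n_progeny) != 1L || is.na(n_progeny) || n_progeny < 1L) {
    stop("n_progeny must be a positive count", call. = FALSE)
  }
  lapply(seq_len(n_progeny), function(i) {
    g1 <- simulate_gamete(mother, map)
    g2 <- simulate_gamete(father, map)
    chrs <- lapply(names(map$lengths_bp), function(ch) list(g1[[ch]], g2[[ch]]))
    names(chrs) <- names(map$lengths_bp)
    structure(list(plant_id = sprintf("%s_%03d", id_prefix, i),
                   chromosomes = chrs),
              class = "plant_genome")
  })
}

#' Simulate an unselected backcross population
#'
#' Produces `n_plants` independent BC\eqn{_n}F\eqn{_1} lineages: each plant
#' descends from the F1 by `generation` successive backcrosses to the
#' recurrent parent, with a single random offspring kept at each step and no
#' selection anywhere. Because the lineages share no pedigree beyond the
#' founders, the population mean of the true recipient-genome fraction has
#' expectation `100 * (1 - 2^-(generation + 1))` (75, 87.5, 93.75 for
#' generations 1-3) and the usual `sd/sqrt(n)` Monte-Carlo standard error,
#' which makes this the neutral-expectation oracle for the selection
#' pipeline.
#'
#' @param n_plants Population size.
#' @param generation Backcross generation number (>= 1).
#' @param map A `genetic_map`.
#' @param id_prefix Prefix for plant identifiers.
#' @return List of `plant_genome` objects.
#' @export
simulate_bc_population <- function(n_plants, generation,
                                   map = genetic_map(),
                                   id_prefix = sprintf("BC%dF1", generation)) {
  stopifnot(n_plants >= 1L, generation >= 1L)
  recipient <- founder_genome(map, "recipient")
  plants <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    g <- f1_genome(map)
    for (k in seq_len(generation)) {
      g <- cross(g, recipient, 1L, map, id_prefix = "lineage")[[1L]]
    }
    g$plant_id <- sprintf("%s_%04d", id_prefix, i)
    plants[[i]] <- g
  }
  plants
}
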