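# shared fixtures, built in code

# two short chromosomes for fast simulator tests
tiny_map <- function(cm_per_mb = 4.0) {
  genetic_map(c(`1` = 20e6, `2` = 15e6), cm_per_mb = cm_per_mb)
}

# a haplotype in the documented internal representation
hap <- function(end, origin) list(end = end, origin = as.integer(origin))

# hand-built diploid genome (single chromosome unless more pairs given)
manual_plant <- function(pairs, plant_id = "manual") {
  structure(list(plant_id = plant_id, chromosomes = pairs),
            class = "plant_genome")
}

# full study panel: Saltol foreground/flank markers plus the fixed
# 89-marker background panel
study_panel <- function() {
  combine_panels(saltol_panel(), synthetic_background_panel())
}

toy_matrix_path <- function() {
  system.file("extdata", "toy_genotypes.csv", package = "mabcr",
              mustWork = TRUE)
}

# replicate vectors with exact mean `m` and exact within-group variance d^2
# (residual pattern -d, 0, +d), for Duncan fixtures
reps3 <- function(m, d) m + c(-d, 0, d)

# %A/%R computed from first principles, independent of package internals
naive_rpg <- function(calls, n_fixed = 0) {
  a <- sum(calls == "A", na.rm = TRUE) + n_fixed
  b <- sum(calls == "B", na.rm = TRUE)
  h <- sum(calls == "H", na.rm = TRUE)
  c(percent_A = 100 * a / (a + b + h),
    percent_R = 100 * (a + 0.5 * h) / (a + b + h))
}
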