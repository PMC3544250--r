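#' Marker roles for three-tier selection
#'
#' Bundles the marker names driving each selection tier. Defaults encode
#' the Saltol introgression scheme: heterozygosity required at the two
#' target-locus markers RM493 and RM3412b every generation; in the first
#' backcross a crossover is demanded distal of the target (recipient
#' homozygosity at RM10825), in later backcrosses proximal (RM10694);
#' background markers cover the rest of the genome.
#'
#' @param foreground Ordered foreground marker names.
#' @param flanks_by_generation Named list, generation number (as `"1"`,
#'   `"2"`, ...) -> named character vector of required flank calls.
#' @param background Background marker names.
#' @return Object of class `selection_roles`.
#' @export
selection_roles <- function(foreground = c("RM493", "RM3412b"),
                            flanks_by_generation = list(
                              `1` = c(RM10825 = "A"),
                              `2` = c(RM10694 = "A"),
                              `3` = c(RM10694 = "A")),
                            background = character(0)) {
  overlap <- intersect(foreground, background)
  if (length(overlap)) {
    stop("configuration error: marker(s) in both foreground and background: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(foreground = foreground,
                 flanks_by_generation = flanks_by_generation,
                 background = background),
            class = "selection_roles")
}

#' Campaign configuration
#'
#' The reproducibility contract for a multi-generation MABC campaign:
#' panel, genetic map, generation count, per-parent population size,
#' number of parents advanced, selection roles, missing-call rate and the
#' single RNG seed from which every stochastic draw flows.
#'
#' @param panel A `marker_panel` containing all role markers.
#' @param map A `genetic_map` (default: shipped chromosome lengths at
#'   4 cM/Mb).
#' @param n_generations Number of backcross generations (default 3).
#' @param pop_size Progeny simulated per advanced parent per generation
#'   (default 300).
#' @param n_parents Plants advanced per generation (default 2;
#'   `pop_size >= n_parents >= 1`).
#' @param seed Integer RNG seed.
#' @param roles A `selection_roles`; default derives foreground markers and
#'   flank schedule from [selection_roles()] defaults and background
#'   markers from the panel rows with role `"background"`.
#' @param missing_rate Per-call missing probability (default 0).
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(panel, map = genetic_map(),
                            n_generations = 3, pop_size = 300,
                            n_parents = 2, seed = 1,
                            roles = NULL, missing_rate = 0) {
  if (is.null(roles)) {
    roles <- selection_roles(background = panel$name[panel$role == "background"])
    if (!all(roles$foreground %in% panel$name)) {
      roles$foreground <- panel$name[panel$role == "foreground"]
    }
  }
  stopifnot(pop_size >= n_parents, n_parents >= 1, n_generations >= 1)
  all_names <- unique(c(roles$foreground, roles$background,
                        unlist(lapply(roles$flanks_by_generation, names))))
  missing <- setdiff(all_names, panel$name)
  if (length(missing)) {
    stop("configuration error: role marker(s) absent from panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (g in seq_len(n_generations)) {
    if (is.null(roles$flanks_by_generation[[as.character(g)]])) {
      stop("configuration error: no flank requirement for generation ", g,
           call. = FALSE)
    }
  }
  structure(list(panel = panel, map = map, n_generations = n_generations,
                 pop_size = pop_size, n_parents = n_parents, seed = seed,
                 roles = roles, missing_rate = missing_rate),
            class = "campaign_config")
}

#' Default Saltol campaign configuration
#'
#' The study-condition defaults: Saltol foreground/flank panel plus the
#' fixed deterministic 89-marker background panel, 3 backcross generations,
#' 300 progeny per parent, 2 parents advanced, 4 cM/Mb Haldane map, no
#' missing data.
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [campaign_config()].
#' @return A `campaign_config`.
#' @export
default_campaign_config <- function(seed = 1, ...) {
  panel <- combine_panels(saltol_panel(), synthetic_background_panel())
  campaign_config(panel, seed = seed, ...)
}

#' Run a marker-assisted backcross campaign
#'
#' Executes the full scheme F1 -> BC1F1 -> ... -> BC\eqn{_n}F\eqn{_1}. Each
#' generation: simulate `pop_size` progeny from each advanced parent
#' crossed to the recurrent parent; score every plant at the foreground,
#' generation-appropriate flank and currently screened background markers;
#' foreground-select (heterozygous at all target markers);
#' recombinant-select (required calls at the generation's flank markers);
#' background-select the top `n_parents` by %R; then retire background
#' markers fixed for the recipient allele in the selected plants from the
#' next generation's screening list (fixed-marker ledger). The final
#' generation's selected plants are summarised over screened plus ledger
#' markers.
#'
#' The campaign is fully reproducible from the config seed. It halts with a
#' diagnostic naming the generation if foreground or recombinant selection
#' leaves no survivors (selection pathologies are surfaced, not resampled
#' away).
#'
#' @param config A `campaign_config`.
#' @return Object of class `selection_trace`: per-generation records
#'   (`genotypes`, `true_rpg`, `foreground_ids`, `recombinant_ids`,
#'   `ranking`, `advanced_ids`, `screened_markers`, `fixed_markers`), the
#'   final-generation `summary` data frame for the selected plants, and the
#'   config.
#' @export
run_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed)
  map <- config$map
  panel <- config$panel
  roles <- config$roles
  recipient <- founder_genome(map, "recipient", "recipient")
  parents <- list(f1_genome(map))
  screened <- roles$background
  fixed <- character(0)
  generations <- vector("list", config$n_generations)

  for (gen in seq_len(config$n_generations)) {
    flank <- roles$flanks_by_generation[[as.character(gen)]]
    progeny <- list()
    for (p in seq_along(parents)) {
      prefix <- sprintf("BC%dF1_P%d", gen, p)
      progeny <- c(progeny,
                   cross(parents[[p]], recipient, config$pop_size, map,
                         id_prefix = prefix))
    }
    marker_names <- unique(c(roles$foreground, names(flank), screened))
    gen_panel <- panel[panel$name %in% marker_names, , drop = FALSE]
    geno <- genotype_plants(progeny, gen_panel,
                            missing_rate = config$missing_rate)
    truth <- stats::setNames(vapply(progeny, true_rpg, numeric(1L)),
                             rownames(geno))
    fg <- foreground_select(geno, roles$foreground)
    if (length(fg) == 0L) {
      stop(sprintf("campaign halted at generation BC%d: no plant passed foreground selection", gen),
           call. = FALSE)
    }
    rec <- recombinant_select(geno[fg, , drop = FALSE], flank)
    if (length(rec) == 0L) {
      stop(sprintf("campaign halted at generation BC%d: no plant passed recombinant selection", gen),
           call. = FALSE)
    }
    ranking <- background_rank(geno[rec, , drop = FALSE], screened,
                               n_fixed = length(fixed))
    advanced <- utils::head(ranking$plant_id, config$n_parents)
    drop <- drop_fixed_markers(geno, advanced, screened)
    generations[[gen]] <- list(
      generation = gen,
      genotypes = geno,
      true_rpg = truth,
      foreground_ids = fg,
      recombinant_ids = rec,
      ranking = ranking,
      advanced_ids = advanced,
      screened_markers = screened,
      fixed_markers = fixed)
    screened <- drop$retained
    fixed <- c(fixed, drop$dropped)
    parents <- progeny[match(advanced, vapply(progeny, `[[`, character(1L),
                                              "plant_id"))]
  }

  last <- generations[[config$n_generations]]
  summary <- last$ranking[last$ranking$plant_id %in% last$advanced_ids, ,
                          drop = FALSE]
  summary$true_rpg <- last$true_rpg[summary$plant_id]
  structure(list(generations = generations, summary = summary,
                 final_screened = screened, final_fixed = fixed,
                 config = config),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("MABC selection trace: %d generation(s), seed %d\n",
              length(x$generations), x$config$seed))
  for (g in x$generations) {
    cat(sprintf("  BC%dF1: %4d plants -> %3d foreground -> %3d recombinant -> advanced %s\n",
                g$generation, nrow(g$genotypes), length(g$foreground_ids),
                length(g$recombinant_ids),
                paste(g$advanced_ids, collapse = ", ")))
  }
  cat(sprintf("  fixed-for-recipient markers accumulated: %d\n",
              length(x$final_fixed)))
  cat("Final selected plants:\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %%A = %.2f, %%R = %.2f (true RPG %.2f)\n",
                s$plant_id[i], s$percent_A[i], s$percent_R[i], s$true_rpg[i]))
  }
  invisible(x)
}

#' Serialize a selection trace to delimited files
#'
#' Writes, per generation, the genotype matrix, the simulated-truth
#' sidecar, the background ranking and a survivors table, plus a campaign
#' summary table and a plain-text report. Output is deterministic given the
#' campaign seed.
#'
#' @param trace A `selection_trace`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_selection_trace <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in trace$generations) {
    tag <- sprintf("bc%d", g$generation)
    f_geno <- file.path(dir, paste0(tag, "_genotypes.csv"))
    write_genotype_matrix(g$genotypes, f_geno)
    f_truth <- file.path(dir, paste0(tag, "_true_rpg.csv"))
    utils::write.table(data.frame(plant_id = names(g$true_rpg),
                                  true_rpg_percent = unname(g$true_rpg)),
                       f_truth, sep = ",", quote = FALSE, row.names = FALSE)
    f_rank <- file.path(dir, paste0(tag, "_ranking.csv"))
    utils::write.table(g$ranking, f_rank, sep = ",", quote = FALSE,
                       row.names = FALSE)
    f_sel <- file.path(dir, paste0(tag, "_selection.csv"))
    stage <- data.frame(
      plant_id = rownames(g$genotypes),
      foreground = rownames(g$genotypes) %in% g$foreground_ids,
      recombinant = rownames(g$genotypes) %in% g$recombinant_ids,
      advanced = rownames(g$genotypes) %in% g$advanced_ids)
    utils::write.table(stage, f_sel, sep = ",", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f_geno, f_truth, f_rank, f_sel)
  }
  f_sum <- file.path(dir, "final_summary.csv")
  utils::write.table(trace$summary, f_sum, sep = ",", quote = FALSE,
                     row.names = FALSE)
  f_led <- file.path(dir, "fixed_marker_ledger.txt")
  writeLines(trace$final_fixed, f_led)
  f_rep <- file.path(dir, "report.txt")
  con <- file(f_rep, "w")
  sink(con); print(trace); sink()
  close(con)
  invisible(c(files, f_sum, f_led, f_rep))
}
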