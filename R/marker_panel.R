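#' @name marker_panel
#' @title SSR marker panels
#'
#' @description A marker panel is a data frame of SSR (microsatellite) loci
#' with one row per marker and a `chromosome_lengths` attribute. Required
#' columns are `name`, `chromosome` and `position_bp`; optional columns
#' (`position_mb`, `forward_primer`, `reverse_primer`, `motif`, `n_repeats`,
#' `ssr_start`, `ssr_end`) may be `NA`. Each marker carries a selection
#' `role` (`"foreground"`, `"flank"` or `"background"`) and a `polymorphic`
#' flag recording whether the locus distinguishes the two parents.
#'
#' Marker positions and SSR spans are 1-based inclusive coordinates, as
#' marker tables print them. (Simulated ancestry segments are 0-based
#' half-open; the conversion happens once, inside [genotype_plants()].)
NULL

.panel_columns <- c("name", "chromosome", "position_bp", "position_mb",
                    "forward_primer", "reverse_primer", "motif", "n_repeats",
                    "ssr_start", "ssr_end", "role", "polymorphic")
.panel_roles <- c("foreground", "flank", "background")

#' Construct and validate a marker panel
#'
#' @param markers Data frame with at least columns `name`, `chromosome`,
#'   `position_bp`. Missing optional columns are added as `NA`; a missing
#'   `role` defaults to `"background"` and a missing `polymorphic` flag to
#'   `TRUE`.
#' @param chromosome_lengths Named numeric vector of chromosome lengths in
#'   bp (default [rice_chromosome_lengths()]).
#' @return A `marker_panel` data frame, sorted by `(chromosome, position_bp)`,
#'   with attribute `chromosome_lengths`.
#' @details Validation enforces: unique marker names; known chromosomes;
#'   positions inside the chromosome; `ssr_start <= ssr_end` where both are
#'   present; and foreground role restricted to the Saltol carrier
#'   chromosome 1.
#' @export
marker_panel <- function(markers, chromosome_lengths = rice_chromosome_lengths()) {
  required <- c("name", "chromosome", "position_bp")
  for (col in required) {
    if (!col %in% names(markers)) {
      stop("marker panel format error: missing required column '", col, "'",
           call. = FALSE)
    }
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!"role" %in% names(markers)) {
    markers$role <- rep("background", nrow(markers))
  }
  if (!"polymorphic" %in% names(markers)) {
    markers$polymorphic <- rep(TRUE, nrow(markers))
  }
  for (col in setdiff(.panel_columns, names(markers))) {
    markers[[col]] <- rep(NA, nrow(markers))
  }
  markers <- markers[, .panel_columns]

  markers$name <- as.character(markers$name)
  markers$chromosome <- as.integer(markers$chromosome)
  for (col in c("position_bp", "position_mb", "ssr_start", "ssr_end")) {
    markers[[col]] <- as.numeric(markers[[col]])
  }
  markers$n_repeats <- as.integer(markers$n_repeats)
  markers$role[is.na(markers$role)] <- "background"
  markers$polymorphic[is.na(markers$polymorphic)] <- TRUE
  markers$polymorphic <- as.logical(markers$polymorphic)

  if (nrow(markers) == 0L) {
    warning("marker panel is empty")
  } else {
    dup <- markers$name[duplicated(markers$name)]
    if (length(dup)) {
      stop("marker panel validation error: duplicate marker name(s): ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    if (anyNA(markers$chromosome) || anyNA(markers$position_bp)) {
      stop("marker panel validation error: chromosome/position_bp must be present for every marker",
           call. = FALSE)
    }
    unknown <- setdiff(as.character(markers$chromosome), names(chromosome_lengths))
    if (length(unknown)) {
      stop("marker panel validation error: chromosome(s) without a configured length: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    len <- chromosome_lengths[as.character(markers$chromosome)]
    bad <- which(markers$position_bp < 1 | markers$position_bp > len)
    if (length(bad)) {
      stop("marker panel validation error: position outside chromosome for marker(s): ",
           paste(markers$name[bad], collapse = ", "), call. = FALSE)
    }
    bad_role <- setdiff(unique(markers$role), .panel_roles)
    if (length(bad_role)) {
      stop("marker panel validation error: unknown role(s): ",
           paste(bad_role, collapse = ", "), call. = FALSE)
    }
    fg_off <- which(markers$role == "foreground" & markers$chromosome != 1L)
    if (length(fg_off)) {
      stop("marker panel validation error: foreground role off chromosome 1 for marker(s): ",
           paste(markers$name[fg_off], collapse = ", "), call. = FALSE)
    }
    both <- !is.na(markers$ssr_start) & !is.na(markers$ssr_end)
    bad_span <- which(both & markers$ssr_start > markers$ssr_end)
    if (length(bad_span)) {
      stop("marker panel validation error: ssr_start > ssr_end for marker(s): ",
           paste(markers$name[bad_span], collapse = ", "), call. = FALSE)
    }
    markers <- markers[order(markers$chromosome, markers$position_bp), ]
  }
  rownames(markers) <- NULL
  structure(markers,
            chromosome_lengths = chromosome_lengths,
            class = c("marker_panel", "data.frame"))
}

#' Read a marker panel from a delimited file
#'
#' Reads a comma- or tab-separated table with header
#' `name,chromosome,position_bp,position_mb,forward_primer,reverse_primer,motif,n_repeats,ssr_start,ssr_end,role`
#' (blank cells become absent values, never zero) and validates it with
#' [marker_panel()].
#'
#' @param path Path to the panel file. The delimiter is detected from the
#'   header line (tab if present, otherwise comma).
#' @param chromosome_lengths Named numeric vector of chromosome lengths (bp).
#' @return A validated `marker_panel`.
#' @seealso [write_marker_panel()], [saltol_panel()]
#' @export
load_marker_panel <- function(path, chromosome_lengths = rice_chromosome_lengths()) {
  if (!file.exists(path)) stop("marker panel file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"), quote = "\"",
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  marker_panel(tab, chromosome_lengths = chromosome_lengths)
}

#' Write a marker panel to a delimited file
#'
#' Inverse of [load_marker_panel()]: `load -> write -> load` round-trips to
#' an identical panel. Absent values are written as blank cells.
#'
#' @param panel A `marker_panel`.
#' @param path Output path (comma-separated).
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  utils::write.table(out, path, sep = ",", na = "", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged Saltol-region marker panel
#'
#' Loads the panel of foreground and recombinant-selection SSR markers on
#' chromosome 1 around the Saltol QTL shipped with the package
#' (`extdata/saltol_markers.csv`): RM493 and RM3412b (foreground) plus the
#' flanking/recombinant markers RM10694, AP3206f, RM10748, RM140, RM10825
#' and RM562. Where an SSR start coordinate is printed it doubles as the
#' marker position; RM3412b and AP3206f carry only a Mb-scale position.
#'
#' @param chromosome_lengths Chromosome length map (bp).
#' @return A `marker_panel` of 8 chromosome-1 markers.
#' @export
saltol_panel <- function(chromosome_lengths = rice_chromosome_lengths()) {
  load_marker_panel(system.file("extdata", "saltol_markers.csv",
                                package = "mabcr", mustWork = TRUE),
                    chromosome_lengths = chromosome_lengths)
}

#' Deterministic genome-wide background marker panel
#'
#' Generates a synthetic panel of polymorphic background SSR markers spread
#' over all chromosomes: markers are allocated per chromosome by largest
#' remainder proportionally to physical length, subject to a minimum per
#' chromosome, and placed at evenly spaced positions. On the Saltol carrier
#' chromosome an exclusion window around the QTL keeps background markers
#' unlinked to the target region. The construction is deterministic, so a
#' fixed `n_markers` yields a fixed panel composition across runs.
#'
#' @param n_markers Total number of background markers (default 89, the
#'   number of genome-wide polymorphic markers in the motivating screen of
#'   477).
#' @param chromosome_lengths Chromosome length map (bp).
#' @param min_per_chromosome Minimum markers per chromosome (default 4).
#' @param exclude Named list mapping chromosome id to a `c(start, end)` bp
#'   window to avoid; default excludes 9-16 Mb on chromosome 1.
#' @return A `marker_panel` with role `"background"`, all polymorphic.
#' @export
synthetic_background_panel <- function(n_markers = 89,
                                       chromosome_lengths = rice_chromosome_lengths(),
                                       min_per_chromosome = 4,
                                       exclude = list(`1` = c(9e6, 16e6))) {
  stopifnot(n_markers >= min_per_chromosome * length(chromosome_lengths))
  chroms <- names(chromosome_lengths)
  share <- n_markers * chromosome_lengths / sum(chromosome_lengths)
  k <- pmax(floor(share), min_per_chromosome)
  rem <- share - floor(share)
  # largest-remainder top-up; deficits (from the minimum) are absorbed first
  while (sum(k) < n_markers) {
    i <- which.max(ifelse(k == pmax(floor(share), min_per_chromosome), rem, -Inf))
    rem[i] <- -Inf
    k[i] <- k[i] + 1L
  }
  while (sum(k) > n_markers) {
    i <- which.max(ifelse(k > min_per_chromosome, k - share, -Inf))
    k[i] <- k[i] - 1L
  }
  rows <- lapply(chroms, function(ch) {
    L <- chromosome_lengths[[ch]]
    ki <- k[[ch]]
    win <- exclude[[ch]]
    if (is.null(win)) {
      pos <- round(seq_len(ki) / (ki + 1) * L)
    } else {
      # place uniformly over the allowed length, then shift past the window
      allowed <- L - (win[2] - win[1])
      x <- seq_len(ki) / (ki + 1) * allowed
      pos <- round(ifelse(x < win[1], x, x + (win[2] - win[1])))
    }
    data.frame(name = sprintf("BG%02d.%d", as.integer(ch), seq_len(ki)),
               chromosome = as.integer(ch), position_bp = pos,
               position_mb = round(pos / 1e6, 1), role = "background",
               polymorphic = TRUE, stringsAsFactors = FALSE)
  })
  marker_panel(do.call(rbind, rows), chromosome_lengths = chromosome_lengths)
}

#' Combine marker panels
#'
#' Binds two panels sharing a chromosome-length map into one validated
#' panel (e.g. the Saltol foreground/flank panel plus a genome-wide
#' background panel).
#'
#' @param ... `marker_panel` objects.
#' @return A `marker_panel`.
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  stopifnot(length(panels) >= 1L)
  lens <- attr(panels[[1L]], "chromosome_lengths")
  marker_panel(do.call(rbind, lapply(panels, as.data.frame)),
               chromosome_lengths = lens)
}

#' Audit printed SSR spans against motif and repeat count
#'
#' For markers whose motif, repeat count and SSR start/end coordinates are
#' all present, the repeat count implied by the printed span is
#' `(ssr_end - ssr_start + 1) / nchar(motif)` (coordinates are 1-based
#' inclusive). A marker is `consistent` when the implied count equals the
#' printed one; inconsistencies are reported, never corrected. Markers with
#' any field absent get `applicable = FALSE` rather than an error.
#'
#' @param panel A `marker_panel` (or any data frame with the SSR columns).
#' @return Data frame with one row per marker: `name`, `implied_repeats`,
#'   `n_repeats`, `consistent`, `applicable`.
#' @examples
#' check_ssr_span(saltol_panel())
#' @export
check_ssr_span <- function(panel) {
  applicable <- !is.na(panel$motif) & !is.na(panel$n_repeats) &
    !is.na(panel$ssr_start) & !is.na(panel$ssr_end)
  implied <- ifelse(applicable,
                    (panel$ssr_end - panel$ssr_start + 1) / nchar(panel$motif),
                    NA_real_)
  data.frame(name = panel$name,
             implied_repeats = implied,
             n_repeats = panel$n_repeats,
             consistent = ifelse(applicable, implied == panel$n_repeats, NA),
             applicable = applicable,
             stringsAsFactors = FALSE)
}

#' Polymorphism rate of a marker screen
#'
#' Percentage of screened markers that were polymorphic between the two
#' parents, rounded half-up to one decimal for parity with printed survey
#' percentages (e.g. 89 polymorphic of 477 screened is 18.7).
#'
#' @param n_polymorphic Number of polymorphic markers.
#' @param n_screened Number of markers screened (> 0).
#' @return Percentage in \[0, 100\], one decimal.
#' @examples
#' polymorphism_rate(89, 477)
#' @export
polymorphism_rate <- function(n_polymorphic, n_screened) {
  if (length(n_screened) != 1L || is.na(n_screened) || n_screened <= 0) {
    stop("n_screened must be a single positive count", call. = FALSE)
  }
  if (length(n_polymorphic) != 1L || is.na(n_polymorphic) ||
      n_polymorphic < 0 || n_polymorphic > n_screened) {
    stop("n_polymorphic must lie in [0, n_screened]", call. = FALSE)
  }
  floor(1000 * n_polymorphic / n_screened + 0.5) / 10
}

#' Validate a marker panel against background-coverage guidelines
#'
#' Produces a plain-text-printable report: per-chromosome counts of
#' polymorphic markers checked against the "at least four polymorphic
#' microsatellite markers per chromosome" background-selection guideline
#' (a warning-level finding, not a failure), plus the SSR span audit of
#' [check_ssr_span()].
#'
#' @param panel A `marker_panel`.
#' @param min_per_chromosome Guideline minimum (default 4).
#' @return Object of class `panel_validation` with elements `per_chromosome`
#'   (data frame `chromosome`, `n_markers`, `n_polymorphic`, `meets_guideline`),
#'   `ssr_audit`, and `ok` (no hard failures; guideline misses and span
#'   inconsistencies are reported as warnings in the printout).
#' @export
validate_marker_panel <- function(panel, min_per_chromosome = 4) {
  lens <- attr(panel, "chromosome_lengths")
  chroms <- as.integer(names(lens))
  per <- data.frame(
    chromosome = chroms,
    n_markers = vapply(chroms, function(ch) sum(panel$chromosome == ch), 0L),
    n_polymorphic = vapply(chroms, function(ch)
      sum(panel$chromosome == ch & panel$polymorphic), 0L))
  per$meets_guideline <- per$n_polymorphic >= min_per_chromosome
  audit <- check_ssr_span(panel)
  structure(list(per_chromosome = per, ssr_audit = audit,
                 min_per_chromosome = min_per_chromosome, ok = TRUE),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat("Marker panel validation\n")
  cat(sprintf("  guideline: >= %d polymorphic markers per chromosome\n",
              x$min_per_chromosome))
  for (i in seq_len(nrow(x$per_chromosome))) {
    r <- x$per_chromosome[i, ]
    cat(sprintf("  chr %2d: %2d markers, %2d polymorphic%s\n",
                r$chromosome, r$n_markers, r$n_polymorphic,
                if (r$meets_guideline) "" else "  [below guideline]"))
  }
  bad <- x$ssr_audit[x$ssr_audit$applicable & !x$ssr_audit$consistent, ]
  if (nrow(bad)) {
    cat("  SSR span inconsistencies (implied vs printed repeats):\n")
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("    %s: span implies %.6g repeats, printed %d\n",
                  bad$name[i], bad$implied_repeats[i], bad$n_repeats[i]))
    }
  } else {
    cat("  SSR spans: all printed repeat counts consistent\n")
  }
  invisible(x)
}
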