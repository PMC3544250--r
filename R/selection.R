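#' Foreground selection
#'
#' Retains exactly the plants that are heterozygous (`"H"`) at every
#' foreground (target-locus) marker; a missing call at a foreground marker
#' disqualifies. In a backcross programme this keeps the carriers of the
#' donor QTL allele.
#'
#' @param matrix Genotype call matrix (plants x markers).
#' @param foreground_markers Marker names; all must be columns of `matrix`.
#' @return Character vector of retained plant ids (row order preserved).
#' @export
foreground_select <- function(matrix, foreground_markers) {
  missing <- setdiff(foreground_markers, colnames(matrix))
  if (length(missing)) {
    stop("configuration error: foreground marker(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- matrix[, foreground_markers, drop = FALSE]
  ok <- rowSums(!is.na(sub) & sub == "H") == length(foreground_markers)
  rownames(matrix)[ok]
}

#' Recombinant selection
#'
#' Pure filtering on flanking markers: retains the plants whose call at each
#' required flank marker equals the required call (normally `"A"`,
#' recipient-homozygous, i.e. a crossover occurred between the target locus
#' and that flank). Missing disqualifies. Callers apply this to an already
#' foreground-selected matrix.
#'
#' @param matrix Genotype call matrix.
#' @param flank_requirements Named character vector, marker name -> required
#'   call.
#' @return Character vector of retained plant ids.
#' @export
recombinant_select <- function(matrix, flank_requirements) {
  missing <- setdiff(names(flank_requirements), colnames(matrix))
  if (length(missing)) {
    stop("configuration error: flank marker(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- matrix[, names(flank_requirements), drop = FALSE]
  ok <- rep(TRUE, nrow(sub))
  for (mk in names(flank_requirements)) {
    ok <- ok & !is.na(sub[, mk]) & sub[, mk] == flank_requirements[[mk]]
  }
  rownames(matrix)[ok]
}

.rpg_counts <- function(matrix, markers, n_fixed = 0L) {
  sub <- matrix[, intersect(markers, colnames(matrix)), drop = FALSE]
  ids <- rownames(sub)
  if (is.null(ids)) ids <- character(nrow(sub))
  n_A <- rowSums(sub == "A", na.rm = TRUE) + n_fixed
  n_B <- rowSums(sub == "B", na.rm = TRUE)
  n_H <- rowSums(sub == "H", na.rm = TRUE)
  n_missing <- rowSums(is.na(sub))
  denom <- n_A + n_B + n_H
  data.frame(plant_id = ids, n_A = n_A, n_H = n_H, n_B = n_B,
             n_missing = n_missing,
             percent_A = 100 * n_A / denom,
             percent_R = 100 * (n_A + 0.5 * n_H) / denom,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Background selection
#'
#' Ranks candidate plants by recurrent-parent genome recovery over the
#' background markers — descending %R (recipient alleles, heterozygotes at
#' half weight), ties broken by descending %A (recipient-homozygous
#' markers), then ascending plant id — and returns the top `k`. Missing
#' calls are excluded from a plant's denominators; markers already recorded
#' as fixed for the recipient allele in earlier generations enter every
#' plant's counts as `n_fixed` additional `"A"` calls, which keeps
#' percentages comparable across generations after fixed markers stop being
#' screened.
#'
#' @param matrix Genotype call matrix of the candidate plants.
#' @param background_markers Background marker names (those present in
#'   `matrix` are used).
#' @param k Number of plants to retain (>= 1).
#' @param n_fixed Count of markers fixed for the recipient allele carried
#'   over from earlier generations (default 0).
#' @return Data frame of the top `k` candidates, ranked, with columns
#'   `plant_id`, `n_A`, `n_H`, `n_B`, `n_missing`, `percent_A`, `percent_R`.
#'   An empty candidate set yields an empty data frame with a warning.
#' @export
background_select <- function(matrix, background_markers, k, n_fixed = 0L) {
  stopifnot(k >= 1L)
  ranked <- background_rank(matrix, background_markers, n_fixed = n_fixed)
  if (nrow(ranked) == 0L) {
    warning("background selection: empty candidate set")
    return(ranked)
  }
  if (k > nrow(ranked)) {
    warning(sprintf("background selection: k = %d exceeds %d candidates; returning all",
                    k, nrow(ranked)))
    k <- nrow(ranked)
  }
  utils::head(ranked, k)
}

#' @rdname background_select
#' @return `background_rank()` returns the full ranking (all candidates).
#' @export
background_rank <- function(matrix, background_markers, n_fixed = 0L) {
  counts <- .rpg_counts(matrix, background_markers, n_fixed = n_fixed)
  counts[order(-counts$percent_R, -counts$percent_A, counts$plant_id), ,
         drop = FALSE]
}

#' Drop markers fixed for the recipient allele
#'
#' Background markers whose call is `"A"` in every selected plant are fixed
#' for the recurrent parent and are not screened in the next backcross
#' generation; they move to the fixed-marker ledger and count as `"A"` in
#' all later %A/%R computations. A missing call is uninformative, not
#' evidence of fixation, so it blocks dropping.
#'
#' @param matrix Genotype call matrix.
#' @param selected_ids Non-empty set of selected plant ids (rows of
#'   `matrix`).
#' @param background_markers Currently screened background marker names.
#' @return List with `retained` and `dropped` marker-name vectors
#'   (`retained` plus `dropped` equals `background_markers`).
#' @export
drop_fixed_markers <- function(matrix, selected_ids, background_markers) {
  stopifnot(length(selected_ids) >= 1L)
  sub <- matrix[selected_ids, intersect(background_markers, colnames(matrix)),
                drop = FALSE]
  fixed_a <- colSums(!is.na(sub) & sub == "A") == length(selected_ids)
  dropped <- colnames(sub)[fixed_a]
  list(retained = setdiff(background_markers, dropped), dropped = dropped)
}
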