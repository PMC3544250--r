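#' Score plants at a marker panel
#'
#' Produces the plants x markers matrix of categorical calls: `"A"` when
#' both haplotypes are of recipient origin at the marker position, `"B"`
#' when both are donor, `"H"` when heterozygous; each call is then
#' independently replaced by missing (`NA`) with probability
#' `missing_rate`. Marker coordinates are 1-based; the single conversion to
#' the simulator's 0-based half-open segments happens here.
#'
#' The missing-data mask is drawn cell-wise over the whole matrix after all
#' calls are made (one `rbinom` draw per cell in column-major order), so
#' the draw order is part of the determinism contract.
#'
#' @param plants List of `plant_genome` objects.
#' @param panel A `marker_panel`; every marker must fall within its
#'   chromosome's length in the plants' genome.
#' @param missing_rate Per-call missing probability in \[0, 1\] (default 0).
#' @return Character matrix with plant ids as row names, marker names as
#'   column names, cells in `{"A","B","H",NA}`.
#' @export
genotype_plants <- function(plants, panel, missing_rate = 0) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  ids <- vapply(plants, function(p) p$plant_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate plant ids", call. = FALSE)
  n <- length(plants); m <- nrow(panel)
  calls <- matrix(NA_character_, n, m, dimnames = list(ids, panel$name))
  by_chr <- split(seq_len(m), panel$chromosome)
  for (ch in names(by_chr)) {
    idx <- by_chr[[ch]]
    pos0 <- panel$position_bp[idx] - 1  # 1-based inclusive -> 0-based
    for (i in seq_len(n)) {
      pair <- plants[[i]]$chromosomes[[ch]]
      if (is.null(pair)) {
        stop("validation error: plants lack chromosome ", ch, call. = FALSE)
      }
      L <- pair[[1L]]$end[length(pair[[1L]]$end)]
      if (any(pos0 >= L)) {
        bad <- panel$name[idx][pos0 >= L]
        stop("validation error: marker(s) beyond chromosome length: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      o1 <- pair[[1L]]$origin[findInterval(pos0, pair[[1L]]$end) + 1L]
      o2 <- pair[[2L]]$origin[findInterval(pos0, pair[[2L]]$end) + 1L]
      calls[i, idx] <- c("A", "H", "B")[o1 + o2 + 1L]
    }
  }
  if (missing_rate > 0) {
    mask <- stats::rbinom(n * m, 1L, missing_rate) == 1L
    calls[matrix(mask, n, m)] <- NA_character_
  }
  calls
}

#' Read and write genotype matrices
#'
#' Delimited-text interchange format for plants x markers call matrices:
#' first column `plant_id`, remaining columns named by marker, cells in
#' `{A,B,H,-}` with `-` for missing.
#'
#' @param matrix Character matrix as returned by [genotype_plants()].
#' @param path File path (comma-separated).
#' @return `write_genotype_matrix()` returns `path` invisibly;
#'   `read_genotype_matrix()` returns the character matrix.
#' @export
write_genotype_matrix <- function(matrix, path) {
  out <- data.frame(plant_id = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", na = "-", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           na.strings = c("-", ""), colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"plant_id" %in% names(tab)) {
    stop("genotype matrix format error: missing column 'plant_id'",
         call. = FALSE)
  }
  m <- as.matrix(tab[, setdiff(names(tab), "plant_id"), drop = FALSE])
  rownames(m) <- tab$plant_id
  bad <- !is.na(m) & !m %in% c("A", "B", "H")
  if (any(bad)) {
    stop("genotype matrix format error: calls must be A, B, H or '-'",
         call. = FALSE)
  }
  m
}

#' Write the simulated-truth sidecar
#'
#' For simulated populations, records each plant's ground-truth recipient
#' genome percentage (`plant_id,true_rpg_percent`) so marker-based
#' estimates can be checked against the simulator.
#'
#' @param plants List of `plant_genome` objects.
#' @param path Output path (comma-separated).
#' @return `path`, invisibly.
#' @export
write_true_rpg <- function(plants, path) {
  out <- data.frame(
    plant_id = vapply(plants, function(p) p$plant_id, character(1L)),
    true_rpg_percent = vapply(plants, true_rpg, numeric(1L)))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
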