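#' Recurrent-parent genome statistics for one plant
#'
#' From a vector of A/H/B calls (plus optionally a count of markers already
#' fixed for the recipient allele, which enter as extra `"A"` calls),
#' computes the two recovery statistics: `percent_A`, the percentage of
#' markers homozygous for the recipient parent,
#' `100 * n_A / (n_A + n_B + n_H)`; and `percent_R`, the percent recipient
#' alleles counting heterozygotes at half weight,
#' `100 * (n_A + 0.5 n_H) / (n_A + n_B + n_H)`. Missing calls are excluded
#' from the denominators.
#'
#' @param calls Character vector of calls in `{"A","B","H",NA}`.
#' @param n_fixed Count of fixed-for-recipient ledger markers (default 0).
#' @param plant_id Optional identifier carried into the result.
#' @return One-row data frame: `plant_id`, `n_A`, `n_H`, `n_B`,
#'   `n_missing`, `percent_A`, `percent_R`.
#' @examples
#' compute_rpg(c(rep("A", 88), "H"))
#' @export
compute_rpg <- function(calls, n_fixed = 0L, plant_id = NA_character_) {
  stopifnot(n_fixed >= 0L)
  bad <- !is.na(calls) & !calls %in% c("A", "B", "H")
  if (any(bad)) stop("calls must be A, B, H or NA", call. = FALSE)
  n_A <- sum(calls == "A", na.rm = TRUE) + n_fixed
  n_B <- sum(calls == "B", na.rm = TRUE)
  n_H <- sum(calls == "H", na.rm = TRUE)
  n_missing <- sum(is.na(calls))
  denom <- n_A + n_B + n_H
  if (denom == 0) {
    stop("undefined result: all calls missing and fixed ledger empty",
         call. = FALSE)
  }
  data.frame(plant_id = plant_id, n_A = n_A, n_H = n_H, n_B = n_B,
             n_missing = n_missing,
             percent_A = 100 * n_A / denom,
             percent_R = 100 * (n_A + 0.5 * n_H) / denom,
             stringsAsFactors = FALSE)
}

#' Per-plant RPG summaries for a genotype matrix
#'
#' @param matrix Genotype call matrix.
#' @param markers Marker names to include (default: all columns).
#' @param n_fixed Fixed-for-recipient ledger count (default 0).
#' @return Data frame, one row per plant, in matrix row order.
#' @export
rpg_summaries <- function(matrix, markers = colnames(matrix), n_fixed = 0L) {
  .rpg_counts(matrix, markers, n_fixed = n_fixed)
}

#' Histogram of recurrent-parent genome recovery
#'
#' Bins per-plant %R values for a frequency-distribution plot of genome
#' recovery in a backcross population. Bins are right-open except the last,
#' which is closed at 100 so complete recovery is counted; counts conserve
#' the number of plants.
#'
#' @param percent_R Numeric vector of per-plant %R values in \[0, 100\], or
#'   a data frame with a `percent_R` column.
#' @param bin_width Bin width in percentage points (default 2.5).
#' @return Object of class `rpg_histogram`: `breaks`, `counts`, `n_plants`.
#' @export
rpg_histogram <- function(percent_R, bin_width = 2.5) {
  if (is.data.frame(percent_R)) percent_R <- percent_R$percent_R
  if (length(percent_R) == 0L) {
    stop("rpg_histogram: empty input", call. = FALSE)
  }
  stopifnot(bin_width > 0, all(percent_R >= 0), all(percent_R <= 100))
  lo <- min(floor(min(percent_R) / bin_width) * bin_width, 100 - bin_width)
  breaks <- seq(lo, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  idx <- findInterval(percent_R, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts,
                 n_plants = length(percent_R)),
            class = "rpg_histogram")
}

#' @export
print.rpg_histogram <- function(x, ...) {
  cat(sprintf("RPG histogram: %d plants, %d bins\n", x$n_plants,
              length(x$counts)))
  for (i in seq_along(x$counts)) {
    cat(sprintf("  [%6.2f, %6.2f%s %4d %s\n", x$breaks[i], x$breaks[i + 1L],
                if (i == length(x$counts)) "]" else ")",
                x$counts[i],
                paste(rep("*", min(x$counts[i], 60L)), collapse = "")))
  }
  invisible(x)
}

#' @param x An `rpg_histogram`.
#' @param ... Passed to [graphics::barplot()].
#' @rdname rpg_histogram
#' @export
plot.rpg_histogram <- function(x, ...) {
  mid <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$counts, names.arg = sprintf("%.1f", mid),
                    space = 0, las = 2,
                    xlab = "% recurrent parent genome (%R)",
                    ylab = "Number of plants", ...)
  invisible(x)
}

# interval glyphs: . recipient, # donor, + heterozygous
.GG_GLYPHS <- c(A = ".", B = "#", H = "+")

.classify_interval <- function(left, right) {
  calls <- c(left, right)
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) return(".")
  if (any(calls == "B")) return("#")
  if (any(calls == "H")) return("+")
  "."
}

#' Graphical genotype of one plant
#'
#' Renders a plant's marker calls as per-chromosome ancestry bars in the
#' style of graphical-genotyping software: marker ticks at physical
#' positions, inter-marker intervals classified by their flanking calls
#' (both flanks recipient-homozygous -> recipient; any donor-homozygous
#' flank -> donor; otherwise heterozygous introgression). Chromosome ends
#' take the nearest marker's class; missing calls are imputed from the
#' nearest non-missing call on the chromosome (leftward ties) before
#' classification.
#'
#' The text rendering uses one glyph per interval separated by `|` marker
#' ticks (`.` recipient, `#` donor, `+` heterozygous), one line per
#' chromosome, and is exactly invertible by [parse_graphical_genotype()].
#'
#' @param matrix Genotype call matrix.
#' @param panel The `marker_panel` the matrix was scored on.
#' @param plant_id Row of `matrix` to render.
#' @return Object of class `graphical_genotype`: per-chromosome marker
#'   tables and interval glyph vectors.
#' @export
graphical_genotype <- function(matrix, panel, plant_id) {
  if (!plant_id %in% rownames(matrix)) {
    stop("lookup error: plant '", plant_id, "' not in matrix", call. = FALSE)
  }
  lens <- attr(panel, "chromosome_lengths")
  panel <- panel[panel$name %in% colnames(matrix), , drop = FALSE]
  chroms <- sort(unique(panel$chromosome))
  per_chr <- lapply(chroms, function(ch) {
    sub <- panel[panel$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$position_bp), , drop = FALSE]
    calls <- matrix[plant_id, sub$name]
    # impute missing from nearest non-missing neighbour (left on ties)
    if (anyNA(calls) && !all(is.na(calls))) {
      obs <- which(!is.na(calls))
      for (i in which(is.na(calls))) {
        calls[i] <- calls[obs[which.min(abs(obs - i))]]
      }
    }
    n <- length(calls)
    glyphs <- character(n + 1L)
    glyphs[1L] <- .classify_interval(calls[1L], calls[1L])
    glyphs[n + 1L] <- .classify_interval(calls[n], calls[n])
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        glyphs[i + 1L] <- .classify_interval(calls[i], calls[i + 1L])
      }
    }
    list(chromosome = ch,
         length_bp = if (!is.null(lens)) lens[[as.character(ch)]] else NA_real_,
         markers = data.frame(name = sub$name, position_bp = sub$position_bp,
                              call = unname(matrix[plant_id, sub$name]),
                              stringsAsFactors = FALSE),
         glyphs = glyphs)
  })
  names(per_chr) <- as.character(chroms)
  structure(list(plant_id = plant_id, chromosomes = per_chr),
            class = "graphical_genotype")
}

#' @export
format.graphical_genotype <- function(x, ...) {
  vapply(x$chromosomes, function(ch)
    sprintf("chr%02d %s", ch$chromosome, paste(ch$glyphs, collapse = "|")),
    character(1L))
}

#' @export
print.graphical_genotype <- function(x, ...) {
  cat(sprintf("Graphical genotype of %s (. recipient, # donor, + heterozygous, | marker)\n",
              x$plant_id))
  writeLines(format(x))
  invisible(x)
}

#' Parse a text graphical genotype
#'
#' Inverse of the text rendering of [graphical_genotype()]: recovers the
#' per-interval glyph classification per chromosome.
#'
#' @param lines Character vector of `"chrNN g|g|...|g"` lines.
#' @return Named list (chromosome) of interval glyph vectors.
#' @export
parse_graphical_genotype <- function(lines) {
  out <- list()
  for (line in lines) {
    m <- regmatches(line, regexec("^chr([0-9]+) (.+)$", line))[[1L]]
    if (length(m) != 3L) stop("unparseable graphical-genotype line: ", line,
                              call. = FALSE)
    out[[as.character(as.integer(m[2L]))]] <- strsplit(m[3L], "|",
                                                       fixed = TRUE)[[1L]]
  }
  out
}

#' @param x A `graphical_genotype`.
#' @param ... Ignored.
#' @rdname graphical_genotype
#' @export
plot.graphical_genotype <- function(x, ...) {
  n <- length(x$chromosomes)
  max_len <- max(vapply(x$chromosomes, function(ch)
    if (is.na(ch$length_bp)) max(ch$markers$position_bp) else ch$length_bp,
    numeric(1L)))
  fill <- c(`.` = "white", `#` = "black", `+` = "grey60")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, max_len), ylim = c(0, n + 1))
  for (i in seq_len(n)) {
    ch <- x$chromosomes[[i]]
    L <- if (is.na(ch$length_bp)) max(ch$markers$position_bp) else ch$length_bp
    y <- n - i + 1
    edges <- c(0, ch$markers$position_bp, L)
    for (j in seq_along(ch$glyphs)) {
      graphics::rect(edges[j], y - 0.3, edges[j + 1L], y + 0.3,
                     col = fill[[ch$glyphs[j]]], border = "black")
    }
    graphics::segments(ch$markers$position_bp, y - 0.3,
                       ch$markers$position_bp, y + 0.3)
    graphics::text(-max_len * 0.01, y, paste0("chr", ch$chromosome),
                   adj = 1, xpd = NA, cex = 0.8)
  }
  graphics::title(main = sprintf("Graphical genotype: %s", x$plant_id),
                  sub = "white recipient, black donor, grey heterozygous")
  invisible(x)
}

#' Duncan's multiple-range test
#'
#' One-way ANOVA followed by Duncan's new multiple-range test: group means
#' are ordered and compared stepwise against least significant ranges
#' `LSR_p = q(p, df) * sqrt(MSE / n)`, where `q(p, df)` is the studentized
#' range quantile at Duncan's protection level `(1 - alpha)^(p - 1)` for a
#' stretch of `p` ordered means and `n` is the (harmonic mean) group size.
#' Ranges not exceeding their LSR — or contained in such a range — are
#' homogeneous; maximal homogeneous stretches become letter groups. Groups
#' sharing a letter are not significantly different at `alpha`. Letters are
#' assigned in order of first appearance in the input group order (the
#' convention used by agronomic tables whose first row is the control).
#' The classical `LSD = t(1 - alpha/2, df) * sqrt(2 MSE / n)` is reported
#' alongside.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   >= 2 replicates), or a data frame with columns `group` and `value`.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Object of class `duncan_mrt`: `table` (data frame `group`, `n`,
#'   `mean`, `letters`, input order), `mse`, `df_error`, `lsd`, `lsr`
#'   (named by stretch size), `alpha`.
#' @examples
#' duncan_mrt(list(ctrl = c(10.1, 10.2, 9.9), trt = c(12.0, 12.1, 11.8)))
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, factor(groups$group, unique(groups$group)))
  }
  stopifnot(alpha > 0, alpha < 1)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 replicates", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  dat <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(names(groups), sizes),
                                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = dat)
  df_error <- fit$df.residual
  mse <- sum(stats::residuals(fit)^2) / df_error
  nh <- length(sizes) / sum(1 / sizes)  # harmonic mean group size
  se <- sqrt(mse / nh)
  k <- length(groups)
  lsr <- vapply(2:k, function(p)
    stats::qtukey((1 - alpha)^(p - 1), p, df_error) * se, numeric(1L))
  names(lsr) <- as.character(2:k)
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * mse / nh)

  means <- vapply(groups, mean, numeric(1L))
  ord <- order(-means)            # descending means
  ms <- means[ord]
  # raw homogeneous reach of each start position
  jraw <- integer(k)
  for (i in seq_len(k)) {
    jraw[i] <- i
    for (j in seq(i + 1L, k, length.out = max(0L, k - i))) {
      if (ms[i] - ms[j] <= lsr[[as.character(j - i + 1L)]]) jraw[i] <- j
    }
  }
  # Duncan protection: a range inside a homogeneous range is homogeneous
  jmax <- cummax(jraw)
  # maximal homogeneous stretches, left to right over ordered means
  stretches <- list()
  i <- 1L
  repeat {
    j <- jmax[i]
    stretches[[length(stretches) + 1L]] <- c(i, j)
    nxt <- which(seq_len(k) > i & jmax > j)
    if (j == k && length(nxt) == 0L) break
    if (length(nxt) == 0L) { if (j == k) break; nxt <- j + 1L }
    i <- min(nxt)
    if (i > k) break
  }
  # membership per group (in ordered space), then letters by first
  # appearance in input order
  member <- lapply(seq_len(k), function(pos)
    which(vapply(stretches, function(s) pos >= s[1L] && pos <= s[2L],
                 logical(1L))))
  member_input <- vector("list", k)
  member_input[ord] <- member
  stretch_letter <- rep(NA_character_, length(stretches))
  nxt_letter <- 1L
  for (g in seq_len(k)) {
    for (s in member_input[[g]]) {
      if (is.na(stretch_letter[s])) {
        stretch_letter[s] <- letters[nxt_letter]
        nxt_letter <- nxt_letter + 1L
      }
    }
  }
  lett <- vapply(member_input, function(ss)
    paste(sort(stretch_letter[ss]), collapse = ""), character(1L))

  structure(list(table = data.frame(group = names(groups), n = as.integer(sizes),
                                    mean = unname(means), letters = lett,
                                    stringsAsFactors = FALSE),
                 mse = mse, df_error = df_error, lsd = lsd, lsr = lsr,
                 alpha = alpha),
            class = "duncan_mrt")
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple-range test (alpha = %g)\n", x$alpha))
  cat(sprintf("  error MS %.6g on %d df; LSD(%g) = %.4g\n",
              x$mse, x$df_error, x$alpha, x$lsd))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-12s n=%d  mean %10.4g  %s\n", x$table$group[i],
                x$table$n[i], x$table$mean[i], x$table$letters[i]))
  }
  cat("  groups sharing a letter are not significantly different\n")
  invisible(x)
}

#' Linear salinity yield-loss model
#'
#' Percent grain-yield reduction for a salinity-sensitive rice crop under
#' the threshold-slope model: no loss up to the threshold electrical
#' conductivity, then a constant percent loss per dS/m, clamped at 100.
#' Defaults are the standard rice figures (threshold 3 dS/m, 12% per dS/m).
#'
#' @param ec_ds_per_m Soil salinity in dS/m (non-negative, vectorized).
#' @param threshold Threshold salinity in dS/m (default 3).
#' @param slope Percent yield loss per dS/m beyond the threshold
#'   (default 12).
#' @return Percent yield reduction in \[0, 100\].
#' @examples
#' salinity_yield_loss(c(3, 4, 6))
#' @export
salinity_yield_loss <- function(ec_ds_per_m, threshold = 3, slope = 12) {
  if (any(is.na(ec_ds_per_m)) || any(ec_ds_per_m < 0)) {
    stop("ec_ds_per_m must be non-negative", call. = FALSE)
  }
  pmin(pmax(slope * (ec_ds_per_m - threshold), 0), 100)
}
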