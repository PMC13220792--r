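#' Apparent free energy of membrane insertion of a segment
#'
#' Scores a candidate transmembrane segment on the biological hydrophobicity
#' scale.  The score is the sum of position-weighted per-residue
#' contributions, a hydrophobic-moment term (100 degrees per residue), and a
#' length-correction polynomial.  Negative values favor membrane insertion.
#'
#' @param segment Amino-acid string (20 canonical letters only; `X` or other
#'   nonstandard letters are a scoring error).
#' @param scale A [dg_scale()] object; defaults to the bundled scale.
#' @return dG_app in kcal/mol (a single number).
#' @examples
#' dg_app(strrep("L", 19)) # poly-leucine: strongly favorable
#' @export
dg_app <- function(segment, scale = dg_scale()) {
  chars <- split_chars(segment)
  codes <- aa_codes(chars)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))
    stop("cannot score residue '", chars[bad[1L]], "' at position ", bad[1L],
         " of segment; only the 20 canonical amino acids are supported")
  }
  L <- length(codes)
  if (L < scale$min_len || L > scale$max_len) {
    stop("segment length ", L, " outside the supported range ",
         scale$min_len, "-", scale$max_len,
         " aa (use dg_scan() for longer stretches)")
  }
  w <- dg_position_weights(L, scale)
  pick <- cbind(codes, seq_len(L))
  d <- w$base[pick]
  sum(d) +
    scale$moment_coef * sqrt(sum(w$sinw[pick])^2 + sum(w$cosw[pick])^2) +
    dg_length_term(L, scale)
}

#' Minimal-dG_app window scan
#'
#' Slides windows of every length in `length_range` across a sequence and
#' returns the window with the lowest dG_app.  Ties are broken by smallest
#' start coordinate, then smallest window length.  This is the full-protein
#' scan used to locate candidate transmembrane segments, and to score
#' unusually long (>40 aa) recorded TMDs by their minimal-dG_app subsegment.
#'
#' @param sequence Amino-acid string.  Positions containing nonstandard
#'   letters (for example `X`) cannot contribute to any window; windows
#'   covering them are skipped.  If no scorable window exists, an error is
#'   raised.
#' @param length_range Integer vector `c(Lmin, Lmax)` of window lengths to
#'   consider (default 19-23 aa).
#' @param scale A [dg_scale()] object.
#' @return A list of class `dg_result` with elements `dg_app`,
#'   `window_start`, `window_end`, `window_length` (1-based inclusive
#'   coordinates within `sequence`).
#' @export
dg_scan <- function(sequence, length_range = c(19L, 23L), scale = dg_scale()) {
  chars <- split_chars(sequence)
  codes <- aa_codes(chars)
  n <- length(codes)
  lmin <- as.integer(length_range[1L])
  lmax <- as.integer(length_range[length(length_range)])
  if (lmin > lmax) stop("length_range must be increasing")
  if (lmin < scale$min_len || lmax > scale$max_len) {
    stop("length_range must lie within the scale's supported range ",
         scale$min_len, "-", scale$max_len, " aa")
  }
  if (n < lmin) {
    stop("sequence (", n, " aa) is shorter than the minimum window length ",
         lmin)
  }
  best <- list(dg = Inf, start = NA_integer_, len = NA_integer_)
  bad <- is.na(codes)
  for (L in lmin:min(lmax, n)) {
    nstarts <- n - L + 1L
    w <- dg_position_weights(L, scale)
    tot <- numeric(nstarts)
    ssin <- numeric(nstarts)
    scos <- numeric(nstarts)
    usable <- rep(TRUE, nstarts)
    for (i in seq_len(L)) {
      idx <- codes[i:(i + nstarts - 1L)]
      na <- is.na(idx)
      if (any(na)) {
        usable[na] <- FALSE
        idx[na] <- 1L
      }
      tot <- tot + w$base[cbind(idx, i)]
      ssin <- ssin + w$sinw[cbind(idx, i)]
      scos <- scos + w$cosw[cbind(idx, i)]
    }
    dg <- tot + scale$moment_coef * sqrt(ssin^2 + scos^2) +
      dg_length_term(L, scale)
    dg[!usable] <- Inf
    # within one length, which.min keeps the leftmost minimum; across
    # lengths, ties resolve to the smallest start, then the smallest length
    k <- which.min(dg)
    if (length(k) && is.finite(dg[k]) &&
        (dg[k] < best$dg ||
         (dg[k] == best$dg && k < best$start))) {
      best <- list(dg = dg[k], start = k, len = L)
    }
  }
  if (!is.finite(best$dg)) {
    stop("no scorable window: every candidate window contains a ",
         "nonstandard residue")
  }
  structure(list(dg_app = best$dg,
                 window_start = best$start,
                 window_end = best$start + best$len - 1L,
                 window_length = best$len),
            class = "dg_result")
}

#' @export
print.dg_result <- function(x, ...) {
  cat(sprintf("dG_app = %.3f kcal/mol over %d-%d (%d aa)\n",
              x$dg_app, x$window_start, x$window_end, x$window_length))
  invisible(x)
}

# Score one TMD sequence the way the census does: whole segment if its length
# is within the scale range; minimal-dG_app scan within the span for longer
# TMDs.  Returns NA (with a reason) rather than erroring.
score_tmd_sequence <- function(seq, scale) {
  L <- nchar(seq)
  res <- tryCatch({
    if (L > scale$max_len) {
      dg_scan(seq, c(19L, 23L), scale)$dg_app
    } else {
      dg_app(seq, scale)
    }
  }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
  res
}

#' Fill in dG_app for every TMD of a census table
#'
#' @param table A `census_table` (see [parse_census_table()]).
#' @param scale A [dg_scale()] object.
#' @param rescore If `FALSE` (default), recorded dG_app values are kept and
#'   only missing ones are computed.  If `TRUE`, all TMDs are rescored and
#'   the per-TMD differences against previously recorded values are returned
#'   in the report.
#' @return The table with `dg_app` filled in; attribute `"dg_report"` holds a
#'   data frame of scoring errors (TMDs that could not be scored, for example
#'   those containing `X`) and, when `rescore = TRUE`, the deltas against
#'   recorded values.
#' @export
score_all_tmds <- function(table, scale = dg_scale(), rescore = FALSE) {
  stopifnot(inherits(table, "census_table"))
  errors <- list()
  deltas <- list()
  for (r in seq_along(table$records)) {
    rec <- table$records[[r]]
    if (nrow(rec$tmds) == 0L) next
    for (k in seq_len(nrow(rec$tmds))) {
      old <- rec$tmds$dg_app[k]
      if (!rescore && !is.na(old)) next
      val <- score_tmd_sequence(rec$tmds$sequence[k], scale)
      if (is.na(val)) {
        errors[[length(errors) + 1L]] <- data.frame(
          accession = rec$accession, tmd = k,
          reason = attr(val, "reason") %||% "unscorable",
          stringsAsFactors = FALSE)
        next
      }
      if (rescore && !is.na(old)) {
        deltas[[length(deltas) + 1L]] <- data.frame(
          accession = rec$accession, tmd = k,
          recorded = old, rescored = val, delta = val - old,
          stringsAsFactors = FALSE)
      }
      rec$tmds$dg_app[k] <- val
    }
    table$records[[r]] <- rec
  }
  attr(table, "dg_report") <- list(
    errors = if (length(errors)) do.call(rbind, errors) else NULL,
    deltas = if (length(deltas)) do.call(rbind, deltas) else NULL,
    scale = scale$provenance)
  table
}
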