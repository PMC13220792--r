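#' Construct a protein record
#'
#' A protein record holds everything the census needs about one protein: its
#' sequence, an optional cleavable signal peptide, the ordered TMD spans
#' (1-based, inclusive on both ends, the UniProt convention) and the membrane
#' side of the N terminus (`"inside"` = cytosolic, N_cyt; `"outside"` =
#' exoplasmic, N_exo).  Proteins with a cleavable signal necessarily have the
#' mature N terminus outside.
#'
#' @param accession Identifier string (unique within a table).
#' @param sequence Amino-acid string; the 20 canonical letters plus `X`.
#' @param tmd_starts,tmd_ends Integer vectors of TMD spans, ordered by start.
#' @param n_terminus_side `"inside"` or `"outside"`.
#' @param gene_name Optional gene symbol.
#' @param signal Optional `c(start, end)` of the signal peptide (must start
#'   at residue 1).
#' @param tmd_dg Optional numeric vector of recorded dG_app values (kcal/mol),
#'   one per TMD; `NA` where unknown.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `protein_record`.
#' @seealso [validate_record()], [deduce_segments()]
#' @export
protein_record <- function(accession, sequence, tmd_starts, tmd_ends,
                           n_terminus_side, gene_name = accession,
                           signal = NULL, tmd_dg = NULL, validate = TRUE) {
  tmd_starts <- as.integer(tmd_starts)
  tmd_ends <- as.integer(tmd_ends)
  n <- length(tmd_starts)
  if (is.null(tmd_dg)) tmd_dg <- rep(NA_real_, n)
  tmds <- data.frame(
    index = seq_len(n),
    start = tmd_starts,
    end = tmd_ends,
    sequence = substring(sequence, tmd_starts, tmd_ends),
    dg_app = as.numeric(tmd_dg),
    stringsAsFactors = FALSE)
  rec <- structure(list(
    accession = accession,
    gene_name = gene_name,
    length = nchar(sequence),
    sequence = sequence,
    signal = if (!is.null(signal)) as.integer(signal) else NULL,
    tmds = tmds,
    n_terminus_side = n_terminus_side
  ), class = "protein_record")
  if (validate) {
    v <- record_violations(rec) # advisory "flag:" entries do not invalidate
    if (length(v)) {
      stop("invalid record ", accession, ": ", paste(v, collapse = "; "))
    }
  }
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<%s> %s, %d aa, %d TMD(s), N terminus %s%s\n",
              x$accession, x$gene_name, x$length, nrow(x$tmds),
              x$n_terminus_side,
              if (!is.null(x$signal))
                sprintf(", signal %d-%d", x$signal[1], x$signal[2]) else ""))
  invisible(x)
}

#' Check a protein record against the data-model invariants
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the record is valid.  Checked rules: sequence letters (canonical 20
#' plus `X`); stated length equals the sequence length; TMD spans within
#' `[1, length]`, strictly ordered by start, mutually non-overlapping and
#' disjoint from the signal peptide; a signal peptide starts at residue 1 and
#' forces `n_terminus_side = "outside"`; TMDs of unusual length (<= 14 aa or
#' >= 35 aa) are reported as `"flag: ..."` entries, which do not invalidate
#' the record.
#'
#' @param record A [protein_record()].
#' @return Character vector of violation messages (possibly empty).  Entries
#'   starting with `"flag:"` are advisory only.
#' @export
validate_record <- function(record) {
  v <- character()
  chars <- split_chars(record$sequence)
  bad <- !(chars %in% c(AA20, AA_UNKNOWN))
  if (any(bad)) {
    v <- c(v, paste0("sequence: nonstandard residue(s) ",
                     paste(unique(chars[bad]), collapse = ","),
                     " at position(s) ",
                     paste(head(which(bad), 5L), collapse = ",")))
  }
  if (record$length != nchar(record$sequence)) {
    v <- c(v, sprintf("length: stated %d != sequence length %d",
                      record$length, nchar(record$sequence)))
  }
  tm <- record$tmds
  n <- nrow(tm)
  if (n > 0L) {
    if (any(tm$start < 1L) || any(tm$end > record$length)) {
      idx <- which(tm$start < 1L | tm$end > record$length)
      v <- c(v, sprintf("tmd %d: span %d-%d outside sequence [1, %d]",
                        idx, tm$start[idx], tm$end[idx], record$length))
    }
    if (any(tm$end < tm$start)) {
      idx <- which(tm$end < tm$start)
      v <- c(v, sprintf("tmd %d: end %d before start %d",
                        idx, tm$end[idx], tm$start[idx]))
    }
    if (n > 1L && any(diff(tm$start) <= 0L)) {
      v <- c(v, "tmds: not strictly ordered by start")
    }
    # brute-force pairwise overlap check (one violation per overlapping pair)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (tm$start[j] <= tm$end[i] && tm$end[j] >= tm$start[i]) {
            v <- c(v, sprintf("tmds %d and %d overlap", i, j))
          }
        }
      }
    }
    len <- tm$end - tm$start + 1L
    odd <- which(len <= 14L | len >= 35L)
    for (i in odd) {
      v <- c(v, sprintf("flag: tmd %d has unusual length %d aa", i, len[i]))
    }
  }
  if (!record$n_terminus_side %in% c("inside", "outside")) {
    v <- c(v, "n_terminus_side: must be 'inside' or 'outside'")
  }
  if (!is.null(record$signal)) {
    s <- record$signal
    if (length(s) != 2L || anyNA(s)) {
      v <- c(v, "signal: must be c(start, end)")
    } else {
      if (s[1L] != 1L) v <- c(v, "signal: must start at residue 1")
      if (s[2L] > record$length) v <- c(v, "signal: end beyond sequence")
      if (n > 0L && s[2L] >= tm$start[1L]) {
        v <- c(v, "signal: overlaps TMD 1")
      }
      if (record$n_terminus_side != "outside") {
        v <- c(v, paste0("n_terminus_side: a cleavable signal forces the ",
                         "mature N terminus outside"))
      }
    }
  }
  v
}

record_violations <- function(record) {
  v <- validate_record(record)
  v[!startsWith(v, "flag:")]
}
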