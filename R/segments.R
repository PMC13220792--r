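#' Deduce loops and tails from TMD coordinates
#'
#' Extramembrane segment coordinates are deduced from the TMD coordinates:
#' for a protein with n TMDs the N-terminal tail (segment 1) runs from
#' residue 1 (or signal_end + 1 when a signal peptide is present) to
#' TMD1_start - 1; internal loop k runs from TMDk_end + 1 to
#' TMD(k+1)_start - 1; and the C-terminal tail (segment n + 1) runs from
#' TMDn_end + 1 to the end of the protein.  Abutting TMDs yield zero-length
#' segments, represented with `end < start` and `length = 0` (never
#' negative).  Together with the signal peptide and the TMDs, the returned
#' segments tile `[1, length]` exactly.
#'
#' @param record A validated [protein_record()].
#' @param assign_sides If `TRUE` (default), also set the membrane side of
#'   every segment via [assign_locations()].
#' @return A data frame with one row per segment (`ordinal`, `start`, `end`,
#'   `length`, `kind` in `n_tail`/`internal_loop`/`c_tail`, and `side` if
#'   assigned).
#' @export
deduce_segments <- function(record, assign_sides = TRUE) {
  n <- nrow(record$tmds)
  first <- if (!is.null(record$signal)) record$signal[2L] + 1L else 1L
  if (n == 0L) {
    seg <- data.frame(ordinal = 1L, start = first, end = record$length,
                      kind = "n_tail", stringsAsFactors = FALSE)
  } else {
    starts <- c(first, record$tmds$end + 1L)
    ends <- c(record$tmds$start - 1L, record$length)
    kind <- c("n_tail", rep("internal_loop", max(0L, n - 1L)), "c_tail")
    seg <- data.frame(ordinal = seq_len(n + 1L), start = starts, end = ends,
                      kind = kind, stringsAsFactors = FALSE)
  }
  seg$length <- pmax(0L, seg$end - seg$start + 1L)
  if (assign_sides) seg <- assign_locations(record, seg)
  seg
}

#' Assign alternating membrane sides to segments
#'
#' The N-terminal tail lies on `n_terminus_side` (inside for N_cyt
#' topologies, outside for N_exo topologies; a cleavable signal forces
#' outside).  Each subsequent segment lies on the opposite side of the
#' previous one, because each TMD crosses the membrane once: segment k is on
#' `n_terminus_side` when it is preceded by an even number of TMDs, and on
#' the opposite side otherwise.
#'
#' @param record A [protein_record()].
#' @param segments Data frame from [deduce_segments()].
#' @return `segments` with a `side` column (`"inside"`/`"outside"`).
#' @export
assign_locations <- function(record, segments) {
  side0 <- record$n_terminus_side
  other <- if (side0 == "inside") "outside" else "inside"
  k <- segments$ordinal
  segments$side <- ifelse((k - 1L) %% 2L == 0L, side0, other)
  segments
}

# Sequence of a segment ("" for zero-length segments).
segment_sequence <- function(record, seg_row) {
  if (seg_row$length == 0L) return("")
  substr(record$sequence, seg_row$start, seg_row$end)
}

# Membrane side of the N-terminal end of TMD k: the side of the segment
# preceding it (segment k).
tmd_n_end_side <- function(segments, k) segments$side[k]
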