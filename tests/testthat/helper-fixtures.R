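# Fixture builders: records with exact, hand-chosen geometry.

# Build a protein record from segment lengths.  loop_lens has n_tmds + 1
# entries (N-tail, internal loops, C-tail).  Specific extramembrane segments
# can be overridden with exact sequences via loop_seqs (named by ordinal);
# specific TMDs via tmd_seqs (named by index).
mk_record <- function(n_tmds, loop_lens, n_side, signal_len = 0L,
                      tmd_len = 21L, tmd_fill = "L", loop_fill = "G",
                      loop_seqs = list(), tmd_seqs = list(),
                      accession = "T1", dg = NULL) {
  stopifnot(length(loop_lens) == n_tmds + 1L)
  tmd_len <- rep_len(tmd_len, n_tmds)
  parts <- character()
  if (signal_len > 0L) parts <- c(parts, strrep("A", signal_len))
  starts <- ends <- integer(n_tmds)
  pos <- signal_len
  for (k in seq_len(n_tmds + 1L)) {
    key <- as.character(k)
    loop <- if (!is.null(loop_seqs[[key]])) loop_seqs[[key]] else
      strrep(loop_fill, loop_lens[k])
    stopifnot(nchar(loop) == loop_lens[k])
    parts <- c(parts, loop)
    pos <- pos + loop_lens[k]
    if (k <= n_tmds) {
      tm <- if (!is.null(tmd_seqs[[key]])) tmd_seqs[[key]] else
        strrep(tmd_fill, tmd_len[k])
      stopifnot(nchar(tm) == tmd_len[k])
      parts <- c(parts, tm)
      starts[k] <- pos + 1L
      pos <- pos + tmd_len[k]
      ends[k] <- pos
    }
  }
  protein_record(accession, paste(parts, collapse = ""),
                 starts, ends, n_side,
                 signal = if (signal_len > 0L) c(1L, signal_len) else NULL,
                 tmd_dg = dg)
}

small_proteome <- function(n = 40L, seed = 5L) {
  generate_proteome(cached_config(n), seed = seed)$table
}

# one calibrated config reused across tests (calibration is deterministic)
cached_config <- function(n_proteins = 40L) {
  key <- "test_config"
  cfg <- memtopo:::.memtopo_cache[[key]]
  if (is.null(cfg)) {
    cfg <- default_config(n_proteins = n_proteins)
    assign(key, cfg, envir = memtopo:::.memtopo_cache)
  }
  cfg$n_proteins <- as.integer(n_proteins)
  cfg
}
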