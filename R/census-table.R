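# Canonical census-table schema and the tolerant reader.
#
# Canonical columns (comma-delimited, UTF-8, header required):
#   accession, gene_name, length, num_tmds, topology, n_terminus_side,
#   signal_start, signal_end, tmd_coords, tmd_dg, sequence
# tmd_coords is a semicolon-separated list of "start-end" pairs; tmd_dg a
# semicolon-separated list of dG_app values aligned with tmd_coords.

CENSUS_COLUMNS <- c("accession", "gene_name", "length", "num_tmds",
                    "topology", "n_terminus_side", "signal_start",
                    "signal_end", "tmd_coords", "tmd_dg", "sequence")

# Common aliases mapped onto the canonical schema.
CENSUS_ALIASES <- list(
  accession = c("accession", "uniprot", "uniprot_accession", "acc", "id"),
  gene_name = c("gene_name", "gene", "gene_symbol", "symbol"),
  length = c("length", "protein_length", "len"),
  num_tmds = c("num_tmds", "n_tmds", "number_of_tmds", "tmd_count"),
  topology = c("topology", "topology_type", "topology_class"),
  n_terminus_side = c("n_terminus_side", "n_term_side", "n_terminus",
                      "nterm_location", "n_location"),
  signal_start = c("signal_start", "sp_start", "signal_peptide_start"),
  signal_end = c("signal_end", "sp_end", "signal_peptide_end"),
  tmd_coords = c("tmd_coords", "tmd_coordinates", "tm_coords",
                 "tmd_coordinate_string"),
  tmd_dg = c("tmd_dg", "tmd_dg_app", "dg_app", "dg"),
  sequence = c("sequence", "seq", "full_sequence"),
  loop_coords = c("loop_coords", "loop_coordinates"),
  loop_locations = c("loop_locations", "loop_sides")
)

normalize_side <- function(x) {
  x <- tolower(trimws(x))
  if (x %in% c("inside", "in", "cytosolic", "cytosol", "cyt", "n_cyt",
               "ncyt")) return("inside")
  if (x %in% c("outside", "out", "exoplasmic", "lumenal", "luminal", "exo",
               "n_exo", "nexo")) return("outside")
  NA_character_
}

parse_coord_string <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "") return(data.frame(start = integer(), end = integer()))
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", parts))
  if (any(vapply(m, length, 0L) != 3L)) {
    stop("malformed coordinate string '", x, "'")
  }
  data.frame(start = as.integer(vapply(m, `[[`, "", 2L)),
             end = as.integer(vapply(m, `[[`, "", 3L)))
}

parse_dg_string <- function(x, n) {
  x <- trimws(x)
  if (is.na(x) || x == "") return(rep(NA_real_, n))
  vals <- suppressWarnings(as.numeric(strsplit(x, ";", fixed = TRUE)[[1L]]))
  if (length(vals) != n) {
    stop("tmd_dg has ", length(vals), " values for ", n, " TMDs")
  }
  vals
}

#' Parse a census table
#'
#' Reads a delimited text table with one row per protein carrying its full
#' topologic description (see the package overview for the canonical schema).
#' The reader is tolerant: common column aliases are mapped onto the
#' canonical names (the mapping used is recorded in the parse report), and
#' TMD coordinates may be given either as a single `"start-end;start-end"`
#' string or as per-TMD column pairs `tmd1_start`/`tmd1_end`, ....  Malformed
#' rows are rejected with a reason, never silently dropped; missing mandatory
#' columns are a hard error naming the column.  Rows whose sequence contains
#' ambiguity codes (B, Z, U, J, O), whose coordinates fall outside the
#' sequence, whose stated length or TMD count disagrees with the data, or
#' that pair a signal peptide with an inside N terminus (internally
#' contradictory) are rejected.  When explicit loop columns are present the
#' loops are recomputed from the TMD coordinates and mismatches are reported
#' in the parse report rather than trusted.
#'
#' @param file Path to a delimited text file (or a connection).
#' @param sep Field delimiter; `","` (canonical) by default, `"\t"` accepted.
#' @return An object of class `census_table`: a list with `records` (list of
#'   [protein_record()]) and `provenance` (source, rows read/parsed/rejected
#'   with reasons, column mapping, loop cross-check mismatches).
#' @export
parse_census_table <- function(file, sep = ",") {
  raw <- read.csv(file, sep = sep, colClasses = "character",
                  check.names = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  src <- if (is.character(file)) file else "<connection>"

  # map aliases onto canonical names
  colmap <- character()
  for (canon in names(CENSUS_ALIASES)) {
    hit <- intersect(CENSUS_ALIASES[[canon]], names(raw))
    if (length(hit)) {
      colmap[[canon]] <- hit[1L]
      names(raw)[names(raw) == hit[1L]] <- canon
    }
  }

  # per-TMD column-pair dialect
  tmd_pair_cols <- grepl("^tmd\\d+_(start|end)$", names(raw))
  has_pairs <- any(tmd_pair_cols)

  mandatory <- c("accession", "sequence", "n_terminus_side")
  if (!has_pairs) mandatory <- c(mandatory, "tmd_coords")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }

  records <- list()
  rejected <- list()
  loop_mismatch <- list()
  reject <- function(i, acc, why) {
    rejected[[length(rejected) + 1L]] <<- data.frame(
      row = i, accession = acc, reason = why, stringsAsFactors = FALSE)
  }
  seen <- character()

  for (i in seq_len(nrow(raw))) {
    row <- raw[i, , drop = FALSE]
    acc <- trimws(row$accession)
    res <- tryCatch({
      if (acc == "") stop("empty accession")
      if (acc %in% seen) stop("duplicate accession")
      seq <- gsub("\\s", "", toupper(row$sequence))
      chars <- unique(split_chars(seq))
      badaa <- intersect(chars, AA_REJECTED)
      if (length(badaa)) {
        stop("nonstandard residue(s) ", paste(badaa, collapse = ","),
             " in sequence")
      }
      side <- normalize_side(row$n_terminus_side)
      if (is.na(side)) {
        stop("unrecognized n_terminus_side '", row$n_terminus_side, "'")
      }
      if (has_pairs) {
        ks <- sort(as.integer(sub("^tmd(\\d+)_start$", "\\1",
                                  grep("^tmd\\d+_start$", names(raw),
                                       value = TRUE))))
        st <- en <- integer()
        for (k in ks) {
          s <- trimws(row[[paste0("tmd", k, "_start")]])
          e <- trimws(row[[paste0("tmd", k, "_end")]])
          if (is.na(s) || s == "") next
          st <- c(st, as.integer(s)); en <- c(en, as.integer(e))
        }
        coords <- data.frame(start = st, end = en)
      } else {
        coords <- parse_coord_string(row$tmd_coords)
      }
      dg <- if ("tmd_dg" %in% names(raw)) {
        parse_dg_string(row$tmd_dg, nrow(coords))
      } else rep(NA_real_, nrow(coords))
      signal <- NULL
      if ("signal_start" %in% names(raw) &&
          !is.na(row$signal_start) && trimws(row$signal_start) != "") {
        signal <- c(as.integer(row$signal_start), as.integer(row$signal_end))
        if (side == "inside") {
          stop("signal peptide recorded together with an inside N terminus")
        }
      }
      if ("length" %in% names(raw) && trimws(row$length %||% "") != "" &&
          !is.na(row$length)) {
        stated <- as.integer(row$length)
        if (!is.na(stated) && stated != nchar(seq)) {
          stop("stated length ", stated, " != sequence length ", nchar(seq))
        }
      }
      if ("num_tmds" %in% names(raw) && trimws(row$num_tmds %||% "") != "" &&
          !is.na(row$num_tmds)) {
        stated <- as.integer(row$num_tmds)
        if (!is.na(stated) && stated != nrow(coords)) {
          stop("stated num_tmds ", stated, " != ", nrow(coords))
        }
      }
      rec <- protein_record(
        accession = acc,
        gene_name = if ("gene_name" %in% names(raw))
          trimws(row$gene_name) else acc,
        sequence = seq,
        tmd_starts = coords$start, tmd_ends = coords$end,
        n_terminus_side = side, signal = signal, tmd_dg = dg,
        validate = FALSE)
      viol <- record_violations(rec)
      if (length(viol)) stop(paste(viol, collapse = "; "))
      rec
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      reject(i, acc, res)
      next
    }
    # cross-check explicit loop columns against recomputed segments
    if (all(c("loop_coords", "loop_locations") %in% names(raw)) &&
        trimws(row$loop_coords %||% "") != "") {
      chk <- tryCatch({
        given <- parse_coord_string(row$loop_coords)
        sides <- vapply(strsplit(row$loop_locations, ";")[[1L]],
                        normalize_side, "")
        seg <- deduce_segments(res)
        given_len <- pmax(0L, given$end - given$start + 1L)
        ok <- nrow(given) == nrow(seg) &&
          all(given_len == seg$length) &&
          length(sides) == nrow(seg) && all(sides == seg$side)
        if (!ok) "loop columns disagree with loops recomputed from TMDs"
        else NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(chk)) {
        loop_mismatch[[length(loop_mismatch) + 1L]] <- data.frame(
          row = i, accession = acc, reason = chk, stringsAsFactors = FALSE)
      }
    }
    seen <- c(seen, acc)
    records[[length(records) + 1L]] <- res
  }

  structure(list(
    records = records,
    provenance = list(
      source = src,
      rows_read = nrow(raw),
      rows_parsed = length(records),
      rejected = if (length(rejected)) do.call(rbind, rejected) else
        data.frame(row = integer(), accession = character(),
                   reason = character()),
      column_map = colmap,
      loop_mismatches = if (length(loop_mismatch))
        do.call(rbind, loop_mismatch) else NULL)
  ), class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("census_table: %d protein record(s)", length(x$records)))
  if (!is.null(p$rows_read)) {
    cat(sprintf(" (parsed %d of %d rows from %s; %d rejected)",
                p$rows_parsed, p$rows_read, p$source, nrow(p$rejected)))
  }
  cat("\n")
  invisible(x)
}

#' Build a census table from records constructed in code
#'
#' @param records List of [protein_record()] objects with unique accessions.
#' @param source Provenance label.
#' @return A `census_table`.
#' @export
census_table <- function(records, source = "in-memory") {
  acc <- vapply(records, `[[`, "", "accession")
  if (anyDuplicated(acc)) stop("duplicate accessions in records")
  structure(list(records = records,
                 provenance = list(source = source,
                                   rows_read = length(records),
                                   rows_parsed = length(records),
                                   rejected = data.frame(
                                     row = integer(), accession = character(),
                                     reason = character()),
                                   column_map = character(),
                                   loop_mismatches = NULL)),
            class = "census_table")
}

#' Write a census table in the canonical dialect
#'
#' Emits a comma-delimited UTF-8 file with the canonical column order.  The
#' topology column is recomputed from the record (never copied from input),
#' and recorded dG_app values are written with enough digits to round-trip.
#'
#' @param table A `census_table`.
#' @param file Output path or connection.
#' @return Invisibly, the data frame that was written.
#' @export
write_census_table <- function(table, file) {
  stopifnot(inherits(table, "census_table"))
  rows <- lapply(table$records, function(rec) {
    seg <- deduce_segments(rec)
    data.frame(
      accession = rec$accession,
      gene_name = rec$gene_name,
      length = rec$length,
      num_tmds = nrow(rec$tmds),
      topology = classify_protein(rec, seg),
      n_terminus_side = rec$n_terminus_side,
      signal_start = if (!is.null(rec$signal)) rec$signal[1L] else NA_integer_,
      signal_end = if (!is.null(rec$signal)) rec$signal[2L] else NA_integer_,
      tmd_coords = paste(sprintf("%d-%d", rec$tmds$start, rec$tmds$end),
                         collapse = ";"),
      tmd_dg = if (all(is.na(rec$tmds$dg_app))) "" else
        paste(ifelse(is.na(rec$tmds$dg_app), "",
                     format(rec$tmds$dg_app, digits = 12, trim = TRUE,
                            scientific = FALSE)), collapse = ";"),
      sequence = rec$sequence,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(CENSUS_COLUMNS)),
                           CENSUS_COLUMNS))
  df <- df[, CENSUS_COLUMNS]
  write.csv(df, file, row.names = FALSE, na = "")
  invisible(df)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a named
#' character vector (names are the first whitespace-delimited token of each
#' header).
#'
#' @param file FASTA path (wrapped or unwrapped).
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readAAStringSet(file)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}
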