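write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("parse_census_table reads the canonical dialect", {
  seq6 <- paste0(strrep("G", 40), strrep("L", 21), strrep("G", 180),
                 strrep("L", 19), strrep("G", 40))
  # TMD2 of this synthetic record spans 242-260 (19 aa), mirroring the
  # coordinate-string convention "start-end;start-end"
  f <- write_lines_tmp(c(
    "accession,gene_name,n_terminus_side,tmd_coords,tmd_dg,sequence",
    sprintf("P00001,GENE1,inside,41-61;242-260,-1.5;-0.117,%s", seq6)))
  tab <- parse_census_table(f)
  expect_identical(length(tab$records), 1L)
  rec <- tab$records[[1]]
  expect_identical(rec$tmds$start, c(41L, 242L))
  expect_identical(rec$tmds$end, c(61L, 260L))
  expect_identical(rec$tmds$end[2] - rec$tmds$start[2] + 1L, 19L)
  expect_equal(rec$tmds$dg_app, c(-1.5, -0.117))
  expect_identical(rec$tmds$sequence[2], strrep("L", 19))
})

test_that("header-only input yields an empty table; missing columns error", {
  f <- write_lines_tmp("accession,gene_name,n_terminus_side,tmd_coords,sequence")
  tab <- parse_census_table(f)
  expect_identical(length(tab$records), 0L)
  f2 <- write_lines_tmp(c("accession,sequence", "A1,GGG"))
  expect_error(parse_census_table(f2), "n_terminus_side")
})

test_that("aliases and the per-TMD column-pair dialect are accepted", {
  seqs <- paste0(strrep("G", 10), strrep("L", 21), strrep("G", 10))
  f <- write_lines_tmp(c(
    "uniprot,gene,n_term_side,tmd1_start,tmd1_end,tmd2_start,tmd2_end,seq",
    sprintf("Q1,G1,cytosolic,11,31,,,%s", seqs)))
  tab <- parse_census_table(f)
  expect_identical(length(tab$records), 1L)
  expect_identical(tab$records[[1]]$tmds$start, 11L)
  expect_identical(tab$records[[1]]$n_terminus_side, "inside")
  expect_true("accession" %in% names(tab$provenance$column_map))
})

test_that("malformed rows are rejected with reasons, not dropped silently", {
  good <- paste0(strrep("G", 10), strrep("L", 21), strrep("G", 10))
  f <- write_lines_tmp(c(
    "accession,n_terminus_side,signal_start,signal_end,tmd_coords,sequence",
    sprintf("OK1,inside,,,11-31,%s", good),
    sprintf("BAD1,inside,,,11-99,%s", good),             # TMD beyond sequence
    sprintf("BAD2,inside,,,11-31,%s", sub("L", "B", good)), # ambiguity code
    sprintf("BAD3,inside,1,5,11-31,%s", good),           # signal + N inside
    sprintf("OK1,inside,,,11-31,%s", good)))             # duplicate accession
  tab <- parse_census_table(f)
  expect_identical(length(tab$records), 1L)
  rej <- tab$provenance$rejected
  expect_identical(nrow(rej), 4L)
  expect_match(rej$reason[rej$accession == "BAD1"], "outside sequence")
  expect_match(rej$reason[rej$accession == "BAD2"], "B")
  expect_match(rej$reason[rej$accession == "BAD3"], "signal")
  expect_match(rej$reason[4], "duplicate")
})

test_that("explicit loop columns are cross-checked, not trusted", {
  good <- paste0(strrep("G", 10), strrep("L", 21), strrep("G", 10))
  f <- write_lines_tmp(c(
    paste0("accession,n_terminus_side,tmd_coords,loop_coords,",
           "loop_locations,sequence"),
    sprintf("A1,inside,11-31,1-10;32-41,inside;outside,%s", good),
    sprintf("A2,inside,11-31,1-10;32-41,outside;inside,%s", good)))
  tab <- parse_census_table(f)
  expect_identical(length(tab$records), 2L)
  mm <- tab$provenance$loop_mismatches
  expect_identical(mm$accession, "A2")
})

test_that("write -> parse round-trips a generated table field-for-field", {
  tab <- score_all_tmds(small_proteome(n = 25, seed = 9))
  f <- tempfile(fileext = ".csv")
  write_census_table(tab, f)
  back <- parse_census_table(f)
  expect_identical(length(back$records), length(tab$records))
  for (i in seq_along(tab$records)) {
    a <- tab$records[[i]]; b <- back$records[[i]]
    expect_identical(b$accession, a$accession)
    expect_identical(b$gene_name, a$gene_name)
    expect_identical(b$sequence, a$sequence)
    expect_identical(b$n_terminus_side, a$n_terminus_side)
    expect_identical(b$signal, a$signal)
    expect_identical(b$tmds$start, a$tmds$start)
    expect_identical(b$tmds$end, a$tmds$end)
    expect_equal(b$tmds$dg_app, a$tmds$dg_app, tolerance = 1e-9)
  }
  # second round trip is the identity on the file
  f2 <- tempfile(fileext = ".csv")
  write_census_table(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("writing an empty table yields a header-only file", {
  f <- tempfile(fileext = ".csv")
  write_census_table(census_table(list()), f)
  lines <- readLines(f)
  expect_identical(length(lines), 1L)
  expect_match(lines, "^\"accession\"")
})

test_that("deduce_segments applies the tail/loop arithmetic", {
  # signal 1-20, single TMD 121-143, length 300:
  # N-tail = 21-120 (100 aa), C-tail = 144-300 (157 aa)
  rec <- protein_record("S1", strrep("A", 300), 121, 143, "outside",
                        signal = c(1, 20))
  seg <- deduce_segments(rec)
  expect_identical(seg$start, c(21L, 144L))
  expect_identical(seg$end, c(120L, 300L))
  expect_identical(seg$length, c(100L, 157L))
  # TMD starting at residue 1 gives a zero-length N-tail
  rec2 <- protein_record("S2", paste0(strrep("L", 21), strrep("G", 30)),
                         1, 21, "inside")
  seg2 <- deduce_segments(rec2)
  expect_identical(seg2$length[1], 0L)
  # abutting TMDs give a zero-length internal loop
  rec3 <- protein_record("S3",
                         paste0(strrep("G", 5), strrep("L", 42),
                                strrep("G", 5)),
                         c(6, 27), c(26, 47), "inside")
  expect_identical(deduce_segments(rec3)$length, c(5L, 0L, 5L))
})

test_that("segments tile the sequence exactly on generated records", {
  tab <- small_proteome(n = 60, seed = 21)
  for (rec in tab$records) {
    seg <- deduce_segments(rec)
    sig <- if (is.null(rec$signal)) 0L else rec$signal[2]
    tmd_total <- sum(rec$tmds$end - rec$tmds$start + 1L)
    expect_identical(sig + tmd_total + sum(seg$length), rec$length)
    expect_identical(nrow(seg), nrow(rec$tmds) + 1L)
    # no overlap, correct ordering of non-empty segments and TMDs
    spans <- rbind(
      if (sig > 0L) data.frame(s = 1L, e = sig),
      data.frame(s = rec$tmds$start, e = rec$tmds$end),
      data.frame(s = seg$start[seg$length > 0], e = seg$end[seg$length > 0]))
    spans <- spans[order(spans$s), ]
    expect_true(all(diff(spans$s) > 0))
    expect_true(all(spans$e[-nrow(spans)] < spans$s[-1]))
  }
})

test_that("segment sides alternate with the parity rule", {
  for (n in 1:12) {
    for (side in c("inside", "outside")) {
      rec <- mk_record(n, rep(3L, n + 1L), side)
      seg <- deduce_segments(rec)
      other <- if (side == "inside") "outside" else "inside"
      expect_identical(seg$side,
                       ifelse((seg$ordinal - 1L) %% 2L == 0L, side, other))
      expect_true(all(seg$side[-1] != seg$side[-nrow(seg)]))
    }
  }
  # one flip: N_cyt single-TMD record has its C-tail outside
  rec <- mk_record(1, c(5L, 60L), "inside")
  expect_identical(deduce_segments(rec)$side, c("inside", "outside"))
  # GPCR shape: N_exo 7-TMD record ends with a cytosolic C-tail
  rec <- mk_record(7, rep(8L, 8L), "outside")
  seg <- deduce_segments(rec)
  expect_identical(seg$side[8], "inside")
})

test_that("validate_record reports violations as data", {
  ok <- mk_record(2, c(5L, 9L, 5L), "inside")
  expect_identical(memtopo:::record_violations(ok), character(0))

  bad <- protein_record("B1", strrep("A", 30), 10, 40, "inside",
                        validate = FALSE)
  v <- validate_record(bad)
  expect_match(v, "tmd 1", all = FALSE)

  # overlapping TMDs: one violation per overlapping pair
  over <- protein_record("B2", strrep("A", 100),
                         c(10, 15, 20), c(30, 35, 40), "inside",
                         validate = FALSE)
  v <- validate_record(over)
  expect_identical(sum(grepl("overlap", v)), 3L)

  flagged <- protein_record("B3",
                            paste0(strrep("G", 5), strrep("L", 40),
                                   strrep("G", 5)),
                            6, 45, "inside", validate = FALSE)
  v <- validate_record(flagged)
  expect_true(any(startsWith(v, "flag:")))
  expect_identical(memtopo:::record_violations(flagged), character(0))
})

test_that("FASTA sequences are read with names", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">sp|Q1|TEST first", "ACDEFGHIKL", "MNPQRSTVWY",
               ">Q2", "LLLLLLLLLLLLLLLLLLL"), f)
  seqs <- read_fasta(f)
  expect_identical(names(seqs), c("sp|Q1|TEST", "Q2"))
  expect_identical(unname(seqs[1]), "ACDEFGHIKLMNPQRSTVWY")
})
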