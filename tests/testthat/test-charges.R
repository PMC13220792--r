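test_that("zone partition applies the cumulative half-up rounding rule", {
  z20 <- zone_partition(20, "outside")
  expect_identical(as.integer(table(factor(z20$zone,
                                           levels = memtopo:::ZONES))),
                   c(4L, 3L, 6L, 3L, 4L))
  z23 <- zone_partition(23, "outside")
  expect_identical(as.integer(table(factor(z23$zone,
                                           levels = memtopo:::ZONES))),
                   c(5L, 3L, 7L, 3L, 5L))
  # zones tile the TMD for every length
  for (L in 5:40) {
    z <- zone_partition(L, "outside")
    expect_identical(nrow(z), L)
    expect_identical(sum(memtopo:::zone_sizes(L)), as.integer(L))
  }
  expect_error(zone_partition(4), "at least 5")
})

test_that("zone orientation follows the TMD's exoplasmic end", {
  zo <- zone_partition(20, "outside")
  zi <- zone_partition(20, "inside")
  expect_identical(zo$zone[1], "exo_interface")
  expect_identical(zi$zone[1], "cyt_interface")
  expect_identical(zi$zone, rev(zo$zone))
  expect_equal(zi$depth, rev(zo$depth))
  # residue centers never sit on a zone boundary
  expect_false(any(zo$depth %in% c(0.2, 0.35, 0.65, 0.8)))
})

test_that("charge dot map records fractional depths and zones", {
  # 20-aa TMD, N-terminal end exoplasmic, K at position 2 from that end
  tmd <- paste0("A", "K", strrep("L", 18))
  rec <- mk_record(1, c(10L, 60L), "outside", tmd_len = 20L,
                   tmd_seqs = list("1" = tmd))
  dm <- charge_dot_map(census_table(list(rec)))
  expect_identical(nrow(dm), 1L)
  expect_equal(dm$depth, (2 - 0.5) / 20)
  expect_identical(dm$zone, "exo_interface")
  # same TMD in the flipped orientation: depth measured from the other end
  rec2 <- mk_record(1, c(10L, 60L), "inside", tmd_len = 20L,
                    tmd_seqs = list("1" = tmd))
  dm2 <- charge_dot_map(census_table(list(rec2)))
  expect_equal(dm2$depth, (19 - 0.5) / 20)
  # charge-free TMD: no entries
  none <- mk_record(1, c(10L, 60L), "outside")
  expect_identical(nrow(charge_dot_map(census_table(list(none)))), 0L)
})

test_that("dot-map subsampling is seeded, sized and reproducible", {
  tab <- small_proteome(n = 30, seed = 2)
  all_tmds <- do.call(rbind, lapply(seq_along(tab$records), function(r) {
    data.frame(rec = r, tmd = seq_len(nrow(tab$records[[r]]$tmds)))
  }))
  n <- 25L
  a <- charge_dot_map(tab, n = n, seed = 99)
  b <- charge_dot_map(tab, n = n, seed = 99)
  expect_identical(a, b)
  expect_lte(length(unique(paste(a$accession, a$tmd))), n)
  expect_error(charge_dot_map(tab, n = 10), "seed")
  expect_error(charge_dot_map(tab, n = nrow(all_tmds) + 1L, seed = 1),
               "exceeds")
})

test_that("zone charge summaries count, never divide by zero", {
  # one K and one E in the core of an otherwise neutral TMD
  tmd <- paste0(strrep("L", 8), "K", "E", strrep("L", 10))
  rec <- mk_record(1, c(10L, 60L), "outside", tmd_len = 20L,
                   tmd_seqs = list("1" = tmd))
  zs <- zone_charge_summary(census_table(list(rec)))
  core <- zs[zs$zone == "core", ]
  expect_identical(core$ratio, "1.00:1")
  expect_equal(core$density_pct, 100 * 2 / 12)
  expect_true(all(zs$density_pct <= 100, na.rm = TRUE))
  # positive-only zone reports "n:0"
  tmd2 <- paste0(strrep("L", 9), "R", strrep("L", 10))
  rec2 <- mk_record(1, c(10L, 60L), "outside", tmd_len = 20L,
                    tmd_seqs = list("1" = tmd2))
  zs2 <- zone_charge_summary(census_table(list(rec2)))
  expect_identical(zs2$ratio[zs2$zone == "core"], "1:0")
})

test_that("zone charge counts conserve the TMD totals", {
  tab <- small_proteome(n = 25, seed = 31)
  zs <- zone_charge_summary(tab)
  by_zone <- zs[zs$zone %in% memtopo:::ZONES, ]
  total_charged <- sum(vapply(tab$records, function(rec) {
    sum(strsplit(paste(rec$tmds$sequence, collapse = ""), "")[[1]] %in%
        c("K", "R", "D", "E"))
  }, 0))
  expect_equal(sum(by_zone$n_pos) + sum(by_zone$n_neg), total_charged)
})

test_that("flank net charges count K/R minus D/E within the window", {
  # N_cyt single TMD; N-tail (inside) carries the charges adjacent to the TMD
  rec <- mk_record(1, c(5L, 60L), "inside", loop_seqs = list("1" = "GASGG"))
  expect_equal(as.numeric(flank_net_charge(rec, 1, "inside", 5)), 0)
  rec2 <- mk_record(1, c(5L, 60L), "inside", loop_seqs = list("1" = "GRKAS"))
  expect_equal(as.numeric(flank_net_charge(rec2, 1, "inside", 5)), 2)
  # only the window-adjacent residues count
  rec3 <- mk_record(1, c(8L, 60L), "inside",
                    loop_seqs = list("1" = "RRRGASGG"))
  expect_equal(as.numeric(flank_net_charge(rec3, 1, "inside", 5)), 0)
  # the whole 8-aa flank counts at W = 10 (scaled 3 * 10/8 by default)
  expect_equal(as.numeric(flank_net_charge(rec3, 1, "inside", 10,
                                           proportional = FALSE)), 3)
  expect_equal(as.numeric(flank_net_charge(rec3, 1, "inside", 10)),
               3 * 10 / 8)
  expect_error(flank_net_charge(rec3, 1, "lumenal", 5), "side")
})

test_that("short flanks scale proportionally and keep their sign", {
  rec <- mk_record(1, c(2L, 60L), "inside", loop_seqs = list("1" = "RK"))
  v <- flank_net_charge(rec, 1, "inside", 10)
  expect_equal(as.numeric(v), 2 * 10 / 2)
  expect_true(attr(v, "scaled"))
  v2 <- flank_net_charge(rec, 1, "inside", 10, proportional = FALSE)
  expect_equal(as.numeric(v2), 2)
  expect_false(attr(v2, "scaled"))
  # zero-length flank contributes zero
  rec0 <- mk_record(1, c(0L, 60L), "inside")
  expect_equal(as.numeric(flank_net_charge(rec0, 1, "inside", 10)), 0)
  # scaling never flips the sign
  set.seed(12)
  for (i in 1:20) {
    L <- sample(1:9, 1)
    loop <- paste(sample(c("G", "K", "R", "D", "E"), L, replace = TRUE),
                  collapse = "")
    r <- mk_record(1, c(L, 60L), "inside",
                   loop_seqs = setNames(list(loop), "1"))
    raw <- flank_net_charge(r, 1, "inside", 10, proportional = FALSE)
    sc <- flank_net_charge(r, 1, "inside", 10)
    expect_identical(sign(as.numeric(sc)), sign(as.numeric(raw)))
  }
})

test_that("combined charge adds the interfacial zone to the 10-aa flank", {
  # R in the cytosolic interfacial zone, D in the cytosolic flank: net 0
  tmd <- paste0(strrep("L", 19), "R") # N_exo: position 20 is cytosolic face
  rec <- mk_record(1, c(10L, 60L), "outside", tmd_len = 20L,
                   tmd_seqs = list("1" = tmd),
                   loop_seqs = list("2" = paste0("GDGGG", strrep("G", 55))))
  expect_equal(combined_flank_charge(rec, 1, "inside"), 0)
  # reduces to the flank charge when the interfacial zone is charge-free
  rec2 <- mk_record(1, c(10L, 60L), "outside", tmd_len = 20L,
                    loop_seqs = list("2" = paste0("GDGGG", strrep("G", 55))))
  expect_equal(combined_flank_charge(rec2, 1, "inside"),
               as.numeric(flank_net_charge(rec2, 1, "inside", 10)))
  # no charges anywhere: zero
  expect_equal(combined_flank_charge(mk_record(1, c(10L, 60L), "outside"),
                                     1, "inside"), 0)
})

test_that("pair charge bias sums the unit, loop included without truncation", {
  # uncharged pair
  r0 <- mk_record(2, c(10L, 8L, 60L), "inside")
  p0 <- find_tmd_pairs(r0)
  b0 <- pair_charge_bias(r0, p0[1, ])
  expect_equal(b0$inside_bias, 0)
  expect_equal(b0$outside_bias, 0)
  # exoplasmic loop NDTE with charge-free interfaces: outside bias -2
  r1 <- mk_record(2, c(10L, 4L, 60L), "inside",
                  loop_seqs = list("2" = "NDTE"))
  p1 <- find_tmd_pairs(r1)
  b1 <- pair_charge_bias(r1, p1[1, ])
  expect_equal(b1$outside_bias, -2)
  # inside bias equals the sum of the two per-TMD combined inside charges
  tab <- small_proteome(n = 20, seed = 41)
  for (rec in tab$records) {
    seg <- deduce_segments(rec)
    pr <- find_tmd_pairs(rec, seg)
    for (p in seq_len(nrow(pr))) {
      b <- pair_charge_bias(rec, pr[p, ], seg)
      expect_equal(b$inside_bias,
                   combined_flank_charge(rec, pr$first[p], "inside", seg) +
                   combined_flank_charge(rec, pr$second[p], "inside", seg))
    }
  }
})

test_that("flipping a record's orientation swaps inside and outside biases", {
  tab <- small_proteome(n = 15, seed = 51)
  for (rec in tab$records) {
    if (!is.null(rec$signal)) next # orientation is forced by the signal
    flipped <- rec
    flipped$n_terminus_side <- if (rec$n_terminus_side == "inside")
      "outside" else "inside"
    seg <- deduce_segments(rec)
    fseg <- deduce_segments(flipped)
    for (k in seq_len(nrow(rec$tmds))) {
      for (w in c(5L, 10L, 15L)) {
        expect_equal(
          as.numeric(flank_net_charge(rec, k, "inside", w, seg)),
          as.numeric(flank_net_charge(flipped, k, "outside", w, fseg)))
      }
      expect_equal(combined_flank_charge(rec, k, "inside", seg),
                   combined_flank_charge(flipped, k, "outside", fseg))
    }
  }
})
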