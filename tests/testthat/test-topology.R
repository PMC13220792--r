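test_that("protein classes follow the Type I-IV / multipass rules", {
  expect_identical(classify_protein(mk_record(1, c(30L, 40L), "outside",
                                              signal_len = 20L)), "SP-I")
  # TA boundary: C-tail of exactly 50 aa is tail-anchored, 51 is Type II
  expect_identical(classify_protein(mk_record(1, c(30L, 50L), "inside")),
                   "SP-IV")
  expect_identical(classify_protein(mk_record(1, c(30L, 51L), "inside")),
                   "SP-II")
  expect_identical(classify_protein(mk_record(1, c(30L, 30L), "outside")),
                   "SP-III")
  expect_identical(classify_protein(mk_record(4, rep(9L, 5L), "outside",
                                              signal_len = 18L)), "MP-SS")
  expect_identical(classify_protein(mk_record(4, rep(9L, 5L), "outside")),
                   "MP-Nexo")
  expect_identical(classify_protein(mk_record(4, rep(9L, 5L), "inside")),
                   "MP-Ncyt")
})

test_that("loop length classes use the 50/100 bin edges", {
  expect_identical(classify_loop(c(0, 50, 51, 100, 101)),
                   c("short", "short", "intermediate", "intermediate",
                     "long"))
})

test_that("greedy pairing reproduces the GPCR and even-N_cyt shapes", {
  # N_exo 7-TMD, all internal loops short: TMD1 unpaired, pairs (2,3)(4,5)(6,7)
  gpcr <- mk_record(7, rep(8L, 8L), "outside")
  p <- find_tmd_pairs(gpcr)
  expect_identical(p$first, c(2L, 4L, 6L))
  expect_identical(p$second, c(3L, 5L, 7L))
  # N_cyt 6-TMD, all loops 10 aa: pairs (1,2)(3,4)(5,6) with contexts
  ncyt <- mk_record(6, rep(10L, 7L), "inside")
  p2 <- find_tmd_pairs(ncyt)
  expect_identical(p2$first, c(1L, 3L, 5L))
  expect_identical(p2$context, c("first_pair", "internal_after_short_cyt",
                                 "internal_after_short_cyt"))
  # single-pass: no pairs
  expect_identical(nrow(find_tmd_pairs(mk_record(1, c(5L, 60L), "inside"))),
                   0L)
  # long exoplasmic loop breaks pairing; the pair after a long cytosolic
  # loop is tagged after_long_cyt
  r <- mk_record(4, c(5L, 10L, 150L, 10L, 5L), "inside")
  p3 <- find_tmd_pairs(r)
  expect_identical(p3$first, c(1L, 3L))
  expect_identical(p3$context, c("first_pair", "after_long_cyt"))
  # intermediate (51-100 aa) preceding cytosolic loop is its own context
  r2 <- mk_record(4, c(5L, 10L, 70L, 10L, 5L), "inside")
  expect_identical(find_tmd_pairs(r2)$context,
                   c("first_pair", "after_intermediate_cyt"))
  # no TMD may sit in two pairs
  tab <- small_proteome(n = 40, seed = 13)
  for (rec in tab$records) {
    p <- find_tmd_pairs(rec)
    expect_identical(anyDuplicated(c(p$first, p$second)), 0L)
  }
})

test_that("signal-anchor classes follow the translocated-domain rules", {
  expect_identical(classify_sa(mk_record(1, c(30L, 40L), "outside")),
                   "Nexo_SA")
  # MP-Ncyt with a 150-aa exoplasmic loop after TMD1
  long1 <- mk_record(2, c(10L, 150L, 10L), "inside")
  expect_identical(classify_sa(long1), "Ncyt_long_SA")
  # MP-Ncyt with a 12-aa exoplasmic loop after TMD1: part of a pair
  pair1 <- mk_record(2, c(10L, 12L, 10L), "inside")
  expect_identical(classify_sa(pair1), "Ncyt_pair_SA")
  # intermediate translocated domain
  mid1 <- mk_record(2, c(10L, 70L, 10L), "inside")
  expect_identical(classify_sa(mid1), "SA_other")
  # Type II single-pass: the C-tail is the translocated domain
  sp2 <- mk_record(1, c(10L, 120L), "inside")
  expect_identical(classify_sa(sp2), "Ncyt_long_SA")
  expect_identical(classify_sa(mk_record(1, c(10L, 70L), "inside")),
                   "SA_other")
  # excluded inputs
  expect_error(classify_sa(mk_record(1, c(30L, 60L), "outside",
                                     signal_len = 20L)), "signal")
  expect_error(classify_sa(mk_record(1, c(30L, 20L), "inside")),
               "tail-anchored")
})

test_that("insertion reactions cover the six core routes", {
  expect_identical(classify_reactions(mk_record(1, c(30L, 40L), "outside",
                                                signal_len = 20L))$reaction,
                   "R1")
  expect_identical(classify_reactions(mk_record(1, c(30L, 20L),
                                                "inside"))$reaction, "R4")
  expect_identical(classify_reactions(mk_record(1, c(30L, 40L),
                                                "outside"))$reaction, "R3")
  expect_identical(classify_reactions(mk_record(1, c(10L, 120L),
                                                "inside"))$reaction, "R2")
  # MP-Ncyt 6-TMD all-short loops: alternating R6a/R6b
  ncyt <- mk_record(6, rep(10L, 7L), "inside")
  expect_identical(classify_reactions(ncyt)$reaction,
                   rep(c("R6a", "R6b"), 3))
  # two TMDs flanking a long exoplasmic loop are R5a/R5b
  r <- mk_record(4, c(5L, 10L, 10L, 150L, 5L), "outside")
  # sides: seg1 out, seg2 in, seg3 out(10), seg4 in... need the long loop
  # exoplasmic; use N_cyt so segment 4 (between TMD3 and TMD4) is outside
  r <- mk_record(4, c(5L, 10L, 10L, 150L, 5L), "inside")
  rx <- classify_reactions(r)$reaction
  expect_identical(rx[3], "R5a")
  expect_identical(rx[4], "R5b")
  # multipass with a signal: TMD1 is R1, downstream pair rules apply
  mpss <- mk_record(3, c(20L, 30L, 8L, 10L), "outside", signal_len = 18L)
  # seg2 (after TMD1) inside, seg3 outside 8 aa -> pair (2,3)
  expect_identical(classify_reactions(mpss)$reaction, c("R1", "R6a", "R6b"))
  # an N_cyt-long SA followed by the long loop's terminating TMD: R2 then R5b
  mpl <- mk_record(2, c(10L, 150L, 10L), "inside")
  expect_identical(classify_reactions(mpl)$reaction, c("R2", "R5b"))
  # every TMD gets exactly one label
  tab <- small_proteome(n = 40, seed = 17)
  for (rec in tab$records) {
    rx <- classify_reactions(rec)
    expect_false(anyNA(rx$reaction))
  }
})

test_that("context tags mark the analysis strata", {
  sp1 <- mk_record(1, c(30L, 40L), "outside", signal_len = 20L)
  expect_true(classify_tmd_context(sp1)$ss_following[1])
  # 4-TMD N_cyt: loops (seg2) short exo, (seg3) 150 cyt, (seg4) short exo:
  # TMD3 is pair-first in the after_long_cyt context
  r <- mk_record(4, c(5L, 10L, 150L, 10L, 5L), "inside")
  ctx <- classify_tmd_context(r)
  expect_identical(ctx$pair_role[3], "first")
  expect_identical(ctx$pair_context[3], "after_long_cyt")
  expect_true(ctx$terminal_mp[4])
  # TMDs flanking a 130-aa exoplasmic loop
  r2 <- mk_record(3, c(5L, 10L, 130L, 5L), "outside")
  ctx2 <- classify_tmd_context(r2)
  expect_identical(ctx2$long_exo_role[2], "first")
  expect_identical(ctx2$long_exo_role[3], "second")
  # the TMD after an N_cyt-long SA is tagged
  mpl <- mk_record(2, c(10L, 150L, 10L), "inside")
  expect_true(classify_tmd_context(mpl)$after_ncyt_long_sa[2])
})

test_that("topology labels are internally consistent on generated data", {
  tab <- small_proteome(n = 50, seed = 23)
  classes <- c("SP-I", "SP-II", "SP-III", "SP-IV", "MP-SS", "MP-Nexo",
               "MP-Ncyt")
  for (rec in tab$records) {
    lab <- topology_labels(rec)
    expect_true(lab$protein_class %in% classes)
    expect_identical(nrow(lab$reactions), nrow(rec$tmds))
    # paired TMDs carry R6a/R6b as first/second unless TMD1 carries an SA
    # or SS reaction
    if (nrow(lab$pairs)) {
      for (p in seq_len(nrow(lab$pairs))) {
        i <- lab$pairs$first[p]
        if (i > 1L) {
          expect_identical(lab$reactions$reaction[i], "R6a")
        }
        expect_true(lab$reactions$reaction[lab$pairs$second[p]] %in%
                    c("R6b"))
      }
    }
  }
})
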