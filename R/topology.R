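#' Topology class of a protein
#'
#' Single-pass proteins with a cleavable signal are Type I (`SP-I`); signal
#' anchors are Type II (`SP-II`, N_cyt with a C-tail > 50 aa), Type III
#' (`SP-III`, N_exo), or Type IV tail-anchored (`SP-IV`, N_cyt with a C-tail
#' <= 50 aa).  Multipass proteins are `MP-SS` (cleavable signal), `MP-Nexo`
#' or `MP-Ncyt` by the side of the N terminus.
#'
#' @param record A [protein_record()].
#' @param segments Segments with sides from [deduce_segments()].
#' @return One of `"SP-I"`, `"SP-II"`, `"SP-III"`, `"SP-IV"`, `"MP-SS"`,
#'   `"MP-Nexo"`, `"MP-Ncyt"`.
#' @export
classify_protein <- function(record, segments = deduce_segments(record)) {
  n <- nrow(record$tmds)
  if (n == 0L) stop("record ", record$accession, " has no TMDs")
  has_ss <- !is.null(record$signal)
  if (n == 1L) {
    if (has_ss) return("SP-I")
    if (record$n_terminus_side == "outside") return("SP-III")
    c_tail <- segments$length[2L]
    if (c_tail <= 50L) "SP-IV" else "SP-II"
  } else {
    if (has_ss) return("MP-SS")
    if (record$n_terminus_side == "outside") "MP-Nexo" else "MP-Ncyt"
  }
}

#' Loop length class
#'
#' @param length Loop length(s) in aa.
#' @return `"short"` (<= 50 aa), `"intermediate"` (51-100 aa) or `"long"`
#'   (> 100 aa); vectorized.
#' @export
classify_loop <- function(length) {
  ifelse(length <= 50L, "short",
         ifelse(length <= 100L, "intermediate", "long"))
}

#' Find TMD pairs
#'
#' A TMD pair is two TMDs separated by a short (<= 50 aa) exoplasmic loop,
#' treated as one insertion unit.  Pairing is greedy left-to-right: walking
#' the TMDs in order, TMD i and TMD i+1 form a pair iff the loop between them
#' is exoplasmic and <= 50 aa and TMD i is not already the second member of a
#' pair.  Because loop sides alternate, greedy pairing can never orphan a TMD
#' between two qualifying loops.  Each pair carries a context from its
#' preceding cytosolic flank: `first_pair` (TMD1-TMD2),
#' `internal_after_short_cyt` (preceding cytosolic loop <= 50 aa),
#' `after_long_cyt` (> 100 aa), or `after_intermediate_cyt` (51-100 aa, kept
#' distinct and excluded from the short/long contrasts).
#'
#' @param record A [protein_record()].
#' @param segments Segments with sides.
#' @return Data frame with columns `first`, `second` (TMD indices),
#'   `loop_ordinal`, `loop_length`, `context`.  Empty for single-pass
#'   proteins.
#' @export
find_tmd_pairs <- function(record, segments = deduce_segments(record)) {
  n <- nrow(record$tmds)
  out <- data.frame(first = integer(), second = integer(),
                    loop_ordinal = integer(), loop_length = integer(),
                    context = character(), stringsAsFactors = FALSE)
  if (n < 2L) return(out)
  paired <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    if (paired[i]) next
    loop <- segments[i + 1L, ] # segment between TMD i and TMD i+1
    if (loop$side != "outside" || loop$length > 50L) next
    context <- if (i == 1L) {
      "first_pair"
    } else {
      prev <- segments$length[i] # preceding cytosolic loop (sides alternate)
      if (prev <= 50L) "internal_after_short_cyt"
      else if (prev > 100L) "after_long_cyt"
      else "after_intermediate_cyt"
    }
    out[nrow(out) + 1L, ] <- list(i, i + 1L, i + 1L, loop$length, context)
    paired[i] <- paired[i + 1L] <- TRUE
  }
  out
}

#' Signal-anchor class of the first TMD
#'
#' Applies to cotranslationally targeted signal-anchor proteins only, i.e.,
#' proteins without a cleavable signal that are not tail-anchored.  The first
#' TMD is `Nexo_SA` when the N terminus is exoplasmic; otherwise `Ncyt_pair_SA`
#' when TMD1 is part of a TMD pair, `Ncyt_long_SA` when the translocated
#' segment downstream of TMD1 (the exoplasmic loop or tail that follows it)
#' is > 100 aa, and `SA_other` for the intermediate 51-100 aa translocated
#' domains that plausibly access either insertion route.
#'
#' @param record A [protein_record()].
#' @param segments Segments with sides.
#' @param pairs Result of [find_tmd_pairs()].
#' @return One of `"Nexo_SA"`, `"Ncyt_long_SA"`, `"Ncyt_pair_SA"`,
#'   `"SA_other"`.
#' @export
classify_sa <- function(record, segments = deduce_segments(record),
                        pairs = find_tmd_pairs(record, segments)) {
  if (!is.null(record$signal)) {
    stop("classify_sa() applies to signal-anchor proteins, not to ",
         "signal-sequence-bearing ", record$accession)
  }
  pclass <- classify_protein(record, segments)
  if (pclass == "SP-IV") {
    stop("classify_sa() excludes tail-anchored proteins ",
         "(posttranslational route): ", record$accession)
  }
  if (record$n_terminus_side == "outside") return("Nexo_SA")
  if (nrow(pairs) > 0L && any(pairs$first == 1L)) return("Ncyt_pair_SA")
  downstream <- segments$length[2L] # exoplasmic loop/tail after TMD1
  if (downstream > 100L) "Ncyt_long_SA" else "SA_other"
}

#' Core insertion reaction of every TMD
#'
#' Maps each TMD to one of six core membrane-insertion reactions:
#' R1 (TMD following a signal-sequence-translocated domain; Sec61 lateral
#' gate), R2 (N_cyt signal anchor with a long translocated downstream loop;
#' Sec61), R3 (N_exo signal anchor; Oxa1-family insertase), R4
#' (posttranslational tail-anchor insertion), R5a/R5b (two TMDs flanking a
#' long > 100 aa exoplasmic loop; Sec61), and R6a/R6b (first/second TMD of a
#' TMD pair; insertase/multipass translocon).  TMDs fitting none of these
#' (intermediate translocated domains, unpaired TMDs) are `residual`, with a
#' sub-reason in `detail`.  Earlier rules win: a TMD already labeled (for
#' example an R2 signal anchor preceding a long exoplasmic loop) is not
#' relabeled by the R5 rule.
#'
#' @param record A [protein_record()].
#' @param segments Segments with sides.
#' @param pairs Result of [find_tmd_pairs()].
#' @param protein_class,sa_class Precomputed labels (computed when `NULL`).
#' @return Data frame with columns `tmd`, `reaction`, `detail`.
#' @export
classify_reactions <- function(record, segments = deduce_segments(record),
                               pairs = find_tmd_pairs(record, segments),
                               protein_class = NULL, sa_class = NULL) {
  n <- nrow(record$tmds)
  if (is.null(protein_class)) protein_class <- classify_protein(record, segments)
  reaction <- rep(NA_character_, n)
  detail <- rep(NA_character_, n)

  if (protein_class == "SP-IV") {
    reaction[1L] <- "R4"
    detail[1L] <- "tail anchor, posttranslational"
  } else if (protein_class %in% c("SP-I", "MP-SS")) {
    reaction[1L] <- "R1"
    detail[1L] <- "TMD following the SS-translocated domain"
  } else {
    if (is.null(sa_class)) sa_class <- classify_sa(record, segments, pairs)
    reaction[1L] <- switch(sa_class,
                           Nexo_SA = "R3",
                           Ncyt_long_SA = "R2",
                           Ncyt_pair_SA = "R6a",
                           SA_other = "residual")
    detail[1L] <- switch(sa_class,
                         Nexo_SA = "N_exo signal anchor",
                         Ncyt_long_SA = "N_cyt signal anchor, long translocated loop",
                         Ncyt_pair_SA = "N_cyt signal anchor opening a TMD pair",
                         SA_other = "signal anchor with intermediate (51-100 aa) translocated domain")
  }
  if (nrow(pairs) > 0L) {
    for (p in seq_len(nrow(pairs))) {
      i <- pairs$first[p]; j <- pairs$second[p]
      if (is.na(reaction[i])) {
        reaction[i] <- "R6a"
        detail[i] <- paste0("first TMD of pair (", pairs$context[p], ")")
      }
      if (is.na(reaction[j])) {
        reaction[j] <- "R6b"
        detail[j] <- paste0("second TMD of pair (", pairs$context[p], ")")
      }
    }
  }
  if (n > 1L) {
    for (m in 2L:n) { # internal segment m sits between TMD m-1 and TMD m
      seg <- segments[m, ]
      if (seg$side == "outside" && seg$length > 100L) {
        if (is.na(reaction[m - 1L])) {
          reaction[m - 1L] <- "R5a"
          detail[m - 1L] <- "first TMD flanking a long exoplasmic loop"
        }
        if (is.na(reaction[m])) {
          reaction[m] <- "R5b"
          detail[m] <- "second TMD flanking a long exoplasmic loop"
        }
      }
    }
  }
  resid <- which(is.na(reaction))
  for (i in resid) {
    reaction[i] <- "residual"
    exo_flanks <- c(if (segments$side[i] == "outside") segments$length[i],
                    if (segments$side[i + 1L] == "outside")
                      segments$length[i + 1L])
    detail[i] <- if (length(exo_flanks) &&
                     any(exo_flanks > 50L & exo_flanks <= 100L)) {
      "unpaired TMD with intermediate exoplasmic flank"
    } else if (i == n) {
      "unpaired terminal TMD"
    } else {
      "unpaired TMD"
    }
  }
  data.frame(tmd = seq_len(n), reaction = reaction, detail = detail,
             stringsAsFactors = FALSE)
}

#' Analysis-stratum context tags for every TMD
#'
#' Tags each TMD with the strata used in downstream property summaries:
#' whether it follows a signal-sequence-translocated domain or an N_cyt-long
#' signal anchor, its role and context within a TMD pair, whether it flanks a
#' long (> 100 aa) exoplasmic loop, and whether it is the terminal C-terminal
#' TMD of a multipass protein.
#'
#' @inheritParams classify_reactions
#' @return Data frame with one row per TMD: `tmd`, `ss_following`,
#'   `after_ncyt_long_sa`, `pair_role` (`"first"`/`"second"`/`NA`),
#'   `pair_context`, `long_exo_role` (`"first"`/`"second"`/`NA`),
#'   `terminal_mp`.
#' @export
classify_tmd_context <- function(record, segments = deduce_segments(record),
                                 pairs = find_tmd_pairs(record, segments),
                                 protein_class = NULL, sa_class = NULL) {
  n <- nrow(record$tmds)
  if (is.null(protein_class)) protein_class <- classify_protein(record, segments)
  if (is.null(sa_class) &&
      protein_class %in% c("SP-II", "SP-III", "MP-Nexo", "MP-Ncyt")) {
    sa_class <- classify_sa(record, segments, pairs)
  }
  ctx <- data.frame(
    tmd = seq_len(n),
    ss_following = FALSE,
    after_ncyt_long_sa = FALSE,
    pair_role = NA_character_,
    pair_context = NA_character_,
    long_exo_role = NA_character_,
    terminal_mp = FALSE,
    stringsAsFactors = FALSE)
  if (protein_class %in% c("SP-I", "MP-SS")) ctx$ss_following[1L] <- TRUE
  if (!is.null(sa_class) && sa_class == "Ncyt_long_SA" && n >= 2L) {
    ctx$after_ncyt_long_sa[2L] <- TRUE
  }
  if (nrow(pairs) > 0L) {
    ctx$pair_role[pairs$first] <- "first"
    ctx$pair_role[pairs$second] <- "second"
    ctx$pair_context[pairs$first] <- pairs$context
    ctx$pair_context[pairs$second] <- pairs$context
  }
  if (n > 1L) {
    for (m in 2L:n) {
      if (segments$side[m] == "outside" && segments$length[m] > 100L) {
        ctx$long_exo_role[m - 1L] <- "first"
        ctx$long_exo_role[m] <- "second"
      }
    }
    ctx$terminal_mp[n] <- TRUE
  }
  ctx
}

#' Full topology labels for one record
#'
#' Convenience wrapper assembling the protein class, signal-anchor class,
#' TMD pairs, per-loop length classes, per-TMD insertion reactions and
#' context tags for one protein.
#'
#' @param record A [protein_record()].
#' @param segments Segments with sides (computed when omitted).
#' @return An object of class `topology_labels`.
#' @export
topology_labels <- function(record, segments = deduce_segments(record)) {
  protein_class <- classify_protein(record, segments)
  pairs <- find_tmd_pairs(record, segments)
  sa_class <- if (protein_class %in% c("SP-II", "SP-III", "MP-Nexo",
                                       "MP-Ncyt")) {
    classify_sa(record, segments, pairs)
  } else NA_character_
  structure(list(
    accession = record$accession,
    protein_class = protein_class,
    sa_class = sa_class,
    pairs = pairs,
    loop_classes = data.frame(ordinal = segments$ordinal,
                              kind = segments$kind,
                              side = segments$side,
                              length = segments$length,
                              class = classify_loop(segments$length),
                              stringsAsFactors = FALSE),
    reactions = classify_reactions(record, segments, pairs,
                                   protein_class,
                                   if (is.na(sa_class)) NULL else sa_class),
    context = classify_tmd_context(record, segments, pairs,
                                   protein_class,
                                   if (is.na(sa_class)) NULL else sa_class)
  ), class = "topology_labels")
}

#' @export
print.topology_labels <- function(x, ...) {
  cat(sprintf("<%s> class %s%s; %d TMD pair(s); reactions: %s\n",
              x$accession, x$protein_class,
              if (!is.na(x$sa_class)) paste0(" (", x$sa_class, ")") else "",
              nrow(x$pairs),
              paste(x$reactions$reaction, collapse = ",")))
  invisible(x)
}
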