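#' Run the full topology census on a table
#'
#' The main entry point: from a validated census table it deduces loops and
#' tails, fills in missing dG_app values, classifies every protein and TMD
#' (topology class, signal-anchor class, TMD pairs, insertion reactions,
#' context strata), computes flanking and interfacial charges, and aggregates
#' the census summary.
#'
#' @param table A `census_table` from [parse_census_table()],
#'   [census_table()] or [generate_proteome()].
#' @param scale A [dg_scale()] object.
#' @param rescore Recompute all dG_app values instead of keeping recorded
#'   ones (see [score_all_tmds()]).
#' @param windows Flanking-charge window widths in residues.
#' @param sequon_min_distance Minimal distance (aa) between a usable
#'   N-glycosylation sequon and any TMD.
#' @param proportional Scale flank charges of short flanks by `W/L`
#'   (see [flank_net_charge()]).
#' @param strict_sequon Use the N!P(ST) sequon motif (Pro disallowed at the
#'   second position); `FALSE` gives plain NX(ST).
#' @return An object of class `memtopo_census` with components `table`
#'   (dG-scored census table), `segments`, `labels`, `tmd_table` (one row per
#'   TMD with all labels), `seg_table` (one row per loop/tail),
#'   `pairs` (all TMD pairs with unit charge biases), `flank_charges`
#'   (per TMD x side x window), `sequons`, `params`, and `summary`
#'   (see [census_report()]).
#' @examples
#' gp <- generate_proteome(default_config(n_proteins = 30), seed = 1)
#' cs <- memtopo_census(gp$table)
#' cs
#' @export
memtopo_census <- function(table, scale = dg_scale(), rescore = FALSE,
                           windows = c(5L, 10L, 15L),
                           sequon_min_distance = 12L,
                           proportional = TRUE,
                           strict_sequon = TRUE) {
  stopifnot(inherits(table, "census_table"))
  table <- score_all_tmds(table, scale, rescore = rescore)
  records <- table$records
  nrec <- length(records)
  segments <- lapply(records, deduce_segments)
  labels <- vector("list", nrec)
  tmd_rows <- vector("list", nrec)
  seg_rows <- vector("list", nrec)
  pair_rows <- vector("list", nrec)
  flank_rows <- vector("list", nrec)
  sequon_rows <- vector("list", nrec)

  for (r in seq_len(nrec)) {
    rec <- records[[r]]
    seg <- segments[[r]]
    lab <- topology_labels(rec, seg)
    labels[[r]] <- lab
    ntm <- nrow(rec$tmds)
    sp <- startsWith(lab$protein_class, "SP")

    ctx <- lab$context
    tmd_rows[[r]] <- data.frame(
      rec = r, accession = rec$accession, tmd = seq_len(ntm),
      start = rec$tmds$start, end = rec$tmds$end,
      length = rec$tmds$end - rec$tmds$start + 1L,
      sequence = rec$tmds$sequence,
      dg_app = rec$tmds$dg_app,
      protein_class = lab$protein_class, single_pass = sp,
      sa_class = ifelse(seq_len(ntm) == 1L, lab$sa_class, NA_character_),
      reaction = lab$reactions$reaction,
      reaction_detail = lab$reactions$detail,
      ss_following = ctx$ss_following,
      after_ncyt_long_sa = ctx$after_ncyt_long_sa,
      pair_role = ctx$pair_role, pair_context = ctx$pair_context,
      long_exo_role = ctx$long_exo_role, terminal_mp = ctx$terminal_mp,
      n_end_side = seg$side[seq_len(ntm)],
      stringsAsFactors = FALSE)

    seg_rows[[r]] <- cbind(
      data.frame(rec = r, accession = rec$accession,
                 protein_class = lab$protein_class, single_pass = sp,
                 stringsAsFactors = FALSE),
      lab$loop_classes)

    if (nrow(lab$pairs)) {
      bias <- lapply(seq_len(nrow(lab$pairs)), function(p) {
        pair_charge_bias(rec, lab$pairs[p, ], seg, proportional)
      })
      pair_rows[[r]] <- cbind(
        data.frame(rec = r, accession = rec$accession,
                   stringsAsFactors = FALSE),
        lab$pairs,
        data.frame(inside_bias = vapply(bias, `[[`, 0, "inside_bias"),
                   outside_bias = vapply(bias, `[[`, 0, "outside_bias")))
    }

    fl <- expand.grid(tmd = seq_len(ntm), side = c("inside", "outside"),
                      window = as.integer(windows),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    fl$net <- NA_real_
    fl$scaled <- FALSE
    for (q in seq_len(nrow(fl))) {
      v <- flank_net_charge(rec, fl$tmd[q], fl$side[q], fl$window[q], seg,
                            proportional)
      fl$net[q] <- as.numeric(v)
      fl$scaled[q] <- attr(v, "scaled")
    }
    cmb <- expand.grid(tmd = seq_len(ntm), side = c("inside", "outside"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cmb$window <- NA_integer_
    cmb$net <- vapply(seq_len(nrow(cmb)), function(q) {
      combined_flank_charge(rec, cmb$tmd[q], cmb$side[q], seg, proportional)
    }, 0)
    cmb$scaled <- FALSE
    cmb <- cmb[, c("tmd", "side", "window", "net", "scaled")]
    flank_rows[[r]] <- cbind(
      data.frame(rec = r, accession = rec$accession,
                 stringsAsFactors = FALSE),
      rbind(fl, cmb))

    sq <- find_sequons(rec, seg, min_tmd_distance = sequon_min_distance,
                       strict = strict_sequon)
    if (nrow(sq)) {
      sequon_rows[[r]] <- cbind(
        data.frame(rec = r, accession = rec$accession, single_pass = sp,
                   stringsAsFactors = FALSE),
        sq)
    }
  }

  rbind_or_empty <- function(rows, proto) {
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) do.call(rbind, rows) else proto
  }
  obj <- structure(list(
    table = table,
    segments = segments,
    labels = labels,
    tmd_table = rbind_or_empty(tmd_rows, NULL),
    seg_table = rbind_or_empty(seg_rows, NULL),
    pairs = rbind_or_empty(pair_rows,
      data.frame(rec = integer(), accession = character(), first = integer(),
                 second = integer(), loop_ordinal = integer(),
                 loop_length = integer(), context = character(),
                 inside_bias = numeric(), outside_bias = numeric())),
    flank_charges = rbind_or_empty(flank_rows, NULL),
    sequons = rbind_or_empty(sequon_rows,
      data.frame(rec = integer(), accession = character(),
                 single_pass = logical(), pos = integer(),
                 motif = character(), side = character(),
                 tmd_distance = integer(), usable = logical())),
    params = list(windows = as.integer(windows),
                  sequon_min_distance = as.integer(sequon_min_distance),
                  proportional = proportional,
                  strict_sequon = strict_sequon,
                  rescore = rescore,
                  scale = scale$provenance)
  ), class = "memtopo_census")
  obj$summary <- census_report(obj)
  obj
}

#' @export
print.memtopo_census <- function(x, ...) {
  s <- x$summary
  cat("memtopo census\n")
  cat(sprintf("  proteins: %d (%d single-pass, %d multipass)\n",
              s$totals$proteins, s$totals$single_pass, s$totals$multipass))
  cat(sprintf("  TMDs:     %d (mean length %.1f aa; mean dG_app %s)\n",
              s$totals$tmds, s$totals$mean_tmd_length,
              if (is.na(s$totals$mean_dg)) "unavailable"
              else sprintf("%+.2f kcal/mol", s$totals$mean_dg)))
  cat(sprintf("  TMD pairs: %d\n", nrow(x$pairs)))
  cat("  classes: ",
      paste(names(s$class_counts), s$class_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.memtopo_census <- function(object, ...) object$summary

#' Plot a census overview
#'
#' Two base-graphics panels: the dG_app histogram of all TMDs (single-pass
#' versus multipass) and the charged-residue depth map across the schematic
#' membrane.
#'
#' @param x A `memtopo_census`.
#' @param which `"dg"`, `"dotmap"`, or both.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.memtopo_census <- function(x, which = c("dg", "dotmap"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1L) {
    op <- par(mfrow = c(1, length(which)))
    on.exit(par(op))
  }
  if ("dg" %in% which) {
    dg <- x$tmd_table$dg_app
    sp <- x$tmd_table$single_pass
    br <- pretty(range(dg, na.rm = TRUE), 30)
    hist(dg[sp], breaks = br, col = adjustcolor("steelblue", 0.6),
         main = "TMD hydrophobicity", xlab = "dG_app (kcal/mol)")
    hist(dg[!sp], breaks = br, col = adjustcolor("firebrick", 0.5),
         add = TRUE)
    abline(v = 0, lty = 2)
    legend("topright", fill = c("steelblue", "firebrick"),
           legend = c("single-pass", "multipass"), bty = "n")
  }
  if ("dotmap" %in% which) {
    dm <- charge_dot_map(x$table)
    cols <- c(R = "navy", K = "skyblue3", E = "darkred", D = "salmon")
    plot(NA, xlim = c(0, 1), ylim = c(1, 0), xlab = "",
         ylab = "fractional depth (exoplasmic -> cytosolic)",
         main = "charged residues in TMDs", xaxt = "n")
    rect(0, 0.8, 1, 0.2, col = adjustcolor("wheat", 0.5), border = NA)
    abline(h = c(0.2, 0.8), lty = 3)
    if (nrow(dm)) {
      points(runif(nrow(dm)), dm$depth, pch = 16, cex = 0.4,
             col = cols[dm$residue])
    }
    legend("bottomright", pch = 16, col = cols, legend = names(cols),
           bty = "n", horiz = TRUE)
  }
  invisible(x)
}
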