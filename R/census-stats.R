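#' Find N-glycosylation sequons and their topologic usability
#'
#' Scans a protein for the sequon motif N-X-[S/T] (with X != P in the default
#' strict form, `N!P(ST)`; plain `NX(ST)` when `strict = FALSE`).  The sequon
#' position is the Asn.  A sequon is usable only when the Asn lies in an
#' exoplasmic (outside) segment and at least `min_tmd_distance` residues away
#' from every TMD; distance to a TMD counts residues between the Asn and the
#' nearest TMD residue, so an Asn immediately adjacent to a TMD has
#' distance 1.
#'
#' @param record A [protein_record()].
#' @param segments Segments with sides.
#' @param min_tmd_distance Usability threshold in aa (default 12).
#' @param strict Disallow Pro at the second motif position (default `TRUE`).
#' @return Data frame: `pos`, `motif` (the three residues), `side` (side of
#'   the segment holding the Asn, or `"tmd"`/`"signal"`), `tmd_distance`,
#'   `usable`.
#' @export
find_sequons <- function(record, segments = deduce_segments(record),
                         min_tmd_distance = 12L, strict = TRUE) {
  chars <- split_chars(record$sequence)
  L <- length(chars)
  empty <- data.frame(pos = integer(), motif = character(),
                      side = character(), tmd_distance = integer(),
                      usable = logical(), stringsAsFactors = FALSE)
  if (L < 3L) return(empty)
  p <- which(chars == "N")
  p <- p[p <= L - 2L]
  p <- p[chars[p + 2L] %in% c("S", "T")]
  if (strict) p <- p[chars[p + 1L] != "P"]
  if (!length(p)) return(empty)

  region_of <- function(pos) {
    if (!is.null(record$signal) && pos <= record$signal[2L]) return("signal")
    tm <- record$tmds
    if (nrow(tm) && any(pos >= tm$start & pos <= tm$end)) return("tmd")
    hit <- which(segments$length > 0L & pos >= segments$start &
                 pos <= segments$end)
    if (length(hit)) segments$side[hit[1L]] else "unassigned"
  }
  tm <- record$tmds
  dist_to_tmds <- function(pos) {
    if (!nrow(tm)) return(Inf)
    d <- ifelse(pos < tm$start, tm$start - pos,
                ifelse(pos > tm$end, pos - tm$end, 0L))
    min(d)
  }
  side <- vapply(p, region_of, "")
  dist <- vapply(p, dist_to_tmds, 0)
  data.frame(pos = p,
             motif = paste0(chars[p], chars[p + 1L], chars[p + 2L]),
             side = side,
             tmd_distance = dist,
             usable = side == "outside" & dist >= min_tmd_distance,
             stringsAsFactors = FALSE)
}

#' Loop and tail length summary
#'
#' Tabulates extramembrane segment lengths by membrane side (exoplasmic /
#' cytosolic), protein topology (single-pass / multipass / all) and segment
#' type (tails / internal loops / both), reporting n, mean and median.
#' Zero-length loops are included.
#'
#' @param census A [memtopo_census()] object.
#' @return Data frame: `location`, `topology`, `type`, `n`, `mean`, `median`.
#' @export
length_summary <- function(census) {
  st <- census$seg_table
  out <- list()
  for (loc in c("outside", "inside")) {
    for (topo in c("single_pass", "multipass", "all")) {
      sel_topo <- switch(topo,
                         single_pass = st$single_pass,
                         multipass = !st$single_pass,
                         all = rep(TRUE, nrow(st)))
      for (type in c("tails", "loops", "both")) {
        sel_type <- switch(type,
                           tails = st$kind %in% c("n_tail", "c_tail"),
                           loops = st$kind == "internal_loop",
                           both = rep(TRUE, nrow(st)))
        len <- st$length[st$side == loc & sel_topo & sel_type]
        out[[length(out) + 1L]] <- data.frame(
          location = if (loc == "outside") "exoplasmic" else "cytosolic",
          topology = topo, type = type, n = length(len),
          mean = if (length(len)) mean(len) else NA_real_,
          median = if (length(len)) median(len) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Amino-acid frequencies of TMD sets
#'
#' Percentage of each amino-acid type across all residues of each TMD set
#' (all, single-pass, multipass), plus the per-residue log2(MP/SP) frequency
#' ratio.  A residue type absent from one set yields an undefined ratio,
#' reported as `NA`.
#'
#' @param census A [memtopo_census()] object, or a named list of character
#'   vectors of TMD sequences (must contain `SP` and `MP` for the ratio).
#' @return List with `freq` (matrix, 20 residues x sets, percentages summing
#'   to 100 per set up to the non-canonical residue share) and `log2_mp_sp`.
#' @export
aa_frequency <- function(census) {
  sets <- if (inherits(census, "memtopo_census")) {
    tt <- census$tmd_table
    list(all = tt$sequence,
         SP = tt$sequence[tt$single_pass],
         MP = tt$sequence[!tt$single_pass])
  } else census
  freq <- sapply(sets, function(seqs) {
    if (!length(seqs) || sum(nchar(seqs)) == 0L) {
      stop("aa_frequency: empty TMD set")
    }
    chars <- split_chars(paste(seqs, collapse = ""))
    100 * as.numeric(table(factor(chars, levels = AA20))) / length(chars)
  })
  rownames(freq) <- AA20
  ratio <- if (all(c("MP", "SP") %in% colnames(freq))) {
    r <- log2(freq[, "MP"] / freq[, "SP"])
    r[!is.finite(r)] <- NA_real_
    r
  } else NULL
  list(freq = freq, log2_mp_sp = ratio)
}

# Standard per-TMD analysis strata over a tmd_table.
standard_tmd_strata <- function(tt) {
  n <- nrow(tt)
  saeq <- function(v) !is.na(tt$sa_class) & tt$sa_class == v
  peq <- function(col, v) !is.na(tt[[col]]) & tt[[col]] == v
  list(
    all = rep(TRUE, n),
    single_pass = tt$single_pass,
    multipass = !tt$single_pass,
    mp_tmd1 = !tt$single_pass & tt$tmd == 1L,
    mp_downstream = !tt$single_pass & tt$tmd > 1L,
    sa_nexo = saeq("Nexo_SA"),
    sa_ncyt_long = saeq("Ncyt_long_SA"),
    sa_ncyt_pair = saeq("Ncyt_pair_SA"),
    sa_other = saeq("SA_other"),
    ss_following = tt$ss_following,
    after_ncyt_long_sa = tt$after_ncyt_long_sa,
    pair_tmds = !is.na(tt$pair_role),
    pair_first = peq("pair_role", "first"),
    pair_second = peq("pair_role", "second"),
    pair_first_pair = peq("pair_context", "first_pair"),
    pair_after_short_cyt = peq("pair_context", "internal_after_short_cyt"),
    pair_after_long_cyt = peq("pair_context", "after_long_cyt"),
    long_exo_first = peq("long_exo_role", "first"),
    long_exo_second = peq("long_exo_role", "second"),
    terminal_mp = tt$terminal_mp & !tt$single_pass
  )
}

#' dG_app distribution per analysis stratum
#'
#' Mean, median and the fractions of insertion-favoring (dG_app < 0) and
#' -disfavoring (> 0) TMDs per stratum.  Strata default to the standard
#' census strata (all/SP/MP, signal-anchor classes, Sec61-downstream classes,
#' pair roles and contexts, long-exoplasmic-loop flanks); empty strata are
#' omitted.
#'
#' @param census A [memtopo_census()] object.
#' @param strata Named list of logical vectors over `census$tmd_table` rows.
#' @return Data frame: `stratum`, `n`, `mean`, `median`, `pct_negative`,
#'   `pct_positive`.
#' @export
dg_distribution <- function(census, strata = NULL) {
  tt <- census$tmd_table
  if (is.null(strata)) strata <- standard_tmd_strata(tt)
  out <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    dg <- tt$dg_app[sel]
    if (!length(dg)) next
    if (anyNA(dg)) {
      bad <- tt[sel & is.na(tt$dg_app), c("accession", "tmd")]
      stop("dG_app missing in stratum '", s, "' for: ",
           paste(head(paste0(bad$accession, "/TMD", bad$tmd), 5L),
                 collapse = ", "))
    }
    out[[length(out) + 1L]] <- data.frame(
      stratum = s, n = length(dg), mean = mean(dg), median = median(dg),
      pct_negative = 100 * mean(dg < 0), pct_positive = 100 * mean(dg > 0),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Positive-inside-rule summary
#'
#' Mean net flanking charge per stratum, membrane side and window (the
#' configured flank windows plus the combined interfacial + 10-aa flank
#' charge, labeled `"combined"`).  Empty strata are omitted, not reported as
#' zero.
#'
#' @param census A [memtopo_census()] object.
#' @param strata Named list of logical vectors over `census$tmd_table` rows;
#'   defaults to the standard census strata.
#' @return Data frame: `stratum`, `side`, `window`, `n`, `mean_net`.
#' @export
positive_inside_summary <- function(census, strata = NULL) {
  tt <- census$tmd_table
  fc <- census$flank_charges
  if (is.null(tt) || is.null(fc)) return(NULL)
  if (is.null(strata)) strata <- standard_tmd_strata(tt)
  fc_key <- paste(fc$rec, fc$tmd)
  tt_key <- paste(tt$rec, tt$tmd)
  fc$row <- match(fc_key, tt_key)
  fc$wlab <- ifelse(is.na(fc$window), "combined", as.character(fc$window))
  out <- list()
  for (s in names(strata)) {
    sel_rows <- which(strata[[s]])
    if (!length(sel_rows)) next
    sub <- fc[fc$row %in% sel_rows, ]
    agg <- aggregate(net ~ side + wlab, data = sub, FUN = mean)
    cnt <- aggregate(net ~ side + wlab, data = sub, FUN = length)
    out[[length(out) + 1L]] <- data.frame(
      stratum = s, side = agg$side, window = agg$wlab, n = cnt$net,
      mean_net = agg$net, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$stratum, res$side,
            suppressWarnings(as.numeric(sub("combined", "99", res$window)))), ]
}

#' Aggregate the census report
#'
#' Populates the full census summary: protein and TMD counts by topology
#' class, loop/tail length statistics, dG_app distributions per stratum,
#' amino-acid frequencies, loop length classes, TMD-pair statistics,
#' flanking-charge means and the sequon census.  All numbers are traceable to
#' the corresponding operation; identical inputs give identical reports.
#'
#' @param census A [memtopo_census()] object.
#' @return An object of class `census_summary`.
#' @export
census_report <- function(census) {
  tt <- census$tmd_table
  classes <- c("SP-I", "SP-II", "SP-III", "SP-IV", "MP-SS", "MP-Nexo",
               "MP-Ncyt")
  if (is.null(tt) || nrow(tt) == 0L) {
    return(structure(list(
      totals = list(proteins = 0L, tmds = 0L, single_pass = 0L,
                    multipass = 0L, mean_tmd_length = NA_real_,
                    median_tmd_length = NA_real_, mean_dg = NA_real_,
                    median_dg = NA_real_, pct_dg_negative = NA_real_),
      class_counts = setNames(rep(0L, length(classes)), classes),
      tmd_counts = setNames(rep(0L, length(classes)), classes),
      sa_counts = integer(), length_stats = NULL, dg_stats = NULL,
      aa_freq = NULL, loop_class_counts = NULL, pair_stats = NULL,
      reaction_counts = integer(), sequon_stats = NULL,
      flank_charge_means = NULL, params = census$params
    ), class = "census_summary"))
  }
  pclass <- vapply(census$labels, `[[`, "", "protein_class")
  class_counts <- table(factor(pclass, levels = classes))
  tmd_counts <- tapply(rep(1L, nrow(tt)),
                       factor(tt$protein_class, levels = classes), sum,
                       default = 0L)
  sa <- vapply(census$labels, function(l) l$sa_class %||% NA_character_, "")
  sa_counts <- table(sa[!is.na(sa)])

  dg_ok <- !anyNA(tt$dg_app)
  totals <- list(
    proteins = length(census$labels),
    tmds = nrow(tt),
    single_pass = sum(startsWith(pclass, "SP")),
    multipass = sum(startsWith(pclass, "MP")),
    mean_tmd_length = mean(tt$length),
    median_tmd_length = median(tt$length),
    mean_dg = if (dg_ok) mean(tt$dg_app) else NA_real_,
    median_dg = if (dg_ok) median(tt$dg_app) else NA_real_,
    pct_dg_negative = if (dg_ok) 100 * mean(tt$dg_app < 0) else NA_real_)

  st <- census$seg_table
  loops <- st[st$kind == "internal_loop", ]
  loop_class_counts <- NULL
  if (nrow(loops)) {
    loop_class_counts <- as.data.frame(with(loops, table(
      side = factor(side, levels = c("outside", "inside")),
      class = factor(class, levels = c("short", "intermediate", "long")))))
    names(loop_class_counts)[3L] <- "n"
    tot_by_side <- tapply(loop_class_counts$n, loop_class_counts$side, sum)
    loop_class_counts$pct <-
      100 * loop_class_counts$n / as.numeric(tot_by_side[loop_class_counts$side])
  }

  pr <- census$pairs
  exo_loops_n <- sum(loops$side == "outside")
  pair_stats <- list(
    n_pairs = nrow(pr),
    by_context = if (nrow(pr)) table(pr$context) else integer(),
    mean_loop_length = if (nrow(pr)) mean(pr$loop_length) else NA_real_,
    median_loop_length = if (nrow(pr)) median(pr$loop_length) else NA_real_,
    pct_of_exo_loops = if (exo_loops_n)
      100 * nrow(pr) / exo_loops_n else NA_real_,
    mean_inside_bias = if (nrow(pr)) mean(pr$inside_bias) else NA_real_,
    mean_outside_bias = if (nrow(pr)) mean(pr$outside_bias) else NA_real_)

  sq <- census$sequons
  sequon_stats <- list(
    n_sequons = nrow(sq),
    n_usable = sum(sq$usable),
    pct_usable_in_single_pass = if (sum(sq$usable))
      100 * sum(sq$usable & sq$single_pass) / sum(sq$usable) else NA_real_,
    motif = if (census$params$strict_sequon) "N!P(ST)" else "NX(ST)",
    min_tmd_distance = census$params$sequon_min_distance)

  aa_freq <- tryCatch(aa_frequency(census), error = function(e) NULL)

  structure(list(
    totals = totals,
    class_counts = c(class_counts),
    tmd_counts = c(tmd_counts),
    sa_counts = c(sa_counts),
    length_stats = length_summary(census),
    dg_stats = if (dg_ok) dg_distribution(census) else NULL,
    aa_freq = aa_freq,
    loop_class_counts = loop_class_counts,
    pair_stats = pair_stats,
    reaction_counts = c(table(tt$reaction)),
    sequon_stats = sequon_stats,
    flank_charge_means = positive_inside_summary(census),
    params = census$params
  ), class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  t <- x$totals
  cat("Membrane-proteome census summary\n")
  cat(sprintf("  %d proteins (%d SP / %d MP), %d TMDs\n",
              t$proteins, t$single_pass, t$multipass, t$tmds))
  if (t$proteins == 0L) return(invisible(x))
  cat(sprintf("  mean TMD length %.1f aa (median %.0f)\n",
              t$mean_tmd_length, t$median_tmd_length))
  if (!is.na(t$mean_dg)) {
    cat(sprintf("  dG_app mean %+.2f, median %+.2f, %.0f%% favoring insertion\n",
                t$mean_dg, t$median_dg, t$pct_dg_negative))
  }
  cat("  protein classes: ",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  if (length(x$sa_counts)) {
    cat("  signal anchors:  ",
        paste(names(x$sa_counts), x$sa_counts, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  TMD pairs: %d (mean loop %.1f aa)\n",
              x$pair_stats$n_pairs, x$pair_stats$mean_loop_length))
  cat(sprintf("  sequons: %d found, %d usable (motif %s, >=%d aa from TMDs)\n",
              x$sequon_stats$n_sequons, x$sequon_stats$n_usable,
              x$sequon_stats$motif, x$sequon_stats$min_tmd_distance))
  invisible(x)
}

#' Serialize a census summary to JSON
#'
#' Deterministic structured rendering of the census report (fixed key order,
#' fixed numeric formatting).
#'
#' @param summary A `census_summary` (or a `memtopo_census`, whose summary is
#'   used).
#' @param file Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report <- function(summary, file = NULL) {
  if (inherits(summary, "memtopo_census")) summary <- summary$summary
  x <- unclass(summary)
  x$class_counts <- as.list(x$class_counts)
  x$tmd_counts <- as.list(x$tmd_counts)
  x$sa_counts <- as.list(x$sa_counts)
  x$reaction_counts <- as.list(x$reaction_counts)
  if (!is.null(x$pair_stats)) {
    x$pair_stats$by_context <- as.list(x$pair_stats$by_context)
  }
  if (!is.null(x$aa_freq)) {
    x$aa_freq <- list(freq = as.data.frame(x$aa_freq$freq),
                      log2_mp_sp = as.list(x$aa_freq$log2_mp_sp))
  }
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(10), na = "null",
                           null = "null")
  if (is.null(file)) return(json)
  writeLines(json, file)
  invisible(json)
}
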