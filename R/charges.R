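ZONES <- c("exo_interface", "core_outer", "core_center", "core_inner",
           "cyt_interface")

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Five-zone partition of a TMD
#'
#' Divides a TMD into an exoplasmic interfacial region (outermost 20%), three
#' hydrophobic-core segments (15%, 30%, 15% of TMD length) and a cytosolic
#' interfacial region (innermost 20%).  Zone boundaries fall at cumulative
#' fractions 0.20, 0.35, 0.65 and 0.80 of the length, each rounded half-up to
#' an integer residue count, which guarantees the zones tile the TMD for
#' every length.  The partition is oriented so that `exo_interface` is the
#' exoplasmic end: when the TMD's N-terminal end faces the cytosol the zone
#' order is reversed along the sequence.
#'
#' @param length TMD length in aa (>= 5).
#' @param n_end_side Membrane side of the TMD's N-terminal end (`"outside"`
#'   or `"inside"`), i.e., the side of the preceding segment.
#' @return Data frame with one row per TMD residue (N- to C-terminal):
#'   `pos` (1-based within the TMD), `zone`, and `depth`, the fractional
#'   depth (pos_from_exo_end - 0.5) / length, running 0 at the exoplasmic
#'   face to 1 at the cytosolic face; residue centers never sit exactly on a
#'   zone boundary.
#' @export
zone_partition <- function(length, n_end_side = "outside") {
  L <- as.integer(length)
  if (L < 5L) stop("zone partition requires a TMD of at least 5 aa, got ", L)
  if (!n_end_side %in% c("inside", "outside")) {
    stop("n_end_side must be 'inside' or 'outside'")
  }
  b <- round_half_up(L * c(0.20, 0.35, 0.65, 0.80))
  sizes <- c(b[1L], diff(b), L - b[4L])
  zones_exo_to_cyt <- rep(ZONES, sizes)
  if (n_end_side == "outside") {
    zone <- zones_exo_to_cyt
    from_exo <- seq_len(L)
  } else {
    zone <- rev(zones_exo_to_cyt)
    from_exo <- L:1L
  }
  data.frame(pos = seq_len(L), zone = zone, depth = (from_exo - 0.5) / L,
             stringsAsFactors = FALSE)
}

# zone sizes only (exo -> cyt order)
zone_sizes <- function(length) {
  L <- as.integer(length)
  b <- round_half_up(L * c(0.20, 0.35, 0.65, 0.80))
  setNames(c(b[1L], diff(b), L - b[4L]), ZONES)
}

#' Charged-residue depth map
#'
#' One entry per charged residue (K, R, D, E) in the selected TMDs, recording
#' its fractional depth within a schematic membrane cross-section (0 =
#' exoplasmic face, 1 = cytosolic face) and its zone, as used for membrane
#' dot-plot visualizations.
#'
#' @param table A `census_table`.
#' @param tmds Optional data frame with columns `rec` (record index) and
#'   `tmd` selecting TMDs; all TMDs by default.
#' @param n Optional subsample size: draw `n` TMDs (without replacement) from
#'   the selection before mapping charges.
#' @param seed Seed for the subsample (required when `n` is given).
#' @return Data frame: `accession`, `tmd`, `residue`, `pos`, `depth`, `zone`.
#' @export
charge_dot_map <- function(table, tmds = NULL, n = NULL, seed = NULL) {
  stopifnot(inherits(table, "census_table"))
  if (is.null(tmds)) {
    tmds <- do.call(rbind, lapply(seq_along(table$records), function(r) {
      k <- nrow(table$records[[r]]$tmds)
      if (k == 0L) return(NULL)
      data.frame(rec = r, tmd = seq_len(k))
    }))
  }
  if (!is.null(n)) {
    if (is.null(seed)) stop("subsampling requires a seed")
    if (n > nrow(tmds)) stop("subsample size exceeds available TMDs")
    set.seed(seed)
    tmds <- tmds[sort(sample.int(nrow(tmds), n)), , drop = FALSE]
  }
  out <- vector("list", nrow(tmds))
  seg_cache <- list()
  for (q in seq_len(nrow(tmds))) {
    r <- tmds$rec[q]; k <- tmds$tmd[q]
    rec <- table$records[[r]]
    key <- as.character(r)
    seg <- seg_cache[[key]]
    if (is.null(seg)) seg_cache[[key]] <- seg <- deduce_segments(rec)
    chars <- split_chars(rec$tmds$sequence[k])
    hit <- which(chars %in% AA_CHARGED)
    if (!length(hit)) next
    zp <- zone_partition(length(chars), tmd_n_end_side(seg, k))
    out[[q]] <- data.frame(accession = rec$accession, tmd = k,
                           residue = chars[hit], pos = hit,
                           depth = zp$depth[hit], zone = zp$zone[hit],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(accession = character(), tmd = integer(),
                      residue = character(), pos = integer(),
                      depth = numeric(), zone = character()))
  }
  do.call(rbind, out)
}

#' Per-zone charge ratios and densities
#'
#' For a set of TMDs, computes per zone (and for the pooled hydrophobic core
#' and pooled interfacial regions) the number of residues, basic and acidic
#' counts, the positive:negative ratio, and the charge density (percent of
#' zone residues that are charged).  A zone without acidic residues reports
#' its ratio as `"<n_pos>:0"` rather than dividing by zero.
#'
#' @inheritParams charge_dot_map
#' @return Data frame: `zone`, `n_residues`, `n_pos`, `n_neg`, `ratio`
#'   (character), `density_pct`.
#' @export
zone_charge_summary <- function(table, tmds = NULL) {
  stopifnot(inherits(table, "census_table"))
  if (is.null(tmds)) {
    tmds <- do.call(rbind, lapply(seq_along(table$records), function(r) {
      k <- nrow(table$records[[r]]$tmds)
      if (k == 0L) return(NULL)
      data.frame(rec = r, tmd = seq_len(k))
    }))
  }
  tot <- setNames(numeric(5L), ZONES)
  pos <- setNames(numeric(5L), ZONES)
  neg <- setNames(numeric(5L), ZONES)
  for (q in seq_len(nrow(tmds))) {
    rec <- table$records[[tmds$rec[q]]]
    k <- tmds$tmd[q]
    seg <- deduce_segments(rec)
    chars <- split_chars(rec$tmds$sequence[k])
    zp <- zone_partition(length(chars), tmd_n_end_side(seg, k))
    tz <- table(factor(zp$zone, levels = ZONES))
    tot <- tot + as.numeric(tz)
    cz <- zp$zone[chars %in% AA_BASIC]
    pos <- pos + as.numeric(table(factor(cz, levels = ZONES)))
    cz <- zp$zone[chars %in% AA_ACIDIC]
    neg <- neg + as.numeric(table(factor(cz, levels = ZONES)))
  }
  core <- c("core_outer", "core_center", "core_inner")
  iface <- c("exo_interface", "cyt_interface")
  rows <- rbind(
    data.frame(zone = ZONES, n_residues = as.numeric(tot),
               n_pos = as.numeric(pos), n_neg = as.numeric(neg)),
    data.frame(zone = "core", n_residues = sum(tot[core]),
               n_pos = sum(pos[core]), n_neg = sum(neg[core])),
    data.frame(zone = "interface", n_residues = sum(tot[iface]),
               n_pos = sum(pos[iface]), n_neg = sum(neg[iface])))
  rows$ratio <- ifelse(rows$n_neg == 0,
                       paste0(rows$n_pos, ":0"),
                       sprintf("%.2f:1", rows$n_pos / rows$n_neg))
  rows$density_pct <- ifelse(rows$n_residues == 0, NA_real_,
                             100 * (rows$n_pos + rows$n_neg) / rows$n_residues)
  rows
}

#' Net flanking charge of a TMD
#'
#' Counts basic (K, R; +1) minus acidic (D, E; -1) residues within a window
#' of `window` residues immediately flanking the TMD on the requested
#' membrane side.  The window never reads into a neighboring TMD or the
#' signal peptide: it is truncated at the flanking segment's boundary.  When
#' the available flank `L` is shorter than the window, the count is scaled
#' proportionally by `window / L` (an expected count over a full window;
#' flagged via the `"scaled"` attribute) unless `proportional = FALSE`; a
#' zero-length flank contributes 0.
#'
#' @param record A [protein_record()].
#' @param tmd_index Which TMD.
#' @param side `"inside"` (cytosolic) or `"outside"` (exoplasmic).
#' @param window Window width in residues (5, 10 and 15 are the standard
#'   choices).
#' @param segments Segments with sides (computed when omitted).
#' @param proportional Scale short flanks by `window / L` (default `TRUE`).
#' @return Net charge (possibly fractional when scaled), with attribute
#'   `"scaled"`.
#' @export
flank_net_charge <- function(record, tmd_index, side, window = 10L,
                             segments = deduce_segments(record),
                             proportional = TRUE) {
  if (!side %in% c("inside", "outside")) {
    stop("side must be 'inside' or 'outside'")
  }
  window <- as.integer(window)
  n <- nrow(record$tmds)
  stopifnot(tmd_index >= 1L, tmd_index <= n)
  # the flanks of TMD k are segments k (preceding) and k+1 (following);
  # they lie on opposite sides, so exactly one matches `side`
  pre <- segments[tmd_index, ]
  post <- segments[tmd_index + 1L, ]
  seg <- if (pre$side == side) pre else post
  preceding <- pre$side == side
  L <- seg$length
  if (L == 0L) return(structure(0, scaled = FALSE))
  w <- min(window, L)
  if (preceding) {
    from <- seg$end - w + 1L; to <- seg$end
  } else {
    from <- seg$start; to <- seg$start + w - 1L
  }
  chars <- split_chars(substr(record$sequence, from, to))
  net <- net_charge(chars)
  scaled <- FALSE
  if (L < window && proportional) {
    net <- net * window / L
    scaled <- TRUE
  }
  structure(net, scaled = scaled)
}

# Net charge over the interfacial zone of a TMD on one membrane side
# (unscaled, zone residues only).
interfacial_charge <- function(record, tmd_index, side, segments) {
  chars <- split_chars(record$tmds$sequence[tmd_index])
  zp <- zone_partition(length(chars), tmd_n_end_side(segments, tmd_index))
  zone <- if (side == "outside") "exo_interface" else "cyt_interface"
  net_charge(chars[zp$zone == zone])
}

#' Combined interfacial plus flanking charge
#'
#' The flanking charge used in the census property panels: the net charge of
#' the 10 residues immediately flanking the TMD (see [flank_net_charge()])
#' plus the net charge of the charged residues within the TMD's own
#' interfacial zone (outermost 20% of TMD residues) on the same side.
#'
#' @inheritParams flank_net_charge
#' @return Net combined charge.
#' @export
combined_flank_charge <- function(record, tmd_index, side,
                                  segments = deduce_segments(record),
                                  proportional = TRUE) {
  if (!side %in% c("inside", "outside")) {
    stop("side must be 'inside' or 'outside'")
  }
  interfacial_charge(record, tmd_index, side, segments) +
    as.numeric(flank_net_charge(record, tmd_index, side, 10L, segments,
                                proportional))
}

#' Charge bias of a TMD pair treated as one unit
#'
#' For a TMD pair (two TMDs with a short exoplasmic loop), the inside bias is
#' the sum of the combined interfacial + flanking cytosolic charges of both
#' TMDs; the outside bias is the net charge over the entire exoplasmic loop
#' plus the exoplasmic interfacial zones of both TMDs (no window truncation
#' or scaling).
#'
#' @param record A [protein_record()].
#' @param pair One row of [find_tmd_pairs()] output.
#' @param segments Segments with sides.
#' @param proportional Passed to the inside [combined_flank_charge()].
#' @return List with `inside_bias` and `outside_bias`.
#' @export
pair_charge_bias <- function(record, pair,
                             segments = deduce_segments(record),
                             proportional = TRUE) {
  i <- pair$first; j <- pair$second
  inside <- combined_flank_charge(record, i, "inside", segments, proportional) +
    combined_flank_charge(record, j, "inside", segments, proportional)
  loop <- segments[pair$loop_ordinal, ]
  loop_net <- net_charge(split_chars(segment_sequence(record, loop)))
  outside <- loop_net +
    interfacial_charge(record, i, "outside", segments) +
    interfacial_charge(record, j, "outside", segments)
  list(inside_bias = inside, outside_bias = outside)
}
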