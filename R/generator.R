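# Synthetic proteome generator.
#
# The generator emulates the statistical structure of the curated human
# membrane-proteome census: topology-class proportions, TMD-count parity
# biases, TMD length and class-conditional hydrophobicity distributions,
# log-scale loop/tail length mixtures, and positive-inside flanking charge
# biases.  Every record carries full truth bookkeeping so discrete labels
# (classes, pairs, loop classes) are exactly recoverable and continuous
# targets are recoverable within Monte-Carlo error.

# residue composition tables (probabilities normalized in code); charged
# residues are never drawn from composition tables -- they are placed by
# explicit draw in the charge phase
COMP_HYDROPHOBIC <- c(L = .30, V = .15, I = .13, A = .12, F = .10, M = .05,
                      W = .03, C = .03, G = .05, S = .02, T = .02)
COMP_POLAR <- c(S = .16, T = .14, N = .12, Q = .12, G = .14, P = .08,
                Y = .07, H = .07, A = .10)
COMP_LOOP <- c(A = .09, G = .11, S = .13, T = .08, P = .09, N = .07, Q = .06,
               H = .04, Y = .04, L = .08, V = .06, I = .04, F = .04, M = .02,
               W = .01, C = .02, E = 0, D = 0, K = 0, R = 0)

# run code under a local RNG state, restoring the caller's stream afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

sample_aa <- function(n, probs) {
  if (n == 0L) return(character())
  probs <- probs / sum(probs)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Default generator configuration
#'
#' Returns a generator configuration whose defaults are the census study
#' conditions: the topology-class mix and TMD-count parity biases of the
#' curated proteome, a TMD length distribution with mean 23.6 aa on support
#' 15-35, per-stratum hydrophobicity targets equal to the published class
#' mean dG_app values (calibrated at build time into polar/hydrophobic
#' composition mixing weights against the bundled dG scale), log-normal
#' loop/tail length mixtures pinned to the published short/intermediate/long
#' proportions, and positive-inside flanking charge targets.
#'
#' @param n_proteins Number of proteins to generate.
#' @param scale The [dg_scale()] used for composition calibration.
#' @param calibration_n Monte-Carlo sample size per calibration grid point.
#' @return An object of class `memtopo_config`.
#' @export
default_config <- function(n_proteins = 1000L, scale = dg_scale(),
                           calibration_n = 250L) {
  class_mix <- c(`SP-I` = 1247, `SP-II` = 477, `SP-III` = 304, `SP-IV` = 220,
                 `MP-SS` = 247, `MP-Nexo` = 978, `MP-Ncyt` = 1390) / 4863

  tmd_count_model <- list(
    # odd-favoring (0.88 odd mass, 7-TMD dominant: GPCR shape)
    "MP-Nexo" = list(counts = c(3, 5, 7, 9, 11, 13, 2, 4, 6, 8, 10, 12),
                     probs = c(.05, .07, .62, .09, .04, .01,
                               .04, .03, .02, .01, .01, .01)),
    # even-favoring (0.89 even mass: transporter/channel shape)
    "MP-Ncyt" = list(counts = c(2, 4, 6, 8, 10, 12, 3, 5, 7, 9, 11),
                     probs = c(.14, .17, .22, .12, .13, .11,
                               .04, .03, .02, .01, .01)),
    "MP-SS" = list(counts = 2:12,
                   probs = c(.18, .12, .14, .10, .12, .08, .08, .06, .06,
                             .03, .03)))

  # discretized normal on 15..35, location solved so the mean is exactly 23.6
  lengths <- 15:35
  mean_for_mu <- function(mu) {
    p <- stats::dnorm(lengths, mu, 3)
    sum(lengths * p / sum(p))
  }
  mu <- stats::uniroot(function(m) mean_for_mu(m) - 23.6, c(20, 27),
                       tol = 1e-12)$root
  p <- stats::dnorm(lengths, mu, 3)
  tmd_length_model <- list(lengths = lengths, probs = p / sum(p),
                           mean = 23.6)

  loop_length_models <- list(
    exo_internal = list(weights = c(short = .918, intermediate = .053,
                                    long = .029),
                        short_meanlog = log(10), short_sdlog = 0.80),
    cyt_internal = list(weights = c(short = .894, intermediate = .062,
                                    long = .044),
                        short_meanlog = log(12), short_sdlog = 0.85),
    long_meanlog = log(60), long_sdlog = 1.0, # length above 100 aa
    tails = list(sp_exo = c(meanlog = log(277), sdlog = 0.88),
                 sp_cyt = c(meanlog = log(76), sdlog = 1.35),
                 mp_exo = c(meanlog = log(24), sdlog = 1.62),
                 mp_cyt = c(meanlog = log(41), sdlog = 1.30)),
    ta_c_tail = c(meanlog = log(15), sdlog = 0.7),
    tail_cap = 4000L)

  charge_bias_models <- list(
    single_pass = c(inside = 2.04, outside = -0.17),
    multipass = c(inside = 0.93, outside = -0.12),
    base_opposite = 0.3)

  dg_targets <- c(ss_following_sp = -1.89,
                  ncyt_long_sa = -1.36,
                  nexo_sa = -0.80,
                  ta = -1.50,
                  ss_following_mp = -0.80,
                  ncyt_pair_sa = 0.47,
                  pair = 1.12,
                  after_ncyt_long = 0.00,
                  long_exo = -0.70,
                  other = 0.89)

  calib <- calibrate_dg_mixture(dg_targets, scale, tmd_length_model,
                                n = calibration_n)

  cfg <- structure(list(
    n_proteins = as.integer(n_proteins),
    class_mix = class_mix,
    tmd_count_model = tmd_count_model,
    tmd_length_model = tmd_length_model,
    composition_models = list(
      targets = dg_targets,
      polar_weights = calib$weights,
      calibration = calib$grid,
      tables = list(hydrophobic = COMP_HYDROPHOBIC / sum(COMP_HYDROPHOBIC),
                    polar = COMP_POLAR / sum(COMP_POLAR),
                    loop = COMP_LOOP / sum(COMP_LOOP))),
    loop_length_models = loop_length_models,
    charge_bias_models = charge_bias_models,
    signal_length_model = c(mean = 22, sd = 4, min = 15, max = 45),
    provenance = c(
      class_mix = "census class counts (1247/477/304/220/247/978/1390 of 4863)",
      tmd_length = "mean TMD length 23.6 aa, support 15-35",
      parity = "0.88 odd bias N_exo multipass / 0.89 even bias N_cyt multipass",
      loops = "short/intermediate/long loop shares 91.8/5.3/2.9 (exo), 89.4/6.2/4.4 (cyt)",
      charges = "flank net-charge means +2.04/-0.17 (SP), +0.93/-0.12 (MP) at W=10",
      dg = "class-conditional mean dG_app targets, calibrated composition mixtures")
  ), class = "memtopo_config")
  validate_config(cfg)
  cfg
}

#' @export
print.memtopo_config <- function(x, ...) {
  cat("memtopo generator configuration\n")
  cat("  n_proteins:", x$n_proteins, "\n")
  cat("  class mix: ",
      paste(names(x$class_mix), sprintf("%.3f", x$class_mix), sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  TMD length mean:", x$tmd_length_model$mean, "aa\n")
  cat("  dG targets: ",
      paste(names(x$composition_models$targets),
            sprintf("%+.2f", x$composition_models$targets), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid generator config: ", what)
  chk(abs(sum(cfg$class_mix) - 1) < 1e-8, "class_mix must sum to 1")
  chk(all(cfg$class_mix >= 0), "class_mix must be non-negative")
  for (cl in names(cfg$tmd_count_model)) {
    m <- cfg$tmd_count_model[[cl]]
    chk(abs(sum(m$probs) - 1) < 1e-8,
        paste0("tmd_count_model[", cl, "] probs must sum to 1"))
    chk(all(m$counts >= 2), paste0("tmd_count_model[", cl,
                                   "] counts must be >= 2"))
  }
  chk(abs(sum(cfg$tmd_length_model$probs) - 1) < 1e-8,
      "tmd_length_model probs must sum to 1")
  chk(all(cfg$tmd_length_model$lengths >= 5),
      "tmd_length_model support must be >= 5 aa")
  cb <- cfg$charge_bias_models
  for (grp in c("single_pass", "multipass")) {
    need <- abs(cb[[grp]]) + 2 * cb$base_opposite
    chk(all(need <= 10),
        paste0("charge_bias_models$", grp,
               ": expected charge count exceeds a 10-aa window"))
  }
  w <- cfg$composition_models$polar_weights
  chk(all(w >= 0 & w <= 1), "calibrated polar weights must lie in [0, 1]")
  invisible(cfg)
}

# Calibrate the polar-mixture weight per hydrophobicity target: on a grid of
# mixing weights w, draw TMDs (lengths from the length model, residues from
# (1-w)*hydrophobic + w*polar) and record the mean dG_app; targets are then
# inverted by monotone interpolation.  Runs under a fixed local RNG stream.
calibrate_dg_mixture <- function(targets, scale, tmd_length_model, n = 250L,
                                 grid = seq(0, 1, by = 0.05)) {
  hyd <- COMP_HYDROPHOBIC / sum(COMP_HYDROPHOBIC)
  pol <- COMP_POLAR / sum(COMP_POLAR)
  alphabet <- union(names(hyd), names(pol))
  hv <- setNames(rep(0, length(alphabet)), alphabet); hv[names(hyd)] <- hyd
  pv <- setNames(rep(0, length(alphabet)), alphabet); pv[names(pol)] <- pol
  means <- with_local_seed(76543L, {
    vapply(grid, function(w) {
      probs <- (1 - w) * hv + w * pv
      lens <- sample(tmd_length_model$lengths, n, replace = TRUE,
                     prob = tmd_length_model$probs)
      mean(vapply(lens, function(L) {
        dg_app(paste(sample(alphabet, L, replace = TRUE, prob = probs),
                     collapse = ""), scale)
      }, 0))
    }, 0)
  })
  if (any(diff(means) <= 0)) {
    o <- order(means) # guard monotonicity for the inversion
    grid <- grid[o]; means <- means[o]
  }
  lo <- min(means); hi <- max(means)
  weights <- vapply(targets, function(t) {
    approx(means, grid, xout = min(max(t, lo), hi), ties = "ordered")$y
  }, 0)
  list(weights = weights, grid = data.frame(w = grid, mean_dg = means))
}

# --- length draws ---------------------------------------------------------

draw_tail <- function(model, cap) {
  min(cap, max(0L, round_half_up(rlnorm(1, model["meanlog"], model["sdlog"]))))
}

draw_internal_loop <- function(side_model, lmods) {
  cls <- sample(names(side_model$weights), 1L, prob = side_model$weights)
  len <- switch(cls,
    short = min(50L, max(0L, round_half_up(
      rlnorm(1, side_model$short_meanlog, side_model$short_sdlog)))),
    intermediate = sample(51:100, 1L),
    long = 101L + round_half_up(
      rlnorm(1, lmods$long_meanlog, lmods$long_sdlog)))
  as.integer(len)
}

# greedy pairing on raw geometry (mirrors the definition: exoplasmic loop
# <= 50 aa, left-to-right, no TMD in two pairs)
greedy_pairs_geom <- function(loop_sides, loop_lengths, n_tmd) {
  first <- integer()
  paired <- rep(FALSE, n_tmd)
  for (i in seq_len(max(0L, n_tmd - 1L))) {
    if (paired[i]) next
    # loop between TMD i and i+1 is segment i+1
    if (loop_sides[i + 1L] == "outside" && loop_lengths[i + 1L] <= 50L) {
      first <- c(first, i)
      paired[i] <- paired[i + 1L] <- TRUE
    }
  }
  first
}

rpois_capped <- function(lambda, cap) {
  if (cap <= 0L || lambda <= 0) return(0L)
  min(cap, rpois(1L, lambda))
}

#' Generate a synthetic proteome
#'
#' Draws a proteome from a generator configuration in three named random
#' substreams (structure, composition, charges), so adding a draw in one
#' phase does not shift the others.  Every record validates, realizes the
#' drawn TMD/loop/charge structure exactly, and is accompanied by truth
#' bookkeeping (intended topology class, signal-anchor class, TMD pairs,
#' loop classes and drawn flank charges).
#'
#' @param config A [default_config()]-style `memtopo_config`.
#' @param seed Integer seed; the same `(config, seed)` always yields a
#'   byte-identical proteome.
#' @return An object of class `generated_proteome`: a list with `table`
#'   (a `census_table`), `truth` (record/pair/loop/flank bookkeeping) and
#'   `config`.
#' @examples
#' gp <- generate_proteome(default_config(n_proteins = 5), seed = 42)
#' gp$truth$records$class
#' @export
generate_proteome <- function(config, seed) {
  validate_config(config)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  n <- config$n_proteins
  lm <- config$loop_length_models
  cm <- config$composition_models
  cb <- config$charge_bias_models

  # ---- phase 1: structure ----
  geom <- with_local_seed(derive_seed(seed, 1L), {
    lapply(seq_len(n), function(i) {
      cls <- sample(names(config$class_mix), 1L, prob = config$class_mix)
      sp <- startsWith(cls, "SP")
      has_ss <- cls %in% c("SP-I", "MP-SS")
      n_side <- switch(cls,
                       `SP-I` = "outside", `SP-II` = "inside",
                       `SP-III` = "outside", `SP-IV` = "inside",
                       `MP-SS` = "outside", `MP-Nexo` = "outside",
                       `MP-Ncyt` = "inside")
      ntmd <- if (sp) 1L else {
        m <- config$tmd_count_model[[cls]]
        as.integer(sample(m$counts, 1L, prob = m$probs))
      }
      tmd_len <- as.integer(sample(config$tmd_length_model$lengths, ntmd,
                                   replace = TRUE,
                                   prob = config$tmd_length_model$probs))
      sig_len <- if (has_ss) {
        s <- config$signal_length_model
        as.integer(min(s["max"], max(s["min"], round_half_up(
          rnorm(1, s["mean"], s["sd"])))))
      } else 0L
      # segment sides by parity of the segment ordinal
      other <- if (n_side == "inside") "outside" else "inside"
      seg_sides <- ifelse(seq_len(ntmd + 1L) %% 2L == 1L, n_side, other)
      tails <- lm$tails
      tail_model <- function(side) {
        if (sp) {
          if (side == "outside") tails$sp_exo else tails$sp_cyt
        } else {
          if (side == "outside") tails$mp_exo else tails$mp_cyt
        }
      }
      seg_len <- integer(ntmd + 1L)
      seg_len[1L] <- draw_tail(tail_model(seg_sides[1L]), lm$tail_cap)
      if (ntmd > 1L) {
        for (k in 2L:ntmd) {
          side_model <- if (seg_sides[k] == "outside") lm$exo_internal
                        else lm$cyt_internal
          seg_len[k] <- draw_internal_loop(side_model, lm)
        }
      }
      last <- ntmd + 1L
      seg_len[last] <- if (cls == "SP-IV") {
        min(50L, max(0L, round_half_up(
          rlnorm(1, lm$ta_c_tail["meanlog"], lm$ta_c_tail["sdlog"]))))
      } else if (cls == "SP-II") {
        v <- draw_tail(tails$sp_exo, lm$tail_cap)
        for (try in 1:50) {
          if (v >= 51L) break
          v <- draw_tail(tails$sp_exo, lm$tail_cap)
        }
        max(51L, v)
      } else {
        draw_tail(tail_model(seg_sides[last]), lm$tail_cap)
      }
      list(class = cls, sp = sp, has_ss = has_ss, n_side = n_side,
           ntmd = ntmd, tmd_len = tmd_len, sig_len = sig_len,
           seg_sides = seg_sides, seg_len = seg_len)
    })
  })

  # derived truth per record (pairs, sa class, loop classes)
  for (i in seq_len(n)) {
    g <- geom[[i]]
    pf <- greedy_pairs_geom(g$seg_sides, g$seg_len, g$ntmd)
    g$pair_first <- pf
    g$sa_class <- if (g$has_ss || g$class == "SP-IV") {
      NA_character_
    } else if (g$n_side == "outside") {
      "Nexo_SA"
    } else if (1L %in% pf) {
      "Ncyt_pair_SA"
    } else if (g$seg_len[2L] > 100L) {
      "Ncyt_long_SA"
    } else "SA_other"
    # per-TMD composition stratum
    strat <- character(g$ntmd)
    paired <- rep(FALSE, g$ntmd)
    paired[pf] <- TRUE
    if (length(pf)) paired[pf + 1L] <- TRUE
    long_exo_flank <- rep(FALSE, g$ntmd)
    if (g$ntmd > 1L) {
      for (m in 2L:g$ntmd) {
        if (g$seg_sides[m] == "outside" && g$seg_len[m] > 100L) {
          long_exo_flank[m - 1L] <- TRUE
          long_exo_flank[m] <- TRUE
        }
      }
    }
    for (k in seq_len(g$ntmd)) {
      strat[k] <- if (k == 1L) {
        if (g$class == "SP-I") "ss_following_sp"
        else if (g$class == "MP-SS") "ss_following_mp"
        else if (g$class == "SP-IV") "ta"
        else switch(g$sa_class,
                    Nexo_SA = "nexo_sa",
                    Ncyt_long_SA = "ncyt_long_sa",
                    Ncyt_pair_SA = "ncyt_pair_sa",
                    SA_other = "other")
      } else if (paired[k]) {
        "pair"
      } else if (k == 2L && !is.na(g$sa_class) &&
                 g$sa_class == "Ncyt_long_SA") {
        "after_ncyt_long"
      } else if (long_exo_flank[k]) {
        "long_exo"
      } else "other"
    }
    g$tmd_stratum <- strat
    geom[[i]] <- g
  }

  # ---- phase 2: composition ----
  tabs <- cm$tables
  alphabet <- union(names(tabs$hydrophobic), names(tabs$polar))
  hv <- setNames(rep(0, length(alphabet)), alphabet)
  hv[names(tabs$hydrophobic)] <- tabs$hydrophobic
  pv <- setNames(rep(0, length(alphabet)), alphabet)
  pv[names(tabs$polar)] <- pv[names(tabs$polar)] + tabs$polar
  seqs <- with_local_seed(derive_seed(seed, 2L), {
    lapply(seq_len(n), function(i) {
      g <- geom[[i]]
      tmd_seq <- vapply(seq_len(g$ntmd), function(k) {
        w <- cm$polar_weights[[g$tmd_stratum[k]]]
        probs <- (1 - w) * hv + w * pv
        paste(sample(alphabet, g$tmd_len[k], replace = TRUE, prob = probs),
              collapse = "")
      }, "")
      seg_seq <- vapply(g$seg_len, function(L) {
        paste(sample_aa(L, tabs$loop), collapse = "")
      }, "")
      sig_seq <- if (g$sig_len > 0L) {
        paste(sample_aa(g$sig_len, tabs$hydrophobic), collapse = "")
      } else ""
      list(tmd = tmd_seq, seg = seg_seq, sig = sig_seq)
    })
  })

  # ---- phase 3: charges ----
  flank_truth <- vector("list", n)
  with_local_seed(derive_seed(seed, 3L), {
    for (i in seq_len(n)) {
      g <- geom[[i]]
      sq <- seqs[[i]]
      bias <- if (g$sp) cb$single_pass else cb$multipass
      base <- cb$base_opposite
      rows <- list()
      place <- function(seg_idx, at_end, avail, target, tmd, side) {
        # lambda scaled by the usable region so the W=10 proportionally
        # scaled measurement is unbiased
        region <- min(10L, avail)
        if (region <= 0L) {
          rows[[length(rows) + 1L]] <<- data.frame(
            tmd = tmd, side = side, drawn_net = 0, region = 0L)
          return(invisible())
        }
        sc <- region / 10
        lp <- (max(target, 0) + base) * sc
        ln <- (max(-target, 0) + base) * sc
        np <- rpois_capped(lp, region)
        nn <- rpois_capped(ln, region - np)
        k <- np + nn
        if (k > 0L) {
          chars <- split_chars(sq$seg[seg_idx])
          L <- length(chars)
          offs <- sample.int(region, k)
          pos <- if (at_end) L - offs + 1L else offs
          letters <- c(sample(AA_BASIC, np, replace = TRUE),
                       sample(AA_ACIDIC, nn, replace = TRUE))
          chars[pos] <- letters
          sq$seg[seg_idx] <<- paste(chars, collapse = "")
        }
        rows[[length(rows) + 1L]] <<- data.frame(
          tmd = tmd, side = side, drawn_net = np - nn, region = region)
      }
      for (k in seq_len(g$ntmd)) {
        pre_side <- g$seg_sides[k]
        post_side <- g$seg_sides[k + 1L]
        pre_len <- g$seg_len[k]
        post_len <- g$seg_len[k + 1L]
        # available room: tails belong to one TMD; internal loops are split
        pre_avail <- if (k == 1L) pre_len else pre_len - pre_len %/% 2L
        post_avail <- if (k == g$ntmd) post_len else post_len %/% 2L
        place(k, at_end = TRUE, pre_avail, unname(bias[pre_side_key(pre_side)]),
              k, pre_side)
        place(k + 1L, at_end = FALSE, post_avail,
              unname(bias[pre_side_key(post_side)]), k, post_side)
      }
      flank_truth[[i]] <- cbind(data.frame(rec = i), do.call(rbind, rows))
      seqs[[i]] <- sq
    }
  })

  # ---- assemble records ----
  records <- vector("list", n)
  truth_rec <- vector("list", n)
  truth_pairs <- vector("list", n)
  truth_loops <- vector("list", n)
  for (i in seq_len(n)) {
    g <- geom[[i]]
    sq <- seqs[[i]]
    acc <- sprintf("SYN%05d", i)
    parts <- character(0)
    starts <- ends <- integer(g$ntmd)
    pos <- 0L
    if (g$sig_len > 0L) {
      parts <- c(parts, sq$sig)
      pos <- pos + g$sig_len
    }
    for (k in seq_len(g$ntmd)) {
      parts <- c(parts, sq$seg[k])
      pos <- pos + g$seg_len[k]
      starts[k] <- pos + 1L
      parts <- c(parts, sq$tmd[k])
      pos <- pos + g$tmd_len[k]
      ends[k] <- pos
    }
    parts <- c(parts, sq$seg[g$ntmd + 1L])
    sequence <- paste(parts, collapse = "")
    records[[i]] <- protein_record(
      accession = acc, gene_name = paste0("GENE", i),
      sequence = sequence, tmd_starts = starts, tmd_ends = ends,
      n_terminus_side = g$n_side,
      signal = if (g$sig_len > 0L) c(1L, g$sig_len) else NULL)
    truth_rec[[i]] <- data.frame(
      rec = i, accession = acc, class = g$class, sa_class = g$sa_class,
      n_tmds = g$ntmd, stringsAsFactors = FALSE)
    if (length(g$pair_first)) {
      truth_pairs[[i]] <- data.frame(
        rec = i, accession = acc, first = g$pair_first,
        second = g$pair_first + 1L, stringsAsFactors = FALSE)
    }
    truth_loops[[i]] <- data.frame(
      rec = i, accession = acc, ordinal = seq_len(g$ntmd + 1L),
      side = g$seg_sides, length = g$seg_len,
      class = classify_loop(g$seg_len), stringsAsFactors = FALSE)
    if (!is.null(flank_truth[[i]])) flank_truth[[i]]$accession <- acc
  }
  structure(list(
    table = census_table(records, source = sprintf(
      "generate_proteome(n=%d, seed=%d)", n, as.integer(seed))),
    truth = list(
      records = if (n) do.call(rbind, truth_rec) else NULL,
      pairs = {
        tp <- truth_pairs[!vapply(truth_pairs, is.null, TRUE)]
        if (length(tp)) do.call(rbind, tp) else
          data.frame(rec = integer(), accession = character(),
                     first = integer(), second = integer())
      },
      loops = if (n) do.call(rbind, truth_loops) else NULL,
      flanks = if (n) do.call(rbind, flank_truth) else NULL),
    config = config,
    seed = as.integer(seed)
  ), class = "generated_proteome")
}

pre_side_key <- function(side) if (side == "inside") "inside" else "outside"

#' @export
print.generated_proteome <- function(x, ...) {
  cat(sprintf("generated_proteome: %d records (seed %d)\n",
              length(x$table$records), x$seed))
  if (!is.null(x$truth$records)) {
    print(table(x$truth$records$class))
  }
  invisible(x)
}

#' Simulate a proteome from a generator configuration
#'
#' `simulate()` method for `memtopo_config`: draws `nsim` independent
#' proteomes.
#'
#' @param object A `memtopo_config`.
#' @param nsim Number of proteomes.
#' @param seed Integer seed (mandatory; proteome j uses a seed derived from
#'   `seed` and j).
#' @param ... Unused.
#' @return A list of `generated_proteome` objects (length `nsim`), or a
#'   single one when `nsim = 1`.
#' @export
simulate.memtopo_config <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("a seed is mandatory")
  out <- lapply(seq_len(nsim), function(j) {
    generate_proteome(object, derive_seed(seed, 100L + j))
  })
  if (nsim == 1) out[[1L]] else out
}

#' Check pipeline recovery of generator truth
#'
#' Runs the classification pipeline over a generated proteome (or accepts a
#' precomputed [memtopo_census()]) and compares: discrete truth — topology
#' classes, signal-anchor classes, TMD pair lists and loop length classes
#' must match exactly, since the generator emits unambiguous geometry — and
#' continuous targets — realized class mix, mean TMD length, and mean
#' single-pass cytosolic 10-aa flank charge, within stated tolerances
#' (calibrated for proteomes of roughly 5,000 proteins).  Per-stratum dG_app
#' means are compared against the composition targets for strata with at
#' least 200 TMDs.
#'
#' @param proteome A `generated_proteome`.
#' @param census Optional `memtopo_census` of `proteome$table` (computed when
#'   omitted).
#' @param tolerances Named list: `class_mix` (absolute probability, default
#'   0.02), `tmd_length` (aa, 0.2), `inside_flank` (charge units, 0.15),
#'   `dg_mean` (kcal/mol, 0.30).
#' @return An object of class `recovery_report`: data frame of checks with
#'   `pass` flags plus attributes; attribute `"pass"` is the conjunction.
#' @export
recovery_check <- function(proteome, census = NULL,
                           tolerances = list(class_mix = 0.02,
                                             tmd_length = 0.2,
                                             inside_flank = 0.15,
                                             dg_mean = 0.30)) {
  stopifnot(inherits(proteome, "generated_proteome"))
  if (is.null(census)) census <- memtopo_census(proteome$table)
  tr <- proteome$truth
  cfg <- proteome$config
  tt <- census$tmd_table
  checks <- list()
  add <- function(check, target, realized, tol, pass) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, target = target, realized = realized, tolerance = tol,
      pass = pass, stringsAsFactors = FALSE)
  }

  # discrete: protein class, sa class
  pclass <- vapply(census$labels, `[[`, "", "protein_class")
  agree <- mean(pclass == tr$records$class)
  add("protein_class_agreement", 1, agree, 0, agree == 1)
  sa <- vapply(census$labels, function(l) l$sa_class %||% NA_character_, "")
  sa_agree <- mean(ifelse(is.na(tr$records$sa_class), is.na(sa),
                          !is.na(sa) & sa == tr$records$sa_class))
  add("sa_class_agreement", 1, sa_agree, 0, sa_agree == 1)

  # discrete: pair lists
  got_pairs <- census$pairs[, c("rec", "first", "second")]
  want_pairs <- tr$pairs[, c("rec", "first", "second")]
  key <- function(d) sort(paste(d$rec, d$first, d$second))
  pairs_ok <- identical(key(got_pairs), key(want_pairs))
  add("pair_list_exact", 1, as.numeric(pairs_ok), 0, pairs_ok)

  # discrete: loop classes
  st <- census$seg_table
  got_loops <- st[order(st$rec, st$ordinal), c("rec", "ordinal", "side",
                                               "class")]
  want_loops <- tr$loops[order(tr$loops$rec, tr$loops$ordinal),
                         c("rec", "ordinal", "side", "class")]
  rownames(got_loops) <- rownames(want_loops) <- NULL
  loops_ok <- identical(got_loops, want_loops)
  add("loop_class_exact", 1, as.numeric(loops_ok), 0, loops_ok)

  # statistical: class mix
  realized_mix <- table(factor(pclass, levels = names(cfg$class_mix))) /
    length(pclass)
  mix_dev <- max(abs(as.numeric(realized_mix) - as.numeric(cfg$class_mix)))
  add("class_mix_max_abs_dev", 0, mix_dev, tolerances$class_mix,
      mix_dev <= tolerances$class_mix)

  # statistical: mean TMD length
  add("mean_tmd_length", cfg$tmd_length_model$mean, mean(tt$length),
      tolerances$tmd_length,
      abs(mean(tt$length) - cfg$tmd_length_model$mean) <=
        tolerances$tmd_length)

  # statistical: single-pass inside flank bias at W = 10
  fc <- census$flank_charges
  sp_rec <- which(vapply(census$labels, function(l)
    startsWith(l$protein_class, "SP"), TRUE))
  sel <- fc$rec %in% sp_rec & fc$side == "inside" & !is.na(fc$window) &
    fc$window == 10L
  target <- unname(cfg$charge_bias_models$single_pass["inside"])
  realized <- mean(fc$net[sel])
  add("sp_inside_flank_w10", target, realized, tolerances$inside_flank,
      abs(realized - target) <= tolerances$inside_flank)

  # statistical: per-stratum dG means (strata mirroring the generator roles)
  strata <- list(
    ss_following_sp = tt$ss_following & tt$single_pass,
    ss_following_mp = tt$ss_following & !tt$single_pass,
    nexo_sa = !is.na(tt$sa_class) & tt$sa_class == "Nexo_SA",
    ncyt_long_sa = !is.na(tt$sa_class) & tt$sa_class == "Ncyt_long_SA",
    ncyt_pair_sa = !is.na(tt$sa_class) & tt$sa_class == "Ncyt_pair_SA",
    ta = tt$protein_class == "SP-IV",
    pair = !is.na(tt$pair_role) & tt$tmd > 1L,
    after_ncyt_long = tt$after_ncyt_long_sa)
  targets <- cfg$composition_models$targets
  for (s in names(strata)) {
    dg <- tt$dg_app[strata[[s]]]
    if (length(dg) < 200L) next
    t <- unname(targets[[s]])
    add(paste0("dg_mean_", s), t, mean(dg), tolerances$dg_mean,
        abs(mean(dg) - t) <= tolerances$dg_mean)
  }

  out <- do.call(rbind, checks)
  structure(out, class = c("recovery_report", "data.frame"),
            pass = all(out$pass))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("generator recovery report (overall ",
      if (attr(x, "pass")) "PASS" else "FAIL", ")\n", sep = "")
  print.data.frame(cbind(x[, 1L, drop = FALSE],
                         round(x[, 2:4], 4), pass = x$pass),
                   row.names = FALSE)
  invisible(x)
}
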