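#' Load the biological hydrophobicity scale
#'
#' Reads the full-model parameter set of the position-dependent biological
#' hydrophobicity scale used to compute apparent free energies of membrane
#' insertion (dG_app, kcal/mol).  The scale combines, for a candidate segment
#' of length L: (i) a per-residue base contribution modulated by a symmetric
#' Gaussian profile across the normalized segment coordinate (with an extra
#' symmetric two-Gaussian term for the interface-seeking aromatics Trp and
#' Tyr), (ii) a hydrophobic-moment term at the alpha-helical periodicity of
#' 100 degrees per residue, and (iii) a quadratic length-correction polynomial
#' in L.  The profile's symmetry about the segment midpoint makes dG_app
#' invariant under sequence reversal.
#'
#' @param file Path to a scale parameter file.  Defaults to the parameter set
#'   bundled with the package (`dg_scale_full_model.tsv`).
#' @return An object of class `dg_scale`: a list with per-residue profile
#'   coefficients, the hydrophobic-moment coefficient and helix angle, the
#'   length-correction coefficients, the supported segment length range, and
#'   a `provenance` string identifying the parameter file.
#' @seealso [dg_app()], [dg_scan()]
#' @export
dg_scale <- function(file = NULL) {
  if (is.null(file)) {
    cached <- get0("default_scale", envir = .memtopo_cache)
    if (!is.null(cached)) return(cached)
    file <- system.file("extdata", "dg_scale_full_model.tsv",
                        package = "memtopo", mustWork = TRUE)
    default <- TRUE
  } else {
    default <- FALSE
  }
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(fields, `[[`, "", 1L)

  prof <- fields[kind == "profile"]
  aa <- vapply(prof, `[[`, "", 2L)
  if (!setequal(aa, AA20)) {
    stop("scale file must provide a profile for each of the 20 canonical ",
         "amino acids; missing: ", paste(setdiff(AA20, aa), collapse = ", "))
  }
  coefs <- lapply(prof, function(f) as.numeric(f[-(1:2)]))
  names(coefs) <- aa
  coefs <- coefs[AA20]

  c0 <- vapply(coefs, `[[`, 0, 1L)
  c1 <- vapply(coefs, `[[`, 0, 2L)
  has_extra <- vapply(coefs, length, 0L) >= 5L
  e0 <- e1 <- e2 <- rep(0, 20L)
  e0[has_extra] <- vapply(coefs[has_extra], `[[`, 0, 3L)
  e1[has_extra] <- vapply(coefs[has_extra], `[[`, 0, 4L)
  e2[has_extra] <- vapply(coefs[has_extra], `[[`, 0, 5L)

  mom <- as.numeric(fields[[which(kind == "moment")]][-1L])
  len <- as.numeric(fields[[which(kind == "length")]][-1L])

  scale <- structure(list(
    c0 = setNames(c0, AA20), c1 = setNames(c1, AA20),
    e0 = setNames(e0, AA20), e1 = setNames(e1, AA20),
    e2 = setNames(e2, AA20),
    has_extra = setNames(has_extra, AA20),
    moment_coef = mom[1L],
    helix_angle_deg = mom[2L],
    # length polynomial: len[1] + len[2]*L + len[3]*L^2
    len_coefs = len,
    min_len = 9L, max_len = 40L,
    provenance = paste0("dg_scale_full_model v1 <", basename(file), ">")
  ), class = "dg_scale")

  if (default) assign("default_scale", scale, envir = .memtopo_cache)
  scale
}

.memtopo_cache <- new.env(parent = emptyenv())

#' @export
print.dg_scale <- function(x, ...) {
  cat("Biological hydrophobicity scale (full model)\n")
  cat("  provenance:      ", x$provenance, "\n", sep = "")
  cat("  moment coef:     ", x$moment_coef, " (", x$helix_angle_deg,
      " deg/residue)\n", sep = "")
  cat("  length poly:     ", paste(signif(x$len_coefs, 6), collapse = ", "),
      " (intercept, L, L^2)\n", sep = "")
  cat("  supported length:", x$min_len, "-", x$max_len, "aa\n")
  invisible(x)
}

# Per-position contribution vectors for a window of length L: a list with
# 20 x L matrices of base contributions and their sin/cos-weighted versions.
# Rows indexed by aa code (match against AA20), columns by window position.
dg_position_weights <- function(L, scale) {
  if (L < 2L) stop("segment length must be at least 2")
  key <- paste0(scale$provenance, "#", L)
  hit <- get0(key, envir = .memtopo_weights)
  if (!is.null(hit)) return(hit)
  i <- 0:(L - 1L)
  x <- 9 * (2 * i / (L - 1L) - 1)
  # base[aa, pos]
  base <- outer(scale$c0, rep(1, L)) * exp(-outer(scale$c1, x^2))
  if (any(scale$has_extra)) {
    idx <- which(scale$has_extra)
    for (k in idx) {
      base[k, ] <- base[k, ] + scale$e0[k] *
        (exp(-scale$e1[k] * (x - scale$e2[k])^2) +
         exp(-scale$e1[k] * (x + scale$e2[k])^2))
    }
  }
  ang <- scale$helix_angle_deg * pi / 180
  out <- list(base = base,
              sinw = sweep(base, 2L, sin(ang * i), `*`),
              cosw = sweep(base, 2L, cos(ang * i), `*`),
              L = L)
  assign(key, out, envir = .memtopo_weights)
  out
}

.memtopo_weights <- new.env(parent = emptyenv())

dg_length_term <- function(L, scale) {
  scale$len_coefs[1L] + scale$len_coefs[2L] * L + scale$len_coefs[3L] * L^2
}
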