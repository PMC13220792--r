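# Independent oracles, deliberately implemented apart from the package code
# paths: the dG oracle re-reads the raw coefficient file and evaluates the
# published formula with plain loops; the scan oracle enumerates every
# window.

read_scale_coefs <- function() {
  file <- system.file("extdata", "dg_scale_full_model.tsv",
                      package = "memtopo", mustWork = TRUE)
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t")
  kind <- vapply(fields, `[[`, "", 1L)
  prof <- list()
  for (f in fields[kind == "profile"]) {
    prof[[f[2L]]] <- as.numeric(f[-(1:2)])
  }
  list(profiles = prof,
       moment = as.numeric(fields[[which(kind == "moment")]][-1L]),
       len = as.numeric(fields[[which(kind == "length")]][-1L]))
}

# literal evaluation of the segment score from the raw coefficients
oracle_dg <- function(segment, coefs = read_scale_coefs()) {
  chars <- strsplit(segment, "")[[1L]]
  L <- length(chars)
  contrib <- numeric(L)
  for (k in seq_len(L)) {
    p <- coefs$profiles[[chars[k]]]
    x <- 9 * (2 * (k - 1) / (L - 1) - 1)
    v <- p[1L] * exp(-p[2L] * x^2)
    if (length(p) >= 5L) {
      v <- v + p[3L] * (exp(-p[4L] * (x - p[5L])^2) +
                        exp(-p[4L] * (x + p[5L])^2))
    }
    contrib[k] <- v
  }
  ang <- coefs$moment[2L] * pi / 180
  s_sin <- 0; s_cos <- 0
  for (k in seq_len(L)) {
    s_sin <- s_sin + contrib[k] * sin(ang * (k - 1))
    s_cos <- s_cos + contrib[k] * cos(ang * (k - 1))
  }
  sum(contrib) + coefs$moment[1L] * sqrt(s_sin^2 + s_cos^2) +
    coefs$len[1L] + coefs$len[2L] * L + coefs$len[3L] * L^2
}

# exhaustive enumeration of all (start, length) windows; ties resolved to
# the smallest start, then the smallest length
oracle_scan <- function(sequence, lmin, lmax, coefs = read_scale_coefs()) {
  n <- nchar(sequence)
  best <- NULL
  for (start in seq_len(n)) {
    for (L in lmin:lmax) {
      if (start + L - 1L > n) next
      dg <- oracle_dg(substr(sequence, start, start + L - 1L), coefs)
      if (is.null(best) || dg < best$dg ||
          (dg == best$dg && (start < best$start ||
                             (start == best$start && L < best$len)))) {
        best <- list(dg = dg, start = start, len = L)
      }
    }
  }
  best
}

random_aa_seq <- function(n, alphabet = memtopo:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

reverse_seq <- function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = "")
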