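# ---- quadripartite (LSC / IRb / SSC / IRa) structure detection --------------

#' Detect the quadripartite structure of a plastome
#'
#' Searches the circular genome for the maximal-length pair of disjoint
#' *exact* inverted repeats of at least `min_ir_len` bp (seed-and-extend over
#' the sequence versus its reverse complement) and returns them together with
#' the two single-copy regions they bound.  The larger single-copy region is
#' labelled LSC and the repeat immediately downstream of it (clockwise, plus
#' strand) IRb, matching the conventional LSC-IRb-SSC-IRa order.  Ties in
#' repeat length are broken by leftmost start.
#'
#' Repeats and single-copy regions may span the origin; such intervals are
#' reported with `end < start` and are interpreted modulo the genome length.
#'
#' @param genome An [annotated_plastome()].
#' @param min_ir_len Minimum inverted-repeat length in bp (default 1000).
#' @return A `quadripartite_structure` (list with intervals `lsc`, `irb`,
#'   `ssc`, `ira`, each `c(start, end)`, and `ir_length`), or `NULL` when no
#'   inverted repeat of the required length exists.
#' @export
detect_quadripartite <- function(genome, min_ir_len = 1000L) {
  s <- genome$sequence
  L <- genome$length
  min_ir_len <- as.integer(min_ir_len)
  if (min_ir_len < 1L) stop("'min_ir_len' must be positive")
  if (L < 2L * min_ir_len) return(NULL)

  k <- min(min_ir_len, 12L)
  sv <- strsplit(s, "", fixed = TRUE)[[1L]]
  cv <- strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]
  sd <- paste0(s, substr(s, 1L, k))
  km <- substring(sd, seq_len(L), seq_len(L) + k - 1L)
  rck <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  uniq <- unique(km)
  km_id <- match(km, uniq)
  rck_id <- match(rck, uniq)
  pos_by_id <- split(seq_len(L), km_id)

  wrap <- function(x) ((x - 1L) %% L) + 1L
  processed <- logical(L)
  best <- NULL

  for (j in seq_len(L)) {
    id <- rck_id[j]
    if (is.na(id)) next
    for (i in pos_by_id[[id]]) {
      cmod <- ((i + j + k - 2L) %% L) + 1L
      if (processed[cmod]) next
      processed[cmod] <- TRUE
      # seed: s[i..i+k-1] == revcomp(s[j..j+k-1]); require disjoint copies
      a1 <- i; a2 <- i + k - 1L; b1 <- j; b2 <- j + k - 1L
      gap1 <- (b1 - a2 - 1L) %% L   # arc from a-copy end to b-copy start
      gap2 <- (a1 - b2 - 1L) %% L   # arc from b-copy end to a-copy start
      if (2L * k + gap1 + gap2 != L) next   # overlapping copies
      while (gap1 >= 2L && sv[wrap(a2 + 1L)] == cv[wrap(b1 - 1L)]) {
        a2 <- a2 + 1L; b1 <- b1 - 1L; gap1 <- gap1 - 2L
      }
      while (gap2 >= 2L && sv[wrap(a1 - 1L)] == cv[wrap(b2 + 1L)]) {
        a1 <- a1 - 1L; b2 <- b2 + 1L; gap2 <- gap2 - 2L
      }
      replen <- a2 - a1 + 1L
      cand_start <- min(wrap(a1), wrap(b1))
      if (is.null(best) || replen > best$len ||
          (replen == best$len && cand_start < best$start)) {
        best <- list(len = replen, start = cand_start,
                     a = c(a1, a2), b = c(b1, b2),
                     gap1 = gap1, gap2 = gap2)
      }
    }
  }

  if (is.null(best) || best$len < min_ir_len) return(NULL)

  a <- wrap(best$a); b <- wrap(best$b)
  # single-copy arcs: gap1 runs a-end -> b-start, gap2 runs b-end -> a-start
  sc1 <- c(wrap(best$a[2L] + 1L), wrap(best$b[1L] - 1L))   # length gap1
  sc2 <- c(wrap(best$b[2L] + 1L), wrap(best$a[1L] - 1L))   # length gap2
  if (best$gap1 >= best$gap2) {
    lsc <- sc1; ssc <- sc2; irb <- b; ira <- a
  } else {
    lsc <- sc2; ssc <- sc1; irb <- a; ira <- b
  }
  out <- structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                        ir_length = best$len, genome_length = L),
                   class = "quadripartite_structure")
  stopifnot(identical(region_sequence(genome, out$irb),
                      revcomp(region_sequence(genome, out$ira))))
  out
}

#' Length of a (possibly origin-spanning) interval on the circle
#'
#' @param interval `c(start, end)`, 1-based inclusive; `end < start` wraps.
#' @param genome_length Circle length in bp.
#' @return Interval length in bp.
#' @export
interval_length <- function(interval, genome_length) {
  ((interval[2L] - interval[1L]) %% genome_length) + 1L
}

#' Extract the sequence of a circular interval
#'
#' @param genome An [annotated_plastome()].
#' @param interval `c(start, end)` 1-based inclusive; wraps when
#'   `end < start`.
#' @return Character string.
#' @export
region_sequence <- function(genome, interval) {
  circular_substr(genome$sequence, interval[1L],
                  interval_length(interval, genome$length))
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  df <- as.data.frame(x)
  cat("quadripartite_structure (IR length ", x$ir_length, " bp)\n", sep = "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.quadripartite_structure <- function(x, ...) {
  regions <- c("LSC", "IRb", "SSC", "IRa")
  ints <- list(x$lsc, x$irb, x$ssc, x$ira)
  data.frame(region = regions,
             start = vapply(ints, function(v) as.integer(v[1L]), 1L),
             end = vapply(ints, function(v) as.integer(v[2L]), 1L),
             length = vapply(ints, function(v)
               as.integer(interval_length(v, x$genome_length)), 1L))
}
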