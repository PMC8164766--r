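## Genomic-context classification of motif hits against ORF annotations.
##
## Categories (strand-aware, flank-inclusive):
##   INTERGENIC          - the flank-inclusive span ends 15-500 nt upstream of
##                         the ORF start
##   SEQUESTER_RBS_OR_AUG - the flank-inclusive span overlaps the start codon
##                         or the detected ribosome-binding site
##   INSIDE_ORF          - the motif 5' end lies after the ORF start, within
##                         100 nt of it
##   UNASSIGNED          - none of the above (includes the 1-14 nt gap the
##                         three category thresholds leave open)
## Precedence: SEQUESTER > INSIDE_ORF > INTERGENIC.

CONTEXT_LEVELS <- c("INTERGENIC", "SEQUESTER_RBS_OR_AUG", "INSIDE_ORF",
                    "UNASSIGNED")

## Strand-local geometry of one hit against a set of same-strand ORFs.
## In the local frame the ORF runs left-to-right from its start S; positions
## are 0-based half-open.  Returns vectors over the ORF rows:
##   S  - ORF start position, fs/fe - hit flank span, m5/m3 - motif span.
strand_local <- function(hit, orfs, genome_length) {
  if (hit$strand == "+") {
    list(S = orfs$start,
         fs = rep(hit$flank_start, nrow(orfs)),
         fe = rep(hit$flank_end, nrow(orfs)),
         m5 = rep(hit$start, nrow(orfs)),
         m3 = rep(hit$end, nrow(orfs)))
  } else {
    L <- genome_length
    list(S = L - orfs$end,
         fs = rep(L - hit$flank_end, nrow(orfs)),
         fe = rep(L - hit$flank_start, nrow(orfs)),
         m5 = rep(L - hit$end, nrow(orfs)),
         m3 = rep(L - hit$start, nrow(orfs)))
  }
}

## Map a strand-local half-open interval back to + frame coordinates.
local_to_plus <- function(s, e, strand, genome_length) {
  if (strand == "+") c(s, e) else c(genome_length - e, genome_length - s)
}

#' Detect a ribosome-binding site upstream of an ORF
#'
#' Scans windows of length 6, then 5, then 4 at spacers 0-15 nt upstream of
#' the start codon (strand-aware) and returns the longest AG-rich window
#' (at most one non-purine and at least 4 purines); among windows of equal
#' length, purine-perfect windows win, then the smallest spacer.
#'
#' @param genome_seq Genome sequence (DNA string, + strand).
#' @param orf One ORF row (`start`, `end`, `strand`; 0-based half-open).
#' @return A list with `start`, `end` (+ frame, 0-based half-open),
#'   `sequence` (coding-strand orientation), `spacer`, `length`; or `NULL`
#'   when no window qualifies or the contig edge leaves < 21 nt upstream.
#' @export
detect_rbs <- function(genome_seq, orf) {
  L <- nchar(genome_seq)
  upstream_len <- if (orf$strand == "+") orf$start else L - orf$end
  if (upstream_len < 21L) {
    message("ORF at contig edge: insufficient upstream sequence for RBS scan")
    return(NULL)
  }
  ## coding-strand upstream sequence, 3' end adjacent to the start codon
  if (orf$strand == "+") {
    up <- substr(genome_seq, orf$start - 21L + 1L, orf$start)
  } else {
    up <- revcomp_dna(substr(genome_seq, orf$end + 1L, orf$end + 21L))
  }
  nup <- nchar(up)
  for (len in c(6L, 5L, 4L)) {
    best <- NULL
    for (spacer in 0:15) {
      e <- nup - spacer            # window end within `up`, 1-based inclusive
      s <- e - len + 1L
      if (s < 1L) next
      win <- substr(up, s, e)
      n_purine <- nchar(gsub("[^AG]", "", win))
      if (n_purine >= 4L && (len - n_purine) <= 1L) {
        np <- len - n_purine
        if (is.null(best) || np < best$np)
          best <- list(win = win, spacer = spacer, np = np)
        if (best$np == 0L) break   # cannot improve at this length
      }
    }
    if (!is.null(best)) {
      ## map window back to + frame coordinates
      if (orf$strand == "+") {
        gs <- orf$start - best$spacer - len
        ge <- orf$start - best$spacer
      } else {
        gs <- orf$end + best$spacer
        ge <- orf$end + best$spacer + len
      }
      return(list(start = gs, end = ge, sequence = best$win,
                  spacer = best$spacer, length = len))
    }
  }
  NULL
}

empty_context <- function() {
  data.frame(category = character(), orf_id = character(),
             distance_to_start = integer(),
             rbs_start = integer(), rbs_end = integer(),
             rbs_sequence = character(), rbs_spacer = integer(),
             alt_orf = character(), terminator_overlap = logical(),
             stringsAsFactors = FALSE)
}

#' Classify one hit into a genomic-context category
#'
#' Chooses the nearest same-strand ORF whose start lies within the retained
#' window (500 nt downstream-of-hit to 100 nt upstream-of-hit in the gene's
#' frame) and applies the category rules with precedence
#' SEQUESTER > INSIDE_ORF > INTERGENIC; hits matching no rule are UNASSIGNED.
#'
#' @param hit One hit row (see [scan_genome()]).
#' @param orfs ORF `data.frame` for the hit's seqid.
#' @param genome_seq Genome sequence (DNA string, + frame).
#' @param flank_inclusive Use the flank-inclusive span for the upstream
#'   distance (flanks count toward distances); `FALSE` measures from the motif
#'   span only.
#' @return One-row `data.frame` with `category`, `orf_id`,
#'   `distance_to_start` (negative = upstream of the ORF start), RBS evidence
#'   columns, `alt_orf`, `terminator_overlap`.
#' @export
classify_context <- function(hit, orfs, genome_seq, flank_inclusive = TRUE) {
  L <- nchar(genome_seq)
  out <- data.frame(category = "UNASSIGNED", orf_id = NA_character_,
                    distance_to_start = NA_integer_,
                    rbs_start = NA_integer_, rbs_end = NA_integer_,
                    rbs_sequence = NA_character_, rbs_spacer = NA_integer_,
                    alt_orf = NA_character_, terminator_overlap = FALSE,
                    stringsAsFactors = FALSE)
  cand <- orfs[orfs$seqid == hit$seqid & orfs$strand == hit$strand, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(out)
  loc <- strand_local(hit, cand, L)
  fs <- if (flank_inclusive) loc$fs else loc$m5
  fe <- if (flank_inclusive) loc$fe else loc$m3
  ## distance from hit to ORF start: positive when the ORF start is
  ## downstream of the hit 3' end, m5 offset when the hit starts inside
  dist <- ifelse(loc$S >= fe, loc$S - fe,
                 ifelse(loc$m5 > loc$S, loc$m5 - loc$S, 0L))
  eligible <- (loc$S >= fe & loc$S - fe <= 500L) |
    (fs < loc$S + 3L & fe > loc$S) |
    (loc$m5 > loc$S & loc$m5 - loc$S <= 100L)
  if (!any(eligible)) return(out)
  pick <- which(eligible)[which.min(dist[eligible])]
  orf <- cand[pick, , drop = FALSE]
  S <- loc$S[pick]; fsx <- fs[pick]; fex <- fe[pick]; m5 <- loc$m5[pick]

  rbs <- detect_rbs(genome_seq, orf)
  rbs_local <- NULL
  if (!is.null(rbs)) {
    if (hit$strand == "+") rbs_local <- c(rbs$start, rbs$end)
    else rbs_local <- c(L - rbs$end, L - rbs$start)
    out$rbs_start <- rbs$start
    out$rbs_end <- rbs$end
    out$rbs_sequence <- rbs$sequence
    out$rbs_spacer <- rbs$spacer
  }
  out$orf_id <- orf$orf_id

  overlaps <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2
  if (overlaps(fsx, fex, S, S + 3L) ||
      (!is.null(rbs_local) && overlaps(fsx, fex, rbs_local[1], rbs_local[2]))) {
    out$category <- "SEQUESTER_RBS_OR_AUG"
    out$distance_to_start <- m5 - S
  } else if (m5 > S && m5 - S <= 100L) {
    out$category <- "INSIDE_ORF"
    out$distance_to_start <- m5 - S
  } else if (S - fex >= 15L && S - fex <= 500L) {
    out$category <- "INTERGENIC"
    out$distance_to_start <- fex - S
  } else {
    out$distance_to_start <- fex - S
  }
  out
}

#' Classify all hits and optionally rescue unassigned ones via altORFs
#'
#' @param hits Hit `data.frame` from [scan_genome()].
#' @param orfs ORF `data.frame`.
#' @param genome_seq Genome sequence (DNA string) or a one-row genome
#'   `data.frame`.
#' @param rescue Attempt altORF rescue of UNASSIGNED hits (see
#'   [find_alt_orfs()]).
#' @param terminators Annotate downstream rho-independent terminator overlap
#'   (see [find_terminator()]).
#' @param flank_inclusive See [classify_context()].
#' @return `hits` with the context columns appended (one category per hit).
#' @export
classify_contexts <- function(hits, orfs, genome_seq, rescue = TRUE,
                              terminators = FALSE, flank_inclusive = TRUE) {
  if (is.data.frame(genome_seq)) genome_seq <- genome_seq$sequence[1]
  if (nrow(hits) == 0L) return(cbind(hits, empty_context()))
  calls <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    call <- classify_context(hits[i, ], orfs, genome_seq, flank_inclusive)
    if (rescue && call$category == "UNASSIGNED") {
      resc <- rescue_with_alt_orf(hits[i, ], genome_seq, flank_inclusive)
      if (!is.null(resc)) call <- resc
    }
    if (terminators) {
      term <- find_terminator(genome_seq, hits[i, ])
      call$terminator_overlap <- !is.null(term) && term$overlaps_stem2
    }
    call
  }))
  cbind(hits, calls)
}

#' Find alternate ORFs near a hit
#'
#' Open reading frames starting at ATG, GTG or TTG with an in-frame stop,
#' at least `min_len` nt long, carrying an AG-rich RBS (per [detect_rbs()])
#' at spacer 0-15 nt.  Used to rescue UNASSIGNED hits.
#'
#' @param genome_seq Genome sequence (DNA string).
#' @param window_start,window_end Search window (+ frame, 0-based half-open).
#' @param strand Strand to search.
#' @param min_len Minimum ORF length in nt (start through stop codon).
#' @return ORF `data.frame` (possibly empty) with `seqid` NA, coordinates in
#'   the + frame.
#' @export
find_alt_orfs <- function(genome_seq, window_start, window_end, strand = "+",
                          min_len = 60L) {
  L <- nchar(genome_seq)
  window_start <- max(0L, window_start)
  window_end <- min(L, window_end)
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  ## work in the strand-local frame over the whole genome so ORFs may extend
  ## beyond the window; only the start codon must lie inside the window
  local_seq <- if (strand == "+") genome_seq else revcomp_dna(genome_seq)
  win <- if (strand == "+") c(window_start, window_end)
  else c(L - window_end, L - window_start)
  for (p in seq(win[1], win[2] - 3L)) {          # local 0-based start codon pos
    codon <- substr(local_seq, p + 1L, p + 3L)
    if (!codon %in% starts) next
    q <- p + 3L
    stop_end <- NA_integer_
    while (q + 3L <= L) {
      c3 <- substr(local_seq, q + 1L, q + 3L)
      if (c3 %in% stops) { stop_end <- q + 3L; break }
      q <- q + 3L
    }
    if (is.na(stop_end) || stop_end - p < min_len) next
    orf_plus <- local_to_plus(p, stop_end, strand, L)
    orf <- data.frame(seqid = NA_character_, start = orf_plus[1],
                      end = orf_plus[2], strand = strand,
                      orf_id = sprintf("altorf_%d_%s", orf_plus[1] + 1L,
                                       strand),
                      stringsAsFactors = FALSE)
    rbs <- detect_rbs(genome_seq, orf)
    if (is.null(rbs)) next
    found[[length(found) + 1L]] <- orf
  }
  if (length(found) == 0L)
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      orf_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, found)
}

## Re-classify an UNASSIGNED hit against altORFs found within +- 300 nt;
## only SEQUESTER or INSIDE_ORF rescues are accepted, flagged via `alt_orf`.
rescue_with_alt_orf <- function(hit, genome_seq, flank_inclusive = TRUE) {
  alt <- find_alt_orfs(genome_seq, hit$start - 300L, hit$end + 300L,
                       strand = hit$strand)
  if (nrow(alt) == 0L) return(NULL)
  alt$seqid <- hit$seqid
  call <- classify_context(hit, alt, genome_seq, flank_inclusive)
  if (call$category %in% c("SEQUESTER_RBS_OR_AUG", "INSIDE_ORF")) {
    call$alt_orf <- call$orf_id
    call
  } else NULL
}

#' Find a rho-independent terminator downstream of a hit
#'
#' Simplified surrogate for dedicated terminator callers: searches from the
#' second stem-loop through 40 nt downstream of the motif for a hairpin with
#' a stem of at least 4 bp (>= 60% G/C pairs) and a 3-8 nt loop, followed
#' within 2 nt by a run of >= 4 U (T) in the next 8 nt.
#'
#' @param genome_seq Genome sequence (DNA string).
#' @param hit One hit row.
#' @return A list with the terminator's strand-local anatomy, + frame
#'   `arm5_start`, `arm5_end`, and `overlaps_stem2`; or `NULL`.
#' @export
find_terminator <- function(genome_seq, hit) {
  L <- nchar(genome_seq)
  local_seq <- if (hit$strand == "+") genome_seq else revcomp_dna(genome_seq)
  ## strand-local coordinates of the search window and of stem2
  if (hit$strand == "+") {
    w0 <- hit$hp2_start
    w1 <- min(L, hit$end + 40L)
    stem2 <- c(hit$hp2_start, hit$hp2_end)
  } else {
    w0 <- L - hit$hp2_end
    w1 <- min(L, (L - hit$start) + 40L)
    stem2 <- c(L - hit$hp2_end, L - hit$hp2_start)
  }
  if (w1 - w0 < 12L) return(NULL)
  region <- rna_view(substr(local_seq, w0 + 1L, w1))
  x <- encode_rna5(region)
  n <- length(x)
  best <- NULL
  for (stem in 4:12) {
    for (loop in 3:8) {
      span <- 2L * stem + loop
      if (span > n) next
      for (i in 0:(n - span)) {
        ok <- TRUE
        gc <- 0L
        for (k in 0:(stem - 1L)) {
          a <- x[i + k + 1L]
          b <- x[i + span - k]
          if (PAIR_CODE5[a, b] == 0L) { ok <- FALSE; break }
          if (PAIR_CODE5[a, b] %in% c(3L, 4L)) gc <- gc + 1L
        }
        if (!ok || gc < 0.6 * stem) next
        ## U tail: within 2 nt after the hairpin, >= 4 U in the next 8 nt
        tail_found <- FALSE
        for (g in 0:2) {
          ts <- i + span + g
          te <- min(n, ts + 8L)
          if (te - ts < 4L) next
          if (sum(x[(ts + 1L):te] == 4L) >= 4L) { tail_found <- TRUE; break }
        }
        if (!tail_found) next
        arm5_local <- c(w0 + i, w0 + i + stem)
        arm5_plus <- local_to_plus(arm5_local[1], arm5_local[2], hit$strand, L)
        overlaps <- arm5_local[1] < stem2[2] && stem2[1] < arm5_local[2]
        cand <- list(stem_bp = stem, loop_len = loop,
                     hairpin_start_local = w0 + i,
                     arm5_start = min(arm5_plus), arm5_end = max(arm5_plus),
                     overlaps_stem2 = overlaps)
        if (is.null(best) ||
            cand$hairpin_start_local < best$hairpin_start_local ||
            (cand$hairpin_start_local == best$hairpin_start_local &&
             cand$stem_bp > best$stem_bp)) best <- cand
      }
    }
  }
  best
}

#' Tally context categories
#'
#' @param calls Output of [classify_contexts()].
#' @return `data.frame` with one row per category: `n`, `fraction`, and
#'   `n_alt_orf_rescued`.
#' @export
category_tally <- function(calls) {
  n <- nrow(calls)
  cat_counts <- table(factor(calls$category, levels = CONTEXT_LEVELS))
  rescued <- if (n > 0L) !is.na(calls$alt_orf) else logical(0)
  resc_counts <- table(factor(calls$category[rescued], levels = CONTEXT_LEVELS))
  data.frame(category = CONTEXT_LEVELS,
             n = as.integer(cat_counts),
             fraction = if (n > 0L) as.numeric(cat_counts) / n else 0,
             n_alt_orf_rescued = as.integer(resc_counts),
             stringsAsFactors = FALSE)
}
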