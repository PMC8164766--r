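## Genome scanning: enumerate dual stem-loop candidates, score against the
## profile, curate, threshold, deduplicate.
##
## Enumeration is complete over (position, stem length): stems are emitted at
## every length from min_stem_bp up to max_stem_bp (all sub-stems included),
## so the scorer, not the enumerator, arbitrates stem extent.  All coordinates
## below are 0-based half-open on the scanned strand; scan_genome() resolves
## them to the + strand frame.

## 5-letter encoding (A C G U N) so N never pairs and never scores.
encode_rna5 <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], c(RNA_BASES, "N"))
  if (anyNA(x)) stop("invalid character in RNA sequence", call. = FALSE)
  x
}

#' Enumerate hairpins with hexanucleotide loops
#'
#' Finds every hairpin with a 6-nt loop and a contiguous stem of canonical
#' pairs (GU wobble included) of length `min_stem_bp` to `max_stem_bp`.
#' Each distinct (position, stem length) is reported once; no hairpin may
#' span an N.
#'
#' @param seq RNA string over A, C, G, U, N.
#' @param constraints A `motif_constraints` object.
#' @return `data.frame` with 0-based `outer_start`, `outer_end`, `stem_bp`,
#'   `loop_start`, `loop_seq`.
#' @export
find_hairpins <- function(seq, constraints = motif_constraints()) {
  empty <- data.frame(outer_start = integer(), outer_end = integer(),
                      stem_bp = integer(), loop_start = integer(),
                      loop_seq = character(), stringsAsFactors = FALSE)
  m <- nchar(seq)
  if (m == 0L) return(empty)
  x <- encode_rna5(seq)
  out <- vector("list", constraints$max_stem_bp)
  for (s in constraints$min_stem_bp:constraints$max_stem_bp) {
    span <- 2L * s + 6L
    n_pos <- m - span + 1L
    if (n_pos < 1L) next
    i <- seq_len(n_pos)           # 1-based outer_start + 1
    ok <- rep(TRUE, n_pos)
    for (k in 0:(s - 1L)) {
      a <- x[i + k]
      b <- x[i + span - 1L - k]
      ok <- ok & (PAIR_CODE5[cbind(a, b)] > 0L)
    }
    ## loop must be N-free
    for (k in s:(s + 5L)) ok <- ok & (x[i + k] != 5L)
    hit <- which(ok)
    if (length(hit) == 0L) next
    out[[s]] <- data.frame(
      outer_start = hit - 1L,
      outer_end = hit - 1L + span,
      stem_bp = s,
      loop_start = hit - 1L + s,
      loop_seq = substring(seq, hit + s, hit + s + 5L),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  res[order(res$outer_start, res$stem_bp), , drop = FALSE]
}

#' Pair hairpins into dual stem-loop candidates
#'
#' All ordered hairpin pairs on one sequence whose gap (linker) lies within
#' the constraint bounds; the two hairpins never overlap (linker >= 2).
#'
#' @param hairpins Output of [find_hairpins()] for one sequence/strand.
#' @param constraints A `motif_constraints` object.
#' @return `data.frame` with index columns `i1`, `i2` into `hairpins` and
#'   `linker_len`.
#' @export
pair_hairpins <- function(hairpins, constraints = motif_constraints()) {
  empty <- data.frame(i1 = integer(), i2 = integer(), linker_len = integer())
  n <- nrow(hairpins)
  if (n < 2L) return(empty)
  ord <- order(hairpins$outer_start)
  starts <- hairpins$outer_start[ord]
  lo <- findInterval(hairpins$outer_end + constraints$linker_min - 0.5, starts) + 1L
  hi <- findInterval(hairpins$outer_end + constraints$linker_max + 0.5, starts)
  lens <- pmax(hi - lo + 1L, 0L)
  if (sum(lens) == 0L) return(empty)
  nz <- lens > 0L
  i1 <- rep.int(seq_len(n)[nz], lens[nz])
  i2 <- ord[sequence(lens[nz], from = lo[nz])]
  linker <- hairpins$outer_start[i2] - hairpins$outer_end[i1]
  data.frame(i1 = i1, i2 = i2, linker_len = linker)
}

## Per-hairpin loop and stem scores against one side of the profile.
hairpin_scores <- function(hairpins, x, loop_tab, stem_tab) {
  n <- nrow(hairpins)
  if (n == 0L) return(list(loop = numeric(), stem = numeric()))
  lsc <- numeric(n)
  for (pos in 1:6) {
    base <- x[hairpins$loop_start + pos]
    lsc <- lsc + loop_tab[cbind(base, pos)]
  }
  ssc <- numeric(n)
  stem_vals <- c(stem_tab, 0)            # index 7 unused guard
  for (s in unique(hairpins$stem_bp)) {
    idx <- which(hairpins$stem_bp == s)
    o <- hairpins$outer_start[idx]
    span <- 2L * s + 6L
    acc <- numeric(length(idx))
    for (k in 0:(s - 1L)) {
      code <- PAIR_CODE5[cbind(x[o + k + 1L], x[o + span - k])]
      acc <- acc + stem_vals[code]
    }
    ssc[idx] <- acc
  }
  list(loop = lsc, stem = ssc)
}

#' Enumerate, curate and score all dual stem-loop candidates on one strand
#'
#' @param seq RNA string (one strand of one sequence).
#' @param profile An `antar_profile`.
#' @param constraints A `motif_constraints` object.
#' @return List with `n_candidates` (structural candidates before curation)
#'   and `candidates`: a `data.frame` of all candidates with anatomy columns,
#'   `curation_violations`, `curated` flag and `score` in bits.
#' @export
enumerate_candidates <- function(seq, profile,
                                 constraints = motif_constraints()) {
  hp <- find_hairpins(seq, constraints)
  pairs <- pair_hairpins(hp, constraints)
  if (nrow(pairs) == 0L)
    return(list(n_candidates = 0L, candidates = empty_candidates()))
  x <- encode_rna5(seq)
  s1 <- hairpin_scores(hp, x, profile$loop_logodds[[1]], profile$stem_logodds[[1]])
  s2 <- hairpin_scores(hp, x, profile$loop_logodds[[2]], profile$stem_logodds[[2]])
  linker_term <- unname(profile$linker_logodds[as.character(pairs$linker_len)])
  score <- s1$loop[pairs$i1] + s1$stem[pairs$i1] +
    s2$loop[pairs$i2] + s2$stem[pairs$i2] + linker_term
  loop1 <- hp$loop_seq[pairs$i1]
  loop2 <- hp$loop_seq[pairs$i2]
  violations <- (substr(loop1, 1, 1) != "A") + (substr(loop1, 4, 4) != "G") +
    (substr(loop2, 1, 1) != "A") + (substr(loop2, 4, 4) != "G")
  cand <- data.frame(
    start = hp$outer_start[pairs$i1],
    end = hp$outer_end[pairs$i2],
    hp1_start = hp$outer_start[pairs$i1], hp1_end = hp$outer_end[pairs$i1],
    hp1_bp = hp$stem_bp[pairs$i1], loop1 = loop1,
    linker_len = pairs$linker_len,
    hp2_start = hp$outer_start[pairs$i2], hp2_end = hp$outer_end[pairs$i2],
    hp2_bp = hp$stem_bp[pairs$i2], loop2 = loop2,
    curation_violations = as.integer(violations),
    score = score,
    stringsAsFactors = FALSE)
  cand$curated <- cand$curation_violations <= constraints$max_conserved_violations
  list(n_candidates = nrow(cand), candidates = cand)
}

empty_candidates <- function() {
  data.frame(start = integer(), end = integer(),
             hp1_start = integer(), hp1_end = integer(), hp1_bp = integer(),
             loop1 = character(), linker_len = integer(),
             hp2_start = integer(), hp2_end = integer(), hp2_bp = integer(),
             loop2 = character(), curation_violations = integer(),
             score = numeric(), curated = logical(),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(seqid = character(), strand = character(),
             start = integer(), end = integer(),
             flank_start = integer(), flank_end = integer(),
             hp1_start = integer(), hp1_end = integer(), hp1_bp = integer(),
             loop1 = character(), linker_len = integer(),
             hp2_start = integer(), hp2_end = integer(), hp2_bp = integer(),
             loop2 = character(), score = numeric(),
             curation_violations = integer(), motif_seq = character(),
             stringsAsFactors = FALSE)
}

#' Scan a genome for ANTAR-target dual stem-loop hits
#'
#' Both strands are scanned; candidates pass the curation filter, then the
#' bit-score threshold, then overlap deduplication.  When ORF annotations are
#' supplied, only hits lying between 500 nt upstream and 100 nt downstream of
#' the nearest same-strand ORF start are retained (without annotations, all
#' hits are emitted and the positional filter defers to the context
#' classifier).  Coordinates are reported on the + strand frame, 0-based
#' half-open.
#'
#' @param genome A one-row `data.frame` from [read_fasta()], or a list/row
#'   with `id` and `sequence` (DNA).
#' @param profile An `antar_profile`.
#' @param min_bits Bit-score threshold (set explicitly or via
#'   [calibrate_threshold()]).
#' @param constraints A `motif_constraints` object.
#' @param orfs Optional ORF `data.frame` (see [read_gff3()]).
#' @param verbose Log per-stage candidate counts to stderr.
#' @return Hit `data.frame` (one row per retained hit).
#' @export
scan_genome <- function(genome, profile, min_bits,
                        constraints = motif_constraints(), orfs = NULL,
                        verbose = FALSE) {
  seqid <- if (is.data.frame(genome)) genome$id[1] else genome$id
  dna <- if (is.data.frame(genome)) genome$sequence[1] else genome$sequence
  L <- nchar(dna)
  min_span <- 2L * (2L * constraints$min_stem_bp + 6L) + constraints$linker_min
  if (L < min_span) {
    message(sprintf("genome '%s' (%d nt) is shorter than the minimal motif (%d nt)",
                    seqid, L, min_span))
    return(empty_hits())
  }
  rna_plus <- rna_view(dna)
  rna_minus <- revcomp_rna(rna_plus)

  per_strand <- function(rna, strand) {
    en <- enumerate_candidates(rna, profile, constraints)
    cand <- en$candidates
    cand <- cand[cand$curated & cand$score >= min_bits, , drop = FALSE]
    if (nrow(cand) == 0L)
      return(list(n = en$n_candidates, hits = empty_hits()))
    if (strand == "-") {
      ## mirror strand-local [s, e) to + frame [L - e, L - s)
      flip <- function(s, e) list(start = L - e, end = L - s)
      sp <- flip(cand$start, cand$end)
      h1 <- flip(cand$hp1_start, cand$hp1_end)
      h2 <- flip(cand$hp2_start, cand$hp2_end)
      hits <- data.frame(
        seqid = seqid, strand = "-",
        start = sp$start, end = sp$end,
        flank_start = pmax(0L, sp$start - 10L),
        flank_end = pmin(L, sp$end + 10L),
        hp1_start = h1$start, hp1_end = h1$end, hp1_bp = cand$hp1_bp,
        loop1 = cand$loop1, linker_len = cand$linker_len,
        hp2_start = h2$start, hp2_end = h2$end, hp2_bp = cand$hp2_bp,
        loop2 = cand$loop2, score = cand$score,
        curation_violations = cand$curation_violations,
        motif_seq = substring(rna, cand$start + 1L, cand$end),
        stringsAsFactors = FALSE)
    } else {
      hits <- data.frame(
        seqid = seqid, strand = "+",
        start = cand$start, end = cand$end,
        flank_start = pmax(0L, cand$start - 10L),
        flank_end = pmin(L, cand$end + 10L),
        hp1_start = cand$hp1_start, hp1_end = cand$hp1_end,
        hp1_bp = cand$hp1_bp, loop1 = cand$loop1,
        linker_len = cand$linker_len,
        hp2_start = cand$hp2_start, hp2_end = cand$hp2_end,
        hp2_bp = cand$hp2_bp, loop2 = cand$loop2, score = cand$score,
        curation_violations = cand$curation_violations,
        motif_seq = substring(rna, cand$start + 1L, cand$end),
        stringsAsFactors = FALSE)
    }
    list(n = en$n_candidates, hits = hits)
  }

  plus <- per_strand(rna_plus, "+")
  minus <- per_strand(rna_minus, "-")
  hits <- rbind(plus$hits, minus$hits)
  n_thresholded <- nrow(hits)
  hits <- dedup_overlapping(hits)
  n_deduped <- nrow(hits)
  if (!is.null(orfs) && nrow(hits) > 0L)
    hits <- hits[orf_proximity_keep(hits, orfs, L), , drop = FALSE]
  if (verbose)
    message(sprintf(
      "scan %s: %d candidates -> %d curated+thresholded -> %d deduped -> %d retained",
      seqid, plus$n + minus$n, n_thresholded, n_deduped, nrow(hits)))
  rownames(hits) <- NULL
  hits
}

## Positional retention: keep hits between 500 nt upstream and 100 nt
## downstream of the nearest same-strand ORF start (flank-inclusive for the
## upstream measure, motif 5' end for the downstream measure).
orf_proximity_keep <- function(hits, orfs, genome_length) {
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    cand <- orfs[orfs$seqid == h$seqid & orfs$strand == h$strand, , drop = FALSE]
    if (nrow(cand) == 0L) return(FALSE)
    loc <- strand_local(h, cand, genome_length)
    any((loc$S - loc$fe >= 0 & loc$S - loc$fe <= 500) |   # upstream
          (loc$fs < loc$S + 3 & loc$fe > loc$S) |          # overlaps start region
          (loc$m5 > loc$S & loc$m5 - loc$S <= 100))        # inside, near start
  }, logical(1))
}

#' Deduplicate overlapping hits
#'
#' Among hits on one seqid whose dual-stem spans overlap by more than 50% of
#' the shorter span, only the highest-scoring hit is kept (ties: leftmost
#' start, then + strand).
#'
#' @param hits Hit `data.frame`.
#' @return Deduplicated hit `data.frame`.
#' @export
dedup_overlapping <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- logical(0)
  out <- vector("list", length(unique(hits$seqid)))
  ix <- 0L
  for (sq in unique(hits$seqid)) {
    h <- hits[hits$seqid == sq, , drop = FALSE]
    ord <- order(-h$score, h$start, h$strand != "+")
    h <- h[ord, , drop = FALSE]
    kept <- integer()
    for (i in seq_len(nrow(h))) {
      ov <- FALSE
      for (j in kept) {
        inter <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
        shorter <- min(h$end[i] - h$start[i], h$end[j] - h$start[j])
        if (inter > 0.5 * shorter) { ov <- TRUE; break }
      }
      if (!ov) kept <- c(kept, i)
    }
    ix <- ix + 1L
    out[[ix]] <- h[sort(kept), , drop = FALSE]
  }
  res <- do.call(rbind, out[seq_len(ix)])
  res[order(res$seqid, res$start), , drop = FALSE]
}

#' Collapse identical hits across strains of a species
#'
#' Within a species label, hits whose motif sequences (flanks excluded) are
#' exactly identical collapse to a single representative: the
#' lexicographically smallest seqid, then the smallest start.  The number of
#' collapsed members is retained as `multiplicity`.
#'
#' @param hits Hit `data.frame`.
#' @param species Character vector of species labels, one per hit.
#' @return Representative hits with a `multiplicity` column.
#' @export
collapse_identical <- function(hits, species) {
  if (nrow(hits) == 0L) return(cbind(hits, multiplicity = integer()))
  stopifnot(length(species) == nrow(hits))
  key <- paste(species, hits$motif_seq, sep = "\r")
  reps <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    r <- h[order(h$seqid, h$start)[1], , drop = FALSE]
    r$multiplicity <- length(idx)
    r
  })
  res <- do.call(rbind, reps)
  res <- res[order(res$seqid, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
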