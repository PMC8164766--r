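## Probabilistic model of the ANTAR-target dual stem-loop family, plus the
## hard curation rules (hexanucleotide loops with conserved A1/G4, 2-25 nt
## linker, >= 3 bp stems).

#' Structural constraints of the dual stem-loop motif
#'
#' @param loop_length Loop length in nt; the family has hexanucleotide loops
#'   (fixed at 6).
#' @param min_stem_bp Minimum contiguous canonical base pairs per stem.
#' @param max_stem_bp Maximum stem length enumerated by the scanner.
#' @param linker_min,linker_max Allowed linker length range in nt.
#' @param max_conserved_violations Number of mismatches tolerated across the
#'   four constrained loop positions (A1/G4 of each loop).  The default 1
#'   reads "allowing a single point variation" as one violation per motif;
#'   set 2 for the per-loop reading.
#' @return A `motif_constraints` object.
#' @export
motif_constraints <- function(loop_length = 6L, min_stem_bp = 3L,
                              max_stem_bp = 10L, linker_min = 2L,
                              linker_max = 25L,
                              max_conserved_violations = 1L) {
  if (loop_length != 6L) stop("loop_length is fixed at 6 nt", call. = FALSE)
  if (min_stem_bp < 3L) stop("min_stem_bp must be >= 3", call. = FALSE)
  if (linker_min < 2L || linker_max > 25L || linker_min > linker_max)
    stop("linker bounds must satisfy 2 <= linker_min <= linker_max <= 25",
         call. = FALSE)
  structure(list(loop_length = 6L, min_stem_bp = as.integer(min_stem_bp),
                 max_stem_bp = as.integer(max_stem_bp),
                 linker_min = as.integer(linker_min),
                 linker_max = as.integer(linker_max),
                 conserved = c(`1` = "A", `4` = "G"),
                 max_conserved_violations = as.integer(max_conserved_violations)),
            class = "motif_constraints")
}

#' Build a motif profile from a seed alignment
#'
#' Loop tables are per-column nucleotide log-odds (base 2) against the
#' background, with a Laplace-style pseudocount distributed by the background.
#' Stem tables are log-odds over the six canonical pair types, pooled across
#' the paired columns of each stem (rows whose two pairing characters do not
#' form a canonical pair are ignored), against the background pair-type
#' probability conditional on canonical pairing.  The linker term is the
#' log-odds of the observed linker-length distribution against a uniform
#' distribution over 2..25 nt.
#'
#' @param seed A `seed_alignment`.
#' @param background Nucleotide frequency vector (ACGU order); defaults to
#'   uniform.  When scanning, pass the scanned genome's mononucleotide
#'   frequencies (high-GC genomes otherwise inflate GC-stem scores).
#' @param pseudocount Positive pseudocount mass (default 1).
#' @return An `antar_profile` object.
#' @export
build_profile <- function(seed, background = rep(0.25, 4), pseudocount = 1.0) {
  stopifnot(inherits(seed, "seed_alignment"))
  n <- length(seed$rows)
  if (n < 2L) stop("seed alignment needs >= 2 rows", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  background <- stats::setNames(background / sum(background), RNA_BASES)
  mat <- do.call(rbind, strsplit(seed$rows, "", fixed = TRUE))
  ann <- seed$annotation

  loop_logodds <- vector("list", 2L)
  consensus_loops <- character(2L)
  for (h in 1:2) {
    cols <- ann$hairpins[[h]]$loop_cols
    tab <- matrix(NA_real_, 4, 6, dimnames = list(RNA_BASES, NULL))
    cons <- character(6)
    for (k in seq_len(6)) {
      obs <- mat[, cols[k]]
      obs <- obs[obs %in% RNA_BASES]
      counts <- table(factor(obs, levels = RNA_BASES))
      freq <- (as.numeric(counts) + pseudocount * background) /
        (length(obs) + pseudocount)
      tab[, k] <- log2(freq / background)
      cons[k] <- RNA_BASES[which.max(freq)]
    }
    loop_logodds[[h]] <- tab
    consensus_loops[h] <- paste(cons, collapse = "")
  }

  ## background pair-type probability conditional on canonical pairing
  bg_pair <- vapply(PAIR_TYPES, function(p) {
    background[substr(p, 1, 1)] * background[substr(p, 2, 2)]
  }, numeric(1))
  bg_pair <- bg_pair / sum(bg_pair)

  stem_logodds <- vector("list", 2L)
  consensus_pairs <- character(2L)
  stem_cols_n <- integer(2L)
  for (h in 1:2) {
    pc <- ann$hairpins[[h]]$pair_cols
    stem_cols_n[h] <- nrow(pc)
    counts <- stats::setNames(numeric(6), PAIR_TYPES)
    for (r in seq_len(nrow(pc))) {
      a <- mat[, pc[r, 1]]
      b <- mat[, pc[r, 2]]
      ok <- a %in% RNA_BASES & b %in% RNA_BASES
      code <- PAIR_CODE[cbind(match(a[ok], RNA_BASES), match(b[ok], RNA_BASES))]
      if (all(code == 0L) && sum(ok) > 0L)
        stop(sprintf(
          "paired columns (%d, %d) contain no canonical pair in any row",
          pc[r, 1], pc[r, 2]), call. = FALSE)
      tb <- tabulate(code[code > 0L], nbins = 6)
      counts <- counts + tb
    }
    freq <- (counts + pseudocount / 6) / (sum(counts) + pseudocount)
    stem_logodds[[h]] <- log2(freq / bg_pair)
    consensus_pairs[h] <- PAIR_TYPES[which.max(freq)]
  }

  ## linker length distribution over 2..25
  if (length(ann$linker_cols) > 0L) {
    linker_mat <- mat[, ann$linker_cols, drop = FALSE]
    lengths <- apply(linker_mat, 1, function(r) sum(r %in% RNA_BASES))
  } else lengths <- rep(0L, n)
  lengths <- lengths[lengths >= 2L & lengths <= 25L]
  counts <- tabulate(factor(lengths, levels = 2:25), nbins = 24)
  linker_prob <- (counts + pseudocount / 24) / (length(lengths) + pseudocount)
  linker_logodds <- stats::setNames(log2(linker_prob * 24), 2:25)

  prof <- structure(list(
    loop_logodds = loop_logodds,
    stem_logodds = stem_logodds,
    linker_logodds = linker_logodds,
    background = background,
    pseudocount = pseudocount,
    n_seed_rows = n,
    consensus = list(loops = consensus_loops, pairs = consensus_pairs,
                     stem_bp = stem_cols_n,
                     linker_len = as.integer(names(which.max(linker_logodds))))
  ), class = "antar_profile")
  prof$max_score <- profile_max_score(prof)
  prof
}

## Maximum attainable bit score: maximize every additive term over the
## admissible candidate space (stem lengths in [min, max] bp).
profile_max_score <- function(profile,
                              constraints = motif_constraints()) {
  loops <- sum(vapply(profile$loop_logodds,
                      function(t) sum(apply(t, 2, max)), numeric(1)))
  stems <- sum(vapply(profile$stem_logodds, function(t) {
    m <- max(t)
    if (m > 0) m * constraints$max_stem_bp else m * constraints$min_stem_bp
  }, numeric(1)))
  loops + stems + max(profile$linker_logodds)
}

#' Score a candidate motif against a profile
#'
#' The bit score is the sum of per-position loop log-odds, per-pair stem
#' log-odds, and the linker-length log-odds term.  It is bounded above by
#' `profile$max_score`.
#'
#' @param profile An `antar_profile`.
#' @param cand A candidate motif: list with `loop1`, `loop2` (6-nt RNA
#'   strings), `stem1_pairs`, `stem2_pairs` (character vectors of canonical
#'   pair types, outer to inner), `linker_len`.
#' @param constraints Structural bounds the candidate must satisfy; violating
#'   them is a contract error (the scanner pre-filters).
#' @return Bit score (numeric scalar).
#' @export
score_candidate <- function(profile, cand,
                            constraints = motif_constraints()) {
  validate_candidate(cand, constraints)
  loop_score <- function(tab, loop) {
    idx <- match(strsplit(loop, "", fixed = TRUE)[[1]], RNA_BASES)
    sum(tab[cbind(idx, 1:6)])
  }
  stem_score <- function(tab, pairs) sum(tab[pairs])
  loop_score(profile$loop_logodds[[1]], cand$loop1) +
    loop_score(profile$loop_logodds[[2]], cand$loop2) +
    stem_score(profile$stem_logodds[[1]], cand$stem1_pairs) +
    stem_score(profile$stem_logodds[[2]], cand$stem2_pairs) +
    profile$linker_logodds[[as.character(cand$linker_len)]]
}

validate_candidate <- function(cand, constraints) {
  if (nchar(cand$loop1) != 6L || nchar(cand$loop2) != 6L)
    stop("contract error: candidate loops must be exactly 6 nt", call. = FALSE)
  for (p in c(cand$stem1_pairs, cand$stem2_pairs))
    if (!p %in% PAIR_TYPES)
      stop("contract error: non-canonical stem pair '", p, "'", call. = FALSE)
  if (length(cand$stem1_pairs) < constraints$min_stem_bp ||
      length(cand$stem2_pairs) < constraints$min_stem_bp)
    stop("contract error: stems must have >= min_stem_bp pairs", call. = FALSE)
  if (cand$linker_len < constraints$linker_min ||
      cand$linker_len > constraints$linker_max)
    stop("contract error: linker length out of bounds", call. = FALSE)
  invisible(TRUE)
}

#' Curation filter: conserved loop positions A1 and G4
#'
#' Checks the four constrained positions (position 1 = A and position 4 = G in
#' each hexanucleotide loop) and passes candidates with at most
#' `max_conserved_violations` mismatches (default: one point variation per
#' motif).
#'
#' @param cand Candidate motif (needs `loop1`, `loop2`).
#' @param constraints A `motif_constraints` object.
#' @return List with `pass` (logical), `violations` (count), `reasons`
#'   (character vector naming each violated position).
#' @export
curation_filter <- function(cand, constraints = motif_constraints()) {
  reasons <- character()
  for (h in 1:2) {
    loop <- if (h == 1) cand$loop1 else cand$loop2
    for (pos in names(constraints$conserved)) {
      want <- constraints$conserved[[pos]]
      got <- substr(loop, as.integer(pos), as.integer(pos))
      if (got != want)
        reasons <- c(reasons, sprintf("loop%d position %s is %s, expected %s",
                                      h, pos, got, want))
    }
  }
  list(pass = length(reasons) <= constraints$max_conserved_violations,
       violations = length(reasons), reasons = reasons)
}

#' Consensus motif anatomy of a profile
#'
#' The argmax candidate: most probable base at each loop position, most
#' probable pair type repeated over the seed's stem lengths (capped to the
#' constraint bounds), most probable linker length.  The linker is filled
#' with A (inert: it cannot pair with itself or with G/C stems).
#'
#' @param profile An `antar_profile`.
#' @param constraints Structural bounds.
#' @return A candidate-motif list with an additional `sequence` field (RNA).
#' @export
consensus_motif <- function(profile, constraints = motif_constraints()) {
  stem_bp <- pmin(pmax(profile$consensus$stem_bp, constraints$min_stem_bp),
                  constraints$max_stem_bp)
  anatomy <- antar_anatomy(
    loops = profile$consensus$loops,
    stems = list(rep(profile$consensus$pairs[1], stem_bp[1]),
                 rep(profile$consensus$pairs[2], stem_bp[2])),
    linker = strrep("A", profile$consensus$linker_len))
  anatomy
}

#' Describe a dual stem-loop motif by its anatomy
#'
#' @param loops Character vector of two 6-nt RNA loops.
#' @param stems List of two character vectors of canonical pair types
#'   (outer to inner).
#' @param linker Linker RNA string (length 2-25).
#' @return A candidate-motif list with the assembled `sequence` (RNA).
#' @export
antar_anatomy <- function(loops, stems, linker) {
  arm5 <- function(pairs) paste(substr(pairs, 1, 1), collapse = "")
  arm3 <- function(pairs) paste(rev(substr(pairs, 2, 2)), collapse = "")
  seq <- paste0(arm5(stems[[1]]), loops[1], arm3(stems[[1]]), linker,
                arm5(stems[[2]]), loops[2], arm3(stems[[2]]))
  list(loop1 = loops[1], loop2 = loops[2],
       stem1_pairs = stems[[1]], stem2_pairs = stems[[2]],
       linker = linker, linker_len = nchar(linker), sequence = seq)
}

#' @export
print.antar_profile <- function(x, ...) {
  cat(sprintf(
    "antar_profile: %d seed rows, stems %s bp, consensus loops %s/%s, max score %.2f bits\n",
    x$n_seed_rows, paste(x$consensus$stem_bp, collapse = "/"),
    x$consensus$loops[1], x$consensus$loops[2], x$max_score))
  invisible(x)
}

#' Serialize a motif profile to a versioned JSON file
#'
#' @param profile An `antar_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(schema = "antarscan-profile/1",
              loop_logodds = lapply(profile$loop_logodds, function(m) {
                ## one ACGU-ordered column per loop position
                stats::setNames(lapply(seq_len(ncol(m)), function(j)
                  unname(m[, j])), paste0("pos", 1:6))
              }),
              stem_logodds = lapply(profile$stem_logodds, as.list),
              linker_logodds = as.list(profile$linker_logodds),
              background = as.list(profile$background),
              pseudocount = profile$pseudocount,
              n_seed_rows = profile$n_seed_rows,
              consensus = profile$consensus,
              max_score = profile$max_score)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a motif profile from JSON
#'
#' @param path Path written by [write_profile_json()].
#' @return An `antar_profile`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$schema, "antarscan-profile/1"))
    stop("unrecognized profile schema: ", obj$schema, call. = FALSE)
  prof <- structure(list(
    loop_logodds = lapply(obj$loop_logodds, function(d) {
      m <- do.call(cbind, d)
      dimnames(m) <- list(RNA_BASES, NULL)
      m
    }),
    stem_logodds = lapply(obj$stem_logodds, function(v)
      stats::setNames(unlist(v), PAIR_TYPES)),
    linker_logodds = stats::setNames(unlist(obj$linker_logodds), 2:25),
    background = stats::setNames(unlist(obj$background), RNA_BASES),
    pseudocount = obj$pseudocount,
    n_seed_rows = obj$n_seed_rows,
    consensus = list(loops = obj$consensus$loops,
                     pairs = obj$consensus$pairs,
                     stem_bp = obj$consensus$stem_bp,
                     linker_len = obj$consensus$linker_len),
    max_score = obj$max_score
  ), class = "antar_profile")
  prof
}
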