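## Composition-preserving shuffled nulls, threshold calibration, and
## false-positive assays.
##
## Dinucleotide shuffling uses the Eulerian-trail construction on the
## nucleotide multigraph (edges = dinucleotides): a uniformly chosen
## last-edge arborescence toward the terminal residue, remaining out-edges
## uniformly permuted, then a walk from the first residue.  This preserves
## the full dinucleotide count vector and both terminal residues exactly.

#' Mononucleotide shuffle
#'
#' Independent uniform permutations of the sequence; base counts are
#' preserved exactly.
#'
#' @param seq Sequence string (DNA or RNA).
#' @param n Number of shuffles.
#' @param seed Integer seed; per-replicate streams are derived from it.
#' @param source_id Label carried into the output.
#' @return A `shuffle_set`: list with `source_id`, `mode`, `n`, `seed`,
#'   `sequences`.
#' @export
shuffle_mono <- function(seq, n, seed, source_id = "seq") {
  if (nchar(seq) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    with_seed(derive_seed(seed, source_id, "mono", i),
              paste(sample(chars), collapse = ""))
  }, character(1))
  structure(list(source_id = source_id, mode = "mono", n = n, seed = seed,
                 sequences = seqs), class = "shuffle_set")
}

#' Dinucleotide-preserving shuffle (Eulerian trail)
#'
#' Every shuffle preserves the exact dinucleotide count vector and the first
#' and last residues.  A sequence whose dinucleotide graph admits a single
#' trail (e.g. a homopolymer) is returned unchanged.
#'
#' @inheritParams shuffle_mono
#' @return A `shuffle_set`.
#' @export
shuffle_di <- function(seq, n, seed, source_id = "seq") {
  if (nchar(seq) < 3L) stop("sequence must have length >= 3", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    with_seed(derive_seed(seed, source_id, "di", i), euler_shuffle(chars))
  }, character(1))
  structure(list(source_id = source_id, mode = "di", n = n, seed = seed,
                 sequences = seqs), class = "shuffle_set")
}

## One dinucleotide-preserving shuffle of a character vector.
euler_shuffle <- function(chars) {
  m <- length(chars)
  verts <- unique(chars)
  if (length(verts) == 1L) return(paste(chars, collapse = ""))
  from <- chars[-m]
  to <- chars[-1L]
  s <- chars[1L]
  t <- chars[m]
  adj <- split(to, factor(from, levels = verts))
  ## choose a random last-edge per non-terminal vertex; accept if the chosen
  ## edges form an arborescence into t (Altschul-Erickson construction)
  others <- setdiff(verts, t)
  for (attempt in 1:1000) {
    last_edge <- vapply(others, function(v) {
      out <- adj[[v]]
      out[sample.int(length(out), 1L)]
    }, character(1))
    ## follow last edges from each vertex; all must reach t without a cycle
    ok <- all(vapply(others, function(v) {
      seen <- character()
      while (v != t) {
        if (v %in% seen || !(v %in% others)) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
    if (attempt == 1000L) return(paste(chars, collapse = ""))
  }
  ## permute remaining out-edges; append the reserved last edge
  walk_adj <- lapply(verts, function(v) {
    out <- adj[[v]]
    if (v %in% others) {
      le <- last_edge[[v]]
      out <- out[-match(le, out)]
      c(sample(out), le)
    } else sample(out)
  })
  names(walk_adj) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(m)
  res[1L] <- s
  v <- s
  for (i in 2:m) {
    nxt <- walk_adj[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    res[i] <- nxt
    v <- nxt
  }
  paste(res, collapse = "")
}

#' Build a negative-control set of shuffled sequences
#'
#' Shuffles each input sequence `per_seq` times (the standard control design for this family
#' is 30 seed RNAs x 500 shuffles = 15,000 sequences).
#'
#' @param seeds Named character vector of sequences.
#' @param per_seq Shuffles per input sequence (>= 1).
#' @param mode `"mono"` or `"di"`.
#' @param seed Integer seed.
#' @param path Optional FASTA output path (headers carry provenance:
#'   `<source>|shuffle_<mode>_<i>`).
#' @return List with `sets` (per-source `shuffle_set`s) and `sequences`
#'   (named character vector of all shuffles).
#' @export
build_negative_set <- function(seeds, per_seq, mode = c("di", "mono"),
                               seed = 1L, path = NULL) {
  mode <- match.arg(mode)
  if (length(seeds) == 0L) stop("no seed sequences supplied", call. = FALSE)
  if (per_seq < 1L) stop("per_seq must be >= 1", call. = FALSE)
  ids <- names(seeds) %||% paste0("seed", seq_along(seeds))
  if (is.null(names(seeds))) names(seeds) <- ids
  fun <- if (mode == "di") shuffle_di else shuffle_mono
  sets <- lapply(ids, function(id) fun(seeds[[id]], per_seq, seed, id))
  names(sets) <- ids
  seqs <- unlist(unname(lapply(sets, function(s) {
    stats::setNames(s$sequences,
                    sprintf("%s|shuffle_%s_%d", s$source_id, mode,
                            seq_len(s$n)))
  })), use.names = TRUE)
  if (!is.null(path)) write_fasta(seqs, path)
  list(sets = sets, sequences = seqs, mode = mode, n = length(seqs),
       seed = seed)
}

#' Calibrate the bit-score threshold on a null set
#'
#' Runs the scanner's gated candidate stream (structural enumeration followed
#' by the curation filter) over every null sequence, pools the candidate
#' scores, and returns the requested quantile (inverse empirical CDF, so
#' quantile 1 is the maximum observed null score).  Null sequences yielding
#' no candidates contribute no scores; their count is reported via attribute
#' `n_without_candidates`.
#'
#' @param profile An `antar_profile`.
#' @param null_sequences Character vector of null sequences (DNA or RNA).
#' @param quantile Quantile of the null score distribution (default 0.999).
#' @param constraints A `motif_constraints` object.
#' @return `min_bits` threshold (numeric scalar) with attributes
#'   `n_scores` and `n_without_candidates`.
#' @export
calibrate_threshold <- function(profile, null_sequences, quantile = 0.999,
                                constraints = motif_constraints()) {
  scores <- null_candidate_scores(profile, null_sequences, constraints)
  if (length(scores$scores) == 0L)
    stop(paste("no structural candidates in the null set;",
               "use more or longer null sequences"), call. = FALSE)
  thr <- unname(stats::quantile(scores$scores, probs = quantile, type = 1))
  attr(thr, "n_scores") <- length(scores$scores)
  attr(thr, "n_without_candidates") <- scores$n_empty
  thr
}

null_candidate_scores <- function(profile, null_sequences, constraints) {
  n_empty <- 0L
  scores <- vector("list", length(null_sequences))
  for (i in seq_along(null_sequences)) {
    en <- enumerate_candidates(rna_view(null_sequences[[i]]), profile,
                               constraints)
    sc <- en$candidates$score[en$candidates$curated]
    if (length(sc) == 0L) n_empty <- n_empty + 1L
    scores[[i]] <- sc
  }
  list(scores = unlist(scores), n_empty = n_empty)
}

#' False-positive assay on a null set
#'
#' Counts null sequences containing at least one curated candidate at or
#' above the threshold.
#'
#' @param profile An `antar_profile`.
#' @param null_sequences Character vector of null sequences.
#' @param min_bits Fixed bit-score threshold.
#' @param constraints A `motif_constraints` object.
#' @return List with `n_sequences`, `sequences_with_hits`, `rate`
#'   (per-sequence), and `total_hits` (per-hit count).
#' @export
fp_assay <- function(profile, null_sequences, min_bits,
                     constraints = motif_constraints()) {
  with_hit <- 0L
  total <- 0L
  for (s in null_sequences) {
    en <- enumerate_candidates(rna_view(s), profile, constraints)
    k <- sum(en$candidates$curated & en$candidates$score >= min_bits)
    if (k > 0L) with_hit <- with_hit + 1L
    total <- total + k
  }
  list(n_sequences = length(null_sequences),
       sequences_with_hits = with_hit,
       rate = with_hit / length(null_sequences),
       total_hits = total)
}
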