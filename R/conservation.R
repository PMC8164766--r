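## Clustering at identity cutoffs and structure-conservation statistics:
## simplified folding energies, structure conservation index (SCI), folding
## z-scores, per-column conservation and pairwise covariation (mutual
## information).
##
## Folding uses a weighted base-pair-maximization model (GC = 3, AU = 2,
## GU = 1; minimum loop 3 nt; no pseudoknots); energies are in surrogate
## units (negative of the maximal pair weight), not kcal/mol.

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with match 1, mismatch 0, linear gap
#' penalty 1; identity is matches divided by alignment columns (global
#' pairwise alignments contain no dual-gap columns).
#'
#' @param a,b Sequences (RNA or DNA; gaps are stripped before alignment).
#' @param details If `TRUE`, attach the aligned strings as attributes.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, details = FALSE) {
  a <- gsub("-", "", a, fixed = TRUE)
  b <- gsub("-", "", b, fixed = TRUE)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("empty sequence in pairwise_identity", call. = FALSE)
  a <- dna_view(a)
  b <- dna_view(b)
  mat <- identity_submat()
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(al))
  sa <- as.character(Biostrings::alignedSubject(al))
  pc <- strsplit(pa, "")[[1]]
  sc <- strsplit(sa, "")[[1]]
  id <- sum(pc == sc & pc != "-") / length(pc)
  if (details) {
    attr(id, "aligned_a") <- pa
    attr(id, "aligned_b") <- sa
  }
  id
}

identity_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  mat["N", "N"] <- 0
  mat
}

#' Cluster sequences by single-linkage at an identity cutoff
#'
#' Builds the graph with edges between sequence pairs whose global identity
#' is at least the cutoff; connected components of size >= 2 become clusters,
#' singletons are counted and discarded.
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @param cutoff Identity cutoff (fraction).
#' @param identity_matrix Optional precomputed identity matrix (as from
#'   [identity_matrix()]) to avoid realigning during cutoff sweeps.
#' @param stats If `TRUE`, compute per-cluster consensus and conservation
#'   statistics (see [cluster_stats()]).
#' @param n_shuffles Shuffles per member for the per-cluster mean z-score
#'   (only used when `stats = TRUE`).
#' @param seed Seed for the z-score shuffles.
#' @return A `cluster_report`: list with `cutoff`, `clusters` (list of member
#'   name vectors), `singletons_discarded`, and (when requested) `stats` per
#'   cluster.
#' @export
cluster_at_identity <- function(seqs, cutoff, identity_matrix = NULL,
                                stats = FALSE, n_shuffles = 50L, seed = 1L) {
  if (length(seqs) < 2L) stop("need >= 2 sequences to cluster", call. = FALSE)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  names(seqs) <- ids
  im <- identity_matrix %||% identity_matrix(seqs)
  adj <- im >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  members <- split(ids, comp$membership)
  clusters <- members[vapply(members, length, integer(1)) >= 2L]
  clusters <- clusters[order(-vapply(clusters, length, integer(1)))]
  names(clusters) <- NULL
  rep <- structure(list(
    cutoff = cutoff,
    clusters = clusters,
    singletons_discarded = sum(vapply(members, length, integer(1)) < 2L),
    n_sequences = length(seqs)), class = "cluster_report")
  if (stats)
    rep$stats <- lapply(clusters, function(m)
      cluster_stats(seqs[m], n_shuffles = n_shuffles, seed = seed))
  rep
}

#' Pairwise identity matrix
#'
#' @param seqs Named character vector.
#' @return Symmetric matrix of global identities.
#' @export
identity_matrix <- function(seqs) {
  n <- length(seqs)
  ids <- names(seqs) %||% paste0("seq", seq_len(n))
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
  }
  m
}

#' Sweep clustering over a range of identity cutoffs
#'
#' @param seqs Named character vector.
#' @param cutoffs Identity cutoffs (default 0.30 to 0.60 in steps of 0.03).
#' @return `data.frame` with `cutoff`, `n_clusters`, `largest_cluster`,
#'   `singletons_discarded`.
#' @export
sweep_clusters <- function(seqs, cutoffs = seq(0.30, 0.60, by = 0.03)) {
  im <- identity_matrix(seqs)
  rows <- lapply(cutoffs, function(ct) {
    rep <- cluster_at_identity(seqs, ct, identity_matrix = im)
    data.frame(cutoff = ct, n_clusters = length(rep$clusters),
               largest_cluster = if (length(rep$clusters) > 0L)
                 max(vapply(rep$clusters, length, integer(1))) else 0L,
               singletons_discarded = rep$singletons_discarded)
  })
  do.call(rbind, rows)
}

#' Simplified RNA folding (weighted base-pair maximization)
#'
#' Dynamic program maximizing the sum of pair weights (GC/CG = 3, AU/UA = 2,
#' GU/UG = 1) with minimum loop 3 nt and no pseudoknots.  Energy is the
#' negative of the maximal weight (surrogate units; more negative = more
#' stable).  Traceback is deterministic (pairing preferred, then maximal
#' span, then leftmost opening position).
#'
#' @param seq RNA string (T is accepted and read as U).
#' @param pair_scale Optional n x n matrix multiplying each pair weight
#'   (used by [compute_sci()] for consensus compatibility penalties).
#' @return A list with `structure` (dot-bracket) and `energy`.
#' @export
fold_simplified <- function(seq, pair_scale = NULL) {
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  x <- match(strsplit(rna_view(seq), "", fixed = TRUE)[[1]], RNA_BASES)
  if (anyNA(x)) stop("invalid alphabet in fold_simplified", call. = FALSE)
  res <- .nussinov_cpp(x, pair_scale, 3L)
  partner <- res$partner
  db <- rep(".", length(x))
  db[partner >= 0 & seq_along(x) - 1L < partner] <- "("
  db[partner >= 0 & seq_along(x) - 1L > partner] <- ")"
  list(structure = paste(db, collapse = ""), energy = -res$score)
}

#' Structure conservation index of an alignment
#'
#' The consensus sequence (column-majority base) is folded with every pair
#' weight scaled by the fraction of rows able to form a canonical pair at
#' those two columns; the SCI is the ratio of this consensus energy to the
#' mean folding energy of the individual (ungapped) rows, 0 when the mean
#' individual energy is 0.  Identical rows give SCI = 1 exactly.
#'
#' @param alignment Character vector of equal-length gapped sequences
#'   (>= 2 rows).
#' @return List with `sci`, `consensus_energy`, `mean_individual_energy`,
#'   `consensus`, `consensus_structure`.
#' @export
compute_sci <- function(alignment) {
  if (length(alignment) < 2L) stop("need >= 2 rows", call. = FALSE)
  rows <- vapply(alignment, function(r) rna_view(chartr(".~", "--", r)),
                 character(1))
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  all_gap <- apply(mat, 2, function(col) all(!col %in% RNA_BASES))
  if (any(all_gap)) {
    message(sprintf("dropping %d all-gap column(s)", sum(all_gap)))
    mat <- mat[, !all_gap, drop = FALSE]
  }
  ncol_a <- ncol(mat)
  consensus <- apply(mat, 2, function(col) {
    col <- col[col %in% RNA_BASES]
    counts <- table(factor(col, levels = RNA_BASES))
    RNA_BASES[which.max(counts)]
  })
  ## fraction of rows forming a canonical pair at each column pair
  base_ind <- lapply(RNA_BASES, function(b) mat == b)
  names(base_ind) <- RNA_BASES
  non_gap <- matrix(mat %in% RNA_BASES, nrow = nrow(mat))
  n_both <- crossprod(non_gap)
  n_pair <- matrix(0, ncol_a, ncol_a)
  for (p in PAIR_TYPES) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    n_pair <- n_pair + crossprod(base_ind[[a]], base_ind[[b]])
  }
  compat <- ifelse(n_both > 0, n_pair / n_both, 0)
  cons_seq <- paste(consensus, collapse = "")
  cons_fold <- fold_simplified(cons_seq, pair_scale = compat)
  indiv <- vapply(rows, function(r) {
    ungapped <- gsub("-", "", r, fixed = TRUE)
    if (nchar(ungapped) == 0L) return(0)
    fold_simplified(ungapped)$energy
  }, numeric(1))
  mean_indiv <- mean(indiv)
  sci <- if (mean_indiv == 0) 0 else cons_fold$energy / mean_indiv
  list(sci = sci, consensus_energy = cons_fold$energy,
       mean_individual_energy = mean_indiv,
       consensus = cons_seq, consensus_structure = cons_fold$structure)
}

#' Folding z-score against composition-matched shuffles
#'
#' z = (E_seq - mean(E_shuffled)) / sd(E_shuffled) using the simplified
#' folding energy; negative z indicates a structure more stable than expected
#' from composition alone.  z = 0 when the shuffle energies are constant.
#'
#' The default null is mononucleotide shuffling — random sequences of the
#' same length and base composition, which is how the z-score's reference
#' set is defined for this statistic.  A dinucleotide-preserving null is
#' available, but note that under the base-pair-maximization energy it
#' retains most of the pairing capacity of GC-alternating stems and so
#' compresses z toward 0 for high-GC motifs.
#'
#' @param seq RNA string.
#' @param n_shuffles Number of shuffles (>= 30).
#' @param mode `"mono"` (same length and base composition, the default) or
#'   `"di"` (dinucleotide-preserving).
#' @param seed Integer seed.
#' @return z-score (numeric scalar).
#' @export
compute_zscore <- function(seq, n_shuffles = 100L, mode = c("mono", "di"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (n_shuffles < 30L) stop("n_shuffles must be >= 30", call. = FALSE)
  e <- fold_simplified(seq)$energy
  fun <- if (mode == "di") shuffle_di else shuffle_mono
  sh <- fun(rna_view(seq), n_shuffles, seed, source_id = "zscore")
  es <- vapply(sh$sequences, function(s) fold_simplified(s)$energy, numeric(1))
  s <- stats::sd(es)
  if (is.na(s) || s == 0) return(0)
  (e - mean(es)) / s
}

#' Per-column conservation of the dual stem-loop alignment
#'
#' Reports the fraction of rows carrying the conserved A at loop position 1
#' and G at loop position 4 of each loop, and the mean fraction of paired
#' columns whose row pair is canonical.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @param annotation Structure annotation as in a `seed_alignment`
#'   (`$annotation`: hairpins with `pair_cols` and `loop_cols`).
#' @return List with `loop1_A1_fraction`, `loop1_G4_fraction`,
#'   `loop2_A1_fraction`, `loop2_G4_fraction`,
#'   `mean_stem_pair_conservation`.
#' @export
column_conservation <- function(alignment, annotation) {
  rows <- vapply(alignment, rna_view, character(1))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  max_col <- max(vapply(annotation$hairpins,
                        function(h) max(h$pair_cols), numeric(1)))
  if (ncol(mat) < max_col)
    stop("annotation does not match alignment length", call. = FALSE)
  frac <- function(col, base) mean(mat[, col] == base)
  h1 <- annotation$hairpins[[1]]
  h2 <- annotation$hairpins[[2]]
  pair_frac <- function(h) {
    vapply(seq_len(nrow(h$pair_cols)), function(r) {
      a <- mat[, h$pair_cols[r, 1]]
      b <- mat[, h$pair_cols[r, 2]]
      ok <- a %in% RNA_BASES & b %in% RNA_BASES
      if (!any(ok)) return(0)
      mean(PAIR_CODE[cbind(match(a[ok], RNA_BASES),
                           match(b[ok], RNA_BASES))] > 0L)
    }, numeric(1))
  }
  list(loop1_A1_fraction = frac(h1$loop_cols[1], "A"),
       loop1_G4_fraction = frac(h1$loop_cols[4], "G"),
       loop2_A1_fraction = frac(h2$loop_cols[1], "A"),
       loop2_G4_fraction = frac(h2$loop_cols[4], "G"),
       mean_stem_pair_conservation = mean(c(pair_frac(h1), pair_frac(h2))))
}

#' Pairwise covariation (mutual information) of paired columns
#'
#' Mutual information in bits over the joint nucleotide frequencies of each
#' paired column pair; rows with a gap in either column are excluded
#' pairwise.
#'
#' @param alignment Character vector of equal-length gapped rows (>= 2).
#' @param pairs Matrix or list of column index pairs.
#' @return Numeric vector of MI values (bits), one per pair.
#' @export
pair_covariation <- function(alignment, pairs) {
  if (length(alignment) < 2L) stop("need >= 2 rows", call. = FALSE)
  rows <- vapply(alignment, rna_view, character(1))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  vapply(seq_len(nrow(pairs)), function(r) {
    a <- mat[, pairs[r, 1]]
    b <- mat[, pairs[r, 2]]
    ok <- a %in% RNA_BASES & b %in% RNA_BASES
    a <- a[ok]; b <- b[ok]
    if (length(a) == 0L) return(0)
    joint <- table(factor(a, RNA_BASES), factor(b, RNA_BASES)) / length(a)
    pa <- rowSums(joint); pb <- colSums(joint)
    mi <- 0
    for (i in 1:4) for (j in 1:4) {
      if (joint[i, j] > 0)
        mi <- mi + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
    }
    unname(mi)
  }, numeric(1))
}

#' Star alignment of a cluster onto a reference member
#'
#' Each member is globally aligned to the reference (the member with the
#' highest mean identity to the others); residues are projected onto the
#' reference columns and insertions relative to the reference are dropped.
#' A simple multiple alignment sufficient for column statistics on families
#' of near-equal length.
#'
#' @param seqs Named character vector (>= 2).
#' @return Character vector of gapped rows, all of the reference's length.
#' @export
align_to_reference <- function(seqs) {
  if (length(seqs) < 2L) stop("need >= 2 sequences", call. = FALSE)
  im <- identity_matrix(seqs)
  ref_i <- which.max(rowMeans(im))
  ref <- seqs[[ref_i]]
  out <- vapply(seq_along(seqs), function(i) {
    if (i == ref_i) return(rna_view(ref))
    id <- pairwise_identity(ref, seqs[[i]], details = TRUE)
    ra <- strsplit(attr(id, "aligned_a"), "")[[1]]
    sa <- strsplit(attr(id, "aligned_b"), "")[[1]]
    rna_view(paste(sa[ra != "-"], collapse = ""))
  }, character(1))
  stats::setNames(out, names(seqs))
}

#' Conservation statistics for one cluster
#'
#' @param seqs Named character vector of cluster members (>= 2).
#' @param n_shuffles Shuffles per member for the mean z-score.
#' @param seed Integer seed.
#' @return List with the alignment, SCI fields from [compute_sci()],
#'   `mean_zscore`, and the `functional_candidate` flag (SCI >= `sci_min`
#'   and mean z <= `z_max`).
#' @param sci_min,z_max Thresholds for the advisory functional-candidate
#'   flag.
#' @export
cluster_stats <- function(seqs, n_shuffles = 50L, seed = 1L,
                          sci_min = 0.4, z_max = -0.5) {
  aln <- align_to_reference(seqs)
  sci <- compute_sci(aln)
  zs <- vapply(seq_along(seqs), function(i)
    compute_zscore(seqs[[i]], n_shuffles = max(30L, n_shuffles),
                   seed = derive_seed(seed, names(seqs)[i] %||% i)),
    numeric(1))
  mean_z <- mean(zs)
  c(sci, list(mean_zscore = mean_z,
              functional_candidate = sci$sci >= sci_min & mean_z <= z_max))
}
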