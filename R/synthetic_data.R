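## Synthetic high-GC genomes with planted dual stem-loop motifs, ORFs, RBS
## sites and ground truth.  The simulator is the desk-scale stand-in for real
## actinobacterial genome sets: it controls composition, motif divergence and
## genomic-context geometry exactly, and every placement is verified against
## the context classifier at generation time.

#' Default dual stem-loop anatomy used by the simulator
#'
#' Canonical loops (A at position 1, G at position 4), GC-rich 6-bp stems as
#' expected in high-GC genomes, and an inert 8-nt poly-A linker (A cannot
#' pair with itself or with the G/C stems).
#'
#' @param stem_bp Stem length in base pairs (3-10).
#' @return An anatomy list (see [antar_anatomy()]).
#' @export
default_antar_anatomy <- function(stem_bp = 6L) {
  pairs1 <- rep(c("GC", "CG"), length.out = stem_bp)
  pairs2 <- rep(c("CG", "GC"), length.out = stem_bp)
  antar_anatomy(loops = c("ACUGUU", "AGCGCA"),
                stems = list(pairs1, pairs2),
                linker = strrep("A", 8L))
}

#' Simulation configuration
#'
#' @param genome_length Genome length in nt.
#' @param gc_fraction G+C fraction of the background (default 0.65,
#'   emulating high-GC actinobacterial genomes).
#' @param n_motifs Number of planted motifs.
#' @param n_orfs Number of ORFs (must be >= `n_motifs`; each motif is placed
#'   relative to its own ORF).
#' @param loop_mutation_rate,stem_mutation_rate Per-position / per-pair
#'   mutation probabilities applied to each planted motif.
#' @param compensatory Stem mutations preserve pairing (structure-preserving
#'   family divergence, the default); `FALSE` mutates one strand only,
#'   breaking the pair.
#' @param context_mix Fractions of intended context labels (must sum to 1);
#'   the default (39/37/24) reflects the category split typical of this RNA family.
#' @param orf_length_range ORF length range in nt (multiples of 3 enforced).
#' @param seed Integer seed; all placement and mutation randomness derives
#'   from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(genome_length = 200000L, gc_fraction = 0.65,
                              n_motifs = 25L, n_orfs = 30L,
                              loop_mutation_rate = 0, stem_mutation_rate = 0,
                              compensatory = TRUE,
                              context_mix = c(INTERGENIC = 0.39,
                                              SEQUESTER_RBS_OR_AUG = 0.37,
                                              INSIDE_ORF = 0.24),
                              orf_length_range = c(300L, 900L),
                              seed = 1L) {
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie in (0, 1)", call. = FALSE)
  if (abs(sum(context_mix) - 1) > 1e-6)
    stop("context_mix must sum to 1", call. = FALSE)
  if (!all(names(context_mix) %in% CONTEXT_LEVELS))
    stop("context_mix names must be context categories", call. = FALSE)
  if (n_orfs < n_motifs)
    stop("n_orfs must be >= n_motifs", call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_motifs = as.integer(n_motifs),
                 n_orfs = as.integer(n_orfs),
                 loop_mutation_rate = loop_mutation_rate,
                 stem_mutation_rate = stem_mutation_rate,
                 compensatory = compensatory, context_mix = context_mix,
                 orf_length_range = as.integer(orf_length_range),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate an i.i.d. background genome
#'
#' @param genome_length Length in nt.
#' @param gc_fraction G+C fraction.
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @return One-row genome `data.frame` (`id`, `sequence`, `length`).
#' @export
generate_genome <- function(genome_length, gc_fraction = 0.65, seed = 1L,
                            id = "synth1") {
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie in (0, 1)", call. = FALSE)
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
             (1 - gc_fraction) / 2)
  seq <- with_seed(derive_seed(seed, "genome", id), paste(
    sample(DNA_BASES, genome_length, replace = TRUE, prob = probs),
    collapse = ""))
  data.frame(id = id, sequence = seq, length = genome_length,
             stringsAsFactors = FALSE)
}

#' Sample a motif instance from an anatomy
#'
#' Loop positions mutate independently at `loop_mutation_rate` (to a uniform
#' different base).  Stem pairs mutate at `stem_mutation_rate`: by default
#' compensatorily (replaced by a uniform different canonical pair, preserving
#' structure, as structured-RNA families diverge); with
#' `compensatory = FALSE` one randomly chosen strand of the pair mutates,
#' usually breaking it (stress mode for the curation filter and covariation
#' statistics).
#'
#' @param anatomy Anatomy list (see [antar_anatomy()]).
#' @param loop_mutation_rate,stem_mutation_rate Mutation probabilities.
#' @param compensatory Preserve stem pairing under mutation.
#' @param linker Optional replacement linker string (length 2-25).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return An anatomy list with the mutated `sequence` (RNA).
#' @export
sample_motif <- function(anatomy, loop_mutation_rate = 0,
                         stem_mutation_rate = 0, compensatory = TRUE,
                         linker = NULL, seed = NULL) {
  run <- function() {
    mut_base <- function(b) sample(setdiff(RNA_BASES, b), 1L)
    mut_loop <- function(loop) {
      ch <- strsplit(loop, "", fixed = TRUE)[[1]]
      hitp <- stats::runif(6) < loop_mutation_rate
      ch[hitp] <- vapply(ch[hitp], mut_base, character(1))
      paste(ch, collapse = "")
    }
    mut_stem <- function(pairs) {
      hitp <- stats::runif(length(pairs)) < stem_mutation_rate
      out <- lapply(seq_along(pairs), function(k) {
        p <- pairs[k]
        if (!hitp[k]) return(list(a = substr(p, 1, 1), b = substr(p, 2, 2)))
        if (compensatory) {
          np <- sample(setdiff(PAIR_TYPES, p), 1L)
          list(a = substr(np, 1, 1), b = substr(np, 2, 2))
        } else {
          a <- substr(p, 1, 1); b <- substr(p, 2, 2)
          if (stats::runif(1) < 0.5) a <- mut_base(a) else b <- mut_base(b)
          list(a = a, b = b)
        }
      })
      out
    }
    loops <- c(mut_loop(anatomy$loop1), mut_loop(anatomy$loop2))
    stems_raw <- list(mut_stem(anatomy$stem1_pairs),
                      mut_stem(anatomy$stem2_pairs))
    lnk <- linker %||% anatomy$linker
    arm5 <- function(st) paste(vapply(st, `[[`, character(1), "a"),
                               collapse = "")
    arm3 <- function(st) paste(rev(vapply(st, `[[`, character(1), "b")),
                               collapse = "")
    seq <- paste0(arm5(stems_raw[[1]]), loops[1], arm3(stems_raw[[1]]), lnk,
                  arm5(stems_raw[[2]]), loops[2], arm3(stems_raw[[2]]))
    pair_or_na <- function(st) vapply(st, function(p) {
      pt <- paste0(p$a, p$b)
      if (pt %in% PAIR_TYPES) pt else NA_character_
    }, character(1))
    list(loop1 = loops[1], loop2 = loops[2],
         stem1_pairs = pair_or_na(stems_raw[[1]]),
         stem2_pairs = pair_or_na(stems_raw[[2]]),
         linker = lnk, linker_len = nchar(lnk), sequence = seq)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a synthetic seed alignment of the motif family
#'
#' Rows are independent draws from the anatomy at the given divergence;
#' linker lengths vary within `linker_range` and are left-aligned and
#' gap-padded, so the alignment carries a realistic linker-length
#' distribution.  The consensus structure line marks both stems and loops.
#'
#' @param n Number of rows (a 30-representative seed is the typical scale).
#' @param anatomy Base anatomy.
#' @param loop_mutation_rate,stem_mutation_rate Row divergence (stem
#'   mutations are compensatory so paired columns stay paired).
#' @param linker_range Linker length range (within 2-25).
#' @param seed Integer seed.
#' @return A `seed_alignment`.
#' @export
make_seed_alignment <- function(n = 30L, anatomy = default_antar_anatomy(),
                                loop_mutation_rate = 0.10,
                                stem_mutation_rate = 0.15,
                                linker_range = c(4L, 12L), seed = 1L) {
  s1 <- length(anatomy$stem1_pairs)
  s2 <- length(anatomy$stem2_pairs)
  max_l <- linker_range[2]
  rows <- with_seed(derive_seed(seed, "seed_alignment"), {
    vapply(seq_len(n), function(i) {
      ll <- sample(linker_range[1]:linker_range[2], 1L)
      lnk <- paste(sample(RNA_BASES, ll, replace = TRUE,
                          prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
      m <- sample_motif(anatomy, loop_mutation_rate, stem_mutation_rate,
                        compensatory = TRUE, linker = lnk)
      ## re-assemble with the gap-padded linker
      pre <- substr(m$sequence, 1L, 2L * s1 + 6L)
      post <- substr(m$sequence, 2L * s1 + 6L + ll + 1L, nchar(m$sequence))
      paste0(pre, lnk, strrep("-", max_l - ll), post)
    }, character(1))
  })
  names(rows) <- sprintf("synthRNA%02d", seq_len(n))
  ss <- paste0(strrep("(", s1), "......", strrep(")", s1),
               strrep(".", max_l),
               strrep("(", s2), "......", strrep(")", s2))
  seed_alignment(rows, ss)
}

#' Plant motifs and ORFs into a background genome
#'
#' ORFs (ATG ... stop, with an AGGAGG ribosome-binding site at a 4-10 nt
#' spacer) are laid out on evenly spaced blocks of the + strand; each motif
#' is placed relative to its own ORF to realize its intended context label
#' under the exact classifier rules, and every placement is verified with
#' [classify_context()] at generation time.
#'
#' @param genome One-row genome `data.frame` (see [generate_genome()]).
#' @param config A `simulation_config`.
#' @param anatomy Base anatomy for planted motifs.
#' @return List with `genome` (motifs written in), `orfs`, and `truth`
#'   (`data.frame`: motif coordinates, strand, intended label, ORF id,
#'   planted RNA sequence, violations introduced by mutation).
#' @export
plant_motifs_and_orfs <- function(genome, config,
                                  anatomy = default_antar_anatomy()) {
  L <- genome$length[1]
  seqid <- genome$id[1]
  chars <- strsplit(genome$sequence[1], "", fixed = TRUE)[[1]]
  block <- L %/% config$n_orfs
  min_upstream <- 700L
  if (block < min_upstream + max(config$orf_length_range) + 100L)
    stop("genome too short for the requested ORF/motif packing; ",
         "increase genome_length or reduce n_orfs", call. = FALSE)

  ## intended labels by largest remainder
  quota <- config$context_mix * config$n_motifs
  counts <- floor(quota)
  rem <- config$n_motifs - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  labels <- rep(names(config$context_mix), times = counts)

  res <- with_seed(derive_seed(config$seed, "plant"), {
    labels <- sample(labels)
    orfs <- vector("list", config$n_orfs)
    truth <- vector("list", config$n_motifs)
    write_seq <- function(pos, s) {
      chars[(pos + 1L):(pos + nchar(s))] <<- strsplit(s, "", fixed = TRUE)[[1]]
    }
    stop_codons <- c("TAA", "TAG", "TGA")
    safe_codons <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES),
                                 1, paste, collapse = ""), stop_codons)
    for (i in seq_len(config$n_orfs)) {
      S <- (i - 1L) * block + min_upstream
      len <- sample(seq(config$orf_length_range[1],
                        config$orf_length_range[2], by = 3L), 1L)
      body <- paste(sample(safe_codons, len / 3L - 2L, replace = TRUE),
                    collapse = "")
      orf_seq <- paste0("ATG", body, sample(stop_codons, 1L))
      write_seq(S, orf_seq)
      spacer <- sample(4:10, 1L)
      write_seq(S - spacer - 6L, "AGGAGG")
      orfs[[i]] <- data.frame(seqid = seqid, start = S, end = S + len,
                              strand = "+", orf_id = sprintf("orf%03d", i),
                              stringsAsFactors = FALSE)
    }
    orf_df <- do.call(rbind, orfs)
    for (i in seq_len(config$n_motifs)) {
      m <- sample_motif(anatomy, config$loop_mutation_rate,
                        config$stem_mutation_rate, config$compensatory)
      mseq <- dna_view(m$sequence)
      mlen <- nchar(mseq)
      S <- orf_df$start[i]
      label <- labels[i]
      if (label == "INTERGENIC") {
        u <- sample(30:300, 1L)
        me <- S - u - 10L
        ms <- me - mlen
      } else if (label == "SEQUESTER_RBS_OR_AUG") {
        me <- S
        ms <- me - mlen
      } else {  # INSIDE_ORF
        off <- sample(15:90, 1L)
        ms <- S + off
        me <- ms + mlen
      }
      write_seq(ms, mseq)
      truth[[i]] <- data.frame(
        motif_id = sprintf("motif%03d", i), seqid = seqid,
        start = ms, end = me, strand = "+", intended_context = label,
        orf_id = orf_df$orf_id[i], motif_seq = m$sequence,
        stringsAsFactors = FALSE)
    }
    list(orfs = orf_df, truth = do.call(rbind, truth))
  })

  genome$sequence[1] <- paste(chars, collapse = "")
  if (is.null(res$truth))
    res$truth <- data.frame(motif_id = character(), seqid = character(),
                            start = integer(), end = integer(),
                            strand = character(),
                            intended_context = character(),
                            orf_id = character(), motif_seq = character(),
                            stringsAsFactors = FALSE)
  ## generation-time self-consistency: every intended label must be what the
  ## classifier returns for the planted geometry
  for (i in seq_len(nrow(res$truth))) {
    tr <- res$truth[i, ]
    pseudo <- data.frame(seqid = tr$seqid, strand = tr$strand,
                         start = tr$start, end = tr$end,
                         flank_start = max(0L, tr$start - 10L),
                         flank_end = min(L, tr$end + 10L),
                         stringsAsFactors = FALSE)
    call <- classify_context(pseudo, res$orfs, genome$sequence[1])
    if (call$category != tr$intended_context)
      stop(sprintf(
        "planting failed: motif %s intended %s but classifies as %s",
        tr$motif_id, tr$intended_context, call$category), call. = FALSE)
  }
  list(genome = genome, orfs = res$orfs, truth = res$truth)
}

#' Simulate a complete dataset (genome, annotations, truth)
#'
#' @param config A `simulation_config`.
#' @param anatomy Base anatomy for planted motifs.
#' @param out_prefix Optional path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.gff3` and `<prefix>.truth.tsv`.
#' @return List with `genome`, `orfs`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             anatomy = default_antar_anatomy(),
                             out_prefix = NULL) {
  genome <- generate_genome(config$genome_length, config$gc_fraction,
                            seed = config$seed)
  planted <- plant_motifs_and_orfs(genome, config, anatomy)
  out <- c(planted, list(config = config))
  if (!is.null(out_prefix)) {
    write_fasta(out$genome, paste0(out_prefix, ".fasta"))
    write_gff3(out$orfs, paste0(out_prefix, ".gff3"))
    tr <- out$truth
    tr$start <- tr$start + 1L   # 1-based inclusive on disk
    utils::write.table(tr, paste0(out_prefix, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Evaluate scan results against planted truth
#'
#' A planted motif is recovered when a hit overlaps it reciprocally by at
#' least 50% (optionally after expanding the truth span by `tolerance` nt).
#'
#' @param truth Truth `data.frame` from the simulator.
#' @param hits Hit `data.frame` from [scan_genome()].
#' @param tolerance Span expansion in nt applied to the truth intervals.
#' @param calls Optional classified hits (from [classify_contexts()]) for a
#'   context confusion table.
#' @return List with `recall`, `precision`, `n_planted`, `n_hits`,
#'   `n_recovered`, `matches` (truth id per hit or NA), and `confusion`
#'   (intended x called table) when `calls` is given.
#' @export
evaluate_recovery <- function(truth, hits, tolerance = 0L, calls = NULL) {
  n_t <- nrow(truth)
  n_h <- nrow(hits)
  match_of_hit <- rep(NA_character_, n_h)
  recovered <- rep(FALSE, n_t)
  if (n_h > 0L && n_t > 0L) {
    for (i in seq_len(n_h)) {
      for (j in seq_len(n_t)) {
        if (hits$seqid[i] != truth$seqid[j]) next
        ts <- truth$start[j] - tolerance
        te <- truth$end[j] + tolerance
        inter <- min(hits$end[i], te) - max(hits$start[i], ts)
        if (inter <= 0) next
        if (inter >= 0.5 * (te - ts) &&
            inter >= 0.5 * (hits$end[i] - hits$start[i])) {
          match_of_hit[i] <- truth$motif_id[j]
          recovered[j] <- TRUE
        }
      }
    }
  }
  out <- list(recall = if (n_t > 0L) mean(recovered) else NA_real_,
              precision = if (n_h > 0L) mean(!is.na(match_of_hit)) else NA_real_,
              n_planted = n_t, n_hits = n_h, n_recovered = sum(recovered),
              matches = match_of_hit)
  if (!is.null(calls) && nrow(calls) == n_h) {
    idx <- !is.na(match_of_hit)
    intended <- truth$intended_context[match(match_of_hit[idx],
                                             truth$motif_id)]
    out$confusion <- table(intended = factor(intended, CONTEXT_LEVELS),
                           called = factor(calls$category[idx],
                                           CONTEXT_LEVELS))
  }
  out
}
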