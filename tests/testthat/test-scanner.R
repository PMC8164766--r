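test_that("hairpin enumeration finds constructed hairpins and nothing in homopolymers", {
  hp <- find_hairpins("GCCACUGUUGGC")
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$stem_bp, 3L)
  expect_equal(hp$loop_seq, "ACUGUU")
  expect_equal(hp$outer_start, 0L)
  expect_equal(hp$outer_end, 12L)

  expect_equal(nrow(find_hairpins("AAAAAAAAAAAA")), 0L)
  expect_equal(nrow(find_hairpins("")), 0L)
})

test_that("hairpin enumeration equals brute force on random sequences", {
  for (s in c(7, 8, 9)) {
    seq <- random_rna(60, seed = s)
    got <- find_hairpins(seq)
    want <- oracle_hairpins(seq)
    expect_equal(got[, c("outer_start", "stem_bp")], want,
                 ignore_attr = TRUE)
  }
  ## N breaks candidate motifs
  seq <- paste0("GCC", "NCUGUU", "GGC")
  expect_equal(nrow(find_hairpins(seq)), 0L)
})

test_that("hairpin pairing respects the 2-25 nt linker bounds", {
  mk <- function(sep) paste0("GCCACUGUUGGC", strrep("A", sep), "GGCAGCGCAGCC")
  cons <- motif_constraints()
  dual_at <- function(sep) {
    hp <- find_hairpins(mk(sep))
    pairs <- pair_hairpins(hp, cons)
    any(hp$outer_start[pairs$i1] == 0 & hp$stem_bp[pairs$i1] == 3 &
          hp$outer_start[pairs$i2] == 12 + sep & pairs$linker_len == sep)
  }
  for (sep in c(2, 10, 25)) expect_true(dual_at(sep))
  for (sep in c(1, 26)) expect_false(dual_at(sep))
})

test_that("candidate enumeration equals brute-force decomposition on short sequences", {
  prof <- fix_profile()
  cons <- motif_constraints()
  seq <- random_rna(150, seed = 11, gc = 0.6)
  en <- enumerate_candidates(seq, prof, cons)
  got <- en$candidates
  ## brute force: all (hairpin1, linker, hairpin2) decompositions
  hp <- oracle_hairpins(seq)
  want <- list()
  for (i in seq_len(nrow(hp))) for (j in seq_len(nrow(hp))) {
    e1 <- hp$outer_start[i] + 2 * hp$stem_bp[i] + 6
    linker <- hp$outer_start[j] - e1
    if (linker >= 2 && linker <= 25)
      want[[length(want) + 1]] <- c(hp$outer_start[i], hp$stem_bp[i],
                                    hp$outer_start[j], hp$stem_bp[j], linker)
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(got), nrow(want))
  key_got <- paste(got$hp1_start, got$hp1_bp, got$hp2_start, got$hp2_bp,
                   got$linker_len)
  key_want <- paste(want[, 1], want[, 2], want[, 3], want[, 4], want[, 5])
  expect_setequal(key_got, key_want)
  ## scores agree with score_candidate on each decomposition
  ch <- strsplit(seq, "")[[1]]
  for (r in sample(seq_len(nrow(got)), 10)) {
    arm_pairs <- function(o, s) {
      span <- 2 * s + 6
      vapply(1:s, function(k) paste0(ch[o + k], ch[o + span - k + 1]),
             character(1))
    }
    cand <- list(loop1 = got$loop1[r], loop2 = got$loop2[r],
                 stem1_pairs = arm_pairs(got$hp1_start[r], got$hp1_bp[r]),
                 stem2_pairs = arm_pairs(got$hp2_start[r], got$hp2_bp[r]),
                 linker_len = got$linker_len[r])
    expect_equal(got$score[r], score_candidate(prof, cand))
  }
  ## funnel monotonicity
  expect_lte(sum(got$curated), en$n_candidates)
  expect_lte(sum(got$curated & got$score >= 5), sum(got$curated))
})

test_that("planted consensus motifs are recovered at their exact spans on both strands", {
  prof <- fix_profile()
  ## plant with stems at max_stem_bp so the best decomposition is the exact span
  motif <- antar_anatomy(
    loops = prof$consensus$loops,
    stems = list(rep(prof$consensus$pairs[1], 10),
                 rep(prof$consensus$pairs[2], 10)),
    linker = strrep("A", 8))
  mdna <- chartr("U", "T", motif$sequence)
  g <- random_dna(20000, seed = 21, gc = 0.65)
  g <- plant_at(g, 5000, mdna)
  genome <- data.frame(id = "g1", sequence = g, length = nchar(g))
  hits <- scan_genome(genome, prof, min_bits = 10)
  planted_span <- c(5000L, 5000L + nchar(mdna))
  hit_at <- hits[hits$start == planted_span[1] & hits$end == planted_span[2], ]
  expect_equal(nrow(hit_at), 1L)
  expect_equal(hit_at$strand, "+")
  expect_equal(hit_at$motif_seq, motif$sequence)
  expect_equal(hit_at$flank_start, planted_span[1] - 10L)
  expect_equal(hit_at$flank_end, planted_span[2] + 10L)

  ## same motif reverse-complemented -> one hit, strand -, same + frame span
  g2 <- plant_at(random_dna(20000, seed = 22, gc = 0.65), 5000,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(mdna))))
  genome2 <- data.frame(id = "g2", sequence = g2, length = nchar(g2))
  hits2 <- scan_genome(genome2, prof, min_bits = 10)
  hit2 <- hits2[hits2$start == planted_span[1] & hits2$end == planted_span[2], ]
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$motif_seq, motif$sequence)
})

test_that("scanning the reverse complement mirrors the hit set", {
  prof <- fix_profile()
  motif <- consensus_motif(prof)
  g <- random_dna(8000, seed = 31, gc = 0.6)
  g <- plant_at(g, 2000, chartr("U", "T", motif$sequence))
  g <- plant_at(g, 5000, chartr("U", "T", motif$sequence))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  fwd <- scan_genome(data.frame(id = "g", sequence = g, length = nchar(g)),
                     prof, min_bits = 10)
  rev <- scan_genome(data.frame(id = "g", sequence = rc, length = nchar(rc)),
                     prof, min_bits = 10)
  expect_equal(nrow(fwd), nrow(rev))
  L <- nchar(g)
  expect_setequal(paste(L - rev$end, L - rev$start, chartr("+-", "-+", rev$strand)),
                  paste(fwd$start, fwd$end, fwd$strand))
  expect_equal(sort(rev$score), sort(fwd$score))
})

test_that("short genomes yield an empty result with a notice", {
  prof <- fix_profile()
  expect_message(
    hits <- scan_genome(data.frame(id = "tiny", sequence = "ACGTACGT",
                                   length = 8L), prof, 0),
    "shorter than the minimal motif")
  expect_equal(nrow(hits), 0L)
})

test_that("overlap deduplication keeps the best hit with deterministic ties", {
  base <- antarscan:::empty_hits()
  mk <- function(start, end, score, strand = "+") {
    data.frame(seqid = "g", strand = strand, start = start, end = end,
               flank_start = start - 10L, flank_end = end + 10L,
               hp1_start = start, hp1_end = start + 18L, hp1_bp = 6L,
               loop1 = "ACUGUU", linker_len = 8L, hp2_start = end - 18L,
               hp2_end = end, hp2_bp = 6L, loop2 = "AGCGCA", score = score,
               curation_violations = 0L, motif_seq = "X")
  }
  ## fully nested, scores 18 vs 15 -> the 18-bit hit
  d <- dedup_overlapping(rbind(base, mk(100, 160, 18), mk(110, 150, 15)))
  expect_equal(d$score, 18)
  ## disjoint -> both kept
  d <- dedup_overlapping(rbind(base, mk(100, 160, 18), mk(300, 360, 15)))
  expect_equal(nrow(d), 2L)
  ## equal score, 60% overlap -> leftmost kept
  d <- dedup_overlapping(rbind(base, mk(124, 184, 18), mk(100, 160, 18)))
  expect_equal(d$start, 100L)
  ## <= 50% overlap of the shorter span -> both kept
  d <- dedup_overlapping(rbind(base, mk(100, 160, 18), mk(130, 190, 17)))
  expect_equal(nrow(d), 2L)
})

test_that("identical RNAs collapse per species with multiplicity", {
  base <- antarscan:::empty_hits()
  mk <- function(seqid, start, seq) {
    data.frame(seqid = seqid, strand = "+", start = start, end = start + 60L,
               flank_start = start - 10L, flank_end = start + 70L,
               hp1_start = start, hp1_end = start + 18L, hp1_bp = 6L,
               loop1 = "ACUGUU", linker_len = 8L, hp2_start = start + 42L,
               hp2_end = start + 60L, hp2_bp = 6L, loop2 = "AGCGCA",
               score = 20, curation_violations = 0L, motif_seq = seq)
  }
  hits <- rbind(base, mk("s1c1", 100, "AAA"), mk("s1c2", 200, "AAA"),
                mk("s1c3", 50, "AAA"), mk("s2c1", 10, "AAA"),
                mk("s1c1", 400, "GGG"))
  species <- c("sp1", "sp1", "sp1", "sp2", "sp1")
  rep <- collapse_identical(hits, species)
  expect_equal(nrow(rep), 3L)
  ## identical sequences in one species -> lexicographically smallest seqid
  aaa_sp1 <- rep[rep$motif_seq == "AAA" & rep$seqid != "s2c1", ]
  expect_equal(aaa_sp1$seqid, "s1c1")
  expect_equal(aaa_sp1$multiplicity, 3L)
  ## same sequence in another species kept separately
  expect_true("s2c1" %in% rep$seqid)
  ## single-nucleotide variants are not collapsed
  expect_true("GGG" %in% rep$motif_seq)
})

test_that("scans and hit tables are byte-identical across reruns", {
  prof <- fix_profile()
  g <- plant_at(random_dna(6000, seed = 41, gc = 0.6), 1500,
                chartr("U", "T", consensus_motif(prof)$sequence))
  genome <- data.frame(id = "g", sequence = g, length = nchar(g))
  h1 <- scan_genome(genome, prof, 10)
  h2 <- scan_genome(genome, prof, 10)
  expect_identical(h1, h2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_hits_tsv(h1, p1); write_hits_tsv(h2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
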