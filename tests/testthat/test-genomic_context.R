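## A pyrimidine-only background guarantees no accidental AG-rich windows.
py_background <- function(len, seed) {
  antarscan:::with_seed(seed, paste(
    sample(c("C", "T"), len, replace = TRUE), collapse = ""))
}

mk_hit <- function(start, end, strand = "+", seqid = "g", L = NULL) {
  data.frame(seqid = seqid, strand = strand, start = start, end = end,
             flank_start = max(0L, start - 10L),
             flank_end = if (is.null(L)) end + 10L else min(L, end + 10L),
             hp1_start = start, hp1_end = start + 18L, hp1_bp = 6L,
             loop1 = "ACUGUU", linker_len = 8L,
             hp2_start = end - 18L, hp2_end = end, hp2_bp = 6L,
             loop2 = "AGCGCA", score = 20, curation_violations = 0L,
             motif_seq = "X", stringsAsFactors = FALSE)
}

test_that("RBS detection finds AG-rich windows with the documented precedence", {
  ## AGGAGG ending 7 nt before the start codon at position 1000
  g <- py_background(1200, seed = 1)
  g <- plant_at(g, 1000 - 7 - 6, "AGGAGG")
  orf <- data.frame(seqid = "g", start = 1000L, end = 1300L, strand = "+",
                    orf_id = "o1")
  rbs <- detect_rbs(g, orf)
  expect_equal(rbs$sequence, "AGGAGG")
  expect_equal(rbs$spacer, 7L)
  expect_equal(rbs$length, 6L)
  expect_equal(substr(g, rbs$start + 1, rbs$end), "AGGAGG")

  ## all-pyrimidine upstream: none
  expect_null(detect_rbs(py_background(1200, seed = 2), orf))

  ## one non-purine tolerated: AGCAGG at spacer 3
  g3 <- plant_at(py_background(1200, seed = 3), 1000 - 3 - 6, "AGCAGG")
  rbs3 <- detect_rbs(g3, orf)
  expect_equal(rbs3$sequence, "AGCAGG")
  expect_equal(rbs3$spacer, 3L)

  ## two non-purines in every frame: rejected (CC breaks all 4-6 windows)
  g4 <- plant_at(py_background(1200, seed = 4), 1000 - 3 - 6, "AGCCGG")
  expect_null(detect_rbs(g4, orf))

  ## contig edge: insufficient upstream
  orf_edge <- data.frame(seqid = "g", start = 10L, end = 310L, strand = "+",
                         orf_id = "o2")
  expect_message(expect_null(detect_rbs(g, orf_edge)), "contig edge")

  ## minus strand: window upstream of the ORF end, coding orientation
  ## (genomic purines read as coding-strand pyrimidines on -)
  gm <- antarscan:::with_seed(5, paste(
    sample(c("A", "G"), 1200, replace = TRUE), collapse = ""))
  ## coding-strand AGGAGG at spacer 4 upstream of a - strand ORF ending at 600
  gm <- plant_at(gm, 600 + 4, chartr("ACGT", "TGCA",
                                     paste(rev(strsplit("AGGAGG", "")[[1]]),
                                           collapse = "")))
  orfm <- data.frame(seqid = "g", start = 300L, end = 600L, strand = "-",
                     orf_id = "o3")
  rbsm <- detect_rbs(gm, orfm)
  expect_equal(rbsm$sequence, "AGGAGG")
  expect_equal(rbsm$spacer, 4L)
})

test_that("context categories follow the documented thresholds and precedence", {
  g <- py_background(2000, seed = 10)
  g <- plant_at(g, 1000, "ATG")
  orfs <- data.frame(seqid = "g", start = 1000L, end = 1600L, strand = "+",
                     orf_id = "orf1")

  ## flanks end 240 nt upstream -> INTERGENIC
  call <- classify_context(mk_hit(700, 750), orfs, g)
  expect_equal(call$category, "INTERGENIC")
  expect_equal(call$distance_to_start, -240L)

  ## flank span overlaps the start codon -> SEQUESTER
  call2 <- classify_context(mk_hit(944, 1004), orfs, g)
  expect_equal(call2$category, "SEQUESTER_RBS_OR_AUG")

  ## motif 5' end 20 nt into the ORF -> INSIDE_ORF
  call3 <- classify_context(mk_hit(1020, 1080), orfs, g)
  expect_equal(call3$category, "INSIDE_ORF")
  expect_equal(call3$distance_to_start, 20L)

  ## 1-14 nt gap touching neither RBS nor AUG -> UNASSIGNED
  call4 <- classify_context(mk_hit(928, 988), orfs, g, flank_inclusive = TRUE)
  expect_equal(call4$category, "UNASSIGNED")

  ## beyond 500 nt -> UNASSIGNED; no ORFs -> UNASSIGNED
  expect_equal(classify_context(mk_hit(100, 160), orfs, g)$category,
               "UNASSIGNED")
  expect_equal(classify_context(mk_hit(700, 750), orfs[0, ], g)$category,
               "UNASSIGNED")

  ## RBS overlap triggers SEQUESTER even without start-codon overlap
  g_rbs <- plant_at(g, 1000 - 8 - 6, "AGGAGG")
  call5 <- classify_context(mk_hit(930, 990), orfs, g_rbs)
  expect_equal(call5$category, "SEQUESTER_RBS_OR_AUG")
})

test_that("the classifier agrees with a literal oracle on randomized geometries", {
  L <- 4000L
  orf_start <- 2000L
  g <- py_background(L, seed = 20)
  geoms <- antarscan:::with_seed(21, data.frame(
    start = sample(1300:2200, 2000, replace = TRUE),
    len = sample(40:80, 2000, replace = TRUE),
    strand = sample(c("+", "-"), 2000, replace = TRUE)))
  orfs <- data.frame(seqid = "g",
                     start = c(orf_start, L - orf_start - 600L),
                     end = c(orf_start + 600L, L - orf_start),
                     strand = c("+", "-"),
                     orf_id = c("fwd", "rev"))
  ## the classifier consumes the detected RBS window; the oracle takes it as
  ## a given input and re-evaluates the category rules literally
  rbs_local <- lapply(1:2, function(k) {
    rbs <- detect_rbs(g, orfs[k, ])
    if (is.null(rbs)) return(NULL)
    if (orfs$strand[k] == "+") c(rbs$start, rbs$end)
    else c(L - rbs$end, L - rbs$start)
  })
  mism <- 0L
  for (i in seq_len(nrow(geoms))) {
    hstart <- geoms$start[i]; hend <- hstart + geoms$len[i]
    strand <- geoms$strand[i]
    hit <- mk_hit(hstart, hend, strand = strand, L = L)
    call <- classify_context(hit, orfs, g)
    ## oracle works in strand-local frame against the same-strand ORF
    if (strand == "+") {
      S <- orf_start
      m5 <- hstart; m3 <- hend
      fs <- hit$flank_start; fe <- hit$flank_end
      rbs <- rbs_local[[1]]
    } else {
      S <- orf_start   # the - ORF mirrors the + one by construction
      m5 <- L - hend; m3 <- L - hstart
      fs <- L - hit$flank_end; fe <- L - hit$flank_start
      rbs <- rbs_local[[2]]
    }
    want <- oracle_classify(m5, m3, fs, fe, S, rbs = rbs)
    if (!identical(call$category, want)) mism <- mism + 1L
  }
  expect_equal(mism, 0L)
})

test_that("category labels are invariant under genome mirroring", {
  sim <- simulate_dataset(simulation_config(genome_length = 30000L,
                                            n_motifs = 6L, n_orfs = 8L,
                                            seed = 33))
  g <- sim$genome$sequence
  L <- nchar(g)
  hits <- do.call(rbind, lapply(seq_len(nrow(sim$truth)), function(i)
    mk_hit(sim$truth$start[i], sim$truth$end[i], seqid = "synth1", L = L)))
  calls <- classify_contexts(hits, sim$orfs, g, rescue = FALSE)

  g_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  orfs_rc <- sim$orfs
  orfs_rc$start <- L - sim$orfs$end
  orfs_rc$end <- L - sim$orfs$start
  orfs_rc$strand <- chartr("+-", "-+", sim$orfs$strand)
  hits_rc <- hits
  hits_rc$start <- L - hits$end
  hits_rc$end <- L - hits$start
  hits_rc$flank_start <- L - hits$flank_end
  hits_rc$flank_end <- L - hits$flank_start
  hits_rc$hp1_start <- L - hits$hp2_end
  hits_rc$hp1_end <- L - hits$hp2_start
  hits_rc$hp2_start <- L - hits$hp1_end
  hits_rc$hp2_end <- L - hits$hp1_start
  hits_rc$strand <- chartr("+-", "-+", hits$strand)
  calls_rc <- classify_contexts(hits_rc, orfs_rc, g_rc, rescue = FALSE)
  expect_equal(calls_rc$category, calls$category)
  expect_equal(calls_rc$orf_id, calls$orf_id)
})

test_that("altORF search requires a start codon, length, and a spaced RBS", {
  ## RBS at spacer 8 + ATG + open frame of 90 nt + stop
  open_frame <- strrep("GCT", 30)
  g <- plant_at(py_background(1000, seed = 40), 400,
                paste0("AGGAGG", strrep("C", 8), "ATG", open_frame, "TAA"))
  alt <- find_alt_orfs(g, 300, 700, strand = "+")
  expect_equal(nrow(alt), 1L)
  expect_equal(alt$start, 400L + 6L + 8L)
  ## GTG start accepted
  g2 <- plant_at(py_background(1000, seed = 41), 400,
                 paste0("AGGAGG", strrep("C", 8), "GTG", open_frame, "TAA"))
  expect_equal(nrow(find_alt_orfs(g2, 300, 700, strand = "+")), 1L)
  ## RBS at spacer 20: rejected
  g3 <- plant_at(py_background(1000, seed = 42), 400,
                 paste0("AGGAGG", strrep("C", 20), "ATG", open_frame, "TAA"))
  expect_equal(nrow(find_alt_orfs(g3, 300, 700, strand = "+")), 0L)
  ## too short: rejected
  g4 <- plant_at(py_background(1000, seed = 43), 400,
                 paste0("AGGAGG", strrep("C", 8), "ATG", strrep("GCT", 10),
                        "TAA"))
  expect_equal(nrow(find_alt_orfs(g4, 300, 700, strand = "+")), 0L)
})

test_that("terminator surrogate needs a GC hairpin followed by a U tail", {
  ## an all-C background pairs with nothing and contributes no U tails
  bg <- strrep("C", 600)
  motif <- chartr("U", "T", default_antar_anatomy()$sequence)
  mlen <- nchar(motif)
  term_hp <- paste0("GCGCGC", "AAAA", "GCGCGC")
  ## CCC spacer keeps one-base-shifted hairpin variants clear of stem2
  mk_genome <- function(tail) plant_at(bg, 200,
                                       paste0(motif, "CCC", term_hp, tail))
  hit <- mk_hit(200, 200 + mlen, L = 600)
  hit$hp2_start <- 200L + mlen - 18L
  hit$hp2_end <- 200L + mlen

  term <- find_terminator(mk_genome("TTTTTTTT"), hit)
  expect_false(is.null(term))
  expect_gte(term$stem_bp, 4L)
  expect_false(term$overlaps_stem2)   # hairpin starts after the motif

  expect_null(find_terminator(mk_genome("ACACACAC"), hit))
  expect_null(find_terminator(plant_at(bg, 200, motif), hit))

  ## a terminator arm inside the second stem span sets the overlap flag
  g_onstem <- plant_at(bg, 200,
                       paste0(substr(motif, 1, mlen - 4), term_hp,
                              "TTTTTTTT"))
  term2 <- find_terminator(g_onstem, hit)
  expect_false(is.null(term2))
  expect_true(term2$overlaps_stem2)
})

test_that("category tallies count fractions and altORF rescues", {
  calls <- data.frame(
    category = c(rep("INTERGENIC", 4), rep("SEQUESTER_RBS_OR_AUG", 4),
                 rep("INSIDE_ORF", 2)),
    alt_orf = c(rep(NA, 8), "altorf_1_+", NA),
    stringsAsFactors = FALSE)
  tal <- category_tally(calls)
  expect_equal(tal$n[tal$category == "INTERGENIC"], 4L)
  expect_equal(tal$fraction[tal$category == "INSIDE_ORF"], 0.2)
  expect_equal(tal$n_alt_orf_rescued[tal$category == "INSIDE_ORF"], 1L)
  expect_equal(sum(tal$n), 10L)

  empty <- category_tally(data.frame(category = character(),
                                     alt_orf = character()))
  expect_equal(sum(empty$n), 0L)

  ## recount oracle on random calls
  rand <- antarscan:::with_seed(60, data.frame(
    category = sample(antarscan:::CONTEXT_LEVELS, 1000, replace = TRUE),
    alt_orf = ifelse(stats::runif(1000) < 0.1, "alt", NA_character_),
    stringsAsFactors = FALSE))
  tal2 <- category_tally(rand)
  for (lv in antarscan:::CONTEXT_LEVELS) {
    expect_equal(tal2$n[tal2$category == lv], sum(rand$category == lv))
    expect_equal(tal2$n_alt_orf_rescued[tal2$category == lv],
                 sum(rand$category == lv & !is.na(rand$alt_orf)))
  }
})
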