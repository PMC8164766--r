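## Shared fixtures, built in code.

## A small divergent seed alignment and its profile (cached per session).
fix_env <- new.env(parent = emptyenv())

fix_seed_aln <- function(n = 12, seed = 3) {
  key <- sprintf("aln_%d_%d", n, seed)
  if (is.null(fix_env[[key]]))
    fix_env[[key]] <- make_seed_alignment(n = n, seed = seed)
  fix_env[[key]]
}

fix_profile <- function(n = 12, seed = 3, background = rep(0.25, 4)) {
  key <- sprintf("prof_%d_%d_%s", n, seed, paste(background, collapse = "_"))
  if (is.null(fix_env[[key]]))
    fix_env[[key]] <- build_profile(fix_seed_aln(n, seed),
                                    background = background)
  fix_env[[key]]
}

## Seed alignment of identical rows (sharp profile), fixed 8-nt linker.
make_identical_seed <- function(n = 10, stem_bp = 6) {
  anatomy <- default_antar_anatomy(stem_bp)
  rows <- stats::setNames(rep(anatomy$sequence, n),
                          sprintf("row%02d", seq_len(n)))
  ss <- paste0(strrep("(", stem_bp), "......", strrep(")", stem_bp),
               strrep(".", nchar(anatomy$linker)),
               strrep("(", stem_bp), "......", strrep(")", stem_bp))
  seed_alignment(rows, ss)
}

## Random RNA/DNA strings under a local seed.
random_rna <- function(len, seed, gc = 0.5) {
  antarscan:::with_seed(seed, paste(
    sample(c("A", "C", "G", "U"), len, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

random_dna <- function(len, seed, gc = 0.5) chartr("U", "T", random_rna(len, seed, gc))

## A strongly stable dual stem-loop: long stems mixing AU and GC pairs, so
## the planted arrangement pairs far more than composition-matched shuffles.
strong_anatomy <- function(stem_bp = 10) {
  antar_anatomy(c("ACUGUU", "AGCGCA"),
                list(rep(c("GC", "AU", "CG", "UA"), length.out = stem_bp),
                     rep(c("CG", "UA", "GC", "AU"), length.out = stem_bp)),
                strrep("A", 8))
}

## Point-mutate an RNA string at a per-position rate (uses the current RNG).
mutate_rna <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
  paste(ch, collapse = "")
}

## Plant a DNA motif into a genome string at a 0-based position.
plant_at <- function(genome_seq, pos, motif_dna) {
  paste0(substr(genome_seq, 1, pos),
         motif_dna,
         substr(genome_seq, pos + nchar(motif_dna) + 1, nchar(genome_seq)))
}
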