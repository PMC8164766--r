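## Shared low-level helpers: alphabets, pairing tables, seeded RNG scoping.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

## Canonical RNA pair types, in the fixed order used by every profile table.
PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

## 4x4 lookup: PAIR_CODE[a, b] is the index into PAIR_TYPES (0 = non-canonical)
## with bases encoded A=1, C=2, G=3, U=4.
PAIR_CODE <- matrix(0L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
PAIR_CODE["A", "U"] <- 1L
PAIR_CODE["U", "A"] <- 2L
PAIR_CODE["G", "C"] <- 3L
PAIR_CODE["C", "G"] <- 4L
PAIR_CODE["G", "U"] <- 5L
PAIR_CODE["U", "G"] <- 6L

## Extension with N (code 5) never pairing, used by the scanner.
PAIR_CODE5 <- rbind(cbind(PAIR_CODE, 0L), 0L)

is_canonical_pair <- function(a, b) {
  PAIR_CODE[cbind(match(a, RNA_BASES), match(b, RNA_BASES))] > 0L
}

#' @noRd
rna_view <- function(dna) chartr("Tt", "Uu", toupper(dna))

#' @noRd
dna_view <- function(rna) chartr("Uu", "Tt", toupper(rna))

## Encode an RNA string as integers A=1 C=2 G=3 U=4, N/other = NA.
encode_rna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_BASES)
}

decode_rna <- function(x) paste(RNA_BASES[x], collapse = "")

revcomp_rna <- function(seq) {
  chartr("ACGUN", "UGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

revcomp_dna <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Deterministic small-integer stream derived from a master seed and a label,
## so that per-sequence / per-replicate RNG streams are reproducible and
## order-independent.  Polynomial byte hash kept below 2^31.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mononucleotide frequencies of a sequence
#'
#' Frequencies over the RNA alphabet (ACGU order; T is read as U), e.g. for
#' use as the scanning background of [build_profile()].
#'
#' @param seq DNA or RNA string.
#' @param pseudo Pseudocount added to each base count.
#' @return Named numeric vector of four frequencies summing to 1.
#' @export
base_frequencies <- function(seq, pseudo = 0) {
  x <- encode_rna(rna_view(seq))
  counts <- tabulate(x, nbins = 4) + pseudo
  stats::setNames(counts / sum(counts), RNA_BASES)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
}
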