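## Independent oracles: brute-force / literal re-implementations kept separate
## from the package code paths they check.

## --- Folding oracle: exhaustive enumeration of all secondary structures ----
## Enumerates every pseudoknot-free structure (min loop 3) as an explicit set
## of pairs and returns the maximum total pair weight.  No dynamic program.
oracle_fold_best <- function(seq) {
  bases <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(bases)
  w <- function(a, b) {
    p <- paste0(bases[a], bases[b])
    switch(p, GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1, 0)
  }
  ## all structures over [i, j] as a list of pair matrices
  enum <- function(i, j) {
    if (j - i + 1 < 5) return(list(matrix(integer(), ncol = 2)))
    out <- enum(i, j - 1)                       # j unpaired
    for (k in i:(j - 4)) {
      if (w(k, j) == 0) next
      left <- if (k > i) enum(i, k - 1) else list(matrix(integer(), ncol = 2))
      right <- enum(k + 1, j - 1)
      for (l in left) for (r in right)
        out[[length(out) + 1]] <- rbind(l, r, c(k, j))
    }
    out
  }
  structs <- enum(1, n)
  best <- 0
  for (s in structs) {
    if (nrow(s) == 0) next
    sc <- sum(vapply(seq_len(nrow(s)), function(r) w(s[r, 1], s[r, 2]),
                     numeric(1)))
    if (sc > best) best <- sc
  }
  -best   # energy convention
}

## --- Hairpin oracle: brute force over all (position, stem length) ----------
oracle_hairpins <- function(seq, min_bp = 3, max_bp = 10) {
  ch <- strsplit(seq, "")[[1]]
  canon <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE, GU = TRUE, UG = TRUE)
  res <- list()
  n <- length(ch)
  for (s in min_bp:max_bp) {
    span <- 2 * s + 6
    if (span > n) next
    for (i in 0:(n - span)) {                   # 0-based outer start
      seg <- ch[(i + 1):(i + span)]
      if (any(seg == "N")) next
      ok <- TRUE
      for (k in 1:s) {
        p <- paste0(seg[k], seg[span - k + 1])
        if (!isTRUE(canon[p])) { ok <- FALSE; break }
      }
      if (ok) res[[length(res) + 1]] <- c(i, s)
    }
  }
  if (length(res) == 0)
    return(data.frame(outer_start = integer(), stem_bp = integer()))
  df <- as.data.frame(do.call(rbind, res))
  names(df) <- c("outer_start", "stem_bp")
  df[order(df$outer_start, df$stem_bp), ]
}

## --- Context oracle: literal re-evaluation of the three category rules -----
## Works directly on strand-local geometry: S = ORF start, start codon
## occupies [S, S+3); rbs = local window or NULL; hit motif [m5, m3) with
## flanks [fs, fe).  Precedence: sequester > inside > intergenic.
oracle_classify <- function(m5, m3, fs, fe, S, rbs = NULL) {
  overlap <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2
  if (overlap(fs, fe, S, S + 3) ||
      (!is.null(rbs) && overlap(fs, fe, rbs[1], rbs[2])))
    return("SEQUESTER_RBS_OR_AUG")
  if (m5 > S && m5 - S <= 100) return("INSIDE_ORF")
  if (S - fe >= 15 && S - fe <= 500) return("INTERGENIC")
  "UNASSIGNED"
}

## All permutations of a small character vector (duplicates included).
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
  out
}

## Dinucleotide count vector (fixed level set) of a string.
dinucleotide_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ab <- c("A", "C", "G", "T", "U")
  di <- paste0(ch[-length(ch)], ch[-1])
  table(factor(di, levels = as.vector(outer(ab, ab, paste0))))
}
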