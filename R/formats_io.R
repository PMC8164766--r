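## File formats and the coordinate contract.
##
## Internal coordinates are 0-based half-open everywhere in this package.
## GFF3 input/output and the hit TSV tables use the 1-based inclusive
## convention of those formats; BED export is 0-based half-open per the BED
## standard.  Genomes are stored as DNA (T); motif logic uses an RNA (U) view.

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and U is converted to T on read (genomes are
#' stored as DNA).  Only the alphabet A, C, G, T, N is accepted; any other
#' character is a format error reported with its record and position.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L)
      stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                   substr(seqs[[i]], bad, bad), ids[[i]], bad), call. = FALSE)
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             length = unname(nchar(seqs)), stringsAsFactors = FALSE)
}

#' Write genome records to FASTA
#'
#' @param genomes A `data.frame` with columns `id` and `sequence` (or a named
#'   character vector of sequences).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (is.data.frame(genomes)) {
    seqs <- stats::setNames(genomes$sequence, genomes$id)
  } else seqs <- genomes
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read ORF annotations from GFF3
#'
#' GFF3 1-based inclusive coordinates are converted to the package's internal
#' 0-based half-open convention.  Only features of the configured types are
#' retained.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types to keep (default CDS and gene).
#' @return A `data.frame` with columns `seqid`, `start`, `end` (0-based
#'   half-open), `strand`, `orf_id`.
#' @export
read_gff3 <- function(path, feature_types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                 error = function(e) stop("GFF3 format error: ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L)
    return(data.frame(seqid = character(), start = integer(), end = integer(),
                      strand = character(), orf_id = character(),
                      stringsAsFactors = FALSE))
  keep <- as.character(gr$type) %in% feature_types
  gr <- gr[keep]
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(!strands %in% c("+", "-"))) {
    i <- which(!strands %in% c("+", "-"))[1L]
    stop(sprintf("GFF3 format error: unknown strand symbol '%s' in feature %d",
                 strands[i], i), call. = FALSE)
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("orf", which(is.na(ids)))
  out <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strands,
    orf_id = ids,
    stringsAsFactors = FALSE
  )
  if (any(out$start < 0L) || any(out$start >= out$end))
    stop("GFF3 format error: feature with start > end", call. = FALSE)
  out
}

#' Write ORF annotations to GFF3
#'
#' @param orfs A `data.frame` as returned by [read_gff3()] (0-based
#'   half-open internal coordinates).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @param type Feature type to emit.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(orfs, path, source = "antarscan", type = "CDS") {
  lines <- c("##gff-version 3")
  if (nrow(orfs) > 0L) {
    lines <- c(lines, sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
      orfs$seqid, source, type, orfs$start + 1L, orfs$end, orfs$strand,
      orfs$orf_id))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Stockholm 1.0 (seed alignment with #=GC SS_cons)

#' Read a seed alignment in Stockholm 1.0 format
#'
#' The alignment must carry a `#=GC SS_cons` consensus-structure line whose
#' brackets (any of `<>`, `()`, `[]`, `{}`) describe exactly two non-nested,
#' non-crossing hairpins, each with a hexanucleotide (6-column) loop and at
#' least 3 paired columns per stem.
#'
#' @param path Path to a Stockholm file.
#' @return A `seed_alignment` object: list with `rows` (named character vector
#'   of gapped RNA strings), `ss_cons` (normalized to `(`/`)`/`.`), `columns`,
#'   and the parsed motif `annotation` (per-stem pair columns, loop columns,
#'   linker columns).
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) stop("Stockholm file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  ss <- character()
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || identical(substr(ln, 1, 2), "//")) next
    if (startsWith(ln, "#=GC SS_cons")) {
      ss <- c(ss, sub("^#=GC SS_cons\\s+", "", ln))
    } else if (startsWith(ln, "#")) {
      next
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L)
        stop("Stockholm format error in line: ", ln, call. = FALSE)
      rows[[parts[1]]] <- paste0(rows[[parts[1]]] %||% "", parts[2])
    }
  }
  if (length(ss) == 0L)
    stop("Stockholm file has no #=GC SS_cons line", call. = FALSE)
  ss_cons <- paste(ss, collapse = "")
  rows <- vapply(rows, identity, character(1))
  seed_alignment(rows, ss_cons)
}

#' Construct and validate a seed alignment
#'
#' @param rows Named character vector of equal-length gapped RNA strings.
#' @param ss_cons Consensus structure string (dot-bracket; `<>`, `[]`, `{}`
#'   accepted and normalized).
#' @return A validated `seed_alignment` object.
#' @export
seed_alignment <- function(rows, ss_cons) {
  if (length(rows) < 1L) stop("seed alignment has no rows", call. = FALSE)
  rows <- vapply(rows, function(r) chartr("tu", "TU", toupper(r)), character(1))
  rows <- vapply(rows, rna_view, character(1))
  rows <- chartr(".~", "--", rows)
  ss_cons <- chartr("<>[]{}", "()()()", ss_cons)
  ss_cons <- gsub("[^()]", ".", ss_cons)
  ncol <- nchar(ss_cons)
  if (any(nchar(rows) != ncol))
    stop("Stockholm format error: rows and SS_cons differ in length",
         call. = FALSE)
  ann <- parse_ss_cons(ss_cons)
  structure(list(rows = rows, ss_cons = ss_cons, columns = ncol,
                 annotation = ann),
            class = "seed_alignment")
}

## Parse a two-hairpin consensus structure into stem pair columns, loop
## columns and linker columns (all 1-based column indices).
parse_ss_cons <- function(ss_cons) {
  chars <- strsplit(ss_cons, "", fixed = TRUE)[[1]]
  stack <- integer()
  pairs <- matrix(integer(), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0L)
        stop("SS_cons validation error: unbalanced brackets", call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L)
    stop("SS_cons validation error: unbalanced brackets", call. = FALSE)
  if (nrow(pairs) == 0L)
    stop("SS_cons validation error: no hairpins found", call. = FALSE)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  ## group pairs into hairpins: a new hairpin starts when an open column lies
  ## beyond every close column seen so far
  groups <- list()
  cur <- integer()
  max_close <- -Inf
  for (r in seq_len(nrow(pairs))) {
    if (length(cur) > 0L && pairs[r, 1] > max_close) {
      groups[[length(groups) + 1L]] <- cur
      cur <- integer()
      max_close <- -Inf
    }
    cur <- c(cur, r)
    max_close <- max(max_close, pairs[r, 2])
  }
  groups[[length(groups) + 1L]] <- cur
  describe <- function(g) {
    p <- pairs[g, , drop = FALSE]
    sprintf("[%d-%d, %d pairs]", min(p[, 1]), max(p[, 2]), nrow(p))
  }
  if (length(groups) != 2L)
    stop(sprintf(
      "SS_cons validation error: expected exactly 2 hairpins, parsed %d: %s",
      length(groups), paste(vapply(groups, describe, character(1)),
                            collapse = " ")), call. = FALSE)
  hairpins <- lapply(groups, function(g) {
    p <- pairs[g, , drop = FALSE]
    ## strict nesting: opens ascending must match closes descending
    p <- p[order(p[, 1]), , drop = FALSE]
    if (any(diff(p[, 2]) >= 0))
      stop("SS_cons validation error: crossing pairs within a hairpin",
           call. = FALSE)
    if (nrow(p) < 3L)
      stop(sprintf(
        "SS_cons validation error: stem %s has < 3 paired columns",
        describe(g)), call. = FALSE)
    inner_open <- max(p[, 1])
    inner_close <- min(p[, 2])
    loop_cols <- seq(inner_open + 1L, inner_close - 1L)
    if (length(loop_cols) != 6L)
      stop(sprintf(
        "SS_cons validation error: hairpin %s loop spans %d columns, not 6",
        describe(g), length(loop_cols)), call. = FALSE)
    list(pair_cols = p, loop_cols = loop_cols,
         span = c(min(p[, 1]), max(p[, 2])))
  })
  linker_cols <- integer()
  gap <- seq(hairpins[[1]]$span[2] + 1L, hairpins[[2]]$span[1] - 1L)
  if (hairpins[[2]]$span[1] - hairpins[[1]]$span[2] > 1L) linker_cols <- gap
  list(hairpins = hairpins, linker_cols = linker_cols)
}

#' Write a seed alignment in Stockholm 1.0 format
#'
#' @param seed A `seed_alignment` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stockholm <- function(seed, path) {
  w <- max(nchar(names(seed$rows)), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", w, names(seed$rows), unname(seed$rows)),
             sprintf("%-*s %s", w, "#=GC SS_cons", seed$ss_cons),
             "//")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat(sprintf("seed_alignment: %d rows x %d columns, 2 hairpins\n",
              length(x$rows), x$columns))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Hit tables

HIT_COLUMNS <- c("seqid", "strand", "start", "end", "flank_start", "flank_end",
                 "hp1_start", "hp1_end", "hp1_bp", "loop1", "linker_len",
                 "hp2_start", "hp2_end", "hp2_bp", "loop2", "score",
                 "curation_violations", "motif_seq")

#' Write motif hits (or context calls) to a TSV file
#'
#' Coordinates are emitted 1-based inclusive.  Rows are ordered
#' deterministically by (seqid, start, score descending).
#'
#' @param hits Hit or context-call `data.frame` with internal 0-based
#'   half-open coordinates.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  if (nrow(out) > 0L) {
    for (cl in intersect(c("start", "flank_start", "hp1_start", "hp2_start",
                           "rbs_start", "alt_orf_start", "term_start"),
                         names(out)))
      out[[cl]] <- out[[cl]] + 1L
    ord <- order(out$seqid, out$start,
                 if ("score" %in% names(out)) -out$score else out$start)
    out <- out[ord, , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a hit TSV written by [write_hits_tsv()]
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with internal 0-based half-open coordinates.
#' @export
read_hits_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("start", "flank_start", "hp1_start", "hp2_start",
                         "rbs_start", "alt_orf_start", "term_start"),
                       names(out)))
    out[[cl]] <- out[[cl]] - 1L
  out
}

#' Export hits as BED6 (0-based half-open, per the BED standard)
#'
#' @param hits Hit `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  if (nrow(hits) == 0L) { writeLines(character(), path); return(invisible(path)) }
  lines <- sprintf("%s\t%d\t%d\t%s\t%.3f\t%s",
                   hits$seqid, hits$start, hits$end,
                   paste0("antar_hit_", seq_len(nrow(hits))),
                   hits$score, hits$strand)
  writeLines(lines, path)
  invisible(path)
}
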