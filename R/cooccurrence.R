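## RNA-hit counts versus externally provided ANTAR-protein counts per genome.
## Protein identification is consumed, never computed: any table with
## genome_id / n_antar_proteins columns (optionally species, genus) works.

#' Summarize co-occurrence of RNA hits and ANTAR proteins per genome
#'
#' @param rna_hits Hit `data.frame` (counted per `seqid`), or a precomputed
#'   `data.frame` with columns `genome_id` and `n_rnas`.
#' @param proteins `data.frame` with columns `genome_id`,
#'   `n_antar_proteins`, optional `species` and `genus`.
#' @return List with `per_genome` (n_rnas, n_proteins, bucket), `buckets`
#'   (genome counts: both / rna_only / protein_only / neither), and
#'   `genus_quartiles` when a genus column is present.
#' @export
cooccurrence_summary <- function(rna_hits, proteins) {
  if (anyDuplicated(proteins$genome_id))
    stop("duplicate genome ids in the protein table", call. = FALSE)
  if (!all(c("genome_id", "n_antar_proteins") %in% names(proteins)))
    stop("protein table needs genome_id and n_antar_proteins", call. = FALSE)
  if (any(proteins$n_antar_proteins < 0))
    stop("protein counts must be non-negative", call. = FALSE)
  if ("n_rnas" %in% names(rna_hits)) {
    rna <- rna_hits[, c("genome_id", "n_rnas")]
  } else {
    counts <- table(rna_hits$seqid)
    rna <- data.frame(genome_id = names(counts),
                      n_rnas = as.integer(counts),
                      stringsAsFactors = FALSE)
  }
  per <- merge(proteins, rna, by = "genome_id", all = TRUE)
  per$n_rnas[is.na(per$n_rnas)] <- 0L
  per$n_antar_proteins[is.na(per$n_antar_proteins)] <- 0L
  per$bucket <- ifelse(per$n_rnas > 0 & per$n_antar_proteins > 0, "both",
                ifelse(per$n_rnas > 0, "rna_only",
                ifelse(per$n_antar_proteins > 0, "protein_only", "neither")))
  buckets <- table(factor(per$bucket,
                          c("both", "rna_only", "protein_only", "neither")))
  out <- list(per_genome = per[order(per$genome_id), ],
              buckets = buckets)
  if ("genus" %in% names(per)) {
    qs <- lapply(split(per, per$genus), function(d) {
      data.frame(genus = d$genus[1], n_genomes = nrow(d),
                 rna_q1 = stats::quantile(d$n_rnas, 0.25),
                 rna_median = stats::median(d$n_rnas),
                 rna_q3 = stats::quantile(d$n_rnas, 0.75),
                 protein_q1 = stats::quantile(d$n_antar_proteins, 0.25),
                 protein_median = stats::median(d$n_antar_proteins),
                 protein_q3 = stats::quantile(d$n_antar_proteins, 0.75),
                 stringsAsFactors = FALSE)
    })
    out$genus_quartiles <- do.call(rbind, c(qs, make.row.names = FALSE))
  }
  out
}
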