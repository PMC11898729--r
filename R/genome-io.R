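#' Write features as GFF3
#'
#' Emits 1-based inclusive coordinates with the feature kind in the `type`
#' column (`CDS`, `rRNA_16S`, `rRNA_23S`, `rRNA_5S`, `ITS`) and `ID` /
#' `genome` attributes. The writer is a plain formatter so output is
#' byte-identical across runs.
#'
#' @param features Tibble with `contig_id`, `start`, `end`, `strand`, `kind`,
#'   `id` and optionally `genome_id`.
#' @param path Output file.
#' @export
write_gff3 <- function(features, path) {
  f <- features
  genome <- f$genome_id %||% sub("\\|.*$", "", f$id)
  attrs <- paste0("ID=", f$id, ";genome=", genome)
  phase <- ifelse(f$kind == "CDS", "0", ".")
  lines <- paste(f$contig_id, "obctools", f$kind, f$start, f$end, ".",
                 f$strand, phase, attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
}

#' Read an annotated assembly (FASTA + GFF3)
#'
#' @param fasta Path to the contig FASTA.
#' @param gff Path to the GFF3 with `CDS`, `rRNA_16S`, `rRNA_23S`, `rRNA_5S`
#'   and `ITS` features. Contigs are grouped into genomes by the `genome`
#'   attribute when present, otherwise the whole file is one genome.
#' @return A list of `obc_genome` objects (`contigs`: named character;
#'   `features`: tibble).
#' @export
read_genome_annotation <- function(fasta, gff) {
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  seqs <- setNames(as.character(contigs), names(contigs))
  g <- rtracklayer::readGFF(gff)
  feats <- tibble(
    contig_id = as.character(g$seqid),
    start = as.integer(g$start), end = as.integer(g$end),
    strand = as.character(g$strand), kind = as.character(g$type),
    id = as.character(g$ID),
    genome_id = if ("genome" %in% names(g)) as.character(g$genome) else
      "genome1")
  split_feats <- split(feats, feats$genome_id)
  lapply(split_feats, function(f) {
    ids <- unique(f$contig_id)
    structure(list(genome_id = f$genome_id[1],
                   contigs = seqs[ids],
                   features = f[, c("contig_id", "start", "end", "strand",
                                    "kind", "id")]),
              class = "obc_genome")
  })
}

#' Write a simulated population to disk
#'
#' Produces `genomes.fna`, `genomes.gff`, `panel.fna`, `panel_labels.tsv` and
#' `truth/genomes.tsv`, `truth/hgt.tsv` under `dir`. Deterministic: the same
#' population writes byte-identical files.
#'
#' @param pop An `obc_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  all_contigs <- unlist(lapply(pop$genomes, `[[`, "contigs"))
  names(all_contigs) <- unlist(lapply(pop$genomes,
                                      function(g) names(g$contigs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(all_contigs),
                              file.path(dir, "genomes.fna"))
  feats <- bind_rows(lapply(pop$genomes, function(g)
    mutate(g$features, genome_id = g$genome_id)))
  write_gff3(feats, file.path(dir, "genomes.gff"))
  panel_seqs <- setNames(pop$panel$seq,
                         paste(pop$panel$label, pop$panel$marker, sep = "|"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel_seqs),
                              file.path(dir, "panel.fna"))
  write_tsv_plain(tibble(id = names(panel_seqs), label = pop$panel$label,
                         marker = pop$panel$marker),
                  file.path(dir, "panel_labels.tsv"))
  write_tsv_plain(pop$truth$genomes, file.path(dir, "truth", "genomes.tsv"))
  write_tsv_plain(pop$truth$hgt, file.path(dir, "truth", "hgt.tsv"))
  invisible(dir)
}

#' Write emitted long reads to disk
#'
#' @param reads Result of [emit_long_reads()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reads <- function(reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads$seqs),
                              file.path(dir, "reads.fna"))
  write_gff3(mutate(reads$features, genome_id = contig_id),
             file.path(dir, "reads.gff"))
  write_tsv_plain(reads$truth, file.path(dir, "reads_truth.tsv"))
  invisible(dir)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
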