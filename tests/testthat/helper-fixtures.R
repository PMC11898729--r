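## Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

## Small truth-labelled population exercised by several modules.
shared_pop <- function() {
  if (is.null(.fixture_env$pop)) {
    cfg <- sim_config(n_species = 3, genomes_per_species = 4,
                      n_island_types = 6, p_hgt = 0.1, seed = 101,
                      n_reads = 60)
    .fixture_env$pop <- simulate_population(cfg)
  }
  .fixture_env$pop
}

shared_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    .fixture_env$analysis <- run_obc_analysis(shared_pop()$genomes,
                                              dnds = FALSE)
  }
  .fixture_env$analysis
}

## Deterministic random protein / DNA strings for alignment tests.
rand_aa <- function(n, seed = NULL) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  draw <- function() paste(sample(aas, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rand_dna_str <- function(n, gc = 0.4, seed = NULL) {
  if (is.null(seed)) obctools:::random_dna(n, gc) else
    withr::with_seed(seed, obctools:::random_dna(n, gc))
}

## Hand-built annotated genome from an ordered parts description:
## tibble(kind, len) with kind in {CDS, spacer, rRNA_16S, ITS, rRNA_23S,
## rRNA_5S}; sequences are random at the given GC.
manual_genome <- function(parts, genome_id = "g1", gc = 0.35, seed = 1,
                          strand = "+") {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(nrow(parts)), function(i) {
      if (parts$kind[i] == "CDS") {
        obctools:::random_cds(parts$len[i] %/% 3L, gc)
      } else {
        obctools:::random_dna(parts$len[i], gc)
      }
    }, character(1))
    ends <- cumsum(nchar(seqs))
    starts <- ends - nchar(seqs) + 1L
    feat <- parts$kind != "spacer"
    features <- tibble::tibble(
      contig_id = genome_id, start = starts[feat], end = ends[feat],
      strand = "+", kind = parts$kind[feat],
      id = paste0(genome_id, "|p", which(feat)))
    g <- structure(list(genome_id = genome_id,
                        contigs = stats::setNames(paste(seqs, collapse = ""),
                                                  genome_id),
                        features = features), class = "obc_genome")
    if (strand == "-") g <- flip_genome(g)
    g
  })
}

## Reverse-complement a single-contig genome and its features.
flip_genome <- function(g) {
  cid <- names(g$contigs)
  L <- nchar(g$contigs[[1]])
  f <- g$features
  s <- L - f$end + 1L
  e <- L - f$start + 1L
  f$start <- s
  f$end <- e
  f$strand <- ifelse(f$strand == "+", "-", "+")
  g$contigs[[1]] <- obctools:::revcomp(g$contigs[[1]])
  g$features <- f
  g
}

## Minimal island stub for orthology tests (only the fields the orthology
## and typing layers read).
fake_island <- function(id, proteins, class = "A", genome = id) {
  structure(list(island_id = id, genome_id = genome, class = class,
                 proteins = proteins,
                 genes = tibble::tibble(id = names(proteins)),
                 segments = tibble::tibble(contig_id = genome, start = 1L,
                                           end = 1L)),
            class = "obc_island")
}
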