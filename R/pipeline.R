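#' All CDS nucleotide sequences of a genome's current contigs
#'
#' @param genome An `obc_genome`.
#' @return Named character vector of CDS (strand-corrected).
#' @keywords internal
genome_cds <- function(genome) {
  f <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  if (!nrow(f)) return(character(0))
  out <- vapply(seq_len(nrow(f)), function(i) {
    s <- substring(genome$contigs[[f$contig_id[i]]], f$start[i], f$end[i])
    if (f$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, f$id)
}

#' Run the full island analysis on a set of genomes
#'
#' Extracts islands, compares them all-vs-all, clusters locus types, builds
#' the backbone AAI matrix, derives locus-vs-genome distance pairs with
#' recent-HGT flags for genome pairs sharing a type, and (optionally) the
#' pooled island-vs-backbone dN/dS contrast.
#'
#' @param genomes Named list of `obc_genome` (e.g. `pop$genomes` or from
#'   [read_genome_annotation()]).
#' @param th An [obc_thresholds()].
#' @param engine Protein search engine (see [compare_islands()]).
#' @param min_len Minimum island length for the genome-level screen (strict
#'   `>`; use 0 to keep everything).
#' @param aai_max_genes Per-genome gene cap for the AAI matrix (evenly
#'   spaced positions; see [aai_matrix()]).
#' @param dnds Whether to compute the dN/dS contrast (the slowest step).
#' @return An `obc_analysis` list: `islands`, `summary`, `comparison`,
#'   `typing`, `aai`, `distance_pairs`, `dnds`.
#' @export
run_obc_analysis <- function(genomes, th = obc_thresholds(),
                             engine = c("auto", "blast", "biostrings"),
                             min_len = 0, aai_max_genes = 16L,
                             dnds = TRUE) {
  engine <- match.arg(engine)
  islands <- unlist(lapply(genomes, extract_islands), recursive = FALSE)
  islands <- filter_islands(islands, min_len)
  islands <- islands[vapply(islands, function(x) nrow(x$genes) > 0,
                            logical(1))]
  names(islands) <- vapply(islands, `[[`, character(1), "island_id")
  cmp <- compare_islands(islands, th, engine)
  typing <- cluster_types(cmp$pairs,
                          vapply(islands, `[[`, character(1), "island_id"),
                          th)
  island_genomes <- tibble(
    island_id = vapply(islands, `[[`, character(1), "island_id"),
    genome_id = vapply(islands, `[[`, character(1), "genome_id"))

  ## backbone proteomes (island genes excluded before any genome comparison)
  island_gene_ids <- unlist(lapply(islands, function(x) x$genes$id))
  all_cds <- lapply(genomes, genome_cds)
  backbone_cds <- lapply(all_cds, function(cds)
    cds[!(names(cds) %in% island_gene_ids)])
  proteomes <- lapply(backbone_cds, function(cds)
    if (length(cds)) setNames(translate_cds(cds), names(cds)) else character(0))
  aai <- aai_matrix(proteomes, engine = engine, max_genes = aai_max_genes)

  dp <- sharing_distance_pairs(typing, cmp, island_genomes, aai)

  dnds_res <- NULL
  if (dnds && nrow(dp)) {
    ortho_cds <- dnds_ortholog_table(dp, cmp, islands, island_genomes,
                                     aai, all_cds)
    if (nrow(ortho_cds)) dnds_res <- aggregate_dnds(ortho_cds)
  }

  structure(list(islands = islands, summary = islands_summary(islands),
                 comparison = cmp, typing = typing,
                 island_genomes = island_genomes, aai = aai,
                 distance_pairs = dp, dnds = dnds_res),
            class = "obc_analysis")
}

#' @export
print.obc_analysis <- function(x, ...) {
  cat("<obc_analysis> ", length(x$islands), " islands, ",
      x$typing$n_types, " locus types, ",
      nrow(x$distance_pairs), " sharing genome pairs (",
      sum(x$distance_pairs$recent_hgt %||% logical(0)),
      " flagged recent HGT)\n", sep = "")
  invisible(x)
}

## Genome pairs sharing a locus type, with genome and locus AAI and the
## recent-HGT flag; restricted to pairs whose island comparison was measured
## directly (an allowed combination with >= 1 passing ortholog).
sharing_distance_pairs <- function(typing, cmp, island_genomes, aai) {
  a <- left_join(typing$assignment, island_genomes, by = "island_id")
  empty <- tibble(genome_a = character(), genome_b = character(),
                  obc_a = character(), obc_b = character(),
                  type_id = character(), aai_genome = numeric(),
                  aai_locus = numeric(), d_g = numeric(), d_l = numeric(),
                  recent_hgt = logical())
  share <- cmp$pairs
  share <- left_join(share,
                     setNames(a[, c("island_id", "type_id", "genome_id")],
                              c("obc_a", "type_a", "genome_a")), by = "obc_a")
  share <- left_join(share,
                     setNames(a[, c("island_id", "type_id", "genome_id")],
                              c("obc_b", "type_b", "genome_b")), by = "obc_b")
  share <- filter(share, .data$type_a == .data$type_b,
                  .data$genome_a != .data$genome_b, .data$n_orth > 0)
  if (!nrow(share)) return(empty)
  share$aai_genome <- aai[cbind(match(share$genome_a, rownames(aai)),
                                match(share$genome_b, colnames(aai)))]
  share$aai_locus <- 100 * share$mean_identity
  share <- share[!is.na(share$aai_genome) & !is.na(share$aai_locus), ]
  if (!nrow(share)) return(empty)
  dp <- distance_pair(share$aai_genome, share$aai_locus)
  bind_rows(tibble(genome_a = share$genome_a, genome_b = share$genome_b,
                   obc_a = share$obc_a, obc_b = share$obc_b,
                   type_id = share$type_a,
                   aai_genome = share$aai_genome,
                   aai_locus = share$aai_locus,
                   d_g = dp$d_g, d_l = dp$d_l, recent_hgt = dp$recent_hgt))
}

## Assemble the ortholog CDS pair table feeding aggregate_dnds(): island
## orthologs from the island comparison, backbone orthologs from the AAI
## matrix RBH set (island genes were excluded there by construction).
dnds_ortholog_table <- function(dp, cmp, islands, island_genomes, aai,
                                all_cds) {
  orth <- cmp$orthologs
  bb <- attr(aai, "orthologs")
  rows <- vector("list", nrow(dp) * 2L)
  for (i in seq_len(nrow(dp))) {
    oa <- dp$obc_a[i]
    ob <- dp$obc_b[i]
    ga <- dp$genome_a[i]
    gb <- dp$genome_b[i]
    io <- orth[(orth$obc_a == oa & orth$obc_b == ob) |
                 (orth$obc_a == ob & orth$obc_b == oa), , drop = FALSE]
    if (nrow(io)) {
      cds_q <- c(islands[[oa]]$cds, islands[[ob]]$cds)[io$query]
      cds_s <- c(islands[[oa]]$cds, islands[[ob]]$cds)[io$subject]
      rows[[2L * i - 1L]] <- tibble(genome_a = ga, genome_b = gb,
                                    compartment = "obc",
                                    cds_a = unname(cds_q),
                                    cds_b = unname(cds_s))
    }
    bo <- bb[(bb$genome_a == ga & bb$genome_b == gb) |
               (bb$genome_a == gb & bb$genome_b == ga), , drop = FALSE]
    if (nrow(bo)) {
      pool <- c(all_cds[[ga]], all_cds[[gb]])
      rows[[2L * i]] <- tibble(genome_a = ga, genome_b = gb,
                               compartment = "backbone",
                               cds_a = unname(pool[bo$query]),
                               cds_b = unname(pool[bo$subject]))
    }
  }
  out <- bind_rows(rows)
  if (nrow(out)) out <- out[!is.na(out$cds_a) & !is.na(out$cds_b), ]
  out
}

#' Evaluate an analysis against the planted truth of a simulated population
#'
#' Reports fragmentation-class recovery, typing accuracy against the
#' identifiable truth partition (adjusted Rand index, requires mclust), and
#' recent-HGT flag recovery (planted cross-species sharing pairs flagged;
#' false positives counted among pairs with genome distance >= 2 that share a
#' type without a planted transfer).
#'
#' @param pop The `obc_population`.
#' @param analysis The matching `obc_analysis`.
#' @return List: `class_accuracy`, `ari`, `hgt` (tibble summary).
#' @export
evaluate_against_truth <- function(pop, analysis) {
  truth <- identifiable_types(pop$truth$genomes)
  sm <- analysis$summary
  m <- left_join(sm, truth, by = "genome_id")
  class_accuracy <- mean(m$class == m$frag_class)
  ari <- NA_real_
  if (requireNamespace("mclust", quietly = TRUE)) {
    am <- left_join(analysis$typing$assignment, analysis$island_genomes,
                    by = "island_id")
    am <- left_join(am, truth, by = "genome_id")
    ari <- mclust::adjustedRandIndex(am$type_id.x, am$identifiable_type)
  }
  dp <- analysis$distance_pairs
  sp_of <- setNames(pop$truth$genomes$species, pop$truth$genomes$genome_id)
  cross <- sp_of[dp$genome_a] != sp_of[dp$genome_b]
  hgt <- tibble(
    n_sharing_pairs = nrow(dp),
    n_cross_species = sum(cross),
    n_cross_flagged = sum(dp$recent_hgt & cross),
    n_false_pos = sum(dp$recent_hgt & !cross & dp$d_g >= 2))
  list(class_accuracy = class_accuracy, ari = ari, hgt = hgt)
}
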