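#' Cluster islands into locus types
#'
#' Two islands share a locus type when they share at least `type_share`
#' (default 90%) of the genes of the smaller one; the pairwise relation is
#' closed transitively (single linkage), so types are the connected
#' components of the sharing graph over all allowed pair comparisons.
#' Islands with no qualifying edge are singletons. Type ids are deterministic:
#' the lexicographically smallest member island id.
#'
#' @param pairs The `pairs` tibble from [compare_islands()] (or any tibble
#'   with `obc_a`, `obc_b`, `allowed`, `shared_fraction`).
#' @param island_ids Character vector of all island ids (so islands without
#'   any edge appear as singletons).
#' @param th An [obc_thresholds()]; `th$type_share` is the edge threshold.
#' @return An `obc_type_assignment`: list with `assignment` (tibble
#'   `island_id`, `type_id`, `singleton`), `members` (named list), `n_types`,
#'   `n_singletons`.
#' @export
cluster_types <- function(pairs, island_ids, th = obc_thresholds()) {
  island_ids <- sort(unique(island_ids))
  edges <- pairs[!is.na(pairs$shared_fraction) & pairs$allowed &
                   pairs$shared_fraction >= th$type_share, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(island_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = island_ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$obc_a, island_ids),
                                    match(edges$obc_b, island_ids)))
  }
  comp <- igraph::components(g)$membership
  assignment <- tibble(island_id = island_ids, comp = comp) |>
    group_by(.data$comp) |>
    mutate(type_id = min(.data$island_id),
           singleton = dplyr::n() == 1L) |>
    ungroup() |>
    select("island_id", "type_id", "singleton")
  members <- split(assignment$island_id, assignment$type_id)
  structure(list(assignment = assignment, members = members,
                 n_types = length(members),
                 n_singletons = sum(assignment$singleton)),
            class = "obc_type_assignment")
}

#' @export
print.obc_type_assignment <- function(x, ...) {
  cat("<obc_type_assignment> ", nrow(x$assignment), " islands in ",
      x$n_types, " types (", x$n_singletons, " singletons)\n", sep = "")
  invisible(x)
}

#' Frequency of locus-type sharing as a function of genome distance
#'
#' Bins genome pairs (those whose islands were both typed) by AAI band and
#' reports, per band, the fraction of pairs whose islands share a locus type,
#' plus the count of cross-species sharing events (AAI below the species
#' boundary).
#'
#' @param assignment An `obc_type_assignment`.
#' @param aai A square AAI matrix (genome ids as dimnames).
#' @param island_genomes Tibble mapping `island_id` to `genome_id`.
#' @param bands Decreasing AAI band edges (default 99, 95, 90, 85).
#' @param th An [obc_thresholds()] (species boundary).
#' @return List: `bands` tibble (band, n_pairs, n_sharing, freq),
#'   `cross_species` tibble of sharing pairs with AAI below the species
#'   boundary.
#' @export
sharing_vs_distance <- function(assignment, aai, island_genomes,
                                bands = c(99, 95, 90, 85),
                                th = obc_thresholds()) {
  a <- left_join(assignment$assignment, island_genomes, by = "island_id")
  ## one island per genome expected; keep first otherwise
  a <- a[!duplicated(a$genome_id), ]
  gids <- intersect(a$genome_id, rownames(aai))
  a <- a[a$genome_id %in% gids, ]
  if (nrow(a) < 2L) {
    return(list(bands = tibble(), cross_species = tibble()))
  }
  cmb <- utils::combn(seq_len(nrow(a)), 2L)
  pair_aai <- aai[cbind(match(a$genome_id[cmb[1, ]], rownames(aai)),
                        match(a$genome_id[cmb[2, ]], colnames(aai)))]
  same_type <- a$type_id[cmb[1, ]] == a$type_id[cmb[2, ]]
  keep <- !is.na(pair_aai)
  if (any(!keep)) message(sum(!keep), " genome pairs lack AAI; excluded")
  pair_aai <- pair_aai[keep]
  same_type <- same_type[keep]
  ga <- a$genome_id[cmb[1, keep]]
  gb <- a$genome_id[cmb[2, keep]]
  brk <- c(0, sort(bands), 100.000001)
  labs <- paste0("[", brk[-length(brk)], ",", c(sort(bands), 100), ")")
  band <- as.character(cut(pair_aai, breaks = brk, right = FALSE,
                           include.lowest = TRUE, labels = labs))
  tab <- tibble(band = band, aai = pair_aai, same_type = same_type) |>
    group_by(.data$band) |>
    summarise(n_pairs = dplyr::n(), n_sharing = sum(.data$same_type),
              freq = mean(.data$same_type), .groups = "drop") |>
    arrange(dplyr::desc(.data$band))
  cross <- tibble(genome_a = ga, genome_b = gb, aai = pair_aai,
                  same_type = same_type) |>
    filter(.data$same_type, .data$aai < th$species_aai)
  list(bands = tab, cross_species = cross)
}

#' Gene-content variation within a locus type
#'
#' For every pair of islands assigned to the same type, counts the genes not
#' matched by an ortholog in the partner (union minus twice the orthologs),
#' optionally annotated with the genome AAI distance.
#'
#' @param assignment An `obc_type_assignment`.
#' @param comparison Result of [compare_islands()] (uses `pairs`).
#' @param island_genomes Optional tibble `island_id` -> `genome_id`.
#' @param aai Optional AAI matrix for the genome distance column.
#' @return Tibble: obc_a, obc_b, type_id, n_genes_a, n_genes_b, n_orth,
#'   n_different (and `genome_distance` = 100 - AAI when available).
#' @export
type_gene_variation <- function(assignment, comparison,
                                island_genomes = NULL, aai = NULL) {
  a <- assignment$assignment
  p <- comparison$pairs
  p <- left_join(p, setNames(a[, c("island_id", "type_id")],
                             c("obc_a", "type_a")), by = "obc_a")
  p <- left_join(p, setNames(a[, c("island_id", "type_id")],
                             c("obc_b", "type_b")), by = "obc_b")
  p <- filter(p, .data$type_a == .data$type_b)
  out <- tibble(obc_a = p$obc_a, obc_b = p$obc_b, type_id = p$type_a,
                n_genes_a = p$n_genes_a, n_genes_b = p$n_genes_b,
                n_orth = p$n_orth,
                n_different = p$n_genes_a + p$n_genes_b - 2L * p$n_orth)
  if (!is.null(island_genomes) && !is.null(aai)) {
    out <- left_join(out, setNames(island_genomes, c("obc_a", "genome_a")),
                     by = "obc_a")
    out <- left_join(out, setNames(island_genomes, c("obc_b", "genome_b")),
                     by = "obc_b")
    out$genome_distance <- 100 - aai[cbind(match(out$genome_a, rownames(aai)),
                                           match(out$genome_b, colnames(aai)))]
  }
  out
}
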