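#' Comparison thresholds
#'
#' Defaults follow the O-antigen locus analysis conventions: island gene
#' orthology at 50% amino-acid identity and 70% coverage of both sequences,
#' same locus type at >= 90% shared genes (of the smaller island), species
#' boundary at 95 AAI and the alternative reference boundary at 85.
#'
#' @param min_identity Minimum fraction of identical aligned residues.
#' @param min_coverage Minimum aligned fraction of each sequence.
#' @param type_share Shared-gene fraction defining a common locus type.
#' @param species_aai AAI (%) species boundary.
#' @param genus_ref_aai Alternative lower AAI (%) boundary.
#' @return An `obc_thresholds` list.
#' @export
obc_thresholds <- function(min_identity = 0.50, min_coverage = 0.70,
                           type_share = 0.90, species_aai = 95,
                           genus_ref_aai = 85) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1,
            type_share >= 0, type_share <= 1,
            species_aai >= 0, species_aai <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 type_share = type_share, species_aai = species_aai,
                 genus_ref_aai = genus_ref_aai), class = "obc_thresholds")
}

## Genome-level AAI gate: the community-standard 30% identity / 70% coverage.
aai_thresholds <- function() obc_thresholds(min_identity = 0.30)

AA_ALPHABET_RE <- "^[ACDEFGHIKLMNPQRSTVWYX*]+$"

#' Align two protein sequences (Smith-Waterman)
#'
#' Local alignment under BLOSUM62 with affine gaps (open 11, extend 1).
#' Identity is identical residues over aligned columns (gap columns count in
#' the alignment length but not the numerator); coverage is the aligned span
#' of each sequence over its full length.
#'
#' @param a,b Amino-acid strings.
#' @return One-row tibble: `query_id`, `subject_id`, `score`, `identity`,
#'   `cov_q`, `cov_s`.
#' @export
align_proteins <- function(a, b) {
  if (!grepl(AA_ALPHABET_RE, a) || !grepl(AA_ALPHABET_RE, b)) {
    abort("invalid amino-acid residues", class = "obc_align_error")
  }
  hits <- align_protein_sets(setNames(a, "a"), setNames(b, "b"))
  hits
}

## Vectorised Smith-Waterman over all pairs of two named protein sets.
align_protein_sets <- function(set_a, set_b, chunk = 4000L) {
  grid <- expand.grid(qi = seq_along(set_a), si = seq_along(set_b))
  n <- nrow(grid)
  out <- vector("list", ceiling(n / chunk))
  mat <- blosum62()
  for (ci in seq_along(out)) {
    rows <- seq((ci - 1L) * chunk + 1L, min(ci * chunk, n))
    qa <- Biostrings::AAStringSet(unname(set_a[grid$qi[rows]]))
    sa <- Biostrings::AAStringSet(unname(set_b[grid$si[rows]]))
    p <- Biostrings::pairwiseAlignment(qa, sa, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 11, gapExtension = 1)
    alen <- Biostrings::nchar(p)
    pat <- Biostrings::pattern(p)
    sub <- Biostrings::subject(p)
    out[[ci]] <- tibble(
      query_id = names(set_a)[grid$qi[rows]],
      subject_id = names(set_b)[grid$si[rows]],
      score = unname(Biostrings::score(p)),
      identity = unname(ifelse(alen > 0, Biostrings::nmatch(p) / alen, 0)),
      cov_q = unname((Biostrings::end(pat) - Biostrings::start(pat) + 1) /
                       nchar(unname(set_a[grid$qi[rows]]))),
      cov_s = unname((Biostrings::end(sub) - Biostrings::start(sub) + 1) /
                       nchar(unname(set_b[grid$si[rows]]))))
  }
  bind_rows(out)
}

#' All-vs-all protein search with command-line BLAST
#'
#' Runs `makeblastdb` + `blastp` (BLOSUM62, gap 11/1, single thread,
#' composition-based statistics and masking off for determinism) on one
#' protein set against itself and returns hits in the same shape as the
#' Smith-Waterman engine.
#'
#' @param prots Named character vector of protein sequences.
#' @param evalue E-value cutoff.
#' @param max_target_seqs Per-query hit cap.
#' @return Hits tibble (`query_id`, `subject_id`, `score`, `identity`,
#'   `cov_q`, `cov_s`), best HSP per pair.
#' @export
blast_all_vs_all <- function(prots, evalue = 1e-5, max_target_seqs = 2000L) {
  if (!has_blast()) abort("blastp/makeblastdb not found on PATH",
                          class = "obc_align_error")
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fa <- file.path(td, "prots.faa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prots), fa)
  system2("makeblastdb", c("-in", fa, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  outf <- file.path(td, "hits.tsv")
  system2("blastp", c(
    "-query", fa, "-db", fa, "-out", outf,
    "-outfmt", shQuote("6 qseqid sseqid pident length qstart qend sstart send qlen slen bitscore"),
    "-evalue", format(evalue), "-max_hsps", "1",
    "-max_target_seqs", max_target_seqs,
    "-num_threads", "1", "-seg", "no", "-comp_based_stats", "0"),
    stdout = FALSE, stderr = FALSE)
  if (!file.size(outf)) {
    return(tibble(query_id = character(), subject_id = character(),
                  score = numeric(), identity = numeric(),
                  cov_q = numeric(), cov_s = numeric()))
  }
  h <- utils::read.table(outf, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("q", "s", "pident", "len", "qstart",
                                       "qend", "sstart", "send", "qlen",
                                       "slen", "bit"))
  tibble(query_id = h$q, subject_id = h$s, score = h$bit,
         identity = h$pident / 100,
         cov_q = (h$qend - h$qstart + 1) / h$qlen,
         cov_s = (h$send - h$sstart + 1) / h$slen)
}

has_blast <- function() {
  nzchar(Sys.which("blastp")) && nzchar(Sys.which("makeblastdb"))
}

## Keep one record per unordered protein pair (the higher-scoring direction),
## with coverages re-oriented onto (p1, p2) = sorted ids.
canonical_hits <- function(hits) {
  swap <- hits$query_id > hits$subject_id
  canon <- tibble(
    p1 = ifelse(swap, hits$subject_id, hits$query_id),
    p2 = ifelse(swap, hits$query_id, hits$subject_id),
    score = hits$score, identity = hits$identity,
    cov1 = ifelse(swap, hits$cov_s, hits$cov_q),
    cov2 = ifelse(swap, hits$cov_q, hits$cov_s))
  canon <- canon[order(canon$p1, canon$p2, -canon$score), ]
  canon[!duplicated(canon[, c("p1", "p2")]), ]
}

#' Reciprocal-best-hit orthologs between two protein sets
#'
#' A pair (x, y) is an ortholog pair iff y is x's best-scoring hit in `set_b`,
#' x is y's best in `set_a`, identity >= `min_identity`, and both coverages
#' >= `min_coverage`. Best-hit ties are broken by higher score, then
#' lexicographically smaller partner id; each gene appears in at most one
#' pair.
#'
#' @param set_a,set_b Named character vectors of protein sequences.
#' @param th An [obc_thresholds()].
#' @param hits Optional precomputed hits tibble (both directions or canonical)
#'   covering the two sets; when NULL the Smith-Waterman engine is used.
#' @return Tibble: `query` (from set_a), `subject` (from set_b), `score`,
#'   `identity`, `cov_q`, `cov_s`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, th = obc_thresholds(),
                                 hits = NULL) {
  if (!length(set_a) || !length(set_b)) {
    return(tibble(query = character(), subject = character(),
                  score = numeric(), identity = numeric(),
                  cov_q = numeric(), cov_s = numeric()))
  }
  if (is.null(hits)) hits <- align_protein_sets(set_a, set_b)
  rbh_from_hits(hits, names(set_a), names(set_b), th)
}

## Shared RBH matcher over a hits table (directional records; the same ids on
## both sides, as in island-vs-itself, are handled naturally).
rbh_from_hits <- function(hits, a_ids, b_ids, th) {
  h <- hits[hits$query_id %in% a_ids & hits$subject_id %in% b_ids, ,
            drop = FALSE]
  h2 <- hits[hits$query_id %in% b_ids & hits$subject_id %in% a_ids, ,
             drop = FALSE]
  ## merge the two directions onto (a, b) orientation, best record per pair
  ab <- bind_rows(
    tibble(a = h$query_id, b = h$subject_id, score = h$score,
           identity = h$identity, cov_q = h$cov_q, cov_s = h$cov_s),
    tibble(a = h2$subject_id, b = h2$query_id, score = h2$score,
           identity = h2$identity, cov_q = h2$cov_s, cov_s = h2$cov_q))
  if (!nrow(ab)) {
    return(tibble(query = character(), subject = character(),
                  score = numeric(), identity = numeric(),
                  cov_q = numeric(), cov_s = numeric()))
  }
  ab <- ab[order(ab$a, ab$b, -ab$score), ]
  ab <- ab[!duplicated(ab[, c("a", "b")]), ]
  ## best partner per a and per b (score desc, then lexicographic partner)
  ab <- ab[order(ab$a, -ab$score, ab$b), ]
  best_b <- ab[!duplicated(ab$a), ]
  ab2 <- ab[order(ab$b, -ab$score, ab$a), ]
  best_a <- ab2[!duplicated(ab2$b), ]
  mutual <- merge(best_b, best_a[, c("a", "b")], by = c("a", "b"))
  keep <- mutual$identity >= th$min_identity &
    mutual$cov_q >= th$min_coverage & mutual$cov_s >= th$min_coverage
  mutual <- mutual[keep, , drop = FALSE]
  mutual <- mutual[order(mutual$a), ]
  tibble(query = mutual$a, subject = mutual$b, score = mutual$score,
         identity = mutual$identity, cov_q = mutual$cov_q,
         cov_s = mutual$cov_s)
}

#' Is a completeness-class combination allowed in pairwise typing?
#'
#' The allowed unordered combinations are AA, AB, AC, AD, BC, BD, CC and DD;
#' BB and CD are excluded (two both-end fragment sets cannot be compared
#' reliably, and left-only vs right-only fragments share no sequence).
#'
#' @param class_a,class_b Completeness classes in `A`-`D`.
#' @return Logical.
#' @export
allowed_combination <- function(class_a, class_b) {
  if (!all(c(class_a, class_b) %in% c("A", "B", "C", "D"))) {
    abort("unknown completeness class", class = "obc_class_error")
  }
  key <- paste(sort(c(class_a, class_b)), collapse = "")
  key %in% c("AA", "AB", "AC", "AD", "BC", "BD", "CC", "DD")
}

#' Shared ortholog fraction between two islands
#'
#' The fraction of reciprocal-best-hit orthologs (at `min_identity` /
#' `min_coverage` of both sequences) over the gene count of the smaller
#' island, the statistic that defines common locus types.
#'
#' @param island_a,island_b `obc_island` objects with >= 1 gene each.
#' @param th An [obc_thresholds()].
#' @param hits Optional precomputed hits covering both islands' proteins.
#' @return One-row tibble (`obc_a`, `obc_b`, `class_a`, `class_b`, `allowed`,
#'   `n_orth`, `shared_fraction`, `mean_identity`). Disallowed combinations
#'   return `allowed = FALSE` with NA statistics.
#' @export
shared_gene_fraction <- function(island_a, island_b, th = obc_thresholds(),
                                 hits = NULL) {
  base <- tibble(obc_a = island_a$island_id, obc_b = island_b$island_id,
                 class_a = island_a$class, class_b = island_b$class)
  if (!allowed_combination(island_a$class, island_b$class)) {
    return(mutate(base, allowed = FALSE, n_orth = NA_integer_,
                  shared_fraction = NA_real_, mean_identity = NA_real_))
  }
  stopifnot(length(island_a$proteins) >= 1, length(island_b$proteins) >= 1)
  rbh <- reciprocal_best_hits(island_a$proteins, island_b$proteins, th, hits)
  n_min <- min(length(island_a$proteins), length(island_b$proteins))
  mutate(base, allowed = TRUE, n_orth = nrow(rbh),
         shared_fraction = nrow(rbh) / n_min,
         mean_identity = if (nrow(rbh)) mean(rbh$identity) else NA_real_)
}

#' All-vs-all island comparison
#'
#' Computes [shared_gene_fraction()] for every allowed completeness-class
#' combination among the islands, using one pooled protein search (BLAST when
#' available, Smith-Waterman otherwise) and the shared RBH matcher per pair.
#'
#' @param islands List of `obc_island` (all with >= 1 gene; gene ids must be
#'   unique across islands).
#' @param th An [obc_thresholds()].
#' @param engine `"auto"` (BLAST if on PATH), `"blast"`, or `"biostrings"`.
#' @return List: `pairs` (one row per allowed unordered pair), `orthologs`
#'   (tibble of RBH gene pairs: obc_a, obc_b, query, subject, identity).
#' @export
compare_islands <- function(islands, th = obc_thresholds(),
                            engine = c("auto", "blast", "biostrings")) {
  engine <- match.arg(engine)
  if (engine == "auto") engine <- if (has_blast()) "blast" else "biostrings"
  ids <- vapply(islands, `[[`, character(1), "island_id")
  names(islands) <- ids
  n_genes <- vapply(islands, function(x) length(x$proteins), integer(1))
  if (any(n_genes == 0L)) abort("islands with zero genes cannot be compared",
                                class = "obc_align_error")
  prots <- unlist(lapply(islands, `[[`, "proteins"))
  names(prots) <- unlist(lapply(islands, function(x) names(x$proteins)))
  if (anyDuplicated(names(prots))) {
    abort("gene ids must be unique across islands", class = "obc_align_error")
  }
  island_of <- rep(ids, times = n_genes)
  names(island_of) <- names(prots)
  cls <- vapply(islands, `[[`, character(1), "class")
  grid <- utils::combn(ids, 2L)
  allowed <- vapply(seq_len(ncol(grid)), function(i)
    allowed_combination(cls[[grid[1, i]]], cls[[grid[2, i]]]), logical(1))
  pair_tbl <- tibble(obc_a = grid[1, allowed], obc_b = grid[2, allowed])

  hits <- if (engine == "blast") {
    blast_all_vs_all(prots)
  } else {
    biostrings_pair_hits(islands, pair_tbl, prots)
  }
  hits$ia <- unname(island_of[hits$query_id])
  hits$ib <- unname(island_of[hits$subject_id])
  hits <- hits[hits$ia != hits$ib, , drop = FALSE]
  swap <- hits$ia > hits$ib
  hits_ab <- tibble(
    ia = ifelse(swap, hits$ib, hits$ia), ib = ifelse(swap, hits$ia, hits$ib),
    a = ifelse(swap, hits$subject_id, hits$query_id),
    b = ifelse(swap, hits$query_id, hits$subject_id),
    score = hits$score, identity = hits$identity,
    cov_a = ifelse(swap, hits$cov_s, hits$cov_q),
    cov_b = ifelse(swap, hits$cov_q, hits$cov_s))
  ## one record per (pair, a, b)
  hits_ab <- hits_ab[order(hits_ab$ia, hits_ab$ib, hits_ab$a, hits_ab$b,
                           -hits_ab$score), ]
  hits_ab <- hits_ab[!duplicated(hits_ab[, c("ia", "ib", "a", "b")]), ]
  ## mutual best per pair
  hits_ab <- hits_ab[order(hits_ab$ia, hits_ab$ib, hits_ab$a, -hits_ab$score,
                           hits_ab$b), ]
  best_b <- hits_ab[!duplicated(hits_ab[, c("ia", "ib", "a")]), ]
  tmp <- hits_ab[order(hits_ab$ia, hits_ab$ib, hits_ab$b, -hits_ab$score,
                       hits_ab$a), ]
  best_a <- tmp[!duplicated(tmp[, c("ia", "ib", "b")]), ]
  mutual <- merge(best_b, best_a[, c("ia", "ib", "a", "b")],
                  by = c("ia", "ib", "a", "b"))
  mutual <- mutual[mutual$identity >= th$min_identity &
                     mutual$cov_a >= th$min_coverage &
                     mutual$cov_b >= th$min_coverage, , drop = FALSE]
  orth <- tibble(obc_a = mutual$ia, obc_b = mutual$ib, query = mutual$a,
                 subject = mutual$b, identity = mutual$identity)
  agg <- orth |>
    group_by(.data$obc_a, .data$obc_b) |>
    summarise(n_orth = dplyr::n(), mean_identity = mean(.data$identity),
              .groups = "drop")
  pairs <- left_join(pair_tbl, agg, by = c("obc_a", "obc_b"))
  pairs$n_orth[is.na(pairs$n_orth)] <- 0L
  pairs <- mutate(pairs,
                  class_a = unname(cls[.data$obc_a]),
                  class_b = unname(cls[.data$obc_b]),
                  allowed = TRUE,
                  n_genes_a = unname(n_genes[.data$obc_a]),
                  n_genes_b = unname(n_genes[.data$obc_b]),
                  n_min = pmin(.data$n_genes_a, .data$n_genes_b),
                  shared_fraction = .data$n_orth / .data$n_min)
  list(pairs = pairs, orthologs = orth)
}

## Smith-Waterman hits restricted to the allowed island pairs (one direction
## per unordered pair; rbh logic re-orients as needed).
biostrings_pair_hits <- function(islands, pair_tbl, prots) {
  out <- vector("list", nrow(pair_tbl))
  for (i in seq_len(nrow(pair_tbl))) {
    a <- islands[[pair_tbl$obc_a[i]]]$proteins
    b <- islands[[pair_tbl$obc_b[i]]]$proteins
    out[[i]] <- align_protein_sets(a, b)
  }
  bind_rows(out)
}

#' Average amino-acid identity between two proteomes
#'
#' AAI = 100 x mean identity over reciprocal-best-hit pairs at the
#' genome-level gate (30% identity, 70% coverage).
#'
#' @param prot_a,prot_b Named character vectors of proteins.
#' @param th Thresholds; defaults to the genome-level gate.
#' @param hits Optional precomputed hits.
#' @return AAI in percent, or `NA_real_` when no RBH pair passes.
#' @export
genome_aai <- function(prot_a, prot_b, th = aai_thresholds(), hits = NULL) {
  rbh <- reciprocal_best_hits(prot_a, prot_b, th, hits)
  if (!nrow(rbh)) return(NA_real_)
  100 * mean(rbh$identity)
}

#' Pairwise AAI matrix over a set of proteomes
#'
#' One pooled search (BLAST when available) plus the shared RBH matcher per
#' genome pair. Genes can be subsampled per proteome for tractability at
#' desk scale; the subsample is deterministic given `seed`.
#'
#' @param proteomes Named list of named character vectors (one per genome).
#' @param th Thresholds (genome-level gate by default).
#' @param engine `"auto"`, `"blast"` or `"biostrings"`.
#' @param max_genes Per-genome gene cap (Inf = use all); the subsample takes
#'   evenly spaced gene positions, so it is deterministic and stays
#'   homologous across genomes with conserved gene order.
#' @return Square symmetric matrix of AAI (%), diagonal 100, `NA` where no
#'   orthologs pass the gate; attribute `"orthologs"` carries the RBH gene
#'   pairs (genome_a, genome_b, query, subject, identity).
#' @export
aai_matrix <- function(proteomes, th = aai_thresholds(),
                       engine = c("auto", "blast", "biostrings"),
                       max_genes = Inf) {
  engine <- match.arg(engine)
  if (engine == "auto") engine <- if (has_blast()) "blast" else "biostrings"
  gids <- names(proteomes)
  stopifnot(!is.null(gids), !anyDuplicated(gids))
  if (is.finite(max_genes)) {
    ## evenly spaced positions along the proteome: deterministic, and for
    ## genomes with conserved gene order the subsamples stay homologous
    proteomes <- lapply(proteomes, function(p) {
      if (length(p) <= max_genes) p else
        p[unique(round(seq(1, length(p), length.out = max_genes)))]
    })
  }
  prots <- unlist(unname(proteomes))
  genome_of <- rep(gids, times = vapply(proteomes, length, integer(1)))
  names(genome_of) <- names(prots)
  hits <- if (engine == "blast") blast_all_vs_all(prots) else {
    h <- align_protein_sets(prots, prots)
    h
  }
  hits$ga <- unname(genome_of[hits$query_id])
  hits$gb <- unname(genome_of[hits$subject_id])
  hits <- hits[hits$ga != hits$gb, , drop = FALSE]
  swap <- hits$ga > hits$gb
  hab <- tibble(
    ga = ifelse(swap, hits$gb, hits$ga), gb = ifelse(swap, hits$ga, hits$gb),
    a = ifelse(swap, hits$subject_id, hits$query_id),
    b = ifelse(swap, hits$query_id, hits$subject_id),
    score = hits$score, identity = hits$identity,
    cov_a = ifelse(swap, hits$cov_s, hits$cov_q),
    cov_b = ifelse(swap, hits$cov_q, hits$cov_s))
  hab <- hab[order(hab$ga, hab$gb, hab$a, hab$b, -hab$score), ]
  hab <- hab[!duplicated(hab[, c("ga", "gb", "a", "b")]), ]
  hab <- hab[order(hab$ga, hab$gb, hab$a, -hab$score, hab$b), ]
  best_b <- hab[!duplicated(hab[, c("ga", "gb", "a")]), ]
  tmp <- hab[order(hab$ga, hab$gb, hab$b, -hab$score, hab$a), ]
  best_a <- tmp[!duplicated(tmp[, c("ga", "gb", "b")]), ]
  mutual <- merge(best_b, best_a[, c("ga", "gb", "a", "b")],
                  by = c("ga", "gb", "a", "b"))
  mutual <- mutual[mutual$identity >= th$min_identity &
                     mutual$cov_a >= th$min_coverage &
                     mutual$cov_b >= th$min_coverage, , drop = FALSE]
  agg <- mutual |>
    group_by(.data$ga, .data$gb) |>
    summarise(aai = 100 * mean(.data$identity), .groups = "drop")
  m <- matrix(NA_real_, length(gids), length(gids),
              dimnames = list(gids, gids))
  diag(m) <- 100
  if (nrow(agg)) {
    idx_a <- match(agg$ga, gids)
    idx_b <- match(agg$gb, gids)
    m[cbind(idx_a, idx_b)] <- agg$aai
    m[cbind(idx_b, idx_a)] <- agg$aai
  }
  attr(m, "orthologs") <- tibble(genome_a = mutual$ga, genome_b = mutual$gb,
                                 query = mutual$a, subject = mutual$b,
                                 identity = mutual$identity)
  m
}
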