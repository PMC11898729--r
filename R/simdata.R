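#' Configuration for the synthetic OBC population generator
#'
#' Defines the study conditions the generator emulates: streamlined AT-rich
#' backbones carrying a single O-antigen biosynthetic cluster (OBC) between the
#' 16S-ITS-23S rRNA block and the 5S rRNA gene, a pool of `n_island_types`
#' discrete island repertoires with depressed GC, lineage divergence producing
#' genomospecies, rare whole-island HGT, contig fragmentation into
#' completeness classes A-D, and 23S-anchored long reads.
#'
#' @param n_species Number of genomospecies.
#' @param genomes_per_species Genomes simulated per species.
#' @param backbone_len Total non-island backbone length in bp (desk default
#'   60000; the real genomes are ~1.3 Mb).
#' @param backbone_gc,island_gc Target GC fractions (defaults 0.294 and 0.238,
#'   the genome-wide and island averages seen in Pelagibacterales).
#' @param n_island_types Number of distinct island repertoires K in the pool.
#' @param island_len_range Island length range in bp (desk default 6000-15000;
#'   real islands span 10-90 kb).
#' @param island_genes_range Range of gene counts per island (real islands
#'   carry 8-101 genes).
#' @param gene_len_range Backbone CDS length range in bp (rounded to codons).
#' @param within_species_div,between_species_div Pairwise nucleotide divergence
#'   (substitutions/site) between genomes of the same species and of different
#'   species.
#' @param p_hgt Per-genome probability of receiving a whole-island horizontal
#'   transfer from another species.
#' @param frag_probs Named probabilities for fragmentation classes A (complete,
#'   one contig), B (both ends, split contigs), C (left/23S side only),
#'   D (right/5S side only). Must sum to 1.
#' @param read_len_range Long-read length range in bp (CCS-like, 5-15 kb).
#' @param min_island_in_read Minimum island bp an anchored read must carry.
#' @param omega_island,omega_backbone dN/dS targets for codon evolution of
#'   island and backbone CDS.
#' @param n_reads Number of long reads emitted by [emit_long_reads()].
#' @param background_read_frac Fraction of reads drawn from random positions
#'   rather than anchored on the 23S gene.
#' @param alt_right_marker Optional feature kind replacing the 5S rRNA as
#'   the island's right-hand neighbour (the relocated-island arrangement);
#'   `NULL` (default) keeps the canonical 5S boundary.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `obc_sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 3,
                       genomes_per_species = 10,
                       backbone_len = 60000,
                       backbone_gc = 0.294,
                       island_gc = 0.238,
                       n_island_types = 8,
                       island_len_range = c(6000, 15000),
                       island_genes_range = c(8, 14),
                       gene_len_range = c(250, 550),
                       within_species_div = 0.01,
                       between_species_div = 0.15,
                       p_hgt = 0.02,
                       frag_probs = c(A = 0.20, B = 0.35, C = 0.23, D = 0.22),
                       read_len_range = c(5000, 15000),
                       min_island_in_read = 5000,
                       omega_island = 0.14,
                       omega_backbone = 0.10,
                       n_reads = 200,
                       background_read_frac = 0.2,
                       alt_right_marker = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(p_hgt, background_read_frac, frag_probs, backbone_gc, island_gc)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities and GC fractions must lie in [0, 1]",
          class = "obc_config_error")
  }
  if (!setequal(names(frag_probs), c("A", "B", "C", "D")) ||
      abs(sum(frag_probs) - 1) > 1e-8) {
    abort("frag_probs must be named A-D and sum to 1",
          class = "obc_config_error")
  }
  if (n_island_types < 1 || n_species < 1 || genomes_per_species < 1) {
    abort("counts must be >= 1", class = "obc_config_error")
  }
  if (island_len_range[1] > island_len_range[2] ||
      island_genes_range[1] > island_genes_range[2]) {
    abort("ranges must be non-degenerate (low <= high)",
          class = "obc_config_error")
  }
  if (island_len_range[2] > backbone_len) {
    abort("island_len_range exceeds backbone capacity",
          class = "obc_config_error")
  }
  if (min_island_in_read > read_len_range[2]) {
    abort("min_island_in_read exceeds the maximum read length",
          class = "obc_config_error")
  }
  structure(cfg, class = "obc_sim_config")
}

#' @export
print.obc_sim_config <- function(x, ...) {
  cat("<obc_sim_config> ", x$n_species, " species x ", x$genomes_per_species,
      " genomes, K=", x$n_island_types, " island types, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Under uniform (JC) substitution GC relaxes toward 0.5 as
## GC(b) = 0.5 + (GC0 - 0.5) exp(-4b/3); root sequences are generated at the
## pre-compensated GC0 so tips sit at the target after branch b.
gc_root_for <- function(target, branch) {
  g0 <- 0.5 + (target - 0.5) * exp(4 * branch / 3)
  min(max(g0, 0.02), 0.98)
}

## Rejecting stop codons (AT-rich) skews accepted codons toward GC; solve for
## the nominal per-base GC whose accepted-codon composition hits the target.
cds_nominal_gc <- function(target) {
  key <- sprintf("cdsgc_%.6f", target)
  if (!is.null(.obc_cache[[key]])) return(.obc_cache[[key]])
  cond_gc <- function(g) {
    pa <- (1 - g) / 2
    pg <- g / 2
    p_taa <- pa^3
    p_tag <- pa^2 * pg
    p_stop <- p_taa + 2 * p_tag
    (3 * g - 2 * p_tag) / (3 * (1 - p_stop))
  }
  g <- stats::uniroot(function(g) cond_gc(g) - target, c(0.005, 0.98))$root
  .obc_cache[[key]] <- g
  g
}

## Random CDS: ATG + (n_codons-2) sense codons + stop, at a target GC.
random_cds <- function(n_codons, gc) {
  stopifnot(n_codons >= 3)
  body <- random_dna(3L * (n_codons - 2L), gc)
  cod <- codon_split(body)
  bad <- which(cod %in% STOP_CODONS)
  while (length(bad)) {
    cod[bad] <- vapply(bad, function(i) random_dna(3, gc), character(1))
    bad <- which(cod %in% STOP_CODONS)
  }
  paste0("ATG", paste(cod, collapse = ""), sample(STOP_CODONS, 1))
}

## Jukes-Cantor style noncoding evolution: Poisson(branch * L) substitutions
## at uniform positions, each to one of the three alternative bases.
evolve_noncoding <- function(seq, branch_len) {
  L <- nchar(seq)
  if (L == 0 || branch_len <= 0) return(seq)
  n_sub <- rpois(1, branch_len * L)
  if (n_sub == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(L, n_sub, replace = TRUE)
  idx <- match(bases[pos], DNA_BASES)
  step <- sample.int(3, n_sub, replace = TRUE)
  bases[pos] <- DNA_BASES[(idx + step - 1L) %% 4L + 1L]
  paste(bases, collapse = "")
}

#' Evolve a coding sequence under a target dN/dS
#'
#' Applies `Poisson(branch_len * L)` accepted substitutions to the mutable part
#' of the CDS (first and last codon held fixed). Proposals pick a uniform site
#' and alternative base; changes creating a stop codon are rejected,
#' synonymous changes are always accepted, and nonsynonymous changes are
#' accepted with probability `omega`, so the realised
#' nonsynonymous/synonymous intensity ratio matches `omega` in expectation.
#'
#' @param seq A character CDS (ATG start, terminal stop, no internal stops).
#' @param branch_len Expected substitutions per (mutable) site.
#' @param omega Target dN/dS ratio in `[0, Inf)`; values > 1 are capped at the
#'   acceptance step by inverting the roles (synonymous changes accepted with
#'   probability `1/omega`).
#' @return The mutated CDS, same length, still a valid CDS.
#' @export
evolve_cds <- function(seq, branch_len, omega) {
  if (!is_valid_cds(seq)) {
    abort("evolve_cds() requires a valid CDS", class = "obc_cds_error")
  }
  if (branch_len <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(bases)
  m <- L / 3L
  if (m <= 2L) return(seq)
  L_mut <- 3L * (m - 2L)
  n_sub <- rpois(1, branch_len * L_mut)
  if (n_sub == 0) return(seq)
  code <- Biostrings::GENETIC_CODE
  p_syn <- if (omega > 1) 1 / omega else 1
  p_non <- if (omega > 1) 1 else omega
  accepted <- 0L
  guard <- 0L
  max_guard <- 1000L * max(n_sub, 10L)
  while (accepted < n_sub && guard < max_guard) {
    guard <- guard + 1L
    i <- sample.int(L_mut, 1L) + 3L
    ci <- (i - 1L) %/% 3L
    cpos <- (3L * ci + 1L):(3L * ci + 3L)
    old_codon <- paste(bases[cpos], collapse = "")
    new_base <- sample(DNA_BASES[DNA_BASES != bases[i]], 1L)
    new_bases <- bases[cpos]
    new_bases[i - 3L * ci] <- new_base
    new_codon <- paste(new_bases, collapse = "")
    if (new_codon %in% STOP_CODONS) next
    syn <- identical(code[[old_codon]], code[[new_codon]])
    p <- if (syn) p_syn else p_non
    if (p >= 1 || runif(1) < p) {
      bases[i] <- new_base
      accepted <- accepted + 1L
    }
  }
  paste(bases, collapse = "")
}

MARKER_LEN <- c(rRNA_16S = 1540L, ITS = 600L, rRNA_23S = 2900L, rRNA_5S = 120L)

#' Generate the pool of island repertoires
#'
#' Draws `n_island_types` ordered gene cassettes. Each repertoire has its own
#' gene complement sampled from an independent random sequence pool, so
#' distinct repertoires share essentially no orthologs by construction.
#'
#' @param cfg An [sim_config()] object.
#' @return A list of repertoires; each has `type_id`, a named character vector
#'   `genes` of CDS, and `spacers` (length `n_genes + 1`) flanking/separating
#'   them.
#' @export
generate_obc_pool <- function(cfg) {
  withr::with_seed(cfg$seed, generate_obc_pool_impl(cfg))
}

generate_obc_pool_impl <- function(cfg) {
  K <- cfg$n_island_types
  ## islands accumulate only the within-species branch; pre-compensate GC
  gc_nc <- gc_root_for(cfg$island_gc, cfg$within_species_div / 2)
  gc_cds <- cds_nominal_gc(gc_nc)
  lapply(seq_len(K), function(k) {
    n_genes <- sample(seq(cfg$island_genes_range[1], cfg$island_genes_range[2]), 1)
    target <- round(runif(1, cfg$island_len_range[1], cfg$island_len_range[2]))
    spacer_len <- sample(0:100, n_genes + 1L, replace = TRUE)
    cds_total <- target - sum(spacer_len)
    if (cds_total < 99L * n_genes) {
      abort(sprintf(
        "infeasible island geometry: %d genes cannot fit %d bp", n_genes, target),
        class = "obc_config_error")
    }
    w <- runif(n_genes, 0.6, 1.4)
    len <- pmax(99L, 3L * as.integer(round(cds_total * w / sum(w) / 3)))
    genes <- vapply(len, function(l) random_cds(l / 3L, gc_cds),
                    character(1))
    names(genes) <- sprintf("T%02d_g%02d", k, seq_len(n_genes))
    list(type_id = sprintf("T%02d", k),
         genes = genes,
         spacers = vapply(spacer_len, random_dna, character(1),
                          gc = gc_nc))
  })
}

## Root backbone layout: left CDS block, 16S-ITS-23S, island slot, 5S,
## right CDS block. Returned as an ordered parts tibble.
root_backbone <- function(cfg) {
  budget <- cfg$backbone_len - sum(MARKER_LEN)
  ## backbone tips sit at between/2 + within/2 from the root
  gc_nc <- gc_root_for(cfg$backbone_gc,
                       (cfg$between_species_div + cfg$within_species_div) / 2)
  gc_cds <- cds_nominal_gc(gc_nc)
  parts <- list()
  used <- 0L
  i <- 0L
  while (TRUE) {
    len <- 3L * as.integer(round(runif(1, cfg$gene_len_range[1],
                                       cfg$gene_len_range[2]) / 3))
    sp <- sample(0:100, 1)
    if (used + len + sp > budget) break
    i <- i + 1L
    parts[[length(parts) + 1L]] <-
      tibble(part_id = sprintf("bb_g%03d", i), kind = "CDS",
             seq = random_cds(len / 3L, gc_cds))
    parts[[length(parts) + 1L]] <-
      tibble(part_id = sprintf("bb_s%03d", i), kind = "spacer",
             seq = random_dna(sp, gc_nc))
    used <- used + len + sp
  }
  n_left <- max(2L, length(parts) %/% 4L * 2L)  # half of the gene/spacer rows
  left <- bind_rows(parts[seq_len(n_left)])
  right <- bind_rows(parts[seq(n_left + 1L, length(parts))])
  right_kind <- cfg$alt_right_marker %||% "rRNA_5S"
  markers <- tibble(
    part_id = c("rrn16S", "its", "rrn23S", "ISLAND", "rrn5S"),
    kind = c("rRNA_16S", "ITS", "rRNA_23S", "ISLAND", right_kind),
    seq = c(random_dna(MARKER_LEN[["rRNA_16S"]], gc_nc),
            random_dna(MARKER_LEN[["ITS"]], gc_nc),
            random_dna(MARKER_LEN[["rRNA_23S"]], gc_nc),
            NA_character_,
            random_dna(MARKER_LEN[["rRNA_5S"]], gc_nc)))
  bind_rows(left, markers, right)
}

## Evolve every part of a backbone tibble along one branch.
evolve_backbone <- function(parts, branch_len, omega) {
  parts$seq <- vapply(seq_len(nrow(parts)), function(i) {
    s <- parts$seq[i]
    if (is.na(s)) return(NA_character_)
    if (parts$kind[i] == "CDS") evolve_cds(s, branch_len, omega)
    else evolve_noncoding(s, branch_len)
  }, character(1))
  parts
}

## Evolve an island repertoire instance along one branch.
evolve_island <- function(rep, branch_len, omega) {
  rep$genes <- vapply(rep$genes, evolve_cds, character(1),
                      branch_len = branch_len, omega = omega)
  rep$spacers <- vapply(rep$spacers, evolve_noncoding, character(1),
                        branch_len = branch_len)
  rep
}

## Interleave island genes and spacers into parts rows.
island_parts <- function(rep) {
  n <- length(rep$genes)
  rows <- vector("list", 2L * n + 1L)
  for (i in seq_len(n)) {
    rows[[2L * i - 1L]] <- tibble(part_id = sprintf("isp%02d", i - 1L),
                                  kind = "spacer", seq = rep$spacers[i])
    rows[[2L * i]] <- tibble(part_id = names(rep$genes)[i], kind = "CDS",
                             seq = unname(rep$genes[i]))
  }
  rows[[2L * n + 1L]] <- tibble(part_id = sprintf("isp%02d", n),
                                kind = "spacer", seq = rep$spacers[n + 1L])
  bind_rows(rows)
}

## Concatenate parts into one contig; emit 1-based inclusive features.
assemble_genome <- function(genome_id, backbone, island) {
  ip <- island_parts(island)
  k <- which(backbone$kind == "ISLAND")
  parts <- bind_rows(backbone[seq_len(k - 1L), ], ip,
                     backbone[seq(k + 1L, nrow(backbone)), ])
  lens <- unname(nchar(parts$seq))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  feat <- parts$kind != "spacer"
  features <- tibble(
    contig_id = genome_id,
    start = starts[feat], end = ends[feat], strand = "+",
    kind = parts$kind[feat],
    id = paste(genome_id, parts$part_id[feat], sep = "|"))
  isl_rows <- which(seq_len(nrow(parts)) %in%
                      (k - 1L + seq_len(nrow(ip))))
  list(seq = paste(parts$seq, collapse = ""),
       features = features,
       island_start = starts[isl_rows[1]],
       island_end = ends[isl_rows[length(isl_rows)]],
       island_gene_ids = paste(genome_id,
                               parts$part_id[isl_rows][parts$kind[isl_rows] == "CDS"],
                               sep = "|"))
}

#' Fragment a genome into contigs for a target completeness class
#'
#' Breakpoints are placed in intergenic gaps inside the island, never inside a
#' marker gene, and always leave at least two island genes on each retained
#' side. Class A keeps the genome as one contig; B splits the island across
#' two contigs (both retained); C keeps only the 23S-bearing left fragment;
#' D keeps only the 5S-bearing right fragment.
#'
#' @param genome An `obc_genome` (from [simulate_population()]).
#' @param target_class One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param seed Optional integer seed for breakpoint choice.
#' @return The genome with `contigs` and `features` replaced by the fragmented
#'   versions and `frag_class` set.
#' @export
fragment_genome <- function(genome, target_class, seed = NULL) {
  run <- function() fragment_genome_impl(genome, target_class)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

fragment_genome_impl <- function(genome, target_class) {
  stopifnot(target_class %in% c("A", "B", "C", "D"))
  full <- genome$full_seq
  feats <- genome$full_features
  gid <- genome$genome_id
  if (target_class == "A") {
    genome$contigs <- setNames(full, gid)
    genome$features <- feats
    genome$frag_class <- "A"
    return(genome)
  }
  isl_genes <- feats[feats$id %in% genome$island_gene_ids, ]
  isl_genes <- isl_genes[order(isl_genes$start), ]
  n <- nrow(isl_genes)
  if (n < 4L) {
    abort("island too short to split (needs >= 4 genes)",
          class = "obc_frag_error")
  }
  gap_i <- sample(2:(n - 2L), 1)  # break between gene gap_i and gap_i + 1
  bp <- (isl_genes$end[gap_i] + isl_genes$start[gap_i + 1L]) %/% 2L
  split_at <- function(lo, hi, cid) {
    keep <- feats$start >= lo & feats$end <= hi
    f <- feats[keep, ]
    f$start <- f$start - lo + 1L
    f$end <- f$end - lo + 1L
    f$contig_id <- cid
    list(seq = substring(full, lo, hi), features = f)
  }
  ## classes C and D lose only the island-adjacent region (the missing
  ## island half plus its marker), as in fragmented SAG assemblies where the
  ## rest of the backbone survives in other contigs
  part_at <- function(pid) feats[endsWith(feats$id, paste0("|", pid)), ][1, ]
  pieces <- switch(
    target_class,
    B = list(split_at(1L, bp, paste0(gid, "_c1")),
             split_at(bp + 1L, nchar(full), paste0(gid, "_c2"))),
    C = {
      e5 <- part_at("rrn5S")$end
      list(split_at(1L, bp, paste0(gid, "_c1")),
           if (e5 < nchar(full))
             split_at(e5 + 1L, nchar(full), paste0(gid, "_c2")))
    },
    D = {
      s16 <- part_at("rrn16S")$start
      list(if (s16 > 1L) split_at(1L, s16 - 1L, paste0(gid, "_c1")),
           split_at(bp + 1L, nchar(full), paste0(gid, "_c2")))
    })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  genome$contigs <- setNames(vapply(pieces, `[[`, character(1), "seq"),
                             vapply(pieces, function(p) p$features$contig_id[1],
                                    character(1)))
  genome$features <- bind_rows(lapply(pieces, `[[`, "features"))
  genome$frag_class <- target_class
  genome
}

#' Simulate a truth-labelled population of genomes
#'
#' Generates the island pool, evolves species ancestors and genomes from a
#' common root (codon model for CDS, uniform substitution for noncoding),
#' places one island per genome between the 16S-ITS-23S block and the 5S gene,
#' plants rare whole-island HGT across species, and fragments each genome
#' according to `frag_probs`. Deterministic given `cfg$seed`.
#'
#' @param cfg An [sim_config()] object.
#' @return An `obc_population`: list with `cfg`, `genomes` (list of
#'   `obc_genome`: `contigs`, `features`, plus the unfragmented `full_seq` /
#'   `full_features` and island truth coordinates), `truth` (tibbles `genomes`
#'   and `hgt`), `panel` (per-species ancestral ITS/23S reference sequences),
#'   and `pool`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "obc_sim_config"))
  withr::with_seed(cfg$seed, simulate_population_impl(cfg))
}

simulate_population_impl <- function(cfg) {
  pool <- generate_obc_pool_impl(cfg)
  root <- root_backbone(cfg)
  sp_ids <- sprintf("sp%02d", seq_len(cfg$n_species))
  ancestors <- lapply(sp_ids, function(s)
    evolve_backbone(root, cfg$between_species_div / 2, cfg$omega_backbone))
  names(ancestors) <- sp_ids

  ## partition island types across species (HGT re-crosses them later)
  type_species <- sp_ids[(seq_len(cfg$n_island_types) - 1L) %% cfg$n_species + 1L]

  genomes <- list()
  truth_rows <- list()
  for (si in seq_along(sp_ids)) {
    sp <- sp_ids[si]
    own_types <- which(type_species == sp)
    if (!length(own_types)) own_types <- seq_along(pool)
    for (gi in seq_len(cfg$genomes_per_species)) {
      gid <- sprintf("%s_g%02d", sp, gi)
      k <- if (length(own_types) == 1L) own_types else sample(own_types, 1)
      bb <- evolve_backbone(ancestors[[sp]], cfg$within_species_div / 2,
                            cfg$omega_backbone)
      isl <- evolve_island(pool[[k]], cfg$within_species_div / 2,
                           cfg$omega_island)
      asm <- assemble_genome(gid, bb, isl)
      genomes[[gid]] <- structure(list(
        genome_id = gid, species = sp, type_id = pool[[k]]$type_id,
        full_seq = asm$seq, full_features = asm$features,
        island_start = asm$island_start, island_end = asm$island_end,
        island_gene_ids = asm$island_gene_ids,
        contigs = NULL, features = NULL, frag_class = NA_character_),
        class = "obc_genome")
    }
  }

  ## plant whole-island HGT across species
  hgt_rows <- list()
  gids <- names(genomes)
  sp_of <- vapply(genomes, `[[`, character(1), "species")
  hgt_draw <- runif(length(gids)) < cfg$p_hgt
  for (i in which(hgt_draw)) {
    donors <- gids[sp_of != sp_of[i]]
    if (!length(donors)) next
    donor <- sample(donors, 1)
    rec <- genomes[[gids[i]]]
    don <- genomes[[donor]]
    isl_seq <- substring(don$full_seq, don$island_start, don$island_end)
    rec <- transplant_island(rec, don, isl_seq)
    genomes[[gids[i]]] <- rec
    hgt_rows[[length(hgt_rows) + 1L]] <-
      tibble(donor = donor, recipient = gids[i], type_id = don$type_id)
  }

  ## fragmentation
  classes <- sample(names(cfg$frag_probs), length(gids), replace = TRUE,
                    prob = cfg$frag_probs)
  for (i in seq_along(gids)) {
    genomes[[gids[i]]] <- fragment_genome_impl(genomes[[gids[i]]], classes[i])
  }

  truth_genomes <- bind_rows(lapply(genomes, function(g) {
    tibble(genome_id = g$genome_id, species = g$species, type_id = g$type_id,
           frag_class = g$frag_class, island_start = g$island_start,
           island_end = g$island_end,
           island_len = g$island_end - g$island_start + 1L,
           n_island_genes = length(g$island_gene_ids))
  }))

  panel <- bind_rows(lapply(sp_ids, function(sp) {
    anc <- ancestors[[sp]]
    tibble(label = sp,
           marker = c("ITS", "23S"),
           seq = c(anc$seq[anc$part_id == "its"],
                   anc$seq[anc$part_id == "rrn23S"]))
  }))

  structure(list(
    cfg = cfg, genomes = genomes,
    truth = list(genomes = truth_genomes,
                 hgt = if (length(hgt_rows)) bind_rows(hgt_rows) else
                   tibble(donor = character(), recipient = character(),
                          type_id = character())),
    panel = panel, pool = pool), class = "obc_population")
}

## Replace the recipient's island with the donor's current island (verbatim
## copy: locus distance ~ 0 while genome distance reflects the species split).
transplant_island <- function(rec, don, donor_island_seq) {
  left <- substring(rec$full_seq, 1L, rec$island_start - 1L)
  right <- substring(rec$full_seq, rec$island_end + 1L, nchar(rec$full_seq))
  shift <- nchar(donor_island_seq) - (rec$island_end - rec$island_start + 1L)
  feats <- rec$full_features
  inside <- feats$start >= rec$island_start & feats$end <= rec$island_end
  feats <- feats[!inside, ]
  after <- feats$start > rec$island_end
  feats$start[after] <- feats$start[after] + shift
  feats$end[after] <- feats$end[after] + shift
  don_feats <- don$full_features
  din <- don_feats$start >= don$island_start & don_feats$end <= don$island_end
  don_feats <- don_feats[din, ]
  offset <- rec$island_start - don$island_start
  don_feats$start <- don_feats$start + offset
  don_feats$end <- don_feats$end + offset
  don_feats$contig_id <- rec$genome_id
  don_feats$id <- sub(paste0("^", don$genome_id, "\\|"),
                      paste0(rec$genome_id, "|hgt_"), don_feats$id)
  feats <- bind_rows(feats, don_feats)
  feats <- feats[order(feats$start), ]
  rec$full_seq <- paste0(left, donor_island_seq, right)
  rec$full_features <- feats
  rec$island_end <- rec$island_start + nchar(donor_island_seq) - 1L
  rec$island_gene_ids <- don_feats$id[don_feats$kind == "CDS"]
  rec$type_id <- don$type_id
  rec
}

#' @export
print.obc_population <- function(x, ...) {
  cat("<obc_population> ", length(x$genomes), " genomes, ",
      length(unique(x$truth$genomes$type_id)), " island types in use, ",
      nrow(x$truth$hgt), " planted HGT events\n", sep = "")
  invisible(x)
}

#' Emit 23S-anchored long reads from a population
#'
#' Anchored reads (fraction `1 - background_read_frac`) are placed so that they
#' contain the complete 23S gene and at least `min_island_in_read` bp of
#' downstream island; background reads start at uniform positions. Read truth
#' records the source genome and the realised island content.
#'
#' @param pop An `obc_population`.
#' @param cfg Defaults to `pop$cfg`.
#' @param seed Integer seed (defaults to `cfg$seed + 1`).
#' @return List with `seqs` (named character), `features` (tibble of ITS/23S
#'   and CDS features fully contained in each read, read coordinates), and
#'   `truth` (tibble: read_id, genome_id, species, type_id, island_bp,
#'   anchored).
#' @export
emit_long_reads <- function(pop, cfg = pop$cfg, seed = cfg$seed + 1L) {
  withr::with_seed(seed, emit_long_reads_impl(pop, cfg))
}

emit_long_reads_impl <- function(pop, cfg) {
  genomes <- pop$genomes
  gids <- names(genomes)
  ## genomes whose island can supply the anchored minimum
  eligible <- gids[vapply(genomes, function(g)
    g$island_end - g$island_start + 1L >= cfg$min_island_in_read, logical(1))]
  if (!length(eligible)) {
    abort("no genome island is long enough for anchored reads",
          class = "obc_config_error")
  }
  seqs <- character(cfg$n_reads)
  truth <- vector("list", cfg$n_reads)
  feat_rows <- vector("list", cfg$n_reads)
  for (r in seq_len(cfg$n_reads)) {
    rid <- sprintf("read%04d", r)
    background <- runif(1) < cfg$background_read_frac
    gid <- if (background) sample(gids, 1) else sample(eligible, 1)
    g <- genomes[[gid]]
    glen <- nchar(g$full_seq)
    f23 <- g$full_features[g$full_features$kind == "rRNA_23S", ]
    s23 <- f23$start[1]; e23 <- f23$end[1]
    len23 <- e23 - s23 + 1L
    if (background) {
      L <- as.integer(round(runif(1, cfg$read_len_range[1],
                                  min(cfg$read_len_range[2], glen))))
      s <- sample.int(glen - L + 1L, 1)
    } else {
      repeat {
        L <- as.integer(round(runif(1, cfg$read_len_range[1],
                                    cfg$read_len_range[2])))
        if (L >= len23 + cfg$min_island_in_read) break
      }
      lo <- max(1L, e23 + cfg$min_island_in_read - L + 1L)
      hi <- min(s23, glen - L + 1L)
      s <- if (hi <= lo) lo else sample(lo:hi, 1)
    }
    e <- min(s + L - 1L, glen)
    seqs[r] <- substring(g$full_seq, s, e)
    island_bp <- max(0L, min(e, g$island_end) - max(s, g$island_start) + 1L)
    anchored <- s <= s23 && e >= e23 && island_bp >= cfg$min_island_in_read
    truth[[r]] <- tibble(read_id = rid, genome_id = gid, species = g$species,
                         type_id = g$type_id, island_bp = island_bp,
                         anchored = anchored)
    ff <- g$full_features
    keep <- ff$start >= s & ff$end <= e
    if (any(keep)) {
      f <- ff[keep, ]
      f$start <- f$start - s + 1L
      f$end <- f$end - s + 1L
      f$contig_id <- rid
      f$id <- paste(rid, sub("^.*\\|", "", f$id), sep = "|")
      feat_rows[[r]] <- f
    }
  }
  list(seqs = setNames(seqs, sprintf("read%04d", seq_len(cfg$n_reads))),
       features = bind_rows(feat_rows),
       truth = bind_rows(truth))
}

#' Identifiable refinement of the planted type partition
#'
#' A planted island type whose observed members are, say, only left-side (C)
#' and right-side (D) fragments cannot be reunited by any gene-sharing method:
#' the fragments share no genes, and C-vs-D (like B-vs-B) comparisons are not
#' among the allowed completeness-class combinations. This refines each
#' planted type into the connected components of the allowed-combination graph
#' over its members' fragmentation classes - the finest partition any typing
#' method could recover - using truth labels only.
#'
#' @param truth_genomes The `truth$genomes` tibble of a population.
#' @return The tibble with an extra `identifiable_type` column.
#' @export
identifiable_types <- function(truth_genomes) {
  out <- truth_genomes
  out$identifiable_type <- NA_character_
  for (tt in unique(out$type_id)) {
    rows <- which(out$type_id == tt)
    cls <- out$frag_class[rows]
    n <- length(rows)
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      i != j && allowed_combination(cls[i], cls[j])))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    out$identifiable_type[rows] <- paste(tt, comp, sep = ".")
  }
  out
}
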