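#' Extract rRNA-marker-bounded islands from an annotated genome
#'
#' The O-antigen cluster sits between the 16S-ITS-23S rRNA block and the 5S
#' rRNA gene, so the 23S gene marks the island's left end and the 5S its
#' right end. Contigs whose markers sit on the reverse strand are flipped
#' first so the 23S is always the left anchor. Per genome:
#'
#' * both markers on one contig, 5S downstream of 23S: a complete (class A)
#'   island spanning the region strictly between the 23S 3' end and the 5S 5'
#'   start;
#' * a 23S-only contig and a 5S-only contig in the same genome: one class B
#'   island with two segments;
#' * only a 23S-only contig: class C (23S 3' end to contig end);
#' * only a 5S-only contig: class D (contig start to 5S 5' start).
#'
#' Island genes are the CDS features falling fully inside the span. Marker
#' genes and the ITS are never part of the island. A 5S upstream of the 23S
#' with no island between is degenerate and skipped with a message.
#'
#' @param genome An `obc_genome` (contigs + features), e.g. from
#'   [simulate_population()] or [read_genome_annotation()].
#' @param right_marker Feature kind bounding the island on the right
#'   (default the 5S rRNA gene; set to another annotated feature kind for
#'   relocated-island arrangements whose right neighbour is not the 5S).
#' @return A list of `obc_island` objects (possibly empty).
#' @export
extract_islands <- function(genome, right_marker = "rRNA_5S") {
  stopifnot(!is.null(genome$contigs), !is.null(genome$features))
  gid <- genome$genome_id
  complete <- list()
  c_cand <- list()
  d_cand <- list()
  for (cid in names(genome$contigs)) {
    nc <- normalize_contig(genome$contigs[[cid]],
                           genome$features[genome$features$contig_id == cid, ],
                           right_marker)
    f <- nc$features
    m23 <- f[f$kind == "rRNA_23S", , drop = FALSE]
    m5 <- f[f$kind == right_marker, , drop = FALSE]
    if (nrow(m23) && nrow(m5)) {
      span <- pick_marker_pair(m23, m5, f)
      if (is.null(span)) {
        message("degenerate marker arrangement on ", cid, "; skipped")
        next
      }
      complete[[length(complete) + 1L]] <-
        list(contig_id = cid, seq = nc$seq, features = f,
             start = span[1], end = span[2])
    } else if (nrow(m23)) {
      s <- min(m23$end) + 1L
      if (s <= nchar(nc$seq)) {
        c_cand[[length(c_cand) + 1L]] <-
          list(contig_id = cid, seq = nc$seq, features = f,
               start = s, end = nchar(nc$seq))
      }
    } else if (nrow(m5)) {
      e <- max(m5$start) - 1L
      if (e >= 1L) {
        d_cand[[length(d_cand) + 1L]] <-
          list(contig_id = cid, seq = nc$seq, features = f, start = 1L, end = e)
      }
    }
  }
  islands <- list()
  if (length(complete)) {
    for (i in seq_along(complete)) {
      suffix <- if (length(complete) > 1L) paste0("_", i) else ""
      islands[[length(islands) + 1L]] <-
        build_island(paste0(gid, "_obc", suffix), gid, "A", complete[i])
    }
  } else if (length(c_cand) && length(d_cand)) {
    islands[[1L]] <- build_island(paste0(gid, "_obc"), gid, "B",
                                  c(c_cand[1], d_cand[1]))
  } else if (length(c_cand)) {
    islands[[1L]] <- build_island(paste0(gid, "_obc"), gid, "C", c_cand[1])
  } else if (length(d_cand)) {
    islands[[1L]] <- build_island(paste0(gid, "_obc"), gid, "D", d_cand[1])
  }
  islands
}

## Flip a contig (and its features) when its markers lie on the minus strand,
## so downstream logic can assume the 23S -> 5S reading direction.
normalize_contig <- function(seq, features, right_marker = "rRNA_5S") {
  markers <- features[features$kind %in% c("rRNA_23S", right_marker), ]
  if (nrow(markers) && all(markers$strand == "-")) {
    L <- nchar(seq)
    f <- features
    new_start <- L - f$end + 1L
    new_end <- L - f$start + 1L
    f$start <- new_start
    f$end <- new_end
    f$strand <- ifelse(f$strand == "-", "+", "-")
    return(list(seq = revcomp(seq), features = f))
  }
  list(seq = seq, features = features)
}

## Choose the marker pair bounding the island on a contig: the nearest valid
## (23S upstream of 5S) pair whose gap contains at least one CDS, leftmost on
## ties; fall back to the tightest valid pair even without CDS.
pick_marker_pair <- function(m23, m5, features) {
  cand <- NULL
  for (i in seq_len(nrow(m23))) {
    for (j in seq_len(nrow(m5))) {
      s <- m23$end[i] + 1L
      e <- m5$start[j] - 1L
      if (e < s) next
      n_cds <- sum(features$kind == "CDS" & features$start >= s &
                     features$end <= e)
      cand <- bind_rows(cand, tibble(s = s, e = e, w = e - s + 1L,
                                     n_cds = n_cds))
    }
  }
  if (is.null(cand) || !nrow(cand)) return(NULL)
  with_cds <- cand[cand$n_cds > 0L, , drop = FALSE]
  pick <- if (nrow(with_cds)) with_cds else cand
  pick <- pick[order(pick$w, pick$s), ]
  c(pick$s[1], pick$e[1])
}

## Assemble an obc_island from one or two (contig, span) segments.
build_island <- function(island_id, genome_id, class, segs) {
  seg_tbl <- bind_rows(lapply(segs, function(s)
    tibble(contig_id = s$contig_id, start = s$start, end = s$end)))
  seg_seqs <- vapply(segs, function(s) substring(s$seq, s$start, s$end),
                     character(1))
  genes <- bind_rows(lapply(segs, function(s) {
    f <- s$features
    g <- f[f$kind == "CDS" & f$start >= s$start & f$end <= s$end, ,
           drop = FALSE]
    if (nrow(g)) g[order(g$start), c("id", "contig_id", "start", "end",
                                     "strand")] else NULL
  }))
  cds <- character(0)
  if (nrow(genes)) {
    cds <- vapply(seq_len(nrow(genes)), function(i) {
      s <- segs[[match(genes$contig_id[i], vapply(segs, `[[`, character(1),
                                                  "contig_id"))]]
      x <- substring(s$seq, genes$start[i], genes$end[i])
      if (genes$strand[i] == "-") revcomp(x) else x
    }, character(1))
    names(cds) <- genes$id
  }
  prot <- if (length(cds)) setNames(translate_cds(cds), names(cds)) else
    character(0)
  isl <- structure(list(
    island_id = island_id, genome_id = genome_id, class = class,
    segments = seg_tbl, segment_seqs = seg_seqs, genes = genes,
    cds = cds, proteins = prot,
    left_anchor = class %in% c("A", "B", "C"),
    right_anchor = class %in% c("A", "B", "D")), class = "obc_island")
  st <- island_stats(isl)
  isl$length <- st$length
  isl$gc <- st$gc
  isl$median_intergenic <- st$median_intergenic
  isl
}

#' @export
print.obc_island <- function(x, ...) {
  cat("<obc_island> ", x$island_id, " class ", x$class, ", ",
      nrow(x$genes), " genes, ", x$length, " bp, GC ",
      round(x$gc, 3), "\n", sep = "")
  invisible(x)
}

#' Per-island summary statistics
#'
#' @param island An `obc_island`.
#' @return A one-row tibble: `gc` ((G+C)/(A+C+G+T), ambiguity codes excluded
#'   from the denominator), `gene_count`, `median_intergenic` (median of
#'   `max(0, gap)` between consecutive CDS within a segment; gaps across
#'   segment boundaries excluded; overlapping genes contribute 0), and
#'   `length` (sum of segment spans).
#' @export
island_stats <- function(island) {
  len <- sum(nchar(island$segment_seqs))
  if (len == 0L) abort("zero-length island", class = "obc_island_error")
  gc <- gc_content(paste(island$segment_seqs, collapse = ""))
  gaps <- numeric(0)
  g <- island$genes
  if (!is.null(g) && nrow(g) > 1L) {
    for (cid in unique(g$contig_id)) {
      gg <- g[g$contig_id == cid, ]
      gg <- gg[order(gg$start), ]
      if (nrow(gg) > 1L) {
        gaps <- c(gaps, pmax(0, gg$start[-1] - gg$end[-nrow(gg)] - 1L))
      }
    }
  }
  tibble(gc = gc,
         gene_count = if (is.null(g)) 0L else nrow(g),
         median_intergenic = if (length(gaps)) median(gaps) else NA_real_,
         length = len)
}

#' Filter islands by minimum length
#'
#' Retains islands strictly longer than `min_len` (the genome-level screen
#' keeps islands > 10 kb), preserving input order.
#'
#' @param islands List of `obc_island`.
#' @param min_len Minimum length in bp (strict inequality).
#' @return The retained sublist.
#' @export
filter_islands <- function(islands, min_len = 10000) {
  if (min_len < 0) abort("min_len must be >= 0", class = "obc_island_error")
  islands[vapply(islands, function(x) x$length > min_len, logical(1))]
}

#' Extract island fragments from 23S-anchored long reads
#'
#' For each read carrying a complete 23S gene, the island runs from the 23S 3'
#' end to the read end (truncated at the 5S 5' start when the read reaches
#' it), after orientation normalisation. Reads contributing fewer than
#' `min_island` bp of island are dropped (the screen keeps reads with at
#' least 5 kb of island). Returned islands are class C; companion ITS and 23S
#' sequences are attached when fully contained in the read.
#'
#' @param reads Result of [emit_long_reads()] or an equivalent list with
#'   `seqs` (named character) and `features` (tibble).
#' @param min_island Minimum island bp (inclusive threshold).
#' @return List of `obc_island` objects, one per retained read, each with
#'   `read_id`, and `its_seq` / `r23s_seq` when available.
#' @export
extract_read_islands <- function(reads, min_island = 5000) {
  out <- list()
  for (rid in names(reads$seqs)) {
    f <- reads$features[reads$features$contig_id == rid, , drop = FALSE]
    if (!nrow(f) || !any(f$kind == "rRNA_23S")) next
    nc <- normalize_contig(reads$seqs[[rid]], f)
    f <- nc$features
    m23 <- f[f$kind == "rRNA_23S", ]
    s <- min(m23$end) + 1L
    e <- nchar(nc$seq)
    m5 <- f[f$kind == "rRNA_5S", ]
    if (nrow(m5) && any(m5$start > s)) e <- min(m5$start[m5$start > s]) - 1L
    if (e - s + 1L < min_island) next
    isl <- build_island(paste0(rid, "_obc"), rid, "C",
                        list(list(contig_id = rid, seq = nc$seq, features = f,
                                  start = s, end = e)))
    isl$read_id <- rid
    its <- f[f$kind == "ITS", ]
    if (nrow(its)) isl$its_seq <- substring(nc$seq, its$start[1], its$end[1])
    isl$r23s_seq <- substring(nc$seq, m23$start[1], m23$end[1])
    out[[length(out) + 1L]] <- isl
  }
  out
}

#' Tabular summary of a set of islands
#'
#' @param islands List of `obc_island`.
#' @return Tibble with one row per island (id, genome, class, length, gc,
#'   gene_count, median_intergenic, n_segments).
#' @export
islands_summary <- function(islands) {
  bind_rows(lapply(islands, function(x)
    tibble(island_id = x$island_id, genome_id = x$genome_id, class = x$class,
           length = x$length, gc = x$gc,
           gene_count = nrow(x$genes) %||% 0L,
           median_intergenic = x$median_intergenic,
           n_segments = nrow(x$segments))))
}

#' Paired island-vs-genome contrasts of GC and intergenic spacer
#'
#' For each island's host genome, computes the genome-wide GC and the median
#' intergenic spacer outside the island, and runs paired t-tests of island vs
#' genome values (GC is expected to be depressed in the island).
#'
#' @param islands List of `obc_island`.
#' @param genomes Named list of `obc_genome` matching `island$genome_id`.
#' @return List with `table` (per-genome paired values) and `gc_test`,
#'   `spacer_test` (`htest` objects, or NULL when fewer than 3 pairs).
#' @export
island_genome_contrasts <- function(islands, genomes) {
  rows <- lapply(islands, function(isl) {
    g <- genomes[[isl$genome_id]]
    if (is.null(g)) return(NULL)
    genome_gc <- gc_content(paste(unlist(g$contigs), collapse = ""))
    f <- g$features[g$features$kind == "CDS", ]
    gaps <- numeric(0)
    for (cid in unique(f$contig_id)) {
      ff <- f[f$contig_id == cid, ]
      ff <- ff[order(ff$start), ]
      backbone <- !(ff$id %in% isl$genes$id)
      if (nrow(ff) > 1L) {
        gap <- pmax(0, ff$start[-1] - ff$end[-nrow(ff)] - 1L)
        keep <- backbone[-1] & backbone[-nrow(ff)]
        gaps <- c(gaps, gap[keep])
      }
    }
    tibble(genome_id = g$genome_id, island_gc = isl$gc, genome_gc = genome_gc,
           island_spacer = isl$median_intergenic,
           genome_spacer = if (length(gaps)) median(gaps) else NA_real_)
  })
  tab <- bind_rows(rows)
  gc_test <- spacer_test <- NULL
  if (nrow(tab) >= 3L) {
    gc_test <- t.test(tab$island_gc, tab$genome_gc, paired = TRUE)
    ok <- !is.na(tab$island_spacer) & !is.na(tab$genome_spacer)
    if (sum(ok) >= 3L) {
      spacer_test <- t.test(tab$island_spacer[ok], tab$genome_spacer[ok],
                            paired = TRUE)
    }
  }
  list(table = tab, gc_test = gc_test, spacer_test = spacer_test)
}
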