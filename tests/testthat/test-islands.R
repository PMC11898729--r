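## A contig laid out as [23S 1-3kb][12 kb of CDS][5S] with known geometry.
island_parts_fixture <- function() {
  tibble::tibble(
    kind = c("rRNA_23S", rep(c("CDS", "spacer"), each = 1, times = 10),
             "rRNA_5S"),
    len = c(3000L, rep(c(1140L, 60L), 10), 100L))
}

test_that("a complete marker pair yields one class-A island with exact span", {
  g <- manual_genome(island_parts_fixture(), seed = 4)
  isl <- extract_islands(g)
  expect_length(isl, 1)
  expect_identical(isl[[1]]$class, "A")
  expect_identical(isl[[1]]$length, 12000L)
  expect_identical(isl[[1]]$segments$start, 3001L)
  expect_identical(isl[[1]]$segments$end, 15000L)
  expect_identical(nrow(isl[[1]]$genes), 10L)
  expect_true(isl[[1]]$left_anchor && isl[[1]]$right_anchor)
})

test_that("marker-only contigs classify as C or D; both halves give B", {
  pc <- tibble::tibble(kind = c("rRNA_23S", "CDS", "spacer", "CDS"),
                       len = c(3000L, 900L, 50L, 900L))
  gc_ <- manual_genome(pc, genome_id = "gc", seed = 5)
  ic <- extract_islands(gc_)
  expect_identical(ic[[1]]$class, "C")
  expect_identical(ic[[1]]$segments$end, sum(pc$len))
  pd <- tibble::tibble(kind = c("CDS", "spacer", "CDS", "rRNA_5S"),
                       len = c(900L, 50L, 900L, 100L))
  gd <- manual_genome(pd, genome_id = "gd", seed = 6)
  id_ <- extract_islands(gd)
  expect_identical(id_[[1]]$class, "D")
  expect_identical(id_[[1]]$segments$start, 1L)
  ## same genome holding a C-like and a D-like contig -> one B island
  gb <- structure(list(
    genome_id = "gb",
    contigs = c(gc_$contigs, gd$contigs),
    features = dplyr::bind_rows(gc_$features, gd$features)),
    class = "obc_genome")
  names(gb$contigs) <- c("gc", "gd")
  ib <- extract_islands(gb)
  expect_length(ib, 1)
  expect_identical(ib[[1]]$class, "B")
  expect_identical(nrow(ib[[1]]$segments), 2L)
  expect_identical(nrow(ib[[1]]$genes), 4L)
})

test_that("degenerate marker order is skipped with a message", {
  parts <- tibble::tibble(kind = c("rRNA_5S", "spacer", "rRNA_23S"),
                          len = c(100L, 500L, 3000L))
  g <- manual_genome(parts, seed = 7)
  expect_message(isl <- extract_islands(g), "degenerate")
  expect_length(isl, 0)
})

test_that("islands are invariant to reverse-complementing the contig", {
  g <- manual_genome(island_parts_fixture(), seed = 8)
  fwd <- extract_islands(g)[[1]]
  rev <- extract_islands(flip_genome(g))[[1]]
  expect_identical(fwd$class, rev$class)
  expect_identical(fwd$length, rev$length)
  expect_identical(fwd$gc, rev$gc)
  expect_identical(unname(fwd$cds), unname(rev$cds))
  expect_identical(fwd$median_intergenic, rev$median_intergenic)
})

test_that("length filter is strictly greater-than and order preserving", {
  g <- manual_genome(island_parts_fixture(), seed = 9)
  isl <- extract_islands(g)
  expect_length(filter_islands(isl, 12000), 0)   # length 12000, strict >
  expect_length(filter_islands(isl, 11999), 1)
  expect_identical(filter_islands(isl, 0), isl)
  expect_error(filter_islands(isl, -1), class = "obc_island_error")
})

test_that("island statistics match hand-computed values", {
  ## GC of an ATGC repeat is exactly 0.5
  isl <- structure(list(segment_seqs = strrep("ATGC", 100),
                        genes = tibble::tibble(contig_id = character(),
                                               start = integer(),
                                               end = integer())),
                   class = "obc_island")
  st <- island_stats(isl)
  expect_identical(st$gc, 0.5)
  ## two CDS at 1-300 and 311-600: single gap of 10
  isl2 <- structure(list(
    segment_seqs = strrep("A", 600),
    genes = tibble::tibble(contig_id = "c", start = c(1L, 311L),
                           end = c(300L, 600L))), class = "obc_island")
  expect_identical(island_stats(isl2)$median_intergenic, 10)
  ## overlapping genes contribute zero, not negative
  isl3 <- structure(list(
    segment_seqs = strrep("A", 600),
    genes = tibble::tibble(contig_id = "c", start = c(1L, 250L),
                           end = c(300L, 600L))), class = "obc_island")
  expect_identical(island_stats(isl3)$median_intergenic, 0)
  expect_error(island_stats(structure(list(segment_seqs = character()),
                                      class = "obc_island")),
               class = "obc_island_error")
})

test_that("read islands respect the inclusive 5 kb floor", {
  mk_read <- function(downstream, rid) {
    parts <- tibble::tibble(kind = c("spacer", "rRNA_23S", "spacer"),
                            len = c(200L, 2900L, downstream))
    g <- manual_genome(parts, genome_id = rid, seed = 12)
    list(seqs = g$contigs, features = g$features)
  }
  r1 <- mk_read(7000L, "r1")
  out1 <- extract_read_islands(r1, 5000)
  expect_length(out1, 1)
  expect_identical(out1[[1]]$length, 7000L)
  expect_identical(out1[[1]]$class, "C")
  expect_length(extract_read_islands(mk_read(4999L, "r2"), 5000), 0)
  expect_length(extract_read_islands(mk_read(5000L, "r3"), 5000), 1)
  ## reads without a 23S are skipped silently
  no23 <- list(seqs = c(r4 = strrep("A", 8000)),
               features = tibble::tibble(contig_id = character(),
                                         start = integer(), end = integer(),
                                         strand = character(),
                                         kind = character(),
                                         id = character()))
  expect_length(extract_read_islands(no23, 5000), 0)
})

test_that("a relocated island bounded by an alternative right marker extracts", {
  cfg <- sim_config(n_species = 1, genomes_per_species = 1,
                    n_island_types = 1,
                    frag_probs = c(A = 1, B = 0, C = 0, D = 0),
                    p_hgt = 0, alt_right_marker = "tRNA_cluster", seed = 44)
  pop <- simulate_population(cfg)
  g <- pop$genomes[[1]]
  ## the canonical 5S boundary is absent; the alternative marker bounds it
  expect_length(extract_islands(g)[[1]]$class, 1)  # falls back to class C
  expect_identical(extract_islands(g)[[1]]$class, "C")
  isl <- extract_islands(g, right_marker = "tRNA_cluster")
  expect_identical(isl[[1]]$class, "A")
  tr <- pop$truth$genomes
  expect_identical(isl[[1]]$segments$start, tr$island_start)
  expect_identical(isl[[1]]$segments$end, tr$island_end)
})

test_that("simulated read islands are retained iff anchored", {
  pop <- shared_pop()
  reads <- emit_long_reads(pop)
  ri <- extract_read_islands(reads, pop$cfg$min_island_in_read)
  kept <- vapply(ri, `[[`, character(1), "read_id")
  tr <- reads$truth
  expect_setequal(kept, tr$read_id[tr$anchored])
})

test_that("island GC is depressed relative to the genome (paired contrast)", {
  pop <- shared_pop()
  islands <- unlist(lapply(pop$genomes, extract_islands), recursive = FALSE)
  ctr <- island_genome_contrasts(islands, pop$genomes)
  expect_true(all(ctr$table$island_gc < ctr$table$genome_gc))
  expect_lt(ctr$gc_test$estimate, 0)        # island minus genome
  expect_lt(ctr$gc_test$p.value, 1e-6)
})
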