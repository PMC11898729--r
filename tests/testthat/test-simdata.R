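test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(frag_probs = c(A = 0.5, B = 0.5, C = 0, D = 0.2)),
               class = "obc_config_error")
  expect_error(sim_config(p_hgt = 1.5), class = "obc_config_error")
  expect_error(sim_config(min_island_in_read = 99999),
               class = "obc_config_error")
  expect_error(sim_config(island_len_range = c(15000, 6000)),
               class = "obc_config_error")
  ## island genes cannot fit the requested span
  cfg <- sim_config(island_len_range = c(900, 1000),
                    island_genes_range = c(30, 30))
  expect_error(generate_obc_pool(cfg), class = "obc_config_error")
})

test_that("island pool repertoires are valid CDS cassettes from disjoint pools", {
  cfg <- sim_config(n_island_types = 5, seed = 21)
  pool <- generate_obc_pool(cfg)
  expect_length(pool, 5)
  for (rep in pool) {
    expect_true(all(vapply(rep$genes, obctools:::is_valid_cds, logical(1))))
    n <- length(rep$genes)
    expect_gte(n, cfg$island_genes_range[1])
    expect_lte(n, cfg$island_genes_range[2])
  }
  ## cross-repertoire ortholog sharing is ~zero when scored by RBH
  a <- fake_island("a", setNames(obctools:::translate_cds(pool[[1]]$genes),
                                 paste0("a", seq_along(pool[[1]]$genes))))
  b <- fake_island("b", setNames(obctools:::translate_cds(pool[[2]]$genes),
                                 paste0("b", seq_along(pool[[2]]$genes))))
  sf <- shared_gene_fraction(a, b)
  expect_lt(sf$shared_fraction, 0.05)
  ## K = 1 degenerate case
  p1 <- generate_obc_pool(sim_config(n_island_types = 1, seed = 3))
  expect_length(p1, 1)
})

test_that("population simulation is deterministic and bookkeeping is exact", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 2,
                    n_island_types = 3, seed = 77, n_reads = 20)
  pop1 <- simulate_population(cfg)
  pop2 <- simulate_population(cfg)
  d1 <- file.path(tempfile(), "p1")
  d2 <- file.path(tempfile(), "p2")
  write_population(pop1, d1)
  write_population(pop2, d2)
  for (f in c("genomes.fna", "genomes.gff", "panel.fna",
              file.path("truth", "genomes.tsv"))) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_identical(nrow(pop1$truth$genomes), 4L)
  expect_false(anyDuplicated(pop1$truth$genomes$genome_id) > 0)
})

test_that("p_hgt = 0 plants no transfers; planted transfers copy the donor type", {
  cfg0 <- sim_config(n_species = 2, genomes_per_species = 3, p_hgt = 0,
                     seed = 5)
  expect_identical(nrow(simulate_population(cfg0)$truth$hgt), 0L)
  cfg1 <- sim_config(n_species = 3, genomes_per_species = 5, p_hgt = 0.5,
                     n_island_types = 6, seed = 6)
  pop <- simulate_population(cfg1)
  hgt <- pop$truth$hgt
  expect_gt(nrow(hgt), 0)
  tg <- pop$truth$genomes
  for (i in seq_len(nrow(hgt))) {
    expect_identical(tg$type_id[tg$genome_id == hgt$recipient[i]],
                     hgt$type_id[i])
  }
})

test_that("codon evolution honours branch length and omega limits", {
  cds <- withr::with_seed(9, obctools:::random_cds(400, 0.3))
  expect_identical(evolve_cds(cds, 0, 0.5), cds)
  expect_error(evolve_cds("ACGTACG", 0.1, 1), class = "obc_cds_error")
  ## omega = 0: only synonymous changes; at a branch short enough to avoid
  ## multi-hit codons (whose pathway averaging spreads counts) NG86 dN = 0
  mut <- withr::with_seed(10, evolve_cds(cds, 0.01, 0))
  expect_true(obctools:::is_valid_cds(mut))
  r <- ng86_dnds(cds, mut)
  expect_identical(r$Nd, 0)
  expect_gt(r$Sd, 0)
  ## omega = 1 on a long CDS: estimate lands in a broad neutral band
  long <- withr::with_seed(11, obctools:::random_cds(3000, 0.35))
  est <- vapply(1:5, function(s) {
    a <- withr::with_seed(100 + s, evolve_cds(long, 0.05, 1))
    b <- withr::with_seed(200 + s, evolve_cds(long, 0.05, 1))
    ng86_dnds(a, b)$ratio
  }, numeric(1))
  expect_gt(mean(est), 0.7)
  expect_lt(mean(est), 1.3)
})

test_that("GC content of emitted islands and backbones tracks the targets", {
  pop <- shared_pop()
  islands <- unlist(lapply(pop$genomes, extract_islands), recursive = FALSE)
  s <- islands_summary(islands)
  long <- s$length >= 5000
  expect_true(all(abs(s$gc[long] - pop$cfg$island_gc) <= 0.015))
  ## backbone: genome minus island
  g <- pop$genomes[[1]]
  bb <- paste0(substring(g$full_seq, 1, g$island_start - 1),
               substring(g$full_seq, g$island_end + 1, nchar(g$full_seq)))
  expect_lt(abs(gc_content(bb) - pop$cfg$backbone_gc), 0.015)
})

test_that("fragmentation produces the requested completeness class", {
  pop <- shared_pop()
  g <- pop$genomes[[which(vapply(pop$genomes, function(x)
    x$frag_class == "A", logical(1)))[1]]]
  for (cls in c("A", "B", "C", "D")) {
    fg <- fragment_genome(g, cls, seed = 31)
    kinds <- fg$features$kind
    if (cls %in% c("A", "B", "C")) expect_true("rRNA_23S" %in% kinds)
    if (cls == "C") expect_false("rRNA_5S" %in% kinds)
    if (cls == "D") expect_false("rRNA_23S" %in% kinds)
    if (cls == "D") expect_true("rRNA_5S" %in% kinds)
    if (cls == "B") expect_gte(length(fg$contigs), 2L)
    ext <- extract_islands(fg)
    expect_length(ext, 1)
    expect_identical(ext[[1]]$class, cls)
  }
})

test_that("anchored long reads carry a complete 23S and enough island", {
  pop <- shared_pop()
  reads <- emit_long_reads(pop)
  tr <- reads$truth
  ## truth map is a bijection onto emitted reads
  expect_setequal(tr$read_id, names(reads$seqs))
  expect_false(anyDuplicated(tr$read_id) > 0)
  ## anchored reads satisfy both anchoring conditions by construction
  anch <- tr[tr$anchored, ]
  expect_gt(nrow(anch), 0)
  expect_true(all(anch$island_bp >= pop$cfg$min_island_in_read))
  feats <- reads$features
  for (rid in anch$read_id) {
    expect_true(any(feats$contig_id == rid & feats$kind == "rRNA_23S"))
  }
  ## read lengths within the configured range
  expect_true(all(nchar(reads$seqs) <= pop$cfg$read_len_range[2]))
})

test_that("extraction round-trips the planted island coordinates", {
  pop <- shared_pop()
  tg <- pop$truth$genomes
  for (gid in tg$genome_id[tg$frag_class == "A"]) {
    isl <- extract_islands(pop$genomes[[gid]])[[1]]
    row <- tg[tg$genome_id == gid, ]
    expect_identical(isl$segments$start, row$island_start)
    expect_identical(isl$segments$end, row$island_end)
    expect_identical(nrow(isl$genes), row$n_island_genes)
  }
})

test_that("identifiable truth refinement splits only unbridgeable types", {
  truth <- tibble::tibble(
    genome_id = paste0("g", 1:6),
    species = "s", type_id = c("T1", "T1", "T1", "T2", "T2", "T3"),
    frag_class = c("A", "C", "D", "C", "D", "B"))
  out <- identifiable_types(truth)
  ## T1 bridged by the A member; T2 (C vs D only) splits; T3 singleton
  expect_length(unique(out$identifiable_type[out$type_id == "T1"]), 1L)
  expect_length(unique(out$identifiable_type[out$type_id == "T2"]), 2L)
  expect_length(unique(out$identifiable_type[out$type_id == "T3"]), 1L)
})
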