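test_that("distance pairs and the twice-rule HGT flag follow the definition", {
  d <- distance_pair(90, 96)
  expect_identical(d$d_g, 10)
  expect_identical(d$d_l, 4)
  expect_true(d$recent_hgt)            # 10 >= 2 * 4
  expect_false(distance_pair(90, 94)$recent_hgt)   # 10 < 12
  d0 <- distance_pair(100, 100)
  expect_identical(d0$d_g, 0)
  expect_false(d0$recent_hgt)          # identical genomes never flagged
  expect_error(distance_pair(0, 50), class = "obc_evodist_error")
  expect_error(distance_pair(101, 50), class = "obc_evodist_error")
})

test_that("NG86 counts match hand-derived single-codon cases", {
  ## identical sequences: no differences, ratio undefined
  r0 <- ng86_dnds("TTTAAA", "TTTAAA")
  expect_identical(r0$Nd + r0$Sd, 0)
  expect_true(is.na(r0$ratio))
  ## TTT (Phe) vs TTA (Leu): one nonsynonymous difference, dS = 0
  r1 <- ng86_dnds("TTT", "TTA")
  expect_identical(r1$Nd, 1)
  expect_identical(r1$Sd, 0)
  expect_identical(r1$dS, 0)
  ## TAT (Tyr) vs TGG (Trp): the TAT->TAG path hits a stop, leaving one
  ## valid path with two nonsynonymous steps
  r2 <- ng86_dnds("TAT", "TGG")
  expect_identical(r2$Nd, 2)
  expect_identical(r2$Sd, 0)
  ## GGT vs GGA (Gly/Gly): synonymous third-position change
  r3 <- ng86_dnds("GGT", "GGA")
  expect_identical(r3$Sd, 1)
  expect_identical(r3$Nd, 0)
  expect_error(ng86_dnds("TTT", "TTTAAA"), class = "obc_evodist_error")
})

test_that("site counts satisfy N + S = 3 x codons and match the oracle", {
  tab <- obctools:::ng86_tables()
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (cod in sense[seq(1, length(sense), by = 7)]) {
    expect_equal(tab$syn_sites[[cod]], oracle_syn_sites(cod), info = cod)
  }
  ## random aligned pairs agree with the pathway-enumeration oracle
  set.seed(42)
  for (i in 1:100) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    got <- c(tab$Nd[c1, c2], tab$Sd[c1, c2])
    want <- oracle_ng86_pair(c1, c2)
    expect_equal(unname(got), unname(want), info = paste(c1, c2))
  }
  ## whole-sequence invariant
  a <- withr::with_seed(6, obctools:::random_cds(200, 0.4))
  b <- withr::with_seed(7, evolve_cds(a, 0.08, 0.5))
  r <- ng86_dnds(a, b)
  expect_equal(r$N + r$S, 3 * r$n_codons)
})

test_that("codon back-threading drops indel columns before counting", {
  a <- "ATGAAATTTGGGCCCTGA"          # M K F G P *
  ## remove the F codon from b: protein alignment gaps it out
  b <- "ATGAAAGGGCCCTGA"             # M K G P *
  pr <- codon_align_pair(a, b)
  expect_identical(nchar(pr$a), nchar(pr$b))
  expect_identical(nchar(pr$a), 12L)  # M K G P retained
  r <- ng86_dnds(pr$a, pr$b)
  expect_identical(r$Nd + r$Sd, 0)
})

test_that("omega recovery is unbiased at desk scale", {
  cds <- withr::with_seed(8, obctools:::random_cds(2500, 0.35))
  est <- vapply(1:6, function(s) {
    a <- withr::with_seed(300 + s, evolve_cds(cds, 0.05, 0.1))
    b <- withr::with_seed(400 + s, evolve_cds(cds, 0.05, 0.1))
    ng86_dnds(a, b)$ratio
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.1), 0.03)
})

test_that("equal island and backbone omega yields a null paired contrast", {
  ## null calibration: same omega in both compartments, 20 seeds
  p_vals <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      rows <- lapply(1:6, function(p) {
        anc_o <- obctools:::random_cds(400, 0.3)
        anc_b <- obctools:::random_cds(400, 0.3)
        tibble::tibble(
          genome_a = paste0("ga", p), genome_b = paste0("gb", p),
          compartment = c("obc", "backbone"),
          cds_a = c(evolve_cds(anc_o, 0.01, 0.12),
                    evolve_cds(anc_b, 0.01, 0.12)),
          cds_b = c(evolve_cds(anc_o, 0.01, 0.12),
                    evolve_cds(anc_b, 0.01, 0.12)))
      })
      agg <- aggregate_dnds(dplyr::bind_rows(rows), align = FALSE)
      if (is.null(agg$test)) NA_real_ else agg$test$p.value
    })
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05, na.rm = TRUE), 0.9)
})

test_that("dN/dS aggregation keeps compartments separate (no double counting)", {
  pop <- shared_pop()
  an <- run_obc_analysis(pop$genomes, dnds = TRUE)
  skip_if(is.null(an$dnds))
  ## island gene ids never appear in the backbone ortholog set
  bb <- attr(an$aai, "orthologs")
  island_ids <- unlist(lapply(an$islands, function(x) x$genes$id))
  expect_length(intersect(c(bb$query, bb$subject), island_ids), 0)
  expect_true(all(c("dnds_obc", "dnds_backbone") %in%
                    names(an$dnds$per_pair)))
})

test_that("the AAI cladogram is ultrametric and conserves leaves", {
  pop <- shared_pop()
  an <- shared_analysis()
  cl <- aai_cladogram(an$aai)
  expect_setequal(cl$phylo$tip.label, rownames(an$aai))
  expect_true(all(diff(cl$hclust$height) >= -1e-9))
  ## cutting at the within/between gap recovers the species
  k <- length(unique(pop$truth$genomes$species))
  cut <- stats::cutree(cl$hclust, k = k)
  sp <- setNames(pop$truth$genomes$species, pop$truth$genomes$genome_id)
  tab <- table(cut, sp[names(cut)])
  expect_true(all(rowSums(tab > 0) == 1))
  ## identical rows merge first at height zero
  m2 <- matrix(c(100, 100, 90,
                 100, 100, 90,
                 90, 90, 100), 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  cl2 <- aai_cladogram(m2)
  expect_setequal(cl2$hclust$labels[-cl2$hclust$merge[1, ]], c("g1", "g2"))
  expect_lt(cl2$hclust$height[1], 1e-9)
  expect_error(aai_cladogram(matrix(c(100, NA, NA, 100), 2)),
               class = "obc_evodist_error")
})

test_that("locus-genome regression matches the closed-form normal equations", {
  perfect <- tibble::tibble(d_g = c(1, 2, 5, 9), d_l = c(1, 2, 5, 9))
  r <- suppressWarnings(regression_locus_vs_genome(perfect))
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  for (s in 1:10) {
    dat <- withr::with_seed(s, tibble::tibble(d_g = runif(20, 0, 10),
                                              d_l = runif(20, 0, 10)))
    r <- regression_locus_vs_genome(dat)
    x <- dat$d_g
    y <- dat$d_l
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b0 <- mean(y) - b1 * mean(x)
    expect_equal(r$slope, b1)
    expect_equal(r$intercept, b0)
  }
  flat <- tibble::tibble(d_g = c(2, 2, 2), d_l = c(1, 2, 3))
  expect_true(is.na(regression_locus_vs_genome(flat)$slope))
})
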