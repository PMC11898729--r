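test_that("alignment identity and coverage behave on constructed pairs", {
  a <- rand_aa(100, seed = 1)
  h <- align_proteins(a, a)
  expect_identical(h$identity, 1)
  expect_identical(h$cov_q, 1)
  expect_identical(h$cov_s, 1)
  ## exact prefix: full identity, 70% query coverage
  h2 <- align_proteins(a, substr(a, 1, 70))
  expect_identical(h2$identity, 1)
  expect_equal(h2$cov_q, 0.7)
  expect_identical(h2$cov_s, 1)
  expect_error(align_proteins("ACDEF#", a), class = "obc_align_error")
})

test_that("random unrelated proteins essentially never pass the 50/70 gate", {
  n <- 1000
  pa <- withr::with_seed(2, replicate(n, rand_aa(100)))
  pb <- withr::with_seed(3, replicate(n, rand_aa(100)))
  hits <- obctools:::align_protein_sets(setNames(pa, paste0("a", 1:n)),
                                        setNames(pb, paste0("a", 1:n)))
  hits <- hits[hits$query_id == hits$subject_id, ]  # elementwise pairs
  pass <- hits$identity >= 0.5 & hits$cov_q >= 0.7 & hits$cov_s >= 0.7
  expect_lt(mean(pass), 0.01)
})

test_that("RBH matches the brute-force oracle on random gene sets", {
  th <- obc_thresholds()
  for (rep in 1:6) {
    seeds <- 100 * rep + 1:2
    n_a <- withr::with_seed(seeds[1], sample(3:12, 1))
    n_b <- withr::with_seed(seeds[2], sample(3:12, 1))
    ## half the genes are mutated copies (real orthologs), half noise
    base <- replicate(min(n_a, n_b), rand_aa(120, seed = 1000 * rep))
    mut <- function(s, seed) withr::with_seed(seed, {
      v <- strsplit(s, "")[[1]]
      i <- sample(length(v), 25)
      v[i] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 25, TRUE)
      paste(v, collapse = "")
    })
    extra <- function(k, seed0) {
      if (k <= 0) return(character(0))
      vapply(seq_len(k), function(i) rand_aa(110, seed = seed0 + i),
             character(1))
    }
    set_a <- setNames(c(base, extra(n_a - length(base), 10 * rep)),
                      paste0("a", seq_len(n_a)))
    set_b <- setNames(c(vapply(seq_along(base), function(i)
      mut(base[i], rep * 7 + i), character(1)),
      extra(n_b - length(base), 20 * rep)),
      paste0("b", seq_len(n_b)))
    got <- reciprocal_best_hits(set_a, set_b, th)
    want <- oracle_rbh(set_a, set_b, th)
    expect_identical(got$query, want$query)
    expect_identical(got$subject, want$subject)
  }
})

test_that("RBH handles identical sets, competition and empty input", {
  set_a <- setNames(vapply(1:5, function(i) rand_aa(80, seed = i),
                           character(1)), paste0("g", 1:5))
  rb <- reciprocal_best_hits(set_a, set_a)
  expect_identical(nrow(rb), 5L)
  expect_identical(rb$query, rb$subject)
  ## two identical queries compete for one target: exactly one pair,
  ## lexicographically smaller id wins the tie
  dup <- c(a1 = set_a[[1]], a2 = set_a[[1]])
  rb2 <- reciprocal_best_hits(dup, set_a["g1"])
  expect_identical(nrow(rb2), 1L)
  expect_identical(rb2$query, "a1")
  expect_identical(nrow(reciprocal_best_hits(character(0), set_a)), 0L)
})

test_that("raising thresholds never increases the ortholog count", {
  pop <- shared_pop()
  islands <- unlist(lapply(pop$genomes, extract_islands), recursive = FALSE)
  same_type <- pop$truth$genomes$genome_id[
    pop$truth$genomes$type_id == pop$truth$genomes$type_id[1]]
  isl <- islands[vapply(islands, function(x)
    x$genome_id %in% same_type[1:2], logical(1))]
  skip_if(length(isl) < 2)
  ns <- vapply(seq(0.3, 0.95, by = 0.1), function(id_th) {
    nrow(reciprocal_best_hits(isl[[1]]$proteins, isl[[2]]$proteins,
                              obc_thresholds(min_identity = id_th)))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
  nc <- vapply(c(0.5, 0.7, 0.9, 0.99), function(cv) {
    nrow(reciprocal_best_hits(isl[[1]]$proteins, isl[[2]]$proteins,
                              obc_thresholds(min_coverage = cv)))
  }, numeric(1))
  expect_true(all(diff(nc) <= 0))
})

test_that("the 13 allowed class combinations are exactly honoured", {
  allowed <- c("AA", "AB", "BA", "AC", "CA", "AD", "DA", "BC", "CB",
               "BD", "DB", "CC", "DD")
  for (x in c("A", "B", "C", "D")) {
    for (y in c("A", "B", "C", "D")) {
      expect_identical(allowed_combination(x, y),
                       paste0(x, y) %in% allowed,
                       info = paste0(x, y))
    }
  }
  expect_error(allowed_combination("A", "E"), class = "obc_class_error")
})

test_that("shared fraction uses the smaller island as denominator", {
  base <- vapply(1:20, function(i) rand_aa(120, seed = 300 + i), character(1))
  small <- fake_island("s", setNames(base[1:10], paste0("s", 1:10)))
  ## large island shares 9 of the small one's genes
  big <- fake_island("b", setNames(c(base[1:9], vapply(1:11, function(i)
    rand_aa(120, seed = 400 + i), character(1))), paste0("b", 1:20)))
  sf <- shared_gene_fraction(small, big)
  expect_identical(sf$shared_fraction, 0.9)
  ## identical islands share everything
  self <- shared_gene_fraction(small, fake_island("s2", small$proteins))
  expect_identical(self$shared_fraction, 1)
  ## disallowed combination reports allowed = FALSE, no fraction
  dis <- shared_gene_fraction(fake_island("x", small$proteins, class = "B"),
                              fake_island("y", big$proteins, class = "B"))
  expect_false(dis$allowed)
  expect_true(is.na(dis$shared_fraction))
})

test_that("compare_islands agrees across engines and is symmetric", {
  pop <- shared_pop()
  islands <- unlist(lapply(pop$genomes, extract_islands), recursive = FALSE)
  islands <- islands[1:6]
  names(islands) <- vapply(islands, `[[`, character(1), "island_id")
  sw <- compare_islands(islands, engine = "biostrings")
  expect_true(all(sw$pairs$shared_fraction >= 0 & sw$pairs$shared_fraction <= 1))
  skip_if(!obctools:::has_blast(), "blast not on PATH")
  bl <- compare_islands(islands, engine = "blast")
  m <- merge(sw$pairs, bl$pairs, by = c("obc_a", "obc_b"))
  expect_identical(m$n_orth.x, m$n_orth.y)
})

test_that("genomovar-level divergence keeps within-species AAI above 99", {
  cfg <- sim_config(n_species = 2, genomes_per_species = 2,
                    n_island_types = 2, within_species_div = 0.005,
                    frag_probs = c(A = 1, B = 0, C = 0, D = 0),
                    p_hgt = 0, seed = 55)
  pop <- simulate_population(cfg)
  an <- run_obc_analysis(pop$genomes, dnds = FALSE)
  aai <- an$aai
  expect_gt(aai["sp01_g01", "sp01_g02"], 99)
  expect_gt(aai["sp02_g01", "sp02_g02"], 99)
  expect_lt(aai["sp01_g01", "sp02_g01"], 95)
})

test_that("genome AAI is 100 for self, symmetric, and separates species", {
  pop <- shared_pop()
  an <- shared_analysis()
  aai <- an$aai
  expect_true(all(diag(aai) == 100))
  expect_lt(max(abs(aai - t(aai)), na.rm = TRUE), 1e-9)
  sp <- setNames(pop$truth$genomes$species, pop$truth$genomes$genome_id)
  same <- outer(sp[rownames(aai)], sp[colnames(aai)], "==")
  ut <- upper.tri(aai)
  expect_gt(min(aai[ut & same], na.rm = TRUE), 98)
  expect_lt(max(aai[ut & !same], na.rm = TRUE), 95)
})
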