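#' Locus vs genome distance and the recent-HGT flag
#'
#' Distances are `100 - AAI` (%) for the genome (backbone orthologs) and the
#' locus (island orthologs). A pair is flagged as a recent horizontal
#' transfer when the genome distance is at least twice the locus distance
#' (the locus moved more recently than the genomes diverged); identical
#' genomes (`d_g = 0`) are never flagged.
#'
#' @param aai_genome,aai_locus AAI values in (0, 100], vectorised.
#' @return Tibble: `d_g`, `d_l`, `recent_hgt`.
#' @export
distance_pair <- function(aai_genome, aai_locus) {
  if (any(aai_genome <= 0 | aai_genome > 100, na.rm = TRUE) ||
      any(aai_locus <= 0 | aai_locus > 100, na.rm = TRUE)) {
    abort("AAI values must lie in (0, 100]", class = "obc_evodist_error")
  }
  d_g <- 100 - aai_genome
  d_l <- 100 - aai_locus
  tibble(d_g = d_g, d_l = d_l,
         recent_hgt = d_g >= 2 * d_l & d_g > 0)
}

## --- NG86 site and pathway tables ------------------------------------------
## Built once per session; cached in the package namespace environment.
.obc_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.obc_cache$blosum62)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    .obc_cache$blosum62 <- get("BLOSUM62", envir = e)
  }
  .obc_cache$blosum62
}

ng86_tables <- function() {
  if (!is.null(.obc_cache$ng86)) return(.obc_cache$ng86)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  is_stop <- code == "*"
  ## synonymous site count per sense codon: per position, fraction of
  ## non-stop single-base changes that are synonymous (renormalised so each
  ## position contributes one site; N + S = 3 per codon)
  syn_sites <- rep(NA_real_, 64)
  names(syn_sites) <- codons
  for (c1 in codons[!is_stop]) {
    s <- 0
    for (p in 1:3) {
      alts <- single_base_variants(c1, p)
      alts <- alts[!(code[alts] == "*")]
      if (!length(alts)) next
      s <- s + mean(code[alts] == code[[c1]])
    }
    syn_sites[c1] <- s
  }
  ## pathway-averaged observed differences per ordered codon pair
  Nd <- Sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  for (i in seq_len(64)) {
    if (is_stop[i]) next
    for (j in seq_len(64)) {
      if (is_stop[j]) next
      d <- pathway_diff_counts(codons[i], codons[j], code)
      Nd[i, j] <- d[1]
      Sd[i, j] <- d[2]
    }
  }
  .obc_cache$ng86 <- list(codons = codons, syn_sites = syn_sites,
                          Nd = Nd, Sd = Sd)
  .obc_cache$ng86
}

single_base_variants <- function(codon, pos) {
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  vapply(DNA_BASES[DNA_BASES != b[pos]], function(nb) {
    v <- b
    v[pos] <- nb
    paste(v, collapse = "")
  }, character(1))
}

## Average (nonsynonymous, synonymous) differences between two sense codons
## over all shortest mutational pathways, excluding pathways that traverse a
## stop codon; c(NA, NA) when every pathway is excluded.
pathway_diff_counts <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  b1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  diff_pos <- which(b1 != b2)
  d <- length(diff_pos)
  if (d == 0L) return(c(0, 0))
  perms <- permutations_of(diff_pos)
  nd_tot <- sd_tot <- 0
  n_valid <- 0L
  for (ord in perms) {
    cur <- b1
    nd <- sd <- 0L
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b2[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (code[[to]] == "*") { ok <- FALSE; break }
      if (code[[from]] == code[[to]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) {
      nd_tot <- nd_tot + nd
      sd_tot <- sd_tot + sd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(NA_real_, NA_real_))
  c(nd_tot / n_valid, sd_tot / n_valid)
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Nei-Gojobori (1986) dN/dS for an aligned CDS pair
#'
#' Counts synonymous and nonsynonymous sites per codon with fractional sites
#' averaged over the two sequences; observed differences in multi-difference
#' codons are averaged over all shortest mutational pathways with equal
#' weight, excluding pathways through stop codons (codon pairs with no valid
#' pathway, or involving a terminal stop codon, contribute nothing).
#' Proportions are Jukes-Cantor corrected: `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param cds_a,cds_b Gap-free, equal-length, in-frame CDS strings.
#' @return One-row tibble: `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`,
#'   `ratio` (`dN/dS`; `NA` when `dS` is 0 or a correction is undefined),
#'   `n_codons` (codons contributing), `n_skipped`.
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    abort("sequences must have equal length", class = "obc_evodist_error")
  }
  if (nchar(cds_a) %% 3 != 0) {
    abort("length must be divisible by 3", class = "obc_evodist_error")
  }
  tab <- ng86_tables()
  ca <- codon_split(cds_a)
  cb <- codon_split(cds_b)
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  if (anyNA(ia) || anyNA(ib)) {
    abort("non-ACGT codons are not supported", class = "obc_evodist_error")
  }
  sa <- tab$syn_sites[ia]
  sb <- tab$syn_sites[ib]
  nd <- tab$Nd[cbind(ia, ib)]
  sd_ <- tab$Sd[cbind(ia, ib)]
  ok <- !is.na(sa) & !is.na(sb) & !is.na(nd)   # drops stops and dead ends
  n_codons <- sum(ok)
  S <- sum((sa[ok] + sb[ok]) / 2)
  N <- 3 * n_codons - S
  Nd_ <- sum(nd[ok])
  Sd2 <- sum(sd_[ok])
  pN <- if (N > 0) Nd_ / N else NA_real_
  pS <- if (S > 0) Sd2 / S else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN)
  dS <- jc(pS)
  ratio <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_
  tibble(N = N, S = S, Nd = Nd_, Sd = Sd2, pN = pN, pS = pS,
         dN = dN, dS = dS, ratio = ratio, n_codons = n_codons,
         n_skipped = sum(!ok))
}

#' Back-thread a protein alignment onto the codon sequences
#'
#' Globally aligns the two translations (BLOSUM62, gaps 11/1), drops gapped
#' columns, and returns the corresponding in-frame, equal-length codon
#' sequences ready for [ng86_dnds()]. Terminal stop codons are excluded.
#'
#' @param cds_a,cds_b CDS strings (multiples of 3).
#' @return List with elements `a` and `b`.
#' @export
codon_align_pair <- function(cds_a, cds_b) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  al <- Biostrings::pairwiseAlignment(pa, pb, type = "global",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1)
  sa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- sa != "-" & sb != "-"
  pos_a <- cumsum(sa != "-")[keep]
  pos_b <- cumsum(sb != "-")[keep]
  cod_a <- codon_split(cds_a)
  cod_b <- codon_split(cds_b)
  list(a = paste(cod_a[pos_a], collapse = ""),
       b = paste(cod_b[pos_b], collapse = ""))
}

#' Pooled dN/dS for island vs backbone gene sets per genome pair
#'
#' For each genome pair, ortholog CDS pairs are codon-aligned and their NG86
#' site/difference counts pooled within each compartment (`obc` island genes
#' vs `backbone`, the genome with the island excluded), giving one dN/dS per
#' pair and compartment. A paired t-test contrasts the island against the
#' backbone across genome pairs.
#'
#' @param ortholog_cds Tibble with `genome_a`, `genome_b`, `compartment`
#'   (`"obc"` or `"backbone"`), `cds_a`, `cds_b` (one row per ortholog pair).
#' @param align Whether to back-thread protein alignments first (FALSE when
#'   the inputs are already aligned and equal length).
#' @return List: `per_pair` (genome_a, genome_b, dnds_obc, dnds_backbone),
#'   `means`, and `test` (paired `htest`, or NULL with < 2 complete pairs).
#' @export
aggregate_dnds <- function(ortholog_cds, align = TRUE) {
  stopifnot(all(c("genome_a", "genome_b", "compartment", "cds_a", "cds_b")
                %in% names(ortholog_cds)))
  pooled <- ortholog_cds |>
    group_by(.data$genome_a, .data$genome_b, .data$compartment) |>
    summarise(res = list(pooled_ng86(.data$cds_a, .data$cds_b, align)),
              .groups = "drop")
  pooled <- bind_rows(lapply(seq_len(nrow(pooled)), function(i)
    mutate(pooled$res[[i]], genome_a = pooled$genome_a[i],
           genome_b = pooled$genome_b[i],
           compartment = pooled$compartment[i])))
  wide <- pooled |>
    select("genome_a", "genome_b", "compartment", "ratio") |>
    tidyr_pivot(names_prefix = "dnds_")
  means <- c(obc = mean(wide$dnds_obc, na.rm = TRUE),
             backbone = mean(wide$dnds_backbone, na.rm = TRUE))
  complete <- !is.na(wide$dnds_obc) & !is.na(wide$dnds_backbone)
  test <- if (sum(complete) >= 2L) {
    t.test(wide$dnds_obc[complete], wide$dnds_backbone[complete],
           paired = TRUE)
  }
  list(per_pair = wide, means = means, test = test)
}

## minimal wide pivot to avoid a tidyr dependency for one call
tidyr_pivot <- function(x, names_prefix) {
  key <- unique(x[, c("genome_a", "genome_b")])
  for (cp in unique(x$compartment)) {
    sub <- x[x$compartment == cp, c("genome_a", "genome_b", "ratio")]
    names(sub)[3] <- paste0(names_prefix, cp)
    key <- left_join(key, sub, by = c("genome_a", "genome_b"))
  }
  for (cp in c("obc", "backbone")) {
    col <- paste0(names_prefix, cp)
    if (!col %in% names(key)) key[[col]] <- NA_real_
  }
  key
}

## Pool NG86 counts over a set of ortholog CDS pairs -> one dN/dS.
pooled_ng86 <- function(cds_a, cds_b, align = TRUE) {
  tot <- c(N = 0, S = 0, Nd = 0, Sd = 0)
  for (i in seq_along(cds_a)) {
    pair <- if (align) codon_align_pair(cds_a[i], cds_b[i]) else
      list(a = cds_a[i], b = cds_b[i])
    if (!nchar(pair$a)) next
    r <- ng86_dnds(pair$a, pair$b)
    tot <- tot + c(r$N, r$S, r$Nd, r$Sd)
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  pN <- if (tot["N"] > 0) tot[["Nd"]] / tot[["N"]] else NA_real_
  pS <- if (tot["S"] > 0) tot[["Sd"]] / tot[["S"]] else NA_real_
  dN <- jc(pN)
  dS <- jc(pS)
  tibble(N = tot[["N"]], S = tot[["S"]], Nd = tot[["Nd"]], Sd = tot[["Sd"]],
         dN = dN, dS = dS,
         ratio = if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_)
}

#' Average-linkage cladogram from an AAI matrix
#'
#' Rows of the AAI matrix are treated as points; pairwise Euclidean distances
#' between rows are clustered by average linkage (UPGMA), the convention used
#' for AAI-based genome cladograms.
#'
#' @param aai Square symmetric AAI matrix with genome ids as dimnames and no
#'   missing values.
#' @return List: `hclust`, `phylo` (ape), `newick` (string with heights).
#' @export
aai_cladogram <- function(aai) {
  if (anyNA(aai)) abort("AAI matrix has missing entries; impute or drop first",
                        class = "obc_evodist_error")
  d <- stats::dist(aai, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy))
}

#' OLS regression of locus distance on genome distance
#'
#' @param pairs Tibble with `d_g` and `d_l` (>= 3 rows).
#' @return List: `slope`, `intercept`, `r_squared`, `model` (`lm`). With zero
#'   variance in `d_g` the slope is `NA`.
#' @export
regression_locus_vs_genome <- function(pairs) {
  stopifnot(nrow(pairs) >= 3L)
  if (sd(pairs$d_g) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, model = NULL))
  }
  m <- lm(d_l ~ d_g, data = pairs)
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       r_squared = summary(m)$r.squared, model = m)
}
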