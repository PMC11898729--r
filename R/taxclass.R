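#' Global nucleotide alignment
#'
#' Needleman-Wunsch with match +1, mismatch -1, gap open -2, gap extend -1
#' (configurable); deterministic tie-breaking from the alignment engine.
#'
#' @param a,b Nucleotide strings (ACGT and IUPAC ambiguity codes).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return List with aligned strings `a` and `b` (equal length, `-` gaps).
#' @export
align_nt <- function(a, b, match = 1, mismatch = -1, gap_open = -2,
                     gap_ext = -1) {
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", a) || !grepl("^[ACGTRYSWKMBDHVN]+$", b)) {
    abort("invalid nucleotide characters", class = "obc_align_error")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = abs(gap_open) - abs(gap_ext),
                                      gapExtension = abs(gap_ext))
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)))
}

#' Jukes-Cantor distance between two sequences
#'
#' `d = -(3/4) log(1 - 4p/3)` where `p` is the mismatch proportion over
#' aligned columns in which both sequences have an unambiguous base; gap and
#' ambiguous columns are excluded. Saturated pairs (`p >= 0.75`) return `NA`.
#'
#' @param a,b Nucleotide strings.
#' @param aligned If TRUE the inputs are already aligned (equal length);
#'   otherwise [align_nt()] is applied first.
#' @return Distance in substitutions/site (`NA` when saturated).
#' @export
jc_distance <- function(a, b, aligned = FALSE) {
  if (!aligned) {
    al <- align_nt(a, b)
    a <- al$a
    b <- al$b
  }
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- va %in% DNA_BASES & vb %in% DNA_BASES
  if (!any(ok)) return(NA_real_)
  p <- mean(va[ok] != vb[ok])
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Saitou-Nei neighbor joining (via ape); any negative branch length is
#' clamped to zero and its magnitude moved to the sister branch, preserving
#' path lengths through the parent node.
#'
#' @param d A square symmetric distance matrix (>= 3 taxa) or `dist`.
#' @return An `ape::phylo` (unrooted).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) abort("need at least 3 taxa", class = "obc_tax_error")
  phy <- ape::nj(as.dist(d))
  neg <- which(phy$edge.length < 0)
  for (i in neg) {
    parent <- phy$edge[i, 1]
    sisters <- which(phy$edge[, 1] == parent)
    sisters <- setdiff(sisters, i)
    excess <- -phy$edge.length[i]
    phy$edge.length[i] <- 0
    if (length(sisters)) {
      phy$edge.length[sisters[1]] <- phy$edge.length[sisters[1]] + excess
    }
  }
  phy
}

#' Stack sequences onto a common reference frame
#'
#' Pairwise-aligns every sequence to the longest one and projects it onto the
#' reference coordinates (insertions relative to the reference are dropped),
#' yielding a rectangular character matrix suitable for column bootstrap.
#' ITS/23S sequences within an order are near-globally alignable, which is
#' the regime this stacking assumes.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @return Character matrix (rows = sequences, columns = reference columns).
#' @export
stack_alignment <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  L <- nchar(ref)
  m <- matrix("-", length(seqs), L, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    if (i == ref_i) {
      m[i, ] <- strsplit(ref, "")[[1]]
      next
    }
    al <- align_nt(ref, seqs[[i]])
    va <- strsplit(al$a, "")[[1]]
    vb <- strsplit(al$b, "")[[1]]
    keep <- va != "-"
    m[i, cumsum(keep)[keep]] <- vb[keep]
  }
  m
}

#' Bootstrap support for NJ splits
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' neighbor-joining tree from Jukes-Cantor distances each time, and reports
#' the frequency (%) with which each internal split of the original tree is
#' recovered. Deterministic given `seed`.
#'
#' @param aln Character matrix from [stack_alignment()] (or any rectangular
#'   alignment, rows = taxa).
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return List: `tree` (the original NJ tree), `support` (per internal node,
#'   in `[0, 100]`, in `ape::prop.clades` order).
#' @export
bootstrap_support <- function(aln, B = 1000L, seed = 1L) {
  if (B < 1) abort("B must be >= 1", class = "obc_tax_error")
  d0 <- jc_matrix(aln)
  tr0 <- nj_tree(d0)
  trees <- withr::with_seed(seed, lapply(seq_len(B), function(b) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    db <- jc_matrix(aln[, cols, drop = FALSE])
    nj_tree(db)
  }))
  counts <- ape::prop.clades(tr0, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = tr0, support = 100 * counts / B)
}

## Pairwise JC distances over the rows of an alignment matrix; saturated or
## empty-overlap pairs fall back to the maximum observable distance.
jc_matrix <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      va <- aln[i, ]
      vb <- aln[j, ]
      ok <- va %in% DNA_BASES & vb %in% DNA_BASES
      p <- if (any(ok)) mean(va[ok] != vb[ok]) else 0.749
      if (p >= 0.75) p <- 0.749
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' Nearest-reference classification of an ITS or 23S sequence
#'
#' Computes the Jukes-Cantor distance from the query to every reference panel
#' entry of the matching marker and returns the closest label. The call is
#' confident only when the margin over the runner-up label is at least
#' `margin` and the best distance is at most `max_dist`; otherwise the label
#' is `"Unclassified"`.
#'
#' @param query Nucleotide string.
#' @param panel Tibble with `label`, `marker`, `seq`.
#' @param marker `"ITS"` or `"23S"`.
#' @param margin Minimum distance margin between the best and the runner-up
#'   label (substitutions/site).
#' @param max_dist Maximum acceptable best distance.
#' @return One-row tibble: `label`, `best_label`, `best_dist`,
#'   `runner_up_label`, `runner_up_dist`, `confident`.
#' @export
classify <- function(query, panel, marker = c("ITS", "23S"), margin = 0.01,
                     max_dist = 0.10) {
  marker <- match.arg(marker)
  p <- panel[panel$marker == marker, , drop = FALSE]
  if (!nrow(p)) abort("empty reference panel", class = "obc_tax_error")
  d <- vapply(p$seq, function(s) jc_distance(query, s), numeric(1))
  d[is.na(d)] <- Inf
  ## best distance per label (panels may hold several entries per label)
  lab_d <- tapply(d, p$label, min)
  ord <- order(lab_d, names(lab_d))
  best <- names(lab_d)[ord[1]]
  best_d <- lab_d[[ord[1]]]
  run <- if (length(lab_d) > 1L) names(lab_d)[ord[2]] else NA_character_
  run_d <- if (length(lab_d) > 1L) lab_d[[ord[2]]] else Inf
  confident <- is.finite(best_d) && best_d <= max_dist &&
    (run_d - best_d) >= margin
  tibble(label = if (confident) best else "Unclassified",
         best_label = best, best_dist = best_d,
         runner_up_label = run, runner_up_dist = run_d,
         confident = confident)
}

#' Classify read islands into genomospecies and tabulate per sample
#'
#' Classifies each read island by its companion ITS (when present) or 23S
#' sequence and returns both the per-read calls and a per-sample by
#' per-genomospecies count matrix of typed OBC reads.
#'
#' @param read_islands List from [extract_read_islands()].
#' @param panel Reference panel tibble (`label`, `marker`, `seq`).
#' @param sample_of Optional named character vector mapping read ids to sample
#'   names (defaults to a single sample).
#' @param margin,max_dist Passed to [classify()].
#' @return List: `calls` (tibble read_id, marker used, label, ...),
#'   `counts` (samples x labels matrix).
#' @export
classify_reads <- function(read_islands, panel, sample_of = NULL,
                           margin = 0.01, max_dist = 0.10) {
  calls <- bind_rows(lapply(read_islands, function(isl) {
    has_its <- !is.null(isl$its_seq) && any(panel$marker == "ITS")
    marker <- if (has_its) "ITS" else "23S"
    q <- if (has_its) isl$its_seq else isl$r23s_seq
    if (is.null(q)) return(NULL)
    res <- classify(q, panel, marker, margin, max_dist)
    mutate(res, read_id = isl$read_id, marker = marker, .before = 1)
  }))
  samples <- if (is.null(sample_of)) setNames(rep("sample1", nrow(calls)),
                                              calls$read_id) else sample_of
  calls$sample <- unname(samples[calls$read_id])
  counts <- table(calls$sample, calls$label)
  list(calls = calls, counts = unclass(as.matrix(counts)))
}
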