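## Independent brute-force oracles, kept deliberately naive and separate from
## the package's own implementations.

## RBH oracle: enumerate every (x, y), check the mutual-best condition by
## direct comparison against all competitors, then apply the thresholds.
oracle_rbh <- function(set_a, set_b, th = obc_thresholds(), hits = NULL) {
  if (is.null(hits)) hits <- obctools:::align_protein_sets(set_a, set_b)
  an <- names(set_a)
  bn <- names(set_b)
  mk <- function(col) {
    m <- matrix(NA_real_, length(an), length(bn), dimnames = list(an, bn))
    m[cbind(hits$query_id, hits$subject_id)] <- hits[[col]]
    m
  }
  score <- mk("score")
  ident <- mk("identity")
  cq <- mk("cov_q")
  cs <- mk("cov_s")
  pairs <- list()
  for (x in an) {
    for (y in bn) {
      if (is.na(score[x, y])) next
      best_for_x <- TRUE
      for (y2 in setdiff(bn, y)) {
        if (!is.na(score[x, y2]) &&
            (score[x, y2] > score[x, y] ||
               (score[x, y2] == score[x, y] && y2 < y))) {
          best_for_x <- FALSE
          break
        }
      }
      if (!best_for_x) next
      best_for_y <- TRUE
      for (x2 in setdiff(an, x)) {
        if (!is.na(score[x2, y]) &&
            (score[x2, y] > score[x, y] ||
               (score[x2, y] == score[x, y] && x2 < x))) {
          best_for_y <- FALSE
          break
        }
      }
      if (!best_for_y) next
      if (ident[x, y] >= th$min_identity && cq[x, y] >= th$min_coverage &&
          cs[x, y] >= th$min_coverage) {
        pairs[[length(pairs) + 1L]] <- c(x, y)
      }
    }
  }
  if (!length(pairs)) return(data.frame(query = character(),
                                        subject = character()))
  out <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(out) <- c("query", "subject")
  out[order(out$query), , drop = FALSE]
}

## NG86 oracle: pathway enumeration written iteratively over explicit
## position orderings (expand.grid of orders), with its own codon utilities.
oracle_ng86_pair <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  dpos <- which(s1 != s2)
  if (!length(dpos)) return(c(Nd = 0, Sd = 0))
  orders <- if (length(dpos) == 1L) matrix(dpos, 1) else {
    perms <- expand.grid(rep(list(dpos), length(dpos)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) ==
                           length(dpos)), , drop = FALSE]
    as.matrix(perms)
  }
  nds <- sds <- c()
  for (r in seq_len(nrow(orders))) {
    cur <- s1
    nd <- sd <- 0
    dead <- FALSE
    for (p in orders[r, ]) {
      prev <- paste(cur, collapse = "")
      cur[p] <- s2[p]
      nxt <- paste(cur, collapse = "")
      if (nxt %in% stops) { dead <- TRUE; break }
      if (code[[prev]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    if (!dead) {
      nds <- c(nds, nd)
      sds <- c(sds, sd)
    }
  }
  if (!length(nds)) return(c(Nd = NA_real_, Sd = NA_real_))
  c(Nd = mean(nds), Sd = mean(sds))
}

## Oracle for synonymous site counts of one codon.
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  if (code[[codon]] == "*") return(NA_real_)
  s <- 0
  b <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    cnt_syn <- 0
    cnt_ok <- 0
    for (nb in setdiff(c("A", "C", "G", "T"), b[p])) {
      v <- b
      v[p] <- nb
      alt <- paste(v, collapse = "")
      if (code[[alt]] == "*") next
      cnt_ok <- cnt_ok + 1
      if (code[[alt]] == code[[codon]]) cnt_syn <- cnt_syn + 1
    }
    if (cnt_ok > 0) s <- s + cnt_syn / cnt_ok
  }
  s
}
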