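# Independent brute-force oracles used to verify the package implementations.
# These deliberately share no code with the package: character-vector string
# handling, exhaustive enumeration, literal textbook formulas.

# Exhaustive isomiR classifier: enumerates every (annotation, 5' offset)
# anchor and every templated-span/tail decomposition, then applies the
# variant-class precedence rule.  Returns NULL when no anchor qualifies.
oracle_classify <- function(seq, ref, seed_len = 16, max_mismatch = 1,
                            max_shift = 5) {
  ma <- matureAnnotations(ref)
  hps <- as.character(hairpins(ref))
  L <- nchar(seq)
  if (L < seed_len) return(NULL)
  sv <- strsplit(seq, "")[[1]]
  cands <- list()
  for (i in seq_len(nrow(ma))) {
    hp <- strsplit(hps[[which(names(hps) == ma$hairpin_id[i])]], "")[[1]]
    for (d5 in -max_shift:max_shift) {
      pos <- ma$start[i] + d5
      if (pos < 0 || pos + seed_len > length(hp)) next
      mm_seed <- sum(sv[1:seed_len] != hp[(pos + 1):(pos + seed_len)])
      if (mm_seed > max_mismatch) next
      spans <- 0L
      for (span in seq_len(min(L, length(hp) - pos))) {
        mm <- sum(sv[1:span] != hp[(pos + 1):(pos + span)])
        if (mm <= max_mismatch && sv[span] == hp[pos + span])
          spans <- c(spans, span)
      }
      span <- max(spans)
      cands[[length(cands) + 1L]] <- list(
        mirna_id = ma$mirna_id[i], d5 = d5, mm = mm_seed, span = span,
        d3 = pos + span - ma$end[i],
        tail = if (span < L) paste(sv[(span + 1):L], collapse = "") else "")
    }
  }
  if (!length(cands)) return(NULL)
  ord <- order(vapply(cands, `[[`, numeric(1), "mm"),
               abs(vapply(cands, `[[`, numeric(1), "d5")),
               vapply(cands, `[[`, character(1), "mirna_id"))
  b <- cands[[ord[1]]]
  cls <- if (b$d5 != 0) {
    "fiveprime_mod"
  } else if (nzchar(b$tail)) {
    u <- unique(strsplit(b$tail, "")[[1]])
    if (length(u) == 1 && u %in% c("A", "U", "G", "C"))
      paste0("NTA-", u) else "NTA-other"
  } else if (b$d3 < 0) "trimming" else if (b$d3 > 0) "elongation"
  else "mature"
  list(mirna_id = b$mirna_id, d5 = b$d5, d3 = b$d3, tail = b$tail,
       class = cls)
}

# Literal Benjamini-Hochberg step-up: adj(i) = min(1, min_{j>=i} n p(j)/j)
# on the sorted p-values, mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Rank-statistic (Mann-Whitney) AUC: pairwise probability that a case
# outranks a control, ties counting one half.
oracle_mw_auc <- function(probs, labels) {
  p1 <- probs[labels == 1]
  p0 <- probs[labels == 0]
  tot <- 0
  for (a in p1) tot <- tot + sum(a > p0) + 0.5 * sum(a == p0)
  tot / (length(p1) * length(p0))
}
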