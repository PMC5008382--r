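#' Seed-alignment policy for anchoring reads to hairpins
#'
#' Reads are anchored by their 5' seed: the first `seed_len` nucleotides
#' must match the hairpin with at most `max_mismatch` mismatches at a start
#' position within `max_5p_shift` of an annotated mature start.  Seed
#' anchoring (rather than full-length alignment) prevents strongly modified
#' molecules — isomiRs with non-templated 3' ends — from failing to map.
#'
#' @param seed_len Seed length in nucleotides (`>= 10`, default 16).
#' @param max_mismatch Mismatches allowed in the seed and in the templated
#'   span (`0` or `1`, default 1).
#' @param max_5p_shift Maximum distance of the read start from an annotated
#'   mature start (default 5).
#' @return A list of class `AlignPolicy`.
#' @export
alignPolicy <- function(seed_len = 16L, max_mismatch = 1L, max_5p_shift = 5L) {
  seed_len <- as.integer(seed_len)
  max_mismatch <- as.integer(max_mismatch)
  max_5p_shift <- as.integer(max_5p_shift)
  stopifnot(seed_len >= 10L, max_mismatch %in% c(0L, 1L), max_5p_shift >= 0L)
  structure(list(seed_len = seed_len, max_mismatch = max_mismatch,
                 max_5p_shift = max_5p_shift),
            class = "AlignPolicy")
}

# number of mismatching positions between two equal-length strings
.mm <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# hairpin strings + annotation rows in a convenient precomputed form
.refIndex <- function(ref) {
  hp <- hairpins(ref)
  list(seq = stats::setNames(as.character(hp), names(hp)),
       len = stats::setNames(Biostrings::width(hp), names(hp)),
       ma = matureAnnotations(ref))
}

#' Anchor one read to a hairpin near an annotated mature start
#'
#' Scans candidate start positions within `max_5p_shift` of every annotated
#' mature start; a hit requires the read's first `seed_len` nucleotides to
#' match the hairpin with at most `max_mismatch` mismatches.  Among hits the
#' one minimizing `(mismatches, |d5|)` is returned, ties broken by
#' lexicographic `mirna_id`.
#'
#' @param seq RNA read sequence (character).
#' @param ref A [ReferenceSet-class].
#' @param policy An [alignPolicy()].
#' @return A list `(hairpin_id, pos, mismatches, mirna_id, d5)` or `NULL`
#'   when no position qualifies (including reads shorter than the seed).
#' @export
alignRead <- function(seq, ref, policy = alignPolicy()) {
  idx <- if (inherits(ref, "ReferenceSet")) .refIndex(ref) else ref
  .alignReadIdx(seq, idx, policy)
}

.alignReadIdx <- function(seq, idx, policy) {
  L <- nchar(seq)
  if (L < policy$seed_len) return(NULL)
  seed <- charToRaw(substr(seq, 1L, policy$seed_len))
  best <- NULL
  ma <- idx$ma
  for (i in seq_len(nrow(ma))) {
    hp_id <- ma$hairpin_id[i]
    hp <- idx$seq[[hp_id]]
    hlen <- idx$len[[hp_id]]
    st <- ma$start[i]
    for (pos in (st - policy$max_5p_shift):(st + policy$max_5p_shift)) {
      if (pos < 0L || pos + policy$seed_len > hlen) next
      win <- charToRaw(substr(hp, pos + 1L, pos + policy$seed_len))
      mm <- sum(seed != win)
      if (mm > policy$max_mismatch) next
      cand <- list(hairpin_id = hp_id, pos = pos, mismatches = mm,
                   mirna_id = ma$mirna_id[i], d5 = pos - st)
      if (is.null(best) ||
          mm < best$mismatches ||
          (mm == best$mismatches && abs(cand$d5) < abs(best$d5)) ||
          (mm == best$mismatches && abs(cand$d5) == abs(best$d5) &&
           cand$mirna_id < best$mirna_id))
        best <- cand
    }
  }
  best
}

#' Classify an anchored read into the isomiR taxonomy
#'
#' Walks the read against the hairpin from the hit position.  The templated
#' span is the maximal read prefix matching the hairpin with at most
#' `max_mismatch` internal mismatches, never ending on a mismatch; the
#' remaining suffix is the non-templated addition (NTA) tail.  5' and 3'
#' offsets are taken against the assigned mature annotation and the variant
#' class follows the precedence: 5' modification, then NTA (by tail
#' nucleotide), then 3' trimming / templated elongation, else mature.
#'
#' The template-first rule means 3' additions that match the hairpin
#' continuation are classified as (templated) elongation, not NTA; only
#' suffix bases failing template comparison form the NTA tail, and
#' mismatches are never attributed to the tail itself — a tail mismatch *is*
#' the NTA signal.
#'
#' @param seq RNA read sequence.
#' @param hit A hit from [alignRead()].
#' @param ref A [ReferenceSet-class].
#' @param policy The [alignPolicy()] used for the mismatch budget.
#' @return A one-row `data.frame` with columns `sequence, mirna_id, d5, d3,
#'   nta_tail, variant_class, length` (and identity
#'   `length = canonical length - d5 + d3 + nchar(nta_tail)`).
#' @examples
#' ref <- makeToyReference()
#' hit <- alignRead("UAGCUUAUCAGACUGAUGUU", ref)
#' classifyRead("UAGCUUAUCAGACUGAUGUU", hit, ref)  # 3' trimming, d3 = -2
#' @export
classifyRead <- function(seq, hit, ref, policy = alignPolicy()) {
  idx <- if (inherits(ref, "ReferenceSet")) .refIndex(ref) else ref
  .classifyReadIdx(seq, hit, idx, policy)
}

.classifyReadIdx <- function(seq, hit, idx, policy) {
  ma <- idx$ma
  i <- match(hit$mirna_id, ma$mirna_id)
  hp <- idx$seq[[hit$hairpin_id]]
  hlen <- idx$len[[hit$hairpin_id]]
  L <- nchar(seq)
  max_t <- min(L, hlen - hit$pos)
  span <- 0L
  if (max_t > 0L) {
    s <- charToRaw(substr(seq, 1L, max_t))
    h <- charToRaw(substr(hp, hit$pos + 1L, hit$pos + max_t))
    is_match <- s == h
    mm_upto <- cumsum(!is_match)
    ok <- which(is_match & mm_upto <= policy$max_mismatch)
    if (length(ok)) span <- max(ok)
  }
  tail <- substr(seq, span + 1L, L)
  d5 <- hit$pos - ma$start[i]
  d3 <- (hit$pos + span) - ma$end[i]
  class <- if (d5 != 0L) {
    "fiveprime_mod"
  } else if (nzchar(tail)) {
    bases <- unique(strsplit(tail, "")[[1]])
    if (length(bases) == 1L && bases %in% c("A", "U", "G", "C"))
      paste0("NTA-", bases) else "NTA-other"
  } else if (d3 < 0L) "trimming" else if (d3 > 0L) "elongation" else "mature"
  data.frame(sequence = seq, mirna_id = hit$mirna_id,
             d5 = as.integer(d5), d3 = as.integer(d3), nta_tail = tail,
             variant_class = class, length = as.integer(L),
             stringsAsFactors = FALSE)
}

#' Call isomiRs for every unique read of a sample
#'
#' Aligns and classifies each unique read, carrying its collapsed count.
#' Unaligned reads are tallied in the `"unaligned"` attribute (total read
#' count failing to anchor).  Output order is deterministic:
#' `(mirna_id, d5, d3, nta_tail, sequence)`.
#'
#' @param urs A [UniqueReadSet-class].
#' @param ref A [ReferenceSet-class].
#' @param policy An [alignPolicy()].
#' @return `data.frame` of isomiR calls with columns `sequence, mirna_id,
#'   d5, d3, nta_tail, variant_class, length, count`, attribute `unaligned`.
#' @export
callSample <- function(urs, ref, policy = alignPolicy()) {
  idx <- .refIndex(ref)
  cnt <- readCounts(urs)
  calls <- vector("list", length(cnt))
  unaligned <- 0L
  for (k in seq_along(cnt)) {
    sq <- names(cnt)[k]
    hit <- .alignReadIdx(sq, idx, policy)
    if (is.null(hit)) {
      unaligned <- unaligned + cnt[[k]]
      next
    }
    cl <- .classifyReadIdx(sq, hit, idx, policy)
    cl$count <- as.integer(cnt[[k]])
    calls[[k]] <- cl
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  out <- if (length(calls)) {
    df <- do.call(rbind, calls)
    df[order(df$mirna_id, df$d5, df$d3, df$nta_tail, df$sequence), ,
       drop = FALSE]
  } else {
    data.frame(sequence = character(), mirna_id = character(),
               d5 = integer(), d3 = integer(), nta_tail = character(),
               variant_class = character(), length = integer(),
               count = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "unaligned") <- unaligned
  out
}
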