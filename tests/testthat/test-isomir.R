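test_that("seed alignment anchors reads at and near the mature start", {
  ref <- mini_ref()
  h <- alignRead("UAGCUUAUCAGACUGAUGUUGA", ref)
  expect_identical(h$pos, 4L)
  expect_identical(h$mismatches, 0L)

  # one nucleotide shaved off the 5' end anchors one position downstream
  h <- alignRead("AGCUUAUCAGACUGAUGUUGA", ref)
  expect_identical(h$pos, 5L)
  ob <- oracle_classify("AGCUUAUCAGACUGAUGUUGA", ref)
  expect_identical(as.integer(ob$d5), 1L)

  expect_null(alignRead("CCCCCCCCCCCCCCCC", ref))
  expect_null(alignRead("UAGCUUAUCAG", ref))  # shorter than the seed
})

test_that("classification reproduces the published panel isomiR calls", {
  ref <- toy_ref()
  cases <- list(
    # 2-nt 3' truncation of miR-21-5p
    list(seq = "UAGCUUAUCAGACUGAUGUU", mirna = "miR-21-5p",
         d5 = 0L, d3 = -2L, tail = "", class = "trimming", len = 20L),
    # 23-nt miR-204-5p variant: +1 templated elongation
    list(seq = "UUCCCUUUGUCAUCCUAUGCCUG", mirna = "miR-204-5p",
         d5 = 0L, d3 = 1L, tail = "", class = "elongation", len = 23L),
    # 1-nt 3' truncation of miR-375
    list(seq = "UUUGUUCGUUCGGCUCGCGUG", mirna = "miR-375",
         d5 = 0L, d3 = -1L, tail = "", class = "trimming", len = 21L),
    # templated +1 continuation of the mir-21-like hairpin (GGGG follows)
    list(seq = "UAGCUUAUCAGACUGAUGUUGAG", mirna = "miR-21-5p",
         d5 = 0L, d3 = 1L, tail = "", class = "elongation", len = 23L),
    # U appended where the template continues with G -> NTA-U
    list(seq = "UAGCUUAUCAGACUGAUGUUGAU", mirna = "miR-21-5p",
         d5 = 0L, d3 = 0L, tail = "U", class = "NTA-U", len = 23L))
  for (cs in cases) {
    hit <- alignRead(cs$seq, ref)
    call <- classifyRead(cs$seq, hit, ref)
    expect_identical(call$mirna_id, cs$mirna)
    expect_identical(call$d5, cs$d5)
    expect_identical(call$d3, cs$d3)
    expect_identical(call$nta_tail, cs$tail)
    expect_identical(call$variant_class, cs$class)
    expect_identical(call$length, cs$len)
  }
})

test_that("classification agrees with the exhaustive oracle on enumerated reads", {
  ref <- toy_ref()
  ma <- matureAnnotations(ref)
  hps <- as.character(hairpins(ref))
  checked <- 0L
  for (i in 1:3) {
    hp <- hps[[ma$hairpin_id[i]]]
    for (L in seq(15L, 28L, by = 3L)) {
      for (s0 in 0:(nchar(hp) - L)) {
        base <- substr(hp, s0 + 1L, s0 + L)
        for (sq in c(base, paste0(base, "U"), paste0(base, "A"))) {
          hit <- alignRead(sq, ref)
          ob <- oracle_classify(sq, ref)
          if (is.null(ob)) {
            expect_null(hit)
            next
          }
          call <- classifyRead(sq, hit, ref)
          expect_identical(call$mirna_id, ob$mirna_id)
          expect_identical(call$d5, as.integer(ob$d5))
          expect_identical(call$d3, as.integer(ob$d3))
          expect_identical(call$nta_tail, ob$tail)
          expect_identical(call$variant_class, ob$class)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 50L)
})

test_that("the length identity holds and canonical reads are mature", {
  ref <- toy_ref(8L)
  ma <- matureAnnotations(ref)
  set.seed(3)
  for (i in seq_len(nrow(ma))) {
    canon <- canonicalSequence(ref, ma$mirna_id[i])
    call <- classifyRead(canon, alignRead(canon, ref), ref)
    expect_identical(call$variant_class, "mature")
    expect_identical(call$d5, 0L)
    expect_identical(call$d3, 0L)
    expect_identical(call$nta_tail, "")
    # random perturbations still satisfy the length identity
    for (rep in 1:5) {
      sq <- substr(canon, 1 + sample(0:2, 1), nchar(canon) - sample(0:3, 1))
      if (sample(c(TRUE, FALSE), 1))
        sq <- paste0(sq, paste(sample(c("A", "U", "G", "C"),
                                      sample(1:2, 1), replace = TRUE),
                               collapse = ""))
      hit <- alignRead(sq, ref)
      if (is.null(hit)) next
      call <- classifyRead(sq, hit, ref)
      canon_len <- ma$end[match(call$mirna_id, ma$mirna_id)] -
        ma$start[match(call$mirna_id, ma$mirna_id)]
      expect_identical(call$length,
                       canon_len - call$d5 + call$d3 + nchar(call$nta_tail))
    }
  }
})

test_that("callSample preserves counts, tallies unaligned reads, and is deterministic", {
  ref <- toy_ref()
  seqs <- c("UAGCUUAUCAGACUGAUGUU", "UUCCCUUUGUCAUCCUAUGCCUG",
            "UUUGUUCGUUCGGCUCGCGUG")
  urs <- collapseReads(rep(seqs, c(5L, 3L, 2L)))
  calls <- callSample(urs, ref)
  expect_identical(nrow(calls), 3L)
  expect_identical(sum(calls$count), 10L)
  expect_identical(attr(calls, "unaligned"), 0L)
  expect_identical(callSample(urs, ref), calls)

  junk <- collapseReads(rep("CCCCCCCCCCCCCCCCCC", 4L))
  empty <- callSample(junk, ref)
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "unaligned"), 4L)
})
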