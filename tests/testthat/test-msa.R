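test_that("identical sequences align gap-free and rows round-trip", {
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         seq = rep("ACDEFGHIKLMNPQRSTVWY", 3))
  msa <- progressive_align(recs, scheme = test_scheme)
  expect_false(any(grepl("-", msa$aseq)))
  expect_equal(msa$aseq, recs$seq)
  # a single sequence is a trivial MSA
  one <- progressive_align(recs[1, ], scheme = test_scheme)
  expect_equal(one$aseq, recs$seq[1])
})

test_that("ungapping any row of an MSA returns its input sequence", {
  withr::with_seed(91, {
    base <- random_peptide(60)
    recs <- tibble::tibble(
      id = sprintf("r%d", 1:5),
      seq = c(base,
              mutate_seq(base, 0.2),
              paste0(substr(base, 1, 30), "WWWWWWWW", substr(base, 31, 60)),
              mutate_seq(base, 0.4),
              substr(base, 5, 60))
    )
    msa <- progressive_align(recs, scheme = test_scheme)
    expect_equal(gsub("-", "", msa$aseq), recs$seq)
    expect_equal(length(unique(nchar(msa$aseq))), 1L)
  })
})

test_that("the progressive result beats each pairwise-seeded alternative", {
  withr::with_seed(92, {
    base <- random_peptide(40)
    recs <- tibble::tibble(
      id = c("x", "y", "z"),
      seq = c(base, mutate_seq(base, 0.1), mutate_seq(base, 0.8))
    )
    ours <- sum_of_pairs(progressive_align(recs, scheme = test_scheme),
                         test_scheme)
    # alternatives: force each of the three possible join orders
    alts <- purrr::map_dbl(list(c("x", "y", "z"), c("x", "z", "y"),
                                c("y", "z", "x")), function(ord) {
      guide <- ape::read.tree(
        text = sprintf("((%s:1,%s:1)N1:1,%s:1)root;", ord[1], ord[2], ord[3])
      )
      sum_of_pairs(progressive_align(recs, guide = guide,
                                     scheme = test_scheme), test_scheme)
    })
    expect_true(all(ours >= alts))
  })
})

test_that("a guide tree with mismatched tips is rejected", {
  recs <- tibble::tibble(id = c("a", "b"), seq = c("ACDEF", "ACDEF"))
  guide <- ape::read.tree(text = "(a:1,zz:1)root;")
  expect_error(progressive_align(recs, guide = guide, scheme = test_scheme),
               "match record ids")
})

test_that("gap-free alignments yield no insertion calls and bad clades error", {
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         seq = rep("ACDEFGHIKLMNPQRSTVWY", 3))
  msa <- progressive_align(recs, scheme = test_scheme)
  expect_equal(nrow(call_insertions(msa, "a")), 0)
  expect_error(call_insertions(msa, c("a", "b", "c")), "no outgroup")
  expect_error(call_insertions(msa, character(0)), "empty")
  expect_error(call_insertions(msa, "nope"), "not all present")
})

test_that("planted clade inserts are called with correct span and bounds hold", {
  withr::with_seed(93, {
    base <- random_peptide(80)
    ins <- random_peptide(15)
    with_ins <- paste0(substr(base, 1, 40), ins, substr(base, 41, 80))
    recs <- tibble::tibble(
      id = c("c1", "c2", "c3", "o1", "o2"),
      seq = c(mutate_seq(with_ins, 0.05), mutate_seq(with_ins, 0.05),
              mutate_seq(with_ins, 0.05), mutate_seq(base, 0.05),
              mutate_seq(base, 0.05))
    )
    msa <- progressive_align(recs, scheme = test_scheme)
    calls <- call_insertions(msa, c("c1", "c2", "c3"))
    expect_equal(nrow(calls), 1)
    expect_lte(abs(calls$length - 15), 2)
    expect_lte(abs(calls$col_start - 40), 2)
    # the configured bounds are recheckable from the MSA
    chars <- msa_char_matrix(msa)
    rownames(chars) <- msa$id
    span <- (calls$col_start + 1):calls$col_end
    occ_c <- colMeans(chars[c("c1", "c2", "c3"), span, drop = FALSE] != "-")
    occ_o <- colMeans(chars[c("o1", "o2"), span, drop = FALSE] != "-")
    expect_true(all(occ_c >= 0.9))
    expect_true(all(occ_o <= 0.1))
    # calls are invariant under row reordering and id renaming
    msa2 <- msa[rev(seq_len(nrow(msa))), ]
    calls2 <- call_insertions(msa2, c("c1", "c2", "c3"))
    expect_equal(calls2$col_start, calls$col_start)
    msa3 <- msa
    msa3$id <- paste0("X", msa3$id)
    calls3 <- call_insertions(msa3, paste0("X", c("c1", "c2", "c3")))
    expect_equal(calls3$col_start, calls$col_start)
  })
})

test_that("insertion location is reported relative to motifs", {
  # reference row with known ungapped motif at [10, 20); insert at column 25
  ref <- paste0(paste(rep("A", 30), collapse = ""))
  ins_rows <- paste0(substr(ref, 1, 25), "WWWWWWWWWW", substr(ref, 26, 30))
  msa <- structure(
    tibble::tibble(
      id = c("ref", "c1", "c2"),
      aseq = c(paste0(substr(ref, 1, 25), "----------", substr(ref, 26, 30)),
               ins_rows, ins_rows)
    ),
    class = c("protein_msa", "tbl_df", "tbl", "data.frame")
  )
  call <- tibble::tibble(col_start = 25L, col_end = 35L)
  ann <- tibble::tibble(motif = "HhH-GPD", ref_id = "ref",
                        start = 10L, end = 20L)
  loc <- locate_insertion(call, ann, msa)
  expect_equal(loc$relation, "downstream-of")
  expect_equal(loc$offset, 5L)
  expect_equal(loc$label, "downstream-of HhH-GPD, offset 5")
  # upstream case
  ann_up <- tibble::tibble(motif = "nudix", ref_id = "ref",
                           start = 28L, end = 30L)
  loc_up <- locate_insertion(call, ann_up, msa)
  expect_equal(loc_up$relation, "upstream-of")
  expect_equal(loc_up$offset, 3L)
  # within case
  ann_in <- tibble::tibble(motif = "adenine-recognition-site", ref_id = "ref",
                           start = 20L, end = 30L)
  loc_in <- locate_insertion(call, ann_in, msa)
  expect_equal(loc_in$relation, "within")
  expect_equal(loc_in$offset, 0L)
  expect_error(
    locate_insertion(call, dplyr::mutate(ann, ref_id = "gone"), msa),
    "not in MSA"
  )
})
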