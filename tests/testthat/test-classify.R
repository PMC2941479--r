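# constructed evidence helpers -------------------------------------------

fake_homology <- function(pid, e) {
  tibble::tibble(
    query_id = "q", subject_id = pid, score = 500, e_value = e,
    q_start = 0L, q_end = 100L, s_start = 0L, s_end = 100L,
    q_aln = "", s_aln = ""
  )
}

fake_domains <- function(pid, models, spec = "specific", e = 1e-30) {
  tibble::tibble(
    protein_id = pid, model = models, start = 0L, end = 100L,
    score = seq(200, 100, length.out = length(models)),
    e_value = rep_len(e, length(models)),
    specificity = rep_len(spec, length(models))
  )
}

fake_reciprocal <- function(pid, ok = TRUE) {
  tibble::tibble(ok = ok, best_family = NA_character_,
                 best_id = NA_character_, best_score = 1, e_value = 1e-40,
                 reason = NA_character_, protein_id = pid)
}

test_that("a candidate passing homology, both domains and reciprocity is present", {
  call <- classify_candidate(
    fake_homology("p1", 1e-30),
    fake_domains("p1", c("Endo3c", "DNAglycosylase_C")),
    fake_reciprocal("p1"),
    species = "S01", family = "MutY"
  )
  expect_equal(call$verdict, "present")
  expect_equal(call$protein_id, "p1")
  expect_true(is.na(call$rejection_reason))
})

test_that("a missing required domain rejects the candidate", {
  call <- classify_candidate(
    fake_homology("p1", 1e-30),
    fake_domains("p1", "Endo3c"), # no DNAglycosylase_C
    fake_reciprocal("p1"),
    species = "S01", family = "MutY"
  )
  expect_equal(call$verdict, "rejected")
  expect_equal(call$rejection_reason, "missing-required-domain")
})

test_that("a best hit to the similar Nth model forces rejection", {
  dh <- dplyr::bind_rows(
    fake_domains("p1", "Endo3c", spec = "similar-only"),
    fake_domains("p1", "Nth") |> dplyr::mutate(score = 400)
  )
  call <- classify_candidate(
    fake_homology("p1", 1e-30), dh, fake_reciprocal("p1"),
    species = "S01", family = "MutY"
  )
  expect_equal(call$verdict, "rejected")
  expect_equal(call$rejection_reason, "similar-domain-best-hit")
})

test_that("a failed reciprocal check rejects the candidate", {
  call <- classify_candidate(
    fake_homology("p1", 1e-30),
    fake_domains("p1", c("Endo3c", "DNAglycosylase_C")),
    fake_reciprocal("p1", ok = FALSE),
    species = "S01", family = "MutY"
  )
  expect_equal(call$verdict, "rejected")
  expect_equal(call$rejection_reason, "failed-reciprocal")
})

test_that("boundary E-values are excluded by strict inequality", {
  # homology at exactly 1e-20
  call <- classify_candidate(
    fake_homology("p1", 1e-20),
    fake_domains("p1", c("Endo3c", "DNAglycosylase_C")),
    fake_reciprocal("p1"),
    species = "S01", family = "MutY"
  )
  expect_equal(call$verdict, "rejected")
  expect_equal(call$rejection_reason, "no-significant-homology")
  # domain at exactly 1e-5
  call2 <- classify_candidate(
    fake_homology("p1", 1e-30),
    fake_domains("p1", c("Endo3c", "DNAglycosylase_C"), e = 1e-5),
    fake_reciprocal("p1"),
    species = "S01", family = "MutY"
  )
  expect_equal(call2$verdict, "rejected")
  expect_equal(call2$rejection_reason, "missing-required-domain")
  # just below both boundaries: present
  call3 <- classify_candidate(
    fake_homology("p1", 0.99e-20),
    fake_domains("p1", c("Endo3c", "DNAglycosylase_C"), e = 0.99e-5),
    fake_reciprocal("p1"),
    species = "S01", family = "MutY"
  )
  expect_equal(call3$verdict, "present")
})

test_that("conflicting passing candidates resolve to the lowest E-value", {
  hh <- dplyr::bind_rows(fake_homology("pA", 1e-40), fake_homology("pB", 1e-30))
  dh <- dplyr::bind_rows(
    fake_domains("pA", c("Endo3c", "DNAglycosylase_C")),
    fake_domains("pB", c("Endo3c", "DNAglycosylase_C"))
  )
  rc <- dplyr::bind_rows(fake_reciprocal("pA"), fake_reciprocal("pB"))
  call <- classify_candidate(hh, dh, rc, species = "S01", family = "MutY")
  expect_equal(call$verdict, "present")
  expect_equal(call$protein_id, "pA")
  expect_equal(call$conflict, 1L)
})

test_that("relaxing thresholds never turns a present call absent", {
  hh <- fake_homology("p1", 1e-25)
  dh <- fake_domains("p1", c("Endo3c", "DNAglycosylase_C"), e = 1e-8)
  rc <- fake_reciprocal("p1")
  strict <- classify_candidate(hh, dh, rc, "S01", "MutY")
  relaxed <- classify_candidate(hh, dh, rc, "S01", "MutY",
                                homology_threshold = 1e-10,
                                domain_threshold = 1e-3)
  expect_equal(strict$verdict, "present")
  expect_equal(relaxed$verdict, "present")
})

test_that("recorded evidence replays to the same verdict", {
  hh <- fake_homology("p1", 1e-25)
  dh <- fake_domains("p1", c("Endo3c", "DNAglycosylase_C"))
  rc <- fake_reciprocal("p1")
  call <- classify_candidate(hh, dh, rc, "S01", "MutY")
  ev <- call$evidence[[1]]
  replay <- classify_candidate(ev$homology, ev$domains, ev$reciprocal,
                               "S01", "MutY")
  expect_equal(replay$verdict, call$verdict)
  expect_equal(replay$protein_id, call$protein_id)
})

test_that("matrix assembly handles empty calls and duplicate presents", {
  empty_calls <- classify_candidate(
    empty_hits(), empty_domain_hits(),
    fake_reciprocal(character(0))[0, ], "S01", "MutY"
  )
  m <- build_matrix(empty_calls, species_order = c("S01", "S02", "S03"))
  expect_equal(dim(m), c(3L, 5L))
  expect_false(any(m$MutY | m$MutM | m$MutT))
  dup <- dplyr::bind_rows(
    tibble::tibble(species = "S01", family = "MutY", protein_id = "a",
                   verdict = "present", rejection_reason = NA, e_value = 1e-30,
                   conflict = 0L, evidence = list(NULL)),
    tibble::tibble(species = "S01", family = "MutY", protein_id = "b",
                   verdict = "present", rejection_reason = NA, e_value = 1e-25,
                   conflict = 0L, evidence = list(NULL))
  )
  expect_error(build_matrix(dup), "duplicate present")
})

test_that("per-group union can cover all families while each row is patchy", {
  calls <- dplyr::bind_rows(purrr::pmap(
    tibble::tibble(
      species = c("M1", "M1", "M2", "M2", "M3", "M3"),
      family = c("MutY", "MutM", "MutM", "MutT", "MutY", "MutT")
    ),
    function(species, family) {
      tibble::tibble(species = species, family = family, protein_id = "x",
                     verdict = "present", rejection_reason = NA_character_,
                     e_value = 1e-30, conflict = 0L, evidence = list(NULL))
    }
  ))
  m <- build_matrix(calls, species_order = c("M1", "M2", "M3"),
                    groups = c(M1 = "molluscs", M2 = "molluscs",
                               M3 = "molluscs"))
  per_row_complete <- m$MutY & m$MutM & m$MutT
  expect_false(any(per_row_complete))
  expect_true(any(m$MutY) && any(m$MutM) && any(m$MutT))
})

test_that("TSV rendering round-trips and carries asterisk annotations", {
  calls <- tibble::tibble(
    species = "S01", family = "MutM", protein_id = "p",
    verdict = "present", rejection_reason = NA_character_,
    e_value = 1e-30, conflict = 0L, evidence = list(NULL)
  )
  m <- build_matrix(calls, species_order = c("S01", "S02"))
  tsv <- render_matrix(m, "tsv")
  back <- parse_matrix_tsv(tsv)
  expect_equal(back$species, m$species)
  for (f in c("MutY", "MutM", "MutT")) expect_equal(back[[f]], m[[f]])
  ann <- tibble::tibble(species = "S01", family = "MutM", mark = "*")
  tsv2 <- render_matrix(m, "tsv", annotations = ann)
  expect_match(tsv2, "1\\*")
  back2 <- parse_matrix_tsv(tsv2)
  expect_equal(back2$MutM, m$MutM)
  # single present cell renders filled in text mode
  m1 <- build_matrix(calls, species_order = "S01", families = "MutM")
  expect_match(render_matrix(m1, "text"), "■")
  expect_error(render_matrix(m, "nope"), "arg")
})
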