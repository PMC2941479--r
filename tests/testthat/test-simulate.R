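test_that("simulated trees satisfy the basic structural contracts", {
  tr2 <- simulate_species_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)
  # seed determinism: byte-identical Newick
  a <- ape::write.tree(simulate_species_tree(16, seed = 7))
  b <- ape::write.tree(simulate_species_tree(16, seed = 7))
  expect_identical(a, b)
  # binary tree identity: leaves + internal nodes = 2n - 1
  tr6 <- simulate_species_tree(6, seed = 3)
  expect_equal(length(tr6$tip.label) + tr6$Nnode, 2 * 6 - 1)
  expect_true(all(tr6$edge.length >= 0))
  expect_error(simulate_species_tree(1, seed = 1), ">= 2")
})

test_that("zero branch lengths leave every leaf equal to the root", {
  tr <- simulate_species_tree(6, seed = 3)
  tr$edge.length <- rep(0, length(tr$edge.length))
  withr::with_seed(1, {
    root <- random_protein(100)
    ev <- evolve_family(tr, "MutM", root, evolution_scenario())
    expect_true(all(ev$records$seq == root))
    expect_true(all(ev$presence$present))
  })
})

test_that("losses propagate to exactly the descendant leaves", {
  tr <- simulate_species_tree(10, seed = 4)
  below <- clade_leaves(tr)
  scen <- evolution_scenario(
    losses = tibble::tibble(family = c("MutT", "MutT"),
                            branch = c("N3", "S01"))
  )
  withr::with_seed(2, {
    ev <- evolve_family(tr, "MutT", random_protein(150), scen)
  })
  expected <- propagate_losses(tr, c("N3", "S01"))
  got <- setNames(ev$presence$present, ev$presence$species)
  expect_equal(got[names(expected)], expected)
  expect_false(any(ev$records$species %in% below[["N3"]]))
})

test_that("planted insertions appear in the whole clade and nowhere else", {
  tr <- simulate_species_tree(8, seed = 6)
  below <- clade_leaves(tr)
  internal <- setdiff(tr$node.label, "root")
  br <- internal[which.max(vapply(internal, function(b)
    length(below[[b]]) <= 4, logical(1)))]
  scen <- evolution_scenario(
    insertions = tibble::tibble(family = "MutM", branch = br,
                                length = 15L, position = 40L)
  )
  withr::with_seed(3, {
    root <- random_protein(120)
    ev <- evolve_family(tr, "MutM", root, scen)
  })
  in_clade <- ev$records$species %in% below[[br]]
  expect_true(all(nchar(ev$records$seq[in_clade]) == 135))
  expect_true(all(nchar(ev$records$seq[!in_clade]) == 120))
  expect_equal(sort(ev$insertion_truth$clade[[1]]), sort(below[[br]]))
})

test_that("scenario validation catches bad branches and positions", {
  tr <- simulate_species_tree(6, seed = 3)
  withr::with_seed(4, {
    root <- random_protein(100)
    expect_error(
      evolve_family(tr, "MutY", root, evolution_scenario(
        losses = tibble::tibble(family = "MutY", branch = "NOPE")
      )),
      "unknown branch"
    )
    expect_error(
      evolve_family(tr, "MutY", root, evolution_scenario(
        insertions = tibble::tibble(family = "MutY", branch = "N1",
                                    length = 10L, position = 500L)
      )),
      "outside"
    )
  })
})

test_that("decoy and genome bookkeeping matches the scenario", {
  tr <- simulate_species_tree(8, seed = 9)
  withr::with_seed(5, {
    root <- random_protein(300)
    recs <- evolve_family(tr, "MutY", root, evolution_scenario())$records
    nth_root <- random_protein(225)
    # two decoys per species on 8 species -> 16 decoy records
    dt <- emit_decoys_and_truncations(tr, recs, nth_root,
                                      evolution_scenario(n_decoys = 2,
                                                         trunc_fraction = 0))
    expect_equal(nrow(dt$decoys), 16)
    expect_equal(nrow(dt$genomes), 0) # no truncation, no genomes needed
    expect_true(all(nchar(dt$records$seq) == 300))
  })
})

test_that("truncated records are terminal clips and genomes hold the full ORF", {
  tr <- simulate_species_tree(8, seed = 9)
  withr::with_seed(6, {
    root <- random_protein(300)
    recs <- evolve_family(tr, "MutY", root, evolution_scenario())$records
    full <- setNames(recs$seq, recs$id)
    dt <- emit_decoys_and_truncations(
      tr, recs, random_protein(225),
      evolution_scenario(n_decoys = 0, trunc_fraction = 0.25,
                         trunc_range = c(30L, 30L))
    )
    expect_equal(nrow(dt$truncated), 2) # 25% of 8
    for (i in seq_len(nrow(dt$truncated))) {
      id <- dt$truncated$id[i]
      trunc_seq <- dt$records$seq[dt$records$id == id]
      expect_equal(nchar(trunc_seq), 270)
      if (dt$truncated$side[i] == "C") {
        expect_equal(trunc_seq, substr(full[[id]], 1, 270))
      } else {
        expect_equal(trunc_seq, substr(full[[id]], 31, 300))
      }
      # the genome carries the complete coding sequence: some reading frame
      # translates to the full protein
      g <- dt$genomes$dna[dt$genomes$protein_id == id]
      frames <- translate_six_frames(g)
      expect_true(any(vapply(frames$protein, function(p)
        grepl(full[[id]], p, fixed = TRUE), logical(1))))
    }
  })
})

test_that("truncations longer than the protein are an error", {
  tr <- simulate_species_tree(4, seed = 2)
  withr::with_seed(7, {
    recs <- evolve_family(tr, "MutT", random_protein(20),
                          evolution_scenario())$records
    expect_error(
      emit_decoys_and_truncations(
        tr, recs, random_protein(225),
        evolution_scenario(n_decoys = 0, trunc_fraction = 1,
                           trunc_range = c(25L, 30L))
      ),
      "longer than the protein"
    )
  })
})

test_that("pairwise identity decays with path length", {
  # single lineage at increasing divergence, averaged over seeds
  bg <- aa_background()
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  ts <- c(0, 0.1, 0.3, 0.6, 1.2)
  means <- vapply(ts, function(t) {
    mean(vapply(1:20, function(s) {
      withr::with_seed(1000 + s, {
        root <- random_protein(200)
        ident(root, mutate_seq(root, t, bg))
      })
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_equal(means[1], 1)
})

test_that("dataset truth presence equals independently propagated losses", {
  sim <- fixture("sim8", simulate_oxog_dataset(8, seed = 5))
  for (fam in c("MutY", "MutM", "MutT")) {
    expected <- propagate_losses(
      sim$tree, sim$truth$losses$branch[sim$truth$losses$family == fam]
    )
    got <- sim$truth$presence
    got <- setNames(got$present[got$family == fam],
                    got$species[got$family == fam])
    expect_equal(got[names(expected)], expected)
  }
  # sampled losses are Dollo-identifiable by construction: per family no
  # nested or sibling loss branches
  expect_equal(nrow(sim$truth$losses),
               nrow(dplyr::distinct(sim$truth$losses)))
})

test_that("simulated datasets are reproducible from their seed", {
  s1 <- simulate_oxog_dataset(6, seed = 11)
  s2 <- simulate_oxog_dataset(6, seed = 11)
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$truth$losses, s2$truth$losses)
})
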