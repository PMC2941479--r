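# Architecture constants for the three 8-oxo-G repair families and the
# Nth-like decoy. Domain blocks are sized to typical CDD footprints: Endo3c
# (HhH-GPD catalytic core, shared superfamily with Nth), DNAglycosylase_C
# (MutY 8-oxo-G recognition domain), OGG_N, and MTH1 (nudix hydrolase core).
domain_lengths <- c(
  Endo3c = 130L, DNAglycosylase_C = 110L, OGG_N = 120L, MTH1 = 130L,
  NthC = 80L
)
linker_len <- 15L
mutt_flank <- 20L

#' Required domain models per gene family
#'
#' MutY requires Endo3c plus DNAglycosylase_C, MutM requires OGG_N plus
#' Endo3c, MutT requires MTH1 only.
#'
#' @return Named list of character vectors.
#' @export
required_domains <- function() {
  list(
    MutY = c("Endo3c", "DNAglycosylase_C"),
    MutM = c("OGG_N", "Endo3c"),
    MutT = "MTH1"
  )
}

# Superfamily relatives: Endo3c and Nth share the HhH glycosylase fold, so a
# candidate region can be explained by either; the scan must decide which is
# specific.
similar_models <- function() {
  list(Endo3c = "Nth", Nth = "Endo3c")
}

# Motif annotations in ungapped coordinates of each family's root (query)
# sequence, 0-based half-open. HhH-GPD sits inside the Endo3c block; the
# adenine recognition site inside DNAglycosylase_C; the nudix motif inside
# MTH1.
oxog_motifs <- function() {
  e <- domain_lengths[["Endo3c"]]
  o <- domain_lengths[["OGG_N"]]
  tibble(
    family = c("MutY", "MutY", "MutM", "MutT"),
    motif = c("HhH-GPD", "adenine-recognition-site", "HhH-GPD", "nudix"),
    start = c(60L, e + linker_len + 10L, o + linker_len + 60L,
              mutt_flank + 20L),
    end = c(85L, e + linker_len + 40L, o + linker_len + 85L,
            mutt_flank + 43L)
  )
}

# i.i.d. per-site substitution: along a branch of length t (expected
# substitutions/site) each site is replaced with probability 1 - exp(-t),
# the replacement drawn from the background (so a small fraction of draws
# restore the original residue). No indels outside planted insertions.
mutate_seq <- function(seq, t, bg = aa_background()) {
  if (t <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < (1 - exp(-t))
  if (any(hit)) {
    chars[hit] <- sample(names(bg), sum(hit), replace = TRUE, prob = bg)
  }
  paste(chars, collapse = "")
}

#' Simulate a random rooted species tree
#'
#' Draws a random rooted binary topology, assigns exponential branch lengths
#' and rescales them so the deepest root-to-leaf path equals `depth`
#' (expected substitutions/site). Leaves are named `S01, S02, ...` and
#' internal nodes `root, N1, N2, ...`. Output is fully determined by `seed`.
#'
#' @param n_leaves Number of species (>= 2).
#' @param seed RNG seed.
#' @param depth Maximum root-to-leaf path length (default 0.25).
#' @return An `ape::phylo` tree with node labels.
#' @export
simulate_species_tree <- function(n_leaves, seed, depth = 0.25) {
  if (n_leaves < 2) abort("n_leaves must be >= 2")
  withr::with_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = TRUE,
                     tip.label = sprintf("S%02d", seq_len(n_leaves)),
                     br = stats::rexp)
    dmax <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / dmax
    tr$node.label <- c("root", paste0("N", seq_len(tr$Nnode - 1)))
    tr
  })
}

# Name of every node (tips then internals), indexed as in tree$edge.
node_names <- function(tree) c(tree$tip.label, tree$node.label)

# Leaves under each node, as a named list over node names.
clade_leaves <- function(tree) {
  n_tip <- length(tree$tip.label)
  nn <- node_names(tree)
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  setNames(below, nn)
}

#' Construct an evolution scenario
#'
#' @param losses Tibble with columns `family`, `branch` (child-node name of
#'   the branch on which the family is lost).
#' @param insertions Tibble with columns `family`, `branch`, `length`,
#'   `position` (0-based insertion point in root coordinates).
#' @param n_decoys Nth-like decoy paralogues per species.
#' @param trunc_fraction Fraction of true gene records with a truncated
#'   terminus.
#' @param trunc_range Length range (residues) of terminal truncations.
#' @return An object of class `evolution_scenario`.
#' @export
evolution_scenario <- function(losses = NULL, insertions = NULL,
                               n_decoys = 2, trunc_fraction = 0.2,
                               trunc_range = c(10L, 40L)) {
  if (is.null(losses)) {
    losses <- tibble(family = character(), branch = character())
  }
  if (is.null(insertions)) {
    insertions <- tibble(family = character(), branch = character(),
                         length = integer(), position = integer())
  }
  structure(
    list(losses = losses, insertions = insertions, n_decoys = n_decoys,
         trunc_fraction = trunc_fraction, trunc_range = trunc_range),
    class = "evolution_scenario"
  )
}

# Two clades of one tree overlap iff one contains the other (or they are
# equal); used to keep planted losses of a family non-nested.
clades_overlap <- function(below, a, b) {
  if (a %in% names(below) && b %in% names(below)) {
    length(intersect(below[[a]], below[[b]])) > 0
  } else {
    a == b
  }
}

#' Sample a Dollo-identifiable evolution scenario
#'
#' Plants `n_losses` (family, branch) loss events such that, per family, no
#' two loss branches are nested or siblings and the family survives in at
#' least one leaf — this makes every planted loss recoverable by Dollo
#' parsimony. Insertions are then placed on internal branches (2 to half the
#' leaves) of clades where the family is fully present. Default insertions:
#' a 15-residue MutM insert 10 residues downstream of the HhH-GPD motif and
#' a 20-residue MutY insert inside the adenine recognition site, matching
#' the insert sizes reported for ascomycete subgroups.
#'
#' @param tree Species tree from [simulate_species_tree()].
#' @param n_losses Number of loss events (default 5).
#' @param families Families to draw losses from.
#' @param insertion_families Families receiving one planted insertion each
#'   (default `c("MutM", "MutY")`, lengths 15 and 20).
#' @param n_decoys,trunc_fraction,trunc_range Passed to
#'   [evolution_scenario()].
#' @return An `evolution_scenario`.
#' @export
sample_scenario <- function(tree, n_losses = 5,
                            families = c("MutY", "MutM", "MutT"),
                            insertion_families = c("MutM", "MutY"),
                            n_decoys = 2, trunc_fraction = 0.2,
                            trunc_range = c(10L, 40L)) {
  below <- clade_leaves(tree)
  nn <- node_names(tree)
  branches <- setdiff(nn, "root")
  n_tip <- length(tree$tip.label)
  parent_of <- function(child) {
    idx <- match(child, nn)
    nn[tree$edge[tree$edge[, 2] == idx, 1]]
  }
  siblings <- function(child) {
    p <- parent_of(child)
    kids <- nn[tree$edge[tree$edge[, 1] == match(p, nn), 2]]
    setdiff(kids, child)
  }
  motifs <- oxog_motifs()
  ins_len <- c(MutY = 20L, MutM = 15L, MutT = 10L)
  ins_pos <- c(
    MutY = motifs$start[motifs$family == "MutY" &
                          motifs$motif == "adenine-recognition-site"] + 5L,
    MutM = motifs$end[motifs$family == "MutM"] + 10L,
    MutT = motifs$end[motifs$family == "MutT"] + 15L
  )
  sample_losses <- function() {
    losses <- tibble(family = character(), branch = character())
    guard <- 0
    while (nrow(losses) < n_losses && guard < 1000) {
      guard <- guard + 1
      fam <- sample(families, 1)
      br <- branches[sample.int(length(branches), 1)]
      same <- losses$branch[losses$family == fam]
      if (any(vapply(same, function(s) clades_overlap(below, br, s),
                     logical(1)))) next
      if (any(siblings(br) %in% same)) next
      lost_leaves <- unique(unlist(below[c(same, br)]))
      if (length(lost_leaves) >= n_tip) next
      losses <- bind_rows(losses, tibble(family = fam, branch = br))
    }
    if (nrow(losses) < n_losses) return(NULL)
    losses
  }
  sample_insertions <- function(losses) {
    insertions <- tibble(family = character(), branch = character(),
                         length = integer(), position = integer())
    for (fam in insertion_families) {
      lost <- unique(unlist(below[losses$branch[losses$family == fam]]))
      cand <- setdiff(nn[(n_tip + 1):length(nn)], "root")
      cand <- cand[vapply(cand, function(b) {
        lv <- below[[b]]
        length(lv) >= 2 && length(lv) <= max(2, floor(n_tip / 2)) &&
          !any(lv %in% lost)
      }, logical(1))]
      if (length(cand) == 0) return(NULL)
      insertions <- bind_rows(insertions, tibble(
        family = fam, branch = cand[sample.int(length(cand), 1)],
        length = ins_len[[fam]], position = ins_pos[[fam]]
      ))
    }
    insertions
  }
  # losses and insertions are sampled jointly: a loss draw that leaves no
  # fully present clade for a planted insertion is rejected and redrawn
  for (try in 1:100) {
    losses <- sample_losses()
    if (is.null(losses)) next
    insertions <- sample_insertions(losses)
    if (!is.null(insertions)) {
      return(evolution_scenario(losses, insertions, n_decoys,
                                trunc_fraction, trunc_range))
    }
  }
  abort("could not sample an identifiable scenario for this tree")
}

#' Evolve one gene family along a species tree
#'
#' Sequences accumulate i.i.d. per-site substitutions proportional to branch
#' length. A loss event on a branch removes the family from every leaf below
#' it; an insertion event splices a random segment into the ancestral
#' sequence on that branch, so it is inherited by the whole clade below (and
#' appears nowhere else). Uses the current RNG state.
#'
#' @param tree Species tree with node labels.
#' @param family Family name (used in record ids, `<species>_<family>`).
#' @param root_seq Protein sequence at the root.
#' @param scenario An [evolution_scenario()]; only this family's events
#'   apply.
#' @param bg Background residue frequencies.
#' @return List with `records` (tibble `id`, `species`, `seq`), `presence`
#'   (tibble `species`, `family`, `present`), and `insertion_truth` (tibble
#'   `family`, `branch`, `length`, `position`, `clade` list-column).
#' @export
evolve_family <- function(tree, family, root_seq, scenario, bg = aa_background()) {
  nn <- node_names(tree)
  losses <- scenario$losses[scenario$losses$family == family, , drop = FALSE]
  insertions <- scenario$insertions[scenario$insertions$family == family, ,
                                    drop = FALSE]
  bad <- setdiff(c(losses$branch, insertions$branch), nn)
  if (length(bad) > 0) {
    abort(paste0("scenario names unknown branch(es): ",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(insertions) > 0) {
    if (any(insertions$position < 0 |
              insertions$position > nchar(root_seq))) {
      abort("insertion position outside the root sequence")
    }
  }
  n_tip <- length(tree$tip.label)
  root_idx <- n_tip + 1L
  seqs <- rep(NA_character_, n_tip + tree$Nnode)
  seqs[root_idx] <- root_seq
  lost <- rep(FALSE, n_tip + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(po$edge))) # parents before children
  for (k in edge_order) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (lost[p]) { lost[ch] <- TRUE; next }
    child_name <- nn[ch]
    if (child_name %in% losses$branch) { lost[ch] <- TRUE; next }
    s <- mutate_seq(seqs[p], po$edge.length[k], bg)
    ins <- insertions[insertions$branch == child_name, , drop = FALSE]
    for (r in seq_len(nrow(ins))) {
      seg <- random_protein(ins$length[r], bg)
      pos <- ins$position[r]
      s <- paste0(substr(s, 1, pos), seg, substr(s, pos + 1, nchar(s)))
    }
    seqs[ch] <- s
  }
  present <- !lost[seq_len(n_tip)]
  below <- clade_leaves(tree)
  records <- tibble(
    id = paste0(tree$tip.label[present], "_", family),
    species = tree$tip.label[present],
    seq = seqs[seq_len(n_tip)][present]
  )
  presence <- tibble(species = tree$tip.label, family = family,
                     present = present)
  insertion_truth <- insertions |>
    mutate(clade = purrr::map(.data$branch, ~ below[[.x]]))
  list(records = records, presence = presence,
       insertion_truth = insertion_truth)
}

# Reverse-translate a protein with uniformly sampled synonymous codons,
# append a stop codon. Uses the current RNG state.
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant decoy paralogues and truncated gene predictions
#'
#' Decoys are Nth-family paralogues evolved from the Nth root along the same
#' tree (`n_decoys` independent paralogues per species): they share the
#' Endo3c-like HhH superfamily core but carry the Nth-specific block, so they
#' exercise the specific-versus-similar rejection. Truncations clip 10-40
#' residues (configurable) off one terminus of a fraction of true gene
#' records; each truncated record gets a genome containing the full
#' unspliced coding sequence, so extension can recover the missing end.
#' Uses the current RNG state.
#'
#' @param tree Species tree.
#' @param records True-gene records (tibble `id`, `species`, `seq`).
#' @param nth_root Root sequence of the Nth decoy family.
#' @param scenario An [evolution_scenario()].
#' @param bg Background frequencies.
#' @return List with `decoys` (tibble `id`, `species`, `seq`), `truncated`
#'   (tibble `id`, `species`, `side`, `n_removed`), modified `records`, and
#'   `genomes` (tibble `species`, `protein_id`, `dna`).
#' @export
emit_decoys_and_truncations <- function(tree, records, nth_root, scenario,
                                        bg = aa_background()) {
  decoys <- purrr::map(seq_len(scenario$n_decoys), function(k) {
    ev <- evolve_family(tree, paste0("Nth", k), nth_root,
                        evolution_scenario(n_decoys = 0), bg)
    ev$records
  })
  decoys <- bind_rows(c(list(tibble(id = character(), species = character(),
                                    seq = character())), decoys))
  n_trunc <- round(scenario$trunc_fraction * nrow(records))
  truncated <- tibble(id = character(), species = character(),
                      side = character(), n_removed = integer())
  genomes <- tibble(species = character(), protein_id = character(),
                    dna = character())
  if (n_trunc > 0) {
    pick <- sample(nrow(records), n_trunc)
    for (i in pick) {
      full <- records$seq[i]
      rng <- seq(scenario$trunc_range[1], scenario$trunc_range[2])
      n_rm <- rng[sample.int(length(rng), 1)]
      if (n_rm >= nchar(full)) {
        abort("truncation longer than the protein")
      }
      side <- sample(c("N", "C"), 1)
      dna <- paste0(random_dna(60), reverse_translate(full), random_dna(60))
      records$seq[i] <- if (side == "C") {
        substr(full, 1, nchar(full) - n_rm)
      } else {
        substr(full, n_rm + 1, nchar(full))
      }
      truncated <- bind_rows(truncated, tibble(
        id = records$id[i], species = records$species[i],
        side = side, n_removed = n_rm
      ))
      genomes <- bind_rows(genomes, tibble(
        species = records$species[i], protein_id = records$id[i], dna = dna
      ))
    }
  }
  list(decoys = decoys, truncated = truncated, records = records,
       genomes = genomes)
}

#' Simulate a full synthetic dataset with planted truth
#'
#' Builds the three family root sequences from shared domain blocks (the
#' Endo3c core is duplicated into family-private copies and an Nth-like
#' decoy copy), generates per-domain seed alignments for PSSM construction,
#' evolves every family and the decoys along a simulated species tree, and
#' plants the scenario's losses, insertions and truncations. Returns the
#' complete truth tables so each pipeline stage has a recovery target.
#'
#' @param n_species Number of species (default 16).
#' @param seed RNG seed; determines everything.
#' @param families Families to simulate.
#' @param scenario An [evolution_scenario()], or `NULL` to sample one with
#'   [sample_scenario()] defaults (5 losses, MutM 15-aa and MutY 20-aa
#'   insertions, 2 decoys/species, 20\% truncation by 10-40 aa).
#' @param depth Maximum root-to-leaf divergence (substitutions/site,
#'   default 0.25).
#' @param seed_divergence Divergence of each domain seed-alignment row from
#'   its consensus (default 0.15).
#' @param family_core_divergence Divergence of each family-private Endo3c
#'   copy from the ancestral core (default 0.2).
#' @param decoy_divergence Divergence of the Nth core from the ancestral
#'   Endo3c core (default 0.3).
#' @param n_seed_seqs Rows per seed alignment (default 8).
#' @return An object of class `oxog_simulation`: `tree`, `proteins`,
#'   `genomes`, `queries`, `family_db`, `seed_alignments`, `motifs`,
#'   `truth` (list: `presence`, `losses`, `insertions`, `truncated`,
#'   `decoy_ids`), `scenario`.
#' @export
simulate_oxog_dataset <- function(n_species = 16, seed = 1,
                                  families = c("MutY", "MutM", "MutT"),
                                  scenario = NULL, depth = 0.25,
                                  seed_divergence = 0.15,
                                  family_core_divergence = 0.2,
                                  decoy_divergence = 0.3,
                                  n_seed_seqs = 8) {
  tree <- simulate_species_tree(n_species, seed, depth)
  bg <- aa_background()
  withr::with_seed(seed + 1L, {
    # ancestral domain blocks
    endo3c_anc <- random_protein(domain_lengths[["Endo3c"]], bg)
    blocks <- list(
      Endo3c = endo3c_anc,
      Endo3c_Y = mutate_seq(endo3c_anc, family_core_divergence, bg),
      Endo3c_M = mutate_seq(endo3c_anc, family_core_divergence, bg),
      Endo3c_N = mutate_seq(endo3c_anc, decoy_divergence, bg),
      DNAglycosylase_C = random_protein(domain_lengths[["DNAglycosylase_C"]], bg),
      OGG_N = random_protein(domain_lengths[["OGG_N"]], bg),
      MTH1 = random_protein(domain_lengths[["MTH1"]], bg),
      NthC = random_protein(domain_lengths[["NthC"]], bg)
    )
    roots <- list(
      MutY = paste0(blocks$Endo3c_Y, random_protein(linker_len, bg),
                    blocks$DNAglycosylase_C),
      MutM = paste0(blocks$OGG_N, random_protein(linker_len, bg),
                    blocks$Endo3c_M),
      MutT = paste0(random_protein(mutt_flank, bg), blocks$MTH1,
                    random_protein(mutt_flank, bg)),
      Nth = paste0(blocks$Endo3c_N, random_protein(linker_len, bg),
                   blocks$NthC)
    )
    # per-domain seed alignments (ungapped rows around each consensus block)
    seed_for <- list(
      Endo3c = blocks$Endo3c, DNAglycosylase_C = blocks$DNAglycosylase_C,
      OGG_N = blocks$OGG_N, MTH1 = blocks$MTH1, Nth = blocks$Endo3c_N
    )
    seed_alignments <- purrr::imap(seed_for, function(consensus, nm) {
      tibble(
        id = sprintf("%s_seed%02d", nm, seq_len(n_seed_seqs)),
        aseq = vapply(seq_len(n_seed_seqs), function(i) {
          mutate_seq(consensus, seed_divergence, bg)
        }, character(1))
      )
    })
    if (is.null(scenario)) scenario <- sample_scenario(tree)
    fam_out <- purrr::map(families, function(fam) {
      evolve_family(tree, fam, roots[[fam]], scenario, bg)
    })
    records <- bind_rows(purrr::map(fam_out, "records"))
    presence <- bind_rows(purrr::map(fam_out, "presence"))
    insertion_truth <- bind_rows(purrr::map(fam_out, "insertion_truth"))
    dt <- emit_decoys_and_truncations(tree, records, roots$Nth, scenario, bg)
    proteins <- bind_rows(dt$records, dt$decoys)
    queries <- tibble(
      family = families,
      id = paste0("query_", families),
      seq = unlist(roots[families], use.names = FALSE)
    )
    family_db <- bind_rows(
      queries,
      tibble(family = "Nth", id = "query_Nth", seq = roots$Nth)
    )
    structure(
      list(
        tree = tree, proteins = proteins, genomes = dt$genomes,
        queries = queries, family_db = family_db,
        seed_alignments = seed_alignments,
        motifs = oxog_motifs() |> filter(.data$family %in% families),
        truth = list(
          presence = presence,
          losses = scenario$losses |> filter(.data$family %in% families),
          insertions = insertion_truth,
          truncated = dt$truncated,
          decoy_ids = dt$decoys$id
        ),
        scenario = scenario, seed = seed
      ),
      class = "oxog_simulation"
    )
  })
}

#' @export
print.oxog_simulation <- function(x, ...) {
  cat("<oxog_simulation>", length(x$tree$tip.label), "species,",
      nrow(x$queries), "families,", nrow(x$proteins), "protein records,",
      nrow(x$truth$losses), "planted losses,",
      nrow(x$truth$insertions), "planted insertions\n")
  invisible(x)
}
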