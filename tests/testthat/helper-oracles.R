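# Independent oracles and shared fixtures for the test suite. The oracles
# here deliberately use different algorithms/decompositions than the package
# implementation so agreement is informative.

test_scheme <- scoring_scheme()

# cached expensive fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_calibration <- function() {
  fixture("calibration", calibrate_evalue(test_scheme, seed = 99))
}

# Exhaustive local-alignment oracle by literal path enumeration: every
# monotone sequence of match / gap columns starting at every (i, j) pair is
# walked, and the best score over partial alignments ending in a match
# column is returned. Exponential; only usable for very short sequences.
bf_local_enum <- function(a, b, scheme) {
  S <- scheme$S
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  best <- 0
  rec <- function(i, j, score, last) {
    if (last == "M" && score > best) best <<- score
    if (i < n && j < m) rec(i + 1, j + 1, score + S[ac[i + 1], bc[j + 1]], "M")
    if (i < n) rec(i + 1, j, score + ge + if (last == "X") 0 else go, "X")
    if (j < m) rec(i, j + 1, score + ge + if (last == "Y") 0 else go, "Y")
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) rec(i, j, S[ac[i], bc[j]], "M")
  }
  best
}

# Independent local-alignment oracle: top-down recursion with memoisation on
# (i, j, state) over best *suffix* extensions — a different decomposition
# from the package's bottom-up prefix DP. Itself validated against
# bf_local_enum on very short pairs.
bf_local_memo <- function(a, b, scheme) {
  S <- scheme$S
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  # best score of an alignment suffix starting just after (i, j) given the
  # previous column's state (1 = match, 2 = gap in b, 3 = gap in a);
  # the empty suffix scores 0 only if the alignment currently ends in match
  suffix <- function(i, j, state) {
    if (!is.na(memo[i + 1, j + 1, state])) return(memo[i + 1, j + 1, state])
    best <- if (state == 1) 0 else -Inf
    if (i < n && j < m) {
      best <- max(best, S[ac[i + 1], bc[j + 1]] + suffix(i + 1, j + 1, 1))
    }
    if (i < n) {
      best <- max(best, ge + (if (state == 2) 0 else go) + suffix(i + 1, j, 2))
    }
    if (j < m) {
      best <- max(best, ge + (if (state == 3) 0 else go) + suffix(i, j + 1, 3))
    }
    memo[i + 1, j + 1, state] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(best, S[ac[i], bc[j]] + suffix(i, j, 1))
    }
  }
  best
}

# Brute-force minimal Dollo loss count: enumerate every subset of branches
# (and the root-absence option for the all-absent profile) and take the
# smallest subset whose downward propagation reproduces the profile.
bf_dollo_min <- function(tree, profile) {
  if (!any(profile)) return(0L) # absence at the root explains all-absent
  leaves <- tree$tip.label
  nn <- c(tree$tip.label, tree$node.label)
  below <- lapply(seq_along(nn), function(k) {
    if (k <= length(leaves)) leaves[k] else ape::extract.clade(tree, k)$tip.label
  })
  names(below) <- nn
  branches <- setdiff(nn, "root")
  masks <- vapply(branches, function(b) {
    sum(2^(match(below[[b]], leaves) - 1))
  }, numeric(1))
  target <- sum(2^(which(profile[leaves]) - 1))
  full <- sum(2^(seq_along(leaves) - 1))
  nb <- length(branches)
  best <- Inf
  for (s in 0:(2^nb - 1)) {
    bits <- which(bitwAnd(s, 2^(0:(nb - 1))) > 0)
    if (length(bits) >= best) next
    absent <- 0
    for (k in bits) absent <- bitwOr(absent, masks[k])
    if (bitwAnd(full, bitwAnd(full, bitwNot(absent))) == target) {
      best <- length(bits)
    }
  }
  as.integer(best)
}

# Brute-force oracle over a whole topology: enumerates every branch subset
# once (subset DP over unions of absent-leaf masks) and returns the minimal
# loss count for every achievable presence mask. The all-absent profile is
# explained by root absence (0 losses).
bf_dollo_table <- function(tree) {
  leaves <- tree$tip.label
  nn <- c(tree$tip.label, tree$node.label)
  below <- lapply(seq_along(nn), function(k) {
    if (k <= length(leaves)) leaves[k] else ape::extract.clade(tree, k)$tip.label
  })
  names(below) <- nn
  branches <- setdiff(nn, "root")
  masks <- vapply(branches, function(b) {
    as.integer(sum(2^(match(below[[b]], leaves) - 1)))
  }, integer(1))
  full <- as.integer(2^length(leaves) - 1)
  nb <- length(branches)
  n_sub <- 2^nb
  unions <- integer(n_sub)
  pop <- integer(n_sub)
  for (s in seq_len(n_sub - 1)) {
    low <- bitwAnd(s, -s)
    rest <- bitwAnd(s, s - 1)
    unions[s + 1] <- bitwOr(unions[rest + 1], masks[round(log2(low)) + 1])
    pop[s + 1] <- pop[rest + 1] + 1L
  }
  present_mask <- bitwAnd(full, bitwNot(unions))
  min_by_mask <- tapply(pop, present_mask, min)
  min_by_mask[["0"]] <- 0L # root absence
  min_by_mask
}

# Independent presence propagation: walk root-to-leaf paths and mark a leaf
# absent iff any branch on its path carries a loss of the family.
propagate_losses <- function(tree, loss_branches) {
  nn <- c(tree$tip.label, tree$node.label)
  parent <- rep(NA_integer_, length(nn))
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2]] <- tree$edge[k, 1]
  }
  vapply(seq_along(tree$tip.label), function(i) {
    node <- i
    while (!is.na(node)) {
      if (nn[node] %in% loss_branches) return(FALSE)
      node <- parent[node]
    }
    TRUE
  }, logical(1)) |> setNames(tree$tip.label)
}

random_peptide <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# background-composition random sequence (the null the E-value calibration
# models; shuffling a real sequence preserves composition the same way)
random_bg_peptide <- function(n) {
  bg <- aa_background()
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

# a catalogue of distinct rooted binary topologies with 4-6 leaves
topology_catalogue <- function(min_count = 20) {
  out <- list()
  seen <- character(0)
  for (n in 4:6) {
    for (s in 1:30) {
      tr <- simulate_species_tree(n, seed = 1000 * n + s)
      key <- ape::write.tree(ape::compute.brlen(tr, 1))
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- tr
      }
    }
  }
  stopifnot(length(out) >= min_count)
  out
}
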