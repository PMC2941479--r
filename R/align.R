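#' Optimal local alignment of two proteins (affine gaps)
#'
#' Exact Smith-Waterman dynamic programming under the scheme's substitution
#' matrix and affine gap penalties. Ties between equal-scoring alignments are
#' broken deterministically in favour of the lexicographically smallest
#' (start in `a`, start in `b`) coordinate pair.
#'
#' @param a,b Protein sequences (single strings, standard alphabet).
#' @param scheme A [scoring_scheme()].
#' @return A one-row tibble: `score`, 0-based half-open spans `a_start`,
#'   `a_end`, `b_start`, `b_end`, and the aligned strings `a_aln`, `b_aln`
#'   (gaps as `-`).
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  ca <- encode_seq(a, scheme$on_unknown)
  cb <- encode_seq(b, scheme$on_unknown)
  r <- cpp_sw_align(ca, cb, scheme$S, scheme$gap_open, scheme$gap_extend)
  achr <- strsplit(toupper(a), "")[[1]]
  bchr <- strsplit(toupper(b), "")[[1]]
  a_aln <- rep("-", length(r$a_idx))
  a_aln[r$a_idx >= 0] <- achr[r$a_idx[r$a_idx >= 0] + 1L]
  b_aln <- rep("-", length(r$b_idx))
  b_aln[r$b_idx >= 0] <- bchr[r$b_idx[r$b_idx >= 0] + 1L]
  tibble(
    score = r$score,
    a_start = r$a_start, a_end = r$a_end,
    b_start = r$b_start, b_end = r$b_end,
    a_aln = paste(a_aln, collapse = ""),
    b_aln = paste(b_aln, collapse = "")
  )
}

# Score an existing gapped alignment pair under a scheme (used to verify that
# returned alignments rescore to their reported raw score).
rescore_alignment <- function(a_aln, b_aln, scheme = scoring_scheme()) {
  ac <- strsplit(a_aln, "")[[1]]
  bc <- strsplit(b_aln, "")[[1]]
  stopifnot(length(ac) == length(bc))
  s <- 0
  in_gap <- FALSE
  for (k in seq_along(ac)) {
    if (ac[k] == "-" || bc[k] == "-") {
      s <- s + scheme$gap_extend + if (in_gap) 0 else scheme$gap_open
      in_gap <- TRUE
    } else {
      s <- s + scheme$S[ac[k], bc[k]]
      in_gap <- FALSE
    }
  }
  s
}

# Global alignment of two proteins; returns score and aligned strings.
global_align <- function(a, b, scheme = scoring_scheme()) {
  ca <- encode_seq(a, scheme$on_unknown)
  cb <- encode_seq(b, scheme$on_unknown)
  # submatrix lookup gives the full column-score grid in one step;
  # wildcard positions (code -1) score 0 against everything
  Spad <- rbind(0, cbind(0, scheme$S))
  colscore <- Spad[ca + 2L, cb + 2L, drop = FALSE]
  dim(colscore) <- c(length(ca), length(cb))
  r <- cpp_nw_ops(colscore, scheme$gap_open, scheme$gap_extend)
  ops <- r$ops
  achr <- strsplit(toupper(a), "")[[1]]
  bchr <- strsplit(toupper(b), "")[[1]]
  ai <- cumsum(ops != 3L)
  bi <- cumsum(ops != 2L)
  a_aln <- rep("-", length(ops))
  a_aln[ops != 3L] <- achr[ai[ops != 3L]]
  b_aln <- rep("-", length(ops))
  b_aln[ops != 2L] <- bchr[bi[ops != 2L]]
  list(score = r$score,
       a_aln = paste(a_aln, collapse = ""),
       b_aln = paste(b_aln, collapse = ""))
}

#' Calibrate an empirical E-value model for local alignment scores
#'
#' Fits a Gumbel (extreme-value) law to the distribution of optimal local
#' alignment scores between random sequences of background composition, by
#' the method of moments. The fitted law gives
#' `E(S; m, n) = K * m * n * exp(-lambda * S)`, the expected number of
#' chance hits of score at least S for a query of length m against a
#' database of total length n.
#'
#' @param scheme A [scoring_scheme()].
#' @param bg Background residue frequencies (named, over [aa_alphabet()]).
#' @param n_shuffles Number of random sequence pairs (>= 100).
#' @param seed RNG seed; the calibration is fully reproducible.
#' @param query_len,db_len Lengths of the random query and subject used
#'   during calibration.
#' @return An object of class `evalue_calibration` with elements `lambda`,
#'   `K`, and the calibration dimensions.
#' @export
calibrate_evalue <- function(scheme = scoring_scheme(), bg = aa_background(),
                             n_shuffles = 200, seed = 1,
                             query_len = 300, db_len = 300) {
  if (n_shuffles < 100) abort("n_shuffles must be >= 100")
  if (any(bg >= 1) || any(bg <= 0)) {
    abort("degenerate background: all frequencies must lie in (0, 1)")
  }
  bg <- bg / sum(bg)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      q <- encode_seq(random_protein(query_len, bg))
      s <- encode_seq(random_protein(db_len, bg))
      cpp_sw_score(q, s, scheme$S, scheme$gap_open, scheme$gap_extend)
    }, numeric(1))
  })
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  lambda <- 1 / beta
  K <- exp(mu / beta) / (query_len * db_len)
  structure(
    list(lambda = lambda, K = K, query_len = query_len, db_len = db_len,
         n_shuffles = n_shuffles, seed = seed),
    class = "evalue_calibration"
  )
}

#' @export
print.evalue_calibration <- function(x, ...) {
  cat("<evalue_calibration> lambda =", signif(x$lambda, 4),
      "K =", signif(x$K, 4), "(", x$n_shuffles, "shuffles )\n")
  invisible(x)
}

#' E-value of a local alignment score
#'
#' @param calibration An [calibrate_evalue()] fit.
#' @param score Raw alignment score(s).
#' @param m Query length.
#' @param n Database length (total residues searched).
#' @return Numeric E-values, floored at 1e-300 so they are always positive.
#' @export
evalue <- function(calibration, score, m, n) {
  log10e <- log10(calibration$K) + log10(m) + log10(n) -
    calibration$lambda * score / log(10)
  pmax(10^pmax(log10e, -300), 1e-300)
}

#' Search a query protein against a proteome
#'
#' Aligns the query against every subject by exact local alignment and
#' reports hits whose E-value is strictly below the threshold (hits at
#' exactly the threshold are excluded), sorted by ascending E-value with
#' ties broken by subject id.
#'
#' @param proteome Data frame with columns `id` and `seq` (a `species`
#'   column, if present, is carried through). May be empty.
#' @param query Query protein sequence (single string).
#' @param scheme A [scoring_scheme()].
#' @param calibration An [calibrate_evalue()] fit.
#' @param threshold E-value cutoff (default `1e-20`, strict `<`).
#' @param query_id Identifier recorded for the query.
#' @return A tibble of hits: `query_id`, `subject_id`, `score`, `e_value`,
#'   plus 0-based half-open alignment coordinates on query (`q_start`,
#'   `q_end`) and subject (`s_start`, `s_end`) and the aligned strings.
#' @export
search_proteome <- function(proteome, query, scheme = scoring_scheme(),
                            calibration, threshold = 1e-20,
                            query_id = "query") {
  if (nrow(proteome) == 0) return(empty_hits())
  m <- nchar(query)
  n_db <- sum(nchar(proteome$seq))
  hits <- purrr::map2(proteome$id, proteome$seq, function(sid, sseq) {
    al <- local_align(query, sseq, scheme)
    tibble(
      query_id = query_id, subject_id = sid, score = al$score,
      e_value = evalue(calibration, al$score, m, n_db),
      q_start = al$a_start, q_end = al$a_end,
      s_start = al$b_start, s_end = al$b_end,
      q_aln = al$a_aln, s_aln = al$b_aln
    )
  })
  hits <- bind_rows(hits)
  hits |>
    filter(.data$e_value < threshold) |>
    arrange(.data$e_value, .data$subject_id)
}

empty_hits <- function() {
  tibble(
    query_id = character(), subject_id = character(), score = numeric(),
    e_value = numeric(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), q_aln = character(),
    s_aln = character()
  )
}

#' Reciprocal best-hit family check
#'
#' Searches a candidate protein back against the family query database and
#' reports whether its best hit belongs to the claimed family — the
#' reciprocal-search confirmation used when validating orthologue calls.
#'
#' @param family_db Data frame with columns `id`, `family`, `seq`: the query
#'   sequences of every family (including decoy families such as Nth).
#' @param candidate_seq Candidate protein sequence.
#' @param claimed_family Family the candidate is being evaluated for.
#' @param scheme,calibration As in [search_proteome()].
#' @return One-row tibble: `ok` (logical), `best_family`, `best_id`,
#'   `best_score`, `e_value`, `reason` (`NA` when ok, otherwise
#'   `"no-reciprocal-hit"` or `"best-hit-other-family"`).
#' @export
reciprocal_check <- function(family_db, candidate_seq, claimed_family,
                             scheme = scoring_scheme(), calibration) {
  stopifnot(all(c("id", "family", "seq") %in% names(family_db)))
  if (nrow(family_db) == 0 || nchar(candidate_seq) == 0) {
    return(tibble(ok = FALSE, best_family = NA_character_,
                  best_id = NA_character_, best_score = NA_real_,
                  e_value = NA_real_, reason = "no-reciprocal-hit"))
  }
  m <- nchar(candidate_seq)
  n_db <- sum(nchar(family_db$seq))
  scores <- vapply(family_db$seq, function(s) {
    cpp_sw_score(encode_seq(candidate_seq, scheme$on_unknown),
                 encode_seq(s, scheme$on_unknown),
                 scheme$S, scheme$gap_open, scheme$gap_extend)
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-scores, family_db$id)
  best <- ord[1]
  if (scores[best] <= 0) {
    return(tibble(ok = FALSE, best_family = NA_character_,
                  best_id = NA_character_, best_score = NA_real_,
                  e_value = NA_real_, reason = "no-reciprocal-hit"))
  }
  ok <- identical(family_db$family[best], claimed_family)
  tibble(
    ok = ok,
    best_family = family_db$family[best],
    best_id = family_db$id[best],
    best_score = scores[best],
    e_value = evalue(calibration, scores[best], m, n_db),
    reason = if (ok) NA_character_ else "best-hit-other-family"
  )
}

# Translate a DNA string in all six reading frames. Stop codons become "*",
# which downstream alignment treats as a wildcard. Returns a tibble with
# frame labels; frames 1:3 forward, -1:-3 on the reverse complement.
translate_six_frames <- function(dna) {
  d <- Biostrings::DNAString(toupper(dna))
  rc <- Biostrings::reverseComplement(d)
  one <- function(x, off) {
    len <- length(x) - off
    len <- len - (len %% 3)
    if (len < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1L, off + len),
      if.fuzzy.codon = "X"
    ))
  }
  tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    protein = c(one(d, 0L), one(d, 1L), one(d, 2L),
                one(rc, 0L), one(rc, 1L), one(rc, 2L))
  )
}

#' Extend a truncated gene prediction from genomic sequence
#'
#' Emulates extension of truncated gene predictions: a full-length reference
#' protein from a related species is aligned against all six reading frames
#' of the candidate's genome, the frame segment overlapping the candidate's
#' locus is identified, and missing terminal residues are appended verbatim
#' from the genome translation. Genomes are treated as unspliced open
#' reading frames (no intron model).
#'
#' @param candidate One-row data frame (or list) with `id` and `seq`.
#' @param genome DNA sequence of the candidate's species (single string),
#'   or `NULL`.
#' @param reference Full-length family member from a related species
#'   (single string).
#' @param scheme A [scoring_scheme()]; unknown translated residues are
#'   treated as wildcards internally.
#' @param min_score Minimum reference-vs-genome local alignment score for an
#'   extension to be attempted.
#' @return One-row tibble: `id`, `seq` (possibly extended), `provenance`
#'   (`"no-extension"`, `"already-complete"` or `"extended"`), `added_nterm`,
#'   `added_cterm`.
#' @export
extend_truncated <- function(candidate, genome, reference,
                             scheme = scoring_scheme(), min_score = 100) {
  out_unchanged <- function(why) {
    tibble(id = candidate$id, seq = candidate$seq, provenance = why,
           added_nterm = 0L, added_cterm = 0L)
  }
  if (is.null(genome) || is.na(genome) || nchar(genome) < 3) {
    return(out_unchanged("no-extension"))
  }
  wild <- scheme
  wild$on_unknown <- "wildcard"
  frames <- translate_six_frames(genome)
  frames <- frames[nchar(frames$protein) >= 10, , drop = FALSE]
  if (nrow(frames) == 0) return(out_unchanged("no-extension"))
  ref_hits <- purrr::map(frames$protein, function(p) {
    local_align(reference, p, wild)
  })
  scores <- vapply(ref_hits, function(h) h$score, numeric(1))
  best <- which.max(scores)
  if (scores[best] < min_score) return(out_unchanged("no-extension"))
  frame_prot <- frames$protein[best]
  hit <- ref_hits[[best]]
  # locus of the (terminal-truncated) candidate inside the frame translation:
  # exact substring match first, alignment as fallback
  loc <- regexpr(candidate$seq, frame_prot, fixed = TRUE)
  if (loc > 0) {
    c_start <- as.integer(loc) - 1L
    c_end <- c_start + nchar(candidate$seq)
  } else {
    cal <- local_align(candidate$seq, frame_prot, wild)
    if (cal$score < min_score) return(out_unchanged("no-extension"))
    c_start <- cal$b_start
    c_end <- cal$b_end
  }
  # reference-supported span must overlap or abut the candidate locus
  if (hit$b_end < c_start || hit$b_start > c_end) {
    return(out_unchanged("no-extension"))
  }
  # pad by the reference overhang: the local alignment may stop a few
  # residues short of the true terminus, but the homologous segment extends
  # to the reference's full span; stop-codon clipping below bounds the pad
  pad_left <- hit$a_start
  pad_right <- nchar(reference) - hit$a_end
  new_start <- max(0L, min(c_start, hit$b_start - pad_left))
  new_end <- min(nchar(frame_prot), max(c_end, hit$b_end + pad_right))
  ext <- substr(frame_prot, new_start + 1L, new_end)
  if (grepl("[*X]", ext)) {
    # never extend across a stop codon; clip back to the clean segment
    # around the candidate locus
    seg <- strsplit(ext, "")[[1]]
    bad <- which(seg %in% c("*", "X"))
    lo <- c_start - new_start + 1L
    hi <- c_end - new_start
    left <- max(c(0L, bad[bad < lo]))
    right <- min(c(length(seg) + 1L, bad[bad > hi]))
    ext <- paste(seg[(left + 1L):(right - 1L)], collapse = "")
    new_start <- new_start + left
  }
  if (identical(ext, candidate$seq)) return(out_unchanged("already-complete"))
  if (nchar(ext) < nchar(candidate$seq)) return(out_unchanged("no-extension"))
  tibble(
    id = candidate$id, seq = ext, provenance = "extended",
    added_nterm = c_start - new_start,
    added_cterm = nchar(ext) - (c_start - new_start) - nchar(candidate$seq)
  )
}
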