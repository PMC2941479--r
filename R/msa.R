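# Residue frequency profile of a set of gapped rows: 20 x L matrix of
# per-column residue frequencies (normalised over residues; all-gap columns
# are all-zero).
profile_freqs <- function(rows) {
  chars <- do.call(rbind, strsplit(rows, ""))
  aa <- aa_alphabet()
  L <- ncol(chars)
  counts <- vapply(aa, function(a) colSums(chars == a), numeric(L))
  if (L == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, aa))
  n_res <- rowSums(counts)
  f <- t(counts / pmax(n_res, 1))
  rownames(f) <- aa
  f
}

# Merge two sub-alignments with affine profile-profile global alignment,
# scoring column pairs by the frequency-weighted average substitution score.
merge_profiles <- function(rows1, rows2, scheme) {
  f1 <- profile_freqs(rows1)
  f2 <- profile_freqs(rows2)
  colscore <- t(f1) %*% scheme$S %*% f2
  r <- cpp_nw_ops(colscore, scheme$gap_open, scheme$gap_extend)
  ops <- r$ops
  expand <- function(rows, consume) {
    chars <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(chars), length(ops))
    out[, consume] <- chars
    apply(out, 1, paste, collapse = "")
  }
  c(expand(rows1, ops != 3L), expand(rows2, ops != 2L))
}

#' Progressive multiple alignment of protein records
#'
#' Builds a multiple alignment by progressive profile-profile merging along a
#' guide tree: the supplied species tree when given, otherwise a UPGMA tree
#' on pairwise global-alignment identity distances. Gaps removed from any
#' row reproduce the input sequence exactly.
#'
#' @param records Data frame with columns `id` and `seq` (>= 1 row).
#' @param guide Optional rooted `ape::phylo` whose tip labels are exactly the
#'   record ids.
#' @param scheme A [scoring_scheme()].
#' @return A `protein_msa`: tibble with `id` and gapped `aseq` (equal
#'   lengths), rows in input order.
#' @export
progressive_align <- function(records, guide = NULL,
                              scheme = scoring_scheme()) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  n <- nrow(records)
  if (n == 0) abort("no sequences to align")
  as_msa <- function(ids, rows) {
    out <- tibble(id = ids, aseq = rows)
    out <- out[match(records$id, out$id), ]
    structure(out, class = c("protein_msa", class(out)))
  }
  if (n == 1) return(as_msa(records$id, records$seq))
  if (is.null(guide)) {
    d <- matrix(0, n, n, dimnames = list(records$id, records$id))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        al <- global_align(records$seq[i], records$seq[j], scheme)
        ac <- strsplit(al$a_aln, "")[[1]]
        bc <- strsplit(al$b_aln, "")[[1]]
        ident <- mean(ac == bc & ac != "-")
        d[i, j] <- d[j, i] <- 1 - ident
      }
    }
    hc <- hclust(as.dist(d), method = "average")
    guide <- ape::as.phylo(hc)
  }
  if (!setequal(guide$tip.label, records$id)) {
    abort("guide tree tips must match record ids exactly")
  }
  seqs <- setNames(records$seq, records$id)
  po <- ape::reorder.phylo(guide, "postorder")
  n_tip <- length(guide$tip.label)
  clusters <- vector("list", n_tip + guide$Nnode)
  for (i in seq_len(n_tip)) {
    clusters[[i]] <- list(ids = guide$tip.label[i],
                          rows = unname(seqs[guide$tip.label[i]]))
  }
  children <- split(po$edge[, 2], po$edge[, 1])
  done <- logical(n_tip + guide$Nnode)
  done[seq_len(n_tip)] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    if (done[p]) next
    kids <- children[[as.character(p)]]
    if (!all(done[kids])) next
    cl <- clusters[[kids[1]]]
    for (ch in kids[-1]) {
      rows <- merge_profiles(cl$rows, clusters[[ch]]$rows, scheme)
      cl <- list(ids = c(cl$ids, clusters[[ch]]$ids), rows = rows)
    }
    clusters[[p]] <- cl
    done[p] <- TRUE
  }
  root <- n_tip + 1L
  as_msa(clusters[[root]]$ids, clusters[[root]]$rows)
}

# Sum-of-pairs score of an MSA under a scheme (affine gaps per row pair).
sum_of_pairs <- function(msa, scheme = scoring_scheme()) {
  n <- nrow(msa)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- strsplit(msa$aseq[i], "")[[1]]
      b <- strsplit(msa$aseq[j], "")[[1]]
      keep <- !(a == "-" & b == "-")
      total <- total + rescore_alignment(paste(a[keep], collapse = ""),
                                         paste(b[keep], collapse = ""),
                                         scheme)
    }
  }
  total
}

#' Call clade-specific insertions in a protein alignment
#'
#' Finds maximal runs of alignment columns that are occupied in the clade
#' rows (occupancy >= `min_purity`) but essentially empty in the outgroup
#' rows (occupancy <= `max_outgroup_occupancy`), of length at least
#' `min_len` — the signature of a lineage-specific sequence insertion.
#'
#' @param msa A `protein_msa`.
#' @param clade Character vector of row ids forming the clade; must be a
#'   non-empty proper subset of the rows.
#' @param min_len Minimum run length in columns (default 8).
#' @param min_purity Minimum mean clade occupancy per column (default 0.9).
#' @param max_outgroup_occupancy Maximum mean outgroup occupancy per column
#'   (default 0.1).
#' @return Tibble of calls: `col_start`, `col_end` (0-based half-open),
#'   `length`, `purity` (mean clade occupancy over the span), and a `clade`
#'   list-column.
#' @export
call_insertions <- function(msa, clade, min_len = 8, min_purity = 0.9,
                            max_outgroup_occupancy = 0.1) {
  if (length(clade) == 0) abort("clade is empty")
  if (!all(clade %in% msa$id)) abort("clade ids not all present in MSA")
  out_ids <- setdiff(msa$id, clade)
  if (length(out_ids) == 0) abort("clade equals all rows: no outgroup")
  chars <- msa_char_matrix(msa)
  rownames(chars) <- msa$id
  occ_clade <- colMeans(chars[clade, , drop = FALSE] != "-")
  occ_out <- colMeans(chars[out_ids, , drop = FALSE] != "-")
  good <- occ_clade >= min_purity & occ_out <= max_outgroup_occupancy
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  if (length(keep) == 0) {
    return(tibble(col_start = integer(), col_end = integer(),
                  length = integer(), purity = numeric(), clade = list()))
  }
  tibble(
    col_start = starts[keep] - 1L,
    col_end = ends[keep],
    length = r$lengths[keep],
    purity = vapply(keep, function(k) {
      span <- starts[k]:ends[k]
      mean(chars[clade, span, drop = FALSE] != "-")
    }, numeric(1)),
    clade = replicate(length(keep), clade, simplify = FALSE)
  )
}

#' Scan all candidate clades of a guide tree for insertions
#'
#' Convenience wrapper: runs [call_insertions()] for the leaf set of every
#' internal branch of `tree` (restricted to ids present in the MSA) and for
#' single leaves, returning the union of calls with a `branch` column.
#'
#' @param msa A `protein_msa` whose ids are `<species>_<family>` or species
#'   names matching the tree tips.
#' @param tree Species tree.
#' @param id_species Optional function mapping row ids to species names
#'   (default strips a `_<family>` suffix).
#' @inheritParams call_insertions
#' @return Tibble of calls with an extra `branch` column.
#' @export
detect_clade_insertions <- function(msa, tree,
                                    id_species = function(id) sub("_[^_]+$", "", id),
                                    min_len = 8, min_purity = 0.9,
                                    max_outgroup_occupancy = 0.1) {
  below <- clade_leaves(tree)
  sp <- id_species(msa$id)
  out <- list()
  for (b in setdiff(node_names(tree), "root")) {
    rows <- msa$id[sp %in% below[[b]]]
    if (length(rows) == 0 || length(rows) == nrow(msa)) next
    calls <- call_insertions(msa, rows, min_len, min_purity,
                             max_outgroup_occupancy)
    if (nrow(calls) > 0) {
      calls$branch <- b
      out[[b]] <- calls
    }
  }
  if (length(out) == 0) {
    return(tibble(col_start = integer(), col_end = integer(),
                  length = integer(), purity = numeric(), clade = list(),
                  branch = character()))
  }
  bind_rows(out)
}

#' Locate an insertion call relative to annotated motifs
#'
#' Maps each motif's ungapped span on its reference row to alignment columns
#' and reports whether the call lies within, upstream of, or downstream of
#' the motif. Offsets are measured in ungapped reference-row residues
#' between the call span and the motif boundary.
#'
#' @param call One-row data frame with `col_start`, `col_end` (as returned
#'   by [call_insertions()]).
#' @param annotations Tibble with `motif`, `ref_id`, `start`, `end`
#'   (0-based half-open, ungapped coordinates on the reference row).
#' @param msa The `protein_msa` containing the reference row.
#' @return Tibble with one row per motif: `motif`, `relation`
#'   (`within`/`upstream-of`/`downstream-of`), `offset` (residues; 0 for
#'   within) and a readable `label`; sorted with the nearest motif first.
#' @export
locate_insertion <- function(call, annotations, msa) {
  out <- purrr::pmap(annotations, function(motif, ref_id, start, end, ...) {
    row <- msa$aseq[msa$id == ref_id]
    if (length(row) != 1) abort(paste0("reference row not in MSA: ", ref_id))
    chars <- strsplit(row, "")[[1]]
    res_cols <- which(chars != "-") # alignment column of each residue
    if (end > length(res_cols)) abort("motif span outside reference sequence")
    m_start_col <- res_cols[start + 1L] - 1L # 0-based columns
    m_end_col <- res_cols[end] # half-open
    if (call$col_start < m_end_col && call$col_end > m_start_col) {
      return(tibble(motif = motif, relation = "within", offset = 0L))
    }
    if (call$col_end <= m_start_col) {
      gap_cols <- (call$col_end + 1L):m_start_col
      off <- if (call$col_end >= m_start_col) 0L else
        sum(chars[gap_cols] != "-")
      return(tibble(motif = motif, relation = "upstream-of",
                    offset = as.integer(off)))
    }
    gap_cols <- (m_end_col + 1L):call$col_start
    off <- if (m_end_col >= call$col_start) 0L else
      sum(chars[gap_cols] != "-")
    tibble(motif = motif, relation = "downstream-of",
           offset = as.integer(off))
  })
  out <- bind_rows(out) |>
    mutate(label = ifelse(.data$relation == "within",
                          paste0("within ", .data$motif),
                          sprintf("%s %s, offset %d", .data$relation,
                                  .data$motif, .data$offset))) |>
    arrange(desc(.data$relation == "within"), .data$offset)
  out
}
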