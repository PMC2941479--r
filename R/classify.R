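#' Classify a candidate set for one species and family
#'
#' Applies the calling rules to the evidence gathered for one
#' (species, family) cell. A candidate scores present iff (a) it has a
#' homology hit with E-value strictly below `homology_threshold`, (b) every
#' required domain for the family is found as a *specific* hit with E-value
#' strictly below `domain_threshold`, and (c) the reciprocal search confirms
#' the family. A candidate whose HhH-superfamily region is better explained
#' by a similar model (e.g. Nth) — a similar-only hit, or a best domain hit
#' to a relative outside the required set — is rejected with reason
#' `"similar-domain-best-hit"`. When several candidates pass, the one with
#' the lowest homology E-value is kept and the conflict is recorded.
#'
#' @param homology_hits Tibble from [search_proteome()] (may pool several
#'   queries), restricted to one species.
#' @param domain_hits Tibble from [scan_domains()] for the candidate
#'   proteins.
#' @param reciprocal Tibble with columns `protein_id`, `ok`, `best_family`
#'   (one row per candidate).
#' @param species,family The cell being classified.
#' @param required Character vector of required domain models (defaults to
#'   [required_domains()] for `family`).
#' @param homology_threshold,domain_threshold Strict E-value cutoffs
#'   (defaults 1e-20 and 1e-5).
#' @param extensions Optional tibble with `protein_id`, `provenance` from
#'   [extend_truncated()], recorded in the evidence.
#' @return A one-row tibble (`candidate_call`): `species`, `family`,
#'   `protein_id`, `verdict` (`present`/`rejected`/`absent`),
#'   `rejection_reason`, `e_value`, `conflict` (number of passing candidates
#'   beyond the first), and an `evidence` list-column.
#' @export
classify_candidate <- function(homology_hits, domain_hits, reciprocal,
                               species, family,
                               required = required_domains()[[family]],
                               homology_threshold = 1e-20,
                               domain_threshold = 1e-5,
                               extensions = NULL) {
  absent <- function(reason) {
    tibble(species = species, family = family, protein_id = NA_character_,
           verdict = "absent", rejection_reason = reason,
           e_value = NA_real_, conflict = 0L,
           evidence = list(list(homology = homology_hits,
                                domains = domain_hits,
                                reciprocal = reciprocal,
                                extensions = extensions)))
  }
  if (nrow(homology_hits) == 0) return(absent("no-candidate"))
  per_candidate <- homology_hits |>
    group_by(.data$subject_id) |>
    summarise(e_value = min(.data$e_value), .groups = "drop") |>
    arrange(.data$e_value, .data$subject_id)
  rows <- purrr::pmap(per_candidate, function(subject_id, e_value) {
    pid <- subject_id
    dh <- domain_hits |> filter(.data$protein_id == pid)
    rc <- reciprocal |> filter(.data$protein_id == pid)
    reason <- NA_character_
    verdict <- "present"
    if (!(e_value < homology_threshold)) {
      verdict <- "rejected"; reason <- "no-significant-homology"
    }
    req <- dh |>
      filter(.data$model %in% required,
             .data$e_value < domain_threshold)
    similar_only_req <- any(req$specificity == "similar-only")
    best_model <- if (nrow(dh) > 0) dh$model[which.max(dh$score)] else NA_character_
    best_is_relative <- !is.na(best_model) && !(best_model %in% required) &&
      any(vapply(required, function(r) {
        best_model %in% (similar_models()[[r]] %||% character())
      }, logical(1)))
    if (is.na(reason) && (similar_only_req || best_is_relative)) {
      verdict <- "rejected"; reason <- "similar-domain-best-hit"
    }
    specific_req <- req |> filter(.data$specificity == "specific")
    if (is.na(reason) && !all(required %in% specific_req$model)) {
      verdict <- "rejected"; reason <- "missing-required-domain"
    }
    if (is.na(reason) && !(nrow(rc) > 0 && isTRUE(rc$ok[1]))) {
      verdict <- "rejected"; reason <- "failed-reciprocal"
    }
    tibble(protein_id = pid, verdict = verdict,
           rejection_reason = reason, e_value = e_value)
  })
  rows <- bind_rows(rows)
  passing <- rows |> filter(.data$verdict == "present")
  chosen <- if (nrow(passing) > 0) passing[1, ] else rows[1, ]
  tibble(
    species = species, family = family,
    protein_id = chosen$protein_id, verdict = chosen$verdict,
    rejection_reason = chosen$rejection_reason, e_value = chosen$e_value,
    conflict = max(nrow(passing) - 1L, 0L),
    evidence = list(list(homology = homology_hits, domains = domain_hits,
                         reciprocal = reciprocal, extensions = extensions,
                         candidates = rows))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Audit every evaluated candidate across all calls
#'
#' Flattens the per-candidate verdicts stored in the evidence trail of each
#' call, one row per (cell, candidate) — useful for checking how decoy
#' paralogues were rejected.
#'
#' @param calls Tibble of calls from [classify_candidate()] /
#'   [call_presence_absence()] (`$calls`).
#' @return Tibble: `species`, `family`, `protein_id`, `verdict`,
#'   `rejection_reason`, `e_value`.
#' @export
audit_candidates <- function(calls) {
  out <- purrr::pmap(
    list(calls$species, calls$family, calls$evidence),
    function(sp, fam, ev) {
      if (is.null(ev$candidates) || nrow(ev$candidates) == 0) return(NULL)
      ev$candidates |> mutate(species = sp, family = fam, .before = 1)
    }
  )
  bind_rows(out)
}

#' Assemble calls into a presence/absence matrix
#'
#' @param calls Tibble of candidate calls from [classify_candidate()].
#' @param species_order Ordered species vector (defaults to order of
#'   appearance).
#' @param families Ordered family vector.
#' @param groups Optional named vector of group labels per species (e.g.
#'   clade names).
#' @return A `pa_matrix`: tibble with `species`, `group` and one logical
#'   column per family; the calls are attached as attribute `"calls"`.
#' @export
build_matrix <- function(calls, species_order = NULL,
                         families = c("MutY", "MutM", "MutT"),
                         groups = NULL) {
  if (is.null(species_order)) species_order <- unique(calls$species)
  dup <- calls |>
    filter(.data$verdict == "present") |>
    dplyr::count(.data$species, .data$family) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate present calls for the same (species, family) cell")
  }
  grid <- tidyr::expand_grid(species = species_order, family = families)
  long <- grid |>
    left_join(
      calls |> select("species", "family", "verdict"),
      by = c("species", "family")
    ) |>
    mutate(present = !is.na(.data$verdict) & .data$verdict == "present")
  wide <- long |>
    select("species", "family", "present") |>
    tidyr::pivot_wider(names_from = "family", values_from = "present")
  wide <- wide |>
    mutate(group = if (is.null(groups)) NA_character_
           else unname(groups[.data$species]), .after = "species")
  structure(wide, class = c("pa_matrix", class(wide)), calls = calls)
}

#' Render a presence/absence matrix
#'
#' @param matrix A `pa_matrix`.
#' @param format `"tsv"` (machine-readable, round-trips through
#'   [parse_matrix_tsv()]), `"text"` (filled/empty cells), or `"html"`.
#' @param annotations Optional tibble (`species`, `family`, `mark`), e.g. an
#'   asterisk on cells whose homologue carries a detected sequence insert.
#' @return A single string.
#' @export
render_matrix <- function(matrix, format = c("tsv", "text", "html"),
                          annotations = NULL) {
  format <- match.arg(format)
  fams <- setdiff(names(matrix), c("species", "group"))
  mark_for <- function(sp, fam) {
    if (is.null(annotations)) return("")
    m <- annotations |>
      filter(.data$species == sp, .data$family == fam)
    if (nrow(m) > 0) m$mark[1] else ""
  }
  if (format == "tsv") {
    header <- paste(c("species", "group", fams), collapse = "\t")
    lines <- vapply(seq_len(nrow(matrix)), function(i) {
      cells <- vapply(fams, function(f) {
        paste0(if (matrix[[f]][i]) "1" else "0",
               mark_for(matrix$species[i], f))
      }, character(1))
      paste(c(matrix$species[i],
              if (is.na(matrix$group[i])) "" else matrix$group[i],
              cells), collapse = "\t")
    }, character(1))
    return(paste(c(header, lines), collapse = "\n"))
  }
  if (format == "text") {
    header <- sprintf("%-12s %s", "species", paste(sprintf("%-6s", fams),
                                                   collapse = " "))
    lines <- vapply(seq_len(nrow(matrix)), function(i) {
      cells <- vapply(fams, function(f) {
        sprintf("%-6s", paste0(if (matrix[[f]][i]) "■" else "□",
                               mark_for(matrix$species[i], f)))
      }, character(1))
      sprintf("%-12s %s", matrix$species[i], paste(cells, collapse = " "))
    }, character(1))
    return(paste(c(header, lines), collapse = "\n"))
  }
  # html
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    cells <- vapply(fams, function(f) {
      bg <- if (matrix[[f]][i]) "#999999" else "#ffffff"
      sprintf("<td style='background:%s'>%s</td>", bg,
              mark_for(matrix$species[i], f))
    }, character(1))
    sprintf("<tr><td>%s</td>%s</tr>", matrix$species[i],
            paste(cells, collapse = ""))
  }, character(1))
  paste0("<table><tr><th>species</th>",
         paste(sprintf("<th>%s</th>", fams), collapse = ""),
         "</tr>", paste(rows, collapse = ""), "</table>")
}

#' Parse a TSV rendering back into a presence/absence matrix
#'
#' Inverse of `render_matrix(format = "tsv")`; annotation marks are ignored
#' for the boolean cells.
#'
#' @param text TSV string.
#' @return A `pa_matrix` (without calls attribute).
#' @export
parse_matrix_tsv <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  fams <- header[-(1:2)]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  out <- tibble(
    species = vapply(body, `[`, character(1), 1),
    group = vapply(body, function(x) {
      g <- x[2]
      if (identical(g, "") || is.na(g)) NA_character_ else g
    }, character(1))
  )
  for (k in seq_along(fams)) {
    out[[fams[k]]] <- vapply(body, function(x) {
      substr(x[k + 2], 1, 1) == "1"
    }, logical(1))
  }
  structure(out, class = c("pa_matrix", class(out)))
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(render_matrix(x, "text"), "\n")
  invisible(x)
}
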