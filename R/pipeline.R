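#' Build and calibrate the domain model set from seed alignments
#'
#' @param seed_alignments Named list of seed-alignment tibbles (`id`,
#'   `aseq`), e.g. from [simulate_oxog_dataset()].
#' @param pseudocount,bg Passed to [build_model()].
#' @param n_shuffles,seq_len Passed to [calibrate_model()].
#' @param seed Base calibration seed (each model uses `seed + index`).
#' @return Named list of calibrated `domain_model`s with superfamily
#'   `similar_to` links (Endo3c and Nth are mutual relatives).
#' @export
build_domain_models <- function(seed_alignments, pseudocount = 5,
                                bg = aa_background(), n_shuffles = 1000,
                                seq_len = 300, seed = 1) {
  sim <- similar_models()
  models <- purrr::imap(seed_alignments, function(aln, nm) {
    m <- build_model(aln, nm, pseudocount, bg,
                     similar_to = sim[[nm]] %||% character())
    calibrate_model(m, bg, n_shuffles, seq_len,
                    seed = seed + match(nm, names(seed_alignments)))
  })
  models
}

#' Call presence/absence of gene families across proteomes
#'
#' The full calling pipeline: for every (species, family) cell, search the
#' family queries against the species proteome (exact local alignment,
#' calibrated E-values, strict `< homology_threshold`), scan candidates
#' against the calibrated domain models, attempt genome-based extension of
#' candidates whose required domains are incomplete, confirm families by
#' reciprocal search, classify, and assemble the presence/absence matrix.
#' Optionally performs one round of query augmentation: orthologues found in
#' the first pass are added as queries and cells still empty are
#' re-searched.
#'
#' @param proteins Tibble of proteome records (`id`, `species`, `seq`).
#' @param queries Tibble of family query sequences (`family`, `id`, `seq`).
#' @param seed_alignments Named list of seed alignments for the domain
#'   models, or pre-built calibrated models via `models`.
#' @param genomes Optional tibble (`species`, `protein_id`, `dna`) of
#'   genomic sequence for (typically truncated) gene predictions.
#' @param family_db Optional reciprocal-search database (`family`, `id`,
#'   `seq`) including decoy families; defaults to `queries`.
#' @param models Optional pre-built calibrated model list (overrides
#'   `seed_alignments`).
#' @param scheme A [scoring_scheme()].
#' @param homology_threshold,domain_threshold Strict E-value cutoffs.
#' @param margin Specificity margin for [scan_domains()].
#' @param calibration_seed Seed for E-value and model calibration.
#' @param augment Run one query-augmentation pass (default TRUE).
#' @param species_order,groups Passed to [build_matrix()].
#' @return An `oxog_calls` object: list with `calls` (tibble of candidate
#'   calls), `matrix` (`pa_matrix`), `extensions`, `models`, `calibration`.
#' @export
call_presence_absence <- function(proteins, queries, seed_alignments = NULL,
                                  genomes = NULL, family_db = NULL,
                                  models = NULL,
                                  scheme = scoring_scheme(),
                                  homology_threshold = 1e-20,
                                  domain_threshold = 1e-5, margin = 0,
                                  calibration_seed = 1, augment = TRUE,
                                  species_order = NULL, groups = NULL) {
  if (is.null(models)) {
    if (is.null(seed_alignments)) {
      abort("either seed_alignments or models must be supplied")
    }
    models <- build_domain_models(seed_alignments, seed = calibration_seed)
  }
  if (is.null(family_db)) family_db <- queries
  calibration <- calibrate_evalue(scheme, seed = calibration_seed)
  families <- unique(queries$family)
  species <- unique(proteins$species)
  if (is.null(species_order)) species_order <- sort(species)

  seq_of <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(proteins))) {
    assign(proteins$id[i], proteins$seq[i], envir = seq_of)
  }
  scan_cache <- new.env(parent = emptyenv())
  scan_protein <- function(pid) {
    if (exists(pid, envir = scan_cache, inherits = FALSE)) {
      return(get(pid, envir = scan_cache))
    }
    hits <- scan_domains(tibble(id = pid, seq = get(pid, envir = seq_of)),
                         models, domain_threshold, margin)
    assign(pid, hits, envir = scan_cache)
    hits
  }

  search_family <- function(sp, fam, extra_queries = NULL) {
    proteome <- proteins |> filter(.data$species == sp)
    qs <- queries |> filter(.data$family == fam)
    if (!is.null(extra_queries)) qs <- bind_rows(qs, extra_queries)
    hits <- purrr::map2(qs$id, qs$seq, function(qid, qseq) {
      search_proteome(proteome, qseq, scheme, calibration,
                      homology_threshold, query_id = qid)
    })
    bind_rows(hits)
  }

  extensions <- list()
  classify_cell <- function(sp, fam, hits) {
    cands <- unique(hits$subject_id)
    ref <- queries$seq[queries$family == fam][1]
    for (pid in cands) {
      dh <- scan_protein(pid)
      req <- required_domains()[[fam]]
      have <- dh |>
        filter(.data$model %in% req, .data$specificity == "specific",
               .data$e_value < domain_threshold)
      if (!all(req %in% have$model) && !is.null(genomes)) {
        g <- genomes |> filter(.data$protein_id == pid)
        if (nrow(g) == 1) {
          ext <- extend_truncated(list(id = pid, seq = get(pid, envir = seq_of)),
                                  g$dna[1], ref, scheme)
          if (ext$provenance == "extended") {
            assign(pid, ext$seq, envir = seq_of)
            if (exists(pid, envir = scan_cache, inherits = FALSE)) {
              rm(list = pid, envir = scan_cache)
            }
            extensions[[pid]] <<- ext
          }
        }
      }
    }
    domain_hits <- bind_rows(purrr::map(cands, scan_protein))
    reciprocal <- bind_rows(purrr::map(cands, function(pid) {
      rc <- reciprocal_check(family_db, get(pid, envir = seq_of), fam,
                             scheme, calibration)
      rc$protein_id <- pid
      rc
    }))
    classify_candidate(hits, domain_hits, reciprocal, sp, fam,
                       homology_threshold = homology_threshold,
                       domain_threshold = domain_threshold)
  }

  cells <- tidyr::expand_grid(species = species_order, family = families)
  calls <- purrr::pmap(cells, function(species, family) {
    classify_cell(species, family, search_family(species, family))
  })
  calls <- bind_rows(calls)

  if (augment) {
    found <- calls |> filter(.data$verdict == "present")
    extra <- purrr::map(families, function(fam) {
      ids <- found$protein_id[found$family == fam]
      ids <- head(ids, 2)
      if (length(ids) == 0) return(NULL)
      tibble(family = fam, id = paste0("aug_", ids),
             seq = vapply(ids, function(p) get(p, envir = seq_of),
                          character(1)))
    })
    names(extra) <- families
    todo <- calls |> filter(.data$verdict != "present")
    for (i in seq_len(nrow(todo))) {
      fam <- todo$family[i]; sp <- todo$species[i]
      if (is.null(extra[[fam]])) next
      hits <- search_family(sp, fam, extra[[fam]])
      if (nrow(hits) == 0) next
      redo <- classify_cell(sp, fam, hits)
      calls[calls$species == sp & calls$family == fam, ] <- redo
    }
  }

  mat <- build_matrix(calls, species_order, families, groups)
  structure(
    list(calls = calls, matrix = mat,
         extensions = bind_rows(extensions),
         models = models, calibration = calibration),
    class = "oxog_calls"
  )
}

#' @export
print.oxog_calls <- function(x, ...) {
  n_present <- sum(x$calls$verdict == "present")
  cat("<oxog_calls>", nrow(x$calls), "cells,", n_present, "present,",
      sum(x$calls$verdict == "rejected"), "rejected,",
      sum(x$calls$verdict == "absent"), "absent\n")
  print(x$matrix)
  invisible(x)
}

#' Run the whole analysis on a simulated dataset
#'
#' Convenience wrapper chaining [call_presence_absence()] and [map_losses()]
#' on a [simulate_oxog_dataset()] object.
#'
#' @param sim An `oxog_simulation`.
#' @param ... Passed to [call_presence_absence()].
#' @return List with `calls` (`oxog_calls`), `losses` (from [map_losses()]).
#' @export
run_oxog_pipeline <- function(sim, ...) {
  res <- call_presence_absence(
    sim$proteins, sim$queries, sim$seed_alignments,
    genomes = sim$genomes, family_db = sim$family_db,
    species_order = sim$tree$tip.label, ...
  )
  losses <- map_losses(res$matrix, sim$tree)
  list(calls = res, losses = losses)
}
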