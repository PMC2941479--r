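#' Build a position-specific scoring model from a seed alignment
#'
#' Column counts are converted to background-relative log-odds with Dirichlet
#' pseudocounts:
#' `log_odds[c, r] = log(((count + pc * bg_r) / (n_c + pc)) / bg_r)`,
#' where `n_c` is the number of residues observed in column c. Columns that
#' are entirely gaps are dropped with a warning; partially gapped columns are
#' kept, with counts taken over residues only.
#'
#' @param seed_alignment Data frame with columns `id` and `aseq` (equal-length
#'   gapped rows), or a character vector of rows.
#' @param name Model name (e.g. `"Endo3c"`).
#' @param pseudocount Total pseudocount mass (default 5).
#' @param bg Background frequencies.
#' @param similar_to Names of models sharing a superfamily with this one
#'   (e.g. Endo3c and Nth are mutual relatives); used by [scan_domains()] for
#'   specific-versus-similar labelling.
#' @return An object of class `domain_model`.
#' @export
build_model <- function(seed_alignment, name, pseudocount = 5,
                        bg = aa_background(), similar_to = character()) {
  rows <- if (is.data.frame(seed_alignment)) seed_alignment$aseq else seed_alignment
  if (length(rows) == 0) abort("seed alignment is empty")
  if (length(unique(nchar(rows))) != 1) abort("seed rows have unequal lengths")
  if (pseudocount <= 0) abort("pseudocount must be positive")
  aa <- aa_alphabet()
  chars <- do.call(rbind, strsplit(toupper(rows), ""))
  keep <- colSums(chars != "-") > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d all-gap column(s) from seed alignment of %s",
                 sum(!keep), name))
    chars <- chars[, keep, drop = FALSE]
  }
  L <- ncol(chars)
  log_odds <- matrix(0, L, 20, dimnames = list(NULL, aa))
  consensus <- character(L)
  for (cidx in seq_len(L)) {
    col <- chars[, cidx]
    col <- col[col != "-"]
    if (!all(col %in% aa)) abort("non-standard residue in seed alignment")
    counts <- table(factor(col, levels = aa))
    n_c <- length(col)
    p <- (as.numeric(counts) + pseudocount * bg) / (n_c + pseudocount)
    log_odds[cidx, ] <- log(p / bg)
    consensus[cidx] <- aa[which.max(log_odds[cidx, ])]
  }
  structure(
    list(name = name, length = L, log_odds = log_odds,
         similar_to = similar_to, consensus = paste(consensus, collapse = ""),
         pseudocount = pseudocount, n_seqs = length(rows),
         calibration = NULL),
    class = "domain_model"
  )
}

#' @export
print.domain_model <- function(x, ...) {
  cat("<domain_model>", x$name, "- length", x$length, "from", x$n_seqs,
      "seed sequence(s);",
      if (is.null(x$calibration)) "uncalibrated" else "calibrated", "\n")
  invisible(x)
}

#' Calibrate the E-value null of a domain model
#'
#' Scans `n_shuffles` random sequences of background composition and fits a
#' Gumbel law (method of moments) to the per-sequence maximum window score.
#' E-values for real scans are scaled linearly by the number of windows
#' examined relative to the calibration sequence.
#'
#' @param model A [build_model()] object.
#' @param bg Background frequencies.
#' @param n_shuffles Number of null sequences (default 1000).
#' @param seq_len Length of each null sequence (default 300).
#' @param seed RNG seed.
#' @return The model with a `calibration` element (`mu`, `beta`,
#'   `n_windows_cal`).
#' @export
calibrate_model <- function(model, bg = aa_background(), n_shuffles = 1000,
                            seq_len = 300, seed = 1) {
  if (seq_len < model$length + 10) seq_len <- model$length + 10
  bg <- bg / sum(bg)
  maxima <- withr::with_seed(seed, {
    cpp_pssm_null_max(seq_len, model$log_odds, cumsum(bg), n_shuffles)
  })
  beta <- sd(maxima) * sqrt(6) / pi
  mu <- mean(maxima) - 0.5772156649 * beta
  model$calibration <- list(mu = mu, beta = beta,
                            n_windows_cal = seq_len - model$length + 1,
                            n_shuffles = n_shuffles, seed = seed)
  model
}

# E-value of a window score for a calibrated model scanned over n_windows.
model_evalue <- function(model, score, n_windows) {
  cal <- model$calibration
  if (is.null(cal)) abort("model is not calibrated; run calibrate_model()")
  log_e <- -(score - cal$mu) / cal$beta + log(n_windows / cal$n_windows_cal)
  pmax(exp(pmax(log_e, -690)), 1e-300)
}

#' Scan proteins for domain-model hits
#'
#' Slides each calibrated model along each protein (ungapped windows) and
#' keeps the best window per model when its E-value is strictly below the
#' threshold. A hit is labelled `"specific"` when its model outscores every
#' related (`similar_to`) model on overlapping windows by more than `margin`,
#' and `"similar-only"` otherwise — the specific-versus-similar distinction
#' used to reject decoy relatives such as Nth.
#'
#' @param proteins Data frame with columns `id` and `seq`.
#' @param models List of calibrated [build_model()] objects.
#' @param threshold E-value cutoff (default `1e-5`, strict `<`).
#' @param margin Score margin a model must exceed its relatives by to count
#'   as specific (default 0: strictly greater wins).
#' @return Tibble of hits: `protein_id`, `model`, `start`, `end` (0-based
#'   half-open span), `score`, `e_value`, `specificity`.
#' @export
scan_domains <- function(proteins, models, threshold = 1e-5, margin = 0) {
  stopifnot(all(c("id", "seq") %in% names(proteins)))
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, function(m) m$name, character(1))
  }
  models <- models[sort(names(models))] # label invariance to supply order
  out <- vector("list", 0)
  for (i in seq_len(nrow(proteins))) {
    codes <- encode_seq(proteins$seq[i], "wildcard")
    n <- length(codes)
    window_scores <- lapply(models, function(m) {
      if (n < m$length) return(NULL)
      cpp_pssm_scan(codes, m$log_odds)
    })
    for (mn in names(models)) {
      ws <- window_scores[[mn]]
      if (is.null(ws)) next
      m <- models[[mn]]
      w <- which.max(ws)
      score <- ws[w]
      e <- model_evalue(m, score, length(ws))
      if (!(e < threshold)) next
      start <- w - 1L
      end <- start + m$length
      # best overlapping-window score of each related model
      sim_best <- -Inf
      for (sn in intersect(m$similar_to, names(models))) {
        ws2 <- window_scores[[sn]]
        if (is.null(ws2)) next
        L2 <- models[[sn]]$length
        wmin <- max(1L, start - L2 + 2L)
        wmax <- min(length(ws2), end)
        if (wmin <= wmax) sim_best <- max(sim_best, max(ws2[wmin:wmax]))
      }
      specificity <- if (score - sim_best > margin) "specific" else "similar-only"
      out[[length(out) + 1]] <- tibble(
        protein_id = proteins$id[i], model = mn,
        start = start, end = end, score = score, e_value = e,
        specificity = specificity
      )
    }
  }
  if (length(out) == 0) return(empty_domain_hits())
  bind_rows(out)
}

empty_domain_hits <- function() {
  tibble(protein_id = character(), model = character(), start = integer(),
         end = integer(), score = numeric(), e_value = numeric(),
         specificity = character())
}
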