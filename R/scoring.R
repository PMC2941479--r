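#' The 20-letter amino-acid alphabet used throughout the package
#'
#' @return Character vector of the 20 standard residues, alphabetical.
#' @export
aa_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' Background amino-acid frequencies
#'
#' Robinson & Robinson residue frequencies, normalised to sum to one. Used as
#' the null composition for random-sequence generation, E-value calibration
#' and PSSM log-odds.
#'
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
aa_background <- function() {
  f <- c(
    A = 0.0787, C = 0.0192, D = 0.0536, E = 0.0629, F = 0.0405,
    G = 0.0738, H = 0.0219, I = 0.0526, K = 0.0595, L = 0.0911,
    M = 0.0215, N = 0.0448, P = 0.0517, Q = 0.0426, R = 0.0512,
    S = 0.0711, T = 0.0584, V = 0.0644, W = 0.0130, Y = 0.0321
  )
  f[aa_alphabet()] / sum(f)
}

#' Construct a protein scoring scheme
#'
#' Bundles a symmetric 20x20 substitution matrix with affine gap penalties.
#' A gap of length k costs `gap_open + k * gap_extend` (both non-positive).
#' The default matrix is BLOSUM62 (from Biostrings), restricted to the 20
#' standard residues, with gap open -11 and extend -1; the original study
#' does not record its search parameters, so these are configurable defaults.
#'
#' @param matrix A 20x20 (or larger, it is subset) named substitution matrix,
#'   or the string `"BLOSUM62"`.
#' @param gap_open,gap_extend Non-positive affine gap penalties.
#' @param on_unknown What to do with residues outside the standard alphabet:
#'   `"reject"` (error, default) or `"wildcard"` (score 0 vs anything).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -11,
                           gap_extend = -1,
                           on_unknown = c("reject", "wildcard")) {
  on_unknown <- match.arg(on_unknown)
  aa <- aa_alphabet()
  if (is.character(matrix) && length(matrix) == 1) {
    if (matrix != "BLOSUM62") abort("only BLOSUM62 is bundled by name")
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    matrix <- env$BLOSUM62
  }
  if (!all(aa %in% rownames(matrix)) || !all(aa %in% colnames(matrix))) {
    abort("substitution matrix must cover the 20 standard residues")
  }
  S <- matrix[aa, aa]
  storage.mode(S) <- "double"
  if (!isTRUE(all.equal(S, t(S)))) abort("substitution matrix must be symmetric")
  if (gap_open > 0 || gap_extend > 0) abort("gap penalties must be <= 0")
  bg <- aa_background()
  exp_score <- as.numeric(t(bg) %*% S %*% bg)
  if (exp_score >= 0) {
    abort("expected score under background frequencies must be negative")
  }
  structure(
    list(S = S, gap_open = gap_open, gap_extend = gap_extend,
         alphabet = aa, on_unknown = on_unknown,
         expected_score = exp_score),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> 20x20 matrix, gap_open =", x$gap_open,
      ", gap_extend =", x$gap_extend,
      ", E[s] =", signif(x$expected_score, 3), "\n")
  invisible(x)
}

# Encode a protein string as 0-based alphabet codes; -1 for unknown when the
# scheme allows wildcards, error otherwise.
encode_seq <- function(seq, on_unknown = "reject") {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    abort("sequence must be a single non-empty string")
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, aa_alphabet()) - 1L
  if (anyNA(codes)) {
    if (identical(on_unknown, "reject")) {
      abort(paste0("unknown residue(s): ",
                   paste(unique(chars[is.na(codes)]), collapse = ", ")))
    }
    codes[is.na(codes)] <- -1L
  }
  codes
}

# Sample a random protein string from background frequencies.
random_protein <- function(n, bg = aa_background()) {
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}
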