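#' Tidy the candidate calls of a pipeline run
#'
#' @param x An `oxog_calls` object.
#' @param ... Unused.
#' @return Tibble with one row per (species, family) cell: `species`,
#'   `family`, `protein_id`, `verdict`, `rejection_reason`, `e_value`,
#'   `conflict`.
#' @export
tidy.oxog_calls <- function(x, ...) {
  x$calls |> select(-"evidence")
}

#' One-row summary of a pipeline run
#'
#' @param x An `oxog_calls` object.
#' @param ... Unused.
#' @return Tibble with `n_species`, `n_families`, `n_present`, `n_rejected`,
#'   `n_absent`, `n_extended`.
#' @export
glance.oxog_calls <- function(x, ...) {
  tibble(
    n_species = length(unique(x$calls$species)),
    n_families = length(unique(x$calls$family)),
    n_present = sum(x$calls$verdict == "present"),
    n_rejected = sum(x$calls$verdict == "rejected"),
    n_absent = sum(x$calls$verdict == "absent"),
    n_extended = nrow(x$extensions)
  )
}

#' Tidy a presence/absence matrix into long form
#'
#' @param x A `pa_matrix`.
#' @param ... Unused.
#' @return Long tibble: `species`, `group`, `family`, `present`.
#' @export
tidy.pa_matrix <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(cols = -c("species", "group"),
                        names_to = "family", values_to = "present")
}

#' Tidy a simulated dataset's truth tables into long form
#'
#' @param x An `oxog_simulation`.
#' @param ... Unused.
#' @return The truth presence table (`species`, `family`, `present`).
#' @export
tidy.oxog_simulation <- function(x, ...) {
  x$truth$presence
}
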