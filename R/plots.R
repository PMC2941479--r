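#' Plot a presence/absence matrix as a filled grid
#'
#' Grey tiles mark presence, white absence, mirroring the conventional
#' phyletic-profile figure; optional marks (e.g. asterisks for
#' insertion-bearing homologues) are drawn on cells.
#'
#' @param object A `pa_matrix`.
#' @param annotations Optional tibble (`species`, `family`, `mark`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_matrix <- function(object, annotations = NULL, ...) {
  long <- tidy.pa_matrix(object) |>
    mutate(species = factor(.data$species, levels = rev(object$species)),
           family = factor(.data$family,
                           levels = setdiff(names(object),
                                            c("species", "group"))))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$family,
                                          y = .data$species,
                                          fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey60",
                                          `FALSE` = "white"),
                               name = "present") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(annotations)) {
    p <- p + ggplot2::geom_text(
      data = annotations |> mutate(present = NA),
      ggplot2::aes(x = .data$family, y = .data$species,
                   label = .data$mark),
      inherit.aes = FALSE, vjust = 0.3
    )
  }
  p
}

#' Plot per-column clade/outgroup occupancy with insertion calls
#'
#' @param object Tibble of insertion calls from [call_insertions()].
#' @param msa The `protein_msa` the calls were made on.
#' @param clade The clade row ids used.
#' @param ... Unused.
#' @return A ggplot object showing occupancy tracks and shaded call spans.
#' @export
plot_insertions <- function(object, msa, clade, ...) {
  chars <- msa_char_matrix(msa)
  rownames(chars) <- msa$id
  out_ids <- setdiff(msa$id, clade)
  df <- tibble(
    column = rep(seq_len(ncol(chars)), 2),
    occupancy = c(colMeans(chars[clade, , drop = FALSE] != "-"),
                  colMeans(chars[out_ids, , drop = FALSE] != "-")),
    track = rep(c("clade", "outgroup"), each = ncol(chars))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column,
                                        y = .data$occupancy,
                                        colour = .data$track)) +
    ggplot2::geom_step() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "alignment column", y = "occupancy")
  if (nrow(object) > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = object$col_start + 0.5, xmax = object$col_end + 0.5,
      ymin = -0.02, ymax = 1.02, alpha = 0.2, fill = "gold"
    )
  }
  p
}

#' Plot a species tree with Dollo loss events on branches
#'
#' @param tree Rooted `ape::phylo` with node labels.
#' @param events Loss-event tibble from [dollo_map()] or
#'   [map_losses()]`$events`.
#' @param ... Unused.
#' @return A ggplot object: the tree with loss labels at the midpoint of
#'   each loss branch.
#' @export
plot_loss_tree <- function(tree, events, ...) {
  n_tip <- length(tree$tip.label)
  nn <- node_names(tree)
  # simple rectangular layout: x = cumulative depth, y = tip order
  depth <- ape::node.depth.edgelength(tree)
  y <- numeric(n_tip + tree$Nnode)
  y[seq_len(n_tip)] <- seq_len(n_tip)
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (p in unique(po$edge[, 1])) {
    y[p] <- mean(y[kids[[as.character(p)]]])
  }
  seg <- tibble(
    x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 2]],
    y = y[tree$edge[, 2]], yend = y[tree$edge[, 2]],
    child = nn[tree$edge[, 2]]
  )
  vert <- tibble(
    x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 1]],
    y = y[tree$edge[, 1]], yend = y[tree$edge[, 2]]
  )
  lab <- events |>
    mutate(x = (seg$x[match(.data$branch, seg$child)] +
                  seg$xend[match(.data$branch, seg$child)]) / 2,
           y = seg$y[match(.data$branch, seg$child)])
  tips <- tibble(x = depth[seq_len(n_tip)], y = y[seq_len(n_tip)],
                 label = tree$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = bind_rows(seg |> select(-"child"), vert),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.1, size = 3) +
    ggplot2::geom_label(data = lab,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$family),
                        size = 3, colour = "firebrick") +
    ggplot2::theme_void() +
    ggplot2::expand_limits(x = max(depth) * 1.15)
}
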