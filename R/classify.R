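#' Classify skeleton components into networks and individual mitochondria
#'
#' Applies the two-class morphometric filter: a component is a
#' \emph{mitochondrial network} iff it has more than one branch and at least
#' one junction; an \emph{individual mitochondrion} iff it has exactly one
#' branch, zero junctions and at least one endpoint. Everything else is
#' \emph{unclassified} with a reason code — in particular fully looped
#' components ("donuts", zero endpoints) and single-pixel "drops" are never
#' forced into either class (drops are individuals but carry the
#' `degenerate` flag). The partition is exhaustive and exclusive.
#'
#' @param graphs a `skeleton_graph` from [analyze_skeleton()].
#' @param components the `component_set` of the mask the skeleton was
#'   computed from (areas and aspect ratios are looked up per object).
#' @return A data.frame of class `mito_objects`, one row per skeleton
#'   component: `component_id` (id in `components`), `mito_class`
#'   (`network` / `individual` / `unclassified`), `reason`, `branch_count`,
#'   `junction_count`, `endpoint_count`, `area_um2`, `aspect_ratio`,
#'   `median_branch_len_um`, `total_branch_len_um`, `degenerate`; branch
#'   length lists are carried in the `branch_lengths_um` list-column.
#' @export
classify_objects <- function(graphs, components) {
  stopifnot(inherits(graphs, "skeleton_graph"),
            inherits(components, "component_set"))
  ncomp <- length(graphs$components)
  h <- nrow(components$labels)
  rows <- vector("list", ncomp)
  for (i in seq_len(ncomp)) {
    ce <- graphs$components[[i]]
    # map the skeleton component to its particle via any skeleton pixel
    comp_id <- components$labels[ce$pixel_idx[1]]
    if (comp_id == 0)
      stop("skeleton component ", i, " lies outside every labeled component")
    st <- components$stats[components$stats$component_id == comp_id, ]
    if (nrow(st) != 1)
      stop("component id ", comp_id, " not found in the component set")
    cls <- "unclassified"
    reason <- NA_character_
    if (ce$branch_count > 1 && ce$junction_count >= 1) {
      cls <- "network"
    } else if (ce$branch_count == 1 && ce$junction_count == 0 &&
               ce$endpoint_count >= 1) {
      cls <- "individual"
      if (ce$degenerate) reason <- "degenerate_single_pixel"
    } else if (ce$endpoint_count == 0) {
      reason <- "loop"
    } else {
      reason <- "ambiguous_topology"
    }
    rows[[i]] <- data.frame(
      component_id = comp_id,
      mito_class = cls,
      reason = reason,
      branch_count = ce$branch_count,
      junction_count = ce$junction_count,
      endpoint_count = ce$endpoint_count,
      area_um2 = st$area_um2,
      aspect_ratio = st$aspect_ratio,
      median_branch_len_um = stats::median(ce$branch_lengths_um),
      total_branch_len_um = sum(ce$branch_lengths_um),
      degenerate = ce$degenerate,
      stringsAsFactors = FALSE)
    rows[[i]]$branch_lengths_um <- list(ce$branch_lengths_um)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(component_id = integer(0), mito_class = character(0),
                      reason = character(0), branch_count = integer(0),
                      junction_count = integer(0), endpoint_count = integer(0),
                      area_um2 = numeric(0), aspect_ratio = numeric(0),
                      median_branch_len_um = numeric(0),
                      total_branch_len_um = numeric(0), degenerate = logical(0))
  class(out) <- c("mito_objects", "data.frame")
  out
}

#' Per-cell morphometric parameters
#'
#' Aggregates classified objects of one cell into the per-cell parameter
#' set: total footprint, the median branch length within networks, the
#' count ratio of individual mitochondria to networks, the median length of
#' individual mitochondria, the connectivity (mean number of junctions per
#' network), and the median aspect ratio of individual mitochondria.
#' Within-cell length distributions are skewed, so per-cell aggregation
#' uses medians. Empty denominators or empty object sets yield `NA`,
#' never silent zeros.
#'
#' @param objects a `mito_objects` table from [classify_objects()].
#' @param footprint_um2 the cell footprint from [mitochondrial_footprint()].
#' @param cell_id identifier recorded in the output (default "cell").
#' @return An object of class `mito_cell`: a one-row data.frame with
#'   `cell_id`, `footprint_um2`, `median_network_branch_len_um`,
#'   `individual_to_network_ratio`, `median_individual_len_um`,
#'   `mean_junctions_per_network`, `median_individual_aspect_ratio`,
#'   `n_networks`, `n_individuals`, `n_unclassified`.
#' @export
cell_morphometrics <- function(objects, footprint_um2, cell_id = "cell") {
  stopifnot(inherits(objects, "mito_objects"))
  if (!is.numeric(footprint_um2) || footprint_um2 < 0)
    stop("`footprint_um2` must be a non-negative number")
  net <- objects[objects$mito_class == "network", ]
  ind <- objects[objects$mito_class == "individual", ]
  n_net <- nrow(net); n_ind <- nrow(ind)
  n_uncl <- sum(objects$mito_class == "unclassified")
  net_branches <- unlist(net$branch_lengths_um)
  out <- data.frame(
    cell_id = cell_id,
    footprint_um2 = footprint_um2,
    median_network_branch_len_um =
      if (n_net > 0) stats::median(net_branches) else NA_real_,
    individual_to_network_ratio =
      if (n_net > 0) n_ind / n_net else NA_real_,
    median_individual_len_um =
      if (n_ind > 0) stats::median(unlist(ind$branch_lengths_um)) else NA_real_,
    mean_junctions_per_network =
      if (n_net > 0) sum(net$junction_count) / n_net else NA_real_,
    median_individual_aspect_ratio =
      if (n_ind > 0) stats::median(ind$aspect_ratio) else NA_real_,
    n_networks = n_net,
    n_individuals = n_ind,
    n_unclassified = n_uncl,
    stringsAsFactors = FALSE)
  class(out) <- c("mito_cell", "data.frame")
  out
}

#' @export
print.mito_cell <- function(x, ...) {
  cat(sprintf("<mito_cell> %s\n", x$cell_id))
  cat(sprintf("  footprint            %8.2f um2\n", x$footprint_um2))
  cat(sprintf("  network branch len   %8.3f um (median)\n",
              x$median_network_branch_len_um))
  cat(sprintf("  individual : network %8.2f (%d : %d, %d unclassified)\n",
              x$individual_to_network_ratio, x$n_individuals, x$n_networks,
              x$n_unclassified))
  cat(sprintf("  individual length    %8.3f um (median)\n",
              x$median_individual_len_um))
  cat(sprintf("  connectivity         %8.2f junctions/network\n",
              x$mean_junctions_per_network))
  cat(sprintf("  individual aspect    %8.2f (median)\n",
              x$median_individual_aspect_ratio))
  invisible(x)
}

#' Full single-cell morphometry from a micrograph
#'
#' Convenience wrapper running the fixed chain: preprocess (rolling ball,
#' median, CLAHE, Otsu), particle analysis, skeletonization, skeleton-graph
#' analysis, classification, and per-cell aggregation.
#'
#' @param img a [micrograph].
#' @param cell_id identifier for the output row.
#' @param preprocess named list of [preprocess_image()] parameters.
#' @param prune_px spur-pruning threshold passed to [prune_skeleton()]
#'   (default 6 px; 0 disables pruning).
#' @return A list of class `cell_analysis`: `cell` (the [cell_morphometrics()]
#'   row), `objects` (the per-object table), `mask`, `skeleton`, `graphs`,
#'   `components`.
#' @examples
#' sp <- scene_spec(n_networks = 1, n_individuals = 3, seed = 7)
#' sc <- generate_scene(sp)
#' res <- analyze_cell(sc$image, cell_id = "demo")
#' res$cell
#' @export
analyze_cell <- function(img, cell_id = "cell", preprocess = list(),
                         prune_px = 6) {
  stopifnot(inherits(img, "micrograph"))
  mask <- do.call(preprocess_image, c(list(img), preprocess))
  comps <- label_components(mask)
  skel <- prune_skeleton(skeletonize(mask), min_px = prune_px)
  graphs <- analyze_skeleton(skel, mask = mask)
  objects <- classify_objects(graphs, comps)
  cell <- cell_morphometrics(objects, mitochondrial_footprint(comps),
                             cell_id = cell_id)
  structure(list(cell = cell, objects = objects, mask = mask,
                 skeleton = skel, graphs = graphs, components = comps),
            class = "cell_analysis")
}

#' @export
print.cell_analysis <- function(x, ...) {
  print(x$cell)
  invisible(x)
}
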