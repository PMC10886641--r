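#' Label connected components of a binary mask
#'
#' 8-connected component labeling ("particle analysis"). For every component
#' the area is reported in pixels and square microns, together with the
#' lengths of the major and minor axes of the intensity-equivalent ellipse
#' (from second-order central moments) and their ratio.
#'
#' For a component whose pixels are perfectly collinear (including single
#' pixels) the minor axis is degenerate; the aspect ratio is then reported
#' from axes floored at one pixel width, so a single pixel has aspect 1.
#'
#' @param mask a [binary_mask].
#' @return An object of class `component_set`: a list with
#'   \describe{
#'     \item{labels}{integer matrix, 0 = background, 1..N component ids}
#'     \item{stats}{data.frame with one row per component: `component_id`,
#'       `area_px`, `area_um2`, `ellipse_major_px`, `ellipse_minor_px`,
#'       `aspect_ratio`}
#'     \item{pixels_per_micron}{the calibration}
#'   }
#'   An empty mask yields an empty (zero-row) component set.
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  ppm <- ppm_of(mask)
  labels <- label_8connected(unclass(mask))
  n <- max(labels)
  if (n == 0) {
    stats <- data.frame(component_id = integer(0), area_px = integer(0),
                        area_um2 = numeric(0), ellipse_major_px = numeric(0),
                        ellipse_minor_px = numeric(0), aspect_ratio = numeric(0))
  } else {
    idx <- which(labels > 0)
    lab <- labels[idx]
    rr <- (idx - 1) %% nrow(labels) + 1
    cc <- (idx - 1) %/% nrow(labels) + 1
    area <- tabulate(lab, nbins = n)
    mr <- tapply(rr, lab, mean)
    mc <- tapply(cc, lab, mean)
    # second-order central moments (+1/12 pixel-integration term keeps a
    # single pixel from collapsing to a zero-size ellipse)
    stats <- data.frame(component_id = seq_len(n), area_px = area)
    mu20 <- tapply((rr - mr[lab])^2, lab, mean) + 1 / 12
    mu02 <- tapply((cc - mc[lab])^2, lab, mean) + 1 / 12
    mu11 <- tapply((rr - mr[lab]) * (cc - mc[lab]), lab, mean)
    tr <- mu20 + mu02
    det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
    l1 <- (tr + det) / 2
    l2 <- pmax((tr - det) / 2, 1 / 12)
    stats$ellipse_major_px <- as.numeric(4 * sqrt(l1))
    stats$ellipse_minor_px <- as.numeric(4 * sqrt(l2))
    stats$aspect_ratio <- stats$ellipse_major_px / stats$ellipse_minor_px
    stats$area_um2 <- stats$area_px / ppm^2
    stats <- stats[, c("component_id", "area_px", "area_um2",
                       "ellipse_major_px", "ellipse_minor_px", "aspect_ratio")]
    rownames(stats) <- NULL
  }
  structure(list(labels = labels, stats = stats, pixels_per_micron = ppm),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, %.3g px/um\n",
              nrow(x$stats), x$pixels_per_micron))
  if (nrow(x$stats) > 0)
    cat(sprintf("  total area %.3f um2\n", sum(x$stats$area_um2)))
  invisible(x)
}

# 8-connected labeling via the adjacency graph of foreground pixels.
label_8connected <- function(m) {
  h <- nrow(m); w <- ncol(m)
  labels <- matrix(0L, h, w)
  idx <- which(m)
  if (length(idx) == 0) return(labels)
  pos <- matrix(0L, h, w)
  pos[idx] <- seq_along(idx)
  rr <- (idx - 1) %% h + 1
  cc <- (idx - 1) %/% h + 1
  edges <- NULL
  # forward half of the 8-neighbourhood is enough for an undirected graph
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    if (!any(ok)) next
    nb <- pos[cbind(r2[ok], c2[ok])]
    has <- nb > 0
    if (any(has))
      edges <- rbind(edges, cbind(pos[cbind(rr[ok], cc[ok])][has], nb[has]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber in first-pixel (column-major scan) order
  first <- tapply(seq_along(idx), memb, min)
  ord <- rank(first)
  labels[idx] <- as.integer(ord[memb])
  labels
}

#' Total mitochondrial footprint
#'
#' The sum of all component areas, i.e. the total mitochondria-positive area
#' of the cell in square microns (foreground pixel count / ppm^2).
#'
#' @param components a `component_set` from [label_components()].
#' @return Footprint in um^2 (0 for an empty mask).
#' @export
mitochondrial_footprint <- function(components) {
  stopifnot(inherits(components, "component_set"))
  sum(components$stats$area_um2)
}
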