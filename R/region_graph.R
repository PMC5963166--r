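#' Region contiguity graphs
#'
#' A `region_graph` holds an ordered set of region identifiers together with
#' a symmetric binary neighborhood matrix `W` (`w_ij = 1` when regions `i`
#' and `j` are neighbors, zero diagonal). The ordering of `region_ids` fixes
#' the row/column order of every matrix and vector used downstream — the
#' CAR prior, Moran's I and the sampler all consume this order.
#'
#' @param region_ids character vector of unique region identifiers, in the
#'   order that defines all downstream row order.
#' @param W symmetric binary matrix with zero diagonal, `length(region_ids)`
#'   rows/columns.
#' @param warn_isolated warn when some region has no neighbors. Isolated
#'   regions are permitted: under the Leroux prior their conditional reduces
#'   to `N(0, tau2 / (1 - rho))`, which is proper for `rho < 1`.
#' @return An object of class `region_graph`: list with `region_ids`, `W`
#'   (0/1 matrix, dimnames set to the ids), and `degrees`.
#' @seealso [graph_from_edgelist()], [graph_from_polygons()],
#'   [connected_components()]
#' @export
region_graph <- function(region_ids, W, warn_isolated = TRUE) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) {
    stop("duplicate region ids: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  }
  n <- length(region_ids)
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (!all(dim(W) == c(n, n))) stop("W must be ", n, " x ", n)
  if (!all(W %in% c(0, 1))) stop("W entries must be 0 or 1")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal (no self-neighbors)")
  if (!isTRUE(all.equal(W, t(W), check.attributes = FALSE))) {
    stop("W must be symmetric")
  }
  dimnames(W) <- list(region_ids, region_ids)
  degrees <- rowSums(W)
  if (warn_isolated && any(degrees == 0)) {
    warning(sum(degrees == 0), " isolated region(s) (no neighbors): ",
            paste(head(region_ids[degrees == 0], 5L), collapse = ", "),
            call. = FALSE)
  }
  structure(
    list(region_ids = region_ids, W = W, degrees = degrees),
    class = "region_graph"
  )
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", length(x$region_ids), "regions,", n_edges(x),
      "edges, mean degree", round(mean(x$degrees), 2), "\n")
  invisible(x)
}

#' Number of undirected edges in a region graph
#' @param graph a [region_graph()].
#' @return integer edge count.
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  as.integer(sum(graph$W) / 2)
}

#' Edge list of a region graph
#' @param graph a [region_graph()].
#' @return data.frame with character columns `id_from`, `id_to`, one row per
#'   undirected edge (`id_from` earlier in the region order).
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  idx <- which(upper.tri(graph$W) & graph$W == 1, arr.ind = TRUE)
  data.frame(
    id_from = graph$region_ids[idx[, 1L]],
    id_to = graph$region_ids[idx[, 2L]],
    stringsAsFactors = FALSE
  )
}

#' Build a region graph from an edge list
#'
#' Neighborhood ingestion route for adjacency supplied as id pairs.
#' Duplicate and reversed pairs collapse to a single undirected edge.
#'
#' @param region_ids ordered character vector of all region ids (regions
#'   with no edges are allowed and become isolated).
#' @param edges two-column matrix or data.frame of id pairs; may have zero
#'   rows.
#' @inheritParams region_graph
#' @return a [region_graph()].
#' @export
graph_from_edgelist <- function(region_ids, edges, warn_isolated = TRUE) {
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  W <- matrix(0, n, n)
  if (length(edges) > 0 && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    from <- as.character(edges[, 1L]); to <- as.character(edges[, 2L])
    unknown <- setdiff(c(from, to), region_ids)
    if (length(unknown)) {
      stop("edge endpoint(s) not in region_ids: ",
           paste(unique(unknown), collapse = ", "))
    }
    if (any(from == to)) {
      stop("self-edge(s) not allowed: ",
           paste(unique(from[from == to]), collapse = ", "))
    }
    i <- match(from, region_ids); j <- match(to, region_ids)
    W[cbind(i, j)] <- 1
    W[cbind(j, i)] <- 1
  }
  region_graph(region_ids, W, warn_isolated = warn_isolated)
}

#' Read a region graph from an edge-list CSV
#'
#' @param path CSV file with header columns `id_from`, `id_to`.
#' @param region_ids optional ordered id vector; defaults to the sorted
#'   unique endpoints found in the file.
#' @inheritParams region_graph
#' @return a [region_graph()].
#' @export
graph_from_edge_csv <- function(path, region_ids = NULL, warn_isolated = TRUE) {
  edges <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id_from", "id_to") %in% names(edges))) {
    stop("edge CSV must have columns id_from, id_to")
  }
  if (is.null(region_ids)) {
    region_ids <- sort(unique(c(edges$id_from, edges$id_to)))
  }
  graph_from_edgelist(region_ids, edges[, c("id_from", "id_to")],
                      warn_isolated = warn_isolated)
}

#' Write a region graph as an edge-list CSV
#'
#' Provenance export: the adjacency actually used can be re-ingested with
#' [graph_from_edge_csv()].
#'
#' @param graph a [region_graph()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(graph, path) {
  write.csv(graph_edges(graph), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Connected components of a region graph
#'
#' Partitions the regions into maximal connected sets; isolated regions
#' (islands) appear as singletons. Useful for checking whether an adjacency
#' file leaves parts of the map disconnected before fitting.
#'
#' @param graph a [region_graph()].
#' @return list of character vectors of region ids, one per component,
#'   ordered by first appearance in the region order.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$W, mode = "undirected")
  comp <- igraph::components(g)
  unname(split(graph$region_ids, comp$membership))
}

#' Build a region graph from GeoJSON polygons by contiguity
#'
#' Reads a GeoJSON `FeatureCollection` with one (multi)polygon feature per
#' region and derives binary contiguity: under the `"queen"` rule two
#' regions are neighbors when their boundaries share at least one point
#' (corner touching counts); under `"rook"` they must share a boundary
#' segment of positive length. The point/segment predicates are exact on
#' the stored coordinates — no snapping or tolerance — so dirty geometries
#' must be cleaned upstream.
#'
#' @param polygon_file path to a GeoJSON FeatureCollection.
#' @param id_field name of the feature property holding the region id.
#' @param rule contiguity rule, `"queen"` (default) or `"rook"`.
#' @inheritParams region_graph
#' @return a [region_graph()], regions ordered as the features appear.
#' @export
graph_from_polygons <- function(polygon_file, id_field = "id",
                                rule = c("queen", "rook"),
                                warn_isolated = TRUE) {
  rule <- match.arg(rule)
  gj <- tryCatch(jsonlite::read_json(polygon_file),
                 error = function(e) stop("unreadable geometry file: ",
                                          conditionMessage(e)))
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  if (length(feats) == 0L) stop("no features in ", polygon_file)
  ids <- vapply(feats, function(f) {
    v <- f$properties[[id_field]]
    if (is.null(v)) stop("feature missing id property '", id_field, "'")
    as.character(v)
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate region ids in ", polygon_file, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  segs <- lapply(feats, function(f) polygon_segments(f$geometry))
  n <- length(ids)
  bbox <- t(vapply(segs, function(s) {
    c(min(s[, 1], s[, 3]), max(s[, 1], s[, 3]),
      min(s[, 2], s[, 4]), max(s[, 2], s[, 4]))
  }, numeric(4)))
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # bounding-box prefilter (closed boxes: touching boxes still compared)
      if (bbox[i, 2] < bbox[j, 1] || bbox[j, 2] < bbox[i, 1] ||
          bbox[i, 4] < bbox[j, 3] || bbox[j, 4] < bbox[i, 3]) next
      if (boundaries_touch(segs[[i]], segs[[j]], rook = (rule == "rook"))) {
        W[i, j] <- W[j, i] <- 1
      }
    }
  }
  region_graph(ids, W, warn_isolated = warn_isolated)
}

# Flatten a GeoJSON Polygon/MultiPolygon geometry into a segment matrix
# (x1, y1, x2, y2), one row per boundary segment of every ring.
polygon_segments <- function(geometry) {
  if (is.null(geometry$type)) stop("feature has no geometry")
  rings <- switch(geometry$type,
    Polygon = geometry$coordinates,
    MultiPolygon = do.call(c, geometry$coordinates),
    stop("unsupported geometry type: ", geometry$type)
  )
  out <- lapply(rings, function(ring) {
    pts <- t(vapply(ring, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]])),
                    numeric(2)))
    k <- nrow(pts)
    if (k < 2L) stop("degenerate ring with fewer than 2 points")
    # rings are closed (last point repeats the first); drop zero-length segs
    seg <- cbind(pts[-k, 1], pts[-k, 2], pts[-1, 1], pts[-1, 2])
    seg[seg[, 1] != seg[, 3] | seg[, 2] != seg[, 4], , drop = FALSE]
  })
  do.call(rbind, out)
}

# Do the boundaries described by two segment sets share a point (queen) or
# a positive-length collinear overlap (rook)?
boundaries_touch <- function(sa, sb, rook = FALSE) {
  for (a in seq_len(nrow(sa))) {
    for (b in seq_len(nrow(sb))) {
      hit <- segment_relation(sa[a, 1], sa[a, 2], sa[a, 3], sa[a, 4],
                              sb[b, 1], sb[b, 2], sb[b, 3], sb[b, 4])
      if (rook) {
        if (hit == 2L) return(TRUE)
      } else if (hit > 0L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Relation of segments p1p2 and p3p4: 0 disjoint, 1 share >= 1 point,
# 2 collinear overlap of positive length.
segment_relation <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross(x3, y3, x4, y4, x1, y1)
  d2 <- cross(x3, y3, x4, y4, x2, y2)
  d3 <- cross(x1, y1, x2, y2, x3, y3)
  d4 <- cross(x1, y1, x2, y2, x4, y4)
  if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) {
    # collinear: project on the dominant axis and compare intervals
    if (abs(x2 - x1) >= abs(y2 - y1)) {
      a <- sort(c(x1, x2)); b <- sort(c(x3, x4))
    } else {
      a <- sort(c(y1, y2)); b <- sort(c(y3, y4))
    }
    lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
    if (hi > lo) return(2L)
    if (hi == lo) return(1L)
    return(0L)
  }
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(1L)
  on_seg <- function(px, py, ax, ay, bx, by) {
    min(ax, bx) <= px && px <= max(ax, bx) &&
      min(ay, by) <= py && py <= max(ay, by)
  }
  if (d1 == 0 && on_seg(x1, y1, x3, y3, x4, y4)) return(1L)
  if (d2 == 0 && on_seg(x2, y2, x3, y3, x4, y4)) return(1L)
  if (d3 == 0 && on_seg(x3, y3, x1, y1, x2, y2)) return(1L)
  if (d4 == 0 && on_seg(x4, y4, x1, y1, x2, y2)) return(1L)
  0L
}
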