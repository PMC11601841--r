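# Area geography: adjacency graphs from polygons, edge lists, and synthetic
# lattices.  Coordinates are treated as already-projected planar values;
# adjacency only needs topology, so no CRS handling is done here.

#' Construct an area adjacency graph
#'
#' Low-level constructor used by [adjacency_from_polygons()],
#' [adjacency_from_edgelist()] and [make_lattice()].  Most users never call it
#' directly.
#'
#' @param area_ids character vector of unique area identifiers (ZCTA codes or
#'   county FIPS).
#' @param edges two-column integer matrix of area indices, one row per
#'   undirected edge; may have zero rows.
#' @param area_names optional display names, recycled against `area_ids`.
#' @param polygons optional list (one element per area) of polygon parts; each
#'   part is a list of rings and each ring a closed two-column coordinate
#'   matrix, mirroring GeoJSON MultiPolygon nesting.
#' @return an object of class `area_graph` with elements `area_ids`,
#'   `area_names`, `edges` (canonical `i < j` rows), `nbr` (adjacency list),
#'   `component` (integer component label per area) and `polygons`.
#' @export
area_graph <- function(area_ids, edges, area_names = NULL, polygons = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    ar_stop("duplicate area ids: ", paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  }
  n <- length(area_ids)
  if (n == 0L) ar_stop("at least one area is required")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n)) ar_stop("edge index out of range")
    # canonicalize: i < j, drop self loops and duplicates
    self <- edges[, 1L] == edges[, 2L]
    if (any(self)) {
      ar_warn(sum(self), " self pair(s) dropped from adjacency")
      edges <- edges[!self, , drop = FALSE]
    }
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    dup <- duplicated(edges)
    if (any(dup)) edges <- edges[!dup, , drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  nbr <- rep(list(integer()), n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  nbr <- lapply(nbr, sort)
  if (!is.null(polygons)) {
    stopifnot(length(polygons) == n)
    if (any(vapply(polygons, function(p) length(p) == 0L, logical(1)))) {
      ar_stop("every area must have at least one polygon ring when polygons are given")
    }
  }
  g <- structure(list(
    area_ids = area_ids,
    area_names = if (is.null(area_names)) area_ids else rep_len(as.character(area_names), n),
    edges = edges,
    nbr = nbr,
    component = graph_components(nbr),
    polygons = polygons
  ), class = "area_graph")
  g
}

# Connected components by breadth-first search; labels are assigned in order
# of first appearance so they are stable under the stored area order.
#' @keywords internal
graph_components <- function(nbr) {
  n <- length(nbr)
  comp <- integer(n)
  label <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    label <- label + 1L
    queue <- s
    comp[s] <- label
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nbr[[v]]) if (comp[w] == 0L) {
        comp[w] <- label
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' @export
print.area_graph <- function(x, ...) {
  cat(sprintf("area_graph: %d areas, %d edges, %d component(s)%s\n",
              length(x$area_ids), nrow(x$edges), max(x$component),
              if (is.null(x$polygons)) "" else ", with polygons"))
  invisible(x)
}

#' Number of areas / edges in an area graph
#' @param graph an `area_graph`.
#' @return integer count.
#' @export
n_areas <- function(graph) length(graph$area_ids)

#' @rdname n_areas
#' @export
n_edges <- function(graph) nrow(graph$edges)

## ---------------------------------------------------------------------------
## polygon contiguity

# snap planar coordinates onto an integer grid so vertex identity is robust
# to last-bit float noise (tolerance is absolute, in coordinate units)
vertex_keys <- function(ring, snap = 1e-8) {
  paste(round(ring[, 1L] / snap), round(ring[, 2L] / snap))
}

ring_open <- function(ring) {
  # drop the closing vertex if the ring is stored closed
  k <- nrow(ring)
  if (k > 1L && all(ring[1L, ] == ring[k, ])) ring[-k, , drop = FALSE] else ring
}

# proper segment crossing test used for self-intersection screening
segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4); o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

ring_self_intersects <- function(ring) {
  v <- ring_open(ring)
  k <- nrow(v)
  if (k < 4L) return(FALSE)
  idx <- cbind(seq_len(k), c(seq_len(k)[-1L], 1L))
  for (a in seq_len(k - 2L)) {
    for (b in (a + 2L):k) {
      if (a == 1L && b == k) next  # adjacent through closure
      if (segments_cross(v[idx[a, 1L], ], v[idx[a, 2L], ], v[idx[b, 1L], ], v[idx[b, 2L], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Build area adjacency from polygon contiguity
#'
#' Two areas are neighbors when their polygons touch: under the `"queen"` rule
#' sharing a single boundary point suffices (corner contact counts), under the
#' `"rook"` rule they must share a boundary segment of positive length.
#' Vertex identity is decided after snapping coordinates to an absolute
#' tolerance, so polygons must share boundary vertices (the usual situation
#' for tessellated administrative geographies).
#'
#' @param polygons list of per-area polygon geometry as in [area_graph()].
#' @param area_ids character ids, one per polygon entry.
#' @param rule `"queen"` (default) or `"rook"` contiguity.
#' @param area_names optional display names.
#' @param snap absolute snapping tolerance for vertex identity.
#' @return an [area_graph()].
#' @export
#' @examples
#' g <- make_lattice(2, 2, rule = "queen")
#' g2 <- adjacency_from_polygons(g$polygons, g$area_ids, rule = "queen")
#' identical(g$edges, g2$edges)
adjacency_from_polygons <- function(polygons, area_ids,
                                    rule = c("queen", "rook"),
                                    area_names = NULL, snap = 1e-8) {
  rule <- match.arg(rule)
  if (length(polygons) == 0L) ar_stop("empty geometry")
  stopifnot(length(polygons) == length(area_ids))
  n <- length(polygons)
  for (i in seq_len(n)) {
    for (part in polygons[[i]]) {
      for (ring in part) {
        if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L) {
          ar_stop("area ", area_ids[[i]], ": each ring must be a coordinate matrix with >= 3 vertices")
        }
        if (!all(is.finite(ring))) ar_stop("area ", area_ids[[i]], ": non-finite coordinates")
        if (ring_self_intersects(ring)) {
          ar_stop("area ", area_ids[[i]], ": self-intersecting polygon ring")
        }
      }
    }
  }
  # queen: shared snapped vertex; rook: shared snapped boundary segment
  key_areas <- new.env(parent = emptyenv())
  add <- function(key, i) {
    prev <- key_areas[[key]]
    if (is.null(prev)) assign(key, i, envir = key_areas)
    else if (!i %in% prev) assign(key, c(prev, i), envir = key_areas)
  }
  for (i in seq_len(n)) {
    for (part in polygons[[i]]) {
      for (ring in part) {
        v <- ring_open(ring)
        keys <- vertex_keys(v, snap)
        if (rule == "queen") {
          for (key in unique(keys)) add(key, i)
        } else {
          nxt <- c(keys[-1L], keys[1L])
          seg <- ifelse(keys < nxt, paste(keys, nxt, sep = "|"), paste(nxt, keys, sep = "|"))
          for (key in unique(seg)) add(key, i)
        }
      }
    }
  }
  pairs <- list()
  for (key in ls(key_areas)) {
    ids <- key_areas[[key]]
    if (length(ids) >= 2L) {
      cmb <- utils::combn(sort(ids), 2L)
      pairs[[length(pairs) + 1L]] <- t(cmb)
    }
  }
  edges <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(), ncol = 2L)
  area_graph(area_ids, edges, area_names = area_names, polygons = polygons)
}

#' Build area adjacency from an explicit edge list
#'
#' @param pairs two-column matrix or data frame of area-id pairs; duplicates
#'   and self pairs are dropped with a warning.
#' @param area_ids the full ordered id list (isolated areas are kept as
#'   singleton components).
#' @param area_names optional display names.
#' @return an [area_graph()] without polygons.
#' @export
adjacency_from_edgelist <- function(pairs, area_ids, area_names = NULL) {
  area_ids <- as.character(area_ids)
  pairs <- as.matrix(pairs)
  if (length(pairs) && ncol(pairs) != 2L) ar_stop("pairs must have two columns")
  idx <- match(c(pairs), area_ids)
  if (anyNA(idx)) {
    bad <- unique(c(pairs)[is.na(idx)])
    ar_stop("unknown area id(s) in edge list: ", paste(bad, collapse = ", "))
  }
  edges <- matrix(idx, ncol = 2L)
  if (nrow(edges)) {
    canon <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    keep <- canon[, 1L] != canon[, 2L]
    ndup <- sum(duplicated(canon[keep, , drop = FALSE]))
    if (ndup > 0L) ar_warn(ndup, " duplicate pair(s) collapsed in edge list")
  }
  area_graph(area_ids, edges, area_names = area_names)
}

#' Synthetic lattice geography
#'
#' A `rows` x `cols` grid of unit-square areas with ids `"Z00001"`,
#' `"Z00002"`, ... in row-major order.  Polygons are populated so GeoJSON
#' export and polygon-based adjacency both work on the fixture.
#'
#' @param rows,cols positive grid dimensions.
#' @param rule contiguity rule, `"queen"` (default) or `"rook"`.
#' @return an [area_graph()] with polygons.
#' @export
#' @examples
#' n_edges(make_lattice(3, 3, rule = "rook"))   # 12
#' n_edges(make_lattice(3, 3, rule = "queen"))  # 20
make_lattice <- function(rows, cols, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  stopifnot(rows >= 1L, cols >= 1L)
  n <- rows * cols
  ids <- sprintf("Z%05d", seq_len(n))
  names <- sprintf("Cell r%dc%d", rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
  polys <- vector("list", n)
  edges <- list()
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      i <- (r - 1L) * cols + cc
      x0 <- cc - 1; y0 <- rows - r  # row 1 on top, map-style
      ring <- rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1), c(x0, y0))
      polys[[i]] <- list(list(ring))
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        if (rule == "rook" && abs(dr) + abs(dc) != 1L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1L && r2 <= rows && c2 >= 1L && c2 <= cols) {
          j <- (r2 - 1L) * cols + c2
          if (j > i) edges[[length(edges) + 1L]] <- c(i, j)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), ncol = 2L)
  area_graph(ids, edges, area_names = names, polygons = polys)
}

## ---------------------------------------------------------------------------
## file readers

#' Read area geography from a GeoJSON FeatureCollection
#'
#' Each Feature must carry `properties.area_id` (string) and may carry
#' `properties.area_name`; geometry must be `Polygon` or `MultiPolygon` with
#' planar coordinates.  Adjacency is derived by [adjacency_from_polygons()].
#'
#' @param path GeoJSON file path.
#' @param rule contiguity rule passed on.
#' @return an [area_graph()].
#' @export
read_geography <- function(path, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    ar_stop("expected a GeoJSON FeatureCollection: ", path)
  }
  feats <- gj$features
  if (length(feats) == 0L) ar_stop("empty geometry: no features in ", path)
  ids <- character(length(feats))
  nms <- character(length(feats))
  polys <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    id <- f$properties$area_id
    if (is.null(id)) ar_stop("feature ", k, " lacks properties.area_id")
    ids[[k]] <- as.character(id)
    nms[[k]] <- as.character(f$properties$area_name %||% id)
    geom <- f$geometry
    ring_mat <- function(rg) {
      m <- do.call(rbind, lapply(rg, function(pt) c(pt[[1L]], pt[[2L]])))
      storage.mode(m) <- "double"
      m
    }
    polys[[k]] <- switch(
      geom$type %||% "none",
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates, function(part) lapply(part, ring_mat)),
      ar_stop("feature ", ids[[k]], ": unsupported geometry type ", geom$type %||% "none")
    )
  }
  adjacency_from_polygons(polys, ids, rule = rule, area_names = nms)
}

#' Write area geography as a GeoJSON FeatureCollection
#'
#' Inverse of [read_geography()]: one Feature per area with `area_id` and
#' `area_name` properties and Polygon/MultiPolygon geometry.
#'
#' @param graph an [area_graph()] with polygons.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geography <- function(graph, path) {
  if (is.null(graph$polygons)) ar_stop("graph has no polygons to write")
  feats <- vector("list", n_areas(graph))
  for (k in seq_len(n_areas(graph))) {
    parts <- graph$polygons[[k]]
    coords <- lapply(parts, function(part) lapply(part, function(ring) {
      ring <- close_ring(ring)
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
    }))
    geometry <- if (length(parts) == 1L) {
      list(type = "Polygon", coordinates = coords[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    feats[[k]] <- list(
      type = "Feature",
      properties = list(area_id = graph$area_ids[[k]],
                        area_name = graph$area_names[[k]]),
      geometry = geometry)
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an edge list from delimited text
#'
#' Expects a header `area_a,area_b`.  When `area_ids` is omitted the id
#' universe is the set of ids appearing in the file.
#'
#' @param path delimited text file.
#' @param area_ids optional full ordered id list.
#' @return an [area_graph()].
#' @export
read_edgelist <- function(path, area_ids = NULL) {
  tab <- utils::read.csv(path, colClasses = "character")
  if (!all(c("area_a", "area_b") %in% names(tab))) {
    ar_stop("edge list must have header area_a,area_b: ", path)
  }
  if (is.null(area_ids)) area_ids <- sort(unique(c(tab$area_a, tab$area_b)))
  adjacency_from_edgelist(cbind(tab$area_a, tab$area_b), area_ids)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
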