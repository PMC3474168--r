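#' Areal adjacency graphs
#'
#' An `adjacency_graph` represents the areal units of a study region and their
#' symmetric neighborhood relation — the support of the intrinsic CAR spatial
#' prior used by [fit_bym()]. It is a list with components `area_ids` (ordered
#' character vector of unique identifiers) and `neighbors` (named list mapping
#' each id to the character vector of its neighbors).
#'
#' Invariants enforced by the constructor: the relation is symmetric, has no
#' self-loops, and every id appearing as a key or neighbor is in `area_ids`.
#' Areas with no neighbors (islands) are allowed; the spatial prior treats
#' them as pure unstructured heterogeneity.
#'
#' @param area_ids Character vector of unique area identifiers.
#' @param neighbors Named list: for each area id, a character vector of
#'   neighboring ids. Areas missing from the list are taken as isolated.
#' @return An object of class `adjacency_graph`.
#' @seealso [read_gal()], [adjacency_from_polygons()], [grid_geography()],
#'   [graph_components()]
#' @export
#' @examples
#' g <- adjacency_graph(c("a", "b", "c"), list(a = "b", b = c("a", "c"), c = "b"))
#' n_areas(g)
adjacency_graph <- function(area_ids, neighbors = list()) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop_fmt("duplicate area ids: %s",
             paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  }
  nb <- stats::setNames(vector("list", length(area_ids)), area_ids)
  for (id in area_ids) nb[[id]] <- character(0)
  for (id in names(neighbors)) {
    if (!id %in% area_ids) stop_fmt("neighbor list key '%s' not in area_ids", id)
    val <- as.character(neighbors[[id]])
    unknown <- setdiff(val, area_ids)
    if (length(unknown)) {
      stop_fmt("area '%s' lists unknown neighbor(s): %s", id,
               paste(unknown, collapse = ", "))
    }
    if (id %in% val) stop_fmt("area '%s' lists itself as a neighbor", id)
    nb[[id]] <- sort(unique(val))
  }
  # enforce symmetry
  for (id in area_ids) {
    for (b in nb[[id]]) {
      if (!id %in% nb[[b]]) {
        stop_fmt("asymmetric adjacency: '%s' lists '%s' but not vice versa", id, b)
      }
    }
  }
  structure(list(area_ids = area_ids, neighbors = nb), class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  ne <- nrow(graph_edges(x))
  deg <- lengths(x$neighbors)
  cat(sprintf("Adjacency graph: %d areas, %d edges", length(x$area_ids), ne))
  if (length(deg)) {
    cat(sprintf(" (degree %d-%d%s)", min(deg), max(deg),
                if (any(deg == 0)) sprintf(", %d isolated", sum(deg == 0)) else ""))
  }
  cat("\n")
  invisible(x)
}

#' Number of areas in an adjacency graph
#' @param graph An [adjacency_graph()].
#' @return Integer count of areas.
#' @export
n_areas <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  length(graph$area_ids)
}

#' Edge list of an adjacency graph
#'
#' @param graph An [adjacency_graph()].
#' @return A two-column character matrix, one row per undirected edge, with
#'   the lexicographically smaller id first.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  from <- rep(names(graph$neighbors), lengths(graph$neighbors))
  to <- unlist(graph$neighbors, use.names = FALSE)
  if (!length(from)) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  }
  keep <- from < to
  cbind(from = from[keep], to = to[keep])
}

#' Connected components of an adjacency graph
#'
#' The intrinsic CAR prior is improper and identified only up to a constant
#' per connected component, so [fit_bym()] applies its sum-to-zero constraint
#' component-wise; this function computes the partition.
#'
#' @param graph An [adjacency_graph()].
#' @return A list of character vectors, each one component's area ids, ordered
#'   by first appearance in `graph$area_ids`.
#' @export
#' @examples
#' graph_components(grid_geography(2, 2)$graph)
graph_components <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  ids <- graph$area_ids
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  comps <- list()
  for (id in ids) {
    if (seen[[id]]) next
    queue <- id
    comp <- character(0)
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      if (seen[[cur]]) next
      seen[[cur]] <- TRUE
      comp <- c(comp, cur)
      queue <- c(queue, graph$neighbors[[cur]][!seen[graph$neighbors[[cur]]]])
    }
    comps[[length(comps) + 1L]] <- ids[ids %in% comp]
  }
  comps
}

#' Read a GAL neighbor-list file
#'
#' Parses the GAL spatial-weights dialect: a header line carrying the number
#' of areas (either `n` alone or the libpysal-style `0 n ...`), then for each
#' area a line `id n_neighbors` followed by a line listing the neighbor ids
#' (blank when there are none). If the file records an edge in one direction
#' only, the edge is symmetrized and a warning is issued.
#'
#' @param path Path to a GAL file.
#' @return An [adjacency_graph()].
#' @export
read_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_fmt("%s: empty GAL file", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n_declared <- suppressWarnings(as.integer(header[[1L]]))
  if (!is.na(n_declared) && n_declared == 0L && length(header) >= 2L) {
    n_declared <- suppressWarnings(as.integer(header[[2L]]))
  }
  if (is.na(n_declared) || n_declared < 0L) {
    stop_fmt("%s line 1: malformed GAL header '%s'", path, lines[[1L]])
  }
  ids <- character(0)
  raw_nb <- list()
  i <- 2L
  while (length(ids) < n_declared) {
    while (i <= length(lines) && !nzchar(trimws(lines[[i]]))) i <- i + 1L
    if (i > length(lines)) {
      stop_fmt("%s: header declares %d areas but file ends after %d",
               path, n_declared, length(ids))
    }
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(toks) != 2L) {
      stop_fmt("%s line %d: expected 'id n_neighbors', got '%s'", path, i, lines[[i]])
    }
    id <- toks[[1L]]
    k <- suppressWarnings(as.integer(toks[[2L]]))
    if (is.na(k) || k < 0L) {
      stop_fmt("%s line %d: bad neighbor count '%s'", path, i, toks[[2L]])
    }
    i <- i + 1L
    nbrs <- character(0)
    if (k > 0L) {
      if (i > length(lines)) stop_fmt("%s: truncated after area '%s'", path, id)
      nbrs <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
      if (length(nbrs) != k) {
        stop_fmt("%s line %d: area '%s' declares %d neighbors but lists %d",
                 path, i, id, k, length(nbrs))
      }
      i <- i + 1L
    } else if (i <= length(lines) && !nzchar(trimws(lines[[i]]))) {
      i <- i + 1L  # optional blank line for isolated areas
    }
    ids <- c(ids, id)
    raw_nb[[id]] <- nbrs
  }
  if (anyDuplicated(ids)) {
    stop_fmt("%s: duplicate area id '%s'", path, ids[duplicated(ids)][[1L]])
  }
  dangling <- setdiff(unique(unlist(raw_nb, use.names = FALSE)), ids)
  if (length(dangling)) {
    stop_fmt("%s: neighbor id(s) not declared as areas: %s", path,
             paste(dangling, collapse = ", "))
  }
  # symmetrize with a warning if needed
  asym <- character(0)
  for (id in ids) {
    for (b in raw_nb[[id]]) {
      if (!id %in% raw_nb[[b]]) {
        raw_nb[[b]] <- c(raw_nb[[b]], id)
        asym <- c(asym, sprintf("%s->%s", id, b))
      }
    }
  }
  if (length(asym)) {
    warn_fmt("%s: symmetrized %d one-directional edge(s): %s", path,
             length(asym), paste(asym, collapse = ", "))
  }
  adjacency_graph(ids, raw_nb)
}

#' Write a GAL neighbor-list file
#'
#' @param graph An [adjacency_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  out <- as.character(length(graph$area_ids))
  for (id in graph$area_ids) {
    nb <- graph$neighbors[[id]]
    out <- c(out, sprintf("%s %d", id, length(nb)),
             if (length(nb)) paste(nb, collapse = " ") else "")
  }
  writeLines(out, path)
  invisible(path)
}

# Normalize one polygon to a list of rings (two-column coordinate matrices).
poly_rings <- function(p) {
  if (is.matrix(p)) p <- list(p)
  lapply(p, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L || !all(is.finite(r))) {
      stop_fmt("invalid polygon ring: need a finite 2-column matrix with >= 3 vertices")
    }
    r
  })
}

vertex_key <- function(xy) sprintf("%.9g|%.9g", xy[, 1L], xy[, 2L])

#' Derive adjacency from polygon geometries
#'
#' Two areas are neighbors when their boundaries touch: under queen contiguity
#' they share at least one boundary vertex (corner contact counts); under rook
#' contiguity they must share a full edge (two consecutive vertices). Contact
#' is assessed on the polygons' vertex sets, the usual discretization in
#' spatial-weights construction, so polygons must share coordinates exactly
#' where they touch.
#'
#' @param polygons Named list of polygons, one per area: a two-column
#'   coordinate matrix (outer ring; closing vertex optional) or a list of such
#'   rings. Names are the area ids.
#' @param queen Logical; `TRUE` (default) for queen contiguity, `FALSE` for rook.
#' @return An [adjacency_graph()].
#' @export
#' @examples
#' sq <- function(x, y) cbind(x + c(0, 1, 1, 0), y + c(0, 0, 1, 1))
#' adjacency_from_polygons(list(a = sq(0, 0), b = sq(1, 0)))
adjacency_from_polygons <- function(polygons, queen = TRUE) {
  ids <- names(polygons)
  if (is.null(ids) || any(!nzchar(ids))) stop_fmt("polygons must be a named list")
  if (anyDuplicated(ids)) {
    stop_fmt("duplicate area ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # map vertex (queen) or edge (rook) keys to the areas touching them
  touch <- new.env(parent = emptyenv())
  for (id in ids) {
    keys <- character(0)
    for (ring in poly_rings(polygons[[id]])) {
      # drop an explicit closing vertex, then re-close for edge keys
      if (all(ring[1L, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
      vk <- vertex_key(ring)
      if (queen) {
        keys <- c(keys, vk)
      } else {
        nxt <- c(vk[-1L], vk[1L])
        keys <- c(keys, paste(pmin(vk, nxt), pmax(vk, nxt), sep = "+"))
      }
    }
    for (k in unique(keys)) {
      assign(k, c(if (exists(k, envir = touch)) get(k, envir = touch), id), envir = touch)
    }
  }
  nb <- stats::setNames(lapply(ids, function(i) character(0)), ids)
  for (k in ls(touch)) {
    shared <- get(k, envir = touch)
    if (length(shared) < 2L) next
    for (a in shared) nb[[a]] <- union(nb[[a]], setdiff(shared, a))
  }
  adjacency_graph(ids, nb)
}

#' Generate a rectangular lattice geography
#'
#' Builds a `rows` x `cols` unit-square lattice with rook adjacency and
#' deterministic area ids `r{i}c{j}` — a synthetic stand-in for a real areal
#' map (a 6 x 11 grid gives the 66 areas of a Halland-sized region).
#'
#' @param rows,cols Positive integers.
#' @return A list with components `graph` (an [adjacency_graph()]) and
#'   `polygons` (named list of unit-square rings, usable with
#'   [adjacency_from_polygons()] and [write_geojson()]).
#' @export
#' @examples
#' gg <- grid_geography(2, 3)
#' gg$graph
grid_geography <- function(rows, cols) {
  if (!is_count(rows) || !is_count(cols) || rows < 1 || cols < 1) {
    stop_fmt("rows and cols must be positive integers")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  id_at <- function(i, j) sprintf("r%dc%d", i, j)
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols), id_at)))
  nb <- stats::setNames(vector("list", length(ids)), ids)
  polys <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      id <- id_at(i, j)
      adj <- character(0)
      if (i > 1) adj <- c(adj, id_at(i - 1, j))
      if (i < rows) adj <- c(adj, id_at(i + 1, j))
      if (j > 1) adj <- c(adj, id_at(i, j - 1))
      if (j < cols) adj <- c(adj, id_at(i, j + 1))
      nb[[id]] <- adj
      polys[[id]] <- cbind(x = (j - 1) + c(0, 1, 1, 0), y = (i - 1) + c(0, 0, 1, 1))
    }
  }
  list(graph = adjacency_graph(ids, nb), polygons = polys)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Expects Polygon features each carrying an `area_id` property; only the
#' outer ring is retained (adjacency is a boundary-contact question, holes are
#' irrelevant for it).
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of two-column coordinate matrices keyed by area id.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_fmt("%s: expected a GeoJSON FeatureCollection", path)
  }
  out <- list()
  for (f in gj$features) {
    id <- f$properties$area_id
    if (is.null(id)) stop_fmt("%s: feature without an 'area_id' property", path)
    if (!identical(f$geometry$type, "Polygon")) {
      stop_fmt("%s: feature '%s' is not a Polygon", path, id)
    }
    ring <- f$geometry$coordinates[[1L]]
    out[[as.character(id)]] <- do.call(rbind, lapply(ring, function(xy) {
      c(as.numeric(xy[[1L]]), as.numeric(xy[[2L]]))
    }))
  }
  if (anyDuplicated(names(out))) stop_fmt("%s: duplicate area_id properties", path)
  out
}

#' Write polygons (with optional per-area properties) as GeoJSON
#'
#' @param polygons Named list of polygon rings as in [adjacency_from_polygons()].
#' @param path Output path.
#' @param properties Optional data frame with an `area_id` column; the
#'   remaining columns become feature properties (for choropleth tools).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(polygons, path, properties = NULL) {
  ids <- names(polygons)
  props <- NULL
  if (!is.null(properties)) {
    stopifnot(is.data.frame(properties), "area_id" %in% names(properties))
    missing_ids <- setdiff(ids, properties$area_id)
    if (length(missing_ids)) {
      stop_fmt("properties missing area id(s): %s", paste(missing_ids, collapse = ", "))
    }
    props <- properties[match(ids, properties$area_id), , drop = FALSE]
  }
  features <- lapply(seq_along(ids), function(k) {
    ring <- poly_rings(polygons[[ids[[k]]]])[[1L]]
    if (!all(ring[1L, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1L, ])
    coords <- lapply(seq_len(nrow(ring)), function(r) as.numeric(ring[r, ]))
    p <- list(area_id = ids[[k]])
    if (!is.null(props)) {
      for (col in setdiff(names(props), "area_id")) p[[col]] <- props[[col]][[k]]
    }
    list(type = "Feature", properties = p,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
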