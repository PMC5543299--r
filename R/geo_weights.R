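#' Build a contiguity weights matrix from an undirected edge list
#'
#' Constructs a symmetric binary spatial weights matrix of a given contiguity
#' order from first-order adjacency edges. Order 1 is the (symmetrized)
#' adjacency itself; order k links areas whose shortest-path distance on the
#' adjacency graph is exactly k, or at most k when `include_lower = TRUE`
#' (the usual "include lower orders" convention for higher-order queen
#' weights).
#'
#' @param edges two-column matrix or data frame of area-id pairs (undirected;
#'   duplicates and orientation are ignored), or `NULL` for no edges.
#' @param area_ids vector of all area identifiers (defines matrix order).
#' @param order contiguity order, integer >= 1.
#' @param include_lower logical; union all orders 1..`order` instead of the
#'   exact order. Default `TRUE`.
#' @return object of class `weights_matrix`: list with `area_ids`, sparse
#'   symmetric binary `W` (zero diagonal), `order`, `include_lower`, and
#'   `islands` (ids with no neighbours).
#' @export
build_weights <- function(edges, area_ids, order = 1L, include_lower = TRUE) {
  if (length(area_ids) < 1L || anyDuplicated(area_ids))
    stop("area_ids must be non-empty and unique")
  if (!is.numeric(order) || length(order) != 1L || is.na(order) || order < 1)
    stop("order must be an integer >= 1")
  order <- as.integer(order)
  n <- length(area_ids)
  ids <- as.character(area_ids)

  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n), dimnames = list(ids, ids))
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    i <- match(as.character(edges[, 1L]), ids)
    j <- match(as.character(edges[, 2L]), ids)
    if (anyNA(i) || anyNA(j)) {
      bad <- unique(c(edges[, 1L][is.na(i)], edges[, 2L][is.na(j)]))
      stop("unknown area id(s) in edge list: ", paste(bad, collapse = ", "))
    }
    keep <- i != j                      # self-loops carry no information
    A <- Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                              x = 1, dims = c(n, n), dimnames = list(ids, ids))
    A@x[] <- 1                          # collapse duplicate edges
  }
  A <- methods::as(A, "generalMatrix")

  # reachability within `order` steps, then strip lower orders if exact
  W <- A
  if (order > 1L) {
    reach <- A
    step <- A
    for (k in seq_len(order - 1L)) {
      step <- Matrix::drop0(step %*% A)
      step@x[] <- 1
      reach <- reach + step
    }
    reach@x[] <- 1
    Matrix::diag(reach) <- 0
    reach <- Matrix::drop0(reach)
    if (include_lower) {
      W <- reach
    } else {
      # exactly order k: reachable in <= k steps but not in <= k-1
      lower <- A
      step <- A
      if (order > 2L) {
        for (k in seq_len(order - 2L)) {
          step <- Matrix::drop0(step %*% A)
          step@x[] <- 1
          lower <- lower + step
        }
        lower@x[] <- 1
      }
      Matrix::diag(lower) <- 0
      W <- Matrix::drop0(reach - Matrix::drop0(lower))
      W@x[] <- 1
      W <- Matrix::drop0(W)
    }
  }

  rs <- Matrix::rowSums(W)
  structure(list(area_ids = area_ids, W = W, order = order,
                 include_lower = include_lower,
                 islands = area_ids[rs == 0]),
            class = "weights_matrix")
}

#' @export
print.weights_matrix <- function(x, ...) {
  cat(sprintf("weights_matrix: %d areas, order %d%s, %d links, %d island(s)\n",
              length(x$area_ids), x$order,
              if (x$include_lower && x$order > 1L) " (incl. lower)" else "",
              as.integer(Matrix::nnzero(x$W) / 2), length(x$islands)))
  invisible(x)
}

#' Neighbour index list of a weights matrix
#'
#' @param w a `weights_matrix`.
#' @return list (one element per area, in `area_ids` order) of integer
#'   neighbour indices.
#' @export
neighbor_list <- function(w) {
  stopifnot(inherits(w, "weights_matrix"))
  n <- length(w$area_ids)
  tw <- methods::as(methods::as(w$W, "CsparseMatrix"), "TsparseMatrix")
  split(tw@i + 1L, factor(tw@j + 1L, levels = seq_len(n)))
}

#' Pairwise Euclidean distances between area centroids
#'
#' @param centroids data frame or matrix with columns `x` and `y` (planar
#'   coordinates), optionally an `id` column used for dimnames.
#' @return symmetric distance matrix with a zero diagonal.
#' @export
pairwise_distances <- function(centroids) {
  cent <- as.data.frame(centroids)
  if (!all(c("x", "y") %in% names(cent))) {
    if (ncol(cent) >= 2 && is.numeric(cent[[1]]) && is.numeric(cent[[2]]))
      names(cent)[1:2] <- c("x", "y")
    else stop("centroids must provide numeric columns x and y")
  }
  xy <- cbind(cent$x, cent$y)
  if (!all(is.finite(xy))) stop("non-finite centroid coordinate")
  D <- as.matrix(stats::dist(xy))
  if ("id" %in% names(cent)) dimnames(D) <- list(cent$id, cent$id)
  D
}

#' Read an undirected edge list from CSV
#'
#' Expects a header and two columns of area ids (`id_a,id_b`); orientation
#' and duplicates are irrelevant.
#'
#' @param path CSV file path.
#' @return two-column character matrix of edges.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("edge list needs two columns (id_a,id_b)")
  as.matrix(df[, 1:2, drop = FALSE])
}

#' Write an undirected edge list to CSV
#'
#' @param edges two-column matrix/data frame of id pairs.
#' @param path output CSV path.
#' @export
write_edge_list <- function(edges, path) {
  df <- as.data.frame(as.matrix(edges)[, 1:2, drop = FALSE])
  names(df) <- c("id_a", "id_b")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive a contiguity edge list from GeoJSON polygons
#'
#' Queen-style contiguity: two polygon features are neighbours when their
#' boundaries share at least one vertex (coordinates compared exactly after
#' rounding to `digits`). Features must carry an `id` property. This is a
#' convenience reader producing the same edge-list representation that
#' [build_weights()] consumes.
#'
#' @param path GeoJSON FeatureCollection file with Polygon/MultiPolygon
#'   features.
#' @param digits coordinate rounding used for vertex matching.
#' @return two-column character matrix of neighbour id pairs.
#' @export
edges_from_geojson <- function(path, digits = 9) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  vert <- function(coords) {     # flatten rings to "x|y" vertex keys
    rings <- list()
    walk <- function(node) {
      if (is.list(node) && length(node) && is.list(node[[1]]) &&
          length(node[[1]]) >= 2 && is.numeric(node[[1]][[1]])) {
        rings[[length(rings) + 1L]] <<- node
      } else if (is.list(node)) lapply(node, walk)
      invisible(NULL)
    }
    walk(coords)
    unique(unlist(lapply(rings, function(r)
      vapply(r, function(p) paste(round(as.numeric(p[1:2]), digits),
                                  collapse = "|"), character(1)))))
  }
  ids <- character(0); verts <- list()
  for (f in gj$features) {
    id <- f$properties$id
    if (is.null(id)) stop("feature without an 'id' property")
    ids <- c(ids, as.character(id))
    verts[[length(verts) + 1L]] <- vert(f$geometry$coordinates)
  }
  n <- length(ids)
  out <- matrix(character(0), ncol = 2)
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    hit <- apply(pairs, 2, function(p)
      length(intersect(verts[[p[1]]], verts[[p[2]]])) > 0)
    out <- cbind(ids[pairs[1, hit]], ids[pairs[2, hit]])
  }
  colnames(out) <- c("id_a", "id_b")
  out
}
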