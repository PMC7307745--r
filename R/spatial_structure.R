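#' Build an area adjacency graph
#'
#' Constructs the adjacency structure of the spatial analysis units
#' (provinces).  Edges are stored as unordered index pairs; duplicates
#' and reversed pairs are collapsed.  Connected components are computed
#' at construction time because the intrinsic CAR prior's rank deficit
#' and sum-to-zero constraints are per component.
#'
#' @param area_ids character vector of unique area labels (length `J`).
#' @param edge_list two-column matrix or data frame of area-label pairs,
#'   one neighbour pair per row.  May have zero rows (all areas then
#'   form singleton components).
#' @return an object of class `adjacency_graph`: a list with elements
#'   `area_ids`, `J`, `edges` (m x 2 integer matrix, first index
#'   smaller), `comp` (integer component label per area), `n_comp`,
#'   `A` (sparse symmetric adjacency matrix) and `deg` (degrees).
#' @export
#' @examples
#' g <- build_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' g$J; g$n_comp
build_graph <- function(area_ids, edge_list = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids))
    stop("duplicate area labels: ",
         paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  J <- length(area_ids)
  if (is.null(edge_list) || NROW(edge_list) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    el <- as.matrix(edge_list)
    if (ncol(el) != 2L) stop("edge_list must have two columns")
    i <- match(as.character(el[, 1]), area_ids)
    j <- match(as.character(el[, 2]), area_ids)
    bad <- unique(c(el[, 1][is.na(i)], el[, 2][is.na(j)]))
    if (length(bad))
      stop("edge endpoints not among area labels: ",
           paste(bad, collapse = ", "))
    if (any(i == j)) stop("self-loop edges are not allowed")
    edges <- cbind(pmin(i, j), pmax(i, j))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(J, J))
  if (nrow(edges)) {
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, J - igraph::vcount(ig)))
    comp <- igraph::components(ig)$membership
  } else {
    comp <- seq_len(J)
  }
  structure(list(area_ids = area_ids, J = J, edges = edges,
                 comp = as.integer(comp), n_comp = length(unique(comp)),
                 A = A, deg = Matrix::rowSums(A)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", x$J, "areas,", nrow(x$edges), "edges,",
      x$n_comp, "connected component(s)\n")
  invisible(x)
}

#' Chain graph with optional chord edges
#'
#' Convenience constructor for an elongated geography: areas are linked
#' along a chain in `latitude` order, with optional extra chords.
#'
#' @param area_ids area labels in chain (north-to-south) order.
#' @param chords optional two-column matrix of extra label pairs.
#' @return an `adjacency_graph`.
#' @export
chain_graph <- function(area_ids, chords = NULL) {
  J <- length(area_ids)
  el <- cbind(area_ids[-J], area_ids[-1])
  if (!is.null(chords)) el <- rbind(el, as.matrix(chords))
  build_graph(area_ids, el)
}

icar_check_centered <- function(u, graph, tol = 1e-8) {
  sums <- tapply(u, graph$comp, sum)
  sizes <- tabulate(graph$comp)
  if (any(abs(sums) > tol))
    stop("ICAR constraint violated: per-component sums of u must be 0")
  if (any(sizes == 1L & abs(u[match(which(sizes == 1L), graph$comp)]) > tol))
    stop("singleton-component entries of u must be exactly 0")
  invisible(TRUE)
}

#' Intrinsic CAR (ICAR) log-density
#'
#' Log-density, up to the fixed additive constant convention below, of
#' the improper intrinsic conditional autoregressive prior used for the
#' spatially correlated random effects:
#' \deqn{\log f(u \mid \tau) = \frac{J - C}{2}\log\tau -
#'   \frac{\tau}{2} \sum_{(j,l) \in E} (u_j - u_l)^2}
#' where `J` is the number of areas, `C` the number of connected
#' components, and the sum runs over neighbour pairs.  No `2*pi` terms
#' are included; this convention is fixed and used consistently by the
#' sampler.
#'
#' @param u numeric vector of spatial effects (length `J`), summing to
#'   zero within each connected component (tolerance `1e-8`; singleton
#'   components are pinned at 0).
#' @param tau positive precision parameter.
#' @param graph an `adjacency_graph`.
#' @return a finite numeric scalar.
#' @export
#' @examples
#' g <- build_graph(c("A", "B"), rbind(c("A", "B")))
#' icar_logdensity(c(0.5, -0.5), 1, g)  # -0.5
icar_logdensity <- function(u, tau, graph) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a positive scalar")
  if (length(u) != graph$J) stop("length(u) must equal graph$J")
  icar_check_centered(u, graph)
  pair_ss <- if (nrow(graph$edges))
    sum((u[graph$edges[, 1]] - u[graph$edges[, 2]])^2) else 0
  ((graph$J - graph$n_comp) / 2) * log(tau) - (tau / 2) * pair_ss
}

## eigen-decomposition of the graph Laplacian, cached on the graph
icar_eigen <- function(graph) {
  L <- diag(graph$deg, graph$J) - as.matrix(graph$A)
  ev <- eigen(L, symmetric = TRUE)
  pos <- ev$values > 1e-9
  list(vectors = ev$vectors[, pos, drop = FALSE], values = ev$values[pos])
}

#' Draw a field from the intrinsic CAR prior
#'
#' Samples on the positive-eigenvalue subspace of the graph Laplacian
#' (independent normals with variance `1/(tau * lambda_i)` on the
#' eigenvectors), then re-centres exactly within each connected
#' component.  Singleton components are 0.
#'
#' @param graph an `adjacency_graph`.
#' @param tau positive precision.
#' @param seed optional integer seed; if supplied the draw is
#'   reproducible (the global RNG state is used and advanced).
#' @return numeric vector of length `graph$J` with exact per-component
#'   zero means.
#' @export
sample_icar <- function(graph, tau, seed = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a positive scalar")
  if (!is.null(seed)) set.seed(seed)
  eg <- icar_eigen(graph)
  u <- if (ncol(eg$vectors))
    as.numeric(eg$vectors %*% (rnorm(length(eg$values)) /
                                 sqrt(tau * eg$values)))
  else rep(0, graph$J)
  cm <- tapply(u, graph$comp, mean)
  u <- u - cm[graph$comp]
  names(u) <- graph$area_ids
  u
}

#' Read an adjacency graph from an edge-list TSV
#'
#' Dialect: tab-separated, one neighbour pair per line, optional header,
#' labels case-sensitive.  Area labels default to those appearing in the
#' file; pass `area_ids` to include isolated areas.
#'
#' @param path file path.
#' @param area_ids optional full set of area labels.
#' @param header does the file carry a header line?
#' @return an `adjacency_graph`.
#' @export
read_graph <- function(path, area_ids = NULL, header = FALSE) {
  el <- read.csv(path, sep = "\t", header = header,
                 colClasses = "character")
  if (ncol(el) < 2L) stop("edge-list file must have two columns: ", path)
  el <- as.matrix(el[, 1:2])
  if (is.null(area_ids))
    area_ids <- sort(unique(c(el[, 1], el[, 2])))
  build_graph(area_ids, el)
}

#' Write an adjacency graph as an edge-list TSV
#' @param graph an `adjacency_graph`.
#' @param path output file path.
#' @export
write_graph <- function(graph, path) {
  el <- cbind(graph$area_ids[graph$edges[, 1]],
              graph$area_ids[graph$edges[, 2]])
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract area identifiers from a GeoJSON feature collection
#'
#' @param path GeoJSON file path (a `FeatureCollection`).
#' @param property optional property key to use as the area id; by
#'   default the feature-level `id` is used, falling back to the first
#'   property.
#' @return character vector of area ids in feature order.
#' @export
geojson_area_ids <- function(path, property = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  vapply(gj$features, function(f) {
    if (!is.null(property)) {
      v <- f$properties[[property]]
      if (is.null(v)) stop("feature lacks property '", property, "'")
      as.character(v)
    } else if (!is.null(f$id)) as.character(f$id)
    else as.character(f$properties[[1]])
  }, character(1))
}
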