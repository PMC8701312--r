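#' Triangulated surface mesh
#'
#' Constructs the shared template geometry on which all per-vertex data live:
#' vertex coordinates in mm, triangle connectivity, the induced edge set and
#' vertex adjacency, and per-vertex Voronoi-style areas (one third of each
#' incident triangle's area).
#'
#' @param vertices numeric matrix, n_vertices x 3, coordinates in mm.
#' @param triangles integer matrix, n_triangles x 3, 1-based vertex indices.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `triangles`, `edges` (E x 2, i < j), `edge_lengths` (mm),
#'   `adjacency` (list of neighbor index vectors), `vertex_area` (mm^2),
#'   `triangle_area` (mm^2), `edge_length_mean` (mm) and `mesh_id`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv)) {
    stop("triangle indices out of range: mesh has ", nv, " vertices")
  }

  tri_area <- triangle_areas(vertices, triangles)
  if (any(tri_area <= 0)) stop("degenerate (zero-area) triangle in mesh")

  # vertex area: one third of each incident triangle
  va <- numeric(nv)
  third <- rep(tri_area / 3, times = 3L)
  idx <- as.vector(triangles)
  va_tab <- tapply(third, idx, sum)
  va[as.integer(names(va_tab))] <- va_tab
  if (any(va <= 0)) stop("isolated vertex with zero area in mesh")

  e_all <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
                 triangles[, c(1L, 3L)])
  e_all <- cbind(pmin(e_all[, 1L], e_all[, 2L]), pmax(e_all[, 1L], e_all[, 2L]))
  edges <- unique(e_all)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  el <- sqrt(rowSums((vertices[edges[, 1L], , drop = FALSE] -
                      vertices[edges[, 2L], , drop = FALSE])^2))

  adj <- vector("list", nv)
  nb_from <- c(edges[, 1L], edges[, 2L])
  nb_to <- c(edges[, 2L], edges[, 1L])
  ord <- order(nb_from)
  adj_split <- split(nb_to[ord], nb_from[ord])
  adj[as.integer(names(adj_split))] <- adj_split

  mesh <- list(
    vertices = vertices,
    triangles = triangles,
    edges = edges,
    edge_lengths = el,
    adjacency = adj,
    vertex_area = va,
    triangle_area = tri_area,
    edge_length_mean = mean(el),
    mesh_id = sprintf("mesh-v%d-f%d-a%.6e", nv, nrow(triangles), sum(tri_area))
  )
  class(mesh) <- "surface_mesh"
  mesh
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c_ <- vertices[triangles[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles,", nrow(x$edges), "edges\n")
  cat("  total area:", format(sum(x$triangle_area)), "mm^2;",
      "mean edge length:", format(x$edge_length_mean), "mm\n")
  cat("  Euler characteristic:", euler_characteristic(x), "\n")
  invisible(x)
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for any closed mesh of sphere topology; used as a construction
#' invariant for synthetic template meshes.
#' @param mesh a `surface_mesh`
#' @return integer
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh$edges) + nrow(mesh$triangles)
}

#' @export
n_vertices <- function(mesh) UseMethod("n_vertices")

#' @export
n_vertices.surface_mesh <- function(mesh) nrow(mesh$vertices)

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
}

#' Geodesic distances along mesh edges
#'
#' Dijkstra shortest paths over the edge graph weighted by Euclidean edge
#' length. This is the distance used both to plant effect patches and to
#' calibrate the smoothing kernel, so planted clusters are guaranteed to be
#' connected in the same adjacency the cluster-finding stage uses.
#'
#' @param mesh a `surface_mesh`
#' @param from integer vector of source vertex indices
#' @return matrix length(from) x n_vertices of distances in mm
#' @export
geodesic_distances <- function(mesh, from) {
  g <- mesh_graph(mesh)
  igraph::distances(g, v = from, weights = mesh$edge_lengths)
}

#' Build a subdivided icosahedral sphere mesh
#'
#' Standard synthetic stand-in for a registered cortical surface template:
#' the icosahedron is subdivided `subdivisions` times (each triangle into
#' four, midpoints projected to the sphere), giving `10 * 4^s + 2` vertices.
#'
#' @param subdivisions non-negative integer subdivision level
#' @param radius sphere radius in mm (default 100, giving a hemisphere-scale
#'   surface area of about 0.126 m^2)
#' @return a `surface_mesh`
#' @examples
#' m <- make_icosphere(1)
#' euler_characteristic(m) # 2
#' @export
make_icosphere <- function(subdivisions, radius = 100) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  s <- 0L
  while (s < subdivisions) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    extra <- list()
    get_mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j), sep = "-")
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      extra[[length(extra) + 1L]] <<- m
      midpoint_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c_ <- f[t, 3L]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      newf[(t - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      newf[(t - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      newf[(t - 1L) * 4L + 3L, ] <- c(c_, ca, bc)
      newf[(t - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- newf
    s <- s + 1L
  }
  surface_mesh(v * radius, f)
}
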