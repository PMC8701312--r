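#' Per-vertex scalar map
#'
#' A vector of one scalar per mesh vertex with a mandatory unit tag and a
#' validity mask. Unit tags prevent the classic failure of mixing raw
#' thickness (mm) with annualized percent change (%/year) in arithmetic:
#' `+` / `-` between maps with different units is an error.
#'
#' @param values numeric vector, one value per mesh vertex
#' @param unit one of `"mm"`, `"percent-per-year"`, `"t"`,
#'   `"dimensionless"`, `"integer-label"`
#' @param mesh a `surface_mesh` (or a mesh_id string) binding the map
#' @param valid logical mask of valid vertices; `NA`s in `values` are
#'   only permitted where `valid` is `FALSE`
#' @return object of class `vertex_map`
#' @export
vertex_map <- function(values, unit, mesh, valid = NULL) {
  unit <- match.arg(unit, c("mm", "percent-per-year", "t", "dimensionless",
                            "integer-label"))
  mesh_id <- if (inherits(mesh, "surface_mesh")) mesh$mesh_id else as.character(mesh)
  if (inherits(mesh, "surface_mesh") && length(values) != n_vertices(mesh)) {
    stop("map has ", length(values), " values but mesh has ",
         n_vertices(mesh), " vertices")
  }
  if (is.null(valid)) valid <- !is.na(values)
  if (any(is.na(values) & valid)) {
    stop("NaN/NA at vertices marked valid; mask missing values explicitly")
  }
  structure(list(values = as.numeric(values), unit = unit,
                 mesh_id = mesh_id, valid = as.logical(valid)),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat("vertex_map [", x$unit, "] on ", x$mesh_id, "\n", sep = "")
  cat("  ", length(x$values), " vertices, ", sum(!x$valid), " masked\n", sep = "")
  v <- x$values[x$valid]
  if (length(v)) {
    cat("  range ", format(min(v)), " .. ", format(max(v)),
        ", mean ", format(mean(v)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.vertex_map <- function(x) length(x$values)

#' @export
Ops.vertex_map <- function(e1, e2) {
  if (nargs() == 1L) {
    r <- e1
    r$values <- get(.Generic)(e1$values)
    return(r)
  }
  u1 <- if (inherits(e1, "vertex_map")) e1$unit else NULL
  u2 <- if (inherits(e2, "vertex_map")) e2$unit else NULL
  if (!is.null(u1) && !is.null(u2)) {
    if (.Generic %in% c("+", "-") && u1 != u2) {
      stop("unit mismatch: cannot ", .Generic, " a '", u1, "' map and a '",
           u2, "' map")
    }
    if (e1$mesh_id != e2$mesh_id) stop("maps are bound to different meshes")
  }
  v1 <- if (is.null(u1)) e1 else e1$values
  v2 <- if (is.null(u2)) e2 else e2$values
  out <- get(.Generic)(v1, v2)
  tmpl <- if (!is.null(u1)) e1 else e2
  if (is.logical(out)) return(out)
  r <- tmpl
  r$values <- out
  if (!is.null(u1) && !is.null(u2)) r$valid <- e1$valid & e2$valid
  r
}

map_values <- function(x) if (inherits(x, "vertex_map")) x$values else x

check_same_mesh <- function(map, mesh) {
  if (inherits(map, "vertex_map") && inherits(mesh, "surface_mesh")) {
    if (length(map$values) != n_vertices(mesh)) {
      stop("map has ", length(map$values), " values but mesh has ",
           n_vertices(mesh), " vertices")
    }
  }
  invisible(TRUE)
}
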