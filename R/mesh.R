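# Triangulated surface meshes and geodesic (edge-graph) distances.
#
# Vertex ids are 1-based inside R; OFF/PLY files use the formats' native
# 0-based face indexing and are converted on read/write.

#' Construct and validate a triangulated surface mesh
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @return object of class `surface_mesh`: list with `vertices` and `faces`.
#' @details Validation requires every face index to be in range and the edge
#'   graph to be connected (isolated vertices count as disconnection).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || any(!is.finite(vertices))) {
    stop("mesh format error: vertices must be a finite n x 3 matrix")
  }
  if (ncol(faces) != 3L || nrow(faces) < 1L) {
    stop("mesh format error: faces must be an m x 3 matrix of vertex indices")
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("mesh format error: face references an out-of-range vertex index")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3])) {
    stop("mesh format error: degenerate face with repeated vertex")
  }
  mesh <- structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
  g <- mesh_graph(mesh)
  comp <- igraph::components(g)
  if (comp$no != 1L) {
    stop("mesh format error: edge graph is disconnected (",
         comp$no, " components)")
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# undirected edge list with Euclidean lengths as weights
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = d)
}

mesh_graph <- function(mesh) {
  el <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(el$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- el$lengths
  g
}

#' Read a triangulated mesh from OFF or ascii PLY
#'
#' Detects the format from the header. Face indices in the file follow the
#' formats' 0-based convention and are converted to 1-based on read. The
#' mesh is validated (index range, connectivity) via [surface_mesh()].
#'
#' @param path path to an OFF or ascii PLY file.
#' @return a `surface_mesh`.
#' @export
read_surface_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh format error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first <- trimws(lines[1])
  if (identical(toupper(first), "OFF")) {
    read_off_lines(lines)
  } else if (identical(tolower(first), "ply")) {
    read_ply_lines(lines)
  } else {
    stop("mesh format error: unrecognized header '", first,
         "' (expected OFF or ascii PLY)")
  }
}

read_off_lines <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- scan(text = paste(lines[-1], collapse = "\n"), what = numeric(),
               quiet = TRUE)
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  pos <- 4L  # skip nv nf ne
  if (length(toks) < pos - 1 + nv * 3) stop("mesh format error: truncated OFF vertex block")
  v <- matrix(toks[pos:(pos - 1 + nv * 3)], ncol = 3, byrow = TRUE)
  pos <- pos + nv * 3L
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (is.na(k) || k != 3L) stop("mesh format error: only triangular faces are supported")
    faces[i, ] <- as.integer(toks[(pos + 1):(pos + 3)]) + 1L
    pos <- pos + 1L + k
  }
  surface_mesh(v, faces)
}

read_ply_lines <- function(lines) {
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("mesh format error: PLY header has no end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format\\s+binary", hdr))) {
    stop("mesh format error: only ascii PLY is supported")
  }
  el <- grep("^element\\s", hdr, value = TRUE)
  counts <- stats::setNames(
    as.integer(sub("^element\\s+\\S+\\s+(\\d+)$", "\\1", el)),
    sub("^element\\s+(\\S+)\\s+\\d+$", "\\1", el)
  )
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  body <- lines[(hdr_end + 1):length(lines)]
  vtoks <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- t(vapply(vtoks, function(t) as.numeric(t[1:3]), numeric(3)))
  ftoks <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(ftoks, function(t) {
    k <- as.integer(t[1])
    if (k != 3L) stop("mesh format error: only triangular faces are supported")
    as.integer(t[2:4]) + 1L
  }, integer(3)))
  surface_mesh(v, faces)
}

#' Write a mesh as OFF
#'
#' @param mesh a `surface_mesh`.
#' @param path output path; face indices are written 0-based per the format.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Geodesic distance field over a mesh
#'
#' Shortest-path distance from a seed vertex to every mesh vertex along the
#' mesh edge graph (Dijkstra, edge weights = Euclidean edge lengths). This
#' edge-graph geodesic overestimates the exact polyhedral geodesic by a
#' discretization factor that shrinks under mesh refinement.
#'
#' @param mesh a `surface_mesh`.
#' @param seed_vertex 1-based vertex id.
#' @return object of class `geodesic_field`: list with `seed` and `distance`
#'   (mm, one value per vertex; `Inf` with a warning for unreachable
#'   vertices).
#' @export
geodesic_field <- function(mesh, seed_vertex) {
  stopifnot(inherits(mesh, "surface_mesh"))
  seed_vertex <- as.integer(seed_vertex)
  if (length(seed_vertex) != 1L || is.na(seed_vertex) ||
      seed_vertex < 1L || seed_vertex > nrow(mesh$vertices)) {
    stop("seed_vertex out of range")
  }
  g <- attr(mesh, "graph")
  if (is.null(g)) g <- mesh_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = seed_vertex, algorithm = "dijkstra"))
  if (any(!is.finite(d))) {
    warning("mesh has vertices unreachable from the seed; distances reported as Inf")
  }
  structure(list(seed = seed_vertex, distance = d), class = "geodesic_field")
}

# cache the igraph on the mesh object (used by localization loops)
with_mesh_graph <- function(mesh) {
  if (is.null(attr(mesh, "graph"))) attr(mesh, "graph") <- mesh_graph(mesh)
  mesh
}

#' Snap catheter pair midpoints to mesh vertices
#'
#' Maps each bipolar-pair midpoint to its nearest mesh vertex (Euclidean);
#' ties are broken by the smallest vertex id. Layout and mesh must share a
#' coordinate frame.
#'
#' @param layout a `catheter_layout`.
#' @param mesh a `surface_mesh`.
#' @return named integer vector: `pair_index -> vertex id`.
#' @export
snap_to_surface <- function(layout, mesh) {
  stopifnot(inherits(layout, "catheter_layout"), inherits(mesh, "surface_mesh"))
  m <- pair_midpoints(layout)
  v <- mesh$vertices
  out <- vapply(seq_len(nrow(m)), function(i) {
    d2 <- (v[, 1] - m[i, 1])^2 + (v[, 2] - m[i, 2])^2 + (v[, 3] - m[i, 3])^2
    which.min(d2)  # which.min returns the first (smallest id) minimum
  }, integer(1))
  stats::setNames(out, rownames(m))
}

#' Synthetic test meshes: icosphere and flat grid
#'
#' `icosphere_mesh()` subdivides an icosahedron and projects vertices to a
#' sphere; `grid_mesh()` builds a flat triangulated rectangular grid in the
#' z = 0 plane. Both are synthetic geometries used for examples and tests.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = icosahedron).
#' @param radius sphere radius, mm.
#' @param center sphere/grid origin.
#' @return a `surface_mesh`.
#' @export
icosphere_mesh <- function(subdivisions = 2, radius = 10, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- midcache[[key]]
      if (is.null(id)) {
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        id <- nrow(v)
        midcache[[key]] <- id
      }
      id
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

#' @rdname icosphere_mesh
#' @param nx,ny grid vertex counts along x and y.
#' @param spacing grid spacing, mm.
#' @export
grid_mesh <- function(nx = 10, ny = 10, spacing = 1, center = c(0, 0, 0)) {
  stopifnot(nx >= 2, ny >= 2)
  xy <- expand.grid(x = (seq_len(nx) - 1) * spacing, y = (seq_len(ny) - 1) * spacing)
  v <- cbind(xy$x + center[1], xy$y + center[2], center[3])
  idx <- function(i, j) (j - 1L) * nx + i
  f <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      f <- rbind(f, c(a, b, d), c(a, d, cc))
    }
  }
  surface_mesh(v, f)
}
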