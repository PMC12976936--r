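#' Tagged quadrilateral shell mesh of a vessel tree
#'
#' The geometric substrate of every pipeline stage: a quad shell mesh with
#' per-element region tags (`AAo`, `arch`, `DAo`, `branch_i`, `TEVG`), named
#' ordered boundary-node loops (`inlet`, `outlet_*`, `anastomosis_*`), a wall
#' thickness and the generating centerline. Structured ring connectivity
#' (`rings`) is carried along where available so deformed lumens can be
#' profiled without re-slicing.
#'
#' @param nodes numeric matrix (n x 3), coordinates in mm.
#' @param quads integer matrix (m x 4), 1-based node connectivity with
#'   consistent outward orientation.
#' @param region character vector of length m, per-element region tag.
#' @param loops named list of ordered integer node-index vectors, each a
#'   closed simple cycle (the closing edge is implicit).
#' @param thickness wall thickness in mm (scalar or named by region).
#' @param centerline a [centerline()] for the main trunk, or `NULL`.
#' @param rings optional named list of integer matrices (one row per axial
#'   ring, one column per circumferential node) for structured tube segments.
#' @param branch_attach optional named numeric vector: trunk arclength (mm) at
#'   which each branch segment takes off.
#' @return An object of class `vessel_model`.
#' @export
vessel_model <- function(nodes, quads, region, loops = list(),
                         thickness = 1.5, centerline = NULL, rings = NULL,
                         branch_attach = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  quads <- as.matrix(quads); storage.mode(quads) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(quads) != 4L) stop("quads must be an m x 4 matrix")
  if (length(region) != nrow(quads))
    stop("region tags must partition the elements (one tag per element)")
  if (nrow(quads) && (min(quads) < 1L || max(quads) > nrow(nodes)))
    stop("quad connectivity references invalid nodes")
  for (nm in names(loops)) {
    lp <- loops[[nm]]
    if (anyDuplicated(lp) || any(lp < 1L) || any(lp > nrow(nodes)))
      stop(sprintf("boundary loop '%s' is not a simple cycle of valid nodes", nm))
  }
  structure(list(nodes = nodes, quads = quads, region = as.character(region),
                 loops = loops, thickness = thickness, centerline = centerline,
                 rings = rings, branch_attach = branch_attach),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf("<vessel_model> %d nodes, %d quads; regions: %s; loops: %s\n",
              nrow(x$nodes), nrow(x$quads),
              paste(unique(x$region), collapse = ", "),
              if (length(x$loops)) paste(names(x$loops), collapse = ", ")
              else "none"))
  invisible(x)
}

# Split each quad (a,b,c,d) into triangles (a,b,c) and (a,c,d); orientation
# is preserved.
triangulate_quads <- function(quads) {
  rbind(quads[, c(1L, 2L, 3L), drop = FALSE],
        quads[, c(1L, 3L, 4L), drop = FALSE])
}

tri_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1L], , drop = FALSE]
  u <- nodes[tris[, 2L], , drop = FALSE] - a
  v <- nodes[tris[, 3L], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a shell mesh
#' @param model a [vessel_model()].
#' @return area in mm^2.
#' @export
surface_area <- function(model) {
  sum(tri_areas(model$nodes, triangulate_quads(model$quads)))
}

loop_centroid <- function(model, loop) {
  if (is.character(loop)) loop <- model$loops[[loop]]
  colMeans(model$nodes[loop, , drop = FALSE])
}

# Best-fit plane normal of an ordered closed polygon (Newell's method).
loop_normal <- function(model, loop) {
  if (is.character(loop)) loop <- model$loops[[loop]]
  p <- model$nodes[loop, , drop = FALSE]
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  unitize(c(sum((p[, 2] - q[, 2]) * (p[, 3] + q[, 3])),
            sum((p[, 3] - q[, 3]) * (p[, 1] + q[, 1])),
            sum((p[, 1] - q[, 1]) * (p[, 2] + q[, 2]))))
}

# Connected components over shared nodes; returns per-node component id.
node_components <- function(model) {
  n <- nrow(model$nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(model$quads))) {
    q <- model$quads[e, ]
    r <- find(q[1L])
    for (j in 2:4) parent[find(q[j])] <- r
  }
  vapply(seq_len(n), find, integer(1))
}

# Apply a function to node coordinates, keeping topology.
map_nodes <- function(model, f) {
  model$nodes <- f(model$nodes)
  model
}
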