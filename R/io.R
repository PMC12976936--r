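#' Write a shell mesh as STL
#'
#' Quads are split into triangles. ASCII and binary STL are supported; no
#' installed R package provides STL at the time of writing, so the format is
#' emitted directly (80-byte header + uint32 count + 50-byte facet records
#' for binary).
#'
#' @param model a [vessel_model()].
#' @param path output file.
#' @param binary write binary STL (default) or ASCII.
#' @param name solid name for ASCII output.
#' @return `path`, invisibly.
#' @export
write_stl <- function(model, path, binary = TRUE, name = "tevgsim") {
  tris <- triangulate_quads(model$quads)
  v1 <- model$nodes[tris[, 1L], , drop = FALSE]
  v2 <- model$nodes[tris[, 2L], , drop = FALSE]
  v3 <- model$nodes[tris[, 3L], , drop = FALSE]
  u <- v2 - v1; v <- v3 - v1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  nt <- nrow(tris)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nt), con, size = 4L, endian = "little")
    rec <- t(cbind(nrm, v1, v2, v3))        # 12 floats per facet
    for (i in seq_len(nt)) {
      writeBin(as.numeric(rec[, i]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(m) sprintf("%.12g %.12g %.12g", m[, 1], m[, 2], m[, 3])
    txt <- c(sprintf("solid %s", name),
             as.vector(rbind(sprintf("  facet normal %s", fmt(nrm)),
                             "    outer loop",
                             sprintf("      vertex %s", fmt(v1)),
                             sprintf("      vertex %s", fmt(v2)),
                             sprintf("      vertex %s", fmt(v3)),
                             "    endloop", "  endfacet")),
             sprintf("endsolid %s", name))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Read an STL surface
#'
#' Reads ASCII or binary STL into a triangle soup; duplicate vertices are
#' merged. Triangles are wrapped in a [vessel_model()] with degenerate quads
#' (fourth node repeated), adequate for distance metrics and visual checks.
#'
#' @param path STL file.
#' @return list with `vertices` (n x 3) and `triangles` (m x 3).
#' @export
read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 6L)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") &&
    !is_binary_stl(path)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    v <- matrix(0, 3L * nt, 3L)
    for (i in seq_len(nt)) {
      vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)
      v[3L * i - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  key <- paste(signif(v[, 1], 12), signif(v[, 2], 12), signif(v[, 3], 12))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- v[uk, , drop = FALSE]
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, triangles = tris)
}

is_binary_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  identical(sz, 84 + 50 * as.numeric(nt))
}

#' Write a tagged quad shell mesh as legacy VTK
#'
#' ASCII legacy VTK unstructured grid with per-cell region tags, readable by
#' ParaView and meshio.
#'
#' @param model a [vessel_model()].
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(model, path) {
  n <- nrow(model$nodes); m <- nrow(model$quads)
  tags <- as.integer(factor(model$region))
  txt <- c("# vtk DataFile Version 3.0", "tevgsim shell mesh", "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", n),
           sprintf("%.10g %.10g %.10g", model$nodes[, 1], model$nodes[, 2],
                   model$nodes[, 3]),
           sprintf("CELLS %d %d", m, 5L * m),
           sprintf("4 %d %d %d %d", model$quads[, 1] - 1L,
                   model$quads[, 2] - 1L, model$quads[, 3] - 1L,
                   model$quads[, 4] - 1L),
           sprintf("CELL_TYPES %d", m),
           rep("9", m),
           sprintf("CELL_DATA %d", m),
           "SCALARS region int 1", "LOOKUP_TABLE default",
           sprintf("%d", tags),
           sprintf("FIELD FieldData 1"),
           sprintf("region_names 1 %d string", nlevels(factor(model$region))),
           levels(factor(model$region)))
  writeLines(txt, path)
  invisible(path)
}

#' Read / write anatomy configuration as YAML
#'
#' @param path YAML file.
#' @return [anatomy_config()] (read) or `path` invisibly (write).
#' @export
read_anatomy_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(anatomy_config, y)
}

#' @rdname read_anatomy_config
#' @param config an [anatomy_config()].
#' @export
write_anatomy_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Serialize deviation specs to / from YAML or CSV rows
#'
#' @param devs list of [deviation_spec()]s.
#' @param path output file (`.yaml`/`.yml` or `.csv`).
#' @return `path` invisibly (write); list of specs (read).
#' @export
write_deviations <- function(devs, path) {
  df <- do.call(rbind, lapply(devs, function(d)
    data.frame(t_LR = d$translation_mm[1], t_AP = d$translation_mm[2],
               t_IS = d$translation_mm[3], r_LR = d$rotation_deg[1],
               r_AP = d$rotation_deg[2], r_IS = d$rotation_deg[3],
               scale = d$scale)))
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])),
                     path)
  else write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deviations
#' @export
read_deviations <- function(path) {
  df <- if (grepl("\\.ya?ml$", path)) {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  } else read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    deviation_spec(c(df$t_LR[i], df$t_AP[i], df$t_IS[i]),
                   c(df$r_LR[i], df$r_AP[i], df$r_IS[i]), df$scale[i]))
}

#' Write hemodynamic / deviation metrics as JSON
#'
#' @param x a named list or metrics record.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
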