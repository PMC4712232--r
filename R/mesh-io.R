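#' Read and write triangulated surfaces (OFF, Gmsh MSH v2 ASCII, binary PLY)
#'
#' Minimal, self-contained readers and writers for the three interchange
#' formats used by the package: OFF, Gmsh MSH version 2 ASCII (triangle
#' elements only), and binary little-endian PLY.
#'
#' @param s A [tri_surface()].
#' @param path File path.
#' @param label Label given to surfaces read from disk.
#' @return Writers return `path` invisibly; readers return a
#'   [tri_surface()].
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
write_off <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(s$vertices), nrow(s$triangles))),
             con)
  utils::write.table(format(s$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, s$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_off <- function(path, label = "surface") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file", call. = FALSE)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vert <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, 3,
                 byrow = TRUE)
  fl <- lapply(lines[(3 + nv):(2 + nv + nf)],
               function(l) scan(text = l, quiet = TRUE))
  if (any(vapply(fl, `[`, numeric(1), 1) != 3)) {
    stop("only triangular faces supported", call. = FALSE)
  }
  tris <- do.call(rbind, lapply(fl, function(x) x[2:4] + 1))
  tri_surface(vert, tris, label)
}

#' @rdname mesh_io
#' @export
write_msh <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(s$vertices); nf <- nrow(s$triangles)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", as.character(nv)), con)
  utils::write.table(cbind(seq_len(nv),
                           format(s$vertices, digits = 17, trim = TRUE,
                                  scientific = FALSE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(nf)), con)
  utils::write.table(cbind(seq_len(nf), 2L, 2L, 0L, 1L, s$triangles),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_msh <- function(path, label = "surface") {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- which(lines == paste0("$", name)) + 1L
    i1 <- which(lines == paste0("$End", name)) - 1L
    if (length(i0) != 1 || length(i1) != 1) {
      stop(sprintf("missing $%s section", name), call. = FALSE)
    }
    lines[i0:i1]
  }
  fmt <- scan(text = sec("MeshFormat")[1], quiet = TRUE)
  if (floor(fmt[1]) != 2) stop("only MSH v2 ASCII supported", call. = FALSE)
  nodes <- sec("Nodes")
  nv <- as.integer(nodes[1])
  nd <- matrix(scan(text = nodes[-1], quiet = TRUE), nv, 4, byrow = TRUE)
  elems <- sec("Elements")
  el <- lapply(elems[-1], function(l) scan(text = l, quiet = TRUE))
  tri <- el[vapply(el, `[`, numeric(1), 2) == 2]
  tris <- do.call(rbind, lapply(tri, function(x) {
    ntags <- x[3]
    x[(4 + ntags):(6 + ntags)]
  }))
  # node ids may be non-contiguous: remap
  id_map <- integer(max(nd[, 1]))
  id_map[as.integer(nd[, 1])] <- seq_len(nv)
  tri_surface(nd[, 2:4], matrix(id_map[as.integer(tris)], ncol = 3), label)
}

#' @rdname mesh_io
#' @export
write_ply <- function(s, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("ply", "format binary_little_endian 1.0",
              sprintf("element vertex %d", nrow(s$vertices)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(s$triangles)),
              "property list uchar int vertex_indices", "end_header")
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(s$vertices)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(s$triangles))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(s$triangles[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path, label = "surface") {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ch <- character()
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("truncated PLY header", call. = FALSE)
      if (b == charToRaw("\n")) break
      ch <- c(ch, rawToChar(b))
    }
    line <- paste(ch, collapse = "")
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (!any(grepl("binary_little_endian", header))) {
    stop("only binary little-endian PLY supported", call. = FALSE)
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 header, value = TRUE)))
  vsize <- if (any(grepl("property double x", header))) 8L else 4L
  vert <- matrix(readBin(con, "numeric", nv * 3, size = vsize,
                         endian = "little"), nv, 3, byrow = TRUE)
  tris <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", 1))
    if (cnt != 3L) stop("only triangular faces supported", call. = FALSE)
    tris[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
  }
  tri_surface(vert, tris, label)
}

#' Write or read a full anatomy with its compartment manifest
#'
#' Each surface is written in the requested mesh format next to a JSON
#' manifest listing `{label, file, conductivity}` per compartment (the heart
#' source surface has conductivity `null`).
#'
#' @param vc A [volume_conductor()].
#' @param dir Output directory (created if missing).
#' @param format `"msh"`, `"off"` or `"ply"`.
#' @return `write_anatomy()` returns the manifest path invisibly;
#'   `read_anatomy()` a [volume_conductor()].
#' @export
write_anatomy <- function(vc, dir, format = c("msh", "off", "ply")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writer <- switch(format, msh = write_msh, off = write_off, ply = write_ply)
  sig <- c(list(torso = vc$torso_sigma),
           lapply(vc$organs, `[[`, "sigma"), list(heart = NULL))
  ss <- anatomy_surfaces(vc)
  manifest <- lapply(names(ss), function(nm) {
    file <- paste0(nm, ".", format)
    writer(ss[[nm]], file.path(dir, file))
    list(label = nm, file = file, conductivity = sig[[nm]])
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mpath)
}

#' @rdname write_anatomy
#' @export
read_anatomy <- function(dir) {
  mpath <- if (dir.exists(dir)) file.path(dir, "manifest.json") else dir
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  dir <- dirname(mpath)
  reader_for <- function(file) {
    ext <- tolower(sub(".*\\.", "", file))
    switch(ext, msh = read_msh, off = read_off,
           ply = read_ply, stop("unknown mesh format: ", file, call. = FALSE))
  }
  entries <- lapply(manifest, function(e) {
    s <- reader_for(e$file)(file.path(dir, e$file), label = e$label)
    list(label = e$label, surface = s, sigma = e$conductivity)
  })
  labels <- vapply(entries, `[[`, character(1), "label")
  torso <- entries[[which(labels == "torso")]]
  heart <- entries[[which(labels == "heart")]]
  organs <- entries[!(labels %in% c("torso", "heart"))]
  volume_conductor(torso$surface,
                   setNames(lapply(organs, function(e)
                     list(surface = e$surface, sigma = e$sigma)),
                     vapply(organs, `[[`, character(1), "label")),
                   heart$surface, torso_sigma = torso$sigma)
}
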