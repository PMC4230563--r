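#' Read a triangle mesh from PLY, OBJ or STL
#'
#' Supported formats: PLY (ascii and binary little-endian, float or double
#' vertex properties), Wavefront OBJ (`v`/`f` records, polygonal faces are
#' fan-triangulated) and STL (ascii and binary; vertices are de-duplicated to
#' rebuild connectivity). Units are taken to be millimetres.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"stl"`; default guessed from the
#'   file extension.
#' @param validate run [validate_mesh()] on the result (default `TRUE`).
#' @param closed when validating, require a closed surface.
#' @param name organ label; default the file base name.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL, validate = TRUE, closed = TRUE,
                      name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "obj", "stl"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  mesh <- switch(format,
                 ply = read_ply(path, name),
                 obj = read_obj(path, name),
                 stl = read_stl(path, name))
  if (validate) mesh <- validate_mesh(mesh, closed = closed)
  mesh
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format one of `"ply"`, `"obj"`, `"stl"`; default guessed from the
#'   extension.
#' @param binary for PLY/STL, write the binary little-endian flavour
#'   (PLY vertices are stored as doubles, STL as the format's float32).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L) {
    stop("refusing to write an empty mesh")
  }
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "obj", "stl"))
  switch(format,
         ply = write_ply(mesh, path, binary),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path, binary))
  invisible(path)
}

# ---- PLY -------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", 1L, size = sz, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(sz < 4L && startsWith(type, "u")))
  }
}

read_ply <- function(path, name) {
  raw <- readBin(path, "raw", file.size(path))
  marker <- charToRaw("end_header")
  hdr_end <- NULL
  # locate end_header + newline in the raw stream
  hits <- which(raw == marker[1])
  for (h in hits) {
    if (h + length(marker) <= length(raw) &&
        identical(raw[h:(h + length(marker) - 1L)], marker)) { hdr_end <- h; break }
  }
  if (is.null(hdr_end)) stop("PLY header missing end_header")
  body_start <- hdr_end + length(marker)
  # skip optional \r and the \n terminating end_header
  while (body_start <= length(raw) && raw[body_start] %in% as.raw(c(13L, 10L))) {
    body_start <- body_start + 1L
    if (raw[body_start - 1L] == as.raw(10L)) break
  }
  hdr_lines <- strsplit(rawToChar(raw[seq_len(hdr_end - 1L)]), "\r?\n")[[1]]
  if (!identical(trimws(hdr_lines[1]), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; elements <- list(); cur <- NULL
  for (ln in hdr_lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                                item_type = tok[4])
      } else {
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (is.null(fmt)) stop("PLY header missing format line")
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }
  ve <- elements[["vertex"]]; fe <- elements[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY missing vertex or face element")

  if (fmt == "ascii") {
    lines <- strsplit(rawToChar(raw[body_start:length(raw)]), "\r?\n")[[1]]
    lines <- lines[nzchar(trimws(lines))]
    nv <- ve$count; nf <- fe$count
    if (length(lines) < nv + nf) stop("PLY data truncated")
    vt <- lapply(strsplit(trimws(lines[seq_len(nv)]), "\\s+"), as.numeric)
    vmat <- do.call(rbind, vt)
    pn <- names(ve$props)
    verts <- vmat[, match(c("x", "y", "z"), pn), drop = FALSE]
    ft <- lapply(strsplit(trimws(lines[nv + seq_len(nf)]), "\\s+"), as.integer)
    faces <- do.call(rbind, lapply(ft, function(r) {
      n <- r[1]; poly <- r[2:(1 + n)] + 1L
      if (n == 3L) matrix(poly, 1L) else
        do.call(rbind, lapply(2:(n - 1L), function(k) c(poly[1], poly[k], poly[k + 1L])))
    }))
  } else {
    con <- rawConnection(raw[body_start:length(raw)], "rb"); on.exit(close(con))
    nv <- ve$count
    pn <- names(ve$props)
    types <- vapply(ve$props, `[[`, "", "type")
    if (length(unique(types)) == 1L &&
        types[1] %in% c("float", "float32", "double", "float64")) {
      vals <- readBin(con, "double", nv * length(pn), size = ply_type_size[[types[1]]],
                      endian = "little")
      vmat <- matrix(vals, nv, length(pn), byrow = TRUE)
    } else {
      vmat <- matrix(NA_real_, nv, length(pn))
      for (i in seq_len(nv)) for (j in seq_along(pn)) {
        vmat[i, j] <- ply_read_scalar(con, ve$props[[j]]$type)
      }
    }
    verts <- vmat[, match(c("x", "y", "z"), pn), drop = FALSE]
    faces <- vector("list", fe$count)
    lp <- fe$props[[1]]
    for (i in seq_len(fe$count)) {
      n <- ply_read_scalar(con, lp$count_type)
      poly <- integer(n)
      for (k in seq_len(n)) poly[k] <- ply_read_scalar(con, lp$item_type)
      poly <- poly + 1L
      faces[[i]] <- if (n == 3L) matrix(poly, 1L) else
        do.call(rbind, lapply(2:(n - 1L), function(k) c(poly[1], poly[k], poly[k + 1L])))
    }
    faces <- do.call(rbind, faces)
  }
  triangle_mesh(verts, faces, name)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           sprintf("property %s x", if (binary) "double" else "float"),
           sprintf("property %s y", if (binary) "double" else "float"),
           sprintf("property %s z", if (binary) "double" else "float"),
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

# ---- OBJ -------------------------------------------------------------------

read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vln <- lines[startsWith(lines, "v ")]
  fln <- lines[startsWith(lines, "f ")]
  if (length(vln) == 0L) stop("OBJ has no vertices")
  verts <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vln), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(sub("^f\\s+", "", fln), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x, "/"), `[`, "", 1L))
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
    if (length(idx) == 3L) matrix(idx, 1L) else
      do.call(rbind, lapply(2:(length(idx) - 1L), function(k) c(idx[1], idx[k], idx[k + 1L])))
  }))
  triangle_mesh(verts, faces, name)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

# ---- STL -------------------------------------------------------------------

stl_soup_to_mesh <- function(tri, name) {
  # tri: (3*nf) x 3 matrix of corner coordinates; weld identical corners
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  first <- match(key, key)
  keep <- which(first == seq_len(nrow(tri)))
  verts <- tri[keep, , drop = FALSE]
  idx <- match(first, keep)
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces, name)
}

read_stl <- function(path, name) {
  txt <- tryCatch(suppressWarnings(readLines(path, n = 2L, warn = FALSE)),
                  error = function(e) character())
  is_ascii <- length(txt) >= 1L && startsWith(trimws(txt[1]), "solid") &&
    (length(txt) < 2L || grepl("facet|endsolid", txt[2]))
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "vertex")]
    tri <- do.call(rbind, lapply(strsplit(sub("^vertex\\s+", "", vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80L)
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    tri <- matrix(NA_real_, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
      tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
      readBin(con, "raw", 2L)
    }
  }
  if (is.null(tri) || nrow(tri) %% 3L != 0L) stop("malformed STL: ", path)
  stl_soup_to_mesh(tri, name)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(n[i, ], t(v[f[i, ], ])), con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
  }
  invisible(path)
}
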