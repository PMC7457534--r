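#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary little-endian PLY, and Wavefront OBJ. Coordinates
#' are taken to be millimetres. Non-triangular faces are fan-triangulated with
#' a warning; degenerate faces are dropped (with a message reporting the
#' count). Per-face organ labels are read from an integer PLY face property
#' \code{label} (with a \code{comment organlabel <code> <name>} map in the
#' header) or from OBJ group names.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"ply"} or \code{"obj"}.
#' @return a \code{\link{triangle_mesh}}.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "obj"))
      stop("cannot infer format from extension: ", path)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, ply = .read_ply(path), obj = .read_obj(path))
}

#' Write a triangle mesh to PLY or OBJ
#'
#' @param mesh a \code{\link{triangle_mesh}}.
#' @param path output file path.
#' @param format \code{"auto"}, \code{"ply"} or \code{"obj"}.
#' @param binary write binary little-endian PLY (ignored for OBJ).
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "obj"))
      stop("cannot infer format from extension: ", path)
  }
  switch(format,
         ply = .write_ply(mesh, path, binary = binary),
         obj = .write_obj(mesh, path))
  invisible(path)
}

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw, off, type) {
  sz <- .ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64"))
    "double" else "integer"
  signed <- !type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")
  val <- readBin(raw[(off + 1L):(off + sz)], what = what, size = sz, n = 1L,
                 signed = if (sz >= 4L) TRUE else signed,
                 endian = "little")
  list(value = as.numeric(val), off = off + sz)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  label_map <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "comment") {
      if (length(tok) >= 4L && tok[2] == "organlabel")
        label_map[tok[3]] <- paste(tok[-(1:3)], collapse = " ")
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  if (!all(c("vertex", "face") %in% names(elements)))
    stop("PLY file lacks vertex or face element")

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    parsed <- .parse_ply_ascii(txt, elements)
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    parsed <- .parse_ply_binary(raw, elements)
  }
  labels <- NULL
  if (!is.null(parsed$labels)) {
    labels <- as.character(parsed$labels)
    hit <- labels %in% names(label_map)
    labels[hit] <- label_map[labels[hit]]
    labels[labels == "0"] <- NA_character_
  }
  .finish_mesh(parsed$vertices, parsed$face_list, labels)
}

.parse_ply_ascii <- function(txt, elements) {
  i <- 1L
  vertices <- NULL
  face_list <- NULL
  labels <- NULL
  for (el in elements) {
    if (el$count == 0L) next
    lines <- txt[i:(i + el$count - 1L)]
    i <- i + el$count
    toks <- strsplit(trimws(lines), "\\s+")
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      mat <- do.call(rbind, lapply(toks, function(t) as.numeric(t)))
      vertices <- mat[, match(c("x", "y", "z"), pn), drop = FALSE]
    } else if (el$name == "face") {
      pn <- vapply(el$props, `[[`, "", "name")
      is_list <- vapply(el$props, `[[`, TRUE, "list")
      face_list <- vector("list", el$count)
      if (any(pn == "label" & !is_list)) labels <- numeric(el$count)
      for (r in seq_len(el$count)) {
        vals <- as.numeric(toks[[r]])
        pos <- 1L
        for (p in seq_along(el$props)) {
          if (is_list[p]) {
            k <- vals[pos]
            idx <- vals[(pos + 1L):(pos + k)]
            if (pn[p] %in% c("vertex_indices", "vertex_index"))
              face_list[[r]] <- idx + 1
            pos <- pos + 1L + k
          } else {
            if (pn[p] == "label") labels[r] <- vals[pos]
            pos <- pos + 1L
          }
        }
      }
    }
    # other elements are skipped (their lines were consumed)
  }
  list(vertices = vertices, face_list = face_list, labels = labels)
}

.parse_ply_binary <- function(raw, elements) {
  off <- 0L
  vertices <- NULL
  face_list <- NULL
  labels <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      types <- vapply(el$props, `[[`, "", "type")
      if (any(vapply(el$props, `[[`, TRUE, "list")))
        stop("list property in PLY vertex element is not supported")
      row_sz <- sum(.ply_type_size[types])
      vertices <- matrix(0, el$count, 3L)
      want <- match(c("x", "y", "z"), pn)
      for (r in seq_len(el$count)) {
        o <- off
        for (p in seq_along(el$props)) {
          s <- .ply_read_scalar(raw, o, types[p])
          w <- match(p, want)
          if (!is.na(w)) vertices[r, w] <- s$value
          o <- s$off
        }
        off <- off + row_sz
      }
    } else if (el$name == "face") {
      pn <- vapply(el$props, `[[`, "", "name")
      is_list <- vapply(el$props, `[[`, TRUE, "list")
      face_list <- vector("list", el$count)
      if (any(pn == "label" & !is_list)) labels <- numeric(el$count)
      for (r in seq_len(el$count)) {
        for (p in seq_along(el$props)) {
          if (is_list[p]) {
            s <- .ply_read_scalar(raw, off, el$props[[p]]$count_type)
            k <- as.integer(s$value)
            off <- s$off
            idx <- numeric(k)
            for (q in seq_len(k)) {
              s <- .ply_read_scalar(raw, off, el$props[[p]]$type)
              idx[q] <- s$value
              off <- s$off
            }
            if (pn[p] %in% c("vertex_indices", "vertex_index"))
              face_list[[r]] <- idx + 1
          } else {
            s <- .ply_read_scalar(raw, off, el$props[[p]]$type)
            if (pn[p] == "label") labels[r] <- s$value
            off <- s$off
          }
        }
      }
    } else {
      sizes <- .ply_type_size[vapply(el$props, `[[`, "", "type")]
      off <- off + el$count * sum(sizes)
    }
  }
  list(vertices = vertices, face_list = face_list, labels = labels)
}

# fan-triangulate polygon faces and build the mesh
.finish_mesh <- function(vertices, face_list, labels) {
  ns <- lengths(face_list)
  if (any(ns < 3L)) stop("face with fewer than 3 vertices")
  if (any(ns > 3L))
    warning(sum(ns > 3L), " non-triangular face(s) fan-triangulated")
  tri <- vector("list", length(face_list))
  lab <- vector("list", length(face_list))
  for (r in seq_along(face_list)) {
    f <- face_list[[r]]
    k <- length(f)
    tri[[r]] <- cbind(f[1], f[2:(k - 1L)], f[3:k])
    if (!is.null(labels)) lab[[r]] <- rep(labels[r], k - 2L)
  }
  triangle_mesh(vertices, do.call(rbind, tri),
                labels = if (is.null(labels)) NULL else unlist(lab))
}

.label_codes <- function(labels) {
  lev <- unique(labels[!is.na(labels)])
  code <- match(labels, lev)
  code[is.na(code)] <- 0L
  list(levels = lev, code = code)
}

.write_ply <- function(mesh, path, binary = FALSE) {
  has_lab <- !is.null(mesh$labels)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"))
  if (has_lab) {
    lc <- .label_codes(mesh$labels)
    hdr <- c(hdr, sprintf("comment organlabel %d %s",
                          seq_along(lc$levels), lc$levels))
  }
  hdr <- c(hdr,
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           if (has_lab) "property int label",
           "end_header")
  if (!binary) {
    vtx <- apply(mesh$vertices, 1L, function(v)
      paste(sprintf("%.9g", v), collapse = " "))
    f0 <- mesh$faces - 1L
    fc <- paste(3L, f0[, 1L], f0[, 2L], f0[, 3L])
    if (has_lab) fc <- paste(fc, lc$code)
    writeLines(c(hdr, vtx, fc), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(t(mesh$vertices)), con, size = 8L, endian = "little")
    for (r in seq_len(nrow(mesh$faces))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[r, ] - 1L), con, size = 4L,
               endian = "little")
      if (has_lab) writeBin(as.integer(lc$code[r]), con, size = 4L,
                            endian = "little")
    }
  }
  invisible(path)
}

.write_obj <- function(mesh, path) {
  out <- c("# wavefront obj",
           apply(mesh$vertices, 1L, function(v)
             paste("v", paste(sprintf("%.9g", v), collapse = " "))))
  if (is.null(mesh$labels)) {
    out <- c(out, paste("f", mesh$faces[, 1L], mesh$faces[, 2L],
                        mesh$faces[, 3L]))
  } else {
    lab <- mesh$labels
    lab[is.na(lab)] <- "unlabeled"
    for (g in unique(lab)) {
      idx <- which(lab == g)
      out <- c(out, paste("g", g),
               paste("f", mesh$faces[idx, 1L], mesh$faces[idx, 2L],
                     mesh$faces[idx, 3L]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

.read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  toks <- strsplit(txt, "\\s+")
  key <- vapply(toks, `[[`, "", 1L)
  vertices <- do.call(rbind, lapply(toks[key == "v"], function(t)
    as.numeric(t[2:4])))
  face_list <- list()
  labels <- character(0)
  cur_lab <- NA_character_
  for (t in toks) {
    if (t[1] %in% c("g", "usemtl")) {
      cur_lab <- if (length(t) > 1L) t[2] else NA_character_
    } else if (t[1] == "f") {
      idx <- as.numeric(vapply(t[-1], function(s)
        strsplit(s, "/", fixed = TRUE)[[1]][1], ""))
      idx[idx < 0] <- nrow(vertices) + idx[idx < 0] + 1
      face_list[[length(face_list) + 1L]] <- idx
      labels <- c(labels, cur_lab)
    }
  }
  if (length(face_list) == 0L) stop("OBJ file has no faces")
  if (all(is.na(labels))) labels <- NULL
  .finish_mesh(vertices, face_list, labels)
}
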