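#' Construct a TriangleMesh
#'
#' @param vertices numeric n x 3 matrix (or coercible) of vertex coordinates.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param junctionRegion optional integer vector of junction-rim vertex
#'   indices.
#' @return a validated \linkS4class{TriangleMesh}.
#' @export
TriangleMesh <- function(vertices, faces, junctionRegion = integer(0)) {
  v <- matrix(as.numeric(as.matrix(vertices)), ncol = 3)
  f <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  new("TriangleMesh", vertices = v, faces = f,
      junctionRegion = as.integer(junctionRegion))
}

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' Duplicate vertices are merged within \code{tol} and face winding is made
#' consistent (outward for closed meshes). A PLY integer vertex property
#' named \code{junction} (1 = junction) populates the junction region;
#' alternatively supply a sidecar JSON via \code{\link{readJunctionJSON}}.
#'
#' @param path file path.
#' @param format one of "auto", "ply", "obj", "stl"; "auto" uses the file
#'   extension.
#' @param tol merge tolerance for duplicate vertices (absolute).
#' @param fixOrientation make winding consistent and outward (default TRUE).
#' @return a \linkS4class{TriangleMesh}.
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj", "stl"),
                     tol = 1e-9, fixOrientation = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj", "stl"))
      stop("cannot infer mesh format from extension '", ext, "'")
    format <- ext
  }
  parsed <- switch(format,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path))
  if (nrow(parsed$faces) == 0L) stop("empty mesh: no faces in ", path)
  m <- TriangleMesh(parsed$vertices, parsed$faces, parsed$junction)
  m <- mergeDuplicateVertices(m, tol = tol)
  if (fixOrientation) m <- fixWinding(m)
  validObject(m)
  m
}

#' Write a triangle mesh
#'
#' PLY output is ASCII and carries the junction region as an integer vertex
#' property \code{junction}; OBJ and STL drop it.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output file path.
#' @param format "auto" (from extension), "ply", "obj" or "stl".
#' @return \code{path}, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    jflag <- integer(nrow(v))
    jflag[mesh@junctionRegion] <- 1L
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 "property int junction",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g %d", v[, 1], v[, 2], v[, 3], jflag),
               con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else if (format == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "stl") {
    writeLines("solid spinemorph", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           tri[, 1], tri[, 2], tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid spinemorph", con)
  } else stop("unknown mesh format: ", format)
  invisible(path)
}

#' Read junction regions from a sidecar JSON
#'
#' The sidecar maps spine ids to 0-based vertex index arrays:
#' \code{{"spine_001": [0, 5, 9], ...}}.
#'
#' @param path JSON file path.
#' @return named list of 1-based integer vectors.
#' @export
readJunctionJSON <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(raw, function(ix) as.integer(ix) + 1L)
}

#' Merge duplicate vertices
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param tol absolute coordinate tolerance; vertices whose coordinates agree
#'   after rounding to this granularity are merged.
#' @return the deduplicated mesh (degenerate faces removed).
#' @export
mergeDuplicateVertices <- function(mesh, tol = 1e-9) {
  v <- mesh@vertices
  if (nrow(v) == 0) return(mesh)
  key <- apply(round(v / tol) * tol, 1, paste, collapse = ",")
  first <- !duplicated(key)
  newv <- v[first, , drop = FALSE]
  map <- match(key, key[first])  # old vertex index -> compacted index
  f <- matrix(map[mesh@faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  jr <- unique(map[mesh@junctionRegion])
  TriangleMesh(newv, f[keep, , drop = FALSE], jr)
}

#' Make face winding consistent and outward
#'
#' Propagates a consistent orientation across edge-adjacent faces and, for
#' closed meshes, flips globally so the signed volume is positive (outward
#' normals).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return the re-wound mesh.
#' @export
fixWinding <- function(mesh) {
  f <- mesh@faces
  nf <- nrow(f)
  if (nf == 0) return(mesh)
  # undirected edge table -> adjacency between faces
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(f[, 1], f[, 2], seq_len(nf)),
                 cbind(f[, 2], f[, 3], seq_len(nf)),
                 cbind(f[, 3], f[, 1], seq_len(nf)))
  keys <- ek(edges[, 1], edges[, 2])
  byEdge <- split(seq_len(nrow(edges)), keys)
  visited <- logical(nf); flipped <- logical(nf)
  for (start in seq_len(nf)) {
    if (visited[start]) next
    queue <- start; visited[start] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      tri <- f[cur, ]; if (flipped[cur]) tri <- rev(tri)
      dir <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
      for (e in seq_len(3)) {
        k <- ek(dir[e, 1], dir[e, 2])
        for (row in byEdge[[k]]) {
          nb <- edges[row, 3]
          if (nb == cur || visited[nb]) next
          ntri <- f[nb, ]
          ndir <- rbind(ntri[c(1, 2)], ntri[c(2, 3)], ntri[c(3, 1)])
          same <- any(ndir[, 1] == dir[e, 1] & ndir[, 2] == dir[e, 2])
          # consistent winding means the shared edge runs in opposite
          # directions in the two faces
          flipped[nb] <- same
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  f[flipped, ] <- f[flipped, c(1, 3, 2)]
  m <- TriangleMesh(mesh@vertices, f, mesh@junctionRegion)
  if (isWatertight(m) && signedVolume(m) < 0)
    m@faces <- m@faces[, c(1, 3, 2)]
  m
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated PLY header in ", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmtline <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmtline)
  if (!binary && !grepl("ascii", fmtline))
    stop("unsupported PLY format: ", fmtline)
  # parse element/property declarations in order
  elements <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(type = tok[4], list = TRUE,
                                    count_type = tok[3])
      } else {
        cur$props[[tok[3]]] <- list(type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY without vertex/face elements: ", path)

  if (binary) {
    dat <- read_ply_binary(con, elements)
  } else {
    dat <- read_ply_ascii(con, elements)
  }
  vnames <- names(elements$vertex$props)
  if (!all(c("x", "y", "z") %in% vnames))
    stop("PLY vertex element lacks x/y/z")
  V <- cbind(dat$vertex$x, dat$vertex$y, dat$vertex$z)
  faces <- dat$face[[1]]
  if (any(vapply(faces, length, 0L) != 3))
    faces <- unlist(lapply(faces, function(p) {
      if (length(p) < 3) stop("face with fewer than 3 vertices")
      # fan-triangulate polygons
      lapply(seq_len(length(p) - 2), function(i) p[c(1, i + 1, i + 2)])
    }), recursive = FALSE)
  F <- do.call(rbind, faces) + 1L
  junction <- integer(0)
  if ("junction" %in% vnames)
    junction <- which(dat$vertex$junction == 1)
  list(vertices = V, faces = F, junction = junction)
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 0L
  out <- list()
  for (el in elements) {
    n <- el$count
    lines <- txt[pos + seq_len(n)]
    if (any(is.na(lines))) stop("truncated PLY body")
    pos <- pos + n
    toks <- strsplit(trimws(lines), "\\s+")
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      # single list property assumed (faces)
      vals <- lapply(toks, function(tk) {
        cnt <- as.integer(tk[1])
        if (length(tk) < cnt + 1) stop("truncated face row")
        as.integer(tk[1 + seq_len(cnt)])
      })
      out[[el$name]] <- list(vals)
    } else {
      mat <- do.call(rbind, lapply(toks, as.numeric))
      cols <- as.data.frame(mat)
      names(cols) <- names(el$props)
      out[[el$name]] <- cols
    }
  }
  out
}

ply_type_info <- function(type) {
  switch(type,
    float = , float32 = list(what = "numeric", size = 4),
    double = , float64 = list(what = "numeric", size = 8),
    char = , int8 = list(what = "integer", size = 1, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
    stop("unknown PLY type: ", type))
}

read_ply_binary <- function(con, elements) {
  rd <- function(type, n = 1) {
    ti <- ply_type_info(type)
    readBin(con, what = ti$what, n = n, size = ti$size,
            signed = if (is.null(ti$signed)) TRUE else ti$signed,
            endian = "little")
  }
  out <- list()
  for (el in elements) {
    pn <- names(el$props)
    isList <- vapply(el$props, `[[`, TRUE, "list")
    if (any(isList)) {
      vals <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        cnt <- rd(el$props[[1]]$count_type)
        vals[[i]] <- as.integer(rd(el$props[[1]]$type, cnt))
      }
      out[[el$name]] <- list(vals)
    } else {
      cols <- lapply(pn, function(p) numeric(el$count))
      names(cols) <- pn
      for (i in seq_len(el$count))
        for (p in pn) cols[[p]][i] <- rd(el$props[[p]]$type)
      out[[el$name]] <- as.data.frame(cols)
    }
  }
  out
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(tk) {
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(is.na(xyz))) stop("malformed OBJ vertex line")
    xyz
  }))
  if (is.null(V)) stop("no vertices in OBJ file ", path)
  faces <- lapply(strsplit(trimws(flines), "\\s+"), function(tk) {
    ix <- suppressWarnings(as.integer(sub("/.*", "", tk[-1])))
    if (any(is.na(ix)) || length(ix) < 3) stop("malformed OBJ face line")
    ix
  })
  F <- matrix(integer(0), 0, 3)
  if (length(faces))
    F <- do.call(rbind, unlist(lapply(faces, function(p)
      lapply(seq_len(length(p) - 2), function(i) p[c(1, i + 1, i + 2)])),
      recursive = FALSE))
  list(vertices = V, faces = F, junction = integer(0))
}

read_stl <- function(path) {
  firstBytes <- readBin(path, "raw", 80)
  isAscii <- identical(rawToChar(firstBytes[1:5]), "solid") &&
    !any(firstBytes == as.raw(0))
  if (isAscii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    if (!length(vl)) stop("no vertices in STL file ", path)
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(tk) as.numeric(tk[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    V <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      V[3 * i - 2:0, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  }
  if (nrow(V) %% 3 != 0) stop("malformed STL: vertex count not multiple of 3")
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F, junction = integer(0))
}
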