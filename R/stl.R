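# Minimal STL (stereolithography) mesh I/O, ASCII and binary, units mm.

#' Write a triangle mesh to STL
#'
#' @param mesh List with `vertices` (n x 3, mm) and `triangles` (m x 3,
#'   1-based vertex indices), e.g. from [brace_mesh()] or an anatomy's
#'   `skin` (`verts`/`tris`).
#' @param path Output path.
#' @param ascii Write ASCII STL if `TRUE`, binary (little-endian, float32)
#'   otherwise.
#' @param name Solid name for the ASCII header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE, name = "nightbrace") {
  V <- mesh$vertices %||% mesh$verts
  Tr <- mesh$triangles %||% mesh$tris
  stopifnot(is.matrix(V), ncol(V) == 3, is.matrix(Tr), ncol(Tr) == 3)
  m <- nrow(Tr)
  p1 <- V[Tr[, 1], , drop = FALSE]
  p2 <- V[Tr[, 2], , drop = FALSE]
  p3 <- V[Tr[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len

  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", name), con)
    for (i in seq_len(m)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(paste("endsolid", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("nightbrace binary STL:", name)))
    writeBin(header[1:80], con)
    writeBin(as.integer(m), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, p1, p2, p3))     # 12 floats per facet
    for (i in seq_len(m)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)     # attribute byte count
    }
  }
  invisible(path)
}

#' Read an STL file
#'
#' Auto-detects ASCII vs binary encoding; returns the triangle soup with
#' vertices deduplicated exactly.
#'
#' @param path STL file (mm).
#' @return List with `vertices` (n x 3) and `triangles` (m x 3 indices).
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("STL parse error at byte 0: empty file")
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  printable <- head_raw >= as.raw(0x20) & head_raw < as.raw(0x7f) |
    head_raw == as.raw(0x0a) | head_raw == as.raw(0x0d)
  txt <- rawToChar(head_raw[printable])
  is_ascii <- grepl("^\\s*solid", txt) && grepl("facet", txt)
  tri_pts <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  n_tri <- nrow(tri_pts) / 3
  key <- apply(tri_pts, 1, function(r) paste(r, collapse = ","))
  uk <- !duplicated(key)
  verts <- tri_pts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  list(vertices = verts,
       triangles = matrix(idx, n_tri, 3, byrow = TRUE))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3 != 0)
    stop("STL parse error: ASCII file has ", length(vl),
         " vertex lines (not a multiple of 3)")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(nums)) stop("STL parse error: malformed vertex line")
  nums
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  if (sz < 84) stop("STL parse error at byte 80: truncated header")
  m <- readBin(con, "integer", size = 4, endian = "little")
  need <- 84 + m * 50
  if (sz < need)
    stop("STL parse error at byte ", sz, ": expected ", need,
         " bytes for ", m, " facets")
  out <- matrix(0, 3 * m, 3)
  for (i in seq_len(m)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    out[(i - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  out
}
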