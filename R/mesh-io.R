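# Mesh file I/O: OBJ, ASCII PLY, and legacy VTK polydata (ASCII + binary).
#
# OBJ stores 1-based face indices (kept as-is internally); PLY and VTK store
# 0-based indices and are shifted at this boundary.  ASCII writers emit 17
# significant digits so a write/read round trip reproduces double-precision
# coordinates bitwise.

FMT_COORD <- "%.17g"

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("obj", "ply", "vtk")) ext else
    stop("cannot guess mesh format from extension: ", path)
}

#' Read a triangle mesh from OBJ, PLY (ASCII) or legacy VTK polydata
#' @param path file path
#' @param format one of `"auto"`, `"obj"`, `"ply"`, `"vtk"`
#' @param label structure tag to attach
#' @return a `triangle_mesh`
#' @export
read_mesh <- function(path, format = "auto", label = "UNLABELED") {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         obj = read_obj(path, label),
         ply = read_ply(path, label),
         vtk = read_vtk(path, label),
         stop("unknown mesh format: ", format))
}

#' Write a triangle mesh to OBJ, PLY (ASCII) or legacy VTK polydata
#' @param mesh a `triangle_mesh`
#' @param path output path
#' @param format `"auto"` (from extension), `"obj"`, `"ply"`, `"vtk"`
#' @param binary write binary legacy VTK (big-endian); ASCII otherwise
#' @export
write_mesh <- function(mesh, path, format = "auto", binary = FALSE) {
  if (format == "auto") format <- guess_format(path)
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         vtk = write_vtk(mesh, path, binary = binary),
         stop("unknown mesh format: ", format))
  invisible(path)
}

read_obj <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  v <- t(vapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                function(p) as.numeric(p[1:3]), numeric(3)))
  f <- t(vapply(strsplit(trimws(sub("^f", "", flines)), "\\s+"), function(p) {
    if (length(p) != 3) stop("non-triangular OBJ face")
    as.integer(sub("/.*", "", p))
  }, integer(3)))
  triangle_mesh(v, f, label)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(paste("v", FMT_COORD, FMT_COORD, FMT_COORD),
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  v <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                function(p) as.numeric(p[1:3]), numeric(3)))
  f <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), function(p) {
    if (as.integer(p[1]) != 3L) stop("non-triangular PLY face")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  triangle_mesh(v, f, label)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf(paste(FMT_COORD, FMT_COORD, FMT_COORD),
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

read_vtk <- function(path, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  l1 <- readLines(con, n = 1)
  if (!grepl("^# vtk DataFile", l1)) stop("not a legacy VTK file: ", path)
  readLines(con, n = 1)  # title
  mode <- trimws(readLines(con, n = 1))
  dataset <- trimws(readLines(con, n = 1))
  if (!grepl("POLYDATA", dataset)) stop("expected DATASET POLYDATA, got: ", dataset)
  pts_hdr <- trimws(readLines(con, n = 1))
  while (!nzchar(pts_hdr)) pts_hdr <- trimws(readLines(con, n = 1))
  tok <- strsplit(pts_hdr, "\\s+")[[1]]
  if (tok[1] != "POINTS") stop("expected POINTS, got: ", pts_hdr)
  nv <- as.integer(tok[2])
  vtype <- tok[3]
  if (mode == "ASCII") {
    vals <- scan(con, what = numeric(), n = 3 * nv, quiet = TRUE)
    v <- matrix(vals, ncol = 3, byrow = TRUE)
    poly_hdr <- trimws(readLines(con, n = 1))
    while (!nzchar(poly_hdr)) poly_hdr <- trimws(readLines(con, n = 1))
    tok <- strsplit(poly_hdr, "\\s+")[[1]]
    if (tok[1] != "POLYGONS") stop("expected POLYGONS, got: ", poly_hdr)
    nf <- as.integer(tok[2])
    ints <- scan(con, what = integer(), n = as.integer(tok[3]), quiet = TRUE)
    f <- matrix(NA_integer_, nf, 3)
    pos <- 1L
    for (i in seq_len(nf)) {
      cnt <- ints[pos]
      if (cnt != 3L) stop("non-triangular VTK polygon")
      f[i, ] <- ints[pos + 1:3] + 1L
      pos <- pos + 4L
    }
  } else if (mode == "BINARY") {
    sz <- if (vtype == "float") 4L else 8L
    v <- matrix(readBin(con, "numeric", n = 3 * nv, size = sz, endian = "big"),
                ncol = 3, byrow = TRUE)
    poly_hdr <- trimws(readLines(con, n = 1))
    while (!nzchar(poly_hdr)) poly_hdr <- trimws(readLines(con, n = 1))
    tok <- strsplit(poly_hdr, "\\s+")[[1]]
    if (tok[1] != "POLYGONS") stop("expected POLYGONS, got: ", poly_hdr)
    nf <- as.integer(tok[2])
    ints <- readBin(con, "integer", n = as.integer(tok[3]), size = 4L, endian = "big")
    f <- matrix(ints, ncol = 4, byrow = TRUE)
    if (any(f[, 1] != 3L)) stop("non-triangular VTK polygon")
    f <- f[, 2:4, drop = FALSE] + 1L
  } else stop("unknown VTK mode: ", mode)
  triangle_mesh(v, f, label)
}

write_vtk <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("# vtk DataFile Version 3.0\n", mesh$label, "\nBINARY\n",
                     "DATASET POLYDATA\n",
                     sprintf("POINTS %d double\n", nrow(v))),
              con, eos = NULL)
    writeBin(as.numeric(t(v)), con, size = 8L, endian = "big")
    writeChar(sprintf("\nPOLYGONS %d %d\n", nrow(f), 4L * nrow(f)), con, eos = NULL)
    writeBin(as.integer(t(cbind(3L, f - 1L))), con, size = 4L, endian = "big")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", mesh$label, "ASCII",
                 "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
    writeLines(sprintf(paste(FMT_COORD, FMT_COORD, FMT_COORD),
                       v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

# --- scene sequences --------------------------------------------------------

#' Write a scene sequence to a directory
#'
#' Emits one mesh file per frame and category named
#' `<category>_<frame:02d>.<ext>`, a plain-text `manifest.tsv`
#' (columns `frame`, `category`, `path`) and a `landmarks.json` holding the
#' per-frame landmark points.
#'
#' @param sequence a `scene_sequence`
#' @param dir output directory (created if needed)
#' @param format `"vtk"`, `"ply"` or `"obj"`
#' @param binary binary VTK output
#' @return the manifest path, invisibly
#' @export
write_scene_sequence <- function(sequence, dir, format = "vtk", binary = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(sequence$frames)) {
    sc <- sequence$frames[[i]]
    for (k in names(sc$structures)) {
      fn <- sprintf("%s_%02d.%s", tolower(k), i - 1L, format)
      write_mesh(sc$structures[[k]], file.path(dir, fn), format, binary = binary)
      rows[[length(rows) + 1]] <- data.frame(frame = i - 1L, category = k, path = fn)
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lm <- lapply(sequence$frames, function(sc) lapply(sc$landmarks, as.numeric))
  jsonlite::write_json(list(phase = sequence$phase, landmarks = lm),
                       file.path(dir, "landmarks.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(manifest)
}

#' Read a scene sequence from a manifest
#'
#' @param manifest path to a `manifest.tsv` (or a directory containing one)
#'   with columns `frame`, `category`, `path`; a `landmarks.json` beside it
#'   supplies the per-frame landmarks
#' @param format mesh format override (`"auto"` uses file extensions)
#' @return a validated `scene_sequence`; topology mismatches across frames
#'   raise an error
#' @export
read_scene_sequence <- function(manifest, format = "auto") {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.tsv")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  dir <- dirname(manifest)
  tab <- read.table(manifest, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("frame", "category", "path") %in% names(tab))) {
    stop("manifest must have columns frame, category, path")
  }
  bad <- setdiff(unique(tab$category), STRUCTURE_CATEGORIES)
  if (length(bad) > 0) stop("unknown category tag in manifest: ", paste(bad, collapse = ", "))
  lmpath <- file.path(dir, "landmarks.json")
  if (!file.exists(lmpath)) stop("landmarks.json not found next to manifest")
  meta <- jsonlite::read_json(lmpath)  # no simplification: keep frame lists
  frames_id <- sort(unique(tab$frame))
  frames <- lapply(seq_along(frames_id), function(i) {
    sub <- tab[tab$frame == frames_id[i], ]
    structures <- setNames(lapply(seq_len(nrow(sub)), function(r) {
      read_mesh(file.path(dir, sub$path[r]), format, label = sub$category[r])
    }), sub$category)
    lm <- meta$landmarks[[i]]
    labeled_scene(structures, lapply(lm, function(x) as.numeric(unlist(x))))
  })
  phase <- if (!is.null(meta$phase)) as.numeric(unlist(meta$phase)) else NULL
  scene_sequence(frames, phase)
}
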