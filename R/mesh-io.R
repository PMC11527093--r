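# Readers and writers for labeled meshes.
#
# Geometry and node fields travel in a VTK legacy ASCII unstructured grid
# (tets as type-10 cells, boundary triangles as type-5 cells carrying an
# integer `tag_id` cell array). The tag-name legend and the landmark nodes
# live in a JSON sidecar `<path>.labels.json` (index_base records the file's
# index convention; VTK is 0-based, all in-memory indices are 1-based).

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a labeled mesh (VTK legacy + JSON label sidecar)
#'
#' @param mesh a [LabeledTetMesh-class]
#' @param path output file (conventionally `.vtk`); the label legend goes to
#'   `<path>.labels.json`.
#' @param fields named list of per-node fields to write; defaults to the
#'   fields stored on the mesh. Pass `list()` for a geometry-only file.
#' @return `path`, invisibly
#' @export
writeLabeledMesh <- function(mesh, path, fields = mesh@nodeFields) {
  n <- nNodes(mesh)
  m <- nTets(mesh)
  tris <- mesh@boundaryTris
  b <- nrow(tris)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  wl("# vtk DataFile Version 3.0")
  wl("atrialLDRBM labeled mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(paste(fmtNum(mesh@nodes[, 1]), fmtNum(mesh@nodes[, 2]),
           fmtNum(mesh@nodes[, 3])))
  wl(sprintf("CELLS %d %d", m + b, 5L * m + 4L * b))
  if (m) wl(paste(4L, mesh@tets[, 1] - 1L, mesh@tets[, 2] - 1L,
                  mesh@tets[, 3] - 1L, mesh@tets[, 4] - 1L))
  if (b) wl(paste(3L, tris[, 1] - 1L, tris[, 2] - 1L, tris[, 3] - 1L))
  wl(sprintf("CELL_TYPES %d", m + b))
  wl(as.character(c(rep(10L, m), rep(5L, b))))
  # tag ids on triangle cells (0 = untagged / volume cell)
  tagIds <- integer(b)
  tagNamesVec <- names(mesh@tags)
  for (i in seq_along(tagNamesVec)) tagIds[mesh@tags[[tagNamesVec[i]]]] <- i
  wl(sprintf("CELL_DATA %d", m + b))
  wl("SCALARS tag_id int 1")
  wl("LOOKUP_TABLE default")
  wl(as.character(c(rep(0L, m), tagIds)))
  if (length(fields)) {
    wl(sprintf("POINT_DATA %d", n))
    wl(sprintf("FIELD nodeFields %d", length(fields)))
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f)) {
        wl(sprintf("%s %d %d double", nm, ncol(f), n))
        wl(paste(fmtNum(f[, 1]), fmtNum(f[, 2]), fmtNum(f[, 3])))
      } else {
        wl(sprintf("%s 1 %d double", nm, n))
        wl(fmtNum(as.numeric(f)))
      }
    }
  }
  legend <- list(
    index_base = 0L,
    tags = as.list(stats::setNames(seq_along(tagNamesVec), tagNamesVec)),
    landmarks = as.list(mesh@landmarks - 1L)
  )
  jsonlite::write_json(legend, paste0(path, ".labels.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

parseVtkTokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk", lines[1])) {
    stop(sprintf("'%s' is not a VTK legacy file", path))
  }
  lines
}

#' Read a labeled mesh written by [writeLabeledMesh()]
#'
#' Reads the VTK legacy unstructured grid (tetrahedra plus tagged boundary
#' triangles) and the JSON label sidecar. File triangle tags are matched to
#' the freshly derived boundary triangulation, so tag sets survive the round
#' trip exactly.
#'
#' @param path the VTK file.
#' @param tagSpec optional named character vector mapping file tag names to
#'   canonical tag names (identity by default).
#' @param mode label-completeness requirement: `"none"` (default) loads any
#'   tag set; `"biatrial"`, `"la_only"`, `"ra_only"` raise an error naming
#'   any missing required tag.
#' @return a [LabeledTetMesh-class]
#' @export
readLabeledMesh <- function(path, tagSpec = NULL,
                            mode = c("none", "biatrial", "la_only", "ra_only")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- parseVtkTokens(path)
  i <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  scanFrom <- function(start, what, nmax) {
    con <- textConnection(lines[start:length(lines)])
    on.exit(close(con))
    scan(con, what = what, n = nmax, quiet = TRUE)
  }
  pts <- matrix(scanFrom(i + 1L, numeric(), 3L * n), ncol = 3, byrow = TRUE)
  i <- grep("^CELLS", lines)[1]
  hdr <- as.integer(strsplit(lines[i], "\\s+")[[1]][2:3])
  raw <- scanFrom(i + 1L, integer(), hdr[2])
  # split records by leading vertex count
  cells <- list(); pos <- 1L; k <- 0L
  tetRows <- matrix(integer(), 0, 4); triRows <- matrix(integer(), 0, 3)
  tetIdx <- integer(); triIdx <- integer()
  tl <- vector("list", hdr[1]); sizes <- integer(hdr[1])
  for (c_i in seq_len(hdr[1])) {
    sz <- raw[pos]
    tl[[c_i]] <- raw[(pos + 1L):(pos + sz)] + 1L
    sizes[c_i] <- sz
    pos <- pos + sz + 1L
  }
  i <- grep("^CELL_TYPES", lines)[1]
  ctypes <- scanFrom(i + 1L, integer(), hdr[1])
  if (any(!ctypes %in% c(5L, 10L))) {
    stop("unsupported cell types present (only tetrahedra and triangles)")
  }
  tets <- do.call(rbind, tl[ctypes == 10L])
  fileTris <- do.call(rbind, tl[ctypes == 5L])
  # tag ids
  tagIds <- NULL
  i <- grep("^CELL_DATA", lines)
  if (length(i)) {
    j <- grep("^SCALARS tag_id", lines)
    if (length(j)) {
      vals <- scanFrom(j[1] + 2L, integer(), hdr[1])
      tagIds <- vals[ctypes == 5L]
    }
  }
  # node fields
  nodeFields <- list()
  i <- grep("^POINT_DATA", lines)
  if (length(i)) {
    j <- grep("^FIELD nodeFields", lines)
    if (length(j)) {
      nf <- as.integer(strsplit(lines[j[1]], "\\s+")[[1]][3])
      at <- j[1] + 1L
      for (k in seq_len(nf)) {
        while (!nzchar(trimws(lines[at]))) at <- at + 1L
        hd <- strsplit(trimws(lines[at]), "\\s+")[[1]]
        nm <- hd[1]; ncomp <- as.integer(hd[2]); cnt <- as.integer(hd[3])
        vals <- scanFrom(at + 1L, numeric(), ncomp * cnt)
        nodeFields[[nm]] <- if (ncomp == 1) vals else
          matrix(vals, ncol = ncomp, byrow = TRUE)
        # advance: values occupy ceiling lines; recompute by scanning lines
        consumed <- 0L; at2 <- at + 1L
        while (consumed < ncomp * cnt) {
          consumed <- consumed +
            length(strsplit(trimws(lines[at2]), "\\s+")[[1]])
          at2 <- at2 + 1L
        }
        at <- at2
      }
    }
  }
  mesh <- newTetMesh(pts, tets)
  tags <- list()
  landmarks <- integer()
  sidecar <- paste0(path, ".labels.json")
  if (file.exists(sidecar) && !is.null(tagIds) && !is.null(fileTris)) {
    legend <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    base <- if (!is.null(legend$index_base)) as.integer(legend$index_base) else 0L
    # match file triangles to derived boundary triangles by vertex key
    bKey <- faceKeys(mesh@boundaryTris)
    fKey <- faceKeys(fileTris)
    map <- match(fKey, bKey)
    if (anyNA(map)) stop("tagged triangles are not boundary triangles")
    for (nm in names(legend$tags)) {
      id <- legend$tags[[nm]]
      outName <- nm
      if (!is.null(tagSpec)) {
        if (nm %in% names(tagSpec)) outName <- tagSpec[[nm]] else next
      }
      tags[[outName]] <- map[which(tagIds == id)]
    }
    if (length(legend$landmarks)) {
      landmarks <- stats::setNames(
        vapply(legend$landmarks, function(v) as.integer(v) + (1L - base),
               integer(1)),
        names(legend$landmarks))
    }
  }
  out <- newLabeledTetMesh(mesh, tags = tags, landmarks = landmarks,
                           nodeFields = nodeFields)
  if (mode != "none") {
    rep <- validateLabels(out, mode)
    if (!rep$ok) {
      stop(sprintf("label validation (%s) failed: %s", mode,
                   paste(rep$messages, collapse = "; ")))
    }
  }
  out
}

#' Write point/element/fiber triplet files
#'
#' Emits `<basename>.pts`, `<basename>.elem` and `<basename>.lon` in the
#' count-header-then-records text convention. Fibers are stored per node
#' (one line per node: f, s, n components); pass `perElement = TRUE` to
#' export per-element fibers by averaging (renormalized) over each tet.
#'
#' @param mesh a [TetMesh-class]
#' @param fibers a [FiberField-class] or NULL (geometry only)
#' @param basename output path prefix
#' @param perElement average node fibers onto elements before writing
#' @return basename, invisibly
#' @export
writePtsElemLon <- function(mesh, fibers = NULL, basename, perElement = FALSE) {
  writeLines(c(as.character(nNodes(mesh)),
               paste(fmtNum(mesh@nodes[, 1]), fmtNum(mesh@nodes[, 2]),
                     fmtNum(mesh@nodes[, 3]))),
             paste0(basename, ".pts"))
  writeLines(c(as.character(nTets(mesh)),
               paste("Tt", mesh@tets[, 1] - 1L, mesh@tets[, 2] - 1L,
                     mesh@tets[, 3] - 1L, mesh@tets[, 4] - 1L, 0L)),
             paste0(basename, ".elem"))
  if (!is.null(fibers)) {
    avg <- function(v) {
      if (!perElement) return(v)
      m <- (v[mesh@tets[, 1], ] + v[mesh@tets[, 2], ] +
              v[mesh@tets[, 3], ] + v[mesh@tets[, 4], ]) / 4
      rowUnit(m)
    }
    f <- avg(fibers@f); s <- avg(fibers@s); nn <- avg(fibers@n)
    writeLines(c(as.character(nrow(f)),
                 paste(fmtNum(f[, 1]), fmtNum(f[, 2]), fmtNum(f[, 3]),
                       fmtNum(s[, 1]), fmtNum(s[, 2]), fmtNum(s[, 3]),
                       fmtNum(nn[, 1]), fmtNum(nn[, 2]), fmtNum(nn[, 3]))),
               paste0(basename, ".lon"))
  }
  invisible(basename)
}
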