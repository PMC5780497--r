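# Gmsh MSH 2.2 (ASCII) import/export with physical groups:
# surfaces 1 cytoplasm, 2 nucleus, 3 bleach (bleach-flagged cytoplasm
# elements); lines 4 outer boundary, 5 membrane.

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' @param mesh a [TriMesh].
#' @param path output file.
#' @export
writeMsh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", "5",
               "2 1 \"cytoplasm\"", "2 2 \"nucleus\"", "2 3 \"bleach\"",
               "1 4 \"outer\"", "1 5 \"membrane\"",
               "$EndPhysicalNames"), con)
  nv <- nrow(mesh@vertices)
  writeLines(c("$Nodes", as.character(nv)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(nv),
                     mesh@vertices[, 1L], mesh@vertices[, 2L]), con)
  writeLines("$EndNodes", con)
  keep <- mesh@edgeClass != "interior"
  le <- mesh@edges[keep, , drop = FALSE]
  lphys <- ifelse(mesh@edgeClass[keep] == "membrane", 5L, 4L)
  tphys <- ifelse(mesh@elementBleach, 3L,
                  ifelse(mesh@elementRegion == "nucleus", 2L, 1L))
  ntot <- nrow(le) + nrow(mesh@triangles)
  writeLines(c("$Elements", as.character(ntot)), con)
  id <- 0L
  if (nrow(le))
    writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(nrow(le)), lphys, lphys,
                       le[, 1L], le[, 2L]), con)
  off <- nrow(le)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", off + seq_len(nrow(mesh@triangles)),
                     tphys, tphys, mesh@triangles[, 1L], mesh@triangles[, 2L],
                     mesh@triangles[, 3L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh from Gmsh MSH 2.2 ASCII format
#'
#' Region labels and bleach flags are recovered from the physical surface
#' tags; edge classes are rebuilt from element adjacency and checked against
#' the physical line elements.
#'
#' @param path input file.
#' @return a [TriMesh].
#' @export
readMsh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i <- match(paste0("$", name), lines)
    j <- match(paste0("$End", name), lines)
    if (is.na(i) || is.na(j)) stop("missing $", name, " section")
    lines[(i + 2L):(j - 1L)]
  }
  nodeLines <- sect("Nodes")
  nodes <- do.call(rbind, lapply(strsplit(nodeLines, " +"), as.numeric))
  vertices <- nodes[order(nodes[, 1L]), 2:3, drop = FALSE]
  elemLines <- sect("Elements")
  fields <- lapply(strsplit(elemLines, " +"), as.integer)
  tris <- NULL; phys <- integer(); memEdges <- NULL
  for (f in fields) {
    etype <- f[2L]; ntags <- f[3L]
    tag <- f[4L]
    conn <- f[(4L + ntags):length(f)]
    if (etype == 2L) {
      tris <- rbind(tris, conn)
      phys <- c(phys, tag)
    } else if (etype == 1L && tag == 5L) {
      memEdges <- rbind(memEdges, sort(conn))
    }
  }
  if (is.null(tris)) stop("no triangles in mesh file")
  region <- ifelse(phys == 2L, "nucleus", "cytoplasm")
  bleach <- phys == 3L
  mesh <- finalizeMesh(vertices, tris, region, bleach)
  if (!is.null(memEdges)) {
    got <- mesh@edges[mesh@edgeClass == "membrane", , drop = FALSE]
    key <- function(m) paste(m[, 1L], m[, 2L])
    if (!setequal(key(got), key(memEdges)))
      warning("membrane line elements disagree with region adjacency; using adjacency")
  }
  mesh
}

#' Read or write a label mask image
#'
#' Masks use integer codes 0 background, 1 cytoplasm, 2 nucleus, 3 bleach,
#' stored as 8-bit single-channel TIFF or PNG (code k stored as gray level
#' k/255).
#'
#' @param path file path; format chosen by extension (.tif/.tiff/.png).
#' @param mask integer matrix of label codes.
#' @return `readLabelMask` returns an integer matrix.
#' @export
readLabelMask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L) stop("label mask must be single-channel")
    img <- img[, , 1L]
  }
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' @rdname readLabelMask
#' @export
writeLabelMask <- function(mask, path) {
  img <- mask / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
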