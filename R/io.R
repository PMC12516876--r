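#' Write a count matrix as a Matrix Market triplet with TSV sidecars
#'
#' Writes the CellRanger-style trio \code{matrix.mtx} / \code{features.tsv} /
#' \code{barcodes.tsv} plus a \code{meta.json} sidecar recording modality,
#' stage, layer and the on-disk orientation. On disk the matrix is stored
#' genes-by-cells (the dominant ecosystem convention); in memory it is always
#' cells-by-genes. The sidecar makes the orientation explicit so a reader can
#' never transpose silently.
#'
#' @param m a \code{\link{count_matrix}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_count_matrix <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- m$values
  if (anyNA(if (methods::is(v, "Matrix")) v@x else v))
    stop("cannot write a matrix containing missing values to MTX")
  sp <- methods::as(methods::as(Matrix::Matrix(t(v), sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(colnames(v), file.path(dir, "features.tsv"))
  writeLines(rownames(v), file.path(dir, "barcodes.tsv"))
  jsonlite::write_json(
    list(modality = m$modality, stage = m$stage, layer = m$layer,
         orientation = "genes-by-cells"),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a count matrix written by \code{write_count_matrix} or a dense table
#'
#' For a directory, reads the MTX trio and its \code{meta.json} sidecar,
#' validating that the MTX dimensions match the id files and that ids are
#' unique. For a single delimited file, reads a dense table with gene columns
#' and a first column of cell ids (or transposed, per \code{orientation}).
#'
#' @param path directory with \code{matrix.mtx}/\code{features.tsv}/
#'   \code{barcodes.tsv}(/\code{meta.json}), or a CSV/TSV file.
#' @param orientation on-disk orientation, \code{"genes-by-cells"} or
#'   \code{"cells-by-genes"}; for MTX directories the sidecar value wins.
#' @param modality,stage,layer tags for the result; for MTX directories the
#'   sidecar values win.
#' @param dense if TRUE return a base dense matrix inside the container.
#' @return a \code{\link{count_matrix}} (cells x genes in memory)
#' @export
read_count_matrix <- function(path,
                              orientation = c("genes-by-cells", "cells-by-genes"),
                              modality = "scRNA", stage = "mixed", layer = "raw",
                              dense = FALSE) {
  orientation <- match.arg(orientation)
  if (dir.exists(path)) {
    metaf <- file.path(path, "meta.json")
    if (file.exists(metaf)) {
      meta <- jsonlite::read_json(metaf)
      modality <- meta$modality; stage <- meta$stage; layer <- meta$layer
      orientation <- meta$orientation
    }
    v <- Matrix::readMM(file.path(path, "matrix.mtx"))
    # expand symmetric/triangular storage before attaching asymmetric ids
    v <- methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
    genes <- readLines(file.path(path, "features.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    if (orientation == "genes-by-cells") {
      if (nrow(v) != length(genes) || ncol(v) != length(cells))
        stop(sprintf("dimension mismatch: MTX is %d x %d but %d genes / %d cells listed",
                     nrow(v), ncol(v), length(genes), length(cells)))
      v <- Matrix::t(v)
      dimnames(v) <- list(cells, genes)
    } else {
      if (nrow(v) != length(cells) || ncol(v) != length(genes))
        stop(sprintf("dimension mismatch: MTX is %d x %d but %d cells / %d genes listed",
                     nrow(v), ncol(v), length(cells), length(genes)))
      dimnames(v) <- list(cells, genes)
    }
    v <- methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
    if (dense) v <- as.matrix(v)
  } else {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, row.names = NULL)
    ids <- as.character(tab[[1]])
    v <- as.matrix(tab[, -1, drop = FALSE])
    rownames(v) <- ids
    if (orientation == "genes-by-cells") v <- t(v)
    if (anyDuplicated(rownames(v))) stop("duplicate cell ids")
    if (anyDuplicated(colnames(v))) stop("duplicate gene ids")
  }
  count_matrix(v, modality = modality, stage = stage, layer = layer)
}

#' Read and write CSV-backed tables (cells, spots, regions)
#'
#' Thin CSV wrappers around the table validators. The CSV dialect is fixed:
#' comma separator, header row, '.' decimal, UTF-8. Unknown columns survive a
#' round trip untouched.
#'
#' @param path CSV file
#' @return the validated table object
#' @export
read_cell_table <- function(path) cell_table(utils::read.csv(path, check.names = FALSE))

#' @rdname read_cell_table
#' @export
read_spot_table <- function(path) spot_table(utils::read.csv(path, check.names = FALSE))

#' @rdname read_cell_table
#' @export
read_region_table <- function(path) region_table(utils::read.csv(path, check.names = FALSE))

#' @rdname read_cell_table
#' @param x table to write
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a polygon region from GeoJSON
#'
#' Accepts a GeoJSON \code{Polygon} geometry, a \code{Feature} wrapping one,
#' or the first feature of a \code{FeatureCollection}. Only the outer ring is
#' used. The ring is validated (at least 3 vertices, simple, positive area).
#'
#' @param path GeoJSON file
#' @param name region name; defaults to the feature's \code{name} property
#'   when present
#' @return a \code{\link{polygon_region}}
#' @export
read_polygon <- function(path, name = NULL) {
  g <- jsonlite::read_json(path)
  feat_name <- NULL
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
  if (identical(g$type, "Feature")) {
    feat_name <- g$properties$name
    g <- g$geometry
  }
  if (!identical(g$type, "Polygon"))
    stop("expected a GeoJSON Polygon geometry, got ", g$type)
  ring <- g$coordinates[[1]]
  v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  polygon_region(v, name = name %||% feat_name %||% "region")
}

#' @rdname read_polygon
#' @param region a \code{polygon_region} to write as a GeoJSON Feature
#' @export
write_polygon <- function(region, path) {
  v <- rbind(region$vertices, region$vertices[1, ])
  coords <- lapply(seq_len(nrow(v)), function(i) list(v[i, 1], v[i, 2]))
  jsonlite::write_json(
    list(type = "Feature",
         properties = list(name = region$name),
         geometry = list(type = "Polygon", coordinates = list(coords))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a one-column gene list
#'
#' @param path text file, one gene id per line (first tab-separated field is
#'   used, so annotated lists work too); blank lines ignored
#' @return character vector of unique gene ids
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  unique(vapply(strsplit(x, "\t"), `[[`, "", 1L))
}

#' Read a homeolog map (group to member genes)
#'
#' Two-column TSV: group id, member gene id (one member per line). Wheat
#' homeologs are the A/B(/D) subgenome copies of a gene; cross-study
#' comparisons sum their expression per group. A gene may belong to one
#' group only.
#'
#' @param path TSV file with columns group, gene (header optional; detected
#'   when the first line is \code{group\tgene})
#' @return named list: group id -> character vector of member genes
#' @export
read_homeolog_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(lines[1]), "group\tgene"))
    lines <- lines[-1]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2)) stop("homeolog map lines need 2 tab-separated fields")
  grp <- vapply(parts, `[[`, "", 1L)
  gene <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(gene)) {
    dup <- gene[duplicated(gene)][1]
    stop("gene ", dup, " is assigned to more than one homeolog group")
  }
  split(gene, grp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
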