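#' Expression count matrix with modality, stage and layer tags
#'
#' The central container of the package: a cells-by-genes numeric matrix
#' (dense or \code{Matrix} sparse) carrying unique cell and gene identifiers
#' plus three tags describing what the values are. The \code{raw} layer must
#' hold nonnegative integer counts; \code{cpm} and \code{lognorm} layers hold
#' nonnegative reals; \code{imputed} matrices may contain missing values for
#' genes not imputed at a given stage.
#'
#' @param values numeric matrix or \code{Matrix::dgCMatrix}, cells in rows and
#'   genes in columns, with complete unique dimnames.
#' @param modality one of \code{"smFISH"}, \code{"scRNA"}, \code{"imputed"}.
#' @param stage one of \code{"W1.5"}, \code{"W2.5"}, \code{"W3.5"},
#'   \code{"mixed"} (Waddington stages of spike development).
#' @param layer one of \code{"raw"}, \code{"cpm"}, \code{"lognorm"}.
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{values}, \code{modality}, \code{stage}, \code{layer}.
#' @export
count_matrix <- function(values,
                         modality = c("smFISH", "scRNA", "imputed"),
                         stage = c("mixed", "W1.5", "W2.5", "W3.5"),
                         layer = c("raw", "cpm", "lognorm")) {
  modality <- match.arg(modality)
  stage <- match.arg(stage)
  layer <- match.arg(layer)
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("`values` must be a matrix or Matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have cell (row) and gene (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids")
  x <- if (methods::is(values, "Matrix")) values@x else values
  if (any(x < 0, na.rm = TRUE))
    stop("negative values are not allowed")
  if (layer == "raw") {
    if (anyNA(x)) stop("raw layer cannot contain missing values")
    if (any(x != floor(x)))
      stop("raw layer must be integer-valued")
  }
  structure(list(values = values, modality = modality,
                 stage = stage, layer = layer),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes | modality=%s stage=%s layer=%s\n",
              nrow(x$values), ncol(x$values), x$modality, x$stage, x$layer))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Cell and gene identifiers of a count matrix
#' @param m a \code{count_matrix}
#' @return character vector of ids
#' @export
cell_ids <- function(m) rownames(m$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$values)

#' Cell metadata table for spatially anchored cells
#'
#' Validates a data frame of segmented-cell records: id, micrometre
#' coordinates (image convention, y increasing downward), optional area,
#' section, stage, and cluster label (may be missing). Unknown columns are
#' preserved untouched.
#'
#' @param df data.frame with at least \code{cell_id}, \code{x}, \code{y}.
#'   Optional: \code{area}, \code{section_id}, \code{stage}, \code{cluster}.
#' @return the validated data.frame with class \code{c("cell_table","data.frame")}
#' @export
cell_table <- function(df) {
  req <- c("cell_id", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cell table missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell ids")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("cell coordinates must be finite")
  if ("area" %in% names(df) && any(!is.na(df$area) & df$area <= 0))
    stop("cell area must be positive when present")
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Transcript spot table
#'
#' One row per detected transcript: gene id and micrometre coordinates on a
#' named tissue section.
#'
#' @param df data.frame with columns \code{gene_id}, \code{x}, \code{y} and
#'   optionally \code{section_id}.
#' @return validated data.frame with class \code{c("spot_table","data.frame")}
#' @export
spot_table <- function(df) {
  req <- c("gene_id", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("spot table missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
      stop("spot coordinates must be finite")
    if (any(!nzchar(as.character(df$gene_id))))
      stop("empty gene_id in spot table")
  }
  class(df) <- unique(c("spot_table", class(df)))
  df
}

#' Delineated polygonal region in micrometre coordinates
#'
#' A simple (non-self-intersecting) closed ring used to delimit a tissue
#' region, e.g. the apical meristem region used for spot-density comparisons.
#' The area is computed with the shoelace formula.
#'
#' @param vertices two-column numeric matrix of (x, y) vertices. A repeated
#'   closing vertex is accepted and dropped.
#' @param name region name.
#' @return object of class \code{polygon_region} with elements \code{name},
#'   \code{vertices} (open ring), \code{area}.
#' @export
polygon_region <- function(vertices, name = "region") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("vertices must have two columns (x, y)")
  storage.mode(vertices) <- "double"
  n <- nrow(vertices)
  if (n >= 2 && all(vertices[1, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 distinct vertices")
  if (!all(is.finite(vertices))) stop("vertices must be finite")
  if (ring_self_intersects(vertices)) stop("polygon ring is self-intersecting")
  a <- shoelace_area(vertices)
  if (a <= 0) stop("polygon has zero area")
  structure(list(name = name, vertices = vertices, area = a),
            class = "polygon_region")
}

#' @export
print.polygon_region <- function(x, ...) {
  cat(sprintf("<polygon_region> '%s': %d vertices, area %.4g um^2\n",
              x$name, nrow(x$vertices), x$area))
  invisible(x)
}

#' Region-level bulk expression table
#'
#' Long-format table of pre-normalized (TMM-scale) bulk expression per gene,
#' spike region and biological replicate, as consumed by
#' \code{\link{region_assignment}}.
#'
#' @param df data.frame with columns \code{gene_id}, \code{region},
#'   \code{replicate}, \code{value}.
#' @return validated data.frame with class \code{c("region_table","data.frame")}
#' @export
region_table <- function(df) {
  req <- c("gene_id", "region", "replicate", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("region table missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$value < 0)) stop("expression values must be nonnegative")
  nrep <- stats::aggregate(replicate ~ gene_id + region, df,
                           function(z) length(unique(z)))
  if (any(nrep$replicate < 2))
    stop("every (gene, region) needs at least 2 replicates")
  class(df) <- unique(c("region_table", class(df)))
  df
}
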