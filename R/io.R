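## Interchange formats: CSV event/survival tables, GeoJSON tumour regions,
## MatrixMarket count matrices. Every writer is atomic (temp file + rename)
## and every artifact round-trips losslessly through its reader.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)   # cross-device fallback
    unlink(tmp)
  }
  invisible(path)
}

## format numerics at 17 significant digits so doubles survive the text
## round trip bit-identically
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
    }
  }
  df
}

#' Read and write tabular artifacts as CSV
#'
#' UTF-8, header row, `.` decimal separator. Doubles are written at full
#' precision so values round-trip bit-identically.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return The path (writer, invisibly) or the data frame (reader).
#' @export
write_table_csv <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(format_full(df), tmp, row.names = FALSE,
                     fileEncoding = "UTF-8")
  })
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write tumour-region polygons as GeoJSON
#'
#' RFC 7946 FeatureCollection of Polygon features; coordinates are
#' micrometres in the core-local frame (origin at the core bounding-box
#' corner), a deliberate local convention since these are microscope, not
#' geographic, coordinates. Rings are written closed (first vertex repeated
#' last).
#'
#' @param regions List of polygon vertex matrices (open or closed rings).
#' @param path File path.
#' @param core_id Identifier stored in each feature's properties.
#' @return The path, invisibly.
#' @export
write_regions_geojson <- function(regions, path, core_id = "core1") {
  features <- lapply(seq_along(regions), function(i) {
    poly <- as.matrix(regions[[i]])
    if (!all(poly[1, ] == poly[nrow(poly), ])) {
      poly <- rbind(poly, poly[1, , drop = FALSE])
    }
    list(type = "Feature",
         properties = list(core_id = core_id, region_index = i),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(poly))))
  })
  gj <- list(type = "FeatureCollection", features = features)
  atomic_write(path, function(tmp) {
    writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), tmp)
  })
}

#' Read tumour-region polygons from GeoJSON
#'
#' Validates that every feature is a Polygon with a closed outer ring of at
#' least 4 positions; violations report the offending feature index.
#'
#' @param path File path.
#' @return List of polygon vertex matrices (open rings, closing edge
#'   implied), with the `core_id` property attached as an attribute.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  core_id <- NULL
  regions <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, ": geometry must be a Polygon", call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, unlist))
    if (nrow(m) < 4) {
      stop("feature ", i, ": ring must have at least 4 positions",
           call. = FALSE)
    }
    if (!all(m[1, ] == m[nrow(m), ])) {
      stop("feature ", i, ": ring is not closed", call. = FALSE)
    }
    core_id <<- f$properties$core_id
    colnames(m) <- c("x", "y")
    m[-nrow(m), , drop = FALSE]
  })
  attr(regions, "core_id") <- core_id
  regions
}

#' Write and read count matrices as MatrixMarket triplets
#'
#' `write_counts_mtx()` writes `matrix.mtx` (1-based indices) plus
#' `genes.tsv` and `cells.tsv` sidecars into a directory; the reader
#' rebuilds the dense genes x cells matrix and rejects files carrying
#' explicit zero entries.
#'
#' @param counts Genes x cells matrix with dimnames.
#' @param dir Directory to hold the triplet and sidecars.
#' @return The directory (writer, invisibly) or the matrix (reader).
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  atomic_write(file.path(dir, "matrix.mtx"), function(tmp) {
    Matrix::writeMM(sp, tmp)
  })
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  if (methods::is(m, "dsparseMatrix") || methods::is(m, "TsparseMatrix")) {
    xs <- methods::slot(methods::as(m, "TsparseMatrix"), "x")
    if (any(xs == 0)) {
      stop("MTX file stores explicit zero entries", call. = FALSE)
    }
  }
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  m <- as.matrix(m)
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  m
}

#' Signed polygon area (shoelace formula)
#'
#' @param poly Two-column vertex matrix (open or closed ring).
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}
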