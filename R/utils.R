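#' @useDynLib eamsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor fft mad median pt quantile rbinom rnorm
#'   runif sd setNames t.test var
#' @importFrom utils head tail write.csv
NULL

# row-wise euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

# normalize rows to unit length; zero rows left untouched
normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n < 1e-12] <- 1
  m / n
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# derive a child seed from a master seed; kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10000L + (as.integer(k) %% 10000L)
}

#' Write points + triangles (+ optional per-point scalars) as legacy ASCII VTK
#'
#' Minimal legacy-format writer for visual inspection of surfaces and maps in
#' ParaView or similar. Scalars are written as POINT_DATA fields.
#'
#' @param path output file path (.vtk)
#' @param points n x 3 numeric matrix (mm)
#' @param triangles m x 3 integer matrix of 1-based point indices, or NULL for
#'   a point cloud
#' @param scalars named list of numeric per-point vectors
#' @return invisibly, the path written
#' @export
write_vtk <- function(path, points, triangles = NULL, scalars = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(points)
  writeLines(c("# vtk DataFile Version 3.0", "eamsim export", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(points, 1L, function(p) paste(format(p, trim = TRUE), collapse = " ")), con)
  if (!is.null(triangles)) {
    m <- nrow(triangles)
    writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
    writeLines(apply(triangles - 1L, 1L, function(tr) paste(c(3L, tr), collapse = " ")), con)
  }
  if (length(scalars)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(scalars[[nm]]), trim = TRUE), con)
    }
  }
  invisible(path)
}
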