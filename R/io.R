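#' Read and write point clouds as ASCII PLY or XYZ
#'
#' Minimal ASCII PLY support for the `vertex` element with `x`, `y`, `z`
#' float properties (the layout this package writes); XYZ files are plain
#' whitespace-separated coordinate triplets.
#'
#' @param cloud a [seed_cloud()].
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   [seed_cloud()].
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "seed_cloud"))
  pts <- cloud_matrix(cloud)
  header <- c("ply", "format ascii 1.0",
              "comment carposort seed cloud (mm)",
              sprintf("element vertex %d", nrow(pts)),
              "property float x", "property float y", "property float z",
              "end_header")
  body <- apply(pts, 1, function(p) paste(format(p, digits = 9,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply"))
    stop_carposort("not a PLY file: %s", path,
                   class = "carposort_io_error")
  end <- match("end_header", lines)
  if (is.na(end))
    stop_carposort("PLY header not terminated",
                   class = "carposort_io_error")
  vline <- grep("^element vertex ", lines[seq_len(end)], value = TRUE)
  n <- as.integer(sub("^element vertex ", "", vline[1]))
  vals <- utils::read.table(text = lines[(end + 1):(end + n)])
  seed_cloud(as.matrix(vals[, 1:3]))
}

#' @rdname write_ply
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "seed_cloud"))
  utils::write.table(cloud_matrix(cloud), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_xyz <- function(path) {
  seed_cloud(as.matrix(utils::read.table(path)[, 1:3]))
}

#' Read and write height-map scans as plain-text grids
#'
#' Row-major whitespace-separated mm height values; intrinsics travel
#' separately (e.g. as JSON via [jsonlite::write_json()]).
#'
#' @param scan a `seed_scan` or plain height matrix.
#' @param path file path.
#' @param intrinsics optional [scan_intrinsics()] to attach on read.
#' @return `write_scan_grid` returns `path` invisibly; `read_scan_grid` a
#'   `seed_scan`.
#' @export
write_scan_grid <- function(scan, path) {
  utils::write.table(as.matrix(scan), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_grid
#' @export
read_scan_grid <- function(path, intrinsics = NULL) {
  h <- as.matrix(utils::read.table(path))
  dimnames(h) <- NULL
  structure(h, class = c("seed_scan", "matrix", "array"),
            intrinsics = intrinsics)
}

#' Save or load a fitted charring curve as JSON
#'
#' @param curve a [charring_curve()].
#' @param path file path.
#' @return `write_curve_json` returns `path` invisibly; `read_curve_json`
#'   the curve.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "charring_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- c("a", "b", "t_zero", "t_one", "fit_residual")
  raw[num] <- lapply(raw[num], as.numeric)   # JSON may render 200 as int
  structure(raw, class = "charring_curve")
}
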