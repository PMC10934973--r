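# Point-cloud and transform interchange: PLY (ascii / binary little-endian),
# PCD v0.7 (ascii / binary), whitespace XYZ, and a JSON transform format.
# Coordinates are millimetres end-to-end; no unit conversion is applied.

#' Write a point cloud to disk
#'
#' Supported formats: PLY (binary little-endian by default, or ASCII), PCD
#' v0.7 (ASCII or binary) and plain whitespace-separated XYZ. Coordinates are
#' written as 64-bit floats (binary formats) or full-precision text, so
#' round-trips are exact. Normals, when present, are stored as
#' `nx ny nz` (PLY) / `normal_x normal_y normal_z` (PCD) / columns 4-6 (XYZ).
#'
#' @param cloud a `point_cloud`.
#' @param path output file path.
#' @param format `"ply"`, `"pcd"`, `"xyz"` or `"auto"` (from the extension).
#' @param ascii logical; write the ASCII variant of PLY/PCD.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        ascii = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") format <- format_from_path(path)
  ok <- tryCatch({
    switch(format,
           ply = write_ply(cloud, path, ascii),
           pcd = write_pcd(cloud, path, ascii),
           xyz = write_xyz(cloud, path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Read a point cloud from disk
#'
#' @param path input file path.
#' @param format `"ply"`, `"pcd"`, `"xyz"` or `"auto"` (from the extension).
#' @return A `point_cloud`; normals are populated when the file carries them.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (format == "auto") format <- format_from_path(path)
  cl <- switch(format,
               ply = read_ply(path),
               pcd = read_pcd(path),
               xyz = read_xyz(path))
  if (n_points(cl) == 0L)
    abort_format(sprintf("'%s' contains no points", path))
  cl
}

format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  switch(ext,
         ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
         abort_parameter(sprintf(
           "cannot infer point-cloud format from extension '.%s'", ext)))
}

## ---- PLY ----

write_ply <- function(cloud, path, ascii) {
  has_n <- !is.null(cloud$normals)
  props <- c("x", "y", "z", if (has_n) c("nx", "ny", "nz"))
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (ascii) "ascii" else "binary_little_endian"),
    sprintf("comment %s", cloud$label),
    sprintf("element vertex %d", n_points(cloud)),
    sprintf("property double %s", props),
    "end_header")
  dat <- if (has_n) cbind(cloud$points, cloud$normals) else cloud$points
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(dat, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.vector(t(dat)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate the header end in the raw bytes (the binary body may hold NULs)
  m <- grepRaw("end_header", raw, fixed = TRUE)
  if (!length(m)) abort_format(sprintf("'%s': PLY header has no end_header", path))
  nl <- grepRaw("\n", raw, fixed = TRUE, all = TRUE)
  body_off <- nl[nl >= m[1]][1]
  if (is.na(body_off))
    abort_format(sprintf("'%s': PLY header has no end_header", path))
  header <- strsplit(rawToChar(raw[seq_len(m[1] - 1L)]), "\r?\n")[[1]]
  if (length(header) == 0 || header[1] != "ply")
    abort_format(sprintf("'%s': not a PLY file", path))
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1)
    abort_format(sprintf("'%s': missing PLY format line", path))
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    abort_format(sprintf("'%s': unsupported PLY format '%s'", path, fmt))
  # elements and properties (only the vertex element is supported)
  el_idx <- grep("^element ", header)
  if (length(el_idx) != 1 || !grepl("^element vertex ", header[el_idx]))
    abort_format(sprintf("'%s': PLY must contain a single vertex element", path))
  nv <- as.integer(strsplit(header[el_idx], "\\s+")[[1]][3])
  prop_lines <- grep("^property ", header, value = TRUE)
  props <- do.call(rbind, strsplit(prop_lines, "\\s+"))
  if (any(props[, 2] == "list"))
    abort_format(sprintf("'%s': PLY list properties are not supported", path))
  types <- props[, 2]
  names_ <- props[, 3]
  sizes <- vapply(types, ply_type_size, integer(1), path = path)
  ncolp <- length(names_)
  label <- sub("^comment ", "", grep("^comment ", header, value = TRUE)[1])
  if (is.na(label)) label <- ""
  if (fmt == "ascii") {
    txt <- rawToChar(raw[(body_off + 1):length(raw)])
    dat <- tryCatch(
      as.matrix(read.table(text = txt, nrows = nv, col.names = names_)),
      error = function(e) abort_format(sprintf(
        "'%s': malformed ASCII PLY body: %s", path, conditionMessage(e))))
    if (nrow(dat) < nv)
      abort_format(sprintf("'%s': expected %d vertices, found %d",
                           path, nv, nrow(dat)))
  } else {
    if (length(unique(sizes)) > 1 || !all(types %in% c("double", "float", "float64", "float32")))
      return(read_ply_binary_mixed(raw, body_off, nv, types, sizes, names_, label, path))
    vals <- readBin(raw[(body_off + 1):length(raw)], "double",
                    n = nv * ncolp, size = sizes[1], endian = "little")
    if (length(vals) < nv * ncolp)
      abort_format(sprintf("'%s': binary PLY body truncated", path))
    dat <- matrix(vals, ncol = ncolp, byrow = TRUE,
                  dimnames = list(NULL, names_))
  }
  ply_to_cloud(dat, names_, label, path)
}

ply_type_size <- function(type, path) {
  switch(type,
         double = , float64 = 8L,
         float = , float32 = 4L,
         abort_format(sprintf("'%s': unsupported PLY property type '%s'",
                              path, type)))
}

# rare case: mixed float32/float64 properties; decode record-wise
read_ply_binary_mixed <- function(raw, body_off, nv, types, sizes, names_,
                                  label, path) {
  rec <- sum(sizes)
  body <- raw[(body_off + 1):length(raw)]
  if (length(body) < nv * rec)
    abort_format(sprintf("'%s': binary PLY body truncated", path))
  dat <- matrix(NA_real_, nv, length(names_), dimnames = list(NULL, names_))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  for (j in seq_along(names_)) {
    idx <- as.vector(outer(seq_len(sizes[j]), (seq_len(nv) - 1L) * rec + offs[j], "+"))
    dat[, j] <- readBin(body[idx], "double", n = nv, size = sizes[j],
                        endian = "little")
  }
  ply_to_cloud(dat, names_, label, path)
}

ply_to_cloud <- function(dat, names_, label, path) {
  need <- c("x", "y", "z")
  if (!all(need %in% names_))
    abort_format(sprintf("'%s': PLY vertex element lacks x/y/z", path))
  pts <- dat[, need, drop = FALSE]
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% names_))
    normals <- dat[, c("nx", "ny", "nz"), drop = FALSE]
  point_cloud(pts, normals = normals, label = label)
}

## ---- PCD v0.7 ----

write_pcd <- function(cloud, path, ascii) {
  has_n <- !is.null(cloud$normals)
  fields <- c("x", "y", "z", if (has_n) c("normal_x", "normal_y", "normal_z"))
  nf <- length(fields)
  n <- n_points(cloud)
  header <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    paste("FIELDS", paste(fields, collapse = " ")),
    paste("SIZE", paste(rep(8, nf), collapse = " ")),
    paste("TYPE", paste(rep("F", nf), collapse = " ")),
    paste("COUNT", paste(rep(1, nf), collapse = " ")),
    sprintf("WIDTH %d", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    sprintf("POINTS %d", n),
    sprintf("DATA %s", if (ascii) "ascii" else "binary"))
  dat <- if (has_n) cbind(cloud$points, cloud$normals) else cloud$points
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(dat, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.vector(t(dat)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_pcd <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate the end of the DATA line in the raw bytes (binary bodies hold NULs)
  m <- grepRaw("DATA ", raw, fixed = TRUE)
  if (!length(m)) abort_format(sprintf("'%s': PCD header has no DATA line", path))
  nl <- grepRaw("\n", raw, fixed = TRUE, all = TRUE)
  body_off <- nl[nl >= m[1]][1]
  if (is.na(body_off))
    abort_format(sprintf("'%s': PCD header has no DATA line", path))
  lines <- strsplit(rawToChar(raw[seq_len(body_off - 1L)]), "\r?\n")[[1]]
  data_i <- grep("^DATA ", lines)[1]
  if (is.na(data_i)) abort_format(sprintf("'%s': PCD header has no DATA line", path))
  header <- lines[seq_len(data_i)]
  get_field <- function(key) {
    ln <- grep(paste0("^", key, " "), header, value = TRUE)
    if (length(ln) != 1)
      abort_format(sprintf("'%s': PCD header lacks %s", path, key))
    strsplit(ln, "\\s+")[[1]][-1]
  }
  fields <- get_field("FIELDS")
  sizes <- as.integer(get_field("SIZE"))
  types <- get_field("TYPE")
  counts <- as.integer(get_field("COUNT"))
  n <- as.integer(get_field("POINTS")[1])
  if (any(counts != 1L))
    abort_format(sprintf("'%s': PCD COUNT > 1 is not supported", path))
  if (!all(types == "F"))
    abort_format(sprintf("'%s': only float PCD fields are supported", path))
  mode <- get_field("DATA")[1]
  if (mode == "ascii") {
    txt <- rawToChar(raw[(body_off + 1):length(raw)])
    dat <- tryCatch(
      as.matrix(read.table(text = txt, nrows = n, col.names = fields)),
      error = function(e) abort_format(sprintf(
        "'%s': malformed ASCII PCD body: %s", path, conditionMessage(e))))
  } else if (mode == "binary") {
    if (length(unique(sizes)) != 1)
      abort_format(sprintf("'%s': mixed PCD field sizes not supported", path))
    vals <- readBin(raw[(body_off + 1):length(raw)], "double",
                    n = n * length(fields), size = sizes[1], endian = "little")
    if (length(vals) < n * length(fields))
      abort_format(sprintf("'%s': binary PCD body truncated", path))
    dat <- matrix(vals, ncol = length(fields), byrow = TRUE,
                  dimnames = list(NULL, fields))
  } else {
    abort_format(sprintf("'%s': unsupported PCD DATA mode '%s'", path, mode))
  }
  if (!all(c("x", "y", "z") %in% fields))
    abort_format(sprintf("'%s': PCD lacks x/y/z fields", path))
  normals <- NULL
  if (all(c("normal_x", "normal_y", "normal_z") %in% fields))
    normals <- dat[, c("normal_x", "normal_y", "normal_z"), drop = FALSE]
  point_cloud(dat[, c("x", "y", "z"), drop = FALSE], normals = normals)
}

## ---- XYZ ----

write_xyz <- function(cloud, path) {
  dat <- if (is.null(cloud$normals)) cloud$points
         else cbind(cloud$points, cloud$normals)
  writeLines(apply(dat, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), path)
  invisible(path)
}

read_xyz <- function(path) {
  dat <- tryCatch(as.matrix(read.table(path)),
                  error = function(e) abort_format(sprintf(
                    "'%s': malformed XYZ file: %s", path, conditionMessage(e))))
  if (!is.numeric(dat) || !ncol(dat) %in% c(3L, 6L))
    abort_format(sprintf(
      "'%s': XYZ files must have 3 (points) or 6 (points + normals) columns",
      path))
  point_cloud(dat[, 1:3, drop = FALSE],
              normals = if (ncol(dat) == 6L) dat[, 4:6, drop = FALSE])
}

## ---- transforms (JSON) ----

#' Write a rigid transform as JSON
#'
#' The file holds the 4x4 homogeneous matrix (row-major), an explicit
#' statement of the column-vector convention `p' = R p + t` (source into
#' target coordinates), and source/target labels plus a timestamp.
#'
#' @param transform a `rigid_transform`.
#' @param path output file path.
#' @param source,target free-text frame labels.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path, source = "", target = "") {
  stopifnot(inherits(transform, "rigid_transform"))
  M <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  obj <- list(
    matrix = apply(M, 1, as.numeric, simplify = FALSE),
    convention = "p' = R * p + t, column vectors; maps source coordinates into target coordinates",
    metadata = list(source = source, target = target,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' Validates rigidity on read: the rotation block must be orthonormal with
#' determinant +1 within 1e-6, and the last row must be `(0, 0, 0, 1)`.
#'
#' @param path input file path.
#' @return A `rigid_transform`.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_format(sprintf(
                    "'%s': invalid JSON: %s", path, conditionMessage(e))))
  M <- obj$matrix
  if (is.list(M)) M <- do.call(rbind, M)
  M <- as.matrix(M)
  if (!all(dim(M) == c(4L, 4L)) || !is.numeric(M))
    abort_format(sprintf("'%s': transform matrix must be 4x4 numeric", path))
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-9)
    abort_format(sprintf("'%s': last matrix row must be (0, 0, 0, 1)", path))
  tryCatch(rigid_transform(M[1:3, 1:3], M[1:3, 4], tol = 1e-6),
           cb3d_parameter_error = function(e) abort_format(sprintf(
             "'%s': matrix is not a rigid transform: %s",
             path, conditionMessage(e))))
}
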