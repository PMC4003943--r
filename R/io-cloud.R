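#' Read a point cloud from XYZ or PLY
#'
#' XYZ files are whitespace-separated `x y z` lines in metres; blank lines
#' and lines starting with `#` are skipped. PLY files (ASCII or binary
#' little-endian) must contain a `vertex` element with `x`, `y`, `z`
#' properties. Point ids are assigned in file order starting at 0.
#'
#' @param path file to read.
#' @param format `"xyz"`, `"ply"`, or `"auto"` (default: by file extension,
#'   falling back to xyz).
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else "xyz"
  }
  switch(format, xyz = read_xyz(path), ply = read_ply(path))
}

#' Write a point cloud to XYZ or PLY
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format `"xyz"`, `"ply"` (ASCII) or `"ply_binary"` (binary
#'   little-endian); `"auto"` picks from the extension.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "xyz", "ply", "ply_binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else "xyz"
  }
  switch(format,
    xyz = write_xyz(cloud, path),
    ply = write_ply(cloud, path, binary = FALSE),
    ply_binary = write_ply(cloud, path, binary = TRUE))
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no data lines in ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed XYZ line(s) ", paste(lineno[bad], collapse = ", "),
         " in ", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(lapply(parts, `[`, 1:3)))),
              ncol = 3, byrow = TRUE)
  bad <- which(!stats::complete.cases(m))
  if (length(bad))
    stop("non-numeric field on line(s) ", paste(lineno[bad], collapse = ", "),
         " in ", path)
  point_cloud(m)
}

write_xyz <- function(cloud, path) {
  writeLines(sprintf("%.9g %.9g %.9g",
                     cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3]),
             path)
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop(path, " is not a PLY file")
  fmt <- NULL
  elements <- list()  # name -> list(count, props = data.frame(name, type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]),
                              props = data.frame(name = character(),
                                                 type = character()))
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        stop("PLY list properties are not supported for vertex data")
      elements[[cur]]$props <- rbind(elements[[cur]]$props,
                                     data.frame(name = tok[3], type = tok[2]))
    } else if (tok[1] == "end_header") break
  }
  if (is.null(elements$vertex))
    stop("PLY file ", path, " has no vertex element")
  props <- elements$vertex$props
  if (!all(c("x", "y", "z") %in% props$name))
    stop("PLY vertex element must have x, y, z properties")
  nv <- elements$vertex$count
  if (!names(elements)[1] == "vertex")
    stop("vertex must be the first PLY element for this reader")

  if (identical(fmt, "ascii")) {
    rows <- readLines(con)
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) < nv) stop("PLY vertex data truncated in ", path)
    vals <- strsplit(trimws(rows[seq_len(nv)]), "\\s+")
    m <- matrix(as.numeric(unlist(lapply(vals, `[`, seq_len(nrow(props))))),
                ncol = nrow(props), byrow = TRUE)
    colnames(m) <- props$name
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- ply_type_size[props$type]
    if (anyNA(sizes)) stop("unknown PLY property type")
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * nv)
    if (length(raw) < rec * nv) stop("PLY vertex data truncated in ", path)
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    m <- matrix(0, nrow = nv, ncol = nrow(props),
                dimnames = list(NULL, props$name))
    for (p in seq_len(nrow(props))) {
      idx <- rep((seq_len(nv) - 1L) * rec, each = sizes[p]) +
        offs[p] + seq_len(sizes[p])
      what <- if (props$type[p] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      m[, p] <- readBin(raw[idx], what, n = nv, size = sizes[p],
                        endian = "little",
                        signed = !(props$type[p] %in% c("uchar", "uint8",
                                                        "ushort", "uint16")))
    }
  } else {
    stop("unsupported PLY format: ", fmt)
  }
  point_cloud(m[, c("x", "y", "z"), drop = FALSE])
}

write_ply <- function(cloud, path, binary = FALSE) {
  n <- n_points(cloud)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(cloud$coords)), con, size = 8L, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g", cloud$coords[, 1],
                       cloud$coords[, 2], cloud$coords[, 3]), con)
  }
  invisible(path)
}
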