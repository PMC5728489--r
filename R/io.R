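# Volume I/O: NRRD (raw/gzip encodings), MHD/RAW, multipage TIFF.
# NRRD and MHD are simple text headers plus a raw little-endian block; both
# are written and parsed here directly. TIFF goes through the `tiff` package
# and is restricted to non-negative integer volumes (8/16-bit); TIFF carries
# no 3D spacing, so the voxel size must be supplied by the caller.

nrrd_types <- data.frame(
  name = c("uint8", "uint16", "int32", "float", "double"),
  nrrd = c("unsigned char", "unsigned short", "int", "float", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  what = c("integer", "integer", "integer", "double", "double"),
  stringsAsFactors = FALSE
)

pick_type <- function(vol, type) {
  if (type != "auto") return(type)
  v <- as.vector(vol)
  if (all(v == round(v)) && min(v) >= 0 && max(v) < 65536) return("uint16")
  if (all(v == round(v)) && abs(max(abs(v))) < 2^31) return("int32")
  "double"
}

#' Write a volume to NRRD, MHD/RAW or multipage TIFF
#'
#' Format chosen from the file extension (`.nrrd`, `.mhd`, `.tif`/`.tiff`).
#' Integer volumes round-trip bit-identically. The voxel size attribute is
#' stored in NRRD/MHD headers (TIFF cannot carry it).
#'
#' @param vol 3D numeric array (or [volume_image()]).
#' @param path output file path.
#' @param type element type: `"auto"` (default), `"uint8"`, `"uint16"`,
#'   `"int32"`, `"float"`, `"double"` (NRRD/MHD only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, type = "auto") {
  check_mask(vol, "vol")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = write_nrrd(vol, path, type),
    mhd = write_mhd(vol, path, type),
    tif = ,
    tiff = write_tiff_volume(vol, path),
    stop("unknown volume format: .", ext)
  )
  invisible(path)
}

#' Read a volume from NRRD, MHD/RAW or multipage TIFF
#'
#' @param path input file path.
#' @param voxel_size_um voxel size override; required for TIFF if the value
#'   is needed downstream (TIFF headers carry none).
#' @return a [volume_image()] (integer-typed data stays exact).
#' @export
read_volume <- function(path, voxel_size_um = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = read_nrrd(path, voxel_size_um),
    mhd = read_mhd(path, voxel_size_um),
    tif = ,
    tiff = read_tiff_volume(path, voxel_size_um),
    stop("unknown volume format: .", ext)
  )
}

write_nrrd <- function(vol, path, type = "auto") {
  type <- pick_type(vol, type)
  ti <- nrrd_types[nrrd_types$name == type, ]
  if (nrow(ti) != 1) stop("unsupported NRRD type: ", type)
  d <- dim(vol)
  vs <- voxel_size(vol)
  hdr <- c("NRRD0004",
           paste("type:", ti$nrrd),
           "dimension: 3",
           paste("sizes:", paste(d, collapse = " ")),
           "encoding: raw",
           "endian: little")
  if (!is.na(vs))
    hdr <- c(hdr, paste("spacings:", paste(rep(vs, 3), collapse = " ")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  v <- as.vector(vol)
  if (ti$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = ti$size, endian = "little")
  invisible(path)
}

parse_kv_header <- function(lines, sep) {
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\s*#", ln) || !grepl(sep, ln, fixed = TRUE)) next
    parts <- strsplit(ln, sep, fixed = TRUE)[[1]]
    key <- tolower(trimws(parts[1]))
    kv[[key]] <- trimws(paste(parts[-1], collapse = sep))
  }
  kv
}

read_nrrd <- function(path, voxel_size_um = NA_real_) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw_all == as.raw(10))
  # header ends at the first blank line
  hdr_end <- NA
  prev <- 0L
  for (i in nl) {
    if (i == prev + 1L) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) stop("corrupt NRRD: no blank line after header")
  hdr_txt <- rawToChar(raw_all[seq_len(hdr_end)])
  lines <- strsplit(hdr_txt, "\n")[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  kv <- parse_kv_header(lines[-1], ":")
  dims <- as.integer(strsplit(kv[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D NRRD volumes are supported")
  tname <- kv[["type"]]
  ti <- nrrd_types[nrrd_types$nrrd == tname, ]
  if (nrow(ti) != 1) stop("unsupported NRRD element type: ", tname)
  enc <- tolower(kv[["encoding"]])
  endian <- if (!is.null(kv[["endian"]])) tolower(kv[["endian"]]) else "little"
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc)
  }
  n <- prod(dims)
  v <- readBin(payload, ti$what, n = n, size = ti$size,
               signed = !(ti$name %in% c("uint8", "uint16")),
               endian = endian)
  if (length(v) != n) stop("corrupt NRRD: truncated data block")
  vs <- voxel_size_um
  if (is.na(vs) && !is.null(kv[["spacings"]])) {
    sp <- as.numeric(strsplit(kv[["spacings"]], "\\s+")[[1]])
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      stop("anisotropic voxel spacing is not supported")
    vs <- sp[1]
  }
  volume_image(array(v, dims), vs)
}

mhd_types <- c(uint8 = "MET_UCHAR", uint16 = "MET_USHORT",
               int32 = "MET_INT", float = "MET_FLOAT",
               double = "MET_DOUBLE")

write_mhd <- function(vol, path, type = "auto") {
  type <- pick_type(vol, type)
  ti <- nrrd_types[nrrd_types$name == type, ]
  d <- dim(vol)
  vs <- voxel_size(vol)
  if (is.na(vs)) vs <- 1
  rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", mhd_types[[type]]),
           paste("ElementSpacing =", paste(rep(vs, 3), collapse = " ")),
           "ElementByteOrderMSB = False",
           paste("ElementDataFile =", rawname))
  writeLines(hdr, path)
  v <- as.vector(vol)
  if (ti$what == "integer") v <- as.integer(round(v))
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(v, con, size = ti$size, endian = "little")
  invisible(path)
}

read_mhd <- function(path, voxel_size_um = NA_real_) {
  kv <- parse_kv_header(readLines(path), "=")
  dims <- as.integer(strsplit(kv[["dimsize"]], "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D MHD volumes are supported")
  tname <- kv[["elementtype"]]
  type <- names(mhd_types)[mhd_types == tname]
  if (length(type) != 1) stop("unsupported MHD element type: ", tname)
  ti <- nrrd_types[nrrd_types$name == type, ]
  sp <- as.numeric(strsplit(kv[["elementspacing"]], "\\s+")[[1]])
  if (length(sp) == 3 && max(sp) - min(sp) > 1e-9 * max(sp))
    stop("anisotropic voxel spacing is not supported (resample first)")
  msb <- identical(tolower(kv[["elementbyteordermsb"]]), "true")
  rawfile <- file.path(dirname(path), kv[["elementdatafile"]])
  if (!file.exists(rawfile)) stop("missing MHD data file: ", rawfile)
  n <- prod(dims)
  v <- readBin(rawfile, ti$what, n = n, size = ti$size,
               signed = !(ti$name %in% c("uint8", "uint16")),
               endian = if (msb) "big" else "little")
  if (length(v) != n) stop("corrupt MHD: truncated data file")
  vs <- if (!is.na(voxel_size_um)) voxel_size_um else sp[1]
  volume_image(array(v, dims), vs)
}

write_tiff_volume <- function(vol, path) {
  v <- as.vector(vol)
  if (any(v != round(v)) || min(v) < 0 || max(v) > 65535)
    stop("TIFF output supports non-negative integers up to 65535; ",
         "use NRRD/MHD for floating-point volumes")
  bits <- if (max(v) < 256) 8L else 16L
  scale <- 2^bits - 1
  d <- dim(vol)
  slices <- lapply(seq_len(d[3]), function(z) t(vol[, , z]) / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = bits)
  invisible(path)
}

read_tiff_volume <- function(path, voxel_size_um = NA_real_) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d1 <- dim(slices[[1]])
  vol <- array(0, c(d1[2], d1[1], length(slices)))
  for (z in seq_along(slices)) vol[, , z] <- t(slices[[z]])
  volume_image(vol, voxel_size_um)
}

#' Write / read landmarks as CSV
#'
#' Coordinates are 0-based voxel indices in (x, y, z) order (x is the
#' fastest-varying axis on disk).
#'
#' @param landmarks data.frame with columns `x, y, z` (0-based) and any
#'   extra columns (e.g. `label`, `name`).
#' @param path CSV file path.
#' @return `path` / the landmarks data.frame.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(all(c("x", "y", "z") %in% names(landmarks)))
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lm <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(lm)))
    stop("landmark CSV must have x,y,z columns (0-based voxel coordinates)")
  lm
}

#' Export a region graph as GraphML and CSV
#'
#' Writes `<stem>_vertices.csv`, `<stem>_edges.csv` and `<stem>.graphml`.
#'
#' @param graph a [build_region_graph()] result.
#' @param stem output path stem (no extension).
#' @param stats optional [compute_stats()] table merged onto the vertices.
#' @return named vector of written paths, invisibly.
#' @export
write_region_graph <- function(graph, stem, stats = NULL) {
  stopifnot(inherits(graph, "region_graph"))
  v <- graph$vertices
  if (!is.null(stats)) {
    # columns already on the vertex frame (e.g. volume) keep the graph's copy
    extra <- c("label", setdiff(names(stats), names(v)))
    v <- merge(v, stats[, extra, drop = FALSE], by = "label", sort = TRUE)
  }
  pv <- paste0(stem, "_vertices.csv")
  pe <- paste0(stem, "_edges.csv")
  pg <- paste0(stem, ".graphml")
  utils::write.csv(v, pv, row.names = FALSE)
  utils::write.csv(graph$edges, pe, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = graph$edges$a, to = graph$edges$b,
                   contact_faces = graph$edges$contact_faces),
    directed = FALSE,
    vertices = data.frame(name = v$label, v[, setdiff(names(v), "label")]))
  igraph::write_graph(g, pg, format = "graphml")
  invisible(c(vertices = pv, edges = pe, graphml = pg))
}
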