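#' Construct a grayscale volume
#'
#' A `grayscale_volume` is a 3D intensity lattice with an isotropic voxel
#' size in micrometres. The array is stored with `dim = c(nz, ny, nx)`, i.e.
#' `vol$data[z, y, x]`, with slices ascending in z. Voxel indices are 0-based
#' in all physical-coordinate math: the centre of voxel `(z, y, x)` lies at
#' `(index + 0.5) * voxel_size_um`.
#'
#' @param data 3D numeric or integer array of finite intensities.
#' @param voxel_size_um positive scalar, micrometres per voxel edge
#'   (isotropic).
#' @param provenance free-text record of where the volume came from.
#' @return An object of class `grayscale_volume` with fields `data`,
#'   `voxel_size_um`, `dims` and `provenance`.
#' @export
grayscale_volume <- function(data, voxel_size_um, provenance = "") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  if (anyNA(data) || !all(is.finite(data)))
    stop("intensities must be finite")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         dims = dim(data), provenance = provenance),
    class = "grayscale_volume"
  )
}

#' Construct a binary void mask
#'
#' Same lattice contract as [grayscale_volume()]; `TRUE` marks void voxels.
#'
#' @param mask 3D logical array, `TRUE` = void.
#' @param voxel_size_um positive scalar, micrometres per voxel edge.
#' @param provenance free-text source record.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_size_um, provenance = "") {
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  if (!is.logical(mask))
    stop("`mask` must be logical")
  if (anyNA(mask))
    stop("`mask` must not contain NA")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(
    list(mask = mask, voxel_size_um = as.numeric(voxel_size_um),
         dims = dim(mask), provenance = provenance),
    class = "binary_volume"
  )
}

#' @export
print.grayscale_volume <- function(x, ...) {
  cat(sprintf("<grayscale_volume> %d x %d x %d (z,y,x), %.4g um/voxel\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_um))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %d x %d x %d (z,y,x), %.4g um/voxel\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_um))
  cat(sprintf("  void fraction %.4g\n", mean(x$mask)))
  invisible(x)
}

# slice (z) of a volume array as a (ny, nx) matrix
.get_slice <- function(arr, z) {
  m <- arr[z, , , drop = TRUE]
  dim(m) <- dim(arr)[2:3]
  m
}

.tiff_bits <- function(arr) {
  mx <- max(arr)
  if (is.logical(arr) || mx <= 255) 8L else 16L
}

#' Read a 3D volume
#'
#' Supported formats: `tiff_stack` (one multi-page TIFF, pages = z slices,
#' ascending), `tiff_dir` (a directory of single-slice TIFFs ordered by the
#' numeric part of their file names), and `raw_headered` (little-endian raw
#' voxels plus a plain-text sidecar `<path>.hdr` declaring dims, dtype and
#' voxel size). Integer data are read bit-exactly; no rescaling is applied.
#'
#' @param path file (or directory for `tiff_dir`) to read.
#' @param voxel_size_um voxel edge length in micrometres. Ignored for
#'   `raw_headered`, whose header carries it.
#' @param format one of `"tiff_stack"`, `"tiff_dir"`, `"raw_headered"`.
#' @return A [grayscale_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL,
                        format = c("tiff_stack", "tiff_dir", "raw_headered")) {
  format <- match.arg(format)
  if (format == "tiff_stack") {
    if (!file.exists(path)) stop("file not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    shp <- lapply(pages, dim)
    if (length(unique(lapply(shp, identity))) != 1L)
      stop("inconsistent slice shapes in TIFF stack")
    arr <- .stack_slices(pages)
  } else if (format == "tiff_dir") {
    if (!dir.exists(path)) stop("directory not found: ", path)
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE)
    if (length(files) == 0L) stop("no TIFF slices in ", path)
    num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", files)))
    if (anyNA(num)) stop("slice file names must contain a slice number")
    files <- files[order(num)]
    pages <- lapply(file.path(path, files),
                    function(f) tiff::readTIFF(f, as.is = TRUE))
    shp <- lapply(pages, dim)
    if (length(unique(shp)) != 1L)
      stop("inconsistent slice shapes across TIFF directory")
    arr <- .stack_slices(pages)
  } else {
    hdr_path <- paste0(path, ".hdr")
    if (!file.exists(path)) stop("file not found: ", path)
    if (!file.exists(hdr_path)) stop("missing header sidecar: ", hdr_path)
    hdr <- .read_kv(hdr_path)
    dims <- as.integer(strsplit(hdr[["dims"]], "[ ,]+")[[1]])
    if (length(dims) != 3L || any(dims <= 0))
      stop("header must declare dims as three positive integers (nz ny nx)")
    dtype <- hdr[["dtype"]]
    voxel_size_um <- as.numeric(hdr[["voxel_size_um"]])
    n <- prod(dims)
    con <- file(path, "rb")
    on.exit(close(con))
    raw_vals <- switch(dtype,
      uint8  = as.integer(readBin(con, "integer", n, size = 1,
                                  signed = FALSE, endian = "little")),
      uint16 = as.integer(readBin(con, "integer", n, size = 2,
                                  signed = FALSE, endian = "little")),
      float64 = readBin(con, "double", n, size = 8, endian = "little"),
      stop("unsupported dtype in header: ", dtype)
    )
    if (length(raw_vals) != n) stop("raw file shorter than declared dims")
    arr <- array(raw_vals, dim = dims)
  }
  if (is.null(voxel_size_um))
    stop("`voxel_size_um` is required for TIFF input")
  grayscale_volume(arr, voxel_size_um, provenance = paste0(format, ":", path))
}

.stack_slices <- function(pages) {
  ny <- dim(pages[[1]])[1]; nx <- dim(pages[[1]])[2]
  nz <- length(pages)
  arr <- array(0L, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  storage.mode(arr) <- storage.mode(pages[[1]])
  arr
}

.read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")),
                         ""),
                  vapply(kv, function(p) trimws(p[1]), ""))
}

#' Write a 3D volume
#'
#' Inverse of [read_volume()]: a round trip is bit-exact for integer data.
#' Binary masks are serialised as 8-bit 0/255.
#'
#' @param volume a [grayscale_volume()] or [binary_volume()].
#' @param path destination file (directory for `tiff_dir`).
#' @param format one of `"tiff_stack"`, `"tiff_dir"`, `"raw_headered"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path,
                         format = c("tiff_stack", "tiff_dir", "raw_headered")) {
  format <- match.arg(format)
  is_mask <- inherits(volume, "binary_volume")
  arr <- if (is_mask) array(ifelse(volume$mask, 255L, 0L),
                            dim = volume$dims) else volume$data
  if (format %in% c("tiff_stack", "tiff_dir")) {
    bits <- .tiff_bits(arr)
    if (max(arr) > 65535 || min(arr) < 0)
      stop("TIFF output supports unsigned 8/16-bit intensities only")
    scale <- 2^bits - 1
    slices <- lapply(seq_len(dim(arr)[1]),
                     function(z) .get_slice(arr, z) / scale)
    if (format == "tiff_stack") {
      tiff::writeTIFF(slices, path, bits.per.sample = bits)
    } else {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      wd <- max(4L, nchar(as.character(length(slices) - 1L)))
      for (z in seq_along(slices))
        tiff::writeTIFF(slices[[z]],
                        file.path(path, sprintf(paste0("%0", wd, "d.tif"),
                                                z - 1L)),
                        bits.per.sample = bits)
    }
  } else {
    mx <- max(arr)
    dtype <- if (is.double(arr) && any(arr != round(arr))) "float64"
             else if (mx <= 255 && min(arr) >= 0) "uint8"
             else if (mx <= 65535 && min(arr) >= 0) "uint16"
             else "float64"
    con <- file(path, "wb")
    if (dtype == "float64") {
      writeBin(as.double(arr), con, size = 8, endian = "little")
    } else {
      writeBin(as.integer(arr), con, size = if (dtype == "uint8") 1L else 2L,
               endian = "little")
    }
    close(con)
    writeLines(c(paste0("dims: ", paste(dim(arr), collapse = " ")),
                 paste0("dtype: ", dtype),
                 paste0("voxel_size_um: ",
                        format(volume$voxel_size_um, digits = 17)),
                 if (is_mask) "phase_encoding: void=255 solid=0"),
               paste0(path, ".hdr"))
  }
  invisible(path)
}

#' Write pore-network tables
#'
#' The `tsv` dialect writes `nodes.tsv` (pore_id, cx_um, cy_um, cz_um,
#' radius_um, volume_um3, coordination) and `links.tsv` (throat_id, pore_a,
#' pore_b, radius_um, length_um, volume_um3). The `statoil_like` dialect
#' writes the conventional four-file node/link layout (`net_node1.dat`,
#' `net_node2.dat`, `net_link1.dat`, `net_link2.dat`) carrying the same
#' fields. Both round-trip losslessly through [read_network_tables()].
#'
#' @param network a `pore_network` (see [build_network()]).
#' @param dir_path output directory (created if needed).
#' @param dialect `"tsv"` or `"statoil_like"`.
#' @return `dir_path`, invisibly.
#' @export
write_network_tables <- function(network, dir_path,
                                 dialect = c("tsv", "statoil_like")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "pore_network"))
  p <- network$pores; t <- network$throats
  if (nrow(t) > 0 && !all(c(t$pore_a, t$pore_b) %in% p$id))
    stop("throat references unknown pore id")
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  meta <- c(paste0("# voxel_size_um=", format(network$voxel_size_um,
                                              digits = 17)),
            paste0("# void_voxel_count=", network$void_voxel_count))
  if (dialect == "tsv") {
    nodes <- data.frame(pore_id = p$id, cx_um = p$cx_um, cy_um = p$cy_um,
                        cz_um = p$cz_um, radius_um = p$radius_um,
                        volume_um3 = p$volume_um3,
                        coordination = p$coordination)
    links <- data.frame(throat_id = t$id, pore_a = t$pore_a,
                        pore_b = t$pore_b, radius_um = t$radius_um,
                        length_um = t$length_um, volume_um3 = t$volume_um3)
    .write_tsv(nodes, file.path(dir_path, "nodes.tsv"), meta)
    .write_tsv(links, file.path(dir_path, "links.tsv"), meta)
  } else {
    # node1: id x y z coordination; node2: id volume radius
    # link1: id pore_a pore_b radius; link2: id length volume
    .write_tsv(data.frame(id = p$id, x = p$cx_um, y = p$cy_um, z = p$cz_um,
                          coordination = p$coordination),
               file.path(dir_path, "net_node1.dat"), meta)
    .write_tsv(data.frame(id = p$id, volume = p$volume_um3,
                          radius = p$radius_um),
               file.path(dir_path, "net_node2.dat"), meta)
    .write_tsv(data.frame(id = t$id, pore_a = t$pore_a, pore_b = t$pore_b,
                          radius = t$radius_um),
               file.path(dir_path, "net_link1.dat"), meta)
    .write_tsv(data.frame(id = t$id, length = t$length_um,
                          volume = t$volume_um3),
               file.path(dir_path, "net_link2.dat"), meta)
  }
  invisible(dir_path)
}

.write_tsv <- function(df, path, comment_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment_lines)) writeLines(comment_lines, con)
  # full double precision so round trips are exact
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- format(df[[j]], digits = 17)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = NA)
}

.read_tsv_meta <- function(path) {
  lines <- readLines(path, n = 10)
  lines <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", lines), "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Read pore-network tables
#'
#' Inverse of [write_network_tables()].
#'
#' @param dir_path directory containing the tables.
#' @param dialect `"tsv"` or `"statoil_like"`.
#' @return A `pore_network`.
#' @export
read_network_tables <- function(dir_path, dialect = c("tsv", "statoil_like")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    nodes <- .read_tsv(file.path(dir_path, "nodes.tsv"))
    links <- .read_tsv(file.path(dir_path, "links.tsv"))
    meta <- .read_tsv_meta(file.path(dir_path, "nodes.tsv"))
    pores <- data.frame(id = nodes$pore_id, cx_um = nodes$cx_um,
                        cy_um = nodes$cy_um, cz_um = nodes$cz_um,
                        radius_um = nodes$radius_um,
                        volume_um3 = nodes$volume_um3,
                        coordination = nodes$coordination)
    throats <- data.frame(id = links$throat_id, pore_a = links$pore_a,
                          pore_b = links$pore_b, radius_um = links$radius_um,
                          length_um = links$length_um,
                          volume_um3 = links$volume_um3)
  } else {
    n1 <- .read_tsv(file.path(dir_path, "net_node1.dat"))
    n2 <- .read_tsv(file.path(dir_path, "net_node2.dat"))
    l1 <- .read_tsv(file.path(dir_path, "net_link1.dat"))
    l2 <- .read_tsv(file.path(dir_path, "net_link2.dat"))
    meta <- .read_tsv_meta(file.path(dir_path, "net_node1.dat"))
    pores <- data.frame(id = n1$id, cx_um = n1$x, cy_um = n1$y, cz_um = n1$z,
                        radius_um = n2$radius[match(n1$id, n2$id)],
                        volume_um3 = n2$volume[match(n1$id, n2$id)],
                        coordination = n1$coordination)
    throats <- data.frame(id = l1$id, pore_a = l1$pore_a, pore_b = l1$pore_b,
                          radius_um = l1$radius,
                          length_um = l2$length[match(l1$id, l2$id)],
                          volume_um3 = l2$volume[match(l1$id, l2$id)])
  }
  if (nrow(throats) > 0) {
    bad <- setdiff(c(throats$pore_a, throats$pore_b), pores$id)
    if (length(bad))
      stop("throat references unknown pore id(s): ",
           paste(bad, collapse = ", "))
  }
  pore_network(pores, throats,
               voxel_size_um = as.numeric(meta[["voxel_size_um"]]),
               void_voxel_count = as.numeric(meta[["void_voxel_count"]]))
}
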