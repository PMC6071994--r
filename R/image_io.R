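# File I/O: grayscale images as ASCII PGM (P2) or PNG, numeric matrices
# as CSV with a commented header, phantoms as a two-channel image pair
# plus a JSON sidecar with run-length-encoded masks and ground truth.
#
# TIFF is not supported in this build (no TIFF reader available); PGM and
# PNG cover the grayscale use cases losslessly enough (16-bit).

#' Read a grayscale image
#'
#' Supports ASCII PGM (`.pgm`, P2), PNG (`.png`; RGB reduced by channel
#' selection or luminance) and plain matrix CSV (`.csv`).  Intensities
#' are rescaled to \[0, 1\] for PGM/PNG.
#'
#' @param path input file.
#' @param channel for RGB PNG: 1-3 to select a channel, or
#'   `"luminance"`.
#' @return numeric matrix (rows = y, cols = x).
#' @export
read_image <- function(path, channel = "luminance") {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 2L) return(arr)
    if (identical(channel, "luminance"))
      return(0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] +
               0.0722 * arr[, , 3L])
    check_number(channel, "channel", positive = TRUE, integerish = TRUE)
    return(arr[, , channel])
  }
  if (ext == "csv") return(read_matrix_csv(path))
  if (ext %in% c("tif", "tiff"))
    stop_invalid("TIFF input is not supported in this build; ",
                 "convert to PGM or PNG")
  stop_invalid("unsupported image format: .", ext)
}

#' Write a matrix as an ASCII PGM (P2) image
#'
#' Values are linearly scaled from `range` to 16-bit integers.
#'
#' @param img numeric matrix.
#' @param path output file.
#' @param range intensity range mapped to \[0, 65535\].
#' @export
write_pgm <- function(img, path, range = c(0, 1)) {
  check_image(img)
  maxval <- 65535L
  span <- max(range[2L] - range[1L], 1e-12)
  q <- round((pmin(pmax(img, range[1L]), range[2L]) - range[1L]) /
               span * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
             con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_pgm <- function(path) {
  tokens <- scan(path, what = character(), comment.char = "#",
                 quiet = TRUE)
  if (tokens[1L] != "P2")
    stop_invalid("only ASCII (P2) PGM is supported")
  dims <- as.integer(tokens[2:3])
  maxval <- as.numeric(tokens[4L])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != dims[1L] * dims[2L])
    stop_invalid("corrupt PGM: pixel count mismatch")
  matrix(vals, nrow = dims[2L], ncol = dims[1L], byrow = TRUE) / maxval
}

#' Write a numeric matrix as CSV with a commented header
#'
#' Header lines (prefixed `#`) record units and the coordinate
#' convention: origin top-left, x rightward (columns), y downward (rows),
#' 0-based pixel-centre coordinates in all serialised tables.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @param comment character vector of extra header lines.
#' @export
write_matrix_csv <- function(m, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", comment),
               "# coordinates: origin top-left, x right, y down, 0-based"),
             con)
  utils::write.table(m, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", comment.char = "#",
                              header = FALSE))
}

# Run-length encode/decode a logical matrix (column-major).
rle_encode_mask <- function(mask) {
  r <- rle(as.logical(mask))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(list(lengths = as.integer(enc$lengths),
                        values = as.logical(enc$values)))
  matrix(v, nrow = enc$dim[1L], ncol = enc$dim[2L])
}

#' Write a phantom to disk
#'
#' Channels go to `dii.pgm` and `nsc.pgm`; masks (run-length encoded),
#' centreline, truth angles, planted clusters, injection site, pixel
#' scale and seed go to `phantom.json`.
#'
#' @param phantom a `phantom`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!inherits(phantom, "phantom")) stop_invalid("`phantom` required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pgm(phantom$dii_image, file.path(dir, "dii.pgm"))
  write_pgm(phantom$nsc_image, file.path(dir, "nsc.pgm"))
  side <- list(
    masks = list(wm = rle_encode_mask(phantom$masks$wm),
                 gm = rle_encode_mask(phantom$masks$gm),
                 background = rle_encode_mask(phantom$masks$background)),
    tract = phantom$tract,
    tract_centerline = unname(as.matrix(phantom$tract_centerline)),
    truth_cluster_angles = phantom$truth_cluster_angles,
    clusters = if (is.null(phantom$clusters)) NULL else
      as.data.frame(phantom$clusters),
    injection_site = unname(phantom$injection_site),
    pixel_scale_um = phantom$pixel_scale_um,
    seed = phantom$seed)
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir phantom directory.
#' @return a `phantom` object.
#' @export
read_phantom <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  masks <- tissue_masks(wm = rle_decode_mask(side$masks$wm),
                        gm = rle_decode_mask(side$masks$gm),
                        background = rle_decode_mask(side$masks$background),
                        pixel_scale_um = side$pixel_scale_um)
  clusters <- NULL
  if (!is.null(side$clusters) && length(side$clusters)) {
    cl <- as.data.frame(side$clusters)
    col_or <- function(v, default)  # all-NA columns serialise to null
      if (is.null(v)) default else unlist(lapply(v, function(x)
        if (is.null(x)) default else x))
    clusters <- nsc_clusters(x = cl$x, y = cl$y, size = cl$size,
                             tissue_class = col_or(cl$tissue_class,
                                                   NA_character_),
                             region_id = col_or(cl$region_id,
                                                NA_integer_),
                             theta_nsc = col_or(cl$theta_nsc, NA_real_),
                             excluded = col_or(cl$excluded, FALSE))
  }
  structure(list(dii_image = read_pgm(file.path(dir, "dii.pgm")),
                 nsc_image = read_pgm(file.path(dir, "nsc.pgm")),
                 masks = masks,
                 tract = side$tract,
                 tract_centerline = cbind(x = side$tract_centerline[, 1L],
                                          y = side$tract_centerline[, 2L]),
                 injection_site = c(x = side$injection_site[1L],
                                    y = side$injection_site[2L]),
                 pixel_scale_um = side$pixel_scale_um,
                 truth_cluster_angles =
                   as.numeric(side$truth_cluster_angles %||% numeric(0)),
                 clusters = clusters,
                 seed = side$seed),
            class = "phantom")
}
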