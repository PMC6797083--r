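# Minimal baseline TIFF I/O (little-endian, uncompressed, grayscale, one
# IFD per channel). The environment this package targets has no TIFF
# library, so the subset of the format the pipeline needs is implemented
# here: 32-bit float or 16-bit unsigned samples, single strip per page,
# pixel size recorded in the ImageDescription tag. The reader understands
# exactly this subset (plus multi-strip pages) and errors clearly on
# anything else; it is not a general TIFF parser.

.le16 <- function(v) {
  v <- as.integer(v)
  as.raw(c(rbind(v %% 256L, v %/% 256L)))
}
.le32 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
                 (v %/% 16777216) %% 256)))
}

.ifd_entry <- function(tag, type, count, value_raw4) {
  c(.le16(tag), .le16(type), .le32(count), value_raw4)
}

#' Write a grayscale TIFF image
#'
#' Writes a matrix (single channel) or a `rows x cols x channels` array as
#' an uncompressed little-endian TIFF, one page per channel, with the pixel
#' size stored in the ImageDescription tag (`pixel_size_um=<value>`).
#'
#' @param img Numeric/integer matrix or 3D array.
#' @param path Output path.
#' @param pixel_size_um Pixel size recorded in metadata; defaults to the
#'   image's `pixel_size_um` attribute or 1.
#' @param dtype `"float32"` (default for numeric data) or `"uint16"`
#'   (default for integer data, e.g. label images).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, pixel_size_um = attr(img, "pixel_size_um"),
                       dtype = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- 1
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  stopifnot(length(dim(img)) == 3L)
  if (is.null(dtype))
    dtype <- if (is.integer(img)) "uint16" else "float32"
  dtype <- match.arg(dtype, c("float32", "uint16"))
  nr <- dim(img)[1]; nc <- dim(img)[2]; nch <- dim(img)[3]
  bps <- if (dtype == "float32") 32L else 16L
  fmt <- if (dtype == "float32") 3L else 1L
  bytes_px <- bps / 8L
  desc <- sprintf("pixel_size_um=%.10g", pixel_size_um)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))

  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  page_meta <- ifd_size + length(desc_raw)
  data_size <- nr * nc * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49, 0x2a, 0x00)), .le32(8)), con)
  offset <- 8
  for (ch in seq_len(nch)) {
    ifd_off <- offset
    desc_off <- ifd_off + ifd_size
    data_off <- desc_off + length(desc_raw)
    next_ifd <- if (ch < nch) data_off + data_size else 0
    entries <- c(
      .ifd_entry(256, 4, 1, .le32(nc)),
      .ifd_entry(257, 4, 1, .le32(nr)),
      .ifd_entry(258, 3, 1, c(.le16(bps), .le16(0))),
      .ifd_entry(259, 3, 1, c(.le16(1), .le16(0))),   # no compression
      .ifd_entry(262, 3, 1, c(.le16(1), .le16(0))),   # black-is-zero
      .ifd_entry(270, 2, length(desc_raw), .le32(desc_off)),
      .ifd_entry(273, 4, 1, .le32(data_off)),
      .ifd_entry(278, 4, 1, .le32(nr)),
      .ifd_entry(279, 4, 1, .le32(data_size)),
      .ifd_entry(339, 3, 1, c(.le16(fmt), .le16(0)))
    )
    writeBin(.le16(n_entries), con)
    writeBin(entries, con)
    writeBin(.le32(next_ifd), con)
    writeBin(desc_raw, con)
    plane <- t(img[, , ch]) # TIFF is row-major
    if (dtype == "float32") {
      writeBin(as.numeric(plane), con, size = 4, endian = "little")
    } else {
      v <- as.integer(plane)
      if (any(v < 0L | v > 65535L))
        stop("uint16 TIFF requires values in [0, 65535]", call. = FALSE)
      writeBin(.le16(v), con)
    }
    offset <- data_off + data_size
  }
  invisible(path)
}

.read_le <- function(raw, off, nbytes) {
  # unsigned little-endian integer from raw vector (1-based offset)
  sum(as.numeric(raw[off:(off + nbytes - 1)]) * 256^(0:(nbytes - 1)))
}

#' Read a grayscale TIFF image written by [write_tiff()]
#'
#' Supports uncompressed little-endian grayscale pages with 16-bit unsigned
#' or 32-bit float samples; multiple pages are returned as channels.
#'
#' @param path TIFF file path.
#' @return Matrix (single page) or `rows x cols x channels` array, with
#'   attribute `pixel_size_um` when present in the metadata. 16-bit pages
#'   are returned as integer, float pages as double.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8 || raw[1] != as.raw(0x49) || raw[2] != as.raw(0x49))
    stop("not a little-endian TIFF file: ", path, call. = FALSE)
  if (.read_le(raw, 3, 2) != 42) stop("bad TIFF magic", call. = FALSE)
  ifd_off <- .read_le(raw, 5, 4)
  planes <- list()
  pixel_size <- NULL
  int_out <- TRUE
  while (ifd_off != 0) {
    n <- .read_le(raw, ifd_off + 1, 2)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- .read_le(raw, e + 1, 2)
      type <- .read_le(raw, e + 3, 2)
      count <- .read_le(raw, e + 5, 4)
      tsize <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4)[as.character(type)]
      if (is.na(tsize)) tsize <- 4
      inline <- tsize * count <= 4
      voff <- if (inline) e + 9 else .read_le(raw, e + 9, 4) + 1
      vals <- vapply(seq_len(count), function(j)
        .read_le(raw, voff + (j - 1) * tsize, tsize), numeric(1))
      tags[[as.character(tag)]] <- list(type = type, values = vals,
                                        offset = voff, count = count)
    }
    need <- function(tg) {
      t <- tags[[as.character(tg)]]
      if (is.null(t)) stop("TIFF missing required tag ", tg, call. = FALSE)
      t$values
    }
    nc <- need(256); nr <- need(257); bps <- need(258)
    comp <- if (!is.null(tags[["259"]])) tags[["259"]]$values else 1
    if (comp != 1) stop("compressed TIFF not supported", call. = FALSE)
    fmt <- if (!is.null(tags[["339"]])) tags[["339"]]$values else 1
    offs <- need(273)
    counts <- need(279)
    if (!is.null(tags[["270"]])) {
      d <- tags[["270"]]
      bytes <- raw[d$offset:(d$offset + d$count - 1)]
      txt <- rawToChar(bytes[bytes != as.raw(0)])
      m <- regmatches(txt, regexec("pixel_size_um=([0-9.eE+-]+)", txt))[[1]]
      if (length(m) == 2) pixel_size <- as.numeric(m[2])
    }
    buf <- do.call(c, lapply(seq_along(offs), function(j)
      raw[(offs[j] + 1):(offs[j] + counts[j])]))
    if (bps == 32 && fmt == 3) {
      v <- readBin(buf, "numeric", nr * nc, size = 4, endian = "little")
      int_out <- FALSE
    } else if (bps == 16 && fmt == 1) {
      v <- readBin(buf, "integer", nr * nc, size = 2, signed = FALSE,
                   endian = "little")
    } else {
      stop("unsupported TIFF sample format (bits=", bps, ", format=", fmt,
           ")", call. = FALSE)
    }
    planes[[length(planes) + 1L]] <- t(matrix(v, nc, nr)) # row-major to R
    ifd_off <- .read_le(raw, ifd_off + 2 + n * 12 + 1, 4)
  }
  out <- if (length(planes) == 1L) planes[[1]]
  else array(unlist(planes), c(dim(planes[[1]]), length(planes)))
  if (int_out) storage.mode(out) <- "integer"
  if (!is.null(pixel_size)) attr(out, "pixel_size_um") <- pixel_size
  out
}

#' Write a measurement table as CSV
#'
#' UTF-8 CSV without row names; numeric values keep full precision
#' (15 significant digits).
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param seed Optional seed recorded as a `# seed:` header comment.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(rows, path, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(rows, con, row.names = FALSE, fileEncoding = "")
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path CSV path.
#' @return data.frame (header comment lines are skipped).
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", encoding = "UTF-8",
                  stringsAsFactors = FALSE)
}

#' Read a scene specification from YAML
#'
#' Expects the [scene_spec()] fields, with `species` a list of
#' [species_spec()] field sets and `counts` alongside.
#'
#' @param path YAML file path.
#' @return A `scene_spec`.
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("image_shape_px", "pixel_size_um", "species", "counts")
  miss <- setdiff(req, names(y))
  if (length(miss))
    stop("scene YAML missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  species <- lapply(y$species, function(s) do.call(species_spec, s))
  args <- y
  args$species <- species
  do.call(scene_spec, args)
}

#' Write a scene specification to YAML
#'
#' @param spec A [scene_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  y <- unclass(spec)
  y$species <- lapply(y$species, unclass)
  yaml::write_yaml(y, path)
  invisible(path)
}
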