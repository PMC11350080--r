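## ENVI hyperspectral container: plain-text .hdr + raw binary, interleaves
## BSQ/BIL/BIP, data types 2 (int16), 4 (float32), 5 (float64).

envi_dtype <- function(code) {
  switch(as.character(code),
         "2" = list(what = "integer", size = 2L),
         "4" = list(what = "double", size = 4L),
         "5" = list(what = "double", size = 8L),
         stop("unsupported ENVI data type ", code,
              " (supported: 2 int16, 4 float32, 5 float64)", call. = FALSE))
}

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0 || !grepl("^ENVI", txt[1])) {
    stop("ENVI format error: header does not start with 'ENVI': ",
         header_path, call. = FALSE)
  }
  # join multi-line { ... } blocks
  joined <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in txt[-1]) {
    buf <- if (open) paste(buf, ln) else ln
    nb_open <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nb_close <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    open <- nb_open > nb_close
    if (!open) {
      joined <- c(joined, buf)
      buf <- ""
    }
  }
  kv <- list()
  for (ln in joined) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  kv
}

envi_field <- function(kv, name, required = TRUE) {
  v <- kv[[name]]
  if (is.null(v) && required) {
    stop("ENVI format error: missing header field '", name, "'",
         call. = FALSE)
  }
  v
}

envi_num_block <- function(val) {
  as.numeric(strsplit(gsub("[{}]", "", val), ",")[[1]])
}

#' Read an ENVI hyperspectral cube
#'
#' Reads the text header (`<path>.hdr` or the header itself) and the raw
#' binary, honouring interleave (bsq/bil/bip), byte order and data type
#' (int16/float32/float64; int16 supports an optional
#' `reflectance scale factor` divisor). Wavelengths are taken from the
#' header's `wavelength` block; the mask defaults to all-TRUE.
#'
#' @param header_path path to the `.hdr` header (or the binary; the `.hdr`
#'   suffix is added when absent).
#' @return a [hypercube].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  if (!grepl("\\.hdr$", header_path)) {
    header_path <- paste0(header_path, ".hdr")
  }
  if (!file.exists(header_path)) {
    stop("ENVI header not found: ", header_path, call. = FALSE)
  }
  data_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(data_path)) {
    stop("ENVI binary not found: ", data_path, call. = FALSE)
  }
  kv <- parse_envi_header(header_path)
  samples <- as.integer(envi_field(kv, "samples"))  # cols
  lines <- as.integer(envi_field(kv, "lines"))      # rows
  bands <- as.integer(envi_field(kv, "bands"))
  dtype <- envi_dtype(envi_field(kv, "data type"))
  interleave <- tolower(envi_field(kv, "interleave"))
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("ENVI format error: interleave must be bsq/bil/bip, got '",
         interleave, "'", call. = FALSE)
  }
  byte_order <- kv[["byte order"]]
  endian <- if (!is.null(byte_order) && as.integer(byte_order) == 1) {
    "big"
  } else {
    "little"
  }
  offset <- if (is.null(kv[["header offset"]])) 0L else
    as.integer(kv[["header offset"]])
  wl <- envi_num_block(envi_field(kv, "wavelength"))
  if (length(wl) != bands) {
    stop("ENVI format error: header declares ", bands, " bands but ",
         length(wl), " wavelengths", call. = FALSE)
  }
  n <- samples * lines * bands
  expect_bytes <- offset + n * dtype$size
  if (file.size(data_path) != expect_bytes) {
    stop("ENVI format error: binary holds ",
         (file.size(data_path) - offset) / dtype$size,
         " values but the header declares ", n,
         " (samples x lines x bands mismatch)", call. = FALSE)
  }
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  vals <- readBin(con, dtype$what, n = n, size = dtype$size,
                  endian = endian, signed = TRUE)
  vals <- as.double(vals)
  if (dtype$size == 2L && !is.null(kv[["reflectance scale factor"]])) {
    vals <- vals / as.numeric(kv[["reflectance scale factor"]])
  }
  arr <- switch(interleave,
    bsq = aperm(array(vals, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(vals, c(bands, samples, lines)), c(3, 2, 1)))
  px <- kv[["pixel size um"]]
  hypercube(arr, wl,
            pixel_size_um = if (is.null(px)) 11 else as.numeric(px))
}

#' Write an ENVI hyperspectral cube
#'
#' Writes `<path>` (raw binary) and `<path>.hdr`. Data types: 4 (float32)
#' and 5 (float64, the default, bit-faithful round-trip). The mask is not
#' serialized (ENVI has no mask concept); reads default to all-TRUE.
#'
#' @param cube a [hypercube].
#' @param path output path for the binary; the header gets `.hdr` appended.
#' @param interleave one of "bsq", "bil", "bip".
#' @param data_type 5 for float64 (default) or 4 for float32.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4, 5)) {
    stop("write_envi supports data types 4 (float32) and 5 (float64)",
         call. = FALSE)
  }
  d <- dim(cube$data)
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  con <- file(path, "wb")
  writeBin(vals, con, size = if (data_type == 5) 8L else 4L,
           endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {stemspec export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("pixel size um = ", format(cube$pixel_size_um, digits = 15)),
    "wavelength units = cm-1",
    paste0("wavelength = {",
           paste(format(cube$axis, digits = 17, trim = TRUE,
                        scientific = FALSE),
                 collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

## raw ENVI writer for non-wavenumber band stacks (e.g. component maps):
## wavelength block carries the band index, band names the component names.
envi_write_array <- function(arr, path, band_names = NULL) {
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  d <- dim(arr)
  con <- file(path, "wb")
  writeBin(as.vector(aperm(arr, c(2, 1, 3))), con, size = 8L,
           endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {stemspec component maps}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    paste0("wavelength = {", paste(seq_len(d[3]), collapse = ", "), "}"),
    if (!is.null(band_names)) {
      paste0("band names = {", paste(band_names, collapse = ", "), "}")
    }
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}
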