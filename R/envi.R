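#' Read an ENVI hypercube
#'
#' Reads a header/binary ENVI pair into a [hypercube]. All three interleaves
#' (BSQ, BIL, BIP) are supported and yield an identical (rows x cols x bands)
#' array; the wavelength grid is taken from the header's `wavelength` block.
#' Supported data types are 4 (32-bit float) and 12 (unsigned 16-bit
#' integer); anything else is rejected.
#'
#' @param header_path path to the `.hdr` text header. The binary file is
#'   looked up next to it: the header path stripped of `.hdr`, then with
#'   `.dat`, `.img` or `.bin` appended.
#' @param kind cube kind to stamp on the result, `"raw"` by default.
#' @return A [hypercube].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path, kind = "raw") {
  if (!file.exists(header_path))
    stop("header file not found: ", header_path)
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")

  scalar_key <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key,
                                        "\\s*=\\s*([^\\n{]+)"),
                                 txt, perl = TRUE))[[1L]]
    if (length(m) < 2L) return(NA_character_)
    trimws(m[2L])
  }
  need <- function(key) {
    v <- scalar_key(key)
    if (is.na(v) || !nzchar(v))
      stop("ENVI header is missing required key '", key, "'")
    v
  }

  samples <- as.integer(need("samples"))
  lines_n <- as.integer(need("lines"))
  bands <- as.integer(need("bands"))
  if (anyNA(c(samples, lines_n, bands)) ||
      any(c(samples, lines_n, bands) < 1L))
    stop("ENVI header declares contradictory dimensions ",
         "(samples/lines/bands must be positive integers)")
  interleave <- tolower(need("interleave"))
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("ENVI header key 'interleave' must be bil, bip or bsq, got '",
         interleave, "'")
  dtype <- as.integer(need("data type"))
  if (!dtype %in% c(4L, 12L))
    stop("ENVI 'data type' ", dtype,
         " unsupported; only 4 (float32) and 12 (uint16) are read")
  byte_order <- as.integer(need("byte order"))
  endian <- if (byte_order == 1L) "big" else "little"

  wl_m <- regmatches(txt, regexec("(?si)wavelength\\s*=\\s*\\{(.*?)\\}",
                                  txt, perl = TRUE))[[1L]]
  if (length(wl_m) < 2L)
    stop("ENVI header is missing required key 'wavelength'")
  wavelengths <- as.numeric(strsplit(gsub("\\s+", "", wl_m[2L]), ",")[[1L]])
  if (anyNA(wavelengths) || length(wavelengths) != bands)
    stop("ENVI header 'wavelength' block has ", length(wavelengths),
         " entries but 'bands' declares ", bands)

  bin_path <- envi_binary_path(header_path)
  if (is.na(bin_path))
    stop("binary file for header not found: ", header_path)
  n <- as.double(samples) * lines_n * bands
  bytes <- if (dtype == 4L) 4 else 2
  if (file.size(bin_path) != n * bytes)
    stop("ENVI integrity error: binary file has ", file.size(bin_path),
         " bytes but header implies ", n * bytes)

  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- if (dtype == 4L) {
    readBin(con, what = "numeric", n = n, size = 4L, endian = endian)
  } else {
    readBin(con, what = "integer", n = n, size = 2L, signed = FALSE,
            endian = endian)
  }

  # reassemble to (rows, cols, bands); R fills the first dimension fastest
  arr <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines_n, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(samples, bands, lines_n)), c(3L, 1L, 2L)),
    bip = aperm(array(v, dim = c(bands, samples, lines_n)), c(3L, 2L, 1L)))
  hypercube(arr, wavelengths, kind)
}

#' Write an ENVI hypercube
#'
#' Writes a header/binary pair readable by [read_envi()]. The round trip is
#' bit-exact for values representable in the declared data type.
#'
#' @param cube a [hypercube].
#' @param header_path output path of the text header; the binary goes to the
#'   same path with `.hdr` replaced by `.dat`.
#' @param interleave storage order on disk: `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type `"float32"` or `"uint16"` (ENVI codes 4 and 12).
#' @return `header_path`, invisibly.
#' @export
write_envi <- function(cube, header_path,
                       interleave = c("bsq", "bil", "bip"),
                       data_type = c("float32", "uint16")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- match.arg(data_type)
  d <- dim(cube$data)
  dtype_code <- if (data_type == "float32") 4L else 12L

  hdr <- c(
    "ENVI",
    "description = {hyperseed export}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", dtype_code),
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    "wavelength = {",
    paste0(" ", paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                      collapse = ", ")),
    "}")
  writeLines(hdr, header_path)

  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube$data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube$data, c(3L, 2L, 1L))))
  bin_path <- sub("\\.hdr$", "", header_path)
  if (identical(bin_path, header_path)) bin_path <- paste0(header_path, ".dat")
  else bin_path <- paste0(bin_path, ".dat")
  con <- file(bin_path, "wb")
  on.exit(close(con))
  if (data_type == "float32") {
    writeBin(v, con, size = 4L, endian = "little")
  } else {
    iv <- as.integer(round(v))
    if (any(iv < 0L) || any(iv > 65535L))
      stop("values outside [0, 65535] cannot be written as uint16")
    # writeBin stores the signed 16-bit pattern; map the upper range onto it
    iv <- ifelse(iv > 32767L, iv - 65536L, iv)
    writeBin(iv, con, size = 2L, endian = "little")
  }
  invisible(header_path)
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  cands <- unique(c(base, paste0(base, c(".dat", ".img", ".bin"))))
  cands <- setdiff(cands, header_path)
  hit <- cands[file.exists(cands)]
  if (length(hit)) hit[1L] else NA_character_
}
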