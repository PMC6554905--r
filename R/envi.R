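#' Read an ENVI hyperspectral cube
#'
#' Parses an ENVI header (plain-text `key = value` file) and reads the
#' associated binary cube into a `raw_cube` with axis order
#' (line, sample, band), independent of the on-disk interleave.
#'
#' Header fields honoured: `samples`, `lines`, `bands`, `interleave`
#' (bil/bip/bsq), `data type` (4 = float32, 5 = float64, 12 = uint16),
#' `byte order`, and the `wavelength = { ... }` list (nm).
#'
#' @param header_path Path to the `.hdr` file. The binary is found by
#'   stripping the `.hdr` extension, or from the same basename with `.dat`,
#'   `.img` or `.raw`.
#' @return A `raw_cube`: list with `irradiance` (3-D array,
#'   line x sample x band), `wavelengths` (nm) and `meta` (remaining header
#'   fields, carried opaquely).
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) {
    stop("ENVI header not found: ", header_path)
  }
  hdr <- parse_envi_header(header_path)
  for (fld in c("samples", "lines", "bands", "interleave", "data type")) {
    if (is.null(hdr[[fld]])) stop("ENVI header missing required field '", fld, "'")
  }
  if (is.null(hdr[["wavelength"]])) {
    stop("ENVI header has no wavelength list; cannot attach a band grid")
  }
  bin_path <- envi_binary_path(header_path)

  ns <- as.integer(hdr$samples)
  nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  if (length(wl) != nb) {
    stop("wavelength list length (", length(wl), ") != bands (", nb, ")")
  }

  dt <- as.integer(hdr[["data type"]])
  spec <- envi_dtype(dt)
  endian <- if (!is.null(hdr[["byte order"]]) && as.integer(hdr[["byte order"]]) == 1) "big" else "little"

  n_expect <- as.numeric(ns) * nl * nb
  sz <- file.size(bin_path)
  if (sz != n_expect * spec$size) {
    stop("ENVI binary size mismatch: file has ", sz, " bytes, header implies ",
         n_expect * spec$size, " bytes")
  }
  vals <- readBin(bin_path, what = spec$what, n = n_expect, size = spec$size,
                  signed = spec$signed, endian = endian)
  vals <- as.numeric(vals)

  interleave <- tolower(hdr$interleave)
  # readBin gives values in file order; map each interleave's (fastest..slowest)
  # axes onto our canonical (line, sample, band)
  arr <- switch(interleave,
    bil = aperm(array(vals, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(nb, ns, nl)), c(3, 2, 1)),
    bsq = aperm(array(vals, dim = c(ns, nl, nb)), c(2, 1, 3)),
    stop("unsupported interleave '", interleave, "' (expected bil, bip or bsq)")
  )
  raw_cube(arr, wl, meta = hdr)
}

#' Write a cube to ENVI format
#'
#' @param cube A `raw_cube` or any list with a 3-D array in `$irradiance` or
#'   `$reflectance` plus `$wavelengths`.
#' @param path Output path without extension; writes `<path>.hdr` and
#'   `<path>.dat`.
#' @param interleave One of "bil", "bip", "bsq".
#' @param data_type ENVI data-type code: 4 (float32), 5 (float64) or
#'   12 (uint16).
#' @return Invisibly, the header path.
#' @export
write_envi <- function(cube, path, interleave = "bil", data_type = 5L) {
  arr <- if (!is.null(cube$irradiance)) cube$irradiance else cube$reflectance
  stopifnot(length(dim(arr)) == 3)
  wl <- cube$wavelengths
  nl <- dim(arr)[1]; ns <- dim(arr)[2]; nb <- dim(arr)[3]
  interleave <- match.arg(tolower(interleave), c("bil", "bip", "bsq"))
  spec <- envi_dtype(data_type)

  perm <- switch(interleave,
    bil = c(2, 3, 1),  # file order fastest-first: sample, band, line
    bip = c(3, 2, 1),  # band, sample, line
    bsq = c(2, 1, 3)   # sample, line, band
  )
  vals <- as.vector(aperm(arr, perm))
  if (spec$what == "integer") vals <- as.integer(round(vals))

  bin_path <- paste0(path, ".dat")
  hdr_path <- paste0(path, ".hdr")
  con <- file(bin_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(if (spec$what == "integer") as.integer(vals) else as.numeric(vals),
           con, size = spec$size, endian = "little")

  hdr <- c(
    "ENVI",
    "description = { grasshsi cube }",
    paste0("samples = ", ns),
    paste0("lines = ", nl),
    paste0("bands = ", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = { ", paste(format(wl, trim = TRUE, digits = 10), collapse = ", "), " }")
  )
  writeLines(hdr, hdr_path)
  invisible(hdr_path)
}

#' Construct a raw irradiance cube
#'
#' @param irradiance 3-D array (line, sample, band) of sensor counts.
#' @param wavelengths Strictly increasing band grid, nm.
#' @param meta Opaque acquisition metadata.
#' @export
raw_cube <- function(irradiance, wavelengths, meta = list()) {
  stopifnot(length(dim(irradiance)) == 3,
            length(wavelengths) == dim(irradiance)[3])
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing")
  }
  structure(list(irradiance = irradiance, wavelengths = as.numeric(wavelengths),
                 meta = meta),
            class = "raw_cube")
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # fold multi-line { ... } blocks onto one line
  txt <- paste(lines, collapse = "\n")
  hdr <- list()
  # consume brace blocks first
  pat <- "([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*\\{([^}]*)\\}"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
      key <- tolower(trimws(sub(pat, "\\1", piece, perl = TRUE)))
      val <- gsub("\\s+", " ", trimws(sub(pat, "\\2", piece, perl = TRUE)))
      hdr[[key]] <- val
    }
    txt <- gsub(pat, "", txt, perl = TRUE)
  }
  for (ln in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", ln, fixed = TRUE)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- tolower(trimws(kv[1]))
    val <- trimws(paste(kv[-1], collapse = "="))
    if (nzchar(key) && nzchar(val)) hdr[[key]] <- val
  }
  hdr
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  cands <- c(base, paste0(base, c(".dat", ".img", ".raw", ".bin")))
  for (p in cands) if (file.exists(p) && !dir.exists(p)) return(p)
  stop("no binary found for ENVI header ", header_path)
}

envi_dtype <- function(code) {
  switch(as.character(code),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "5"  = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported ENVI data type ", code, " (supported: 4, 5, 12)")
  )
}
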