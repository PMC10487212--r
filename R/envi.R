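#' Write a hypercube in ENVI header + binary layout
#'
#' Writes `<base>.hdr` (text header with `samples`, `lines`, `bands`,
#' `data type`, `interleave`, `wavelength`) and `<base>.dat` (float32
#' binary in the requested interleave). Sample (column) index varies
#' fastest within a line, as in the ENVI convention.
#'
#' @param cube a [hypercube()].
#' @param base path without extension.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @return `base`, invisibly.
#' @export
write_envi <- function(cube, base, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  lines <- d[1]; samples <- d[2]; bands <- d[3]
  # reorder to the chosen interleave; R arrays are column-major
  x <- switch(interleave,
    # BSQ: sample, line, band
    bsq = aperm(cube$data, c(2, 1, 3)),
    # BIL: sample, band, line
    bil = aperm(cube$data, c(2, 3, 1)),
    # BIP: band, sample, line
    bip = aperm(cube$data, c(3, 2, 1))
  )
  hdr <- c(
    "ENVI",
    sprintf("description = {chemmap %s frame, sensor %s}",
            cube$frame_kind, cube$sensor_id),
    sprintf("samples = %d", samples),
    sprintf("lines = %d", lines),
    sprintf("bands = %d", bands),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(base)
}

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  # join brace-delimited multi-line values
  joined <- character(0)
  buf <- NULL
  for (line in txt) {
    if (is.null(buf)) {
      if (grepl("\\{", line) && !grepl("\\}", line)) buf <- line
      else joined <- c(joined, line)
    } else {
      buf <- paste(buf, line)
      if (grepl("\\}", line)) { joined <- c(joined, buf); buf <- NULL }
    }
  }
  kv <- list()
  for (line in joined) {
    if (!grepl("=", line)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    kv[[key]] <- val
  }
  kv
}

#' Read an ENVI header + binary hypercube
#'
#' Accepts BSQ, BIL and BIP interleaves of float32/float64 data with the
#' wavelength list in the header.
#'
#' @param hdr_path path to the `.hdr` file (the binary is looked up beside
#'   it as `.dat`, `.img`, `.raw` or extensionless).
#' @param sensor_id,frame_kind metadata for the returned [hypercube()].
#' @return A [hypercube()].
#' @export
read_envi <- function(hdr_path, sensor_id = "unknown",
                      frame_kind = "reflectance") {
  kv <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(need, names(kv))
  if (length(missing)) {
    stop("ENVI header missing field(s): ", paste(missing, collapse = ", "))
  }
  samples <- as.integer(kv$samples); lines <- as.integer(kv$lines)
  bands <- as.integer(kv$bands)
  dtype <- as.integer(kv[["data type"]])
  if (!dtype %in% c(4L, 5L)) {
    stop("unsupported ENVI data type ", dtype, " (need 4=float32 or ",
         "5=float64)")
  }
  size <- if (dtype == 4L) 4L else 8L
  interleave <- tolower(kv$interleave)
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported interleave '", interleave, "'")
  }
  wl <- numeric(0)
  if (!is.null(kv$wavelength)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", kv$wavelength), ",")[[1]])
  }
  if (length(wl) && length(wl) != bands) {
    stop("header declares bands = ", bands, " but the wavelength list has ",
         length(wl), " entries")
  }
  if (!length(wl)) wl <- seq_len(bands)

  base <- sub("\\.hdr$", "", hdr_path)
  bin <- NULL
  for (ext in c(".dat", ".img", ".raw", "")) {
    cand <- paste0(base, ext)
    if (file.exists(cand) && cand != hdr_path) { bin <- cand; break }
  }
  if (is.null(bin)) stop("no binary file found beside ", hdr_path)
  n <- samples * lines * bands
  expected <- n * size
  actual <- file.info(bin)$size
  if (actual != expected) {
    stop("binary size ", actual, " B does not match header shape (",
         expected, " B expected)")
  }
  con <- file(bin, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = size, endian = "little")
  arr <- switch(interleave,
    bsq = aperm(array(x, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(x, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(x, c(bands, samples, lines)), c(3, 2, 1))
  )
  hypercube(arr, wl, sensor_id, frame_kind)
}

#' Write a labelled ROI mask as an ENVI byte image
#'
#' @param mask integer matrix of labels (0 = background).
#' @param base path without extension.
#' @export
write_envi_mask <- function(mask, base) {
  hdr <- c(
    "ENVI",
    "description = {chemmap ROI label mask}",
    sprintf("samples = %d", ncol(mask)),
    sprintf("lines = %d", nrow(mask)),
    "bands = 1",
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 1",
    "interleave = bsq",
    "byte order = 0"
  )
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(mask)), con, size = 1)
  invisible(base)
}
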