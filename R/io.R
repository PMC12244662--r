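## Image and configuration I/O: PNG/TIFF via the png and tiff packages,
## PGM (P2/P5) with a built-in codec, run configuration as JSON.

.luminance <- function(arr) {
  ## Rec. 601 luma for RGB(A) arrays
  if (length(dim(arr)) == 2L) return(arr)
  if (dim(arr)[3L] >= 3L)
    0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
  else arr[, , 1L]
}

.readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM (P2/P5) file: ", path, call. = FALSE)
  tokens <- character(0)
  buf <- character(0)
  ## header: width, height, maxval; '#' starts a comment
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "")
      stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  dims <- as.integer(tokens)
  w <- dims[1L]; h <- dims[2L]; maxv <- dims[3L]
  n <- w * h
  if (magic == "P5") {
    sz <- if (maxv > 255L) 2L else 1L
    vals <- readBin(con, "integer", n, size = sz, signed = FALSE,
                    endian = "big")
  } else {
    vals <- scan(con, integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM data: ", path, call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}

.writePGM <- function(img, path) {
  q <- matrix(.quantize256(img), nrow(img), ncol(img))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
            eos = NULL)
  writeBin(as.integer(t(q)), con, size = 1L)
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (by extension), converts RGB(A) to grayscale by
#' Rec. 601 luminance, and returns intensities normalized to `[0, 1]`.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.pgm` file.
#' @return Numeric matrix in `[0, 1]` (rows = image rows).
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = .luminance(png::readPNG(path)),
                tif = ,
                tiff = .luminance(tiff::readTIFF(path)),
                pgm = .readPGM(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  img <- pmin(pmax(img, 0), 1)
  .assertImage(img, minDim = 3L, arg = path)
  img
}

#' Write a grayscale image
#'
#' Writes an 8-bit grayscale PNG, TIFF or PGM chosen by the file
#' extension; values outside `[0, 1]` are clipped with a warning.
#' Quantization to 8 bits happens only here, at write time.
#'
#' @param img Numeric matrix.
#' @param path Output path (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @return `path`, invisibly.
#' @export
writeImageGray <- function(img, path) {
  .assertImage(img)
  if (any(img < 0) || any(img > 1)) {
    warning("image values clipped to [0, 1] on write", call. = FALSE)
    img <- pmin(pmax(img, 0), 1)
  }
  img <- matrix(.quantize256(img) / 255, nrow(img), ncol(img))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         pgm = .writePGM(img, path),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Default run configuration
#'
#' All tunables of the pipeline as one JSON-serializable list, with the
#' study-configuration defaults (1000 iterations, hypervolume convergence
#' threshold 0.01, diversity threshold 0.2, 3600 s time limit, 31
#' benchmark runs, window sides 3/5/7/9, Oustaloup constants N = 2,
#' M = 20).
#'
#' @return Named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(popSize = 50L, maxIter = 1000L, hvThreshold = 0.01,
       hvWindow = 50L, diversityThreshold = 0.2, timeLimit = 3600,
       runs = 31L, windowSides = c(3L, 5L, 7L, 9L),
       alphaLo = 0.6, alphaHi = 1.0, depth = 4L,
       rho = c(0.8, 0.8, 0.8), sccMax = 0.9, stagnationMax = 5L,
       minPop = 10L, maxPop = 60L, oustaloupN = 2L, oustaloupM = 20L,
       band = c(0.01, 100), hvRef = c(2, 2), costModel = "proxy",
       seed = 1L)
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [defaultRunConfig()].
#'
#' @param path JSON file path.
#' @return Named list merging the file over the defaults.
#' @export
readRunConfig <- function(path) {
  cfg <- defaultRunConfig()
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user
  cfg
}

#' Write fused-image metrics as CSV
#'
#' One row per image pair with columns ENT, MI (per source), FMI, Qabf,
#' SSIM (per source), fitness1, cost, wallclock seconds.
#'
#' @param report Named list as from [metricReport()], plus optional
#'   `fitness1`, `cost`, `wallclock_s`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeMetricsCSV <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
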