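# Plain-text file formats. Labeled masks and images travel as ASCII PGM
# (P2; maxval up to 65535, i.e. 16-bit labels); probability maps as a
# whitespace-separated numeric matrix with a one-line dimension header.
# Both formats are trivial, portable, diffable, and need no image library.

#' Write an integer matrix as an ASCII PGM (P2) image
#'
#' Used for images, binary masks (0/255) and 16-bit labeled masks
#' (0 background, labels 1..K).
#'
#' @param m Integer (or logical) matrix; values in `0..maxval`.
#' @param path Output file path.
#' @param maxval Maximum gray value; default the larger of `max(m)` and 1,
#'   capped at 65535.
#' @export
write_pgm <- function(m, path, maxval = NULL) {
  if (is.logical(m)) m <- m * 255L
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("m must be a numeric matrix", call. = FALSE)
  }
  m <- round(m)
  if (min(m) < 0) stop("PGM values must be non-negative", call. = FALSE)
  if (is.null(maxval)) maxval <- max(max(m), 1)
  if (maxval > 65535) stop("PGM maxval cannot exceed 65535", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), format(maxval, scientific = FALSE)), con)
  # raster rows = matrix rows, top to bottom
  writeLines(apply(m, 1L, paste, collapse = " "), con)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path File path.
#' @return Integer matrix (H x W).
#' @export
read_pgm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  tok <- scan(text = paste(raw, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1L] != "P2") {
    stop("not an ASCII (P2) PGM file: ", path, call. = FALSE)
  }
  w <- as.integer(tok[2L])
  h <- as.integer(tok[3L])
  vals <- as.integer(tok[-(1:4)])
  if (length(vals) != h * w) {
    stop("PGM pixel count mismatch in ", path, call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a probability map as plain text
#'
#' One-line header `H W`, then the matrix rows.
#'
#' @param p Numeric H x W matrix in `[0, 1]`.
#' @param path Output file path.
#' @export
write_probmap <- function(p, path) {
  check_probmap(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(p), ncol(p)), con)
  writeLines(apply(p, 1L, function(r) paste(format(r, digits = 9), collapse = " ")), con)
}

#' Read a probability map written by [write_probmap()]
#'
#' @param path File path.
#' @return Numeric H x W matrix.
#' @export
read_probmap <- function(path) {
  tok <- scan(path, what = numeric(), quiet = TRUE)
  h <- as.integer(tok[1L])
  w <- as.integer(tok[2L])
  if (length(tok) != 2L + h * w) {
    stop("probability map size mismatch in ", path, call. = FALSE)
  }
  matrix(tok[-(1:2)], nrow = h, ncol = w, byrow = TRUE)
}

#' Run-length encode an instance set (DSB submission dialect)
#'
#' One row per object; pixels are 1-based column-major indices encoded as
#' space-separated `start length` pairs.
#'
#' @param x An [instance_set()].
#' @param image_id Identifier written in the `ImageId` column.
#' @param path Optional CSV output path; when `NULL` only the data frame is
#'   returned.
#' @return Invisibly, a data frame with columns `ImageId`, `EncodedPixels`.
#' @export
write_dsb_rle <- function(x, image_id, path = NULL) {
  stopifnot(inherits(x, "instance_set"))
  enc <- vapply(x$objects, function(idx) {
    # idx is sorted column-major, which is exactly the RLE pixel order
    brk <- c(TRUE, diff(idx) != 1L)
    starts <- idx[brk]
    lens <- diff(c(which(brk), length(idx) + 1L))
    paste(rbind(starts, lens), collapse = " ")
  }, character(1L))
  df <- data.frame(ImageId = rep(image_id, length(enc)),
                   EncodedPixels = enc, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
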