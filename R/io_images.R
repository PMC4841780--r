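## Plain-text image IO. Plate scans travel as NetPBM PGM (P2, ASCII), the
## one grayscale raster format that needs no binary toolchain; 3D
## fluorescence stacks use a small PGM-like text format that carries the
## voxel size in its header. All quantification functions also accept the
## in-memory matrix/array directly, so these formats are a transport detail.

#' Write a grayscale image as ASCII PGM (P2)
#'
#' @param img numeric matrix, row 1 = image top. Values are rounded to
#'   integers; `maxval` must bound them.
#' @param path output path.
#' @param maxval maximum gray value recorded in the header.
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  img <- round(img)
  if (any(img < 0) || any(img > maxval))
    stopf("pixel values outside [0, %d]", maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# spiscreen plate image"),
               sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  writeLines(apply(img, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#' @param path file path.
#' @return integer matrix, row 1 = image top.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stopf("%s is not an ASCII PGM (P2) file", path)
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  w <- vals[1]; h <- vals[2]
  px <- vals[-(1:3)]
  if (length(px) != w * h) stopf("PGM pixel count mismatch in %s", path)
  matrix(as.integer(px), nrow = h, ncol = w, byrow = TRUE)
}

#' Write a 3D fluorescence stack as text
#'
#' Slices are stored top z-slice first, each as rows of whitespace-separated
#' values; the header records dimensions and the voxel size in nm.
#'
#' @param stack numeric array `(z, y, x)`.
#' @param path output path.
#' @param voxel_nm numeric length-3 `(z, y, x)` voxel edge lengths in nm.
#' @export
write_stack <- function(stack, path, voxel_nm = attr(stack, "voxel_nm")) {
  if (length(dim(stack)) != 3L) stopf("stack must be a 3D array")
  if (is.null(voxel_nm) || length(voxel_nm) != 3L)
    stopf("voxel_nm (z, y, x) is required")
  d <- dim(stack)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("SPISTACK1",
               sprintf("# dims z y x: %d %d %d", d[1], d[2], d[3]),
               sprintf("# voxel_nm z y x: %g %g %g",
                       voxel_nm[1], voxel_nm[2], voxel_nm[3])), con)
  for (z in seq_len(d[1]))
    writeLines(apply(stack[z, , , drop = TRUE], 1L,
                     function(r) paste(format(r, digits = 10), collapse = " ")),
               con)
  invisible(path)
}

#' Read a text fluorescence stack written by [write_stack()]
#' @param path file path.
#' @return numeric array `(z, y, x)` with attribute `voxel_nm`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  lines <- readLines(path)
  if (lines[1] != "SPISTACK1") stopf("%s is not a spiscreen stack", path)
  hdr <- lines[grepl("^#", lines)]
  d <- as.integer(strsplit(sub(".*:", "", hdr[grepl("dims", hdr)]), " +")[[1]][-1])
  v <- as.numeric(strsplit(sub(".*:", "", hdr[grepl("voxel", hdr)]), " +")[[1]][-1])
  vals <- scan(text = paste(lines[!grepl("^#", lines)][-1], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != prod(d)) stopf("stack value count mismatch in %s", path)
  a <- aperm(array(vals, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  attr(a, "voxel_nm") <- v
  a
}
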