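# Image and dataset I/O. On-disk formats: 8-bit grayscale PNG (via the png
# package) and plain-text PGM (P2) for tiny fixtures. Masks follow the
# `<stem>_mask.png` convention with lesion = 255; loaders accept 0/1 or
# 0/255 coding.

#' Read a grayscale image
#'
#' PNG (8- or 16-bit; colour is averaged to gray) or plain-text PGM (P2).
#' Intensities are scaled to `[0, 1]`.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                             c(1, 2), mean)
    img
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    stop("unsupported image format '.", ext, "' (PNG and PGM are supported)",
         call. = FALSE)
  }
}

#' Write a grayscale image
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path (`.png` or `.pgm`); 8-bit output.
#' @export
write_gray <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext == "pgm") write_pgm(img, path)
  else stop("unsupported image format '.", ext, "'", call. = FALSE)
  invisible(path)
}

read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}

write_pgm <- function(img, path) {
  v <- round(img * 255)
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             apply(v, 1, paste, collapse = " "))   # one line per image row
  writeLines(lines, path)
  invisible(path)
}

#' Load paired image/mask samples from a directory
#'
#' Every image `<stem>.png` with a sibling `<stem>_mask.png` becomes one
#' sample; mask intensities above 0.5 are lesion.
#'
#' @param dir directory to scan.
#' @return sample list (`image`, `mask`, `provenance` = file path).
#' @export
load_samples <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.(png|pgm)$", full.names = TRUE)
  imgs <- files[!grepl("_mask\\.(png|pgm)$", files)]
  if (length(imgs) == 0) stop("no images found under ", dir, call. = FALSE)
  lapply(imgs, function(f) {
    stem <- tools::file_path_sans_ext(f)
    ext <- tools::file_ext(f)
    mf <- paste0(stem, "_mask.", ext)
    if (!file.exists(mf))
      stop("missing mask for image: ", f, " (expected ", mf, ")",
           call. = FALSE)
    img <- read_gray(f)
    msk <- (read_gray(mf) > 0.5) * 1
    if (!identical(dim(img), dim(msk)))
      stop("image/mask shape mismatch for ", f, call. = FALSE)
    list(image = img, mask = msk, provenance = f)
  })
}

#' Write a sample list as paired PNGs plus a manifest CSV
#'
#' @param samples sample list.
#' @param dir output directory (created if needed).
#' @param stem filename stem, default `"phantom"`.
#' @param format `"png"` or `"pgm"`.
#' @return invisibly, the manifest path.
#' @export
write_samples <- function(samples, dir, stem = "phantom", format = "png") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(samples)) {
    base <- file.path(dir, sprintf("%s_%04d", stem, i))
    write_gray(samples[[i]]$image, paste0(base, ".", format))
    write_gray(samples[[i]]$mask, paste0(base, "_mask.", format))
  }
  manifest <- attr(samples, "manifest")
  mpath <- file.path(dir, "manifest.csv")
  if (!is.null(manifest)) write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
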