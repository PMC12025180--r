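# Readers and writers: 8-bit grayscale PNG images (16-bit TIFF accepted on
# read), strict {0, 255} PNG masks, and tab-separated manifests.

LUMA_WEIGHTS <- c(0.2126, 0.7152, 0.0722)  # BT.709 luminance

#' Read a grayscale image
#'
#' PNG or TIFF; 3-channel inputs are converted to luminance with fixed
#' BT.709 weights (0.2126, 0.7152, 0.0722). Values are returned in `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch({
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  }, error = function(e) stop("unreadable image file ", path, ": ", conditionMessage(e)))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) {
      x <- LUMA_WEIGHTS[1] * x[, , 1] + LUMA_WEIGHTS[2] * x[, , 2] + LUMA_WEIGHTS[3] * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  pmin(pmax(x, 0), 1)
}

#' Read a strict binary mask
#'
#' An 8-bit PNG whose pixels must all be 0 or 255; any other value is an
#' error (masks are annotations, not images, and intermediate gray levels
#' indicate a corrupted file).
#'
#' @param path file path.
#' @return binary numeric matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: file does not exist: ", path)
  x <- tryCatch(png::readPNG(path),
                error = function(e) stop("unreadable mask file ", path, ": ", conditionMessage(e)))
  if (length(dim(x)) == 3L) x <- x[, , 1]
  v <- round(x * 255)
  if (!all(v %in% c(0, 255))) {
    bad <- sort(unique(v[!(v %in% c(0, 255))]))
    stop("mask ", path, " contains values other than {0, 255}: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  (v == 255) * 1
}

#' Write an 8-bit grayscale PNG image
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a binary mask as a {0, 255} PNG
#' @param mask binary matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read / write dataset manifests
#'
#' Tab-separated UTF-8 with header columns `sample_id`, `image_path`,
#' `mask_paths` (semicolon-joined, ordered by annotator id), `condition`,
#' `patient_id`, `eye`, `annotator_ids`, `split`.
#'
#' @param manifest data.frame.
#' @param path file path.
#' @return `read_manifest` returns the data.frame (validated: unique sample
#'   ids); `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "image_path", "mask_paths", "condition",
            "patient_id", "eye", "annotator_ids", "split")
  missing <- setdiff(need, names(m))
  if (length(missing)) stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("manifest sample_ids are not unique")
  m
}

#' Load a dataset written by [generate_dataset()] into memory
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @param manifest_file manifest file name.
#' @return list with `manifest`, `images`, `masks` (list of per-annotator
#'   lists), in manifest row order.
#' @export
load_dataset <- function(dir, manifest_file = "manifest.tsv") {
  manifest <- read_manifest(file.path(dir, manifest_file))
  images <- lapply(manifest$image_path, function(p) read_image(file.path(dir, p)))
  masks <- lapply(manifest$mask_paths, function(mp) {
    lapply(strsplit(mp, ";", fixed = TRUE)[[1]], function(p) read_mask(file.path(dir, p)))
  })
  list(manifest = manifest, images = images, masks = masks)
}
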