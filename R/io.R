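# Reading and writing images, masks, feature tables, selections and splits.

read_gray <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format `%s` for %s (use PNG or TIFF).", ext, path))
  )
  if (length(dim(arr)) != 2L) {
    abort(sprintf("Image %s is not single-channel grayscale (dimensions: %s).",
                  path, paste(dim(arr), collapse = "x")))
  }
  arr * 255
}

#' Load an image/mask pair from disk
#'
#' Reads an 8- or 16-bit grayscale PNG/TIFF intensity image and its binary
#' mask. Intensities are returned on the 0-255 scale regardless of bit depth;
#' any nonzero mask pixel becomes 1. RGB inputs are rejected rather than
#' silently converted. The `source_id` is taken from the image filename stem.
#'
#' @param image_path,mask_path Paths to the image and mask files.
#' @return An [image_sample()].
#' @export
load_image_mask_pair <- function(image_path, mask_path) {
  img <- read_gray(image_path)
  msk <- read_gray(mask_path)
  if (!identical(dim(img), dim(msk))) {
    abort(sprintf("Dimension mismatch between %s (%s) and %s (%s).",
                  image_path, paste(dim(img), collapse = "x"),
                  mask_path, paste(dim(msk), collapse = "x")))
  }
  image_sample(img, msk != 0,
               source_id = tools::file_path_sans_ext(basename(image_path)))
}

#' Write an image sample to disk
#'
#' Writes the intensity image (PNG or TIFF, 8- or 16-bit; intensities are
#' rounded to the bit-depth grid), the mask as an 8-bit PNG with values
#' 0/255, and a JSON sidecar with any generator parameters attached to the
#' sample. Integer-valued images round-trip exactly at either bit depth.
#'
#' @param sample An [image_sample()].
#' @param dir Output directory (created if needed).
#' @param name Base filename (defaults to the sample's `source_id`).
#' @param format `"png"` or `"tiff"` for the intensity image.
#' @param bits 8 or 16 bits per sample.
#' @return Invisibly, the paths written (image, mask, sidecar).
#' @export
write_image_sample <- function(sample, dir, name = NULL,
                               format = c("png", "tiff"), bits = 8L) {
  stopifnot(inherits(sample, "image_sample"))
  format <- match.arg(format)
  if (!bits %in% c(8L, 16L)) abort("`bits` must be 8 or 16.")
  if (format == "png" && bits == 16L) {
    abort("16-bit output requires `format = \"tiff\"`; PNG output is 8-bit.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  name <- name %||% sample$source_id

  scale <- 2^bits - 1
  img01 <- round(pmin(pmax(sample$image, 0), 255) / 255 * scale) / scale
  image_path <- file.path(dir, paste0(name, if (format == "png") ".png" else ".tiff"))
  if (format == "png") {
    png::writePNG(img01, image_path)
  } else {
    tiff::writeTIFF(img01, image_path, bits.per.sample = as.integer(bits))
  }
  mask_path <- file.path(dir, paste0(name, "_mask.png"))
  png::writePNG(sample$mask * 1.0, mask_path)

  sidecar <- file.path(dir, paste0(name, ".json"))
  meta <- list(
    source_id = sample$source_id,
    origin = sample$origin,
    params = if (!is.null(sample$params)) unclass(sample$params) else NULL
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(image = image_path, mask = mask_path, sidecar = sidecar))
}

feature_table_cols <- c(
  "sample_id", "source_id", "contrast", "noise", "density",
  "het_detrended", "het_raw", "medial_mean"
)

#' Write a feature table to CSV
#'
#' Columns: sample_id, source_id, contrast, noise, density, het_detrended,
#' het_raw, medial_mean. Numeric values are written with 17 significant
#' digits, so reading the file back reproduces the doubles exactly.
#'
#' @param dataset A [new_mapped_dataset()] carrying the morphometry feature
#'   columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "mapped_dataset"))
  df <- as.data.frame(dataset)
  missing_cols <- setdiff(feature_table_cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Dataset lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  df <- df[, feature_table_cols]
  for (j in 3:8) df[[j]] <- sprintf("%.17g", df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]; restores an unnormalized
#' [new_mapped_dataset()] with the fixed feature column order.
#'
#' @param path CSV path.
#' @return A `mapped_dataset` tibble.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("Malformed CSV %s: %s", path, conditionMessage(e)))
  )
  missing_cols <- setdiff(feature_table_cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Feature table %s lacks column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  for (col in feature_table_cols[3:8]) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("Non-numeric value in column `%s` of %s (data line %d).",
                    col, path, if (is.na(bad)) NA_integer_ else bad))
    }
  }
  new_mapped_dataset(
    as_tibble(df[, feature_table_cols]),
    feature_cols = c("contrast", "noise", "density", "het_detrended")
  )
}

#' Write a selection result as JSON
#'
#' Emits the selected sample ids, the FUS value, and a provenance block
#' (parameters, seeds, package version) for replay.
#'
#' @param selection A `selection_result`.
#' @param path Output JSON path.
#' @param params Optional named list of run parameters to record.
#' @return Invisibly, `path`.
#' @export
write_selection_json <- function(selection, path, params = list()) {
  stopifnot(inherits(selection, "selection_result"))
  payload <- list(
    sample_ids = selection$sample_ids,
    source_ids = selection$source_ids,
    selected_indices = selection$selected_indices,
    fus = selection$fus,
    provenance = c(
      list(
        k = selection$k,
        seed = selection$seed,
        base_seed = selection$base_seed,
        n_trials = selection$n_trials,
        artifact_version = as.character(utils::packageVersion("vesselect"))
      ),
      params
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a split (or list of splits) as JSON
#'
#' @param splits A `split_spec` or list of them.
#' @param path Output JSON path.
#' @param sample_ids Optional sample-id vector for translating indices.
#' @return Invisibly, `path`.
#' @export
write_split_json <- function(splits, path, sample_ids = NULL) {
  if (inherits(splits, "split_spec")) splits <- list(splits)
  payload <- purrr::map(splits, function(s) {
    list(
      train_indices = s$train_indices,
      val_indices = s$val_indices,
      train_ids = if (!is.null(sample_ids)) sample_ids[s$train_indices],
      val_ids = if (!is.null(sample_ids)) sample_ids[s$val_indices],
      provenance = c(
        s$provenance,
        list(artifact_version = as.character(utils::packageVersion("vesselect")))
      )
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
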