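# File I/O: 8-bit single-channel PNG/TIFF images, PNG masks, CSV metric
# reports, dataset-split utilities and run manifests.

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format '", ext, "' for ", path))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 1L) arr <- arr[, , 1]
    else stop("multi-channel input not supported (", dim(arr)[3],
              " channels): ", path, "; convert to 8-bit grayscale first")
  }
  arr
}

#' Read / write grayscale ultrasound images
#'
#' Images are stored as 8-bit single-channel PNG or TIFF; in R they are
#' `[H, W]` matrices with intensities 0..255. Writing then reading an
#' image is an exact round trip for integer-valued intensities.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return `read_image`: numeric matrix with values in 0..255.
#' @export
read_image <- function(path) {
  round(read_raster(path) * 255)
}

#' @rdname read_image
#' @param img `[H, W]` matrix, intensities 0..255.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  arr <- pmin(pmax(img, 0), 255) / 255
  switch(ext,
         png = png::writePNG(arr, path),
         tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
         stop("unsupported image format '", ext, "' for ", path))
  invisible(path)
}

#' Read / write binary masks
#'
#' Masks are 8-bit single-channel PNGs with 0 = background and 255 =
#' foreground; on read, values are binarized at 128.
#'
#' @param path file path.
#' @return `read_mask`: integer `[H, W]` matrix with values 0/1.
#' @export
read_mask <- function(path) {
  arr <- read_raster(path)
  as_mask(matrix(as.integer(arr >= 128 / 255), nrow(arr), ncol(arr)))
}

#' @rdname read_mask
#' @param mask binary `[H, W]` matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Evaluate all prediction/truth mask pairs in two directories
#'
#' Matches PNG files by name, computes the full metrics report per image
#' and writes a CSV with one row per image plus mean and standard
#' deviation summary rows.
#'
#' @param pred_dir,truth_dir directories of mask PNGs with matching
#'   file names.
#' @param out_csv optional path for the CSV report.
#' @return the report data frame, invisibly when `out_csv` is given.
#' @export
evaluate_dirs <- function(pred_dir, truth_dir, out_csv = NULL) {
  files <- sort(list.files(truth_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("no PNG masks found in ", truth_dir)
  missing <- setdiff(files, list.files(pred_dir, pattern = "\\.png$"))
  if (length(missing) > 0L)
    stop("prediction missing for: ", paste(missing, collapse = ", "))
  preds <- lapply(file.path(pred_dir, files), read_mask)
  truths <- lapply(file.path(truth_dir, files), read_mask)
  names(preds) <- tools::file_path_sans_ext(files)
  tab <- evaluate_batch(preds, truths)
  if (!is.null(out_csv)) {
    utils::write.csv(tab, out_csv, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' k-fold and leave-one-group-out dataset splits
#'
#' `split_kfold` assigns `n` items to `k` folds (fourfold by default,
#' shuffled under `seed`). `split_leave_one_group_out` builds one fold
#' per group for series data, optionally subsampling each training
#' sequence at a fixed stride from its first image.
#'
#' @param n number of items.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of folds, each `list(train, test)` index vectors.
#' @export
split_kfold <- function(n, k = 4L, seed = 1L) {
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' @rdname split_kfold
#' @param groups vector of group labels, one per item.
#' @param stride keep every `stride`-th training item within each group,
#'   starting from its first (1 keeps all).
#' @export
split_leave_one_group_out <- function(groups, stride = 1L) {
  gl <- unique(groups)
  lapply(gl, function(g) {
    train <- integer(0)
    for (og in setdiff(gl, g)) {
      idx <- which(groups == og)
      train <- c(train, idx[seq(1L, length(idx), by = stride)])
    }
    list(train = sort(train), test = which(groups == g), test_group = g)
  })
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seed, paths, package
#' version and timestamp of a pipeline run as JSON, so any run can be
#' reproduced exactly.
#'
#' @param command name of the pipeline command.
#' @param config configuration list snapshot.
#' @param seed integer seed used for the run.
#' @param inputs,outputs character vectors of paths.
#' @param path destination JSON file.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(command, config, seed, inputs, outputs, path) {
  manifest <- list(command = command, config = config, seed = seed,
                   inputs = inputs, outputs = outputs,
                   package_version = as.character(utils::packageVersion("tenduseg")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a run manifest
#'
#' @param path manifest JSON file.
#' @return the manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
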