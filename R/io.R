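#' Plain-text volume format (.svtx)
#'
#' A portable text serialization for label maps and image grids: the first
#' line is a JSON header (dimensions, storage type, spacing and arbitrary
#' metadata such as tissue tables or channel energies), followed by the
#' array values in column-major order. Round trips are exact for integer
#' data and to full double precision (17 significant digits) for reals.
#'
#' @param x numeric/integer array, [tissue_phantom()] or [spectral_image()].
#' @param path output path ending in `.svtx`.
#' @param meta extra metadata stored in the header.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, meta = list()) {
  if (!grepl("\\.svtx$", path))
    stop("unknown volume extension (expected .svtx): ", path, call. = FALSE)
  if (inherits(x, "tissue_phantom")) {
    meta <- c(meta, list(kind = "tissue_phantom",
                         tissue_table = as.list(x$tissue_table),
                         spacing = x$spacing))
    arr <- x$labels
  } else if (inherits(x, "spectral_image")) {
    meta <- c(meta, list(kind = "spectral_image",
                         energies_keV = x$energies_keV))
    arr <- x$data
  } else {
    meta <- c(meta, list(kind = "array"))
    arr <- x
  }
  header <- jsonlite::toJSON(c(list(dims = dim(arr) %||% length(arr),
                                    type = storage.mode(arr)), meta),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  vals <- if (is.integer(arr)) format(as.vector(arr))
          else format(as.vector(arr), digits = 17, scientific = TRUE,
                      trim = TRUE)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!grepl("\\.svtx$", path))
    stop("unknown volume extension (expected .svtx): ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("truncated volume file: ", path, call. = FALSE)
  meta <- tryCatch(jsonlite::fromJSON(lines[1]),
                   error = function(e)
                     stop("corrupt volume header in ", path, call. = FALSE))
  vals <- scan(text = lines[2], what = double(), quiet = TRUE)
  if (length(vals) != prod(meta$dims))
    stop("truncated volume data in ", path, " (expected ", prod(meta$dims),
         " values, found ", length(vals), ")", call. = FALSE)
  arr <- array(vals, dim = meta$dims)
  if (identical(meta$type, "integer")) storage.mode(arr) <- "integer"
  switch(meta$kind %||% "array",
    tissue_phantom = tissue_phantom(arr, unlist(meta$tissue_table),
                                    spacing = meta$spacing),
    spectral_image = spectral_image(arr, meta$energies_keV),
    arr)
}

#' Write a lesion-cohort manifest as CSV
#' @param cohort a [make_lesion_cohort()] result.
#' @param path csv path.
#' @param volume_dir if non-NULL, also write every lesion volume there as
#'   `.svtx` and record the paths.
#' @export
write_cohort_manifest <- function(cohort, path, volume_dir = NULL) {
  man <- cohort$manifest
  if (!is.null(volume_dir)) {
    dir.create(volume_dir, showWarnings = FALSE, recursive = TRUE)
    man$path <- vapply(cohort$samples, function(s) {
      p <- file.path(volume_dir, paste0(s$id, ".svtx"))
      write_volume(s$volume, p, meta = list(label = s$label,
                                            size_mm = s$size_mm))
      p
    }, "")
  }
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Write / read MRF weights as JSON
#' @param weights an [mrf_weight_set()].
#' @param path json path.
#' @export
write_mrf_weights <- function(weights, path) {
  # kernels stored flat (column-major) to keep the JSON schema unambiguous
  payload <- list(window = weights$window, tissues = weights$tissues,
                  energies_keV = weights$energies_keV,
                  kernels = lapply(weights$weights, function(chs)
                    lapply(chs, as.vector)))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname write_mrf_weights
#' @export
read_mrf_weights <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  w <- as.integer(p$window[[1]])
  kernels <- lapply(p$kernels, function(chs)
    lapply(chs, function(k) matrix(unlist(k), w, w)))
  mrf_weight_set(kernels, w, unlist(p$tissues),
                 unlist(p$energies_keV))
}
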