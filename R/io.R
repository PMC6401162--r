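# TIFF + sidecar-JSON persistence. Intensities go to 16-bit TIFF; complex
# fields go to paired 32-bit float pages (Re, Im), each page affine-mapped
# to [0, 1] with the offset/scale recorded in the sidecar so the round trip
# is lossless to float32 precision.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a hologram frame as 16-bit TIFF with a JSON geometry sidecar
#'
#' @param holo a [hologram_frame()].
#' @param path output TIFF path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_hologram_tiff <- function(holo, path) {
  stopifnot(inherits(holo, "hologram_frame"))
  mx <- max(holo$intensity)
  tiff::writeTIFF(holo$intensity / mx, path, bits.per.sample = 16)
  jsonlite::write_json(list(
    type = "hologram", scale = mx, preprocessed = holo$preprocessed,
    geometry = holo$geometry[c("wavelength", "pixel_pitch", "z2",
                               "medium_index")]),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hologram frame written by [write_hologram_tiff()]
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return a [hologram_frame()].
#' @export
read_hologram_tiff <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  g <- do.call(optical_geometry, as.list(meta$geometry))
  hologram_frame(img * meta$scale, g, preprocessed = isTRUE(meta$preprocessed))
}

.encode01 <- function(m) {
  lo <- min(m); hi <- max(m)
  sc <- if (hi > lo) hi - lo else 1
  list(page = (m - lo) / sc, offset = lo, scale = sc)
}

#' Write a field stack as a multi-page TIFF with a JSON sidecar
#'
#' Complex planes become interleaved Re/Im float pages; RGB planes become one
#' RGB page each. Page offsets/scales, the z list, pitch and modality go to
#' the sidecar.
#'
#' @param stack a [field_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "field_stack"))
  cplx <- is.complex(stack$planes[[1]])
  pages <- list(); offsets <- numeric(0); scales <- numeric(0)
  for (p in stack$planes) {
    if (cplx) {
      er <- .encode01(Re(p)); ei <- .encode01(Im(p))
      pages <- c(pages, list(er$page, ei$page))
      offsets <- c(offsets, er$offset, ei$offset)
      scales <- c(scales, er$scale, ei$scale)
    } else {
      ep <- .encode01(p)
      pages <- c(pages, list(ep$page))
      offsets <- c(offsets, ep$offset)
      scales <- c(scales, ep$scale)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(
    type = "field_stack", complex = cplx, z_list = stack$z_list,
    pitch = stack$pitch, modality = stack$modality,
    wavelength = stack$wavelength,
    page_offsets = offsets, page_scales = scales),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field stack written by [write_field_stack_tiff()]
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return a [field_stack()].
#' @export
read_field_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dec <- function(k) pages[[k]] * meta$page_scales[k] + meta$page_offsets[k]
  planes <- list()
  if (isTRUE(meta$complex)) {
    for (k in seq_len(length(pages) / 2))
      planes[[k]] <- dec(2 * k - 1) + 1i * dec(2 * k)
  } else {
    planes <- lapply(seq_along(pages), dec)
  }
  field_stack(planes, meta$z_list, meta$pitch, meta$modality,
              wavelength = meta$wavelength)
}

#' Write a paired-patch dataset to a directory
#'
#' Layout: `pairs/{split}/{id}_input.tif` (Re/Im float pages),
#' `{id}_target.tif` (RGB), plus `manifest.csv` recording every patch.
#'
#' @param dataset a [build_paired_dataset()] result.
#' @param dir output directory (created).
#' @return the manifest data.frame, invisibly.
#' @export
write_pairs_dataset <- function(dataset, dir) {
  rows <- list()
  for (sp in c("train", "val", "test")) {
    spdir <- file.path(dir, "pairs", sp)
    dir.create(spdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(dataset[[sp]])) {
      pr <- dataset[[sp]][[i]]
      id <- sprintf("%s_%04d", sp, i)
      er <- .encode01(Re(pr$input)); ei <- .encode01(Im(pr$input))
      in_path <- file.path(spdir, paste0(id, "_input.tif"))
      tiff::writeTIFF(list(er$page, ei$page), in_path, bits.per.sample = 32)
      jsonlite::write_json(list(page_offsets = c(er$offset, ei$offset),
                                page_scales = c(er$scale, ei$scale)),
                           .sidecar_path(in_path), auto_unbox = TRUE,
                           digits = NA)
      tiff::writeTIFF(pr$target, file.path(spdir, paste0(id, "_target.tif")),
                      bits.per.sample = 16)
      rows[[length(rows) + 1]] <- data.frame(
        id = id, split = sp, phantom_id = pr$phantom_id %||% NA_integer_,
        z = pr$z, row = pr$row %||% NA_integer_, col = pr$col %||% NA_integer_)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a paired-patch dataset written by [write_pairs_dataset()]
#'
#' @param dir dataset directory.
#' @return a list with `train`, `val`, `test` pair lists and the `manifest`.
#' @export
read_pairs_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  out <- list(train = list(), val = list(), test = list())
  for (r in seq_len(nrow(manifest))) {
    sp <- manifest$split[r]; id <- manifest$id[r]
    in_path <- file.path(dir, "pairs", sp, paste0(id, "_input.tif"))
    meta <- jsonlite::read_json(.sidecar_path(in_path),
                                simplifyVector = TRUE)
    pages <- tiff::readTIFF(in_path, all = TRUE)
    inp <- (pages[[1]] * meta$page_scales[1] + meta$page_offsets[1]) +
      1i * (pages[[2]] * meta$page_scales[2] + meta$page_offsets[2])
    tgt <- tiff::readTIFF(file.path(dir, "pairs", sp,
                                    paste0(id, "_target.tif")))
    out[[sp]][[length(out[[sp]]) + 1]] <-
      list(input = inp, target = tgt, z = manifest$z[r],
           phantom_id = manifest$phantom_id[r])
  }
  out$manifest <- manifest
  out
}

#' Save / load a trained model
#'
#' Weights as a serialized single file plus a JSON config and a CSV training
#' history alongside.
#'
#' @param model a `brightfield_gan`.
#' @param path output path for the weights file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "brightfield_gan"))
  saveRDS(model, path)
  jsonlite::write_json(list(gen_cfg = unclass(model$gen_cfg),
                            disc_cfg = unclass(model$disc_cfg),
                            train_cfg = unclass(model$train_cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$history$validation,
                   paste0(path, ".history.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
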