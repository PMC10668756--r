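#' Segmentation project
#'
#' A project groups images with their per-comet segmentations. Each comet
#' entry carries its boundary contours (simple closed polygons in 0-based
#' pixel coordinates, closed implicitly last-to-first), an exact
#' run-length encoding of its head and tail masks, and a manual-edit flag.
#' Comets flagged as manual are never overwritten when automatic
#' segmentation is re-applied.
#'
#' @param config optional named list recorded verbatim in the project (a
#'   snapshot of the segmentation configuration).
#' @return An object of class `comet_project`.
#' @seealso [save_project()], [load_project()], [project_set_segmentation()]
#' @export
new_project <- function(config = list()) {
  structure(
    list(schema_version = PROJECT_SCHEMA_VERSION,
         package_version = as.character(utils::packageVersion("cometseg")),
         images = list(), comets = list(), config = config),
    class = "comet_project"
  )
}

PROJECT_SCHEMA_VERSION <- 1L

#' @export
print.comet_project <- function(x, ...) {
  ncomet <- sum(vapply(x$comets, length, 0L))
  cat(sprintf("<comet_project> schema v%d: %d image(s), %d comet(s)\n",
              x$schema_version, length(x$images), ncomet))
  invisible(x)
}

#' Register an image in a project
#'
#' Records the path, an MD5 checksum and the pixel dimensions.
#'
#' @param project a [new_project()] object.
#' @param path image file path (must exist; checksummed).
#' @param id image identifier; defaults to the file name.
#' @return The updated project.
#' @export
project_add_image <- function(project, path, id = basename(path)) {
  stopifnot(inherits(project, "comet_project"))
  img <- read_image(path)
  project$images[[id]] <- list(id = id, path = path,
                               md5 = unname(tools::md5sum(path)),
                               width = img$width, height = img$height)
  if (is.null(project$comets[[id]])) project$comets[[id]] <- list()
  project
}

seg_to_comet_entry <- function(seg, comet_id) {
  list(id = comet_id,
       head_contour = mask_to_contour(seg$head),
       tail_contour = mask_to_contour(seg$tail),
       head_rle = mask_to_rle(seg$head),
       tail_rle = mask_to_rle(seg$tail),
       has_tail = isTRUE(seg$has_tail),
       accepted = isTRUE(seg$accepted),
       discard_reason = seg$discard_reason %||% "none",
       manual = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Store automatic segmentation results for an image
#'
#' Replaces the automatic comet entries of `image_id` with `segs`. Entries
#' whose `manual` flag is set survive re-segmentation untouched; new
#' automatic comets are appended after them.
#'
#' @param project a project; `image_id` must be registered.
#' @param image_id image identifier.
#' @param segs list of segmentations as returned by [segment_image()].
#' @return The updated project.
#' @export
project_set_segmentation <- function(project, image_id, segs) {
  stopifnot(inherits(project, "comet_project"))
  if (is.null(project$images[[image_id]])) {
    stop(sprintf("image '%s' is not registered in the project", image_id))
  }
  old <- project$comets[[image_id]] %||% list()
  kept <- Filter(function(e) isTRUE(e$manual), old)
  auto <- lapply(seq_along(segs), function(i) {
    seg_to_comet_entry(segs[[i]], comet_id = length(kept) + i)
  })
  project$comets[[image_id]] <- c(kept, auto)
  project
}

#' Manually replace a comet's contours
#'
#' Sets the head (and optionally tail) contour of one comet, rasterizes the
#' polygons to masks, and flags the entry as manual so later automatic
#' re-segmentation leaves it alone.
#'
#' @param project a project.
#' @param image_id image identifier.
#' @param comet_id index of the comet within that image's list.
#' @param head_contour n x 2 matrix of 0-based (x, y) vertices.
#' @param tail_contour optional n x 2 matrix; NULL clears the tail.
#' @return The updated project.
#' @export
project_edit_comet <- function(project, image_id, comet_id, head_contour,
                               tail_contour = NULL) {
  stopifnot(inherits(project, "comet_project"))
  info <- project$images[[image_id]]
  if (is.null(info)) stop(sprintf("image '%s' is not registered", image_id))
  entry <- project$comets[[image_id]][[comet_id]]
  if (is.null(entry)) stop(sprintf("no comet %s in image '%s'", comet_id, image_id))
  hmask <- polygon_to_mask(head_contour, info$height, info$width)
  tmask <- polygon_to_mask(tail_contour, info$height, info$width)
  tmask <- tmask & !hmask
  entry$head_contour <- head_contour
  entry$tail_contour <- if (is.null(tail_contour)) {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  } else tail_contour
  entry$head_rle <- mask_to_rle(hmask)
  entry$tail_rle <- mask_to_rle(tmask)
  entry$has_tail <- any(tmask)
  entry$manual <- TRUE
  project$comets[[image_id]][[comet_id]] <- entry
  project
}

contour_to_json <- function(ct) {
  if (is.null(ct) || nrow(ct) == 0) return(list())
  unname(lapply(seq_len(nrow(ct)), function(i) c(ct[i, 1], ct[i, 2])))
}

json_to_contour <- function(lst) {
  if (!length(lst)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  m <- do.call(rbind, lapply(lst, function(p) as.numeric(unlist(p))))
  colnames(m) <- c("x", "y")
  m
}

#' Save / load a project as JSON
#'
#' The on-disk format is a single JSON document with a `schema_version`
#' field; contours, run-length masks, flags and the configuration snapshot
#' round-trip losslessly. Loading a document with a different schema version
#' raises an error of class `cometseg_version_error`.
#'
#' @param project a `comet_project`.
#' @param path destination / source file path.
#' @return `save_project` returns `path` invisibly; `load_project` returns
#'   the reconstructed `comet_project`.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "comet_project"))
  ser <- unclass(project)
  ser$config <- unclass(ser$config)
  ser$images <- unname(ser$images)
  ser$comets <- lapply(names(project$comets), function(id) {
    list(image_id = id,
         comets = unname(lapply(project$comets[[id]], function(e) {
           e$head_contour <- contour_to_json(e$head_contour)
           e$tail_contour <- contour_to_json(e$tail_contour)
           e
         })))
  })
  json <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
  atomic_write(json, path)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path), "cometseg_io_error")
  ser <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ver <- ser$schema_version
  if (is.null(ver) || ver != PROJECT_SCHEMA_VERSION) {
    stop(errorCondition(
      sprintf("project schema version %s not supported (expected %d)",
              ver %||% "<missing>", PROJECT_SCHEMA_VERSION),
      class = c("cometseg_version_error", "cometseg_error")))
  }
  project <- new_project(config = ser$config %||% list())
  project$package_version <- ser$package_version %||% NA_character_
  for (im in ser$images) {
    im$md5 <- im$md5 %||% NA_character_
    project$images[[im$id]] <- im
  }
  for (blk in ser$comets) {
    project$comets[[blk$image_id]] <- lapply(blk$comets, function(e) {
      e$head_contour <- json_to_contour(e$head_contour)
      e$tail_contour <- json_to_contour(e$tail_contour)
      e$head_rle <- lapply(e$head_rle, function(v) as.integer(unlist(v)))
      e$tail_rle <- lapply(e$tail_rle, function(v) as.integer(unlist(v)))
      e
    })
  }
  project
}

# write-then-rename so partially written files never replace good ones
atomic_write <- function(text, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(text, tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Reconstruct head/tail masks for a comet entry
#'
#' Uses the exact run-length encoding when present, falling back to
#' rasterizing the stored contours.
#'
#' @param entry one element of `project$comets[[image_id]]`.
#' @param height,width image dimensions (used for the contour fallback).
#' @return list with logical matrices `head` and `tail`.
#' @export
comet_entry_masks <- function(entry, height, width) {
  get1 <- function(rle, contour) {
    if (!is.null(rle) && !is.null(rle$nrow)) rle_to_mask(rle)
    else polygon_to_mask(contour, height, width)
  }
  list(head = get1(entry$head_rle, entry$head_contour),
       tail = get1(entry$tail_rle, entry$tail_contour))
}
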