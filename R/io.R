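#' Write a synthetic scene to an HDF5 container
#'
#' Layout mirrors the acquisition container used throughout the pipeline:
#' `/tiles/<i>/stack` (z-stack array), `/tiles/<i>/stage_xy` (nm),
#' `/details/<j>/image`, `/truth/<j>/mask` and `/truth/<j>/labels`.
#'
#' @param path output file path (overwritten).
#' @param tiles optional `tile_set`.
#' @param details optional list of detail-image matrices.
#' @param truth optional list of per-detail lists with `mask` (logical
#'   matrix) and `labels` (named character vector, e.g. condition and
#'   QC label).
#' @return `path`, invisibly.
#' @export
write_scene_h5 <- function(path, tiles = NULL, details = NULL, truth = NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (!is.null(tiles)) {
    rhdf5::h5createGroup(path, "tiles")
    rhdf5::h5write(tiles$pixel_size_nm, path, "tiles/pixel_size_nm")
    rhdf5::h5write(tiles$overlap_fraction, path, "tiles/overlap_fraction")
    for (i in seq_along(tiles$tiles)) {
      grp <- sprintf("tiles/%d", i)
      rhdf5::h5createGroup(path, grp)
      stack <- simplify2array(tiles$tiles[[i]]$planes)
      rhdf5::h5write(stack, path, paste0(grp, "/stack"))
      rhdf5::h5write(as.numeric(tiles$stage_xy[i, ]), path,
                     paste0(grp, "/stage_xy"))
    }
  }
  if (!is.null(details)) {
    rhdf5::h5createGroup(path, "details")
    for (j in seq_along(details)) {
      grp <- sprintf("details/%d", j)
      rhdf5::h5createGroup(path, grp)
      rhdf5::h5write(details[[j]], path, paste0(grp, "/image"))
    }
  }
  if (!is.null(truth)) {
    rhdf5::h5createGroup(path, "truth")
    for (j in seq_along(truth)) {
      grp <- sprintf("truth/%d", j)
      rhdf5::h5createGroup(path, grp)
      rhdf5::h5write(truth[[j]]$mask * 1L, path, paste0(grp, "/mask"))
      labs <- truth[[j]]$labels
      rhdf5::h5write(paste(names(labs), unname(labs), sep = "="),
                     path, paste0(grp, "/labels"))
    }
  }
  invisible(path)
}

#' Read a scene HDF5 container written by [write_scene_h5()]
#'
#' @param path HDF5 file path.
#' @return A list with `tiles` (`tile_set` or NULL), `details`, `truth`.
#' @export
read_scene_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  out <- list(tiles = NULL, details = NULL, truth = NULL)
  group_ids <- function(parent) {
    kids <- contents$name[contents$group == paste0("/", parent)]
    sort(as.integer(kids[grepl("^[0-9]+$", kids)]))
  }
  if (any(contents$name == "tiles" & contents$group == "/")) {
    ids <- group_ids("tiles")
    planes_of <- function(a) lapply(seq_len(dim(a)[3]), function(k) a[, , k])
    stacks <- list()
    stage <- matrix(0, length(ids), 2,
                    dimnames = list(NULL, c("x_nm", "y_nm")))
    for (i in seq_along(ids)) {
      a <- rhdf5::h5read(path, sprintf("tiles/%d/stack", ids[i]))
      stacks[[i]] <- image_stack(planes_of(a))
      stage[i, ] <- rhdf5::h5read(path, sprintf("tiles/%d/stage_xy", ids[i]))
    }
    out$tiles <- structure(
      list(tiles = stacks, stage_xy = stage,
           pixel_size_nm = as.numeric(rhdf5::h5read(path,
                                                    "tiles/pixel_size_nm")),
           overlap_fraction = as.numeric(rhdf5::h5read(path,
                                                       "tiles/overlap_fraction"))),
      class = "tile_set")
  }
  if (any(contents$name == "details" & contents$group == "/")) {
    out$details <- lapply(group_ids("details"), function(j) {
      as_mat(rhdf5::h5read(path, sprintf("details/%d/image", j)))
    })
  }
  if (any(contents$name == "truth" & contents$group == "/")) {
    out$truth <- lapply(group_ids("truth"), function(j) {
      kv <- rhdf5::h5read(path, sprintf("truth/%d/labels", j))
      kv <- strsplit(kv, "=", fixed = TRUE)
      list(mask = as_mat(rhdf5::h5read(path,
                                       sprintf("truth/%d/mask", j))) > 0,
           labels = stats::setNames(vapply(kv, `[`, "", 2),
                                    vapply(kv, `[`, "", 1)))
    })
  }
  out
}

#' Write a tile stack as a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the stack maximum (recorded in
#' the return value) since TIFF stores normalized floats here.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return The scale factor used, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  mx <- max(vapply(stack$planes, max, 1))
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(lapply(stack$planes, function(p) p / scale), path,
                  bits.per.sample = 16L)
  invisible(scale)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF path.
#' @param scale intensity scale factor to undo [write_stack_tiff()].
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, scale = 1) {
  planes <- tiff::readTIFF(path, all = TRUE)
  image_stack(lapply(planes, function(p) as_mat(p) * scale))
}
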