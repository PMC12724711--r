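#' Bioluminescence image stack
#'
#' A light container for a sequence of single-channel frames sharing one
#' pixel geometry: `frames` is a numeric array `[row, col, frame]`,
#' `timestamps` gives the acquisition time of each frame in hours from
#' recording start (strictly increasing, possibly uneven, e.g. the mixed
#' every-12-h-then-every-4-h gestational schedule), `roi_mask` is a logical
#' image marking the fixed abdominal region of interest and
#' `background_mask` a disjoint logical image used for background
#' subtraction. `zt0_offset` anchors Zeitgeber Time as for traces.
#'
#' @param frames numeric array `[row, col, frame]` (a list of matrices is
#'   also accepted).
#' @param timestamps hours, one per frame, strictly increasing.
#' @param roi_mask,background_mask logical matrices matching the frame
#'   shape; must not overlap.
#' @param zt0_offset hours from recording start to the reference lights-on.
#' @param meta list of labels.
#' @return an `image_stack` object.
#' @export
image_stack <- function(frames, timestamps, roi_mask = NULL,
                        background_mask = NULL, zt0_offset = 0, meta = list()) {
  if (is.list(frames)) {
    shp <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1)))) {
      stopf("all frames must share one shape")
    }
    frames <- array(unlist(frames), dim = c(shp, length(frames)))
  }
  if (length(dim(frames)) != 3) stopf("frames must be a [row, col, frame] array")
  if (dim(frames)[3] != length(timestamps)) {
    stopf("%d frames but %d timestamps", dim(frames)[3], length(timestamps))
  }
  if (any(diff(timestamps) <= 0)) stopf("frame timestamps must strictly increase")
  shp <- dim(frames)[1:2]
  chk_mask <- function(m, what) {
    if (!is.null(m)) {
      if (!identical(dim(m), as.integer(shp))) stopf("%s shape mismatch", what)
      storage.mode(m) <- "logical"
    }
    m
  }
  roi_mask <- chk_mask(roi_mask, "roi_mask")
  background_mask <- chk_mask(background_mask, "background_mask")
  if (!is.null(roi_mask) && !is.null(background_mask) &&
      any(roi_mask & background_mask)) {
    stopf("roi and background regions must be disjoint")
  }
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 roi_mask = roi_mask, background_mask = background_mask,
                 zt0_offset = zt0_offset, meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px, %d frames over %.1f h (ROI %s px)\n",
              d[1], d[2], d[3], diff(range(x$timestamps)),
              if (is.null(x$roi_mask)) "?" else sum(x$roi_mask)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Read and write image stacks (multi-frame TIFF + JSON sidecar)
#'
#' Frames are written as 32-bit float TIFF. Because float TIFF storage here
#' is defined on `[0, 1]`, frames are affinely rescaled on write and the
#' scale is recorded in the sidecar (`<path>.json`, which also carries
#' timestamps, the ZT reference and the masks), then undone on read; the
#' round trip is exact to 32-bit float precision.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `read_stack()` returns an [image_stack()].
#' @export
write_stack <- function(stack, path) {
  rng <- range(stack$frames)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- (stack$frames - rng[1]) / scale
  tiff::writeTIFF(lapply(seq_len(dim(norm)[3]), function(i) norm[, , i]),
                  path, bits.per.sample = 32, reduce = FALSE)
  side <- list(timestamps = stack$timestamps, zt0_offset = stack$zt0_offset,
               offset = rng[1], scale = scale, meta = stack$meta)
  if (!is.null(stack$roi_mask)) side$roi_mask <- which(stack$roi_mask) - 1L
  if (!is.null(stack$background_mask)) {
    side$background_mask <- which(stack$background_mask) - 1L
  }
  side$shape <- dim(stack$frames)[1:2]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fr <- tiff::readTIFF(path, all = TRUE)
  frames <- simplify2array(fr) * side$scale + side$offset
  shp <- as.integer(side$shape)
  unmask <- function(idx) {
    if (is.null(idx)) return(NULL)
    m <- matrix(FALSE, shp[1], shp[2]); m[idx + 1L] <- TRUE; m
  }
  image_stack(frames, side$timestamps, roi_mask = unmask(side$roi_mask),
              background_mask = unmask(side$background_mask),
              zt0_offset = side$zt0_offset,
              meta = as.list(side$meta %||% list()))
}
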