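# ---- field container, TIFF and manifest I/O ------------------------------

CHANNELS <- c("hoechst", "anion", "lysotracker", "pi")

#' Multi-channel image field
#'
#' A named list of single-channel integer matrices of equal dimensions
#' (channels `hoechst`, `anion`, `lysotracker`, `pi`; a channel may be
#' absent), plus the pixel size and free-form acquisition metadata
#' (field id, condition, culture age in hours, frame number).
#'
#' @param channels named list of numeric matrices.
#' @param pixel_size_um physical pixel size.
#' @param metadata list of acquisition metadata.
#' @export
image_field <- function(channels, pixel_size_um, metadata = list()) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  if (!length(channels) || is.null(names(channels)))
    stop("`channels` must be a named list")
  bad <- setdiff(names(channels), CHANNELS)
  if (length(bad))
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CHANNELS, collapse = "/"), ")")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L)
    stop("channel dimension mismatch across channels")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 metadata = metadata),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_field> %d x %d px @ %.3g um/px; channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Per-cell time-lapse trace
#'
#' @param cell_id identifier.
#' @param time_min increasing frame times in minutes.
#' @param pi_trace background-subtracted PI cell fluorescence per frame.
#' @param fba_trace FBA cell fluorescence per frame.
#' @param death_frame first frame meeting the death rule, or `NA`.
#' @export
timelapse_trace <- function(cell_id, time_min, pi_trace, fba_trace,
                            death_frame = NA_integer_) {
  if (length(time_min) == 0L) stop("empty trace")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("`time_min` must be strictly increasing")
  structure(list(cell_id = cell_id, time_min = time_min,
                 pi = pi_trace, fba = fba_trace,
                 death_frame = as.integer(death_frame)),
            class = "timelapse_trace")
}

# ---- 16-bit grayscale TIFF -----------------------------------------------

#' Write one channel as a 16-bit grayscale TIFF
#' @param image integer matrix with values in 0..65535.
#' @param path output file path.
#' @export
write_channel_tiff <- function(image, path) {
  v <- pmin(pmax(round(image), 0), 65535)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a single-plane grayscale TIFF into an integer matrix
#'
#' 8- and 16-bit inputs both load to plain integer counts on their native
#' scale (0..255 / 0..65535).
#' @param path file path.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  x <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != 1L) stop("not a single-plane grayscale TIFF: ", path)
    x <- x[, , 1L]
  }
  bits <- attr(x, "bits.per.sample") %||% 16L
  matrix(as.integer(round(x * (2^bits - 1))), nrow(x), ncol(x))
}

#' Write a field (all channels + manifest rows) to a directory
#'
#' Files are named `{field_id}_{channel}_{frame}.tif`; returns the manifest
#' rows describing them.
#' @param field an `image_field`.
#' @param dir output directory (created if missing).
#' @export
write_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- field$metadata
  fid <- md$field_id %||% "field1"
  frame <- md$frame %||% 1L
  rows <- lapply(names(field$channels), function(ch) {
    fn <- sprintf("%s_%s_%03d.tif", fid, ch, frame)
    write_channel_tiff(field$channels[[ch]], file.path(dir, fn))
    data.frame(field_id = fid, condition = md$condition %||% NA_character_,
               treatment = md$treatment %||% NA_character_,
               time_h = md$time_h %||% NA_real_, frame = frame,
               channel = ch, file_path = fn,
               pixel_size_um = field$pixel_size_um,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read one field/frame from manifest rows
#'
#' @param manifest_rows data frame with columns `field_id`, `frame`,
#'   `channel`, `file_path`, `pixel_size_um` and optional metadata columns,
#'   all describing a single field and frame.
#' @param dir directory that `file_path` entries are relative to.
#' @param require_channels channels that must be present (e.g. `"pi"` for a
#'   viability run).
#' @return an `image_field`.
#' @export
read_field <- function(manifest_rows, dir = ".",
                       require_channels = character()) {
  m <- manifest_rows
  if (length(unique(m$field_id)) != 1L || length(unique(m$frame)) != 1L)
    stop("manifest rows must describe a single field and frame")
  if (anyDuplicated(m$channel))
    stop("duplicate channel entries in manifest")
  missing_ch <- setdiff(require_channels, m$channel)
  if (length(missing_ch))
    stop("configuration error: required channel(s) missing from manifest: ",
         paste(missing_ch, collapse = ", "))
  channels <- lapply(seq_len(nrow(m)), function(i)
    read_channel_tiff(file.path(dir, m$file_path[i])))
  names(channels) <- m$channel
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("channel dimension mismatch across channels")
  image_field(channels, m$pixel_size_um[1L],
              metadata = list(field_id = m$field_id[1L],
                              condition = m$condition[1L] %||% NA,
                              time_h = m$time_h[1L] %||% NA,
                              frame = m$frame[1L]))
}

#' Write a label map as 16-bit TIFF
#' @param labels integer matrix of labels.
#' @param path output path.
#' @export
write_label_tiff <- function(labels, path) {
  write_channel_tiff(labels, path)
}
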