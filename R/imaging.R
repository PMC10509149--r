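## Raw-image plumbing: encode absorbance records as a 16-bit grayscale
## frame sequence (each fibre a horizontal row band whose mean intensity is
## I = I0 10^-A) and recover absorbance from such a stack. Stacks live in
## memory as integer arrays (frames x rows x columns); a multi-page TIFF
## export is available when the tiff package is installed.

#' Render an image stack from absorbance records
#'
#' @param records An `absorbance_records` data frame on a common time grid.
#' @param acq An `acquisition_spec` (binning halves the spatial
#'   dimensions).
#' @param I0 Source intensity in counts (default 48000, inside the 16-bit
#'   range); intensities above 65535 are clipped with a warning.
#' @param band_px Rows per fibre band at binning 1 (default 8).
#' @param width_px Frame width at binning 1 (default 64).
#' @return List with `stack` (integer array frames x rows x cols) and
#'   `sidecar`: the band-to-fibre map plus acquisition metadata, as written
#'   to JSON alongside exported stacks.
#' @export
render_image_stack <- function(records, acq = acquisition_spec(),
                               I0 = 48000, band_px = 8, width_px = 64) {
  stopifnot(inherits(records, "data.frame"))
  fibres <- sort(unique(records$fibre), decreasing = TRUE)
  times <- sort(unique(records$time_s))
  A <- matrix(NA_real_, length(fibres), length(times))
  idx <- cbind(match(records$fibre, fibres), match(records$time_s, times))
  A[idx] <- records$absorbance
  if (anyNA(A)) stop("records are not on a common time grid")

  bp <- band_px / acq$binning
  wp <- width_px / acq$binning
  nrow_img <- bp * length(fibres)
  I <- I0 * 10^(-A)
  if (any(I > 65535)) {
    warning("intensity overflow; clipping to 65535")
    I[I > 65535] <- 65535
  }
  stack <- array(0L, dim = c(length(times), nrow_img, wp))
  for (k in seq_along(fibres)) {
    rows <- ((k - 1) * bp + 1):(k * bp)
    for (j in seq_along(times))
      stack[j, rows, ] <- as.integer(round(I[k, j]))
  }
  bands <- data.frame(fibre = fibres,
                      row_lo = (seq_along(fibres) - 1) * bp + 1,
                      row_hi = seq_along(fibres) * bp)
  sidecar <- list(bands = bands, times = times, I0 = I0,
                  frame_period = attr(records, "frame_period"),
                  beam_on_time = attr(records, "beam_on_time"),
                  binning = acq$binning)
  list(stack = stack, sidecar = sidecar)
}

#' Extract absorbance records from an image stack
#'
#' Per fibre band, A(t) = -log10(I(t) / <I_pre>) where <I_pre> is the mean
#' band intensity over the frames before the beam-on time recorded in the
#' sidecar. Requires pre-beam frames (or an explicit `I0`).
#'
#' @param stack Integer array (frames x rows x cols).
#' @param sidecar Sidecar list as produced by [render_image_stack()] (or
#'   read back from JSON).
#' @param I0 Optional explicit reference intensity, overriding the
#'   pre-beam baseline.
#' @return An `absorbance_records` data frame.
#' @export
extract_absorbance <- function(stack, sidecar, I0 = NULL) {
  stopifnot(length(dim(stack)) == 3, !is.null(sidecar$bands))
  times <- sidecar$times
  bands <- as.data.frame(sidecar$bands)
  t0 <- sidecar$beam_on_time
  pre <- which(times < t0)
  if (is.null(I0) && length(pre) == 0)
    stop("no pre-beam frames in stack; supply an explicit I0")
  recs <- lapply(seq_len(nrow(bands)), function(k) {
    rows <- bands$row_lo[k]:bands$row_hi[k]
    I_t <- vapply(seq_along(times),
                  function(j) mean(stack[j, rows, ]), numeric(1))
    ref <- if (is.null(I0)) mean(I_t[pre]) else I0
    data.frame(fibre = bands$fibre[k], time_s = times,
               absorbance = -log10(I_t / ref))
  })
  out <- do.call(rbind, recs)
  structure(out, class = c("absorbance_records", "data.frame"),
            frame_period = sidecar$frame_period,
            beam_on_time = t0)
}

#' Export / import an image stack as multi-page TIFF plus JSON sidecar
#'
#' Requires the tiff package. The stack is written as 16-bit grayscale
#' pages; the sidecar (band map, times, reference intensity) as
#' `<path>.json`.
#'
#' @param x Output of [render_image_stack()].
#' @param path TIFF path.
#' @export
write_image_stack <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write TIFF stacks")
  pages <- lapply(seq_len(dim(x$stack)[1]),
                  function(j) x$stack[j, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(x$sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0L, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (j in seq_along(pages))
    stack[j, , ] <- as.integer(round(pages[[j]] * 65535))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(stack = stack, sidecar = sidecar)
}
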