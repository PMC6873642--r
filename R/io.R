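# Readers and writers for the on-disk formats: single-channel PNG (8/16-bit)
# and TIFF (16-bit or float32) images, fibre layout and signal CSVs, metric
# report CSVs, study directories and generator checkpoints.

#' Read a grayscale image into an ImageFrame
#'
#' PNG and TIFF are supported; multi-channel images are averaged to one
#' channel. Values are returned as floats in \code{[0, 1]}.
#'
#' @param path file path ending in \code{.png}, \code{.tif} or \code{.tiff}.
#' @param role role tag for the returned frame.
#' @return an \linkS4class{ImageFrame}.
#' @export
readImageFrame <- function(path, role = "") {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension '.", ext, "' (use png/tif/tiff)")
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  ImageFrame(img, role = role)
}

#' Write an ImageFrame to disk
#'
#' PNG is written at 8 bits, TIFF at 8/16 bits or as float32
#' (\code{bits = 32}, near-exact round-trip). Values must already be in
#' \code{[0, 1]}.
#'
#' @param frame \linkS4class{ImageFrame} or matrix.
#' @param path output path; the extension selects the format.
#' @param bits TIFF only: 8, 16 or 32 (float32).
#' @return the path, invisibly.
#' @export
writeImageFrame <- function(frame, path, bits = 16) {
  m <- .fd(frame)
  if (min(m) < 0 || max(m) > 1)
    stop("frame values must be in [0, 1] before writing")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    stopifnot(bits %in% c(8, 16, 32))
    tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported image extension '.", ext, "' (use png/tif/tiff)")
  }
  invisible(path)
}

#' Fibre layout CSV round-trip
#'
#' Layout CSVs have the header \code{fibre_id,x,y} with 0-based ids and
#' floating-point coordinates in pixel units. The FOV is stored in a comment
#' header line \code{# fov <cx> <cy> <radius>}.
#'
#' @param layout a \linkS4class{FibreLayout}.
#' @param path CSV path.
#' @return \code{writeFibreLayout}: the path, invisibly;
#'   \code{readFibreLayout}: a \linkS4class{FibreLayout}.
#' @export
writeFibreLayout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fov %.17g %.17g %.17g", fovCenter(layout)[1],
                     fovCenter(layout)[2], fovRadius(layout)), con)
  p <- positions(layout)
  df <- data.frame(fibre_id = seq_len(nrow(p)) - 1L, x = p[, 1], y = p[, 2])
  write.csv(format(df, digits = 17, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname writeFibreLayout
#' @export
readFibreLayout <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# fov "))
    stop("missing '# fov' header in layout file ", path)
  fov <- as.numeric(strsplit(trimws(sub("# fov", "", hdr)), " +")[[1]])
  df <- read.csv(path, comment.char = "#")
  FibreLayout(cbind(df$x, df$y), fovCenter = fov[1:2], fovRadius = fov[3])
}

#' Signal vector CSV round-trip
#'
#' Signal CSVs have the header \code{fibre_id,signal} (0-based ids); the
#' padded length and normalization flag travel in comment header lines.
#'
#' @param signals a \linkS4class{FibreSignalVector}.
#' @param path CSV path.
#' @return \code{writeSignalVector}: the path, invisibly;
#'   \code{readSignalVector}: a \linkS4class{FibreSignalVector}.
#' @export
writeSignalVector <- function(signals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# padded_length %d normalized %d",
                     paddedLength(signals), as.integer(isNormalized(signals))),
             con)
  n <- nFibres(signals)
  df <- data.frame(fibre_id = fibreIds(signals),
                   signal = signalValues(signals)[seq_len(n)])
  write.csv(format(df, digits = 17, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname writeSignalVector
#' @export
readSignalVector <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# padded_length "))
    stop("missing '# padded_length' header in signal file ", path)
  meta <- as.integer(strsplit(trimws(hdr), " +")[[1]][c(3, 5)])
  df <- read.csv(path, comment.char = "#")
  FibreSignalVector(df$signal, paddedLength = meta[1],
                    normalized = meta[2] == 1L, fibreIds = df$fibre_id)
}

#' Write a metrics report CSV
#'
#' Per-image rows under the header
#' \code{image_id,ssim_hr,dgcf_hr,dgcf_lr,tot_cs}, followed by an aggregate
#' footer block (\code{mean ± sd}, 2 decimal places) mirroring the standard
#' results-table formatting.
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write.csv(reportRows(report), con, row.names = FALSE, quote = FALSE)
  ag <- reportAggregates(report)
  writeLines("# aggregates", con)
  for (i in seq_len(nrow(ag)))
    writeLines(sprintf("# %s %.2f ± %.2f", ag$metric[i], ag$mean[i],
                       ag$sd[i]), con)
  invisible(path)
}

#' Generator checkpoint round-trip
#'
#' Checkpoints serialize the generator parameters together with its
#' architecture spec, the training-config snapshot and \code{N_F}, so
#' inference is fully reproducible from the file alone.
#'
#' @param generator a generator handle.
#' @param path checkpoint path (\code{.rds}).
#' @param config optional [trainingConfig()] snapshot.
#' @param NF optional padded vector length used in training.
#' @return \code{writeCheckpoint}: the path, invisibly;
#'   \code{readCheckpoint}: list with \code{generator}, \code{config},
#'   \code{NF}.
#' @export
writeCheckpoint <- function(generator, path, config = NULL, NF = NULL) {
  stopifnot(inherits(generator, "srGenerator"))
  saveRDS(list(spec = generator$spec, params = generator$params,
               config = config, NF = NF), path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  ck <- readRDS(path)
  gen <- structure(list(spec = ck$spec, params = ck$params,
                        ctxCache = new.env()),
                   class = "srGenerator")
  list(generator = gen, config = ck$config, NF = ck$NF)
}

#' Write a synthetic study to a directory
#'
#' Materializes a study as \code{hr/}, \code{lr/} (16-bit PNG),
#' \code{signals/} (CSV), \code{layout.csv} and \code{metadata.csv}.
#'
#' @param study a \code{fibreStudy} from [generateStudy()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  for (d in file.path(dir, c("hr", "lr", "signals")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (fid in names(study$hr)) {
    writeImageFrame(study$hr[[fid]], file.path(dir, "hr",
                                               paste0(fid, ".png")))
    # noisy fibre signals can push reconstructed values slightly above 1;
    # writing saturates them, as a real detector would
    writeImageFrame(clamp(frameData(study$lr[[fid]]), 0, 1),
                    file.path(dir, "lr", paste0(fid, ".png")))
    writeSignalVector(study$signals[[fid]],
                      file.path(dir, "signals", paste0(fid, ".csv")))
  }
  writeFibreLayout(study$layout, file.path(dir, "layout.csv"))
  write.csv(study$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
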