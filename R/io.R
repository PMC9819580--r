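## Dataset and image I/O.
##
## Paired datasets travel as HDF5 files with layout /pairs/input and
## /pairs/target (N x depth x lateral, float32) plus attributes fraction,
## dynamic_range_db, seed.  R has no HDF5 binding in this stack, so the
## reading/writing is delegated to a bundled python helper (h5py), with
## pixels exchanged as raw little-endian float32.

h5bridge <- function() {
  p <- system.file("python", "h5bridge.py", package = "usbwx")
  if (p == "") stop("h5bridge.py not found in the installed package")
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("no python interpreter on PATH (needed for HDF5 I/O)")
  list(py = py, script = p)
}

run_bridge <- function(args) {
  b <- h5bridge()
  out <- suppressWarnings(system2(b$py, c(shQuote(b$script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("HDF5 bridge failed: ", paste(out, collapse = "\n"))
  invisible(out)
}

#' Write a paired dataset to HDF5
#'
#' Layout: `/pairs/input`, `/pairs/target` (N x depth x lateral, float32),
#' attributes `fraction`, `dynamic_range_db`, `seed`.
#'
#' @param pairs a `paired_dataset`.
#' @param path output `.h5` path.
#' @param seed optional provenance seed stored as an attribute.
#' @export
write_paired_h5 <- function(pairs, path, seed = NULL) {
  stopifnot(inherits(pairs, "paired_dataset"))
  if (!dir.exists(dirname(path)) && nzchar(dirname(path)))
    dir.create(dirname(path), recursive = TRUE)
  d <- dim(pairs$input)                     # H, W, N
  td <- tempfile(); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  inbin <- file.path(td, "in.bin"); tgtbin <- file.path(td, "tgt.bin")
  meta <- file.path(td, "meta.json")
  # (N, H, W) C-order on the python side == R array (W, H, N) column-major
  wr <- function(a, f) {
    con <- file(f, "wb")
    writeBin(as.numeric(aperm(a, c(2, 1, 3))), con, size = 4, endian = "little")
    close(con)
  }
  wr(pairs$input, inbin); wr(pairs$target, tgtbin)
  jsonlite::write_json(list(shape = c(d[3], d[1], d[2]),
                            fraction = pairs$fraction,
                            dynamic_range_db = pairs$dynamic_range_db,
                            seed = seed),
                       meta, auto_unbox = TRUE, null = "null")
  run_bridge(c("write", shQuote(path), shQuote(inbin), shQuote(tgtbin),
               shQuote(meta)))
  invisible(path)
}

#' Read a paired dataset from HDF5
#'
#' @param path `.h5` file with the layout written by [write_paired_h5()].
#' @return a `paired_dataset`.
#' @export
read_paired_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  td <- tempfile(); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  inbin <- file.path(td, "in.bin"); tgtbin <- file.path(td, "tgt.bin")
  meta <- file.path(td, "meta.json")
  run_bridge(c("read", shQuote(path), shQuote(inbin), shQuote(tgtbin),
               shQuote(meta)))
  m <- jsonlite::read_json(meta, simplifyVector = TRUE)
  sh <- m$shape                              # (N, H, W)
  rd <- function(f) {
    con <- file(f, "rb")
    v <- readBin(con, "numeric", n = prod(sh), size = 4, endian = "little")
    close(con)
    aperm(array(v, c(sh[3], sh[2], sh[1])), c(2, 1, 3))
  }
  structure(list(input = rd(inbin), target = rd(tgtbin),
                 fraction = if (!is.null(m$fraction)) m$fraction else NA_real_,
                 dynamic_range_db = if (!is.null(m$dynamic_range_db))
                   m$dynamic_range_db else NA_real_),
            class = "paired_dataset")
}

#' Probe an HDF5 paired dataset without loading pixels
#'
#' @param path `.h5` file.
#' @return list with `n_images`, `shape` (depth, lateral) and attributes.
#' @export
probe_paired_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- tempfile(fileext = ".json")
  on.exit(unlink(meta), add = TRUE)
  run_bridge(c("probe", shQuote(path), shQuote(meta)))
  m <- jsonlite::read_json(meta, simplifyVector = TRUE)
  list(n_images = m$shape[1], shape = m$shape[2:3],
       fraction = m$fraction, dynamic_range_db = m$dynamic_range_db)
}

#' Export B-mode images to PNG or float TIFF
#'
#' PNG quantizes with the round-half-up convention `round(p * 255)`; float
#' TIFF is lossless.
#'
#' @param images matrix, `bmode_image`, or H x W x N array in `[0,1]`.
#' @param dir output directory (created if missing).
#' @param format `"png8"` or `"tiff_float"`.
#' @param prefix file-name prefix.
#' @return character vector of files written.
#' @export
export_images <- function(images, dir, format = c("png8", "tiff_float"),
                          prefix = "image") {
  format <- match.arg(format)
  x <- if (inherits(images, "bmode_image")) images$pixels else images
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (min(x) < 0 || max(x) > 1)
    stop("pixels outside [0,1]: refusing to clip silently")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(dim(x)[3])
  for (i in seq_len(dim(x)[3])) {
    img <- x[, , i]
    if (format == "png8") {
      files[i] <- file.path(dir, sprintf("%s_%03d.png", prefix, i))
      # round half up (floor(v + 0.5)), then back to [0,1] for png::writePNG
      png::writePNG(floor(img * 255 + 0.5) / 255, files[i])
    } else {
      files[i] <- file.path(dir, sprintf("%s_%03d.tiff", prefix, i))
      tiff::writeTIFF(img, files[i], bits.per.sample = 32L)
    }
  }
  files
}

#' Split image indices into train/validation/test sets
#'
#' The 60/20/20 convention; explicit counts override the proportional split
#' (useful when the total does not divide evenly).
#'
#' @param n total number of images.
#' @param counts optional `c(train, val, test)` overriding the 60/20/20.
#' @param seed shuffling seed.
#' @return list with `train`, `val`, `test` index vectors.
#' @export
split_dataset <- function(n, counts = NULL, seed = 1L) {
  if (is.null(counts)) {
    tr <- round(0.6 * n); va <- round(0.2 * n)
    counts <- c(tr, va, n - tr - va)
  }
  if (sum(counts) > n) stop("split counts exceed n")
  set.seed(seed)
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(counts[1])]),
       val = sort(idx[counts[1] + seq_len(counts[2])]),
       test = sort(idx[counts[1] + counts[2] + seq_len(counts[3])]))
}

#' Read / write a run configuration (YAML)
#'
#' Every pipeline run can snapshot its configuration next to its outputs so
#' results are reproducible from the file + seed alone.
#'
#' @param config named list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
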