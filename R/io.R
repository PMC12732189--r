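#' Construct a frame stack
#'
#' A `frame_stack` is the package's unit of data: one fluoroscopy clip stored
#' as a `T x H x W` array of grayscale intensities (optionally `T x H x W x C`
#' before channel reduction), together with its frame rate, subject identifier,
#' study-level label and provenance.
#'
#' @param frames numeric array with dimensions `T x H x W` (or `T x H x W x C`
#'   for multi-channel sources prior to [reduce_channels()]).
#' @param fps frames per second (default 25, the usual fluoroscopy frame rate).
#' @param subject_id subject identifier string.
#' @param label one of `"normal"`, `"abnormal"`, `"unlabeled"`.
#' @param source_path provenance string (file path or `"synthetic"`).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 25, subject_id = NA_character_,
                        label = c("unlabeled", "normal", "abnormal"),
                        source_path = NA_character_) {
  label <- match.arg(label)
  if (!is.array(frames) || !(length(dim(frames)) %in% c(3L, 4L))) {
    stop("`frames` must be a T x H x W (or T x H x W x C) array")
  }
  d <- dim(frames)
  if (any(d[1:3] < 1L)) stop("frame stack dimensions must be positive")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  structure(
    list(frames = frames, fps = fps, subject_id = as.character(subject_id),
         label = label, source_path = as.character(source_path)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames, %d x %d px%s, fps %s, subject %s, label %s\n",
              d[1], d[2], d[3],
              if (length(d) == 4L) sprintf(", %d channels", d[4]) else "",
              format(x$fps), x$subject_id, x$label))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[1]

# Replace pixel data, keeping metadata.
set_frames <- function(stack, frames) {
  stack$frames <- frames
  stack
}

infer_format <- function(path, format_hint = NULL) {
  if (!is.null(format_hint) && format_hint != "auto") return(format_hint)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff",
         npz = "npz",
         npy = "npy",
         avi = , mp4 = "video",
         dcm = , dicom = "dicom",
         stop(sprintf("cannot infer video format from extension '%s' (%s)", ext, path)))
}

#' Read a clip into a frame stack
#'
#' Supported containers are multi-page TIFF and NumPy `.npy`/`.npz` stacks.
#' Compressed video (AVI/MP4) and DICOM multiframe are recognized but require
#' decoders that this package does not bundle; they raise an informative error
#' suggesting conversion to a lossless container.
#'
#' @param path file path.
#' @param format_hint one of `"auto"`, `"tiff"`, `"npy"`, `"npz"`.
#' @param fps,subject_id,label metadata attached to the returned stack.
#' @return a [frame_stack()].
#' @export
read_stack <- function(path, format_hint = "auto", fps = 25,
                       subject_id = NA_character_, label = "unlabeled") {
  if (!file.exists(path)) stop(sprintf("cannot read clip: file '%s' does not exist", path))
  fmt <- infer_format(path, format_hint)
  frames <- switch(fmt,
    tiff = read_tiff_stack(path),
    npy = read_npy(path),
    npz = read_npz_first(path),
    video = stop(sprintf(
      "'%s': compressed video (AVI/MP4) decoding is not available; convert the clip to multi-page TIFF or NPZ first", path)),
    dicom = stop(sprintf(
      "'%s': DICOM multiframe support requires an external converter; export the frames to multi-page TIFF or NPZ", path)),
    stop(sprintf("unsupported format '%s' for '%s'", fmt, path)))
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  if (dim(frames)[1] < 1L) stop(sprintf("'%s' contains zero frames", path))
  frame_stack(frames, fps = fps, subject_id = subject_id, label = label,
              source_path = path)
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop(sprintf("'%s' contains zero frames", path))
  nd <- length(dim(pages[[1]]))
  if (nd == 2L) {
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  } else {
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (t in seq_along(pages)) arr[t, , , ] <- pages[[t]]
  }
  arr
}

#' Write a frame stack
#'
#' Lossless writers: multi-page TIFF (16-bit, intensities clipped to
#' quantization), `.npy` (float64, bit-exact) and `.npz`.
#'
#' @param stack a [frame_stack()].
#' @param path output path; the extension selects the container.
#' @param bits TIFF bit depth (8 or 16).
#' @export
write_stack <- function(stack, path, bits = 16L) {
  fmt <- infer_format(path)
  frames <- stack$frames
  if (fmt == "tiff") {
    if (length(dim(frames)) != 3L) stop("TIFF writer expects single-channel frames")
    pages <- lapply(seq_len(dim(frames)[1]), function(t) clamp01(frames[t, , ]))
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  } else if (fmt == "npy") {
    write_npy(frames, path)
  } else if (fmt == "npz") {
    write_npz(list(frames = frames), path)
  } else {
    stop(sprintf("unsupported output format for '%s'", path))
  }
  invisible(path)
}

#' Reduce a multi-channel stack to its first channel
#'
#' Fluoroscopy recordings exported as RGB carry duplicated chroma channels;
#' only the first (brightness) channel is retained.
#'
#' @param stack a [frame_stack()] with 1 or 3 channels.
#' @return a single-channel [frame_stack()].
#' @export
reduce_channels <- function(stack) {
  d <- dim(stack$frames)
  if (length(d) == 3L) return(stack)
  nc <- d[4]
  if (!nc %in% c(1L, 3L)) {
    stop(sprintf("expected 1 or 3 channels, got %d", nc))
  }
  set_frames(stack, array(stack$frames[, , , 1L], d[1:3]))
}

#' Clip eligibility rules
#'
#' Clips shorter than `min_frames` frames are unlikely to span a complete
#' swallow (about one second at 25 fps) and are excluded; very narrow frames
#' and, optionally, unlabeled clips are excluded as well.
#'
#' @param min_frames minimum clip length in frames (default 25).
#' @param min_dim minimum spatial side in pixels (default 128; clinical
#'   corpora are typically around 1015 x 1015, synthetic phantoms smaller, so
#'   this is configurable).
#' @param require_label exclude clips whose label is `"unlabeled"`.
#' @export
eligibility_rules <- function(min_frames = 25L, min_dim = 128L, require_label = FALSE) {
  stopifnot(min_frames >= 1L)
  structure(list(min_frames = as.integer(min_frames), min_dim = as.integer(min_dim),
                 require_label = isTRUE(require_label)),
            class = "eligibility_rules")
}

#' Decide whether a clip is eligible
#'
#' @param stack a [frame_stack()].
#' @param rules an [eligibility_rules()] object.
#' @return a list with `eligible` (logical) and `reason` (`NA` when eligible,
#'   otherwise one of `"min_frames"`, `"min_dim"`, `"no_label"`).
#' @export
check_eligibility <- function(stack, rules = eligibility_rules()) {
  d <- dim(stack$frames)
  if (d[1] < rules$min_frames) {
    return(list(eligible = FALSE, reason = "min_frames"))
  }
  if (min(d[2], d[3]) < rules$min_dim) {
    return(list(eligible = FALSE, reason = "min_dim"))
  }
  if (rules$require_label && identical(stack$label, "unlabeled")) {
    return(list(eligible = FALSE, reason = "no_label"))
  }
  list(eligible = TRUE, reason = NA_character_)
}

#' Read / write a clip manifest
#'
#' The manifest is a CSV with columns `clip_id, subject_id, label, path`
#' (plus `n_frames` when written by the simulator).
#'
#' @param path CSV path.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clip_id", "subject_id", "label")
  if (!all(need %in% names(m))) {
    stop(sprintf("manifest '%s' must contain columns %s", path, paste(need, collapse = ", ")))
  }
  m
}

#' @rdname read_manifest
#' @param manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

## ---- minimal NumPy .npy / .npz support (no R package reads these) ----

npy_descr <- function(x) if (is.integer(x)) "<i4" else "<f8"

# Write a numeric/integer array as NumPy .npy v1.0 (C-order).
write_npy <- function(x, path) {
  if (is.null(dim(x))) dim(x) <- length(x)
  shape <- dim(x)
  descr <- npy_descr(x)
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    descr,
                    if (length(shape) == 1L) sprintf("%d,", shape)
                    else paste(shape, collapse = ", "))
  base <- 6L + 2L + 2L
  pad <- 64L - ((base + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  # C-order: last axis fastest -> reverse axes before flattening
  xc <- if (length(shape) > 1L) aperm(x, rev(seq_along(shape))) else x
  if (descr == "<i4") {
    writeBin(as.integer(xc), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(xc), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_npy_con <- function(con) {
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY"))))) {
    stop("not an NPY file (bad magic)")
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  n <- prod(shape)
  x <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<u2" = readBin(con, "integer", n, size = 2L, endian = "little", signed = FALSE),
    "|u1" = as.integer(readBin(con, "raw", n)),
    stop(sprintf("unsupported NPY dtype '%s'", descr)))
  if (length(shape) > 1L) {
    if (fortran) {
      dim(x) <- shape
    } else {
      dim(x) <- rev(shape)
      x <- aperm(x, rev(seq_along(shape)))
    }
  }
  x
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_npy_con(con)
}

# Read all members of an .npz archive into a named list of arrays.
read_npz <- function(path) {
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  out <- lapply(files, read_npy)
  names(out) <- sub("\\.npy$", "", basename(files))
  out
}

read_npz_first <- function(path) {
  members <- read_npz(path)
  if (length(members) == 0L) stop(sprintf("'%s' contains zero frames", path))
  nm <- if ("frames" %in% names(members)) "frames" else names(members)[1]
  members[[nm]]
}

# CRC-32 (IEEE), table-driven; operates on a raw vector.
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) else bitwShiftR(bitwAnd(c, -2L), 1)
        }
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L) + 1L
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), tab[idx])
  }
  bitwXor(crc, -1L)
}

uint_bytes <- function(x, size) {
  # little-endian unsigned encoding of a (possibly negative 32-bit) integer
  v <- as.double(x)
  if (v < 0) v <- v + 4294967296
  out <- raw(size)
  for (i in seq_len(size)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

# Write a named list of arrays as an uncompressed (stored) .npz archive.
write_npz <- function(arrays, path) {
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays))
  members <- lapply(names(arrays), function(nm) {
    tmp <- tempfile(fileext = ".npy")
    write_npy(arrays[[nm]], tmp)
    bytes <- readBin(tmp, "raw", file.info(tmp)$size)
    unlink(tmp)
    list(name = paste0(nm, ".npy"), bytes = bytes, crc = crc32(bytes))
  })
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(members))
  pos <- 0L
  for (i in seq_along(members)) {
    m <- members[[i]]
    offsets[i] <- pos
    name_raw <- charToRaw(m$name)
    local_hdr <- c(uint_bytes(0x04034b50, 4), uint_bytes(20, 2), uint_bytes(0, 2),
                   uint_bytes(0, 2), uint_bytes(0, 2), uint_bytes(0, 2),
                   uint_bytes(m$crc, 4), uint_bytes(length(m$bytes), 4),
                   uint_bytes(length(m$bytes), 4), uint_bytes(length(name_raw), 2),
                   uint_bytes(0, 2))
    writeBin(c(local_hdr, name_raw, m$bytes), con)
    pos <- pos + length(local_hdr) + length(name_raw) + length(m$bytes)
  }
  cd_start <- pos
  cd_len <- 0L
  for (i in seq_along(members)) {
    m <- members[[i]]
    name_raw <- charToRaw(m$name)
    central <- c(uint_bytes(0x02014b50, 4), uint_bytes(20, 2), uint_bytes(20, 2),
                 uint_bytes(0, 2), uint_bytes(0, 2), uint_bytes(0, 2), uint_bytes(0, 2),
                 uint_bytes(m$crc, 4), uint_bytes(length(m$bytes), 4),
                 uint_bytes(length(m$bytes), 4), uint_bytes(length(name_raw), 2),
                 uint_bytes(0, 2), uint_bytes(0, 2), uint_bytes(0, 2), uint_bytes(0, 2),
                 uint_bytes(0, 4), uint_bytes(offsets[i], 4))
    writeBin(c(central, name_raw), con)
    cd_len <- cd_len + length(central) + length(name_raw)
  }
  eocd <- c(uint_bytes(0x06054b50, 4), uint_bytes(0, 2), uint_bytes(0, 2),
            uint_bytes(length(members), 2), uint_bytes(length(members), 2),
            uint_bytes(cd_len, 4), uint_bytes(cd_start, 4), uint_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}
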