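#' Read darknet-style annotation files
#'
#' The darknet/YOLO annotation dialect stores one text file per frame, one
#' object per line: `class cx cy w h`, all four geometry fields normalised
#' to fractions of the frame size with `(cx, cy)` the box centre. This
#' converts to the package's absolute-pixel, 0-based corner convention; the
#' conversion is the only place the two conventions meet.
#'
#' @param path A single `.txt` file, or a directory of them (read in sorted
#'   order; the frame index is taken from the first run of digits in each
#'   file name, falling back to 0-based file order).
#' @param frame_w,frame_h Frame dimensions in pixels (the format stores
#'   fractions, so they must be supplied).
#' @param frame Frame index for a single-file read; default 0.
#' @return A ground-truth tibble. Blank files yield zero rows.
#' @export
read_darknet_annotations <- function(path, frame_w, frame_h, frame = 0L) {
  stopifnot(frame_w > 0, frame_h > 0)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    idx <- suppressWarnings(
      as.integer(sub(".*?(\\d+).*", "\\1", basename(files))))
    idx[is.na(idx)] <- seq_along(files)[is.na(idx)] - 1L
    return(dplyr::bind_rows(purrr::map2(
      files, idx, read_darknet_annotations,
      frame_w = frame_w, frame_h = frame_h)))
  }
  if (!file.exists(path)) rlang::abort(paste0("no such annotation file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_ground_truth())
  rows <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 5 || anyNA(f)) {
      rlang::abort(sprintf("%s line %d: expected 'class cx cy w h'", path, i))
    }
    if (any(f[2:5] < 0) || any(f[2:5] > 1)) {
      rlang::abort(sprintf("%s line %d: fractions must lie in [0, 1]", path, i))
    }
    f
  })
  m <- do.call(rbind, rows)
  ground_truth(x = (m[, 2] - m[, 4] / 2) * frame_w,
               y = (m[, 3] - m[, 5] / 2) * frame_h,
               w = m[, 4] * frame_w, h = m[, 5] * frame_h,
               frame = frame)
}

#' Write darknet-style annotation files
#'
#' One file per frame, named `frame_%06d.txt`; frames without boxes get an
#' empty file so that frame counts survive the round trip.
#'
#' @param gts Ground-truth tibble.
#' @param dir Output directory (created if needed).
#' @param frame_w,frame_h Frame dimensions in pixels.
#' @param n_frames Total number of frames; defaults to `max(frame) + 1`.
#' @return Invisibly, the written file paths.
#' @export
write_darknet_annotations <- function(gts, dir, frame_w, frame_h,
                                      n_frames = NULL) {
  validate_boxes(gts, "ground-truth box")
  if (is.null(n_frames)) {
    n_frames <- if (nrow(gts) > 0) max(gts$frame) + 1L else 0L
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_frames)
  for (t in seq_len(n_frames) - 1L) {
    g <- gts[gts$frame == t, , drop = FALSE]
    lines <- sprintf("0 %.6f %.6f %.6f %.6f",
                     (g$x + g$w / 2) / frame_w, (g$y + g$h / 2) / frame_h,
                     g$w / frame_w, g$h / frame_h)
    paths[t + 1L] <- file.path(dir, sprintf("frame_%06d.txt", t))
    writeLines(lines, paths[t + 1L])
  }
  invisible(paths)
}

#' Read a Pascal-VOC XML annotation file
#'
#' The VOC dialect stores boxes as `xmin/ymin/xmax/ymax`, 1-based and
#' inclusive on both ends. Conversion to the 0-based half-open convention
#' is `x = xmin - 1`, `w = xmax - xmin + 1` (so `xmin=1, xmax=10` covers
#' the same ten pixel columns as `x=0, w=10`).
#'
#' @param path XML file path.
#' @param frame Frame index stamped on the boxes; default 0.
#' @return A list with `gt` (ground-truth tibble) and `size`
#'   (`c(w, h)` from the file's `<size>` element).
#' @export
read_voc_xml <- function(path, frame = 0L) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "./size")
  if (is.na(size)) rlang::abort(paste0(path, ": missing <size> element"))
  fw <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  fh <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  objs <- xml2::xml_find_all(doc, "./object")
  num <- function(o, el) {
    node <- xml2::xml_find_first(o, paste0("./bndbox/", el))
    if (is.na(node)) {
      rlang::abort(sprintf("%s: object missing <bndbox>/<%s>", path, el))
    }
    as.numeric(xml2::xml_text(node))
  }
  if (length(objs) == 0) {
    return(list(gt = empty_ground_truth(), size = c(fw, fh)))
  }
  xmin <- vapply(objs, num, numeric(1), "xmin")
  ymin <- vapply(objs, num, numeric(1), "ymin")
  xmax <- vapply(objs, num, numeric(1), "xmax")
  ymax <- vapply(objs, num, numeric(1), "ymax")
  label <- vapply(objs, function(o) {
    n <- xml2::xml_find_first(o, "./name")
    if (is.na(n)) "bird" else xml2::xml_text(n)
  }, character(1))
  list(gt = ground_truth(x = xmin - 1, y = ymin - 1,
                         w = xmax - xmin + 1, h = ymax - ymin + 1,
                         frame = frame, label = label),
       size = c(fw, fh))
}

#' Write a Pascal-VOC XML annotation file
#'
#' @param gts Ground-truth tibble (one frame's boxes).
#' @param path Output file.
#' @param frame_w,frame_h Frame dimensions for the `<size>` element.
#' @return Invisibly, `path`.
#' @export
write_voc_xml <- function(gts, path, frame_w, frame_h) {
  validate_boxes(gts, "ground-truth box")
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", basename(path))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(frame_w))
  xml2::xml_add_child(size, "height", as.character(frame_h))
  xml2::xml_add_child(size, "depth", "1")
  for (i in seq_len(nrow(gts))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", gts$label[i])
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(gts$x[i] + 1))
    xml2::xml_add_child(bb, "ymin", format(gts$y[i] + 1))
    xml2::xml_add_child(bb, "xmax", format(gts$x[i] + gts$w[i]))
    xml2::xml_add_child(bb, "ymax", format(gts$y[i] + gts$h[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

DETECTION_SCHEMA <- "skywatch-detections-v1"

#' Write detections as line-delimited JSON
#'
#' First line is a header object carrying the schema version; every
#' following line is one detection record. The full double precision of
#' every numeric field is preserved, so write-then-read is lossless.
#'
#' @param dets Detection tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_detections <- function(dets, path) {
  validate_detections(dets)
  header <- jsonlite::toJSON(list(schema = DETECTION_SCHEMA,
                                  n = nrow(dets)), auto_unbox = TRUE)
  body <- vapply(seq_len(nrow(dets)), function(i) {
    jsonlite::toJSON(list(frame = dets$frame[i], x = dets$x[i],
                          y = dets$y[i], w = dets$w[i], h = dets$h[i],
                          confidence = dets$confidence[i],
                          source_id = dets$source_id[i]),
                     auto_unbox = TRUE, digits = I(17))
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a line-delimited detection file
#'
#' @param path File written by [write_detections()].
#' @return A detection tibble.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) rlang::abort(paste0(path, ": empty detection file"))
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$schema, DETECTION_SCHEMA)) {
    rlang::abort(sprintf("%s: unknown schema '%s'", path, header$schema))
  }
  body <- lines[-1]
  if (length(body) == 0) return(empty_detections())
  recs <- lapply(body, jsonlite::fromJSON)
  detections(x = vapply(recs, `[[`, numeric(1), "x"),
             y = vapply(recs, `[[`, numeric(1), "y"),
             w = vapply(recs, `[[`, numeric(1), "w"),
             h = vapply(recs, `[[`, numeric(1), "h"),
             confidence = vapply(recs, `[[`, numeric(1), "confidence"),
             frame = vapply(recs, function(r) as.integer(r$frame), integer(1)),
             source_id = vapply(recs, `[[`, character(1), "source_id"))
}

#' Write a frame as plain-text PGM (P2)
#'
#' @param frame Numeric matrix with intensities 0--255.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_pgm <- function(frame, path) {
  check_frame(frame)
  v <- round(pmin(pmax(frame, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), "255"), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text PGM (P2) frame
#'
#' @param path PGM file.
#' @return Numeric matrix.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") rlang::abort(paste0(path, ": not an ASCII PGM (P2) file"))
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) rlang::abort(paste0(path, ": truncated PGM data"))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a frame sequence as PNG files
#'
#' Needs the `png` package. Files are named `frame_%06d.png`.
#'
#' @param frames List of numeric matrices (0--255).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_frames_png <- function(frames, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    rlang::abort("the png package is required to write PNG frames")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame_%06d.png", i - 1L))
    png::writePNG(pmin(pmax(frames[[i]], 0), 255) / 255, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of PNG frames
#'
#' @param dir Directory of grayscale PNGs (sorted order = frame order).
#' @return List of numeric matrices with intensities 0--255.
#' @export
read_frames_png <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    rlang::abort("the png package is required to read PNG frames")
  }
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img * 255
  })
}
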