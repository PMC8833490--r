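#' Read a detection stream
#'
#' Reads per-frame detector records from JSON Lines or CSV. Each record
#' carries `camera_id`, `frame_index`, `timestamp`, `posture`,
#' `confidence` and the normalized center-format box `cx, cy, w, h`;
#' a record with null/empty posture and box encodes a frame where the
#' detector saw nothing (a gap). Unknown fields are ignored. Malformed
#' rows abort with the offending line number.
#'
#' @param path File path; the dialect is taken from the extension
#'   (`.jsonl`/`.json` vs `.csv`) unless `format` is given.
#' @param format `"jsonl"`, `"csv"`, or `NULL` to guess from `path`.
#' @param fps Frames per second of the stream (default 5).
#' @return A named list of [detection_series()], one per `camera_id`.
#' @seealso [write_detections()]
#' @export
read_detections <- function(path, format = NULL, fps = 5) {
  format <- detect_format(path, format)
  if (format == "jsonl") {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    rows <- lapply(seq_along(txt), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(txt[i]),
                      error = function(e) stop(sprintf(
                        "parse error at line %d: %s", i, conditionMessage(e)),
                        call. = FALSE))
      as.data.frame(lapply(rec[!vapply(rec, is.null, TRUE)], identity),
                    stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(lapply(rows, pad_detection_row), make.row.names = FALSE))
    lines <- seq_along(txt)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    lines <- seq_len(nrow(df)) + 1L # header occupies line 1
  }
  if (is.null(df) || nrow(df) == 0)
    return(structure(list(), names = character(0)))
  for (col in c("camera_id", "frame_index")) {
    if (!col %in% names(df) || all(is.na(df[[col]])))
      stop(sprintf("missing mandatory field '%s'", col), call. = FALSE)
  }
  if (!"posture" %in% names(df)) df$posture <- NA_character_
  df$posture[df$posture %in% c("", "NA")] <- NA_character_
  for (col in setdiff(DETECTION_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[DETECTION_COLUMNS]
  validate_detection_records(df, lines = lines)
  out <- lapply(split(df, df$camera_id), function(s) {
    s <- s[order(s$frame_index), , drop = FALSE]
    detection_series(s, fps = fps, camera_id = s$camera_id[1])
  })
  out[order(names(out))]
}

pad_detection_row <- function(row) {
  for (col in setdiff(DETECTION_COLUMNS, names(row))) row[[col]] <- NA
  row[DETECTION_COLUMNS]
}

detect_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("jsonl", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "json", "ndjson")) "jsonl"
  else if (ext == "csv") "csv"
  else stop("cannot infer stream format from extension: ", path, call. = FALSE)
}

#' Write detection series to a stream file
#'
#' Inverse of [read_detections()]: one record per frame, gaps written as
#' records with null posture/confidence/box so that round trips preserve
#' logical content exactly.
#'
#' @param series A single [detection_series()] or a list of them.
#' @param path Output file path.
#' @param format `"jsonl"`, `"csv"`, or `NULL` to guess from `path`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(series, path, format = NULL) {
  format <- detect_format(path, format)
  if (is.data.frame(series)) series <- list(series)
  df <- do.call(rbind, c(lapply(series, as.data.frame), make.row.names = FALSE))
  if (is.null(df)) df <- empty_detection_frame()
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(df) > 0)
      for (i in seq_len(nrow(df))) {
        rec <- as.list(df[i, ])
        rec <- rec[!vapply(rec, is.na, TRUE)]
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
      }
  }
  invisible(path)
}

empty_detection_frame <- function() {
  data.frame(camera_id = character(0), frame_index = integer(0),
             timestamp = numeric(0), posture = character(0),
             confidence = numeric(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' Read a class-name table
#'
#' One label per line; the 0-based line number is the class index, as in
#' Darknet `.names` files.
#'
#' @param path Path to the names file.
#' @return Character vector of class names (index = position - 1).
#' @export
read_class_names <- function(path) {
  nm <- trimws(readLines(path, warn = FALSE))
  nm[nzchar(nm)]
}

#' Read YOLO/Darknet annotation files
#'
#' One `.txt` file per image, each line `class cx cy w h` with
#' normalized center-format coordinates, as written by LabelImg in YOLO
#' mode. The image id is the file name without extension.
#'
#' @param label_dir Directory of `.txt` annotation files.
#' @param class_names Character vector mapping 0-based class index to
#'   label, e.g. from [read_class_names()].
#' @return A label set: data frame with columns `image_id`, `posture`,
#'   `cx`, `cy`, `w`, `h`, and attribute `class_names`. Images whose
#'   file is empty are present with zero boxes (recorded in attribute
#'   `image_ids`, which lists every annotation file seen).
#' @export
read_yolo_labels <- function(label_dir, class_names) {
  files <- sort(list.files(label_dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0) stop("no .txt annotation files in ", label_dir,
                               call. = FALSE)
  rows <- list()
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(v) != 5 || any(is.na(v)))
        stop(sprintf("%s line %d: expected 'class cx cy w h'", basename(f), i),
             call. = FALSE)
      cls <- v[1] + 1
      if (cls < 1 || cls > length(class_names) || v[1] != round(v[1]))
        stop(sprintf("%s line %d: unknown class index %s", basename(f), i, v[1]),
             call. = FALSE)
      if (any(v[2:3] < 0 | v[2:3] > 1) || any(v[4:5] <= 0 | v[4:5] > 1))
        stop(sprintf("%s line %d: coordinate out of normalized range",
                     basename(f), i), call. = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        image_id = id, posture = class_names[cls],
        cx = v[2], cy = v[3], w = v[4], h = v[5])
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(0), posture = character(0),
               cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0))
  structure(out, class_names = class_names,
            image_ids = tools::file_path_sans_ext(basename(files)))
}

#' Read Pascal-VOC XML annotations
#'
#' Reads the corner-pixel dialect written by LabelImg (`xmin`, `ymin`,
#' `xmax`, `ymax` plus the image `size` element) and converts to the
#' normalized center format used everywhere else:
#' `cx = (xmin + xmax) / (2 W)`, `w = (xmax - xmin) / W`, analogously
#' for y.
#'
#' @param xml_files Character vector of XML file paths.
#' @return A label set as in [read_yolo_labels()]; `class_names` is the
#'   sorted set of object names encountered.
#' @export
read_voc_labels <- function(xml_files) {
  rows <- list()
  ids <- character(0)
  for (f in xml_files) {
    doc <- xml2::read_xml(f)
    id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
    if (is.na(id) || !nzchar(id)) id <- tools::file_path_sans_ext(basename(f))
    id <- tools::file_path_sans_ext(id)
    ids <- c(ids, id)
    size <- xml2::xml_find_first(doc, "./size")
    if (is.na(xml2::xml_name(size)))
      stop(basename(f), ": missing <size> element", call. = FALSE)
    W <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
    H <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
    if (!isTRUE(W > 0) || !isTRUE(H > 0))
      stop(basename(f), ": invalid image size", call. = FALSE)
    for (obj in xml2::xml_find_all(doc, "./object")) {
      name <- xml2::xml_text(xml2::xml_find_first(obj, "./name"))
      num <- function(tag) as.numeric(xml2::xml_text(
        xml2::xml_find_first(obj, paste0("./bndbox/", tag))))
      xmin <- num("xmin"); xmax <- num("xmax")
      ymin <- num("ymin"); ymax <- num("ymax")
      if (!isTRUE(xmin < xmax) || !isTRUE(ymin < ymax))
        stop(basename(f), ": degenerate box (xmin >= xmax or ymin >= ymax)",
             call. = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        image_id = id, posture = name,
        cx = (xmin + xmax) / (2 * W), cy = (ymin + ymax) / (2 * H),
        w = (xmax - xmin) / W, h = (ymax - ymin) / H)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(0), posture = character(0),
               cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0))
  validate_boxes(out, where = "VOC annotation")
  structure(out, class_names = sort(unique(out$posture)), image_ids = ids)
}

#' Convert a normalized center-format box back to pixel corners
#'
#' @param box Data frame of boxes from [bbox()].
#' @param width,height Image size in pixels.
#' @return Data frame with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
box_to_pixels <- function(box, width, height) {
  data.frame(
    xmin = (box$cx - box$w / 2) * width,
    ymin = (box$cy - box$h / 2) * height,
    xmax = (box$cx + box$w / 2) * width,
    ymax = (box$cy + box$h / 2) * height
  )
}
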