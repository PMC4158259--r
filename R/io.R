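# Serialization: frames, graph files, marker files, tracking records,
# and the run configuration embedded in every output for provenance.

GRAPH_FORMAT_VERSION <- "1.0"

#' Default run configuration
#'
#' All tunable thresholds in one place, serialized with every output for
#' provenance: `lam` (threshold-search shrink factor, 0.1), `dif_accept`
#' (NCC pair-acceptance level, 0.8), `dif_reject` (subgraph rejection
#' level, 0.2), `kl_threshold` (trajectory acceptance, 0.1),
#' `max_features` (keypoints per frame, 200), `ratio` (descriptor ratio
#' test, 0.8), `ransac_tol` (inlier tolerance in px, 3), `stride`
#' (tracking decimation, 3) and `seed`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `gg_config`.
#' @export
gg_config <- function(...) {
  cfg <- list(lam = 0.1, dif_accept = 0.8, dif_reject = 0.2,
              kl_threshold = 0.1, max_features = 200L, ratio = 0.8,
              ransac_tol = 3, stride = 3L, min_overlap = 0.25, seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    gg_stop(paste("unknown config fields:", paste(bad, collapse = ", ")),
            "gg_invalid_parameter")
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$lam > 0, cfg$lam < 1, cfg$dif_accept <= 1, cfg$dif_reject >= -1,
            cfg$kl_threshold > 0, cfg$max_features >= 1, cfg$ratio > 0,
            cfg$ratio <= 1, cfg$ransac_tol > 0, cfg$stride >= 1)
  structure(cfg, class = c("gg_config", "list"))
}

provenance <- function(config) {
  list(package = "gastrograph",
       version = as.character(utils::packageVersion("gastrograph")),
       config = unclass(config))
}

#' Read an image frame from disk
#'
#' Reads a PNG or TIFF file and converts it to an 8-bit-equivalent
#' grayscale intensity matrix in `[0, 1]`; color inputs are converted with
#' ITU-R BT.601 luma weights (0.299 R + 0.587 G + 0.114 B), the same
#' conversion used everywhere in the package.
#'
#' @param path Image file (`.png`, `.tif`/`.tiff`).
#' @param frame_id Identifier; defaults to the file name without extension.
#' @param site_label Anatomic-site tag.
#' @return An [image_frame()].
#' @export
read_frame <- function(path, frame_id = NULL,
                       site_label = "default") {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    gg_stop(sprintf("unsupported image format '%s' (PNG/TIFF supported)", ext),
            "gg_format_error"))
  img <- to_gray(arr)
  image_frame(img, frame_id %||% tools::file_path_sans_ext(basename(path)),
              site_label)
}

#' Convert an image array to grayscale
#'
#' @param arr Matrix (returned unchanged) or rows x cols x channels array;
#'   3+ channels are combined with BT.601 luma weights, extra channels
#'   (alpha) ignored.
#' @return 2-D numeric matrix.
#' @export
to_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
    }
    return(arr[, , 1])
  }
  gg_stop("cannot interpret array as an image", "gg_invalid_input")
}

#' Write a grayscale frame as PNG
#' @param image 2-D matrix in `[0, 1]`.
#' @param path Output path.
#' @export
write_frame_png <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Read all frames from a directory
#'
#' Frames are read in lexicographic file-name order (the acquisition
#' order convention); video-container decoding is upstream of this tool.
#'
#' @param dir Directory of PNG/TIFF files.
#' @param site_labels Optional per-file site labels (recycled if length 1).
#' @return List of [image_frame()] objects.
#' @export
read_frame_dir <- function(dir, site_labels = "default") {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) gg_stop("no image files found", "gg_format_error")
  labs <- rep_len(site_labels, length(files))
  Map(function(f, l) read_frame(f, site_label = l), files, labs)
}

tf9 <- function(t) as.numeric(t(unclass(t)))   # row-major 9 floats

tf_from9 <- function(v) {
  affine_transform(matrix(as.numeric(v), 3, 3, byrow = TRUE))
}

#' Save an image graph to a JSON file
#'
#' Versioned, documented container: `frames` (ids, site labels, relative
#' image paths), `threshold`, and `edges` — one record per unordered
#' connected pair with the similarity (12 significant digits) and the
#' forward transform as a row-major 9-float array.  Per the graph-matrix
#' sentinel convention, sub-threshold similarities are not persisted.
#' The reverse transform is reconstructed as the inverse on load.
#'
#' @param g An `image_graph`.
#' @param path Output file.
#' @param image_dir When given, frame images are written there as PNGs and
#'   referenced by relative path, making the file self-contained.
#' @param config `gg_config` recorded for provenance.
#' @return `path`, invisibly.
#' @export
save_graph <- function(g, path, image_dir = NULL, config = gg_config()) {
  ids <- g$frame_ids
  paths <- rep(NA_character_, length(ids))
  if (!is.null(image_dir)) {
    dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
    base <- normalizePath(dirname(path), mustWork = FALSE)
    idir <- normalizePath(image_dir, mustWork = FALSE)
    # store paths relative to the graph file when possible
    rel <- if (startsWith(paste0(idir, "/"), paste0(base, "/"))) {
      sub("^/", "", substring(idir, nchar(base) + 1L))
    } else idir
    for (i in seq_along(ids)) {
      fname <- paste0(ids[i], ".png")
      paths[i] <- if (nzchar(rel)) file.path(rel, fname) else fname
      write_frame_png(g$frames[[i]]$image, file.path(image_dir, fname))
    }
  }
  edges <- graph_edges(g)
  edge_list <- lapply(seq_len(nrow(edges)), function(r) {
    i <- edges[r, 1]; j <- edges[r, 2]
    list(i = ids[i], j = ids[j],
         similarity = as.numeric(sprintf("%.12g", g$similarity[i, j])),
         transform = tf9(graph_transform(g, i, j)))
  })
  obj <- list(format = "gastrograph-image-graph",
              format_version = GRAPH_FORMAT_VERSION,
              provenance = provenance(config),
              threshold = g$threshold,
              frames = lapply(seq_along(ids), function(i) {
                list(id = ids[i], site_label = g$site_labels[i],
                     image_path = paths[i])
              }),
              edges = edge_list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load an image graph from a JSON file
#'
#' @param path Graph file written by [save_graph()].
#' @param image_dir Directory to resolve relative image paths against;
#'   defaults to the graph file's directory.  Frames without a stored
#'   image path load with a `NULL` image (usable for pathway algebra but
#'   not for NCC/SSD computation).
#' @return An `image_graph`.
#' @export
load_graph <- function(path, image_dir = dirname(path)) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    gg_stop(sprintf("cannot parse graph file: %s", conditionMessage(e)),
                            "gg_format_error")
                  })
  if (!identical(obj$format, "gastrograph-image-graph")) {
    gg_stop("not a gastrograph image-graph file (field: format)", "gg_format_error")
  }
  if (!identical(obj$format_version, GRAPH_FORMAT_VERSION)) {
    gg_stop(sprintf("unsupported graph format version '%s' (field: format_version)",
                    obj$format_version %||% "<missing>"), "gg_format_error")
  }
  if (is.null(obj$frames) || is.null(obj$threshold)) {
    gg_stop("graph file is missing 'frames' or 'threshold'", "gg_format_error")
  }
  ids <- vapply(obj$frames, function(f) f$id %||%
                  gg_stop("frame record missing id (field: frames[].id)", "gg_format_error"),
                character(1))
  sites <- vapply(obj$frames, function(f) f$site_label %||% "default", character(1))
  frames <- lapply(seq_along(obj$frames), function(i) {
    p <- obj$frames[[i]]$image_path
    img <- NULL
    if (!is.null(p) && !is.na(p)) {
      fp <- file.path(image_dir, p)
      if (file.exists(fp)) img <- read_frame(fp)$image
    }
    structure(list(image = img, frame_id = ids[i], site_label = sites[i]),
              class = "image_frame")
  })
  n <- length(ids)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  transforms <- list()
  for (e in obj$edges %||% list()) {
    if (is.null(e$i) || is.null(e$j) || is.null(e$similarity) ||
        length(e$transform) != 9L) {
      gg_stop("malformed edge record (fields: edges[].{i,j,similarity,transform})",
              "gg_format_error")
    }
    i <- match(e$i, ids); j <- match(e$j, ids)
    if (is.na(i) || is.na(j)) {
      gg_stop("edge references unknown frame id (field: edges[].i/j)",
              "gg_format_error")
    }
    sim[i, j] <- sim[j, i] <- as.numeric(e$similarity)
    t <- tf_from9(unlist(e$transform))
    transforms[[paste0(ids[i], "->", ids[j])]] <- t
    transforms[[paste0(ids[j], "->", ids[i])]] <- affine_invert(t)
  }
  features <- lapply(frames, function(f) {
    if (is.null(f$image)) empty_feature_set(f$frame_id)
    else extract_features(f$image, frame_id = f$frame_id)
  })
  structure(
    list(frame_ids = ids, frames = frames, site_labels = sites,
         similarity = sim, transforms = transforms,
         threshold = as.numeric(obj$threshold), features = features),
    class = "image_graph")
}

#' Save / load marker files
#'
#' Markers serialize as a JSON list of `{label, x, y, radius, frame_id}`.
#'
#' @param markers A `marker_set`.
#' @param path File path.
#' @param frame_id Frame the markers were placed on.
#' @param config `gg_config` for provenance.
#' @return `path` (save) or a `marker_set` (load).
#' @export
save_markers <- function(markers, path, frame_id = NA_character_,
                         config = gg_config()) {
  obj <- list(format = "gastrograph-markers",
              provenance = provenance(config),
              frame_id = frame_id,
              markers = lapply(seq_len(nrow(markers)), function(r) {
                list(label = markers$label[r], x = markers$x[r],
                     y = markers$y[r], radius = markers$radius[r])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname save_markers
#' @export
load_markers <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path), error = function(e) {
    gg_stop(sprintf("cannot parse marker file: %s", conditionMessage(e)),
            "gg_format_error")
  })
  if (!identical(obj$format, "gastrograph-markers")) {
    gg_stop("not a gastrograph marker file (field: format)", "gg_format_error")
  }
  rows <- lapply(obj$markers, function(m) {
    if (is.null(m$x) || is.null(m$y) || is.null(m$radius)) {
      gg_stop("malformed marker record (fields: markers[].{x,y,radius})",
              "gg_format_error")
    }
    data.frame(label = as.integer(m$label %||% NA), x = as.numeric(m$x),
               y = as.numeric(m$y), radius = as.numeric(m$radius))
  })
  out <- do.call(rbind, rows)
  attr(out, "frame_id") <- obj$frame_id
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Write / read tracking records
#'
#' Tracking output is JSON-lines: a header line with provenance, then one
#' record per frame with the retargeted markers and visibility flags.
#'
#' @param records A `tracking_record` data.frame from [track_sequence()].
#' @param path File path.
#' @param config `gg_config` for provenance.
#' @export
write_tracking <- function(records, path, config = gg_config()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- list(format = "gastrograph-tracking",
                 provenance = provenance(config))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (fi in unique(records$frame_index)) {
    sub <- records[records$frame_index == fi, , drop = FALSE]
    rec <- list(frame_id = sub$frame_id[1], frame_index = fi,
                computed = sub$computed[1],
                path_length = sub$path_length[1],
                markers = lapply(seq_len(nrow(sub)), function(r) {
                  list(label = sub$label[r], x = sub$x[r], y = sub$y[r],
                       radius = sub$radius[r], visible = sub$visible[r])
                }))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_tracking
#' @export
read_tracking <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) gg_stop("empty tracking file", "gg_format_error")
  header <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) {
    gg_stop("cannot parse tracking header", "gg_format_error")
  })
  if (!identical(header$format, "gastrograph-tracking")) {
    gg_stop("not a gastrograph tracking file (field: format)", "gg_format_error")
  }
  rows <- lapply(lines[-1], function(l) {
    rec <- tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
                    error = function(e) {
                      gg_stop("malformed tracking record line", "gg_format_error")
                    })
    do.call(rbind, lapply(rec$markers, function(m) {
      data.frame(frame_id = rec$frame_id, frame_index = rec$frame_index,
                 label = m$label, x = m$x, y = m$y, radius = m$radius,
                 visible = m$visible, computed = rec$computed,
                 path_length = rec$path_length %||% NA_integer_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tracking_record", "data.frame")
  out
}

#' Write a marker overlay PNG
#'
#' Rasterizes the markers as green circle outlines over the grayscale
#' frame (the on-screen display convention for retargeted lesions).
#' Invisible markers are skipped.
#'
#' @param image 2-D matrix in `[0, 1]`.
#' @param markers A `marker_set` (optionally with a `visible` column).
#' @param path Output PNG path.
#' @export
write_overlay <- function(image, markers, path) {
  nr <- nrow(image); nc <- ncol(image)
  rgb <- array(pmin(pmax(image, 0), 1), dim = c(nr, nc, 3L))
  vis <- if ("visible" %in% names(markers)) markers$visible else TRUE
  vis <- rep_len(vis, nrow(markers))
  for (r in seq_len(nrow(markers))) {
    if (!vis[r]) next
    th <- seq(0, 2 * pi, length.out = max(32L, round(4 * markers$radius[r])))
    xs <- round(markers$x[r] + markers$radius[r] * cos(th))
    ys <- round(markers$y[r] + markers$radius[r] * sin(th))
    keep <- xs >= 0 & xs < nc & ys >= 0 & ys < nr
    for (k in which(keep)) {
      rgb[ys[k] + 1, xs[k] + 1, ] <- c(0, 1, 0)
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
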