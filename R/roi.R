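# Polygonal organ regions of interest and per-organ collagen summaries.
#
# ROIs are drawn per frame on the co-registered B-mode image and rasterized
# with the even-odd rule: a pixel belongs to the ROI iff its center falls
# inside the closed polygon. Pixel centers use 0-based coordinates (x = col
# index, y = row index, pixel (0,0) top-left), the same convention recorded
# in annotation files and stack metadata.

#' Create an ROI annotation
#'
#' @param frame 1-based frame index within the stack.
#' @param organ One of `"uterus"`, `"internal_os"`, `"external_os"`,
#'   `"vagina"`.
#' @param polygon An `n x 2` matrix (or list of `(x, y)` pairs) of vertices
#'   in 0-based pixel coordinates; at least 3 vertices, simple (no
#'   self-intersection), non-zero area.
#' @return A list of class `spa_roi`.
#' @export
roi_annotation <- function(frame, organ, polygon) {
  if (!organ %in% organ_levels()) {
    hint <- if (grepl("cervix|os", organ, ignore.case = TRUE)) {
      " Did you mean 'internal_os' or 'external_os'?"
    } else ""
    spa_abort(
      sprintf("Unknown organ label '%s'; expected one of %s.%s",
              organ, paste(organ_levels(), collapse = ", "), hint),
      "spa_vocabulary_error")
  }
  if (is.list(polygon) && !is.data.frame(polygon)) {
    polygon <- do.call(rbind, lapply(polygon, as.numeric))
  }
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    spa_abort("Polygon needs at least 3 (x, y) vertices.", "spa_annotation_error")
  }
  if (any(!is.finite(polygon))) {
    spa_abort("Polygon vertices must be finite.", "spa_annotation_error")
  }
  # drop a duplicated closing vertex
  n <- nrow(polygon)
  if (all(polygon[1, ] == polygon[n, ]) && n > 3L) {
    polygon <- polygon[-n, , drop = FALSE]
  }
  if (abs(polygon_area(polygon)) < 1e-12) {
    spa_abort("Polygon has zero area.", "spa_annotation_error")
  }
  if (!polygon_is_simple(polygon)) {
    spa_abort("Polygon is self-intersecting.", "spa_annotation_error")
  }
  structure(list(frame = as.integer(frame), organ = organ, polygon = polygon),
            class = "spa_roi")
}

# signed shoelace area
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share a vertex)
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      if (segments_intersect(p[edges[i, 1], ], p[edges[i, 2], ],
                             p[edges[j, 1], ], p[edges[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Rasterize an ROI polygon to a boolean mask
#'
#' Even-odd (crossing number) rasterization: a pixel is inside iff a ray
#' from its center crosses the closed polygon boundary an odd number of
#' times. Deterministic; pixel centers at 0-based integer coordinates.
#'
#' @param annotation An [roi_annotation()].
#' @param height,width Image dimensions in pixels.
#' @return A logical `height x width` matrix.
#' @export
rasterize_roi <- function(annotation, height, width) {
  stopifnot(inherits(annotation, "spa_roi"))
  p <- annotation$polygon
  if (any(p[, 1] < -0.5) || any(p[, 1] > width - 0.5) ||
      any(p[, 2] < -0.5) || any(p[, 2] > height - 0.5)) {
    spa_abort("Polygon extends outside the image bounds.", "spa_bounds_error")
  }
  # pixel centers: x = 0..width-1 (cols), y = 0..height-1 (rows)
  px <- rep(0:(width - 1L), each = height)
  py <- rep(0:(height - 1L), times = width)
  inside <- rep(FALSE, height * width)
  n <- nrow(p)
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]
    xj <- p[j, 1]; yj <- p[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Per-organ mean collagen concentration
#'
#' Pools the collagen channel over the union of each organ's per-frame ROI
#' pixels (pixel-pooled, not mean-of-frame-means) and reports one mean per
#' organ. Degenerate pixels -- where unmixing was undefined and zeros were
#' imputed -- are excluded from the mean.
#'
#' @param conc An `spa_conc_map` from [unmix_stack()].
#' @param annotations A list of [roi_annotation()]s (any organs, any frames).
#' @param animal_id Label recorded in the output.
#' @param organ Optional: restrict to one organ label.
#' @return A tibble with one row per organ: `animal_id`, `organ`,
#'   `mean_collagen_au`, `n_pixels`, `n_frames`.
#' @export
organ_mean <- function(conc, annotations, animal_id, organ = NULL) {
  stopifnot(inherits(conc, "spa_conc_map"))
  if (inherits(annotations, "spa_roi")) annotations <- list(annotations)
  organs <- vapply(annotations, function(a) a$organ, character(1))
  keep <- if (is.null(organ)) rep(TRUE, length(annotations)) else organs == organ
  if (!any(keep)) {
    spa_abort(
      sprintf("No annotations for organ '%s'.", organ %||% "<any>"),
      "spa_empty_error")
  }
  d <- dim(conc$maps)
  collagen <- conc_channel(conc, "collagen")
  tibble::tibble(organ = organs[keep], ann = annotations[keep]) |>
    dplyr::group_by(.data$organ) |>
    dplyr::group_modify(function(g, key) {
      vals <- purrr::map(g$ann, function(a) {
        if (a$frame < 1L || a$frame > d[1]) {
          spa_abort(
            sprintf("Annotation frame %d outside the stack (1-%d).", a$frame, d[1]),
            "spa_bounds_error")
        }
        mask <- rasterize_roi(a, d[3], d[4])
        eligible <- mask & !matrix(conc$degenerate[a$frame, , ], d[3], d[4])
        matrix(collagen[a$frame, , ], d[3], d[4])[eligible]
      })
      pooled <- unlist(vals)
      if (length(pooled) == 0L) {
        spa_abort(
          sprintf("ROI for organ '%s' contains no eligible (non-degenerate) pixels.",
                  key$organ),
          "spa_empty_error")
      }
      tibble::tibble(mean_collagen_au = mean(pooled),
                     n_pixels = length(pooled),
                     n_frames = length(unique(vapply(g$ann, `[[`, 1L, "frame"))))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(animal_id = animal_id, .before = 1) |>
    dplyr::arrange(match(.data$organ, organ_levels()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write ROI annotation files
#'
#' JSON sidecar with a header declaring the coordinate convention and one
#' record per frame per organ:
#' `{"frame": f, "organ": "...", "polygon": [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @return `read_annotations()` returns a list of [roi_annotation()]s.
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  anns <- doc$annotations
  if (is.null(anns)) {
    spa_abort("Annotation file has no 'annotations' field.", "spa_format_error")
  }
  frames <- unlist(anns$frame)
  organs <- unlist(anns$organ)
  polys <- anns$polygon
  if (length(frames) != length(organs) || length(frames) != length(polys)) {
    spa_abort("Annotation records are inconsistent.", "spa_format_error")
  }
  purrr::pmap(list(frames, organs, polys), function(f, o, poly) {
    roi_annotation(f, o, do.call(rbind, lapply(poly, unlist)))
  })
}

#' @rdname read_annotations
#' @param annotations A list of [roi_annotation()]s.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "spa_roi")) annotations <- list(annotations)
  doc <- list(
    coordinate_convention = "0-based pixel centers; x = column, y = row; pixel (0,0) top-left; frame indices 1-based",
    annotations = list(
      frame = vapply(annotations, function(a) a$frame, integer(1)),
      organ = vapply(annotations, function(a) a$organ, character(1)),
      polygon = purrr::map(annotations, "polygon")
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
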