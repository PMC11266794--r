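#' Binarize a grayscale image
#'
#' Converts a grayscale pixel grid into a binary ink mask. A pixel is ink
#' (`1`) when its intensity is less than or equal to the threshold, matching
#' the dark-ink-on-white convention of lineage diagrams.
#'
#' @param image Numeric matrix of intensities in `[0, 1]` (as returned by
#'   [png::readPNG()] for a grayscale image), or a 3-d array whose channels
#'   are averaged to gray first. Rows are image rows (top to bottom).
#' @param threshold Intensity cutoff. Pixels with intensity `<= threshold`
#'   become ink. The default `NULL` picks a threshold automatically by Otsu's
#'   method on a 256-bin histogram.
#' @return An integer matrix of 0/1 with the same dimensions, class
#'   `lineage_image`.
#' @examples
#' img <- matrix(c(1, 1, 0, 1), 2, 2)
#' binarize(img, threshold = 0.5)
#' @export
binarize <- function(image, threshold = NULL) {
  if (is.array(image) && length(dim(image)) == 3L) {
    # average color channels (drop alpha if present)
    nc <- min(dim(image)[3L], 3L)
    image <- apply(image[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a non-empty matrix or 3-d array")
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  if (threshold < min(0, min(image)) || threshold > max(1, max(image)))
    stop("'threshold' outside the intensity range")
  out <- matrix(as.integer(image <= threshold), nrow(image), ncol(image))
  class(out) <- c("lineage_image", class(out))
  out
}

# Otsu's between-class variance maximization on a 256-bin histogram.
otsu_threshold <- function(image, nbins = 256L) {
  x <- as.vector(image)
  breaks <- seq(min(x), max(x), length.out = nbins + 1L)
  if (breaks[1L] == breaks[nbins + 1L]) return(breaks[1L])
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Delete narrow elements from a binary diagram
#'
#' Removes the vertical connector lines and death markers of a lineage
#' diagram, leaving only the horizontal division bars. The default mode
#' replays the diagram-processing rule of scanning the image row by row and
#' deleting every within-row run of ink that is at most `max_width_px` wide:
#' vertical lines and 'X' marker strokes are at most 2 px wide in any row,
#' whereas division bars are wider. A connected-component mode (8-connected,
#' erase components whose bounding-box width is `<= max_width_px`) is
#' available for diagrams whose elements never touch.
#'
#' @param image Binary 0/1 matrix (see [binarize()]).
#' @param max_width_px Maximum width (in px) of elements to delete.
#'   Default 2, the connector-line width of the diagram dialect.
#' @param method `"run"` (default) deletes within-row ink runs of width
#'   `<= max_width_px`; `"component"` deletes 8-connected components whose
#'   bounding-box width is `<= max_width_px`.
#' @return The filtered binary matrix. Idempotent: applying it twice gives
#'   the same result as once.
#' @export
strip_narrow_elements <- function(image, max_width_px = 2L,
                                  method = c("run", "component")) {
  method <- match.arg(method)
  stopifnot(max_width_px >= 1L)
  img <- unclass_image(image)
  if (method == "run") {
    res <- apply(img, 1L, strip_row_runs, max_w = max_width_px)
    out <- if (is.matrix(res)) t(res) else matrix(res, nrow(img), ncol(img))
  } else {
    lab <- label_components8(img)
    if (max(lab) > 0L) {
      cols <- col(img)[lab > 0L]
      ids <- lab[lab > 0L]
      wmin <- tapply(cols, ids, min)
      wmax <- tapply(cols, ids, max)
      drop_ids <- as.integer(names(wmin))[(wmax - wmin + 1L) <= max_width_px]
      img[lab %in% drop_ids] <- 0L
    }
    out <- img
  }
  storage.mode(out) <- "integer"
  class(out) <- c("lineage_image", class(out))
  out
}

strip_row_runs <- function(row, max_w) {
  r <- rle(row > 0)
  drop <- r$values & r$lengths <= max_w
  r$values <- r$values & !drop
  as.integer(inverse.rle(r))
}

# 8-connected component labelling of a binary matrix, via per-row runs and
# union-find merging with overlapping (offset +/- 1 column) runs in the
# previous row.
label_components8 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  prev_runs <- NULL  # data.frame: start, end, id
  next_id <- 0L
  for (r in seq_len(h)) {
    rl <- rle(img[r, ] > 0)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    starts <- starts[keep]; ends <- ends[keep]
    ids <- integer(length(starts))
    for (k in seq_along(starts)) {
      id <- 0L
      if (!is.null(prev_runs) && nrow(prev_runs) > 0L) {
        # 8-connectivity: runs touch if column ranges overlap when widened by 1
        ov <- which(prev_runs$end >= starts[k] - 1L & prev_runs$start <= ends[k] + 1L)
        for (m in ov) {
          pid <- find(prev_runs$id[m])
          if (id == 0L) id <- pid
          else if (pid != id) parent[pid] <- id
        }
      }
      if (id == 0L) {
        next_id <- next_id + 1L
        parent[next_id] <- next_id
        id <- next_id
      }
      ids[k] <- id
      lab[r, starts[k]:ends[k]] <- id
    }
    prev_runs <- if (length(starts)) data.frame(start = starts, end = ends, id = ids)
                 else NULL
  }
  if (next_id > 0L) {
    roots <- vapply(seq_len(next_id), find, integer(1))
    remap <- match(roots, unique(roots))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Count horizontal bars per image row
#'
#' Scans each row of a (stripped) binary lineage image and counts the maximal
#' horizontal runs of ink pixels — the discrete division bars crossing that
#' row. Connectivity is within-row only, so a 2 px-tall bar is counted in
#' both of its rows.
#'
#' @param image Binary 0/1 matrix, typically output of
#'   [strip_narrow_elements()].
#' @return Integer vector `V` of length `nrow(image)`: bar count per row.
#' @examples
#' count_bars_per_row(rbind(c(0, 1, 1, 1, 0, 1, 1, 0)))  # 2
#' @export
count_bars_per_row <- function(image) {
  img <- unclass_image(image)
  ink <- img > 0
  # a run starts where a pixel is ink and its left neighbour is not
  starts <- ink & !cbind(FALSE, ink[, -ncol(ink), drop = FALSE])
  as.integer(rowSums(starts))
}

#' Two-anchor linear time calibration
#'
#' Builds the linear map from image row coordinate to hours of development
#' passing exactly through two anchor points, e.g. the seam-cell division
#' peaks that mark the onset of L2 and L3.
#'
#' @param anchor1,anchor2 Numeric length-2 vectors `c(row, hour)`.
#' @return An object of class `time_calibration` with fields `slope` (h/px),
#'   `intercept` (h at row 0) and `anchors`.
#' @examples
#' cal <- calibrate_time(c(448.5, 16), c(684.5, 25))
#' time_at_row(cal, 1034)  # about 38.33 h
#' @export
calibrate_time <- function(anchor1, anchor2) {
  stopifnot(length(anchor1) == 2L, length(anchor2) == 2L)
  if (anchor1[1L] == anchor2[1L])
    stop("anchor rows must be distinct (slope undefined)")
  if (anchor1[2L] == anchor2[2L])
    stop("anchor hours must be distinct")
  slope <- (anchor2[2L] - anchor1[2L]) / (anchor2[1L] - anchor1[1L])
  intercept <- anchor1[2L] - slope * anchor1[1L]
  structure(
    list(slope = slope, intercept = intercept,
         anchors = rbind(anchor1, anchor2, deparse.level = 0)),
    class = "time_calibration"
  )
}

#' @rdname calibrate_time
#' @param cal A `time_calibration` object.
#' @param row Numeric vector of row coordinates.
#' @export
time_at_row <- function(cal, row) {
  stopifnot(inherits(cal, "time_calibration"))
  cal$intercept + cal$slope * row
}

#' @export
print.time_calibration <- function(x, ...) {
  cat("Two-anchor time calibration\n")
  cat(sprintf("  hour(row) = %.6f + %.6f * row  [h, h/px]\n",
              x$intercept, x$slope))
  cat(sprintf("  anchors: row %.1f -> %g h; row %.1f -> %g h\n",
              x$anchors[1, 1], x$anchors[1, 2], x$anchors[2, 1], x$anchors[2, 2]))
  invisible(x)
}

#' Inverse-kernel smoothing of per-row division counts
#'
#' Smooths the raw per-row bar counts into a division-density curve with an
#' inverse-distance kernel: weight `k_0 = 1` at the centre and
#' `k_j = 1 / |j|^exponent` at offset `j`. Each row's count distributes its
#' kernel mass over the window, with the weights normalized at the source
#' row over the offsets that fall inside the series; total density therefore
#' equals total counts exactly, for any input, including at the boundaries.
#'
#' @param counts Numeric vector of per-row counts `V`.
#' @param half_width Window half-width `w` (in rows); offsets `-w..w`.
#'   `0` returns the counts unchanged.
#' @param exponent Exponent of the inverse-distance weight (default 1).
#' @return Numeric vector of densities, same length as `counts`, with the
#'   kernel weights attached as attribute `"kernel"`.
#' @examples
#' smooth_density(c(0, 0, 4, 0, 0), half_width = 2)
#' @export
smooth_density <- function(counts, half_width = 10L, exponent = 1) {
  stopifnot(half_width >= 0L, is.numeric(counts))
  n <- length(counts)
  w <- as.integer(half_width)
  offs <- seq.int(-w, w)
  k <- ifelse(offs == 0L, 1, 1 / abs(offs)^exponent)
  if (w == 0L || n == 0L) {
    out <- as.numeric(counts)
  } else {
    # per-source normalizer: sum of kernel weights whose destination is in range
    norm <- numeric(n)
    for (j in seq_along(offs)) {
      o <- offs[j]
      dest_ok <- (seq_len(n) + o) >= 1L & (seq_len(n) + o) <= n
      norm <- norm + k[j] * dest_ok
    }
    src <- counts / norm
    out <- numeric(n)
    for (j in seq_along(offs)) {
      o <- offs[j]
      i_dest <- seq_len(n) + o
      ok <- i_dest >= 1L & i_dest <= n
      out[i_dest[ok]] <- out[i_dest[ok]] + k[j] * src[ok]
    }
  }
  attr(out, "kernel") <- stats::setNames(k, offs)
  out
}

#' Division-density pipeline for a lineage diagram image
#'
#' Runs the full diagram-to-density procedure: binarize, delete narrow
#' elements (connectors and death markers), count division bars per row,
#' calibrate rows to developmental hours through two anchors, and smooth the
#' counts with the inverse kernel.
#'
#' @param image Grayscale matrix/array, binary matrix, or path to a PNG file.
#' @param anchors List of two `c(row, hour)` anchors (see [calibrate_time()]).
#' @param threshold Binarization threshold; `NULL` for automatic (Otsu).
#' @param half_width Kernel half-width in rows (default 10).
#' @param max_width_px Deletion width for narrow elements (default 2).
#' @param exponent Kernel exponent (default 1).
#' @param strip_method Passed to [strip_narrow_elements()].
#' @return An object of class `division_density`: a list with `data` (a
#'   data.frame with columns `row`, `time_h`, `count`, `density`),
#'   `calibration`, and the parameters used. Rows are 0-based in the `row`
#'   column, matching image pixel coordinates.
#' @export
lineage_density <- function(image, anchors,
                            threshold = NULL, half_width = 10L,
                            max_width_px = 2L, exponent = 1,
                            strip_method = "run") {
  if (is.character(image)) image <- png::readPNG(image)
  bin <- if (is_binary_matrix(image)) {
    m <- unclass_image(image); storage.mode(m) <- "integer"
    class(m) <- c("lineage_image", class(m)); m
  } else binarize(image, threshold)
  stripped <- strip_narrow_elements(bin, max_width_px, method = strip_method)
  counts <- count_bars_per_row(stripped)
  stopifnot(is.list(anchors), length(anchors) == 2L)
  cal <- calibrate_time(anchors[[1L]], anchors[[2L]])
  density <- smooth_density(counts, half_width, exponent)
  rows0 <- seq_len(nrow(bin)) - 1L  # 0-based pixel rows
  structure(
    list(
      data = data.frame(row = rows0, time_h = time_at_row(cal, rows0),
                        count = counts, density = as.numeric(density)),
      calibration = cal,
      kernel = attr(density, "kernel"),
      params = list(half_width = half_width, max_width_px = max_width_px,
                    exponent = exponent, threshold = threshold,
                    strip_method = strip_method)
    ),
    class = "division_density"
  )
}

# an ink mask (1 = ink) as opposed to a grayscale intensity grid (0 = dark):
# only explicit lineage_image objects or integer 0/1 matrices qualify
is_binary_matrix <- function(x) {
  is.matrix(x) && (inherits(x, "lineage_image") || is.integer(unclass(x))) &&
    all(unclass(x) %in% c(0L, 1L))
}

unclass_image <- function(x) {
  if (inherits(x, "lineage_image")) x <- unclass(x)
  if (!is.matrix(x)) stop("expected a matrix image")
  x
}

#' @export
print.division_density <- function(x, ...) {
  d <- x$data
  cat("Division-density series\n")
  cat(sprintf("  %d rows, %g total division-row counts\n",
              nrow(d), sum(d$count)))
  cat(sprintf("  time span: %.2f - %.2f h; kernel half-width %d\n",
              min(d$time_h), max(d$time_h), x$params$half_width))
  pk <- d$row[which.max(d$count)]
  cat(sprintf("  highest raw count %d at row %d (%.2f h)\n",
              max(d$count), pk, d$time_h[which.max(d$count)]))
  invisible(x)
}

#' @export
summary.division_density <- function(object, ...) {
  d <- object$data
  structure(list(
    n_rows = nrow(d),
    total_counts = sum(d$count),
    total_density = sum(d$density),
    peak_row = d$row[which.max(d$count)],
    peak_time_h = d$time_h[which.max(d$count)],
    time_range_h = range(d$time_h)
  ), class = "summary.division_density")
}

#' @export
print.summary.division_density <- function(x, ...) {
  cat(sprintf(
    "Division density: %d rows; sum(counts) = %g, sum(density) = %g\n",
    x$n_rows, x$total_counts, x$total_density))
  cat(sprintf("  raw-count peak at row %d (%.2f h); span %.2f-%.2f h\n",
              x$peak_row, x$peak_time_h, x$time_range_h[1], x$time_range_h[2]))
  invisible(x)
}

#' @export
as.data.frame.division_density <- function(x, ...) x$data

#' @export
plot.division_density <- function(x, ...) {
  d <- x$data
  graphics::plot(d$time_h, d$density, type = "l",
                 xlab = "time post hatching (h)",
                 ylab = "division density (events/row)", ...)
  graphics::rug(d$time_h[d$count > 0])
  invisible(x)
}
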