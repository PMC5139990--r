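# Shoebox serialization.  The container is JSON lines: one object per
# shoebox with row-major integer `counts` and `mask` arrays plus truth
# metadata, so datasets stream and diff cleanly.  A per-pixel CSV export
# is provided for interoperability with table-oriented tools.

shoebox_to_record <- function(sb) {
  list(id = if (is.null(sb$id)) NA_integer_ else sb$id,
       width = ncol(sb$counts), height = nrow(sb$counts),
       peak = sb$peak,
       counts = as.integer(t(sb$counts)),   # row-major
       mask = as.integer(t(sb$mask)),
       truth = sb$truth)
}

record_to_shoebox <- function(rec) {
  h <- rec$height; w <- rec$width
  truth <- rec$truth
  if (!is.null(truth$outliers)) {
    truth$outliers$hot <- as.integer(unlist(truth$outliers$hot))
    truth$outliers$zinger <- as.integer(unlist(truth$outliers$zinger))
  }
  structure(list(counts = matrix(as.integer(rec$counts), h, w, byrow = TRUE),
                 mask = matrix(as.integer(rec$mask), h, w, byrow = TRUE),
                 peak = as.numeric(rec$peak),
                 truth = truth,
                 id = if (is.null(rec$id) || is.na(rec$id)) NULL
                      else as.integer(rec$id)),
            class = "shoebox")
}

#' Read and write shoebox collections (JSON lines)
#'
#' One JSON object per line; `counts` and `mask` are row-major integer
#' arrays, `peak` the peak pixel coordinate, `truth` the generating
#' parameters when the shoebox is synthetic.  Writing then reading
#' reproduces the collection exactly.
#'
#' @param x A `"shoebox"`, list of shoeboxes or `"shoebox_set"`.
#' @param path File path.
#' @return `read_shoeboxes()` returns a `"shoebox_set"`;
#'   `write_shoeboxes()` returns `path` invisibly.
#' @export
write_shoeboxes <- function(x, path) {
  if (inherits(x, "shoebox")) x <- list(x)
  lines <- vapply(x, function(sb)
    as.character(jsonlite::toJSON(shoebox_to_record(sb),
                                  auto_unbox = TRUE, digits = NA,
                                  null = "null")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_shoeboxes
#' @export
read_shoeboxes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  out <- lapply(lines, function(l)
    record_to_shoebox(jsonlite::fromJSON(l, simplifyVector = TRUE)))
  structure(out, class = "shoebox_set")
}

#' Per-pixel table of a shoebox collection
#'
#' @param x A list of shoeboxes.
#' @return Data frame with one row per pixel: `shoebox_id`, `x`, `y`
#'   (absolute pixel coordinates), `counts` and `label`
#'   (`"background"`, `"foreground"` or `"invalid"`).
#' @export
shoeboxes_to_pixel_table <- function(x) {
  if (inherits(x, "shoebox")) x <- list(x)
  labels <- c("background", "foreground", "invalid")
  do.call(rbind, lapply(seq_along(x), function(i) {
    sb <- x[[i]]
    g <- coord_grids(ncol(sb$counts), nrow(sb$counts))
    data.frame(shoebox_id = if (is.null(sb$id)) i else sb$id,
               x = as.vector(g$x), y = as.vector(g$y),
               counts = as.vector(sb$counts),
               label = labels[as.vector(sb$mask) + 1L])
  }))
}
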