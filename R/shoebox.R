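# Synthetic reflection shoeboxes with known ground truth.
#
# A shoebox is the small pixel neighbourhood around a predicted Bragg
# peak.  Pixel centres sit at integer coordinates with x = column
# (1..width) and y = row (1..height); the peak position is the grid
# centre by default.  The mask labels each pixel as background (0),
# foreground (1) or invalid (2).

MASK_BACKGROUND <- 0L
MASK_FOREGROUND <- 1L
MASK_INVALID <- 2L

#' Specification of a synthetic shoebox
#'
#' @param width,height Grid size in pixels; `width * height >= 9`.
#' @param background Either a single positive rate `lambda`
#'   (counts/pixel, constant model) or a length-3 numeric
#'   `c(a, b, c)` giving a log-plane
#'   `mu(x, y) = exp(a + b dx + c dy)` with `(dx, dy)` relative to the
#'   peak position.
#' @param peak `NULL`, or `list(counts =, sigma =)`: expected total
#'   photon counts of a discretized isotropic Gaussian peak with spread
#'   `sigma` (pixels), centred on the peak position and deposited on
#'   the foreground pixels.
#' @param foreground `NULL` for no foreground region (all pixels are
#'   background -- the default when there is no peak), `"ellipse"` for a
#'   central ellipse of semi-axes `fg_radius` (default 1.5 px: a 3x3
#'   block on the default 9x9 grid -- typical MX shoebox scale), or an
#'   explicit logical matrix of dim `height x width`.  A peak implies
#'   `"ellipse"` unless given.
#' @param fg_radius Semi-axes of the foreground ellipse, length 1 or 2
#'   `(rx, ry)`.
#' @param outliers `NULL` or `list(n_hot =, hot_value =, zinger_prob =,
#'   zinger_scale =)`; see [inject_outliers()].
#' @param seed Optional integer seed used by [simulate_shoebox()].
#' @return An object of class `"shoebox_spec"`.
#' @export
shoebox_spec <- function(width = 9, height = 9, background = 1,
                         peak = NULL, foreground = NULL,
                         fg_radius = 1.5, outliers = NULL, seed = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (width * height < 9) stop("shoebox must contain at least 9 pixels")
  if (!length(background) %in% c(1, 3))
    stop("`background` must be a rate or log-plane coefficients (a, b, c)")
  if (length(background) == 1 && background < 0)
    stop("background rate `lambda` must be non-negative")
  if (!is.null(peak)) {
    if (is.null(peak$counts) || is.null(peak$sigma) ||
        peak$counts < 0 || peak$sigma <= 0)
      stop("`peak` must be list(counts >= 0, sigma > 0)")
    if (is.null(foreground)) foreground <- "ellipse"
  }
  if (length(fg_radius) == 1) fg_radius <- rep(fg_radius, 2)
  structure(list(width = width, height = height,
                 background = as.numeric(background), peak = peak,
                 foreground = foreground, fg_radius = fg_radius,
                 outliers = outliers, seed = seed),
            class = "shoebox_spec")
}

peak_position <- function(spec) c(ceiling(spec$width / 2),
                                  ceiling(spec$height / 2))

# height x width matrices of pixel-centre coordinates
coord_grids <- function(width, height) {
  list(x = matrix(rep(seq_len(width), each = height), height, width),
       y = matrix(rep(seq_len(height), width), height, width))
}

build_mask <- function(spec) {
  mask <- matrix(MASK_BACKGROUND, spec$height, spec$width)
  fg <- spec$foreground
  if (is.null(fg)) return(mask)
  if (is.matrix(fg)) {
    if (!all(dim(fg) == c(spec$height, spec$width)))
      stop("foreground mask dimensions must match the shoebox")
    mask[fg] <- MASK_FOREGROUND
    return(mask)
  }
  if (!identical(fg, "ellipse")) stop("unknown foreground specification")
  ctr <- peak_position(spec)
  g <- coord_grids(spec$width, spec$height)
  inside <- ((g$x - ctr[1]) / spec$fg_radius[1])^2 +
    ((g$y - ctr[2]) / spec$fg_radius[2])^2 <= 1
  if (!any(inside) || all(inside))
    stop("invalid mask geometry: foreground ellipse covers none or all pixels")
  mask[inside] <- MASK_FOREGROUND
  mask
}

background_mean_grid <- function(spec) {
  ctr <- peak_position(spec)
  g <- coord_grids(spec$width, spec$height)
  if (length(spec$background) == 1)
    matrix(spec$background, spec$height, spec$width)
  else
    exp(spec$background[1] + spec$background[2] * (g$x - ctr[1]) +
          spec$background[3] * (g$y - ctr[2]))
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a reflection shoebox
#'
#' Background pixels receive independent Poisson counts with the
#' spec's per-pixel mean; foreground pixels additionally receive
#' independent Poisson counts whose means follow a discretized isotropic
#' Gaussian normalized over the foreground region, so the expected total
#' peak signal equals `peak$counts`.  Outliers, if specified, are then
#' injected via [inject_outliers()].  Fully reproducible for a given
#' seed.
#'
#' @param spec A [shoebox_spec()].
#' @param seed Integer seed (defaults to `spec$seed`; `NULL` uses the
#'   current RNG stream).
#' @return An object of class `"shoebox"`: integer `counts` and `mask`
#'   matrices, the `peak` position, and a `truth` list with the
#'   generating parameters.
#' @export
simulate_shoebox <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "shoebox_spec"))
  with_seed(seed, {
    mask <- build_mask(spec)
    mu_bg <- background_mean_grid(spec)
    counts <- matrix(rpois(length(mu_bg), mu_bg),
                     spec$height, spec$width)
    if (!is.null(spec$peak) && spec$peak$counts > 0) {
      ctr <- peak_position(spec)
      g <- coord_grids(spec$width, spec$height)
      w <- exp(-((g$x - ctr[1])^2 + (g$y - ctr[2])^2) /
                 (2 * spec$peak$sigma^2))
      fg <- mask == MASK_FOREGROUND
      if (!any(fg)) stop("peak requested but foreground mask is empty")
      w[!fg] <- 0
      w <- w / sum(w)
      counts[fg] <- counts[fg] + rpois(sum(fg), spec$peak$counts * w[fg])
    }
    sb <- structure(list(counts = counts, mask = mask,
                         peak = peak_position(spec),
                         truth = list(background = spec$background,
                                      kind = if (length(spec$background) == 1)
                                        "constant" else "planar",
                                      peak = spec$peak, seed = seed,
                                      outliers = NULL)),
                    class = "shoebox")
    if (!is.null(spec$outliers)) sb <- inject_outliers(sb, spec$outliers)
    sb
  })
}

#' Inject outlier pixels into a shoebox
#'
#' Hot pixels: `n_hot` distinct background pixels are overwritten with
#' the constant `hot_value` (defective pixels always reporting a large
#' count).  Zingers: each background pixel independently gains
#' `Poisson(zinger_scale)` extra counts with probability `zinger_prob`
#' (cosmic-ray-like random spikes).  Foreground pixels are never touched
#' unless `include_foreground = TRUE`.  Ground-truth outlier positions
#' are recorded in `truth$outliers` (linear indices into the count
#' matrix).
#'
#' @param sb A `"shoebox"`.
#' @param outliers `list(n_hot = 0, hot_value = 65535, zinger_prob = 0,
#'   zinger_scale = 50)`; missing entries take these defaults.
#' @param include_foreground Allow outliers on foreground pixels.
#' @param seed Optional seed.
#' @return The modified shoebox.
#' @export
inject_outliers <- function(sb, outliers, include_foreground = FALSE,
                            seed = NULL) {
  stopifnot(inherits(sb, "shoebox"))
  o <- utils::modifyList(list(n_hot = 0L, hot_value = 65535L,
                              zinger_prob = 0, zinger_scale = 50),
                         as.list(outliers))
  with_seed(seed, {
    eligible <- if (include_foreground) seq_along(sb$counts)
                else which(sb$mask == MASK_BACKGROUND)
    hot_idx <- integer(0)
    if (o$n_hot > 0) {
      if (o$n_hot > length(eligible))
        stop("n_hot exceeds the number of eligible background pixels")
      hot_idx <- sample(eligible, o$n_hot)
      sb$counts[hot_idx] <- as.integer(o$hot_value)
    }
    zing_idx <- integer(0)
    if (o$zinger_prob > 0) {
      hit <- eligible[runif(length(eligible)) < o$zinger_prob]
      zing_idx <- hit
      if (length(hit) > 0)
        sb$counts[hit] <- sb$counts[hit] +
          rpois(length(hit), o$zinger_scale)
    }
    sb$truth$outliers <- list(hot = hot_idx, zinger = zing_idx,
                              spec = o)
    sb
  })
}

#' @rdname shoebox_accessors
#' @name shoebox_accessors
#' @title Shoebox pixel accessors
#' @description `background_counts()` / `foreground_counts()` extract
#'   the counts of the pixels with the corresponding mask label;
#'   `background_coords()` returns their `(x, y)` pixel coordinates
#'   relative to the peak position (the planar-model origin).
#' @param sb A `"shoebox"`.
#' @return Numeric vector of counts, or a data frame with `x`, `y`.
#' @export
background_counts <- function(sb) as.numeric(sb$counts[sb$mask == MASK_BACKGROUND])

#' @rdname shoebox_accessors
#' @export
foreground_counts <- function(sb) as.numeric(sb$counts[sb$mask == MASK_FOREGROUND])

#' @rdname shoebox_accessors
#' @export
background_coords <- function(sb) {
  g <- coord_grids(ncol(sb$counts), nrow(sb$counts))
  idx <- sb$mask == MASK_BACKGROUND
  data.frame(x = g$x[idx] - sb$peak[1], y = g$y[idx] - sb$peak[2])
}

foreground_coords <- function(sb) {
  g <- coord_grids(ncol(sb$counts), nrow(sb$counts))
  idx <- sb$mask == MASK_FOREGROUND
  data.frame(x = g$x[idx] - sb$peak[1], y = g$y[idx] - sb$peak[2])
}

#' Summation integration of a shoebox
#'
#' Reflection intensity by summation: total foreground counts minus the
#' modelled background summed over the foreground region.  The variance
#' is `sum(foreground counts) + sum(modelled background)`: the Poisson
#' variance of the foreground total plus the Poisson variance the
#' background model attributes to the subtracted pedestal (estimation
#' error of the background parameters is not propagated).
#'
#' @param sb A `"shoebox"` with a non-empty foreground.
#' @param background The background model: a scalar (counts/pixel), a
#'   length-3 count-scale plane `c(a, b, c)` over peak-relative
#'   coordinates, or a `"bg_fit"` from [robust_glm_fit()].
#' @return `list(intensity =, variance =)`.
#' @export
summation_integrate <- function(sb, background) {
  stopifnot(inherits(sb, "shoebox"))
  fg <- sb$mask == MASK_FOREGROUND
  if (!any(fg)) stop("foreground mask is empty")
  if (missing(background) || is.null(background))
    stop("a background estimate is required")
  co <- foreground_coords(sb)
  bg_fg <-
    if (inherits(background, "bg_fit")) {
      if (background$degenerate) rep(0, nrow(co))
      else if (background$model$kind == "constant")
        rep(exp(background$beta[1]), nrow(co))
      else exp(background$beta[1] + background$beta[2] * co$x +
                 background$beta[3] * co$y)
    } else if (length(background) == 3) {
      background[1] + background[2] * co$x + background[3] * co$y
    } else if (length(background) == 1) {
      rep(background, nrow(co))
    } else stop("unrecognized background estimate")
  total <- sum(sb$counts[fg])
  list(intensity = total - sum(bg_fg),
       variance = total + sum(pmax(bg_fg, 0)))
}

# Deterministic per-index sub-seed: a splitmix-style multiplicative hash
# of (seed, index) on the 31-bit prime field, so dataset reproducibility
# does not depend on iteration order.  mulmod31 does modular
# multiplication without exceeding double precision.
mulmod31 <- function(a, b, m = 2147483647) {
  b1 <- b %/% 65536; b0 <- b %% 65536
  (((a * b1) %% m) * 65536 + a * b0) %% m
}

sub_seed <- function(seed, i) {
  m <- 2147483647
  h <- (abs(seed) + mulmod31(i %% m, 2654435761 %% m)) %% m
  h <- mulmod31(h + 1, 40503)
  h <- mulmod31(h + 1, 2246822519 %% m)
  as.integer(h %% (m - 1) + 1)
}

#' Simulate a dataset of shoeboxes
#'
#' Generates `n` independent shoeboxes.  Each shoebox uses a sub-seed
#' derived deterministically from `(seed, index)` by an integer hash, so
#' the collection is reproducible and any single member can be
#' regenerated in isolation.
#'
#' @param n Number of shoeboxes.
#' @param spec A [shoebox_spec()], or a function `f(i)` returning the
#'   spec for shoebox `i`.
#' @param seed Integer master seed.
#' @return A list of `"shoebox"` objects (class `"shoebox_set"`), each
#'   carrying its `id` and sub-seed.
#' @export
simulate_dataset <- function(n, spec, seed = 1L) {
  if (n < 1) stop("`n` must be at least 1")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- if (is.function(spec)) spec(i) else spec
    sb <- simulate_shoebox(sp, seed = sub_seed(seed, i))
    sb$id <- i
    out[[i]] <- sb
  }
  structure(out, class = "shoebox_set", seed = seed)
}
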