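#' Study-area geometry
#'
#' The study plane is a local planar coordinate system in km.  Detection
#' is possible only inside the `total` region; the nested `core` region
#' is monitored intensively (higher detection).  Regions are axis-aligned
#' rectangles `c(xmin, xmax, ymin, ymax)` by default; either may instead
#' be given as a WKT `POLYGON` string (requires the mgcv package for
#' point-in-polygon tests).  The default geometry mirrors a ~60 km^2
#' total area with a ~40 km^2 core: total 10 x 6 km, core 8 x 5 km.
#'
#' @param total rectangle `c(xmin, xmax, ymin, ymax)` in km, or a WKT
#'   POLYGON string.
#' @param core region contained in `total`, same formats.
#' @return object of class `study_area`.
#' @examples
#' area <- study_area()
#' area_km2(area)
#' @export
study_area <- function(total = c(0, 10, 0, 6), core = c(1, 9, 0.5, 5.5)) {
  parse_region <- function(r, what) {
    if (is.character(r)) {
      poly <- parse_wkt_polygon(r)
      return(structure(list(kind = "polygon", poly = poly), what = what))
    }
    if (!is.numeric(r) || length(r) != 4L || r[1] >= r[2] || r[3] >= r[4]) {
      stop(sprintf("'%s' must be c(xmin, xmax, ymin, ymax) with positive extent, or WKT", what))
    }
    structure(list(kind = "rect", rect = as.numeric(r)), what = what)
  }
  area <- structure(list(total = parse_region(total, "total"),
                         core = parse_region(core, "core")),
                    class = "study_area")
  # core must be contained in total: check on a grid of core points
  pts <- region_grid(area$core, n = 25L)
  if (!all(point_in_region(pts[, 1], pts[, 2], area$total))) {
    stop("'core' region must be contained in 'total'")
  }
  area
}

# vertices / sample grid of a region, used for containment checks
region_grid <- function(region, n = 25L) {
  if (region$kind == "rect") {
    r <- region$rect
    g <- expand.grid(x = seq(r[1], r[2], length.out = n),
                     y = seq(r[3], r[4], length.out = n))
    as.matrix(g)
  } else {
    region$poly
  }
}

#' @export
print.study_area <- function(x, ...) {
  fmt <- function(r) {
    if (r$kind == "rect") sprintf("rect [%g, %g] x [%g, %g]", r$rect[1], r$rect[2], r$rect[3], r$rect[4])
    else sprintf("polygon (%d vertices)", nrow(r$poly))
  }
  cat("Study area (km): total", fmt(x$total), "| core", fmt(x$core), "\n")
  invisible(x)
}

#' Area of the total and core regions in km^2
#' @param area a [study_area] object.
#' @return named numeric `c(total =, core =)`.
#' @export
area_km2 <- function(area) {
  one <- function(r) {
    if (r$kind == "rect") (r$rect[2] - r$rect[1]) * (r$rect[4] - r$rect[3])
    else {  # shoelace
      p <- r$poly
      abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2])) / 2
    }
  }
  c(total = one(area$total), core = one(area$core))
}

# minimal WKT POLYGON reader (outer ring only)
parse_wkt_polygon <- function(wkt) {
  s <- gsub("^\\s*POLYGON\\s*\\(\\(", "", toupper(trimws(wkt)))
  s <- sub("\\)\\).*$", "", s)
  parts <- strsplit(strsplit(s, ",")[[1]], "\\s+")
  xy <- t(vapply(parts, function(p) as.numeric(p[nzchar(p)][1:2]), numeric(2)))
  if (nrow(xy) < 3L || any(!is.finite(xy))) stop("cannot parse WKT polygon: ", wkt)
  # drop closing vertex if repeated
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  colnames(xy) <- c("x", "y")
  xy
}

point_in_region <- function(x, y, region) {
  if (region$kind == "rect") {
    r <- region$rect
    x >= r[1] & x <= r[2] & y >= r[3] & y <= r[4]
  } else {
    if (!requireNamespace("mgcv", quietly = TRUE)) {
      stop("polygon study areas require the 'mgcv' package")
    }
    mgcv::in.out(rbind(region$poly, region$poly[1, ]), cbind(x, y))
  }
}

#' Movement parameters
#'
#' Inter-annual movement is a random walk with independent Student-t
#' steps of scale `sigma` (km) in x and y, with fixed degrees of freedom
#' (default 5) giving heavy tails.  Breeders additionally stay at exactly
#' the same site with probability `p_stay` (site fidelity, per current
#' habitat); fledglings always move (`p_stay = 0` for natal dispersal).
#' Scales differ by age class and habitat; all parameters are constant
#' across years.
#'
#' @param sigma_fl natal-dispersal scale per habitat (km), length 2.
#' @param sigma_br breeding-dispersal scale per habitat (km), length 2.
#' @param p_stay breeder site-fidelity probability per habitat.
#' @param df Student-t degrees of freedom (default 5).
#' @return object of class `movement_params`.
#' @export
movement_params <- function(sigma_fl = c(1.0, 1.5), sigma_br = c(0.3, 0.5),
                            p_stay = c(0.55, 0.35), df = 5) {
  stopifnot(df > 0)
  structure(list(
    sigma_fl = check_habitat_vector(sigma_fl, "sigma_fl", 1e-12, Inf),
    sigma_br = check_habitat_vector(sigma_br, "sigma_br", 1e-12, Inf),
    p_stay   = check_habitat_vector(p_stay, "p_stay", 0, 1),
    df       = as.numeric(df)
  ), class = "movement_params")
}

movement_sigma <- function(params, age, habitat) {
  sig <- if (age == "fledgling") params$sigma_fl else params$sigma_br
  sig[[habitat]]
}

movement_pstay <- function(params, age, habitat) {
  if (age == "fledgling") 0 else params$p_stay[[habitat]]  # no fidelity for natal dispersal
}

#' Log density of the dispersal kernel
#'
#' The yearly step is Student-t in each axis independently, with common
#' scale `sigma` and `df` degrees of freedom:
#' `log T((x' - x)/sigma; df) + log T((y' - y)/sigma; df) - 2 log sigma`.
#'
#' @param dest,origin locations `c(x, y)` in km (or 2-column matrices).
#' @param sigma kernel scale in km, > 0.
#' @param df degrees of freedom, > 0 (default 5).
#' @return log density (vectorised over rows).
#' @export
kernel_logdensity <- function(dest, origin, sigma, df = 5) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0 (sigma = 0 arises only through site fidelity)")
  if (df <= 0) stop("'df' must be > 0")
  d <- rbind_xy(dest) - rbind_xy(origin)
  dt(d[, 1] / sigma, df, log = TRUE) + dt(d[, 2] / sigma, df, log = TRUE) -
    2 * log(sigma)
}

rbind_xy <- function(p) {
  if (is.matrix(p)) p else matrix(p, ncol = 2L)
}

#' Sample the next-year location
#'
#' Breeders stay at exactly the origin with probability `p_stay` of the
#' current habitat; otherwise (and always for fledglings, whose first
#' transition is natal dispersal) the new location is the origin plus an
#' independent Student-t step in each axis.
#'
#' @param origin location `c(x, y)` in km.
#' @param age `"fledgling"` or `"breeder"` (age at the start of the
#'   transition).
#' @param habitat `"Short"` or `"Tall"` (habitat at the origin).
#' @param params a [movement_params] object.
#' @param n number of independent transitions to draw.
#' @return list with `loc` (n x 2 matrix) and `stay` (integer 0/1
#'   vector).
#' @export
sample_next_location <- function(origin, age, habitat, params, n = 1L) {
  age <- match.arg(age, c("fledgling", "breeder"))
  habitat <- match.arg(habitat, HABITATS)
  ps <- movement_pstay(params, age, habitat)
  sig <- movement_sigma(params, age, habitat)
  stay <- rbinom(n, 1L, ps)
  loc <- matrix(rep(as.numeric(origin[1:2]), each = n), ncol = 2L)
  mv <- stay == 0L
  nm <- sum(mv)
  if (nm > 0) {
    loc[mv, 1] <- loc[mv, 1] + sig * rt(nm, params$df)
    loc[mv, 2] <- loc[mv, 2] + sig * rt(nm, params$df)
  }
  colnames(loc) <- c("x", "y")
  list(loc = loc, stay = stay)
}

#' Individual emigration probability
#'
#' Probability that an individual's next-year location falls outside the
#' total study area (where detection is zero, so the move is a permanent
#' emigration from the monitored population):
#' `(1 - p_stay) * Pr(origin + t-step outside total)`,
#' estimated by Monte-Carlo integration of the dispersal kernel.
#'
#' @param origin location `c(x, y)` inside the total area.
#' @param age,habitat stratum of the individual at the origin.
#' @param params a [movement_params] object.
#' @param area a [study_area] object.
#' @param n_mc Monte-Carlo sample size (>= 1e4 recommended).
#' @return scalar probability in \[0, 1\].
#' @export
emigration_probability <- function(origin, age, habitat, params, area,
                                   n_mc = 1e4) {
  if (!point_in_region(origin[1], origin[2], area$total)) {
    stop("'origin' must lie inside the total study area")
  }
  ps <- movement_pstay(params, age, habitat)
  if (ps >= 1) return(0)
  sig <- movement_sigma(params, age, habitat)
  x <- origin[1] + sig * rt(n_mc, params$df)
  y <- origin[2] + sig * rt(n_mc, params$df)
  (1 - ps) * mean(!point_in_region(x, y, area$total))
}

#' Population-level emigration rates by stratum
#'
#' Arithmetic mean of [emigration_probability()] over a set of origin
#' locations (e.g. observed or posterior-sampled breeding/natal sites),
#' stratified by age class and habitat.
#'
#' @param origins data.frame with columns `x`, `y`, `age`
#'   (fledgling/breeder) and `habitat` (Short/Tall).
#' @param params a [movement_params] object.
#' @param area a [study_area] object.
#' @param n_mc Monte-Carlo sample size per origin.
#' @return data.frame with one row per age x habitat stratum and the mean
#'   emigration rate (`NA` with a warning for empty strata).
#' @export
population_emigration_rate <- function(origins, params, area, n_mc = 1e4) {
  stopifnot(is.data.frame(origins), nrow(origins) > 0,
            all(c("x", "y", "age", "habitat") %in% names(origins)))
  grid <- expand.grid(age = c("fledgling", "breeder"), habitat = HABITATS,
                      stringsAsFactors = FALSE)
  grid$rate <- NA_real_
  grid$n <- 0L
  for (k in seq_len(nrow(grid))) {
    sel <- origins$age == grid$age[k] & origins$habitat == grid$habitat[k]
    grid$n[k] <- sum(sel)
    if (!any(sel)) next
    sub <- origins[sel, , drop = FALSE]
    grid$rate[k] <- mean(vapply(seq_len(nrow(sub)), function(i) {
      emigration_probability(c(sub$x[i], sub$y[i]), grid$age[k],
                             grid$habitat[k], params, area, n_mc = n_mc)
    }, numeric(1)))
  }
  if (any(grid$n == 0L)) {
    warning("empty strata flagged as missing (NA): ",
            paste(grid$age[grid$n == 0], grid$habitat[grid$n == 0],
                  sep = "/", collapse = ", "))
  }
  grid
}
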