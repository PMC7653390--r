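#' Planar regions
#'
#' Regions are the geometric building blocks of a scenario: the waiting area,
#' the source and target areas, and obstacles. A region is either an
#' axis-aligned rectangle or a simple polygon; all coordinates are metres.
#' Containment uses the closed-set convention: points on the boundary are
#' inside.
#'
#' @param xmin,ymin,xmax,ymax rectangle extent in metres.
#' @return an object of class `ccoop_region`.
#' @examples
#' a <- region_rect(0, 0, 1.55, 1.70)
#' region_area(a)
#' @export
region_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax), is.numeric(ymax))
  if (!(xmax > xmin && ymax > ymin)) {
    stop("degenerate rectangle: need xmax > xmin and ymax > ymin")
  }
  structure(
    list(
      kind = "rectangle",
      vertices = matrix(
        c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
        ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y"))
      )
    ),
    class = "ccoop_region"
  )
}

#' @rdname region_rect
#' @param vertices n x 2 numeric matrix of polygon vertices (counter-clockwise
#'   or clockwise, not closed).
#' @export
region_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(is.numeric(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  colnames(vertices) <- c("x", "y")
  reg <- structure(list(kind = "polygon", vertices = vertices), class = "ccoop_region")
  if (region_area(reg) <= 0) stop("degenerate polygon: area must be > 0")
  reg
}

is_region <- function(x) inherits(x, "ccoop_region")

rect_bounds <- function(region) {
  v <- region$vertices
  c(
    xmin = min(v[, 1]), ymin = min(v[, 2]),
    xmax = max(v[, 1]), ymax = max(v[, 2])
  )
}

#' Region area
#'
#' Shoelace formula; exact for rectangles.
#'
#' @param region a `ccoop_region`.
#' @return area in square metres.
#' @export
region_area <- function(region) {
  stopifnot(is_region(region))
  v <- region$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Region centroid
#'
#' @param region a `ccoop_region`.
#' @return length-2 numeric `c(x, y)`.
#' @export
region_centroid <- function(region) {
  stopifnot(is_region(region))
  if (region$kind == "rectangle") {
    b <- rect_bounds(region)
    return(unname(c((b["xmin"] + b["xmax"]) / 2, (b["ymin"] + b["ymax"]) / 2)))
  }
  v <- region$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  c(sum((v[, 1] + v[j, 1]) * cr) / (6 * a), sum((v[, 2] + v[j, 2]) * cr) / (6 * a))
}

#' Point-in-region test (closed set)
#'
#' @param region a `ccoop_region`.
#' @param xy numeric length-2 point or n x 2 matrix.
#' @return logical vector, one entry per point; boundary points count as inside.
#' @export
region_contains <- function(region, xy) {
  stopifnot(is_region(region))
  xy <- rbind_points(xy)
  if (region$kind == "rectangle") {
    b <- rect_bounds(region)
    return(xy[, 1] >= b["xmin"] & xy[, 1] <= b["xmax"] &
             xy[, 2] >= b["ymin"] & xy[, 2] <= b["ymax"])
  }
  vapply(seq_len(nrow(xy)), function(i) point_in_polygon(xy[i, ], region$vertices),
         logical(1))
}

# Ray casting with an explicit on-edge check so the boundary is inside.
point_in_polygon <- function(p, v, tol = 1e-12) {
  n <- nrow(v)
  j <- c(2:n, 1)
  for (k in seq_len(n)) {
    if (point_seg_dist(p, v[k, ], v[j[k], ]) <= tol) return(TRUE)
  }
  inside <- FALSE
  for (k in seq_len(n)) {
    a <- v[k, ]; b <- v[j[k], ]
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (p[1] < xint) inside <- !inside
    }
  }
  inside
}

point_seg_dist <- function(p, a, b) {
  ab <- b - a
  den <- sum(ab * ab)
  if (den == 0) return(sqrt(sum((p - a)^2)))  # degenerate segment
  t <- min(1, max(0, sum((p - a) * ab) / den))
  sqrt(sum((a + t * ab - p)^2))
}

#' Distance from points to a region
#'
#' Euclidean distance to the nearest point of the region; 0 for points inside
#' (closed set). This is the target potential of the locomotion layer and the
#' clearance test against obstacles.
#'
#' @param xy numeric length-2 point or n x 2 matrix.
#' @param region a `ccoop_region`.
#' @return numeric vector of distances in metres.
#' @export
region_distance <- function(xy, region) {
  stopifnot(is_region(region))
  xy <- rbind_points(xy)
  if (region$kind == "rectangle") {
    b <- rect_bounds(region)
    dx <- pmax(b["xmin"] - xy[, 1], 0, xy[, 1] - b["xmax"])
    dy <- pmax(b["ymin"] - xy[, 2], 0, xy[, 2] - b["ymax"])
    return(unname(sqrt(dx^2 + dy^2)))
  }
  v <- region$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  vapply(seq_len(nrow(xy)), function(i) {
    p <- xy[i, ]
    if (point_in_polygon(p, v)) return(0)
    min(vapply(seq_len(n), function(k) point_seg_dist(p, v[k, ], v[j[k], ]), numeric(1)))
  }, numeric(1))
}

rbind_points <- function(xy) {
  if (is.null(dim(xy))) {
    stopifnot(length(xy) == 2)
    xy <- matrix(xy, ncol = 2)
  }
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, is.numeric(xy))
  xy
}

#' @export
print.ccoop_region <- function(x, ...) {
  b <- rect_bounds(x)
  cat(sprintf(
    "<region:%s> area %.3f m^2, bbox [%.2f, %.2f] x [%.2f, %.2f]\n",
    x$kind, region_area(x), b["xmin"], b["xmax"], b["ymin"], b["ymax"]
  ))
  invisible(x)
}
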