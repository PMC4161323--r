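#' Planar polygon geometry
#'
#' All geometry in this package is planar Euclidean in a single projected
#' coordinate reference system with metre units (an OSGB-style easting /
#' northing system). A coastline is represented as a land polygon: a list
#' with elements \code{rings} (list of two-column matrices, the first ring
#' the outer boundary, any further rings holes) or, for convenience, a
#' single two-column matrix taken as one outer ring.
#'
#' @name seasens-geometry
#' @keywords internal
NULL

#' Parse a WKT POLYGON into a land polygon
#'
#' Supports \code{POLYGON ((...))} with optional interior rings. Coordinates
#' are metres in the projected CRS.
#'
#' @param wkt character scalar of WKT.
#' @return A land polygon: \code{list(rings = list(matrix, ...))}.
#' @export
parse_wkt_polygon <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1L)
  wkt <- trimws(wkt)
  if (!grepl("^POLYGON", wkt, ignore.case = TRUE))
    stop("only WKT POLYGON is supported")
  body <- sub("^POLYGON\\s*\\(", "", wkt, ignore.case = TRUE)
  body <- sub("\\)$", "", body)
  ring_strings <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1]]
  if (length(ring_strings) == 0L) stop("malformed WKT: no rings found")
  rings <- lapply(ring_strings, function(rs) {
    rs <- gsub("[()]", "", rs)
    pts <- strsplit(trimws(strsplit(rs, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    if (anyNA(m)) stop("malformed WKT: non-numeric coordinate")
    m
  })
  as_land_polygon(rings)
}

#' @rdname parse_wkt_polygon
#' @param rings a two-column matrix or list of such matrices.
#' @export
as_land_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  if (is.list(rings) && !is.null(rings$rings)) return(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L)
      stop("each ring needs >= 3 vertices with 2 columns")
    # drop duplicated closing vertex; rings are treated as implicitly closed
    if (all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop("degenerate ring")
    r
  })
  structure(list(rings = rings), class = "land_polygon")
}

# signed shoelace area of an open ring (m^2); sign gives orientation
ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

# ray-casting point-in-ring test (boundary counts as inside)
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    crossings <- which((y > py[k]) != (y[j] > py[k]))
    xi <- x[j][crossings] +
      (py[k] - y[j][crossings]) / (y[crossings] - y[j][crossings]) *
      (x[crossings] - x[j][crossings])
    inside[k] <- sum(px[k] < xi, na.rm = TRUE) %% 2L == 1L
  }
  inside
}

#' Test whether points lie on land
#'
#' @param x,y numeric vectors of planar coordinates (m).
#' @param land a land polygon (see [as_land_polygon()]).
#' @return logical vector.
#' @export
point_on_land <- function(x, y, land) {
  land <- as_land_polygon(land)
  inside <- point_in_ring(x, y, land$rings[[1L]])
  if (length(land$rings) > 1L) {
    for (h in land$rings[-1L]) inside <- inside & !point_in_ring(x, y, h)
  }
  inside
}

# Sutherland-Hodgman clip of a (possibly concave) ring against an axis-aligned
# rectangle; returns an open ring matrix or NULL if the intersection is empty.
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_edge <- function(poly, keep, intersect) {
    if (is.null(poly) || nrow(poly) == 0L) return(NULL)
    n <- nrow(poly)
    out <- matrix(numeric(0), ncol = 2L)
    prev <- poly[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- poly[i, ]
      cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    if (nrow(out) == 0L) NULL else out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  poly <- ring
  poly <- clip_edge(poly, function(p) p[1L] >= xmin, function(p, q) ix(p, q, xmin, 1L))
  poly <- clip_edge(poly, function(p) p[1L] <= xmax, function(p, q) ix(p, q, xmax, 1L))
  poly <- clip_edge(poly, function(p) p[2L] >= ymin, function(p, q) ix(p, q, ymin, 2L))
  poly <- clip_edge(poly, function(p) p[2L] <= ymax, function(p, q) ix(p, q, ymax, 2L))
  poly
}

# land area (m^2) of `land` within an axis-aligned rectangle
land_area_in_rect <- function(land, xmin, xmax, ymin, ymax) {
  land <- as_land_polygon(land)
  area <- 0
  for (i in seq_along(land$rings)) {
    clipped <- clip_ring_rect(land$rings[[i]], xmin, xmax, ymin, ymax)
    if (is.null(clipped) || nrow(clipped) < 3L) next
    a <- ring_area(clipped)
    area <- area + if (i == 1L) a else -a
  }
  max(area, 0)
}

# min distance (m) from points to the boundary segments of all rings
dist_to_boundary <- function(px, py, land) {
  land <- as_land_polygon(land)
  d <- rep(Inf, length(px))
  for (ring in land$rings) {
    x1 <- ring[, 1L]; y1 <- ring[, 2L]
    n <- length(x1)
    x2 <- x1[c(2:n, 1L)]; y2 <- y1[c(2:n, 1L)]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    len2[len2 == 0] <- .Machine$double.eps
    for (k in seq_along(px)) {
      t <- pmin(pmax(((px[k] - x1) * dx + (py[k] - y1) * dy) / len2, 0), 1)
      dk <- sqrt((px[k] - (x1 + t * dx))^2 + (py[k] - (y1 + t * dy))^2)
      d[k] <- min(d[k], min(dk))
    }
  }
  d
}
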