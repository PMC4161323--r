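#' Build the prediction grid
#'
#' Tiles a bounding box with square cells (default 3 km) and, when a
#' coastline (land polygon) is supplied, clips each cell to the sea:
#' interior sea cells keep the full cell area (9 km^2 at the default cell
#' size), coastal cells get the sea fraction of that area, and land-only
#' cells are flagged \code{is_sea = FALSE}. Cell centroids are cell-centre
#' based and cells are indexed row-major from the lower-left corner.
#'
#' @param bbox numeric vector \code{c(xmin, ymin, xmax, ymax)} in metres.
#' @param cellsize cell edge length in metres (default 3000).
#' @param coastline optional land polygon ([as_land_polygon()] /
#'   [parse_wkt_polygon()]); \code{NULL} means all-sea.
#' @param region optional function \code{f(x, y)} returning a region label
#'   per centroid, or a single label for all cells (default \code{"main"}).
#' @return data frame with columns \code{cell_id, x, y, area} (km^2),
#'   \code{cdist} (km, \code{NA} without a coastline), \code{region},
#'   \code{is_sea}.
#' @export
make_grid <- function(bbox, cellsize = 3000, coastline = NULL, region = "main") {
  stopifnot(length(bbox) == 4L, cellsize > 0)
  xmin <- bbox[1L]; ymin <- bbox[2L]; xmax <- bbox[3L]; ymax <- bbox[4L]
  nx <- floor((xmax - xmin) / cellsize + 1e-9)
  ny <- floor((ymax - ymin) / cellsize + 1e-9)
  if (nx < 1L || ny < 1L) stop("bounding box smaller than one cell")
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  cx <- xmin + (ix - 0.5) * cellsize
  cy <- ymin + (iy - 0.5) * cellsize
  full_km2 <- (cellsize / 1000)^2
  if (is.null(coastline)) {
    area <- rep(full_km2, length(cx))
    cdist <- rep(NA_real_, length(cx))
    is_sea <- rep(TRUE, length(cx))
  } else {
    land <- as_land_polygon(coastline)
    area <- numeric(length(cx))
    for (k in seq_along(cx)) {
      la <- land_area_in_rect(land,
                              cx[k] - cellsize / 2, cx[k] + cellsize / 2,
                              cy[k] - cellsize / 2, cy[k] + cellsize / 2)
      area[k] <- max(full_km2 - la / 1e6, 0)
    }
    is_sea <- area > full_km2 * 1e-6
    cdist <- suppressWarnings(coast_distance(cx, cy, land))
  }
  reg <- if (is.function(region)) region(cx, cy) else rep(region, length(cx))
  data.frame(cell_id = seq_along(cx), x = cx, y = cy,
             area = area, cdist = cdist, region = reg, is_sea = is_sea,
             stringsAsFactors = FALSE)
}

#' Minimum distance to coast
#'
#' Planar minimum distance (km) from points to the coastline boundary.
#' Points on land return 0 with a warning rather than an error, so that
#' segments straddling the shoreline survive ingestion and can be flagged
#' downstream.
#'
#' @param x,y numeric vectors, metres.
#' @param coastline land polygon.
#' @return numeric vector of distances in km.
#' @export
coast_distance <- function(x, y, coastline) {
  land <- as_land_polygon(coastline)
  d <- dist_to_boundary(x, y, land) / 1000
  on_land <- point_on_land(x, y, land)
  if (any(on_land)) {
    warning(sum(on_land), " point(s) fall on land; coast distance set to 0")
    d[on_land] <- 0
  }
  d
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster reader for the bathymetry layer. Depth is stored as
#' positive metres below sea level.
#'
#' @param path file path.
#' @return object of class \code{ascii_grid}: list with \code{ncols, nrows,
#'   xll, yll, cellsize, nodata} and matrix \code{z} (rows from north to
#'   south, as stored in the file).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  z <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  z[z == nodata] <- NA_real_
  structure(list(ncols = hdr$ncols, nrows = hdr$nrows,
                 xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = nodata, z = z),
            class = "ascii_grid")
}

#' Write an ESRI ASCII grid
#' @param grid an \code{ascii_grid} object.
#' @param path output file path.
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$ncols), paste("nrows", grid$nrows),
               paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
               paste("cellsize", grid$cellsize),
               paste("NODATA_value", grid$nodata)), con)
  z <- grid$z
  z[is.na(z)] <- grid$nodata
  apply(z, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Depth lookup
#'
#' Nearest-cell raster lookup (segments are small relative to the raster, so
#' a footprint mean is not attempted). Points outside the raster extent
#' return \code{NA}.
#'
#' @param x,y numeric vectors, metres.
#' @param bathymetry an \code{ascii_grid}.
#' @return numeric vector of depths, positive metres below sea level.
#' @export
depth_at <- function(x, y, bathymetry) {
  g <- bathymetry
  col <- floor((x - g$xll) / g$cellsize) + 1L
  row <- g$nrows - floor((y - g$yll) / g$cellsize)
  out <- rep(NA_real_, length(x))
  ok <- col >= 1L & col <= g$ncols & row >= 1L & row <= g$nrows
  out[ok] <- g$z[cbind(row[ok], col[ok])]
  out
}

#' Drop effort from surveys that did not record a species
#'
#' Some at-sea surveys record only a subset of species (e.g. auk-only
#' surveys). Keeping their segments as zero effort for unrecorded species
#' would inflate apparent effort and bias densities low, so for a given
#' analysis species those segments (and their observations) are dropped.
#'
#' @param observations observation table with \code{segment_id, species}.
#' @param segments segment table with \code{segment_id, species_recorded}
#'   (\code{"all"} or a semicolon-separated list of species codes).
#' @param species the analysis species.
#' @return \code{list(segments =, observations =)} filtered tables.
#' @export
filter_by_species_coverage <- function(observations, segments, species) {
  recorded <- vapply(segments$species_recorded, function(sr) {
    sr == "all" || species %in% strsplit(sr, ";")[[1]]
  }, logical(1L), USE.NAMES = FALSE)
  seg_keep <- segments[recorded, , drop = FALSE]
  obs_keep <- observations[observations$segment_id %in% seg_keep$segment_id &
                             observations$species == species, , drop = FALSE]
  list(segments = seg_keep, observations = obs_keep)
}

#' Locate grid cells containing points
#'
#' @param x,y point coordinates (m).
#' @param grid a grid from [make_grid()].
#' @return integer vector of \code{cell_id} (NA outside the grid).
#' @export
locate_cell <- function(x, y, grid) {
  cs <- sort(unique(grid$x))
  cellsize <- if (length(cs) > 1L) min(diff(cs)) else {
    ys <- sort(unique(grid$y)); if (length(ys) > 1L) min(diff(ys)) else stop("degenerate grid")
  }
  xmin <- min(grid$x) - cellsize / 2
  ymin <- min(grid$y) - cellsize / 2
  nx <- length(unique(grid$x))
  ny <- length(unique(grid$y))
  ix <- floor((x - xmin) / cellsize) + 1L
  iy <- floor((y - ymin) / cellsize) + 1L
  id <- ifelse(ix >= 1L & ix <= nx & iy >= 1L & iy <= ny,
               (iy - 1L) * nx + ix, NA_integer_)
  id[!is.na(id) & !(id %in% grid$cell_id)] <- NA_integer_
  as.integer(id)
}

#' Tabular readers and writers
#'
#' Segments, observations, grids and layers travel as delimited text (CSV
#' with a header row). Writing then re-reading round-trips all fields.
#'
#' @param x data frame to write.
#' @param path file path.
#' @name seasens-io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname seasens-io
#' @export
read_table_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  # all-NA columns come back logical; optional schema columns are numeric
  for (j in seq_along(x)) {
    if (is.logical(x[[j]]) && all(is.na(x[[j]]))) x[[j]] <- as.numeric(x[[j]])
  }
  x
}
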