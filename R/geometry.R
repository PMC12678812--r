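# Minimal planar polygon kernel over WKT text geometries.
#
# A geometry is a list of parts; each part is a list of rings; each ring is
# a closed numeric matrix (lon, lat), first row == last row. The first ring
# of a part is its outer boundary, further rings are holes (even-odd
# semantics). Coordinates are geographic (WGS84 lon/lat). Intersection
# predicates are computed in lon/lat; areas for threshold decisions use a
# Lambert cylindrical equal-area transform, which is exactly equal-area.

EARTH_RADIUS_KM <- 6371.0088

#' Parse WKT POLYGON / MULTIPOLYGON text
#'
#' @param wkt a single WKT string.
#' @return a geometry object (class `adist_geom`): list of parts, each a
#'   list of closed coordinate-matrix rings (outer ring first).
#' @export
#' @examples
#' g <- parse_wkt("POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))")
#' geom_area(g)
parse_wkt <- function(wkt) {
  s <- stringr::str_squish(wkt)
  type <- stringr::str_to_upper(stringr::str_extract(s, "^[A-Za-z]+"))
  if (!type %in% c("POLYGON", "MULTIPOLYGON")) {
    rlang::abort(sprintf("unsupported WKT type: %s", type %||% "<none>"),
                 class = "aliendist_geometry_error")
  }
  body <- stringr::str_sub(s, stringr::str_locate(s, "\\(")[1], -1)
  # peel one nesting level: a POLYGON body holds rings, a MULTIPOLYGON body
  # holds polygons which hold rings
  parts <- if (type == "POLYGON") list(body) else split_wkt_groups(strip_outer(body))
  geom <- purrr::map(parts, function(p) {
    rings <- split_wkt_groups(strip_outer(p))
    purrr::map(rings, function(r) {
      r <- stringr::str_remove_all(r, "[()]")
      xy <- stringr::str_split_1(stringr::str_squish(r), ",\\s*")
      m <- do.call(rbind, purrr::map(xy, ~ as.numeric(stringr::str_split_1(stringr::str_squish(.x), "\\s+"))))
      close_ring(m)
    })
  })
  structure(geom, class = "adist_geom")
}

# Drop the outermost parentheses of "( ... )".
strip_outer <- function(s) {
  s <- stringr::str_squish(s)
  stringr::str_sub(s, 2, -2)
}

# Split "(...),(...)" into its top-level parenthesized groups.
split_wkt_groups <- function(s) {
  chars <- stringr::str_split_1(s, "")
  depth <- cumsum((chars == "(") - (chars == ")"))
  start <- which(chars == "(" & depth == 1)
  end <- which(chars == ")" & depth == 0)
  purrr::map2_chr(start, end, ~ paste(chars[.x:.y], collapse = ""))
}

close_ring <- function(m) {
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
  m
}

#' Serialize a geometry to WKT
#' @param geom an `adist_geom` (or a bare coordinate matrix for one ring).
#' @return WKT string (POLYGON or MULTIPOLYGON).
#' @export
format_wkt <- function(geom) {
  if (is.matrix(geom)) geom <- structure(list(list(close_ring(geom))), class = "adist_geom")
  fmt_ring <- function(r) paste0("(", paste(sprintf("%.10g %.10g", r[, 1], r[, 2]), collapse = ", "), ")")
  fmt_part <- function(p) paste0("(", paste(vapply(p, fmt_ring, character(1)), collapse = ", "), ")")
  if (length(geom) == 1) paste0("POLYGON ", fmt_part(geom[[1]]))
  else paste0("MULTIPOLYGON (", paste(vapply(geom, fmt_part, character(1)), collapse = ", "), ")")
}

# Shoelace area of one ring (unsigned, planar in given coordinates).
ring_area <- function(m) {
  n <- nrow(m) - 1
  if (n < 3) return(0)
  x <- m[1:n, 1]; y <- m[1:n, 2]
  xn <- m[2:(n + 1), 1]; yn <- m[2:(n + 1), 2]
  abs(sum(x * yn - xn * y)) / 2
}

# Lambert cylindrical equal-area: exact areas on the sphere, in km^2.
to_equal_area <- function(m) {
  cbind(EARTH_RADIUS_KM * m[, 1] * pi / 180,
        EARTH_RADIUS_KM * sin(m[, 2] * pi / 180))
}

#' Polygon area
#' @param geom an `adist_geom`.
#' @param equal_area if `TRUE` (default) return km^2 on the sphere via an
#'   equal-area transform; otherwise planar square degrees.
#' @return non-negative numeric scalar; holes are subtracted.
#' @export
geom_area <- function(geom, equal_area = FALSE) {
  sum(purrr::map_dbl(geom, function(part) {
    a <- purrr::map_dbl(part, function(r) {
      if (equal_area) r <- to_equal_area(r)
      ring_area(r)
    })
    a[1] - sum(a[-1])
  }))
}

# Even-odd point-in-ring test (boundary points give implementation-defined
# results; callers needing boundary exclusion test with strict = TRUE).
point_in_ring <- function(px, py, m) {
  n <- nrow(m) - 1
  x1 <- m[1:n, 1]; y1 <- m[1:n, 2]
  x2 <- m[2:(n + 1), 1]; y2 <- m[2:(n + 1), 2]
  crosses <- ((y1 > py) != (y2 > py)) &
    (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
  sum(crosses) %% 2 == 1
}

#' Point-in-polygon test (even-odd rule, holes respected)
#' @param px,py coordinates of the point.
#' @param geom an `adist_geom`.
#' @return logical scalar.
#' @export
point_in_geom <- function(px, py, geom) {
  any(purrr::map_lgl(geom, function(part) {
    inside <- vapply(part, function(r) point_in_ring(px, py, r), logical(1))
    inside[1] && sum(inside[-1]) %% 2 == 0
  }))
}

# Is every part's outer ring convex (and hole-free)? Clipping via
# Sutherland-Hodgman is exact only against convex clip rings.
geom_is_convex <- function(geom) {
  all(purrr::map_lgl(geom, function(part) {
    if (length(part) > 1) return(FALSE)
    m <- part[[1]]; n <- nrow(m) - 1
    if (n < 3) return(FALSE)
    v1 <- m[c(2:n, 1), ] - m[1:n, ]
    v2 <- v1[c(2:n, 1), ]
    cr <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
    all(cr >= -1e-12) || all(cr <= 1e-12)
  }))
}

# Sutherland-Hodgman: clip a subject ring against one convex ring.
# Returns the clipped ring (possibly with 0 rows).
clip_ring_convex <- function(subject, clip) {
  n <- nrow(clip) - 1
  # ensure counter-clockwise clip ring so "inside" is left of each edge
  if (ring_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject[-nrow(subject), , drop = FALSE]
  for (i in seq_len(nrow(clip) - 1)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[i + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2]); d2 <- c(b[1] - a[1], b[2] - a[2])
      denom <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / denom
      p + t * d1
    }
    nxt <- matrix(numeric(0), ncol = 2)
    m <- nrow(out)
    for (j in seq_len(m)) {
      p <- out[j, ]; q <- out[if (j == m) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) nxt <- rbind(nxt, p)
      if (pin != qin) nxt <- rbind(nxt, inter(p, q))
    }
    out <- nxt
  }
  if (nrow(out) >= 3) close_ring(out) else out
}

ring_signed_area <- function(m) {
  n <- nrow(m) - 1
  x <- m[1:n, 1]; y <- m[1:n, 2]
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

#' Intersection area of two geometries
#'
#' Exact (Sutherland-Hodgman clipping) when the clip geometry `b` is
#' convex and hole-free; otherwise estimated by regular grid sampling over
#' the overlapping bounding box (resolution `grid_n` x `grid_n`), which is
#' documented as an approximation for concave reference layers.
#'
#' @param a,b `adist_geom` objects (`b` is the clip geometry).
#' @param equal_area report km^2 instead of square degrees.
#' @param grid_n sampling resolution for the concave fallback.
#' @return non-negative numeric scalar.
#' @export
geom_intersection_area <- function(a, b, equal_area = FALSE, grid_n = 120) {
  bba <- geom_bbox(a); bbb <- geom_bbox(b)
  if (bba[1] >= bbb[3] || bbb[1] >= bba[3] || bba[2] >= bbb[4] || bbb[2] >= bba[4]) return(0)
  if (geom_is_convex(b)) {
    total <- 0
    for (pa in a) {
      for (pb in b) {
        outer <- clip_ring_convex(pa[[1]], pb[[1]])
        if (is.matrix(outer) && nrow(outer) >= 4) {
          area_fun <- function(r) ring_area(if (equal_area) to_equal_area(r) else r)
          total <- total + area_fun(outer)
          # subtract hole overlap of the subject's holes with the clip
          for (h in pa[-1]) {
            hc <- clip_ring_convex(h, pb[[1]])
            if (is.matrix(hc) && nrow(hc) >= 4) total <- total - area_fun(hc)
          }
        }
      }
    }
    return(max(total, 0))
  }
  # concave clip: grid-sample the joint bounding box
  xlo <- max(bba[1], bbb[1]); xhi <- min(bba[3], bbb[3])
  ylo <- max(bba[2], bbb[2]); yhi <- min(bba[4], bbb[4])
  xs <- seq(xlo, xhi, length.out = grid_n + 1); xs <- (xs[-1] + xs[-length(xs)]) / 2
  ys <- seq(ylo, yhi, length.out = grid_n + 1); ys <- (ys[-1] + ys[-length(ys)]) / 2
  pts <- expand.grid(x = xs, y = ys)
  hit <- vapply(seq_len(nrow(pts)), function(i) {
    point_in_geom(pts$x[i], pts$y[i], a) && point_in_geom(pts$x[i], pts$y[i], b)
  }, logical(1))
  cell <- if (equal_area) {
    dx <- (xhi - xlo) / grid_n; dy <- (yhi - ylo) / grid_n
    # mean cell area under the equal-area transform
    (EARTH_RADIUS_KM * dx * pi / 180) *
      (EARTH_RADIUS_KM * (sin(yhi * pi / 180) - sin(ylo * pi / 180)) / grid_n)
  } else {
    ((xhi - xlo) / grid_n) * ((yhi - ylo) / grid_n)
  }
  sum(hit) * cell
}

#' Do two geometries overlap with positive area?
#'
#' Boundary contact (shared edges or corner touches) does not count as
#' overlap: the test requires interior intersection with area above
#' `tol` square degrees.
#'
#' @param a,b `adist_geom` objects.
#' @param tol minimal area (square degrees) counted as overlap.
#' @return logical scalar.
#' @export
geom_overlaps <- function(a, b, tol = 1e-9) {
  geom_intersection_area(a, b) > tol
}

geom_bbox <- function(geom) {
  xs <- unlist(purrr::map(geom, ~ purrr::map(.x, ~ .x[, 1])))
  ys <- unlist(purrr::map(geom, ~ purrr::map(.x, ~ .x[, 2])))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' Validate a geometry
#'
#' Checks ring closure, minimal vertex count, finite coordinates and
#' non-zero area. Degenerate geometries are rejected at load so invalid
#' range-map features can be skipped and logged rather than crash overlay.
#'
#' @param geom an `adist_geom`.
#' @return `TRUE` if valid, otherwise `FALSE`.
#' @export
geom_is_valid <- function(geom) {
  ok <- tryCatch({
    all(purrr::map_lgl(geom, function(part) {
      all(purrr::map_lgl(part, function(r) {
        nrow(r) >= 4 && all(is.finite(r)) && isTRUE(all.equal(r[1, ], r[nrow(r), ]))
      }))
    })) && geom_area(geom) > 0
  }, error = function(e) FALSE)
  isTRUE(ok)
}

# Convenience: unit-square geometry [x0,x0+w] x [y0,y0+w]
square_geom <- function(x0, y0, w = 1) {
  m <- rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + w), c(x0, y0 + w), c(x0, y0))
  structure(list(list(m)), class = "adist_geom")
}
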