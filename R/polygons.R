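# Spatial resolution for Clipper integer scaling: fine enough that grid
# clipping conserves area to ~1e-12 relative on a ~20-km workspace.
CLIP_EPS <- 1e-8

# Internal planar-polygon helpers. A "poly" is the polyclip representation:
# a list of rings, each ring a list(x =, y =) of vertices (no closing
# repeat). Boolean output from Clipper has positively oriented outer rings
# and negatively oriented holes, so the signed shoelace areas sum to the
# net enclosed area.

ring_area_signed <- function(r) {
  x <- r$x; y <- r$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

poly_area_m2 <- function(p) {
  if (length(p) == 0) return(0)
  sum(vapply(p, ring_area_signed, numeric(1)))
}

poly_area_km2 <- function(p) poly_area_m2(p) / 1e6

poly_empty <- function(p) length(p) == 0 || abs(poly_area_m2(p)) < 1e-12

poly_op <- function(A, B, op) {
  if (length(A) == 0) {
    if (op == "union") return(B)
    return(list())
  }
  if (length(B) == 0) {
    if (op == "intersection") return(list())
    return(A)
  }
  polyclip::polyclip(A, B, op = op,
                     fillA = "nonzero", fillB = "nonzero",
                     eps = CLIP_EPS)
}

poly_union_all <- function(polys) {
  out <- list()
  for (p in polys) out <- poly_op(out, p, "union")
  out
}

# Outward dilation (round joins); delta <= 0 handled by caller.
poly_offset <- function(p, delta, arctol = NULL) {
  arctol <- arctol %||% max(abs(delta) / 5000, 0.001)
  polyclip::polyoffset(p, delta, jointype = "round", arctol = arctol,
                       eps = CLIP_EPS)
}

# Band of half-width w around the closed outline(s) of p (round joins).
poly_boundary_band <- function(p, halfwidth, arctol = NULL) {
  if (halfwidth <= 0) return(list())
  arctol <- arctol %||% max(halfwidth / 5000, 0.0005)
  polyclip::polylineoffset(p, halfwidth, jointype = "round",
                           endtype = "closedline", arctol = arctol,
                           eps = CLIP_EPS)
}

# Disc centred on the origin (the radar in the planar workspace).
disc_poly <- function(radius, center = c(0, 0), n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(list(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th)))
}

rect_poly <- function(xmin, ymin, xmax, ymax) {
  list(list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax)))
}

poly_bbox <- function(p) {
  xs <- unlist(lapply(p, `[[`, "x"))
  ys <- unlist(lapply(p, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Even-odd point-in-polygon over all rings; points on any ring edge or
# vertex count as inside (needed for the deterministic edge precedence in
# assign_region()). Vectorised over points.
points_in_poly <- function(x, y, p) {
  if (length(p) == 0) return(rep(FALSE, length(x)))
  crossings <- integer(length(x))
  on_edge <- logical(length(x))
  for (r in p) {
    pip <- sp::point.in.polygon(x, y, r$x, r$y)
    crossings <- crossings + (pip == 1L)
    on_edge <- on_edge | pip >= 2L
  }
  on_edge | (crossings %% 2L == 1L)
}
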