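#' Geometric primitive of a bone segment
#'
#' The six primitives used to stylize bone segments: box, elliptic cylinder,
#' deformed cylinder (two parallel coaxial elliptic bases linearly
#' interpolated along the height, a ruled solid; the truncated cone is the
#' circular special case), isosceles triangular prism, ellipsoid and tube
#' (the solid between two nested circular cylinders). All lengths in mm.
#'
#' Dimension fields by kind: box `h, a, b` (height x length x width);
#' cylinder `h, a, b` (height x major x minor axis); deformed cylinder
#' `h, a, b, c, d` (lower base axes `a, b`, upper base axes `c, d`); prism
#' `h, a, b` (height x triangular base length x equal side length); ellipsoid
#' `h, a, b` (three axes); tube `h, a, b` (height x outer x inner diameter).
#'
#' @param kind shape kind, full name or table code (`"b"`, `"c"`, `"dc"`,
#'   `"p"`, `"e"`, `"t"`).
#' @param h,a,b,c,d dimensions in mm (`c`, `d` only for the deformed
#'   cylinder).
#' @return an object of class `spsd_shape`.
#' @examples
#' shape_spec("cylinder", h = 27, a = 35, b = 47)
#' @export
shape_spec <- function(kind, h, a, b, c = NA, d = NA) {
  if (kind %in% names(.shape_names)) kind <- .shape_names[[kind]]
  kind <- match.arg(kind, unname(.shape_names))
  code <- .shape_codes[[names(.shape_names)[.shape_names == kind]]]
  chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid ", kind, ": ", what)
  chk(is.finite(h) && h > 0, "h must be positive")
  chk(is.finite(a) && a > 0, "a must be positive")
  chk(is.finite(b) && b > 0, "b must be positive")
  if (kind == "deformed_cylinder") {
    chk(is.finite(c) && c > 0 && is.finite(d) && d > 0,
        "upper-base axes c, d must be positive")
  } else {
    chk(is.na(c) && is.na(d), "c, d are only defined for the deformed cylinder")
  }
  if (kind == "tube") chk(a > b, "outer diameter must exceed inner diameter")
  if (kind == "prism") chk(b > a / 2, "equal side must exceed half the base")
  structure(list(kind = kind, code = code, h = h, a = a, b = b, c = c, d = d),
            class = "spsd_shape")
}

#' @export
print.spsd_shape <- function(x, ...) {
  dims <- c(x$h, x$a, x$b, x$c, x$d)
  cat("<spsd_shape>", x$kind, paste(dims[!is.na(dims)], collapse = " x "),
      "mm\n")
  invisible(x)
}

#' Closed-form volume of a shape
#'
#' Box `h a b`; elliptic cylinder `pi h a b / 4`; deformed cylinder
#' `(pi h / 24) (2ab + 2cd + ad + cb)` (integral of the interpolated elliptic
#' cross-section); prism `h (a/2) sqrt(b^2 - a^2/4)`; ellipsoid
#' `(pi/6) h a b`; tube `(pi h / 4)(a^2 - b^2)`.
#'
#' @param shape an `spsd_shape`.
#' @return volume in mm^3.
#' @export
analytic_volume <- function(shape) {
  stopifnot(inherits(shape, "spsd_shape"))
  with(shape, switch(kind,
    box = h * a * b,
    cylinder = pi * h * a * b / 4,
    deformed_cylinder = pi * h / 24 * (2 * a * b + 2 * c * d + a * d + c * b),
    prism = h * (a / 2) * sqrt(b^2 - a^2 / 4),
    ellipsoid = pi / 6 * h * a * b,
    tube = pi * h / 4 * (a^2 - b^2)))
}

#' Valid cortical face designations for a shape kind
#'
#' Rectangular box faces are named `ha`, `hb`, `ab` after the edges that span
#' them; each name denotes the pair of parallel faces, and a suffix 1 or 2
#' selects a single face of the pair. Prism faces are `ah` (the rectangular
#' face through the base edge), `bh`/`ch` (the two equal-side faces; the
#' distinction is arbitrary but fixed -- the faces are mirror-symmetric) and
#' `abb` (the triangular bases). Curved surfaces are `lateral`; the whole
#' ellipsoid surface is `total`. Cylinder and tube bases are `ab1`/`ab2`
#' (cylinder bases are normally uncovered; a few printed records cover one).
#'
#' @param kind shape kind (full name or table code).
#' @return character vector of valid face ids.
#' @export
valid_faces <- function(kind) {
  if (kind %in% names(.shape_names)) kind <- .shape_names[[kind]]
  switch(kind,
    box = c("ha", "ha1", "ha2", "hb", "hb1", "hb2", "ab", "ab1", "ab2"),
    cylinder = c("lateral", "ab1", "ab2"),
    deformed_cylinder = "lateral",
    prism = c("ah", "bh", "ch", "abb", "abb1", "abb2"),
    ellipsoid = "total",
    tube = c("lateral", "ab1", "ab2"),
    stop("unknown shape kind: ", kind))
}

# pack a cortical data.frame into the offset vector the C++ kernel expects
.pack_cortical <- function(shape, cortical) {
  z <- function(n) numeric(n)
  if (is.null(cortical) || nrow(cortical) == 0L) {
    return(switch(shape$kind, box = z(6), prism = z(5), z(3)))
  }
  bad <- setdiff(cortical$face, valid_faces(shape$kind))
  if (length(bad)) {
    stop("face(s) ", paste(bad, collapse = ", "), " invalid for ", shape$kind)
  }
  set <- function(v, i, t) { v[i] <- v[i] + t; v }
  out <- switch(shape$kind, box = z(6), prism = z(5), z(3))
  for (i in seq_len(nrow(cortical))) {
    f <- cortical$face[i]; t <- cortical$thickness[i]
    out <- switch(shape$kind,
      box = switch(f,
        hb = set(out, 1:2, t), hb1 = set(out, 1, t), hb2 = set(out, 2, t),
        ha = set(out, 3:4, t), ha1 = set(out, 3, t), ha2 = set(out, 4, t),
        ab = set(out, 5:6, t), ab1 = set(out, 5, t), ab2 = set(out, 6, t)),
      prism = switch(f,
        ah = set(out, 1, t), bh = set(out, 2, t), ch = set(out, 3, t),
        abb = set(out, 4:5, t), abb1 = set(out, 4, t), abb2 = set(out, 5, t)),
      ellipsoid = set(out, 1, t),
      # cylinder, deformed cylinder, tube
      switch(f,
        lateral = set(out, 1, t), ab1 = set(out, 2, t), ab2 = set(out, 3, t)))
  }
  out
}

# grid extents (x, y, z) in mm for a shape
.shape_extent <- function(shape) {
  with(shape, switch(kind,
    box = c(a, b, h),
    cylinder = c(a, b, h),
    deformed_cylinder = c(max(a, c), max(b, d), h),
    prism = c(a, sqrt(b^2 - a^2 / 4), h),
    ellipsoid = c(a, b, h),
    tube = c(a, a, h)))
}

.shape_dims <- function(shape) {
  as.numeric(c(shape$h, shape$a, shape$b,
               ifelse(is.na(shape$c), 0, shape$c),
               ifelse(is.na(shape$d), 0, shape$d)))
}

# validate that the cortical layers leave a spongiosa interior, and return
# the analytic total/spongiosa/cortical volumes (mm^3)
.analytic_media <- function(shape, cortical) {
  tot <- analytic_volume(shape)
  off <- .pack_cortical(shape, cortical)
  sp <- with(shape, switch(kind,
    box = {
      A <- a - off[1] - off[2]; B <- b - off[3] - off[4]; H <- h - off[5] - off[6]
      if (A <= 0 || B <= 0 || H <= 0) -1 else A * B * H
    },
    cylinder = {
      A <- a - 2 * off[1]; B <- b - 2 * off[1]; H <- h - off[2] - off[3]
      if (A <= 0 || B <= 0 || H <= 0) -1 else pi * H * A * B / 4
    },
    deformed_cylinder = {
      A0 <- a - 2 * off[1]; B0 <- b - 2 * off[1]
      A1 <- c - 2 * off[1]; B1 <- d - 2 * off[1]
      if (min(A0, B0, A1, B1) <= 0) -1 else
        pi * h / 24 * (2 * A0 * B0 + 2 * A1 * B1 + A0 * B1 + A1 * B0)
    },
    prism = {
      a2 <- a / 2; m <- sqrt(b^2 - a2^2); nrm <- sqrt(m^2 + a2^2)
      tb <- off[1]; tr <- off[2]; tl <- off[3]
      H <- h - off[4] - off[5]
      y3 <- m - (tr + tl) * nrm / (2 * a2)
      x3 <- (tl - tr) * nrm / (2 * m)
      x1 <- (a2 * m - tr * nrm - tb * a2) / m
      x2 <- -(a2 * m - tl * nrm - tb * a2) / m
      if (H <= 0 || y3 <= tb || x1 <= x2) -1 else {
        xs <- c(x2, x1, x3); ys <- c(tb, tb, y3)
        area <- abs(sum(xs * ys[c(2, 3, 1)] - xs[c(2, 3, 1)] * ys)) / 2
        area * H
      }
    },
    ellipsoid = {
      A <- a - 2 * off[1]; B <- b - 2 * off[1]; H <- h - 2 * off[1]
      if (min(A, B, H) <= 0) -1 else pi / 6 * A * B * H
    },
    tube = {
      ro <- a / 2 - off[1]; ri <- b / 2; H <- h - off[2] - off[3]
      if (ro <= ri || H <= 0) -1 else pi * H * (ro^2 - ri^2)
    }))
  if (sp <= 0) {
    stop("cortical layer consumes the whole segment (no spongiosa left)")
  }
  list(total = tot, spongiosa = sp, cortical = max(0, tot - sp))
}

#' Default voxel edge for a segment
#'
#' The working resolution is 0.7 x Tb.Th, clamped to a configurable range
#' (default 0.04-0.25 mm, i.e. 40-250 um). When the clamp binds the result
#' carries attribute `clamped = TRUE`.
#'
#' @param tb_th mean trabecular thickness in mm.
#' @param clamp length-2 numeric, allowed voxel range in mm.
#' @return voxel edge length in mm.
#' @examples
#' default_voxel_size(0.29) # 0.203
#' @export
default_voxel_size <- function(tb_th, clamp = c(0.04, 0.25)) {
  stopifnot(tb_th > 0, length(clamp) == 2L, clamp[1] < clamp[2])
  v <- 0.7 * tb_th
  out <- min(max(v, clamp[1]), clamp[2])
  attr(out, "clamped") <- out != v
  out
}

#' Rasterize a shape on an isotropic voxel grid
#'
#' Centre-point sampling: a voxel belongs to the shape iff its centre does,
#' which makes axis-aligned box volumes exact and the voxel-count volume an
#' unbiased first-order approximation of the closed form for the other
#' shapes. Labels: 0 background, 1 marrow, 2 trabecular bone, 3 cortical
#' bone. With `cortical = NULL` the whole interior is marrow.
#'
#' @param shape an `spsd_shape`.
#' @param voxel_size voxel edge in mm.
#' @param cortical optional `data.frame(face, thickness)`; see
#'   [apply_cortical_shell()].
#' @param max_voxels refuse grids larger than this (memory guard).
#' @return an object of class `spsd_phantom`: list with `labels` (3-D integer
#'   array), `voxel_size`, `shape`, `cortical`, `origin`.
#' @export
voxelize_shape <- function(shape, voxel_size, cortical = NULL,
                           max_voxels = 4e8) {
  stopifnot(inherits(shape, "spsd_shape"), voxel_size > 0)
  ext <- .shape_extent(shape)
  n <- pmax(1L, as.integer(ceiling(ext / voxel_size - 1e-9)))
  if (prod(n) > max_voxels) {
    stop(sprintf("grid %d x %d x %d (%.2g voxels) exceeds the budget of %.2g",
                 n[1], n[2], n[3], prod(as.numeric(n)), max_voxels))
  }
  # x, y centred; z from 0; prism y from 0
  orig <- c(-n[1] * voxel_size / 2, -n[2] * voxel_size / 2, 0)
  if (shape$kind == "box") orig[1:2] <- -ext[1:2] / 2
  if (shape$kind == "prism") orig[2] <- 0
  if (!is.null(cortical)) .analytic_media(shape, cortical) # validates
  lab <- cpp_label_shape(shape$code, .shape_dims(shape), voxel_size, n, orig,
                         .pack_cortical(shape, cortical))
  structure(list(labels = lab, voxel_size = voxel_size, shape = shape,
                 cortical = cortical, origin = orig),
            class = "spsd_phantom")
}

#' Relabel the cortical shell of a voxel phantom
#'
#' Voxels within the stated thickness inward of each designated face become
#' cortical bone (label 3); non-designated faces keep marrow at the surface.
#' The shell is realized within one voxel of the nominal thickness. Must be
#' applied before trabeculae are generated.
#'
#' @param phantom an `spsd_phantom` from [voxelize_shape()].
#' @param cortical `data.frame(face, thickness)` with faces valid for the
#'   phantom's shape (see [valid_faces()]); `NULL` or empty leaves the
#'   phantom without cortex.
#' @return the relabelled `spsd_phantom`.
#' @export
apply_cortical_shell <- function(phantom, cortical) {
  stopifnot(inherits(phantom, "spsd_phantom"))
  if (any(phantom$labels == 2L)) {
    stop("cortical shell must be applied before trabeculae are generated")
  }
  voxelize_shape(phantom$shape, phantom$voxel_size, cortical)
}

#' @export
print.spsd_phantom <- function(x, ...) {
  n <- dim(x$labels)
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf("<spsd_phantom> %s, %d x %d x %d voxels @ %g mm\n",
              x$shape$kind, n[1], n[2], n[3], x$voxel_size))
  cat(sprintf("  background %d | marrow %d | trabecular %d | cortical %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Voxel-counted media volumes of a phantom
#' @param phantom an `spsd_phantom`.
#' @return named numeric vector (mm^3): `total`, `marrow`, `trabecular`,
#'   `cortical`, `spongiosa`.
#' @export
phantom_volumes <- function(phantom) {
  stopifnot(inherits(phantom, "spsd_phantom"))
  v3 <- phantom$voxel_size^3
  tab <- tabulate(phantom$labels + 1L, nbins = 4L)
  c(total = sum(tab[2:4]) * v3, marrow = tab[2] * v3,
    trabecular = tab[3] * v3, cortical = tab[4] * v3,
    spongiosa = (tab[2] + tab[3]) * v3)
}

#' Shape and cortical specification of a database segment row
#'
#' @param rec one row of `spsd_db()$segments`.
#' @return `record_shape()` returns the [shape_spec()] of the record;
#'   `record_cortical()` its `data.frame(face, thickness)` or `NULL`.
#' @export
record_shape <- function(rec) {
  shape_spec(rec$shape, h = rec$h, a = rec$a, b = rec$b,
             c = rec$c_ax, d = rec$d_ax)
}

#' @rdname record_shape
#' @export
record_cortical <- function(rec) {
  ct <- rec$cortical
  if (is.list(ct) && !is.data.frame(ct)) ct <- ct[[1]]
  ct
}
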