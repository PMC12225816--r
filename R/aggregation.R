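#' Media volumes of one segment
#'
#' Computes the trabecular bone (TBV), cortical bone (CBV) and bone marrow
#' (BMV) volumes of a segment model. The analytic path uses the closed-form
#' shape volume and the eroded-shape closed forms for the cortical layer
#' (box/prism interiors shrink per-face, cylinder-family axes erode by twice
#' the lateral thickness), then splits spongiosa as TBV = BV/TV x spongiosa.
#' The voxel path counts labelled voxels of a generated phantom; the two
#' paths agree within discretization tolerance. Volumes are multiplied by the
#' truncation correction `k_s` (whole-bone extent over modelled extent) and
#' the multiplicity `n_s` (number of similar models in the skeleton) when
#' `corrected = TRUE`.
#'
#' @param rec one row of `spsd_db()$segments`.
#' @param mode `"analytic"` (default) or `"voxel"`.
#' @param voxel_size voxel edge for the voxel path; `NULL` for the default.
#' @param seed seed for the rod process in voxel mode.
#' @param corrected apply `k_s` and `n_s` (default `TRUE`).
#' @return object of class `spsd_media`: named numeric vector (cm^3) with
#'   elements `tbv`, `cbv`, `bmv`, `spongiosa`, `total`, plus attributes
#'   `n_s`, `k_s`, `level = "segment"`.
#' @export
segment_media_volumes <- function(rec, mode = c("analytic", "voxel"),
                                  voxel_size = NULL, seed = NULL,
                                  corrected = TRUE) {
  mode <- match.arg(mode)
  sh <- record_shape(rec)
  ct <- record_cortical(rec)
  if (mode == "analytic") {
    med <- .analytic_media(sh, ct)
    tbv <- rec$bvtv * med$spongiosa
    v <- c(tbv = tbv, cbv = med$cortical, bmv = med$spongiosa - tbv,
           spongiosa = med$spongiosa, total = med$total)
  } else {
    if (is.null(voxel_size)) voxel_size <- as.numeric(default_voxel_size(rec$tb_th))
    ph <- generate_segment_phantom(rec, voxel_size = voxel_size, seed = seed)
    pv <- phantom_volumes(ph)
    v <- c(tbv = pv[["trabecular"]], cbv = pv[["cortical"]],
           bmv = pv[["marrow"]], spongiosa = pv[["spongiosa"]],
           total = pv[["total"]])
  }
  f <- if (corrected) rec$k_s * rec$n_s else 1
  structure(v * f / 1000, n_s = rec$n_s, k_s = rec$k_s, level = "segment",
            class = "spsd_media")
}

#' @export
print.spsd_media <- function(x, ...) {
  cat(sprintf("<spsd_media level=%s> TBV %.2f | CBV %.2f | BMV %.2f cm^3\n",
              attr(x, "level"), x[["tbv"]], x[["cbv"]], x[["bmv"]]))
  invisible(x)
}

#' Skeleton-level media volumes and masses
#'
#' Sums corrected segment media volumes over all records of one reference
#' phantom and converts them to masses with the age-specific media densities
#' (bone mass covers trabecular plus cortical bone; marrow mass is BMV times
#' the marrow density). Only hematopoietic segments are in the database, so
#' the totals describe the hematopoietic skeleton.
#'
#' @param db an `spsd_db`.
#' @param age reference age group.
#' @param sex `"male"` or `"female"` (ignored below 15 years).
#' @param mode `"analytic"` or `"voxel"`.
#' @param multiplicity optional named numeric vector of `n_s` overrides,
#'   names matching segment keys.
#' @param truncation optional named numeric vector of `k_s` overrides.
#' @param ... passed to [segment_media_volumes()] in voxel mode.
#' @return list with `per_site` (data.frame of site sums, cm^3), `totals`
#'   (`spsd_media`), `masses` (named vector, g: `bone`, `marrow`).
#' @export
skeleton_totals <- function(db, age, sex = c("male", "female"),
                            mode = c("analytic", "voxel"),
                            multiplicity = NULL, truncation = NULL, ...) {
  mode <- match.arg(mode)
  seg <- spsd_segments(db, age, sex)
  if (!is.null(multiplicity)) {
    miss <- setdiff(names(multiplicity), seg$key)
    if (length(miss)) stop("multiplicity override for unknown segment(s): ",
                           paste(miss, collapse = "; "))
    i <- match(names(multiplicity), seg$key)
    seg$n_s[i] <- multiplicity
  }
  if (!is.null(truncation)) {
    i <- match(names(truncation), seg$key)
    if (anyNA(i)) stop("truncation override for unknown segment(s)")
    seg$k_s[i] <- truncation
  }
  if (any(is.na(seg$n_s) | is.na(seg$k_s))) {
    stop("unresolved multiplicity for: ",
         paste(seg$key[is.na(seg$n_s) | is.na(seg$k_s)], collapse = "; "))
  }
  per <- t(vapply(seq_len(nrow(seg)), function(i) {
    unclass(segment_media_volumes(seg[i, ], mode = mode, ...))
  }, numeric(5)))
  site <- vapply(seq_len(nrow(seg)), function(i) {
    .am_site(seg$site[i], seg$segment[i])
  }, "")
  per_site <- aggregate(per[, c("tbv", "cbv", "bmv")],
                        by = list(site = site), FUN = sum)
  totals <- structure(colSums(per), level = "skeleton", class = "spsd_media")
  dens <- media_density(db, age)
  masses <- c(bone = (totals[["tbv"]] + totals[["cbv"]]) * dens[["bone"]],
              marrow = totals[["bmv"]] * dens[["marrow"]])
  list(per_site = per_site, totals = totals, masses = masses,
       per_segment = data.frame(key = seg$key, site = site, per))
}

# area-weighted mean cortical thickness over the covered faces of a segment;
# 0 for cortex-free segments
.segment_ctth <- function(rec) {
  ct <- record_cortical(rec)
  if (is.null(ct) || nrow(ct) == 0L) return(0)
  sh <- record_shape(rec)
  # perimeter of an ellipse with axes A, B (Ramanujan)
  per <- function(A, B) {
    x <- A / 2; y <- B / 2
    pi * (3 * (x + y) - sqrt((3 * x + y) * (x + 3 * y)))
  }
  face_area <- function(f) {
    with(sh, switch(sh$kind,
      box = switch(substr(f, 1, 2),
        ha = h * a * (if (f == "ha") 2 else 1),
        hb = h * b * (if (f == "hb") 2 else 1),
        ab = a * b * (if (f == "ab") 2 else 1)),
      cylinder = if (f == "lateral") per(a, b) * h else pi * a * b / 4,
      deformed_cylinder = per((a + c) / 2, (b + d) / 2) * h,
      prism = {
        a2 <- a / 2; m <- sqrt(b^2 - a2^2)
        tri <- a * m / 2
        switch(substr(f, 1, 2), ah = h * a, bh = h * b, ch = h * b,
               ab = tri * (if (f == "abb") 2 else 1))
      },
      ellipsoid = { # Thomsen approximation
        p <- 1.6075; x <- (a / 2)^p; y <- (b / 2)^p; z <- (h / 2)^p
        4 * pi * ((x * y + x * z + y * z) / 3)^(1 / p)
      },
      tube = if (f == "lateral") pi * a * h else pi * (a^2 - b^2) / 4))
  }
  areas <- vapply(ct$face, face_area, 1.0)
  sum(ct$thickness * areas) / sum(areas)
}

#' Active-marrow-weighted effective dose-forming parameters
#'
#' Averages the parameters that drive the dose to active marrow the way the
#' skeleton-average dose itself is formed: each skeletal site is weighted by
#' its active-marrow fraction, and within a site (or a pooled site group)
#' each segment is weighted by its share of corrected marrow volume (marrow
#' is distributed uniformly within a segment). Reported are the effective
#' spongiosa volume (weighted mean single-model spongiosa volume), the
#' effective BV/TV, and the effective cortical thickness (per-segment values
#' are area-weighted means over covered faces; cortex-free segments
#' contribute zero).
#'
#' @param db an `spsd_db`.
#' @param age reference age group.
#' @param sex `"male"` or `"female"`.
#' @return list with `spongiosa_cm3`, `bvtv`, `ct_th_mm`, and the per-segment
#'   weight table.
#' @export
effective_parameters <- function(db, age, sex = c("male", "female")) {
  seg <- spsd_segments(db, age, sex)
  am <- db$am[db$am$age == age, , drop = FALSE]
  site <- vapply(seq_len(nrow(seg)), function(i) {
    .am_site(seg$site[i], seg$segment[i])
  }, "")
  groups <- strsplit(am$sites, "|", fixed = TRUE)
  gidx <- vapply(site, function(s) {
    h <- which(vapply(groups, function(g) s %in% g, TRUE))
    if (length(h) != 1L) stop("no active-marrow entry for site ", s,
                              " at age ", age)
    h
  }, 1L)
  covered <- unlist(groups) %in% site
  if (!all(covered)) {
    stop("active-marrow site(s) without segments: ",
         paste(setdiff(unlist(groups), site), collapse = ", "))
  }
  med <- t(vapply(seq_len(nrow(seg)), function(i) {
    m <- segment_media_volumes(seg[i, ])
    c(bmv = m[["bmv"]],
      spong1 = m[["spongiosa"]] / (seg$n_s[i] * seg$k_s[i]))
  }, numeric(2)))
  # segment weight: AM fraction of its group x its BMV share within the group
  wgroup <- am$am_fraction[gidx]
  bmv_group <- tapply(med[, "bmv"], gidx, sum)[as.character(gidx)]
  w <- wgroup * med[, "bmv"] / bmv_group
  w <- w / sum(w)
  ctth <- vapply(seq_len(nrow(seg)), function(i) .segment_ctth(seg[i, ]), 1.0)
  list(spongiosa_cm3 = sum(w * med[, "spong1"]),
       bvtv = sum(w * seg$bvtv),
       ct_th_mm = sum(w * ctth),
       weights = data.frame(key = seg$key, site = site, weight = w,
                            bvtv = seg$bvtv, ct_th = ctth,
                            spongiosa_cm3 = med[, "spong1"]))
}

#' Volume fraction of the vertebral body in a lumbar vertebra
#'
#' Ratio of the closed-form volume of the lumbar body segment to the volume
#' of the whole vertebra assembled with anatomical multiplicities: one body,
#' one spinous process, two transverse processes and -- where the phantom
#' models them -- two superior processes and two lamina+inferior processes.
#' Per-vertebra multiplicities are the stored skeleton multiplicities divided
#' by the five lumbar levels.
#'
#' @param db an `spsd_db`.
#' @param age reference age group.
#' @param sex `"male"` or `"female"`.
#' @return the volume fraction (dimensionless), with attribute `parts`
#'   listing the component volumes (mm^3).
#' @export
vertebral_body_fraction <- function(db, age, sex = c("male", "female")) {
  seg <- spsd_segments(db, age, sex)
  lum <- seg[vapply(seq_len(nrow(seg)), function(i) {
    seg$site[i] == "Vertebra" && .am_site(seg$site[i], seg$segment[i]) ==
      "Lumbar vertebrae"
  }, TRUE), , drop = FALSE]
  if (nrow(lum) == 0L) stop("no lumbar segments for this phantom")
  nn <- .norm_name(lum$segment)
  is_body <- grepl("body", nn)
  if (sum(is_body) != 1L) stop("expected exactly one lumbar body segment")
  vol <- vapply(seq_len(nrow(lum)), function(i) {
    analytic_volume(record_shape(lum[i, ]))
  }, 1.0)
  mult <- lum$n_s / 5
  v_body <- vol[is_body] * mult[is_body]
  v_all <- sum(vol * mult)
  structure(v_body / v_all,
            parts = setNames(vol * mult, lum$segment))
}
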