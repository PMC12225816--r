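#' Configuration of inter-individual parameter variability
#'
#' Describes how individualized parameter sets are drawn around a reference
#' segment record: linear dimensions are normally distributed and positively
#' correlated (by default perfectly, through one shared factor), Tb.Th and
#' Tb.Sp are lognormal with a negative rank correlation (Gaussian copula, by
#' default comonotone-negative), cortical thickness is an independent normal
#' truncated at zero, and BV/TV is drawn uniformly inside a per-segment
#' admissible band. Correlation magnitudes are configurable because only the
#' signs are anatomically established; the defaults are the extreme values,
#' the simplest model consistent with those signs. Per-segment CV magnitudes
#' are placeholders to be supplied from population data when available.
#'
#' @param dims_cv CV of linear dimensions, percent.
#' @param ctth_cv CV of cortical thickness, percent.
#' @param tbth_cv,tbsp_cv CVs of Tb.Th and Tb.Sp, percent.
#' @param dims_corr correlation of the latent normals behind the linear
#'   dimensions, in `[0, 1]`; 1 means one shared scale factor.
#' @param tbth_tbsp_corr Gaussian-copula correlation of (Tb.Th, Tb.Sp), in
#'   `[-1, 0]`; -1 is comonotone-negative (Spearman rank correlation -1).
#' @param bvtv_range_rel half-width of the admissible BV/TV band, relative to
#'   the record value (default 0.25, i.e. +/- 25 percent, clipped to (0, 1));
#'   0 keeps BV/TV fixed.
#' @param max_resample resampling bound for draws that violate record
#'   invariants (negative dimensions, cortex swallowing the segment).
#' @return object of class `spsd_varcfg`.
#' @export
variability_config <- function(dims_cv = 5, ctth_cv = 10, tbth_cv = 22,
                               tbsp_cv = 23, dims_corr = 1,
                               tbth_tbsp_corr = -1, bvtv_range_rel = 0.25,
                               max_resample = 100) {
  stopifnot(dims_cv >= 0, ctth_cv >= 0, tbth_cv >= 0, tbsp_cv >= 0,
            dims_corr >= 0, dims_corr <= 1,
            tbth_tbsp_corr >= -1, tbth_tbsp_corr <= 0,
            bvtv_range_rel >= 0, bvtv_range_rel < 1, max_resample >= 1)
  structure(list(dims_cv = dims_cv, ctth_cv = ctth_cv, tbth_cv = tbth_cv,
                 tbsp_cv = tbsp_cv, dims_corr = dims_corr,
                 tbth_tbsp_corr = tbth_tbsp_corr,
                 bvtv_range_rel = bvtv_range_rel,
                 max_resample = max_resample),
            class = "spsd_varcfg")
}

#' Draw a cohort of individualized parameter sets for one segment
#'
#' @param rec one row of `spsd_db()$segments`.
#' @param cfg an `spsd_varcfg`.
#' @param n cohort size.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data.frame with one row per draw: the scaled dimensions present in
#'   the record (`h`, `a`, `b`, `c_ax`, `d_ax`), `ct_scale` (multiplier
#'   applied to every cortical face thickness), `tb_th`, `tb_sp`, `bvtv`.
#' @export
sample_cohort <- function(rec, cfg, n, seed = NULL) {
  stopifnot(inherits(cfg, "spsd_varcfg"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  dims <- c("h", "a", "b", "c_ax", "d_ax")
  base <- vapply(dims, function(f) rec[[f]], 1.0)
  present <- !is.na(base)
  shape0 <- record_shape(rec)
  ct0 <- record_cortical(rec)

  cv <- cfg$dims_cv / 100
  rho <- cfg$dims_corr
  draw_dims <- function(m) {
    z0 <- rnorm(m)
    out <- matrix(NA_real_, m, length(dims), dimnames = list(NULL, dims))
    for (j in which(present)) {
      zj <- sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(m)
      out[, j] <- base[j] * (1 + cv * zj)
    }
    out
  }

  cvt <- cfg$ctth_cv / 100
  draw_ct <- function(m) {
    if (is.null(ct0) || cvt == 0) return(rep(1, m))
    g <- 1 + cvt * rnorm(m)
    for (it in seq_len(cfg$max_resample)) {
      bad <- g <= 0
      if (!any(bad)) break
      g[bad] <- 1 + cvt * rnorm(sum(bad))
    }
    if (any(g <= 0)) stop("cortical thickness factor not positive after resampling")
    g
  }

  lp_th <- .lnorm_pars(rec$tb_th, cfg$tbth_cv / 100)
  lp_sp <- .lnorm_pars(rec$tb_sp, cfg$tbsp_cv / 100)
  z1 <- rnorm(n)
  z2 <- cfg$tbth_tbsp_corr * z1 +
    sqrt(1 - cfg$tbth_tbsp_corr^2) * rnorm(n)
  tb_th <- if (cfg$tbth_cv == 0) rep(rec$tb_th, n) else
    exp(lp_th["meanlog"] + lp_th["sdlog"] * z1)
  tb_sp <- if (cfg$tbsp_cv == 0) rep(rec$tb_sp, n) else
    exp(lp_sp["meanlog"] + lp_sp["sdlog"] * z2)

  r <- cfg$bvtv_range_rel
  bvtv <- if (r == 0) rep(rec$bvtv, n) else
    runif(n, max(1e-3, rec$bvtv * (1 - r)), min(0.999, rec$bvtv * (1 + r)))

  dm <- draw_dims(n)
  ct <- draw_ct(n)

  # re-validate every draw against the record invariants; resample violators
  valid_draw <- function(i) {
    d <- dm[i, ]
    if (any(d[present] <= 0)) return(FALSE)
    sh <- try(shape_spec(shape0$kind, h = d[["h"]], a = d[["a"]], b = d[["b"]],
                         c = d[["c_ax"]], d = d[["d_ax"]]), silent = TRUE)
    if (inherits(sh, "try-error")) return(FALSE)
    if (!is.null(ct0)) {
      cts <- ct0; cts$thickness <- cts$thickness * ct[i]
      ok <- try(.analytic_media(sh, cts), silent = TRUE)
      if (inherits(ok, "try-error")) return(FALSE)
    }
    TRUE
  }
  for (it in seq_len(cfg$max_resample)) {
    bad <- which(!vapply(seq_len(n), valid_draw, TRUE))
    if (length(bad) == 0L) break
    dm[bad, ] <- draw_dims(length(bad))
    ct[bad] <- draw_ct(length(bad))
  }
  bad <- which(!vapply(seq_len(n), valid_draw, TRUE))
  if (length(bad)) {
    stop("could not draw valid parameter sets after ", cfg$max_resample,
         " resampling rounds (", length(bad), " draws violate invariants)")
  }
  out <- as.data.frame(dm)
  out$ct_scale <- ct
  out$tb_th <- tb_th
  out$tb_sp <- tb_sp
  out$bvtv <- bvtv
  out
}

#' Draw one individualized segment record
#'
#' With all CVs zero the output equals the input record.
#'
#' @param rec one row of `spsd_db()$segments`.
#' @param cfg an `spsd_varcfg`.
#' @param seed integer seed.
#' @return a one-row segment record with perturbed parameters.
#' @export
sample_individual <- function(rec, cfg, seed = NULL) {
  d <- sample_cohort(rec, cfg, 1L, seed = seed)
  out <- rec
  for (f in c("h", "a", "b", "c_ax", "d_ax")) {
    if (!is.na(out[[f]])) out[[f]] <- d[[f]]
  }
  ct <- record_cortical(out)
  if (!is.null(ct)) {
    ct$thickness <- ct$thickness * d$ct_scale
    out$cortical <- list(ct)
  }
  out$tb_th <- d$tb_th
  out$tb_sp <- d$tb_sp
  out$bvtv <- d$bvtv
  out
}

#' Cohort coefficients of variation of segment media volumes
#'
#' Generates `n` individualized parameter sets and evaluates the media
#' volumes of each through the closed-form (analytic) path -- no
#' voxelization -- returning the empirical CVs of trabecular bone, cortical
#' bone and marrow volume with first-order Monte Carlo standard errors.
#'
#' @param rec one row of `spsd_db()$segments`.
#' @param cfg an `spsd_varcfg`.
#' @param n cohort size (at least 100 recommended).
#' @param seed integer seed.
#' @return data.frame with rows `tbv`, `cbv`, `bmv`: columns `mean_cm3`,
#'   `cv_pct`, `cv_se_pct`, `n`.
#' @export
cohort_media_cv <- function(rec, cfg, n = 1000, seed = NULL) {
  draws <- sample_cohort(rec, cfg, n, seed = seed)
  ct0 <- record_cortical(rec)
  kind <- record_shape(rec)$kind
  vols <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("tbv", "cbv", "bmv")))
  for (i in seq_len(n)) {
    sh <- shape_spec(kind, h = draws$h[i], a = draws$a[i], b = draws$b[i],
                     c = draws$c_ax[i], d = draws$d_ax[i])
    ct <- ct0
    if (!is.null(ct)) ct$thickness <- ct$thickness * draws$ct_scale[i]
    med <- .analytic_media(sh, ct)
    tbv <- draws$bvtv[i] * med$spongiosa
    vols[i, ] <- c(tbv, med$cortical, med$spongiosa - tbv) / 1000
  }
  cvp <- function(x) if (mean(x) == 0) 0 else 100 * sd(x) / mean(x)
  cv <- apply(vols, 2, cvp)
  # first-order SE of a sample CV (normal approximation)
  se <- cv * sqrt((1 + 2 * (cv / 100)^2) / (2 * n))
  data.frame(medium = colnames(vols), mean_cm3 = colMeans(vols),
             cv_pct = cv, cv_se_pct = se, n = n, row.names = NULL)
}
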