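#' @useDynLib spsd, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm sd cor quantile setNames aggregate
#' @importFrom utils read.delim write.csv head
NULL

.spsd_ages <- c("newborn", "1y", "5y", "10y", "15y", "adult")
.sexed_ages <- c("15y", "adult")

# Printed per-age census of unique segments and their shapes (reference
# constants used by validate_db(); shape columns b, c, dc, p, e, t).
.census_printed <- data.frame(
  age    = c(.spsd_ages, "total"),
  n      = c(34, 39, 43, 38, 64, 71, 289),
  shared = c(NA, NA, NA, NA, 28, 23, NA),
  b      = c(11, 15, 17, 17, 39, 43, 142),
  c      = c(13, 13, 15, 11, 14, 17, 83),
  dc     = c(9, 10, 10, 9, 9, 9, 56),
  p      = c(0, 1, 1, 1, 1, 1, 5),
  e      = c(1, 0, 0, 0, 0, 0, 1),
  t      = c(0, 0, 0, 0, 1, 1, 2),
  stringsAsFactors = FALSE
)

.shape_codes <- c(b = 1L, c = 2L, dc = 3L, p = 4L, e = 5L, t = 6L)
.shape_names <- c(b = "box", c = "cylinder", dc = "deformed_cylinder",
                  p = "prism", e = "ellipsoid", t = "tube")

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "spsd")
  if (!nzchar(path)) stop("embedded resource not found: ", name)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("NA", ""))
}

# "lateral:0.5;ab1:3.6" -> data.frame(face, thickness); NA/"" -> NULL
.parse_cortical <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed cortical spec: ", s)
  data.frame(face = vapply(kv, `[`, "", 1L),
             thickness = as.numeric(vapply(kv, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

.format_cortical <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("")
  df <- df[order(df$face), , drop = FALSE]
  paste(sprintf("%s:%g", df$face, df$thickness), collapse = ";")
}

# case/punctuation-insensitive segment-name normalization used when matching
# male and female rows of the same reference age
.norm_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.apply_curation <- function(seg, cur) {
  num_fields <- c("h", "a", "b", "c_ax", "d_ax")
  for (r in seq_len(nrow(cur))) {
    cr <- cur[r, ]
    hit <- seg$age == cr$age & seg$site == cr$site & seg$segment == cr$segment &
      (cr$sex == "any" | seg$sex == cr$sex)
    if (!any(hit)) {
      stop("curation entry ", cr$id, " matches no database row (",
           cr$age, "/", cr$sex, "/", cr$site, "/", cr$segment, ")")
    }
    fld <- cr$field
    for (i in which(hit)) {
      cur_val <- if (fld %in% num_fields) {
        v <- seg[[fld]][i]
        if (is.na(v)) "NA" else format(v)
      } else as.character(seg[[fld]][i])
      printed <- if (is.na(cr$printed)) "NA" else as.character(cr$printed)
      if (fld %in% num_fields) {
        ok <- (printed == "NA" && cur_val == "NA") ||
          (printed != "NA" && cur_val != "NA" &&
             isTRUE(all.equal(as.numeric(printed), as.numeric(cur_val))))
      } else ok <- identical(printed, cur_val)
      if (!ok) {
        stop("curation entry ", cr$id, ": stored value ", cur_val,
             " does not match the printed value ", printed)
      }
      new <- cr$curated
      if (fld %in% num_fields) {
        seg[[fld]][i] <- if (identical(new, "NA")) NA_real_ else as.numeric(new)
      } else if (fld == "sex_specific") {
        seg[[fld]][i] <- as.logical(new)
      } else {
        seg[[fld]][i] <- new
      }
    }
  }
  seg
}

#' Load the skeletal segment parameter database
#'
#' Reads the embedded parameter tables (segment geometry and
#' microarchitecture, active-marrow distribution, media composition and
#' densities) and returns them as a single database object. In `"curated"`
#' mode the curation table -- the documented list of corrections of
#' typographic slips in the printed source tables -- is applied; `"raw"` mode
#' returns the tables exactly as printed. The two modes differ on exactly the
#' rows listed in the curation table.
#'
#' @param mode `"curated"` (default) or `"raw"`.
#' @return An object of class `spsd_db`: a list with elements `segments`,
#'   `am`, `composition`, `densities`, `curation` and `mode`. `segments` has
#'   one row per printed table row (male and female tables of the 15-year-old
#'   and adult phantoms are separate rows); `cortical` is a list column of
#'   `data.frame(face, thickness)` (`NULL` when the segment has no cortex,
#'   e.g. newborn vertebrae).
#' @examples
#' db <- spsd_db()
#' segment_count(db, "newborn")
#' @export
spsd_db <- function(mode = c("curated", "raw")) {
  mode <- match.arg(mode)
  seg <- .extdata("segments.tsv")
  seg$sex_specific <- FALSE
  cur <- .extdata("curation.tsv")
  if (mode == "curated") seg <- .apply_curation(seg, cur)
  seg$cortical <- lapply(seg$cortical, function(s) {
    if (is.na(s)) NULL else .parse_cortical(s)
  })
  # unique keys; printed duplicates (e.g. the five 1-y sacrum "Body" rows)
  # are disambiguated with an ordinal suffix
  base <- paste(seg$age, seg$sex, seg$site, seg$segment, sep = "/")
  key <- base
  for (k in unique(base[duplicated(base)])) {
    i <- which(base == k)
    key[i] <- paste0(k, " (", seq_along(i), ")")
  }
  seg$key <- key
  db <- list(segments = seg,
             am = .extdata("am_distribution.tsv"),
             composition = .extdata("composition.tsv"),
             densities = .extdata("densities.tsv"),
             curation = cur,
             mode = mode)
  class(db) <- "spsd_db"
  .check_db_integrity(db)
  db
}

.check_db_integrity <- function(db) {
  seg <- db$segments
  bad <- which(!seg$shape %in% names(.shape_codes))
  if (length(bad)) stop("unknown shape code in row ", bad[1], ": ", seg$shape[bad[1]])
  bad <- which(is.na(seg$h) & seg$shape != "e" | is.na(seg$a) | is.na(seg$b))
  if (db$mode == "curated" && length(bad)) {
    stop("missing dimension in segment row ", bad[1], " (", seg$key[bad[1]], ")")
  }
  if (!all(db$am$age %in% .spsd_ages)) stop("unknown age group in AM table")
  invisible(db)
}

#' @export
print.spsd_db <- function(x, ...) {
  cat("<spsd_db> mode:", x$mode, "-", nrow(x$segments), "segment rows,",
      segment_count(x), "unique segments\n")
  invisible(x)
}

#' Segment records of one reference phantom
#'
#' @param db an `spsd_db` object.
#' @param age one of `"newborn"`, `"1y"`, `"5y"`, `"10y"`, `"15y"`, `"adult"`.
#' @param sex `"male"` or `"female"`; ignored for ages up to 10 years whose
#'   tables are not sex-specific.
#' @return The matching rows of `db$segments`.
#' @export
spsd_segments <- function(db, age, sex = c("male", "female")) {
  stopifnot(inherits(db, "spsd_db"))
  age <- match.arg(age, .spsd_ages)
  seg <- db$segments
  if (age %in% .sexed_ages) {
    sex <- match.arg(sex)
    seg[seg$age == age & seg$sex == sex, , drop = FALSE]
  } else {
    seg[seg$age == age, , drop = FALSE]
  }
}

# fields compared when deciding whether a male and a female row of the same
# age describe one shared (not sex-specific) segment
.record_signature <- function(rows) {
  num <- c("h", "a", "b", "c_ax", "d_ax", "bvtv", "tb_th", "sigma_tb_th",
           "tb_sp", "sigma_tb_sp")
  vals <- lapply(seq_len(nrow(rows)), function(i) {
    v <- vapply(num, function(f) {
      x <- rows[[f]][i]
      if (is.na(x)) "NA" else format(x, digits = 12)
    }, "")
    paste(rows$shape[i], paste(v, collapse = "|"),
          .format_cortical(rows$cortical[[i]]), sep = "||")
  })
  unlist(vals)
}

# male/female row pairing for one sexed age; returns a data.frame with the
# matched indices and a logical `shared`
.sex_pairs <- function(db, age) {
  m <- spsd_segments(db, age, "male")
  f <- spsd_segments(db, age, "female")
  mk <- paste(m$site, .norm_name(m$segment))
  fk <- paste(f$site, .norm_name(f$segment))
  common <- intersect(mk, fk)
  im <- match(common, mk)
  iff <- match(common, fk)
  shared <- .record_signature(m[im, ]) == .record_signature(f[iff, ]) &
    !m$sex_specific[im] & !f$sex_specific[iff]
  list(male = m, female = f, im = im, iff = iff, shared = shared)
}

# unique segment rows for one age (shared male/female records counted once,
# represented by the male row)
.unique_rows <- function(db, age) {
  if (!age %in% .sexed_ages) return(spsd_segments(db, age))
  p <- .sex_pairs(db, age)
  drop_f <- p$iff[p$shared]
  if (length(drop_f)) rbind(p$male, p$female[-drop_f, ]) else rbind(p$male, p$female)
}

#' Count unique segment models
#'
#' Counts segment records; for the sex-specific reference ages (15 years and
#' adult) a record whose full normalized parameter set is identical between
#' the male and the female table is counted once.
#'
#' @param db an `spsd_db` object.
#' @param scope `"all"` or one reference age.
#' @return integer count.
#' @examples
#' db <- spsd_db()
#' segment_count(db)             # 289
#' segment_count(db, "newborn")  # 34
#' @export
segment_count <- function(db, scope = "all") {
  stopifnot(inherits(db, "spsd_db"))
  if (identical(scope, "all")) {
    return(sum(vapply(.spsd_ages, function(a) nrow(.unique_rows(db, a)), 1L)))
  }
  scope <- match.arg(scope, .spsd_ages)
  nrow(.unique_rows(db, scope))
}

#' Number of shared (not sex-specific) segments at a sexed reference age
#' @param db an `spsd_db` object.
#' @param age `"15y"` or `"adult"`.
#' @return integer count of records identical between the sexes.
#' @export
segment_shared_count <- function(db, age = c("15y", "adult")) {
  age <- match.arg(age)
  sum(.sex_pairs(db, age)$shared)
}

#' Tally unique segments by geometric primitive
#'
#' @param db an `spsd_db` object.
#' @param scope `"all"` or one reference age.
#' @return named integer vector over shape codes
#'   (`b`, `c`, `dc`, `p`, `e`, `t`).
#' @export
shape_census <- function(db, scope = "all") {
  stopifnot(inherits(db, "spsd_db"))
  ages <- if (identical(scope, "all")) .spsd_ages else match.arg(scope, .spsd_ages)
  shapes <- unlist(lapply(ages, function(a) .unique_rows(db, a)$shape))
  out <- table(factor(shapes, levels = names(.shape_codes)))
  setNames(as.integer(out), names(.shape_codes))
}

# canonical active-marrow site for a segment row
.am_site <- function(site, segment) {
  if (site != "Vertebra") return(site)
  n <- tolower(segment)
  if (grepl("^c", n) | grepl("^cervical", n)) return("Cervical vertebrae")
  if (grepl("^l", n) | grepl("^lumbar", n)) return("Lumbar vertebrae")
  if (grepl("^t", n) | grepl("^thoracic", n)) return("Thoracic vertebrae")
  stop("cannot classify vertebral segment: ", segment)
}

#' Active-marrow fraction of a skeletal site
#'
#' Looks up the percentage of total active (red) marrow assigned to a
#' skeletal site for a given reference phantom. Some sites are pooled in the
#' source distribution (for adults, clavicle + scapula + ribs share one
#' value); for members of such a group the group value is returned with the
#' membership attached. A site that is not hematopoietic at the given age
#' raises an error of class `spsd_no_am` -- absence of active marrow is an
#' explicit signal, not a zero.
#'
#' @param db an `spsd_db` object.
#' @param age reference age group.
#' @param sex `"male"` or `"female"` (the distribution is shared between the
#'   sexes; the argument is accepted for interface symmetry).
#' @param site site name, e.g. `"Skull"` or `"Lumbar vertebrae"`.
#' @return numeric percentage with attributes `group` (character vector of
#'   the pooled sites) and `grouped` (logical).
#' @export
am_fraction <- function(db, age, sex = c("male", "female"), site) {
  stopifnot(inherits(db, "spsd_db"))
  age <- match.arg(age, .spsd_ages)
  am <- db$am[db$am$age == age, , drop = FALSE]
  groups <- strsplit(am$sites, "|", fixed = TRUE)
  hit <- which(vapply(groups, function(g) site %in% g, TRUE))
  if (length(hit) == 0L) {
    known <- site %in% unlist(strsplit(db$am$sites, "|", fixed = TRUE))
    msg <- if (known) {
      paste0("site ", site, " has no active marrow at age ", age)
    } else paste0("unknown site: ", site)
    stop(structure(class = c("spsd_no_am", "error", "condition"),
                   list(message = msg, call = sys.call())))
  }
  structure(am$am_fraction[hit],
            group = groups[[hit]],
            grouped = length(groups[[hit]]) > 1L)
}

#' Consistency report for the segment database
#'
#' Runs the internal consistency checks: positivity and range invariants of
#' every record, validity of cortical face designations, normalization of the
#' active-marrow distribution (each phantom must sum to 100 +/- 0.1 percent),
#' media composition sums, monotonicity of bone density with age, the
#' documented extremal claims (minimum/maximum bone volume fraction, cortical
#' thickness range 0.1-3.7 mm, linear dimension range 2-88 mm), and the
#' printed per-age census of unique segments and shapes. All checks pass in
#' curated mode; raw mode reports the rows that curation corrects.
#'
#' @param db an `spsd_db` object.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_db <- function(db) {
  stopifnot(inherits(db, "spsd_db"))
  seg <- db$segments
  res <- list()
  add <- function(check, pass, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(check = check, pass = pass,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }

  # AM normalization per phantom (15y and adult each cover two phantoms)
  sums <- vapply(.spsd_ages, function(a) {
    sum(db$am$am_fraction[db$am$age == a])
  }, 1.0)
  add("am_sums_100", all(abs(sums - 100) <= 0.1),
      paste(sprintf("%s=%.2f", .spsd_ages, sums), collapse = ", "))

  dims <- c("h", "a", "b", "c_ax", "d_ax")
  dvals <- unlist(seg[dims])
  add("dims_positive", all(dvals > 0, na.rm = TRUE), "")
  add("bvtv_in_unit_interval", all(seg$bvtv > 0 & seg$bvtv < 1), "")
  add("micro_positive", all(seg$tb_th > 0 & seg$tb_sp > 0), "")
  add("multiplicity", all(seg$n_s >= 1 & seg$k_s >= 1), "")

  faces_ok <- vapply(seq_len(nrow(seg)), function(i) {
    ct <- seg$cortical[[i]]
    if (is.null(ct)) return(TRUE)
    all(ct$face %in% valid_faces(seg$shape[i])) && all(ct$thickness > 0)
  }, TRUE)
  add("cortical_faces_valid", all(faces_ok),
      if (all(faces_ok)) "" else paste(seg$key[!faces_ok], collapse = "; "))

  imin <- which.min(seg$bvtv); imax <- which.max(seg$bvtv)
  add("min_bvtv", seg$bvtv[imin] == 0.06 &&
        seg$site[imin] == "Humerus" && seg$age[imin] == "adult",
      sprintf("%.2f at %s", seg$bvtv[imin], seg$key[imin]))
  add("max_bvtv", seg$bvtv[imax] == 0.6 &&
        seg$age[imax] == "newborn" && grepl("^C", seg$segment[imax]),
      sprintf("%.2f at %s", seg$bvtv[imax], seg$key[imax]))

  ct_all <- unlist(lapply(seg$cortical, function(x) if (is.null(x)) NULL else x$thickness))
  add("ctth_range_01_37", isTRUE(all.equal(range(ct_all), c(0.1, 3.7))),
      sprintf("[%g, %g] mm", min(ct_all), max(ct_all)))
  add("max_linear_dim_88", isTRUE(all.equal(max(dvals, na.rm = TRUE), 88)),
      sprintf("%g mm", max(dvals, na.rm = TRUE)))
  add("min_linear_dim_2", isTRUE(all.equal(min(dvals, na.rm = TRUE), 2)),
      sprintf("%g mm", min(dvals, na.rm = TRUE)))

  dn <- db$densities[match(.spsd_ages, db$densities$age), ]
  add("bone_density_nondecreasing", !is.unsorted(dn$bone_density),
      paste(dn$bone_density, collapse = ", "))
  add("marrow_density_values",
      all(dn$marrow_density[dn$age != "adult"] == 1.0) &&
        dn$marrow_density[dn$age == "adult"] == 0.98, "")

  cs <- tapply(db$composition$mass_fraction, db$composition$medium, sum)
  add("composition_sums_100", all(abs(cs - 100) <= 0.5),
      paste(sprintf("%s=%.1f", names(cs), cs), collapse = ", "))

  # printed census reproduction
  cen_ok <- TRUE; cen_det <- character()
  for (i in seq_len(nrow(.census_printed))) {
    row <- .census_printed[i, ]
    scope <- if (row$age == "total") "all" else row$age
    n <- segment_count(db, scope)
    sc <- shape_census(db, scope)
    ok <- n == row$n && all(sc == unlist(row[names(.shape_codes)]))
    if (!is.na(row$shared)) {
      ok <- ok && segment_shared_count(db, row$age) == row$shared
    }
    if (!ok) {
      cen_ok <- FALSE
      cen_det <- c(cen_det, sprintf("%s: n=%d [%s]", row$age, n,
                                    paste(sc, collapse = ",")))
    }
  }
  add("census_matches_printed", cen_ok, paste(cen_det, collapse = "; "))

  do.call(rbind, res)
}

#' Media density for a reference age
#' @param db an `spsd_db` object.
#' @param age reference age group.
#' @return named numeric vector `c(bone = , marrow = )` in g/cm^3.
#' @export
media_density <- function(db, age) {
  age <- match.arg(age, .spsd_ages)
  i <- match(age, db$densities$age)
  c(bone = db$densities$bone_density[i], marrow = db$densities$marrow_density[i])
}

#' Export the embedded tables as CSV files
#' @param db an `spsd_db` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_tables <- function(db, dir = ".") {
  stopifnot(inherits(db, "spsd_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- db$segments
  seg$cortical <- vapply(seg$cortical, .format_cortical, "")
  paths <- file.path(dir, c("segments.csv", "am_distribution.csv",
                            "composition.csv", "densities.csv", "curation.csv"))
  write.csv(seg, paths[1], row.names = FALSE)
  write.csv(db$am, paths[2], row.names = FALSE)
  write.csv(db$composition, paths[3], row.names = FALSE)
  write.csv(db$densities, paths[4], row.names = FALSE)
  write.csv(db$curation, paths[5], row.names = FALSE)
  invisible(paths)
}

# resolve a segment key like "adult/male/Femur/Neck" (exact or unique
# case-insensitive substring match)
.resolve_key <- function(db, key) {
  keys <- db$segments$key
  i <- which(keys == key)
  if (length(i) == 1L) return(i)
  i <- grep(tolower(key), tolower(keys), fixed = TRUE)
  if (length(i) == 1L) return(i)
  if (length(i) == 0L) stop("no segment matches key: ", key)
  stop("ambiguous key '", key, "'; candidates: ",
       paste(keys[i], collapse = "; "))
}
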