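#' Write a voxel phantom as an NRRD file
#'
#' Writes the label array as NRRD (detached headers are not used; the header
#' records the voxel size in mm, the label legend, the originating segment
#' key, the generation seed, the database mode and the package version --
#' enough to regenerate the phantom bit-identically).
#'
#' @param phantom an `spsd_phantom`.
#' @param path output file path.
#' @param encoding `"gzip"` (default), `"raw"` or `"ascii"`.
#' @param db_mode database mode recorded in the header.
#' @return invisibly, `path`.
#' @export
write_nrrd <- function(phantom, path, encoding = c("gzip", "raw", "ascii"),
                       db_mode = "curated") {
  stopifnot(inherits(phantom, "spsd_phantom"))
  encoding <- match.arg(encoding)
  n <- dim(phantom$labels)
  seed <- phantom$generation$seed
  hdr <- c(
    "NRRD0004",
    "# labelled bone-segment voxel phantom",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", n[1], n[2], n[3]),
    sprintf("spacings: %.9g %.9g %.9g", phantom$voxel_size,
            phantom$voxel_size, phantom$voxel_size),
    sprintf("encoding: %s", encoding),
    "endian: little",
    sprintf("space units: \"mm\" \"mm\" \"mm\""),
    "labels:=0 background|1 marrow|2 trabecular bone|3 cortical bone",
    sprintf("segment:=%s", phantom$record_key %||% "ad hoc"),
    sprintf("seed:=%s", if (is.null(seed)) "none" else seed),
    sprintf("dbmode:=%s", db_mode),
    sprintf("generator:=spsd %s",
            as.character(utils::packageVersion("spsd"))),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writLines <- paste0(paste(hdr, collapse = "\n"), "\n")
  writeChar(writLines, con, eos = NULL)
  bytes <- as.raw(as.integer(phantom$labels))
  if (encoding == "gzip") {
    writeBin(memCompress(bytes, "gzip"), con)
  } else if (encoding == "raw") {
    writeBin(bytes, con)
  } else {
    writeChar(paste(as.integer(phantom$labels), collapse = " "), con,
              eos = NULL)
  }
  invisible(path)
}

#' Read an NRRD phantom written by [write_nrrd()]
#'
#' Supports the subset of NRRD this package emits (3-D uint8, gzip/raw/ascii
#' encodings, isotropic spacings).
#'
#' @param path NRRD file path.
#' @return a list with `labels` (3-D integer array), `voxel_size` and the
#'   header key-values.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !nzchar(ln)) break
    hdr <- c(hdr, ln)
  }
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^", key, ": "), "", ln[1]) else NULL
  }
  sizes <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  spac <- as.numeric(strsplit(get_field("spacings"), " ")[[1]])
  enc <- get_field("encoding")
  nvox <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  labels <- switch(enc,
    raw = as.integer(payload[seq_len(nvox)]),
    gzip = as.integer(memDecompress(payload, "gzip")[seq_len(nvox)]),
    ascii = as.integer(strsplit(trimws(rawToChar(payload)), "[ \n]+")[[1]]),
    stop("unsupported encoding: ", enc))
  kv <- grep(":=", hdr, value = TRUE)
  kvs <- strsplit(kv, ":=", fixed = TRUE)
  meta <- setNames(vapply(kvs, `[`, "", 2L), vapply(kvs, `[`, "", 1L))
  list(labels = array(labels, sizes), voxel_size = spac[1],
       meta = as.list(meta))
}

#' Serialize a morphometry or generation report as JSON
#' @param report an `spsd_morphometry` or a generation report list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  rep2 <- unclass(report)
  rep2$rods <- NULL
  jsonlite::write_json(rep2, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
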