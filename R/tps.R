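#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect written by common 2-D digitizing tools: records
#' start with `LM=k`, followed by k lines of "x y" coordinates (y-up), with
#' optional `IMAGE=`, `ID=` and `SCALE=` lines. `ID=` is used as the
#' specimen id when present, else the `IMAGE=` file stem, else the record's
#' sequential index. A `SCALE=` factor multiplies the coordinates.
#'
#' @param path Path to a TPS file.
#' @param scheme A [landmark_scheme()]; every record must have `LM=` equal
#'   to `scheme$n_landmarks`.
#' @return A list of configurations, each a list with elements `id`,
#'   `coords` (k x 2 matrix) and `metadata`.
#' @export
read_tps <- function(path, scheme) {
  if (!file.exists(path)) stop("TPS file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L)
    stop("empty TPS file (no LM= records): ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L],
                                         ignore.case = TRUE)))
    if (is.na(k))
      stop(sprintf("TPS record %d: malformed LM= line", r), call. = FALSE)
    if (k != scheme$n_landmarks)
      stop(sprintf("TPS record %d: LM=%d does not match scheme (%d landmarks)",
                   r, k, scheme$n_landmarks), call. = FALSE)
    body <- block[-1L]
    is_kv <- grepl("=", body, fixed = TRUE)
    coord_lines <- body[!is_kv]
    if (length(coord_lines) != k)
      stop(sprintf("TPS record %d: expected %d coordinate lines, found %d",
                   r, k, length(coord_lines)), call. = FALSE)
    xy <- suppressWarnings(
      do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric)))
    if (is.null(dim(xy)) || ncol(xy) != 2L || anyNA(xy))
      stop(sprintf("TPS record %d: non-numeric or non-2D coordinates", r),
           call. = FALSE)
    kv <- body[is_kv]
    keys <- toupper(sub("\\s*=.*$", "", kv))
    vals <- sub("^[^=]*=\\s*", "", kv)
    id <- NULL
    if ("ID" %in% keys) id <- vals[match("ID", keys)]
    else if ("IMAGE" %in% keys)
      id <- tools::file_path_sans_ext(basename(vals[match("IMAGE", keys)]))
    if (is.null(id) || !nzchar(id)) id <- as.character(r)
    if ("SCALE" %in% keys) {
      sc <- suppressWarnings(as.numeric(vals[match("SCALE", keys)]))
      if (is.na(sc))
        stop(sprintf("TPS record %d: non-numeric SCALE=", r), call. = FALSE)
      xy <- xy * sc
    }
    configs[[r]] <- list(id = id, coords = unname(xy), metadata = list())
  }
  ids <- vapply(configs, `[[`, "", "id")
  if (anyDuplicated(ids))
    warning("duplicate specimen ids in TPS file: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Writes the same dialect [read_tps()] accepts (`LM=`, coordinate lines,
#' `ID=`). Coordinates are written as digitized, without a scale factor.
#'
#' @param configs List of configurations (`id`, `coords`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  out <- unlist(lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    c(sprintf("LM=%d", nrow(cf$coords)),
      sprintf("%.10g %.10g", cf$coords[, 1L], cf$coords[, 2L]),
      sprintf("ID=%s", cf$id %||% as.character(i)))
  }))
  writeLines(out, path)
  invisible(path)
}
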