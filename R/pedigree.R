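# Pedigree handling and the numerator relationship matrix.

#' Construct a pedigree
#'
#' Validates individual/dam/sire records, appends parents that are named
#' but have no record of their own as founders, checks for cycles, and
#' stores records in topological (parents-before-offspring) order.
#'
#' @param id Character vector of individual ids (unique).
#' @param dam,sire Character vectors of parent ids; unknown parents as
#'   `NA`, `""`, or `"0"`.
#' @param sex,family Optional per-individual annotations carried along.
#' @return Object of class `pedigree`: data frame with columns `id`,
#'   `dam`, `sire`, `founder` (plus `sex`/`family` when given), in
#'   topological order.
#' @export
pedigree <- function(id, dam, sire, sex = NULL, family = NULL) {
  id <- as.character(id)
  clean_ <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & (p == "" | p == "0" | toupper(p) == "NA")] <- NA_character_
    p
  }
  dam <- clean_(dam)
  sire <- clean_(sire)
  if (anyDuplicated(id))
    stop("duplicate individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  if (length(dam) != length(id) || length(sire) != length(id))
    stop("id, dam and sire must have equal length", call. = FALSE)

  extra <- setdiff(c(dam, sire), c(id, NA))
  if (length(extra) > 0L) {
    message("adding ", length(extra),
            " named-but-unlisted parent(s) as founders: ",
            paste(extra, collapse = ", "))
    id <- c(id, extra)
    dam <- c(dam, rep(NA_character_, length(extra)))
    sire <- c(sire, rep(NA_character_, length(extra)))
    if (!is.null(sex)) sex <- c(as.character(sex), rep(NA, length(extra)))
    if (!is.null(family)) family <- c(as.character(family),
                                      rep(NA, length(extra)))
  }

  # Kahn topological sort; leftovers indicate a cycle.
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  parents <- cbind(ifelse(is.na(dam), NA_integer_, idx[dam]),
                   ifelse(is.na(sire), NA_integer_, idx[sire]))
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(parents[, 1L]) | placed[parents[, 1L]]) &
                     (is.na(parents[, 2L]) | placed[parents[, 2L]]))
    if (length(ready) == 0L) break
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  if (length(order) < n)
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "), call. = FALSE)

  df <- data.frame(id = id, dam = dam, sire = sire,
                   stringsAsFactors = FALSE)[order, ]
  df$founder <- is.na(df$dam) & is.na(df$sire)
  if (!is.null(sex)) df$sex <- as.character(sex)[order]
  if (!is.null(family)) df$family <- as.character(family)[order]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read a pedigree from delimited text
#'
#' Expects a header with columns `id`, `dam`, `sire` (case-insensitive;
#' optional `sex` and `family`), comma- or tab-separated. Unknown parents
#' may be empty, `0` or `NA`.
#'
#' @param path Path to the file.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path,
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id, dam, sire (found: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  pedigree(df$id, df$dam, df$sire,
           sex = if ("sex" %in% names(df)) df$sex else NULL,
           family = if ("family" %in% names(df)) df$family else NULL)
}

#' Write a pedigree to delimited text
#'
#' @param ped A [pedigree()].
#' @param path Output path (CSV; unknown parents written as empty fields).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$founder <- NULL
  df$dam[is.na(df$dam)] <- ""
  df$sire[is.na(df$sire)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals (%d founders, %d with known parents)\n",
              nrow(x), sum(x$founder), sum(!x$founder)))
  invisible(x)
}

#' Numerator (additive) relationship matrix
#'
#' Builds Wright's numerator relationship matrix A (twice the kinship
#' coefficient) by the tabular method in topological order: founders are
#' unrelated and non-inbred, `a(i,i) = 1 + a(dam_i, sire_i) / 2` and
#' `a(i,j) = (a(dam_i, j) + a(sire_i, j)) / 2`, with unknown parents
#' contributing zero.
#'
#' @param ped A [pedigree()].
#' @return An n x n symmetric matrix with the pedigree ids as dimnames,
#'   in pedigree (topological) order.
#' @export
relationship_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in idx) {
    di <- d[i]; si <- s[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (di > 0L) A[di, j] else 0) +
                    (if (si > 0L) A[si, j] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (di > 0L && si > 0L) 0.5 * A[di, si] else 0
  }
  A
}
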