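#' Declare a landmark scheme
#'
#' A landmark scheme describes the template of a 2-D landmark configuration
#' for a bilaterally symmetric structure: which landmarks form left/right
#' pairs, which lie on the midline, and which are semilandmarks allowed to
#' slide along the chord between two neighbouring points during
#' superimposition. Indices are 1-based and every landmark must appear in
#' exactly one of `pairs` or `midline`.
#'
#' @param n_landmarks Integer, total number of landmarks per configuration.
#' @param pairs Two-column integer matrix (or list of length-2 vectors);
#'   each row is a (left, right) bilateral pair.
#' @param midline Integer vector of landmarks lying on the midline axis.
#' @param semilandmarks Three-column integer matrix (or list of length-3
#'   vectors): semilandmark index, neighbour before, neighbour after. May be
#'   empty.
#' @return An object of class `landmark_scheme`.
#' @seealso [viper_head_scheme()] for the built-in 40-landmark dorsal
#'   head scheme, [read_landmark_scheme()] to load a scheme from YAML.
#' @export
landmark_scheme <- function(n_landmarks, pairs, midline,
                            semilandmarks = NULL) {
  pairs <- to_index_matrix_(pairs, 2L, "pairs")
  midline <- as.integer(midline)
  semilandmarks <- if (is.null(semilandmarks) || length(semilandmarks) == 0L)
    matrix(integer(0), 0L, 3L)
  else to_index_matrix_(semilandmarks, 3L, "semilandmarks")
  n_landmarks <- as.integer(n_landmarks)

  used <- c(pairs[, 1L], pairs[, 2L], midline)
  if (anyDuplicated(used))
    stop("landmark indices appear more than once across pairs/midline",
         call. = FALSE)
  if (length(used) != n_landmarks || !setequal(used, seq_len(n_landmarks)))
    stop(sprintf(
      "pairs and midline must partition 1..%d (2*|pairs| + |midline| = %d)",
      n_landmarks, length(used)), call. = FALSE)
  if (nrow(semilandmarks) > 0L) {
    if (any(semilandmarks < 1L | semilandmarks > n_landmarks))
      stop("semilandmark indices out of range", call. = FALSE)
    bad <- semilandmarks[, 2L] == semilandmarks[, 3L] |
      semilandmarks[, 1L] == semilandmarks[, 2L] |
      semilandmarks[, 1L] == semilandmarks[, 3L]
    if (any(bad))
      stop("semilandmark neighbours must be distinct from each other and from the semilandmark",
           call. = FALSE)
  }
  structure(list(n_landmarks = n_landmarks, pairs = pairs,
                 midline = midline, semilandmarks = semilandmarks),
            class = "landmark_scheme")
}

to_index_matrix_ <- function(x, ncol, what) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.integer))
  x <- matrix(as.integer(x), ncol = ncol)
  if (any(is.na(x))) stop(sprintf("non-integer entries in %s", what),
                          call. = FALSE)
  x
}

#' The 40-landmark dorsal head scheme for meadow vipers
#'
#' Eighteen bilateral pairs, four midline landmarks (1, 34, 35, 40) and
#' twelve sliding semilandmarks (18--29) tracing the supraocular outline
#' (between landmarks 8--10 and 9--11) and the posterior head border
#' (between 10--16 and 11--17). Fixed landmarks mark the apical, canthal,
#' supraocular, frontal and parietal scales.
#'
#' @return A [landmark_scheme()] with 40 landmarks.
#' @export
viper_head_scheme <- function() {
  pairs <- rbind(
    c(2L, 3L), c(4L, 5L), c(6L, 7L), c(8L, 9L), c(10L, 11L),
    c(12L, 13L), c(14L, 15L), c(16L, 17L),
    c(18L, 19L), c(20L, 21L),                  # supraocular semilandmarks
    c(22L, 23L), c(24L, 25L), c(26L, 27L), c(28L, 29L), # posterior border
    c(30L, 31L), c(32L, 33L), c(36L, 37L), c(38L, 39L))
  semis <- rbind(
    c(18L, 8L, 20L), c(20L, 18L, 10L),   # right supraocular chain 8-18-20-10
    c(19L, 9L, 21L), c(21L, 19L, 11L),   # left chain 9-19-21-11
    c(22L, 10L, 24L), c(24L, 22L, 26L), c(26L, 24L, 28L), c(28L, 26L, 16L),
    c(23L, 11L, 25L), c(25L, 23L, 27L), c(27L, 25L, 29L), c(29L, 27L, 17L))
  landmark_scheme(40L, pairs, midline = c(1L, 34L, 35L, 40L),
                  semilandmarks = semis)
}

#' Read a landmark scheme from a YAML file
#'
#' The file must contain `n_landmarks`, `pairs` (list of two-element lists),
#' `midline`, and optionally `semilandmarks` (list of three-element lists:
#' index, neighbour before, neighbour after).
#'
#' @param path Path to a YAML scheme description.
#' @return A [landmark_scheme()].
#' @export
read_landmark_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  landmark_scheme(y$n_landmarks, y$pairs, unlist(y$midline), y$semilandmarks)
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("Landmark scheme: %d landmarks (%d bilateral pairs, %d midline, %d semilandmarks)\n",
              x$n_landmarks, nrow(x$pairs), length(x$midline),
              nrow(x$semilandmarks)))
  invisible(x)
}

# Permutation that swaps left and right labels; identity on the midline.
scheme_swap_ <- function(scheme) {
  perm <- seq_len(scheme$n_landmarks)
  perm[scheme$pairs[, 1L]] <- scheme$pairs[, 2L]
  perm[scheme$pairs[, 2L]] <- scheme$pairs[, 1L]
  perm
}
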