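#' Build a genetic map
#'
#' Creates a marker map laid out over a configurable number of linkage groups,
#' with genetic positions in centimorgans and physical positions in megabases.
#' Physical positions are derived from the genetic positions with a constant
#' Mb/cM expansion factor, which is adequate for plotting and fitting LD decay
#' on a physical axis.
#'
#' @param n_markers Total number of markers to place.
#' @param n_lg Number of linkage groups (default 28, an octoploid
#'   strawberry-like genome).
#' @param total_length_cm Total map length in centimorgans, split evenly across
#'   linkage groups (default 1729.5 cM).
#' @param mb_per_cm Physical-to-genetic expansion factor (Mb per cM,
#'   default 0.4).
#' @param spacing `"uniform"` draws marker positions uniformly at random within
#'   each linkage group; `"even"` spaces them regularly.
#' @param seed Integer seed for the random spacing.
#'
#' @return A tibble of class `genetic_map` with columns `marker_id`,
#'   `linkage_group`, `pos_cm`, `pos_mb`, sorted by group and position.
#' @export
#' @examples
#' make_genetic_map(100, n_lg = 4, total_length_cm = 400, seed = 1)
make_genetic_map <- function(n_markers, n_lg = 28, total_length_cm = 1729.5,
                             mb_per_cm = 0.4, spacing = c("uniform", "even"),
                             seed = NULL) {
  spacing <- match.arg(spacing)
  assert_that(n_markers >= n_lg, "need at least one marker per linkage group")
  lg_len <- total_length_cm / n_lg
  per_lg <- diff(floor(seq(0, n_markers, length.out = n_lg + 1L)))
  with_seed(seed, {
    pos <- lapply(seq_len(n_lg), function(g) {
      k <- per_lg[g]
      p <- if (spacing == "uniform") sort(stats::runif(k, 0, lg_len)) else
        seq(0, lg_len, length.out = k + 2L)[-c(1L, k + 2L)]
      tibble(linkage_group = g, pos_cm = p)
    })
    map <- dplyr::bind_rows(pos)
  })
  map$marker_id <- sprintf("M%05d", seq_len(nrow(map)))
  map$pos_mb <- map$pos_cm * mb_per_cm
  map <- map[, c("marker_id", "linkage_group", "pos_cm", "pos_mb")]
  validate_genetic_map(tibble::new_tibble(map, class = "genetic_map"))
}

#' Coerce and validate a genetic map
#'
#' @param x A data frame with columns `marker_id`, `linkage_group`, `pos_cm`
#'   and optionally `pos_mb`.
#' @param mb_per_cm Expansion factor used to fill `pos_mb` when absent.
#' @return A validated `genetic_map` tibble.
#' @export
as_genetic_map <- function(x, mb_per_cm = 0.4) {
  assert_that(is.data.frame(x), "genetic map must be a data frame")
  need <- c("marker_id", "linkage_group", "pos_cm")
  assert_that(all(need %in% names(x)),
              paste("genetic map needs columns:", paste(need, collapse = ", ")))
  x <- as_tibble(x)
  if (!"pos_mb" %in% names(x)) x$pos_mb <- x$pos_cm * mb_per_cm
  x <- dplyr::arrange(x, .data$linkage_group, .data$pos_cm)
  validate_genetic_map(tibble::new_tibble(x, class = "genetic_map"))
}

validate_genetic_map <- function(map) {
  assert_that(nrow(map) >= 1L, "genetic map is empty")
  assert_that(!anyDuplicated(map$marker_id), "marker ids must be unique")
  ok <- vapply(split(map$pos_cm, map$linkage_group),
               function(p) !is.unsorted(p), logical(1))
  assert_that(all(ok), "positions must be non-decreasing within linkage groups")
  map
}

# Split a map into per-linkage-group marker index lists (in map order).
lg_index <- function(map) split(seq_len(nrow(map)), map$linkage_group)
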