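#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @useDynLib cyclegp, .registration = TRUE
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations funnel through this so
# that a fixed seed is a hard reproducibility contract.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed: expand one master seed into per-stage seeds that stay
# well below .Machine$integer.max. Uses a small LCG step on (seed, tag hash).
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(master) * 48271 + h * 9973) %% 2147483563) + 1L
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

`%ifna%` <- function(x, y) if (is.null(x) || length(x) == 0L || all(is.na(x))) y else x

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
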