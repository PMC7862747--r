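#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: `G = W W' / (2 * sum_j p_j (1 - p_j))` with
#' `W = calls - 2 p_j`, allele frequencies taken from the observed panel or
#' supplied (e.g. the frequencies of a reference set of unique individuals
#' when clones recur across trials).
#'
#' @param g A [geno_matrix()] with no missing calls (impute first).
#' @param freq_source `"observed"` or `"supplied"`.
#' @param freqs Per-marker allele frequencies when `freq_source = "supplied"`,
#'   in marker-column order.
#' @return A `grm` object: `values` (symmetric matrix with individual ids),
#'   `allele_freqs`, `denom`.
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0, 1, 2, 1, 2, 1, 0, 1, 1, 1, 1, 1), 3,
#'                  byrow = TRUE, dimnames = list(paste0("i", 1:3),
#'                                                paste0("m", 1:4))))
#' vanraden_grm(g)
vanraden_grm <- function(g, freq_source = c("observed", "supplied"),
                         freqs = NULL) {
  freq_source <- match.arg(freq_source)
  calls <- g$calls
  assert_that(!anyNA(calls), "missing calls present; impute first")
  assert_that(nrow(calls) >= 2, "need at least 2 individuals")
  p <- if (freq_source == "observed") colMeans(calls) / 2 else {
    assert_that(!is.null(freqs) && length(freqs) == ncol(calls),
                "supplied freqs must match marker columns")
    as.numeric(freqs)
  }
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    abort(paste0("monomorphic markers present (filter first): ",
                 paste(utils::head(colnames(calls)[mono], 5), collapse = ", "),
                 if (sum(mono) > 5) sprintf(" ... (%d total)", sum(mono)) else ""))
  }
  W <- sweep(calls, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  structure(list(values = G, allele_freqs = p, denom = denom,
                 individual_ids = rownames(calls)),
            class = "grm")
}

#' @exportS3Method base::print
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d, mean diagonal %.3f\n",
              nrow(x$values), ncol(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Inverse of a (blended) genomic relationship matrix
#'
#' Inverts `(1 - blend) * G + blend * I`. Clonal panels with duplicated
#' genotypes make `G` singular by construction, so a small identity blend
#' (default 0.01 in downstream callers) guarantees the inverse exists.
#'
#' @param grm A [vanraden_grm()] object (or bare symmetric matrix).
#' @param blend Identity weight in `[0, 1)`.
#' @return The inverse matrix, with ids preserved.
#' @export
grm_inverse <- function(grm, blend = 0) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  assert_that(nrow(G) == ncol(G) && max(abs(G - t(G))) < 1e-8,
              "grm must be square symmetric")
  assert_that(blend >= 0 && blend < 1, "blend must be in [0, 1)")
  Gb <- (1 - blend) * G + blend * diag(nrow(G))
  Ginv <- tryCatch(chol2inv(chol(Gb)), error = function(e) NULL)
  if (is.null(Ginv)) {
    abort(if (blend == 0)
      "G is singular; retry with a positive blend (e.g. 0.01)"
      else "blended G could not be inverted; increase blend")
  }
  dimnames(Ginv) <- dimnames(G)
  Ginv
}

#' Blend a GRM towards the identity
#' @param grm A `grm` or matrix.
#' @param blend Identity weight in `[0, 1)`.
#' @return Matrix `(1 - blend) G + blend I`.
#' @export
grm_blend <- function(grm, blend = 0.01) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  (1 - blend) * G + blend * diag(nrow(G))
}

#' Write/read a GRM as plain text
#'
#' Lower-triangle 3-column CSV (`id1`, `id2`, `value`).
#' @param grm A `grm` object.
#' @param path Output file.
#' @return `path` invisibly (write) or a symmetric matrix (read).
#' @export
write_grm <- function(grm, path) {
  G <- grm$values
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  readr::write_csv(tibble(id1 = rownames(G)[idx[, 1]],
                          id2 = colnames(G)[idx[, 2]],
                          value = G[idx]), path)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  ids <- unique(c(tab$id1, tab$id2))
  G <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  G[cbind(match(tab$id1, ids), match(tab$id2, ids))] <- tab$value
  G[upper.tri(G)] <- t(G)[upper.tri(G)]
  G
}
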