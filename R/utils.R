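#' The six staging markers
#'
#' Marker panel used throughout: CD24, CD25, CD73, CD117, CD200 and CD371.
#' All staging, clustering and progression functions restrict to these
#' channels unless told otherwise.
#'
#' @return Character vector of the six marker names.
#' @export
gd_markers <- function() {
  c("CD24", "CD25", "CD73", "CD117", "CD200", "CD371")
}

#' The seven developmental stages
#'
#' @return Character vector `"A"` to `"G"`.
#' @export
gd_stages <- function() {
  LETTERS[1:7]
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. Keeps all generators reproducible without
# clobbering the session RNG.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

#' Deterministic largest-remainder allocation
#'
#' Splits `n` items over categories in proportion to `fractions`, rounding
#' deterministically: each category gets `floor(n * f)` and the remaining
#' items go to the largest fractional remainders (ties broken by category
#' order). Counts always sum to `n` exactly.
#'
#' @param n Total count (non-negative integer).
#' @param fractions Named non-negative numeric vector summing to 1.
#' @return Named integer vector summing to `n`.
#' @export
allocate_counts <- function(n, fractions) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  check_fractions(fractions, "fractions")
  target <- n * fractions
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- target - base
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  out <- as.integer(base)
  names(out) <- names(fractions)
  out
}

check_fractions <- function(x, what, tol = 1e-9) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort(sprintf("`%s` must be a named numeric vector", what))
  }
  if (any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", what))
  }
  if (abs(sum(x) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12g)", what, sum(x)))
  }
  invisible(x)
}

# Extract the marker intensity matrix from an event tibble.
marker_matrix <- function(events, markers = gd_markers()) {
  missing <- setdiff(markers, names(events))
  if (length(missing) > 0) {
    abort(sprintf("missing marker column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  as.matrix(events[markers])
}

#' Are event intensities arcsinh-transformed?
#'
#' @param events An event tibble.
#' @return `TRUE` if [arcsinh_transform()] has been applied.
#' @export
is_transformed <- function(events) {
  isTRUE(attr(events, "transformed"))
}

require_transformed <- function(events, fn) {
  if (!is_transformed(events)) {
    abort(sprintf("%s() expects arcsinh-transformed events; run arcsinh_transform() first", fn))
  }
  invisible(events)
}

# Squared Euclidean cross-distance between rows of two matrices.
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# Seeded uniform per-group downsample; groups smaller than n_per keep all
# rows (flagged via the "short_groups" attribute).
downsample_by_group <- function(data, group_col, n_per, seed) {
  idx <- split(seq_len(nrow(data)), data[[group_col]])
  short <- names(idx)[vapply(idx, length, 1L) < n_per]
  keep <- local_seed(seed, {
    unlist(lapply(idx, function(i) {
      if (length(i) <= n_per) i else sort(sample(i, n_per))
    }), use.names = FALSE)
  })
  out <- data[sort(keep), , drop = FALSE]
  attr(out, "short_groups") <- short
  out
}
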