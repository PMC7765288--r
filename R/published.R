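#' Published promax-rotated loading matrix for the 33 retained variables
#'
#' The reference PCA solution for the five infant sleep composites: the
#' pattern matrix of the 33 retained sleep variables on the components
#' *Sleep Activity*, *Sleep Variability*, *Sleep Day*, *Sleep Timing* and
#' *Sleep Night*. Row names are variable ids from [variable_registry()].
#' This matrix is an input (a printed reference), not a computed result; it
#' drives [prune_and_assign()]'s reference assignment and the structural
#' checks on composite sizes.
#'
#' @return numeric matrix, 33 x 5, rownames = variable ids, colnames =
#'   composite names.
#' @export
published_loadings <- function() {
  tab <- matrix(c(
    # id, Activity, Variability, Day, Timing, Night
    19, -0.89,  0.05,  0.00, -0.01, -0.02,
    23,  0.88,  0.04,  0.05,  0.02,  0.19,
    21,  0.86, -0.01, -0.11,  0.00,  0.16,
    25,  0.79, -0.13, -0.14,  0.03, -0.13,
    30, -0.77,  0.09,  0.04, -0.03,  0.15,
    27,  0.76, -0.05,  0.10,  0.01,  0.02,
    22,  0.72,  0.09,  0.10,  0.01,  0.05,
    24,  0.70,  0.07,  0.28, -0.05,  0.02,
    48, -0.69, -0.18,  0.17,  0.04,  0.09,
    28,  0.58, -0.08, -0.28,  0.01,  0.12,
    14, -0.05,  0.87, -0.07, -0.08,  0.04,
    16,  0.04,  0.86,  0.03, -0.11, -0.07,
    18, -0.06,  0.73,  0.10,  0.00,  0.00,
    10, -0.09,  0.73, -0.05,  0.02,  0.11,
    12,  0.00,  0.73, -0.08, -0.01, -0.05,
     4, -0.13,  0.72,  0.02,  0.14,  0.19,
     6,  0.10,  0.64, -0.04,  0.06, -0.10,
     2,  0.20,  0.58,  0.05, -0.02, -0.11,
    32, -0.10,  0.04, -0.92,  0.11, -0.17,
    34,  0.03, -0.06,  0.86, -0.12, -0.14,
    36,  0.00,  0.01,  0.82, -0.11, -0.26,
    47, -0.02, -0.24, -0.76,  0.07, -0.02,
    40, -0.01,  0.11,  0.72,  0.32,  0.05,
    33,  0.06,  0.12, -0.68,  0.03, -0.21,
    44, -0.12, -0.05, -0.56, -0.39,  0.12,
     9,  0.03, -0.01,  0.03,  1.01,  0.32,
     3,  0.08, -0.03,  0.01,  0.97,  0.37,
    11, -0.02, -0.01,  0.08,  0.93, -0.18,
     5, -0.05, -0.04,  0.08,  0.76, -0.52,
     1, -0.07,  0.00, -0.04,  0.68, -0.49,
    15,  0.11,  0.03, -0.01,  0.12,  0.99,
    13,  0.18,  0.00,  0.05,  0.08,  0.96,
    17, -0.40, -0.03,  0.04,  0.06,  0.78
  ), ncol = 6L, byrow = TRUE)
  m <- tab[, -1, drop = FALSE]
  rownames(m) <- as.character(as.integer(tab[, 1]))
  colnames(m) <- composite_names()
  m
}

#' Names of the five sleep composites
#' @return character vector of length 5 (printed column order).
#' @export
composite_names <- function() {
  c("Sleep Activity", "Sleep Variability", "Sleep Day", "Sleep Timing",
    "Sleep Night")
}

#' Variable ids excluded from the reference composite solution
#'
#' Fourteen variables were dropped for loading below 0.512 in absolute value
#' on every component; *Sleep Duration 24 h* (38) was additionally dropped
#' for interpretability (it loaded highest on *Sleep Day*, blurring the
#' day/night split).
#'
#' @return list with elements `low_loading` (14 ids) and `interpretability`
#'   (id 38).
#' @export
published_excluded_ids <- function() {
  list(
    low_loading = c(7L, 8L, 20L, 26L, 29L, 31L, 35L, 37L, 39L, 41L, 42L,
                    43L, 45L, 46L),
    interpretability = 38L
  )
}

#' Published per-component proportions of variance explained
#' @return named numeric vector over the five composites (sums to 0.71).
#' @export
published_variance_explained <- function() {
  stats::setNames(c(0.19, 0.14, 0.14, 0.13, 0.11), composite_names())
}
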