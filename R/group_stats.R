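#' Wilcoxon signed-rank test against zero
#'
#' Two-sided test of whether per-subject estimates are systematically
#' different from chance level. Zero differences are dropped (Wilcoxon's
#' original rule). The exact null distribution is used for n <= 25 when
#' there are no ties among the absolute values; larger or tied samples use
#' the normal approximation with continuity correction.
#'
#' @param values Numeric vector of per-subject estimates (length >= 2).
#' @return Two-sided p-value. A sample that is entirely zero returns p = 1.
#' @export
wilcoxon_vs_zero <- function(values) {
  if (length(values) < 2) {
    stop("wilcoxon_vs_zero needs at least 2 subjects", call. = FALSE)
  }
  x <- values[values != 0]
  if (length(x) == 0) return(1)
  exact <- length(x) <= 25 && !anyDuplicated(abs(x))
  suppressWarnings(
    wilcox.test(x, mu = 0, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment of a p-value vector and the selection mask at level
#' `q`. Adjusted p-values are monotone after sorting; the mask is exactly
#' `adjusted <= q`.
#'
#' @param p Numeric vector of p-values (may be empty).
#' @param q FDR level (default 0.05).
#' @return A list with `$adjusted` and logical `$selected`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(list(adjusted = numeric(0), selected = logical(0)))
  }
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, selected = adjusted <= q)
}

#' Group-level map across subjects
#'
#' Second-level analysis of per-subject score (or gain) maps: at every
#' location (voxel, or channel x time sample) the across-subject mean,
#' standard error of the mean, a two-sided Wilcoxon signed-rank p-value
#' against zero, and a significance mask after Benjamini-Hochberg FDR
#' correction applied jointly across all locations.
#'
#' @param maps A list of [score_map()] / [gain()] objects (one per
#'   subject, same target shape), or a locations x subjects matrix.
#' @param q FDR level (default 0.05).
#' @return A `group_result`: a tibble with columns `location`, `mean`,
#'   `sem`, `p`, `p_adjusted`, `selected`; the mask reshaped to the
#'   original score shape is in attribute `"mask"`.
#' @export
group_map <- function(maps, q = 0.05) {
  if (is.list(maps)) {
    shape <- NULL
    cols <- lapply(maps, function(m) {
      s <- if (inherits(m, "gain_map")) m$delta else m$scores
      shape <<- dim(s) %||% length(s)
      as.numeric(s)
    })
    value_mat <- do.call(cbind, cols)
  } else {
    value_mat <- as.matrix(maps)
    shape <- nrow(value_mat)
  }
  if (ncol(value_mat) < 2) {
    stop("group_map needs at least 2 subjects", call. = FALSE)
  }
  mu <- rowMeans(value_mat)
  sem <- apply(value_mat, 1, sd) / sqrt(ncol(value_mat))
  p <- apply(value_mat, 1, wilcoxon_vs_zero)
  bh <- fdr_bh(p, q)
  out <- tibble::tibble(location = seq_len(nrow(value_mat)), mean = mu,
                        sem = sem, p = p, p_adjusted = bh$adjusted,
                        selected = bh$selected)
  attr(out, "mask") <- array(bh$selected, dim = shape)
  attr(out, "q") <- q
  class(out) <- c("group_result", class(out))
  out
}
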