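# Two-group statistical battery: Shapiro-Wilk-gated choice between the
# unequal-variance t-test and the Mann-Whitney U test, Benjamini-Hochberg
# correction over one pooled comparison family, and Spearman correlations.

#' Normality-gated two-group comparison
#'
#' Applies Shapiro-Wilk to both samples; when both look normal
#' (p >= `alpha_normality` in each), a two-sided unequal-variance (Welch)
#' t-test is used, otherwise a two-sided Mann-Whitney U test with the
#' tie-corrected normal approximation. The test actually used is
#' recorded alongside group means and SDs.
#'
#' @param a,b Numeric samples (each n >= 3).
#' @param alpha_normality Normality gate level (default 0.05).
#' @param variable Optional variable name carried into the result.
#' @return A one-row data.frame of class `comparison_result` with columns
#'   `variable`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `test`, `p_value`.
#' @export
compare_groups <- function(a, b, alpha_normality = 0.05, variable = NA_character_) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs at least 3 finite observations", call. = FALSE)
  }
  normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE) # shapiro.test rejects constant input
    stats::shapiro.test(x)$p.value >= alpha_normality
  }
  if (normal(a) && normal(b)) {
    test <- "t_test"
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  } else {
    test <- "mann_whitney"
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  out <- data.frame(variable = variable, mean_a = mean(a), sd_a = stats::sd(a),
                    n_a = length(a), mean_b = mean(b), sd_b = stats::sd(b),
                    n_b = length(b), test = test, p_value = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted Q-values
#'
#' Step-up false-discovery-rate adjustment:
#' q_(i) = min over j >= i of (m p_(j) / j), capped at 1, reported in the
#' input order. The adjusted value of the family's largest p equals that
#' p itself.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with significance flag
#'
#' Pearson correlation of mid-ranked data, with the two-sided p-value from
#' the t approximation (ties handled by average ranks).
#'
#' @param x,y Equal-length numeric samples (n >= 4).
#' @param alpha Significance level for the flag (default 0.05).
#' @return A one-row data.frame with columns `rho`, `p_value`,
#'   `significant`.
#' @export
spearman_correlation <- function(x, y, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation is undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(rho = unname(ct$estimate), p_value = ct$p.value,
             significant = ct$p.value < alpha)
}

#' Assemble the pooled statistical report
#'
#' Binds a family of two-group comparisons, attaches Benjamini-Hochberg
#' Q-values computed across the whole family at once (demographic, QCT
#' and pressure variables alike, mirroring a single pooled test family),
#' and optionally attaches a long-format Spearman correlation table
#' between lung-function variables and computational outputs.
#'
#' @param comparisons List of `comparison_result` rows (or a data.frame
#'   already bound together).
#' @param correlations Optional data.frame of correlation entries.
#' @return An object of class `stat_report`: list with `comparisons`
#'   (with `q_value`) and `correlations`.
#' @export
build_report <- function(comparisons, correlations = NULL) {
  if (is.data.frame(comparisons)) comp <- comparisons
  else comp <- do.call(rbind, comparisons)
  if (is.null(comp) || !nrow(comp)) stop("empty comparison family", call. = FALSE)
  comp$q_value <- bh_adjust(comp$p_value)
  rownames(comp) <- NULL
  structure(list(comparisons = comp, correlations = correlations),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("stat_report: %d comparisons (%d with Q < 0.05)\n",
              nrow(x$comparisons), sum(x$comparisons$q_value < 0.05)))
  if (!is.null(x$correlations)) {
    cat(sprintf("  %d correlation entries (%d significant)\n",
                nrow(x$correlations), sum(x$correlations$significant)))
  }
  invisible(x)
}

#' Spearman correlation matrix in long format
#'
#' Correlates every column of `left` with every column of `right` and
#' returns one row per pair.
#'
#' @param left,right data.frames of equal row count (subjects).
#' @param alpha Significance level for the flags.
#' @return data.frame with columns `var_x`, `var_y`, `rho`, `p_value`,
#'   `significant`.
#' @export
correlation_matrix <- function(left, right, alpha = 0.05) {
  out <- list()
  for (vx in names(left)) {
    for (vy in names(right)) {
      row <- spearman_correlation(left[[vx]], right[[vy]], alpha)
      out[[length(out) + 1L]] <- cbind(data.frame(var_x = vx, var_y = vy,
                                                  stringsAsFactors = FALSE), row)
    }
  }
  do.call(rbind, out)
}
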