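#' Compare per-subject errors across conditions
#'
#' Reproduces the study's statistical workflow. For paired designs
#' (the same subject-and-hand datasets under every condition): a Friedman
#' omnibus test across three or more conditions, followed by pairwise
#' Wilcoxon signed-rank post-hoc tests. For unpaired designs: a
#' Kruskal-Wallis omnibus (three or more groups) and pairwise Wilcoxon
#' rank-sum tests. Pairwise p-values are Bonferroni-corrected (multiplied
#' by the number of pairs, capped at 1) and flagged at corrected p < 0.05.
#' Signed-rank p-values use the exact small-sample distribution for
#' n <= 25 pairs and the normal approximation above.
#'
#' @param errors Paired design: an n_subjects x n_conditions matrix (or
#'   data.frame) of per-dataset mean errors, columns named by condition.
#'   Unpaired design: a named list of numeric vectors.
#' @param design `"paired"` or `"unpaired"`.
#' @param alpha Significance level applied to corrected p-values.
#' @return An object of class `condition_comparison`: `omnibus` (method,
#'   statistic, p_value) and `pairwise` (data.frame with raw and
#'   Bonferroni-corrected p-values and a `significant` flag).
#' @export
compare_conditions <- function(errors, design = c("paired", "unpaired"),
                               alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired") {
    m <- as.matrix(errors)
    if (ncol(m) < 2) stop("need at least 2 conditions")
    if (anyNA(m)) stop("paired design requires complete matched subjects")
    conds <- colnames(m) %||% paste0("cond", seq_len(ncol(m)))
    colnames(m) <- conds
    omnibus <- if (ncol(m) >= 3) {
      ft <- stats::friedman.test(m)
      st <- unname(ft$statistic); pv <- ft$p.value
      if (!is.finite(st)) { st <- 0; pv <- 1 }  # all ranks tied
      list(method = "Friedman", statistic = st, p_value = pv)
    } else NULL
    test_pair <- function(a, b) {
      n <- length(a)
      stats::wilcox.test(a, b, paired = TRUE, exact = n <= 25,
                         correct = TRUE)
    }
    groups <- lapply(seq_len(ncol(m)), function(j) m[, j])
    names(groups) <- conds
  } else {
    groups <- errors
    if (!is.list(groups) || length(groups) < 2)
      stop("unpaired design needs a list of >= 2 condition vectors")
    conds <- names(groups) %||% paste0("cond", seq_along(groups))
    names(groups) <- conds
    omnibus <- if (length(groups) >= 3) {
      kt <- stats::kruskal.test(groups)
      list(method = "Kruskal-Wallis", statistic = unname(kt$statistic),
           p_value = kt$p.value)
    } else NULL
    test_pair <- function(a, b) stats::wilcox.test(a, b, paired = FALSE)
  }

  pairs <- utils::combn(length(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    wt <- suppressWarnings(test_pair(groups[[i1]], groups[[i2]]))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1  # e.g. all paired differences are zero
    data.frame(condition_a = conds[i1], condition_b = conds[i2],
               statistic = unname(wt$statistic), p_raw = p)
  })
  pw <- do.call(rbind, rows)
  pw$p_bonferroni <- stats::p.adjust(pw$p_raw, method = "bonferroni")
  pw$significant <- pw$p_bonferroni < alpha
  structure(list(omnibus = omnibus, pairwise = pw, design = design,
                 alpha = alpha),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> (", x$design, " design)\n", sep = "")
  if (!is.null(x$omnibus))
    cat(sprintf("  omnibus %s: statistic %.3f, p = %.4g\n",
                x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
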