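# Group statistics as thin wrappers over base R tests, with pinned
# small-sample behavior (zero/tie handling, exact-vs-approximate thresholds)
# and explicit undefined-case flagging. No multiple-testing correction is
# applied anywhere.

mcell_stat <- function(test_name, statistic, df = NA, n = NA, p_value = NA,
                       alternative = NA_character_, group_labels = NULL,
                       undefined = FALSE, note = NULL) {
  structure(list(test_name = test_name, statistic = statistic, df = df, n = n,
                 p_value = p_value, alternative = alternative,
                 group_labels = group_labels, undefined = undefined,
                 note = note),
            class = "mcell_stat")
}

#' @export
print.mcell_stat <- function(x, ...) {
  cat(sprintf("<mcell_stat> %s", x$test_name))
  if (!is.null(x$group_labels)) cat(" [", paste(x$group_labels, collapse = " vs "), "]")
  cat("\n")
  if (isTRUE(x$undefined)) {
    cat("  undefined:", if (is.null(x$note)) "degenerate data" else x$note, "\n")
  } else {
    # report statistics to 2 decimals and p to 4, the house style of the tables
    cat(sprintf("  statistic %.2f, %s, p = %.4f%s\n", x$statistic,
                if (all(is.na(x$df))) sprintf("n = %s", paste(x$n, collapse = ","))
                else sprintf("df = %s", paste(x$df, collapse = ",")),
                x$p_value,
                if (is.null(x$note)) "" else paste0(" (", x$note, ")")))
  }
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of symmetry about `mu`. Values equal to `mu`
#' are dropped (signed-rank convention). The exact distribution is used for
#' n <= 25 without ties; the normal approximation with continuity correction
#' otherwise. With n < 6 non-zero values the exact two-sided p cannot reach
#' 0.05 (minimum `2/2^n`), which triggers a warning. All values equal to `mu`
#' give an undefined-flagged result.
#'
#' @param values numeric sample.
#' @param mu null-hypothesis center (e.g. 1 for integration indices).
#' @return an object of class `mcell_stat`.
#' @export
wilcoxon_one_sample <- function(values, mu = 1) {
  values <- values[is.finite(values)]
  nz <- values[values != mu]
  n <- length(nz)
  if (n == 0)
    return(mcell_stat("Wilcoxon one-sample", NA, n = 0, undefined = TRUE,
                      note = "all values equal mu"))
  if (n < 6)
    warning("with n = ", n, " the exact two-sided p cannot reach 0.05 ",
            "(minimum ", signif(2 / 2^n, 3), ")", call. = FALSE)
  ties <- any(duplicated(abs(nz - mu)))
  ht <- suppressWarnings(stats::wilcox.test(nz, mu = mu,
                                            alternative = "two.sided",
                                            exact = (n <= 25 && !ties),
                                            correct = TRUE))
  mcell_stat("Wilcoxon one-sample", unname(ht$statistic), n = n,
             p_value = ht$p.value, alternative = "two.sided",
             note = if (n <= 25 && !ties) "exact" else "normal approximation")
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction, referred to a chi-squared distribution
#' with k - 1 df (base [stats::kruskal.test()]). All observations identical
#' across groups gives an undefined-flagged result. H is invariant to group
#' relabeling and ordering.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @param group_labels optional labels.
#' @return an object of class `mcell_stat`.
#' @export
kruskal_wallis <- function(groups, group_labels = names(groups)) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    return(mcell_stat("Kruskal-Wallis", NA, group_labels = group_labels,
                      undefined = TRUE, note = "all observations identical"))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  mcell_stat("Kruskal-Wallis", unname(ht$statistic),
             df = unname(ht$parameter), n = length(x),
             p_value = ht$p.value, group_labels = group_labels)
}

#' Single-predictor linear model with ANOVA F test
#'
#' OLS fit of `response ~ predictor` and the F test of the predictor,
#' `F = (SSR/1) / (SSE/(n-2))`. A perfect fit (SSE = 0) is reported with
#' `statistic = Inf` and p = 0, flagged in `note`; zero predictor variance is
#' an error.
#'
#' @param response,predictor numeric vectors of equal length (n >= 3).
#' @return an object of class `mcell_stat` with the fitted slope in `note`'s
#'   companion field `slope`.
#' @export
linear_model_anova <- function(response, predictor) {
  ok <- is.finite(response) & is.finite(predictor)
  response <- response[ok]; predictor <- predictor[ok]
  n <- length(response)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(predictor) <= 0)
    stop("zero predictor variance", call. = FALSE)
  fit <- stats::lm(response ~ predictor)
  sse <- sum(stats::residuals(fit)^2)
  if (sse < 1e-12 * sum((response - mean(response))^2) || sse == 0) {
    out <- mcell_stat("LM ANOVA", Inf, df = c(1, n - 2), n = n, p_value = 0,
                      note = "perfect fit (SSE = 0)")
  } else {
    an <- stats::anova(fit)
    out <- mcell_stat("LM ANOVA", an$`F value`[1], df = c(1, n - 2), n = n,
                      p_value = an$`Pr(>F)`[1])
  }
  out$slope <- unname(stats::coef(fit)[2])
  out
}

#' Paired t test
#'
#' t statistic on within-pair differences with df = n - 1. Zero-variance
#' differences (including all-identical pairs with a non-zero constant shift)
#' are undefined-flagged rather than an error; identical pairs give t = 0,
#' p = 1.
#'
#' @param values_a,values_b paired numeric vectors of equal length, n >= 2.
#' @return an object of class `mcell_stat`.
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(mcell_stat("paired t", 0, df = length(d) - 1, n = length(d),
                        p_value = 1, alternative = "two.sided",
                        note = "identical pairs"))
    return(mcell_stat("paired t", NA, n = length(d), undefined = TRUE,
                      note = "zero-variance differences"))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  mcell_stat("paired t", unname(ht$statistic), df = unname(ht$parameter),
             n = length(d), p_value = ht$p.value, alternative = "two.sided")
}

#' Firing-incidence table
#'
#' Percentage of cells that fired at least one action potential per modality,
#' rounded to one decimal (so 3 of 60 cells gives 5.0 and 4 of 60 gives 6.7).
#'
#' @param fired_flags data frame with columns `cell`, `modality`, `fired`
#'   (one logical per cell per modality).
#' @return data frame with columns `modality`, `n_cells`, `n_fired`,
#'   `percent`.
#' @export
firing_incidence <- function(fired_flags) {
  stopifnot(is.data.frame(fired_flags),
            all(c("cell", "modality", "fired") %in% names(fired_flags)))
  if (nrow(fired_flags) == 0) stop("empty firing table", call. = FALSE)
  mods <- unique(fired_flags$modality)
  out <- do.call(rbind, lapply(mods, function(m) {
    sub <- fired_flags[fired_flags$modality == m, , drop = FALSE]
    per_cell <- tapply(sub$fired, sub$cell, any)
    data.frame(modality = m, n_cells = length(per_cell),
               n_fired = sum(per_cell),
               percent = round(100 * sum(per_cell) / length(per_cell), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
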