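# Multisensory and sequence integration indices, and the
# inverse-effectiveness regression.

#' Multisensory integration indices
#'
#' From windowed mean responses to the multisensory (`M`), tectal-only (`T`)
#' and auditory-only (`A`) conditions:
#' `MSI/Max = M / max(T, A)` (> 1 indicates multisensory enhancement, < 1
#' inhibition) and `MSI/Sum = M / (T + A)` (> 1 supralinear, = 1 linear, < 1
#' sublinear integration). For non-negative unisensory responses
#' `msi_sum <= msi_max <= 2 * msi_sum`, and both indices are invariant to a
#' common positive rescaling of `M`, `T`, `A`.
#'
#' @param M_mV,T_mV,A_mV windowed mean depolarizations (mV).
#' @param condition optional condition tag (train descriptor).
#' @return object of class `msi_record`: list with `M_mV`, `T_mV`, `A_mV`,
#'   `msi_max`, `msi_sum`, `enhancement` (`msi_max > 1`), `supralinear`
#'   (`msi_sum > 1`), `condition`.
#' @export
msi_indices <- function(M_mV, T_mV, A_mV, condition = NA_character_) {
  stopifnot(is.finite(M_mV), is.finite(T_mV), is.finite(A_mV))
  if (max(T_mV, A_mV) <= 0 || T_mV + A_mV <= 0)
    stop("undefined index: non-positive unisensory denominator", call. = FALSE)
  msi_max <- M_mV / max(T_mV, A_mV)
  msi_sum <- M_mV / (T_mV + A_mV)
  structure(list(M_mV = M_mV, T_mV = T_mV, A_mV = A_mV,
                 msi_max = msi_max, msi_sum = msi_sum,
                 enhancement = msi_max > 1, supralinear = msi_sum > 1,
                 condition = condition),
            class = "msi_record")
}

#' @export
print.msi_record <- function(x, ...) {
  cat(sprintf("<msi_record>%s M %.3f, T %.3f, A %.3f mV\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$M_mV, x$T_mV, x$A_mV))
  cat(sprintf("  MSI/Max %.3f (%s), MSI/Sum %.3f (%s)\n",
              x$msi_max, if (x$enhancement) "enhancement" else "no enhancement",
              x$msi_sum,
              if (x$supralinear) "supralinear" else if (x$msi_sum == 1) "linear" else "sublinear"))
  invisible(x)
}

#' S1-S2 sequence-integration index
#'
#' For a pair of stimuli 50 ms apart: `Resp1` is the contribution of the first
#' stimulus measured in a 12-ms window starting 50 ms after S1 onset on
#' S1-only trials, `Resp2` the S2-alone response at S2 onset, and `Resp(1+2)`
#' the paired response after S2. The index
#' `Resp(1+2) / (Resp1 + Resp2)` is < 1 for inhibitory (prepulse-suppressed)
#' integration, 1 for linear, > 1 for facilitated integration. For
#' multisensory sequences (AT, TA) it is the MSI/Sum index up to the 50-ms
#' offset of the first component.
#'
#' @param resp1_mV,resp2_mV,resp12_mV windowed mean depolarizations (mV).
#' @param sequence one of `"AA"`, `"AT"`, `"TA"`, `"TT"` (free-form allowed).
#' @return object of class `seq_integration`: list with the three responses,
#'   `s1s2_index` and `sequence`.
#' @export
s1s2_index <- function(resp1_mV, resp2_mV, resp12_mV, sequence = NA_character_) {
  stopifnot(is.finite(resp1_mV), is.finite(resp2_mV), is.finite(resp12_mV))
  if (resp1_mV + resp2_mV <= 0)
    stop("undefined index: non-positive denominator", call. = FALSE)
  structure(list(resp1_mV = resp1_mV, resp2_mV = resp2_mV,
                 resp12_mV = resp12_mV,
                 s1s2_index = resp12_mV / (resp1_mV + resp2_mV),
                 sequence = sequence),
            class = "seq_integration")
}

#' @export
print.seq_integration <- function(x, ...) {
  cat(sprintf("<seq_integration>%s Resp1 %.3f + Resp2 %.3f -> Resp(1+2) %.3f mV; index %.3f\n",
              if (is.na(x$sequence)) "" else paste0(" [", x$sequence, "]"),
              x$resp1_mV, x$resp2_mV, x$resp12_mV, x$s1s2_index))
  invisible(x)
}

#' Inverse-effectiveness regression
#'
#' Ordinary least-squares fit of a multisensory index on the magnitude of the
#' unisensory response, with the F test of the single predictor. A negative,
#' significant slope is the single-cell signature of inverse effectiveness:
#' relative multisensory enhancement shrinks as the unisensory drive grows.
#'
#' @param magnitude_mV unisensory response magnitudes (max or sum of the
#'   unisensory components, mV).
#' @param index the multisensory indices (MSI/Max or MSI/Sum).
#' @param predictor,response labels recording which variants were supplied.
#' @return object of class `inverse_effectiveness`: list with `slope`,
#'   `intercept`, `F_stat`, `df`, `p_value`, `n`, labels, and the underlying
#'   `lm` fit. `coef()`, `summary()` and `plot()` methods are provided.
#' @export
inverse_effectiveness <- function(magnitude_mV, index,
                                  predictor = "max_unisensory",
                                  response = "msi_max") {
  ok <- is.finite(magnitude_mV) & is.finite(index)
  magnitude_mV <- magnitude_mV[ok]; index <- index[ok]
  n <- length(index)
  if (n < 3) stop("need at least 3 finite records", call. = FALSE)
  if (stats::var(magnitude_mV) <= 0)
    stop("degenerate predictor: zero variance in magnitudes", call. = FALSE)
  fit <- stats::lm(index ~ magnitude_mV)
  # a perfect (collinear) fit makes anova() warn about its F test; the
  # limiting F = Inf, p = 0 report is still the right summary here
  an <- suppressWarnings(stats::anova(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 F_stat = an$`F value`[1], df = c(1L, n - 2L),
                 p_value = an$`Pr(>F)`[1], n = n,
                 predictor = predictor, response = response, fit = fit),
            class = "inverse_effectiveness")
}

#' @export
print.inverse_effectiveness <- function(x, ...) {
  cat(sprintf("<inverse_effectiveness> %s ~ %s, n = %d\n",
              x$response, x$predictor, x$n))
  cat(sprintf("  slope %.4f, intercept %.4f; F(%d,%d) = %.2f, p = %.4g\n",
              x$slope, x$intercept, x$df[1], x$df[2], x$F_stat, x$p_value))
  invisible(x)
}

#' @export
coef.inverse_effectiveness <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.inverse_effectiveness <- function(object, ...) summary(object$fit, ...)

#' @export
plot.inverse_effectiveness <- function(x, ...,
                                       xlab = paste(x$predictor, "(mV)"),
                                       ylab = x$response) {
  d <- x$fit$model
  plot(d$magnitude_mV, d$index, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}
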