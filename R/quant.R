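# Quantitative layer: qPCR standard-curve absolute quantification,
# actin-normalized relative quantification (delta-delta-Ct), and phenotype
# group statistics.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(amount).  Amplification efficiency is
#' `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle, slope -3.3219).
#'
#' @param amount amounts of the standards (> 0, >= 3 distinct values), or a
#'   data frame with `amount` and `ct` columns (e.g. the standard rows of a
#'   [gen_qpcr()] plate).
#' @param ct observed Ct values (omit when `amount` is a data frame).
#' @return object of class `standard_curve`: `slope` (Ct per log10 unit),
#'   `intercept` (Ct at amount 1), `r2`, `efficiency`, `fit` (the `lm`).
#' @export
fit_standard_curve <- function(amount, ct) {
  if (is.data.frame(amount)) {
    ct <- amount$ct
    amount <- amount$amount
  }
  keep <- complete.cases(amount, ct)
  amount <- amount[keep]; ct <- ct[keep]
  if (any(amount <= 0)) stop("standard amounts must be positive")
  if (length(unique(amount)) < 3)
    stop("need >= 3 distinct standard amounts")
  fit <- lm(ct ~ log10(amount))
  slope <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are expected
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r2 = r2, efficiency = 10^(-1 / slope) - 1, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.4f %+.4f log10(amount); R2 = %.4f, eff = %.1f%%\n",
    x$intercept, x$slope, x$r2, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification against a standard curve
#'
#' Inverts the curve, `amount = 10^((ct - intercept) / slope)`, and divides
#' by a normalization denominator — micrograms of input total RNA or grams
#' of sample mass, giving e.g. fmol per microgram RNA or fmol per gram.
#'
#' @param ct Ct value(s) of the unknowns.
#' @param curve a [fit_standard_curve()] result (or list with `slope`,
#'   `intercept`).
#' @param denominator normalization denominator (same for all cts or
#'   vectorized); default 1 (no normalization).
#' @return normalized amounts.
#' @export
absolute_quant <- function(ct, curve, denominator = 1) {
  if (curve$slope == 0) stop("degenerate standard curve (slope = 0)")
  if (any(denominator <= 0)) stop("denominator must be positive")
  10^((ct - curve$intercept) / curve$slope) / denominator
}

#' Relative quantification by delta-delta-Ct
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; fold change
#' `2^-(dCt - mean dCt of the control arm)`.  The control arm's geometric
#' mean fold is 1 by construction.
#'
#' @param plate data frame `sample`, `arm`, `gene`, `ct` (replicate wells
#'   are averaged per sample x gene).
#' @param target_gene,reference_gene gene labels.
#' @param control_arm label of the control arm.
#' @return data frame `sample`, `arm`, `dct`, `fold`, with per-arm mean
#'   folds in attribute `"arm_means"`.
#' @export
relative_ddct <- function(plate, target_gene, reference_gene,
                          control_arm = "control") {
  stopifnot(all(c("sample", "arm", "gene", "ct") %in% names(plate)))
  mean_ct <- function(gene) {
    sub <- plate[plate$gene == gene, ]
    tapply(sub$ct, sub$sample, mean)
  }
  ct_t <- mean_ct(target_gene)
  ct_r <- mean_ct(reference_gene)
  samples <- unique(plate$sample)
  if (!all(samples %in% names(ct_t)) || !all(samples %in% names(ct_r)))
    stop("target or reference gene missing for some samples")
  dct <- ct_t[samples] - ct_r[samples]
  arm <- plate$arm[match(samples, plate$sample)]
  if (!control_arm %in% arm) stop("control arm not present")
  ddct <- dct - mean(dct[arm == control_arm])
  out <- data.frame(sample = samples, arm = arm, dct = unname(dct),
                    fold = unname(2^(-ddct)), stringsAsFactors = FALSE)
  attr(out, "arm_means") <- tapply(out$fold, out$arm, mean)
  out
}

#' Compare phenotype groups
#'
#' Two arms: two-sided Student's t-test (equal variances by default, Welch
#' via `var_equal = FALSE`).  Three or more arms: one-way ANOVA.  Effects
#' are reported against the control arm: `effect_abs = treated mean -
#' control mean` and `effect_pct = 100 * effect_abs / control mean` (for
#' designs with more than two arms the last arm is contrasted).
#'
#' @param table phenotype data frame (`arm` plus trait columns), e.g. from
#'   [gen_phenotypes()].
#' @param trait trait column to analyse.
#' @param control_arm control arm label (default "control").
#' @param test "auto" (t for 2 arms, anova otherwise), "t" or "anova".
#' @param var_equal use the pooled-variance Student t (default TRUE).
#' @return object of class `group_comparison`: `trait`, `arms`, `test`,
#'   `statistic`, `p`, `effect_abs`, `effect_pct`, `n_per_group`.
#' @export
compare_groups <- function(table, trait, control_arm = "control",
                           test = c("auto", "t", "anova"),
                           var_equal = TRUE) {
  test <- match.arg(test)
  stopifnot(trait %in% names(table), "arm" %in% names(table))
  arms <- unique(table$arm)
  if (length(arms) < 2) stop("need at least two arms")
  if (!control_arm %in% arms) stop("control arm not present")
  n_per <- table(table$arm)
  if (any(n_per < 2)) stop("need >= 2 observations per arm")
  x <- table[[trait]]
  if (test == "auto") test <- if (length(arms) == 2) "t" else "anova"
  if (test == "t" && length(arms) != 2)
    stop("t-test requires exactly two arms")
  if (test == "t") {
    tt <- t.test(x[table$arm != control_arm], x[table$arm == control_arm],
                 var.equal = var_equal)
    statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    fit <- aov(x ~ factor(arm), data = data.frame(x = x, arm = table$arm))
    s <- summary(fit)[[1]]
    statistic <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  }
  treated_arm <- setdiff(arms, control_arm)
  treated_arm <- treated_arm[length(treated_arm)]
  mu_c <- mean(x[table$arm == control_arm])
  mu_t <- mean(x[table$arm == treated_arm])
  structure(list(trait = trait, arms = arms, test = test,
                 statistic = statistic, p = p,
                 effect_abs = mu_t - mu_c,
                 effect_pct = 100 * (mu_t - mu_c) / mu_c,
                 control_mean = mu_c,
                 n_per_group = as.integer(n_per)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s [%s]: %s = %.3f, p = %.4g; effect = %+.3f (%+.2f%%)\n",
    x$trait, paste(x$arms, collapse = " vs "),
    if (x$test == "t") "t" else "F", x$statistic, x$p,
    x$effect_abs, x$effect_pct))
  invisible(x)
}
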