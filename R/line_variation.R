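#' Among-line variation F test for sex ratio
#'
#' Quasi-binomial GLM (logit link) of brood male/female counts on line
#' identity; over-dispersion is absorbed by the quasi-likelihood dispersion
#' estimate and the line term is tested with an F test against the
#' intercept-only model, with `(n_lines - 1, n_broods - n_lines)` degrees of
#' freedom.
#'
#' @param broods a `brood_table` (see [read_brood_table()]).
#' @return list of class `among_line_test`: `F`, `df1`, `df2`, `p_value`,
#'   `dispersion`, `boundary_lines` (lines whose totals are all-male or
#'   all-female, where the GLM fits a boundary logit).
#' @export
among_line_ftest <- function(broods) {
  lines <- unique(broods$line_id)
  if (length(lines) < 2) stop("need at least two lines")
  line <- factor(broods$line_id)
  fit <- glm(cbind(n_males, n_females) ~ line, family = stats::quasibinomial(),
             data = broods)
  null <- glm(cbind(n_males, n_females) ~ 1, family = stats::quasibinomial(),
              data = broods)
  a <- anova(null, fit, test = "F")
  tot_m <- tapply(broods$n_males, line, sum)
  tot_f <- tapply(broods$n_females, line, sum)
  res <- list(F = a$F[2], df1 = a$Df[2], df2 = fit$df.residual,
              p_value = a$`Pr(>F)`[2],
              dispersion = summary(fit)$dispersion,
              boundary_lines = names(tot_m)[tot_m == 0 | tot_f == 0])
  class(res) <- "among_line_test"
  res
}

#' @export
print.among_line_test <- function(x, ...) {
  cat(sprintf("among-line variation (quasi-binomial GLM): F_%d,%d = %.3f, P %s\n",
              x$df1, x$df2, x$F,
              if (x$p_value < 1e-4) "< 0.0001" else sprintf("= %.4g", x$p_value)))
  cat(sprintf("  dispersion estimate = %.3f\n", x$dispersion))
  if (length(x$boundary_lines))
    cat("  boundary (all-male or all-female) lines:",
        paste(x$boundary_lines, collapse = ", "), "\n")
  invisible(x)
}

#' Broad-sense heritability from a line panel
#'
#' One-way random-effects model `value ~ 1 + (1 | line)` fitted by REML
#' ([lme4::lmer]); broad-sense heritability is the intraclass correlation
#' `H2 = V_line / (V_line + V_res)`.  For proportion traits the arcsine-
#' square-root transform is applied first (the classical variance-
#' stabilising choice for brood sex ratios).  The likelihood-ratio statistic
#' compares the maximum-likelihood fits with and without the line effect and
#' is referred to a chi-squared with 1 df — conservative at the
#' `V_line = 0` boundary.
#'
#' @param values per-brood trait values (proportions for
#'   `transform = "arcsine-sqrt"`).
#' @param line_ids per-brood line identifiers.
#' @param transform `"arcsine-sqrt"` or `"identity"`.
#' @param trait optional trait name for printing.
#' @return object of class `heritability_estimate`: `trait`, `transform`,
#'   `v_line`, `v_res`, `h2`, `lr`, `p_value`, `n_lines`, `n_broods`.
#' @export
broad_sense_h2 <- function(values, line_ids, transform = c("arcsine-sqrt", "identity"),
                           trait = "trait") {
  transform <- match.arg(transform)
  line_ids <- as.character(line_ids)
  stopifnot(length(values) == length(line_ids))
  ok <- !is.na(values) & !is.na(line_ids)
  values <- values[ok]; line_ids <- line_ids[ok]
  nl <- length(unique(line_ids))
  if (nl < 3) stop("need at least three lines")
  if (max(table(line_ids)) < 2)
    stop("need replicate broods within lines to separate V_line from V_res")
  y <- if (transform == "arcsine-sqrt") {
    if (any(values < 0 | values > 1)) stop("arcsine-sqrt needs values in [0, 1]")
    asin(sqrt(values))
  } else values
  d <- data.frame(y = y, line = factor(line_ids))
  fit <- lme4::lmer(y ~ 1 + (1 | line), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_line <- vc$vcov[vc$grp == "line"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  fit_ml <- lme4::lmer(y ~ 1 + (1 | line), data = d, REML = FALSE)
  null_ml <- lm(y ~ 1, data = d)
  lr <- max(0, 2 * (as.numeric(logLik(fit_ml)) - as.numeric(logLik(null_ml))))
  h2 <- if (v_line + v_res > 0) v_line / (v_line + v_res) else 0
  res <- list(trait = trait, transform = transform, v_line = v_line,
              v_res = v_res, h2 = h2, lr = lr,
              p_value = pchisq(lr, df = 1, lower.tail = FALSE),
              n_lines = nl, n_broods = length(y))
  class(res) <- "heritability_estimate"
  res
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("broad-sense heritability of %s (%s scale):\n", x$trait, x$transform))
  cat(sprintf("  H2 = %.3f  (V_line = %.4g, V_res = %.4g; %d lines, %d broods)\n",
              x$h2, x$v_line, x$v_res, x$n_lines, x$n_broods))
  cat(sprintf("  Likelihood Ratio = %.3f, P %s\n", x$lr,
              if (x$p_value < 1e-4) "< 0.0001" else sprintf("= %.4g", x$p_value)))
  invisible(x)
}

#' Line-mean correlation between two traits
#'
#' Ordinary least squares of per-line trait means of y on x; reports slope,
#' standard error, t and p.
#'
#' @param line_means_x,line_means_y named per-line means (matched by name
#'   when both are named).
#' @return list of class `trait_correlation`: `b`, `se`, `t`, `p_value`,
#'   `r2`, `n_lines`, `means` (the data used).
#' @export
trait_correlation <- function(line_means_x, line_means_y) {
  if (!is.null(names(line_means_x)) && !is.null(names(line_means_y))) {
    ids <- intersect(names(line_means_x), names(line_means_y))
    line_means_x <- line_means_x[ids]; line_means_y <- line_means_y[ids]
  }
  n <- length(line_means_x)
  if (n < 3) stop("need at least three matched lines")
  if (sd(line_means_x) == 0) stop("zero variance in x")
  fit <- lm(line_means_y ~ line_means_x)
  sm <- summary(fit)
  co <- sm$coefficients
  res <- list(b = co[2, 1], se = co[2, 2], t = co[2, 3], p_value = co[2, 4],
              r2 = sm$r.squared, n_lines = n,
              means = data.frame(x = line_means_x, y = line_means_y))
  class(res) <- "trait_correlation"
  res
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat(sprintf("line-mean regression: b = %.4g (s.e. = %.4g), t = %.3f, P = %.3g (n = %d lines)\n",
              x$b, x$se, x$t, x$p_value, x$n_lines))
  invisible(x)
}
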