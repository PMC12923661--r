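## Statistical battery: paired Wilcoxon and effect sizes, linear
## mixed-effects models with a patient random intercept, group contrasts
## by speech label, per-segment z-tests with Benjamini-Hochberg control,
## logistic and correlation analyses.

#' Paired Wilcoxon signed-rank test
#'
#' Exact distribution for n <= 25 non-zero differences (no ties), normal
#' approximation with tie/zero correction otherwise; the method used is
#' recorded. Missing pairs are dropped and counted.
#'
#' @param pre,intra paired numeric vectors.
#' @return list: `statistic` (V), `p`, `n` (non-zero differences),
#'   `method`, `nDropped`.
#' @export
wilcoxonSignedRank <- function(pre, intra) {
  ok <- !is.na(pre) & !is.na(intra)
  d <- intra[ok] - pre[ok]
  nz <- d != 0
  n <- sum(nz)
  if (all(d == 0)) stop("all paired differences are zero; p undefined")
  if (n < 5L) warning("fewer than 5 non-zero differences")
  exact <- n <= 25L && !any(duplicated(abs(d[nz])))
  wt <- suppressWarnings(
    wilcox.test(intra[ok], pre[ok], paired = TRUE, exact = exact,
                correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
       method = if (exact) "exact" else "normal approximation",
       nDropped = sum(!ok))
}

#' Wilcoxon rank-sum test between two groups
#'
#' @param x,y numeric vectors (independent groups).
#' @return list: `statistic` (W), `p`, `n` (c(nx, ny)), `method`.
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  exact <- length(x) <= 25L && length(y) <= 25L &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(x), length(y)),
       method = if (exact) "exact" else "normal approximation")
}

#' Paired Cohen's d with interpretation band
#'
#' d = mean(delta) / sd(delta) with sample SD (n-1). Bands: negligible
#' [0, 0.2), small [0.2, 0.5), moderate [0.5, 0.8), large > 0.8 (band
#' boundaries are left-closed on the magnitude, so |d| = 0.5 is
#' "moderate"). Zero-SD differences are flagged, not divided.
#'
#' @param pre,intra paired numeric vectors.
#' @return list: `d`, `band`, `n`, `degenerate` (TRUE when sd = 0).
#' @export
cohensD <- function(pre, intra) {
  ok <- !is.na(pre) & !is.na(intra)
  d <- intra[ok] - pre[ok]
  if (length(d) < 2L) stop("need at least 2 pairs")
  s <- sd(d)
  if (s == 0)
    return(list(d = NA_real_, band = "degenerate", n = length(d),
                degenerate = TRUE))
  dd <- mean(d) / s
  list(d = dd, band = effectBand(dd), n = length(d), degenerate = FALSE)
}

#' @rdname cohensD
#' @param d effect size.
#' @export
effectBand <- function(d) {
  a <- abs(d)
  if (a < 0.2) "negligible" else if (a < 0.5) "small"
  else if (a < 0.8) "moderate" else "large"
}

#' Paired comparison via a linear mixed-effects model
#'
#' Random-intercept model value ~ timepoint (+ covariate) + (1 |
#' subject) fit by REML; the reported p is the Wald normal p of the
#' timepoint effect. With no covariate and balanced pairs the timepoint
#' estimate equals the mean paired difference. Singular fits are flagged
#' and accompanied by a fallback paired t-test.
#'
#' @param values numeric vector (stacked pre and intra).
#' @param timepoint factor/character of "pre"/"intra" per value.
#' @param subject subject id per value.
#' @param covariate optional numeric covariate per value.
#' @return list: `estimate` (intra - pre), `se`, `p`, `singular`,
#'   `fallbackP` (paired t, only when singular).
#' @export
pairedLMM <- function(values, timepoint, subject, covariate = NULL) {
  tp <- factor(timepoint, levels = c("pre", "intra"))
  df <- data.frame(y = values, tp = tp, subj = factor(subject))
  form <- y ~ tp + (1 | subj)
  if (!is.null(covariate)) {
    df$cov <- covariate
    form <- y ~ tp + cov + (1 | subj)
  }
  ok <- stats::complete.cases(df)
  df <- df[ok, , drop = FALSE]
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE,
                                     control = lme4::lmerControl(
                                       calc.derivs = FALSE)))
  co <- summary(fit)$coefficients
  est <- co["tpintra", "Estimate"]
  se <- co["tpintra", "Std. Error"]
  p <- 2 * pnorm(-abs(est / se))
  singular <- lme4::isSingular(fit)
  fallbackP <- NA_real_
  if (singular) {
    wide <- split(df$y, list(df$subj, df$tp))
    pre <- tapply(df$y[df$tp == "pre"], df$subj[df$tp == "pre"], mean)
    intra <- tapply(df$y[df$tp == "intra"], df$subj[df$tp == "intra"],
                    mean)
    common <- intersect(names(pre), names(intra))
    if (length(common) >= 2L)
      fallbackP <- t.test(intra[common], pre[common],
                          paired = TRUE)$p.value
  }
  list(estimate = est, se = se, p = p, singular = singular,
       fallbackP = fallbackP)
}

#' Per-segment tests of mean change against zero
#'
#' For each tract segment, the statistic is z = mean(delta) /
#' (sd(delta) / sqrt(n)); Benjamini-Hochberg adjustment is applied
#' across the segments of the matrix (one testing family = one metric
#' of one tract and side). Segments missing in more than half of the
#' subjects are excluded and reported.
#'
#' Because the standard error is estimated from the same n subjects,
#' the statistic follows a Student t distribution with n - 1 degrees of
#' freedom under the null; a normal reference inflates the tail
#' probabilities several-fold at cohort sizes around 30, so the default
#' p-value uses the t reference (`reference = "normal"` reproduces the
#' plain z-test).
#'
#' @param deltas subjects x segments matrix of paired changes.
#' @param reference "t" (default, calibrated) or "normal".
#' @return data.frame: segment, n, mean, se, z, p, pFdr, excluded.
#' @export
segmentZTest <- function(deltas, reference = c("t", "normal")) {
  reference <- match.arg(reference)
  deltas <- as.matrix(deltas)
  ns <- ncol(deltas)
  n <- colSums(!is.na(deltas))
  excluded <- n < nrow(deltas) / 2 | n < 3L
  mu <- colMeans(deltas, na.rm = TRUE)
  se <- apply(deltas, 2, sd, na.rm = TRUE) / sqrt(n)
  z <- mu / se
  p <- if (reference == "t") 2 * stats::pt(-abs(z), df = pmax(n - 1, 1))
       else 2 * pnorm(-abs(z))
  p[excluded] <- NA_real_
  pf <- rep(NA_real_, ns)
  pf[!excluded] <- bhFDR(p[!excluded])
  data.frame(segment = seq_len(ns), n = n, mean = mu, se = se, z = z,
             p = p, pFdr = pf, excluded = excluded)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up procedure with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values (elementwise >= raw).
#' @export
bhFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Correlation between tract change and a structural volume
#'
#' Pearson product-moment correlation (the default) of a per-subject
#' tract change against ventricular or tumor volume, with a two-sided p;
#' Spearman is available as an option.
#'
#' @param delta per-subject tract metric change.
#' @param volume per-subject ventricle or tumor volume.
#' @param method "pearson" (default) or "spearman".
#' @return list: `r`, `p`, `n`, `method`.
#' @export
changeCorrelation <- function(delta, volume,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(delta) & !is.na(volume)
  if (sum(ok) < 5L) warning("fewer than 5 complete pairs")
  if (sd(delta[ok]) == 0 || sd(volume[ok]) == 0)
    stop("zero variance; correlation undefined")
  ct <- suppressWarnings(cor.test(delta[ok], volume[ok], method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       method = method)
}

#' Speech-disturbance increase label from SARA speech subscores
#'
#' TRUE iff the early postoperative score rose by at least one point
#' relative to the presurgical score. Scores range 0 (normal) to 6
#' (anarthria); missing scores yield a missing label.
#'
#' @param saraT0,saraT1 integer scores in 0..6.
#' @return logical vector (NA where a score is missing).
#' @export
speechLabel <- function(saraT0, saraT1) {
  chk <- function(x) {
    bad <- !is.na(x) & (x < 0 | x > 6 | x != round(x))
    if (any(bad)) stop("SARA speech subscores must be integers in 0..6")
  }
  chk(saraT0); chk(saraT1)
  ifelse(is.na(saraT0) | is.na(saraT1), NA, (saraT1 - saraT0) >= 1)
}

#' Logistic regression of outcome on age and sex
#'
#' Maximum-likelihood logistic fit label ~ age + sex with Wald p per
#' covariate. Complete or quasi-complete separation is detected (fitted
#' probabilities collapsing to 0/1) and flagged.
#'
#' @param age numeric years.
#' @param sex factor/character.
#' @param label logical/0-1 outcome (both classes must be present).
#' @return list: `coefficients` (matrix with estimates, SE, z, p),
#'   `separation` flag, `n`.
#' @export
logisticOutcome <- function(age, sex, label) {
  ok <- !is.na(age) & !is.na(sex) & !is.na(label)
  lab <- as.integer(label[ok])
  if (length(unique(lab)) < 2L)
    stop("outcome has a single class; logistic fit undefined")
  df <- data.frame(lab = lab, age = age[ok], sex = factor(sex[ok]))
  form <- if (nlevels(df$sex) > 1L) lab ~ age + sex else lab ~ age
  fit <- suppressWarnings(glm(form, data = df, family = binomial()))
  pr <- predict(fit, type = "response")
  separation <- any(pr > 1 - 1e-8 | pr < 1e-8) || !fit$converged
  list(coefficients = summary(fit)$coefficients,
       separation = separation, n = nrow(df))
}
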