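#' Repeated-measures one-way ANOVA with Greenhouse-Geisser correction
#'
#' Fits the within-subject one-way layout (subjects x conditions) and
#' corrects the F-test degrees of freedom for departures from sphericity with
#' the Greenhouse-Geisser epsilon, estimated from the double-centered sample
#' covariance `C` of the conditions as
#' `epsilon = (tr C)^2 / ((k - 1) * sum(C^2))` and clamped to its analytic
#' range `[1/(k - 1), 1]`. The p-value comes from the F distribution at
#' `(k - 1) * epsilon` and `(k - 1)(n - 1) * epsilon` degrees of freedom.
#' With two conditions epsilon is exactly 1 and the test coincides with the
#' two-sided paired t-test (`F = t^2`).
#'
#' @param mat Numeric matrix, one row per subject (experiment/donor), one
#'   column per condition. Rows containing missing values are dropped
#'   (complete-case analysis).
#' @return A list: `F`, `df1`, `df2` (corrected), `epsilon`, `p`, `n`, `k`.
#' @export
rm_anova_gg <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (n < 2L) {
    stop("insufficient data: fewer than 2 complete subjects", call. = FALSE)
  }
  grand <- mean(mat)
  colm <- colMeans(mat)
  rowm <- rowMeans(mat)
  ss_cond <- n * sum((colm - grand)^2)
  resid <- mat - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  S <- stats::cov(mat)
  C <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(C))^2 / ((k - 1) * sum(C^2))
  eps <- min(1, max(1 / (k - 1), eps))
  p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  list(F = f, df1 = df1 * eps, df2 = df2 * eps, epsilon = eps, p = p,
       n = n, k = k)
}

#' Dunnett many-to-one comparisons for a repeated-measures design
#'
#' Compares every condition against the designated control within subjects,
#' using the repeated-measures ANOVA error term (degrees of freedom
#' `(n - 1)(k - 1)`) and the balanced Dunnett correlation 1/2 between
#' contrasts. With a single comparison (k = 2) the procedure reduces exactly
#' to the two-sided paired t-test.
#'
#' @param mat Numeric matrix, subjects x conditions, with column names;
#'   incomplete rows are dropped.
#' @param control Column name of the control condition (default `"NT"`).
#' @return A `data.frame`: `condition`, `estimate` (condition minus control
#'   mean), `tstat`, `df`, `p_adj`.
#' @export
dunnett_rm <- function(mat, control = "NT") {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat)) || !control %in% colnames(mat)) {
    stop(sprintf("control condition '%s' not found among columns", control),
         call. = FALSE)
  }
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L) {
    stop("insufficient data: fewer than 2 complete subjects", call. = FALSE)
  }
  grand <- mean(mat)
  colm <- colMeans(mat)
  rowm <- rowMeans(mat)
  resid <- mat - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  if (mse <= 0) {
    stop("degenerate design: zero within-subject error variance", call. = FALSE)
  }
  treat <- setdiff(colnames(mat), control)
  est <- colm[treat] - colm[[control]]
  tstat <- est / sqrt(2 * mse / n)
  df <- (n - 1) * (k - 1)
  p_adj <- dunnett_pvalues(tstat, rep(sqrt(0.5), length(treat)), df)
  data.frame(condition = treat, estimate = unname(est),
             tstat = unname(tstat), df = df, p_adj = unname(p_adj),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Student's t-test (two-sample pooled-variance or paired)
#'
#' Thin wrapper around [stats::t.test()] with the conventions used
#' throughout the package: two-tailed, pooled-variance by default for two
#' independent samples (Welch available by flag), paired on request.
#'
#' @param x,y Numeric value vectors (equal length if `paired`).
#' @param paired Paired test?
#' @param welch Use the Welch unequal-variance form instead of the pooled
#'   form (ignored when `paired`)?
#' @return A list: `t`, `df`, `p`.
#' @export
ttest <- function(x, y, paired = FALSE, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal-length groups", call. = FALSE)
  }
  if (paired) {
    if (stats::sd(x - y) == 0) {
      if (all(x == y)) return(list(t = 0, df = length(x) - 1, p = 1))
      stop("degenerate paired differences: zero variance", call. = FALSE)
    }
    ht <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
      }
      stop("degenerate groups: zero variance in both groups", call. = FALSE)
    }
    ht <- stats::t.test(x, y, var.equal = !welch)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Relative expression by the 2^(-dCT) method
#'
#' Computes `2^-(CT_target - CT_reference)` per sample, the standard
#' single-normalizer relative quantification (reference GAPDH for mRNA,
#' a stably expressed control miRNA such as miR-93-3p for miRNA assays).
#' Samples flagged as below the detection limit are reported as censored
#' (`NA` with `detected = FALSE`), never imputed as zero.
#'
#' @param ct_target,ct_reference Cycle-threshold values (vectors of equal
#'   length).
#' @param detected Logical vector; `FALSE` marks targets below the detection
#'   limit. Defaults to all detected.
#' @return A `data.frame` with `dct`, `rel_expr` and `detected`; the number
#'   of detected samples is attached as `attr(, "n_detected")`.
#' @export
ddct <- function(ct_target, ct_reference, detected = NULL) {
  stopifnot(length(ct_target) == length(ct_reference))
  if (is.null(detected)) detected <- rep(TRUE, length(ct_target))
  bad <- detected & (!is.finite(ct_target) | !is.finite(ct_reference) |
                       ct_target <= 0 | ct_reference <= 0)
  if (any(bad)) {
    stop("CT values must be positive and finite unless flagged not-detected",
         call. = FALSE)
  }
  dct <- ifelse(detected, ct_target - ct_reference, NA_real_)
  out <- data.frame(dct = dct, rel_expr = 2^(-dct), detected = detected)
  attr(out, "n_detected") <- sum(detected)
  out
}

#' Relative firefly activity from a dual-luciferase plate
#'
#' Computes the per-well firefly/Renilla ratio and normalizes each well to
#' the mean ratio of the same construct's NT (non-targeting control RNA)
#' co-transfection arm, so that each construct's NT arm averages exactly 1.
#' Wells with non-positive Renilla luminescence are excluded with a warning.
#'
#' @param wells A `data.frame` with columns `construct` (e.g. WT / MUT
#'   binding-site reporter), `arm` (`"NT"` or the miRNA label), `firefly`
#'   and `renilla` (RLU).
#' @return The valid wells with added columns `ratio` and `rel_activity`.
#' @export
luciferase_relative <- function(wells) {
  need <- c("construct", "arm", "firefly", "renilla")
  stopifnot(all(need %in% names(wells)))
  bad <- !is.finite(wells$renilla) | wells$renilla <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d well(s) with non-positive Renilla signal",
                    sum(bad)), call. = FALSE)
    wells <- wells[!bad, , drop = FALSE]
  }
  wells$ratio <- wells$firefly / wells$renilla
  out <- lapply(split(wells, wells$construct), function(w) {
    nt <- w$ratio[w$arm == "NT"]
    if (length(nt) == 0L) {
      stop(sprintf("construct '%s' has no NT co-transfection arm",
                   w$construct[1]), call. = FALSE)
    }
    w$rel_activity <- w$ratio / mean(nt)
    w
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bacterial titre from a spot-plated dilution series
#'
#' Estimates CFU/ml from 10-fold serial dilutions spot-plated in fixed-volume
#' replicates (the gentamicin-protection readout): the most concentrated
#' dilution whose mean spot count lies in the countable range is selected and
#' `CFU/ml = mean count x (1000 / spot volume in ul) x 10^dilution`.
#'
#' @param counts Integer matrix of colony counts, one row per dilution, one
#'   column per replicate spot (default geometry: six 10 ul spots).
#' @param dilutions Vector of 10-fold dilution exponents `d` (one per row);
#'   a spot of dilution `d` contains `volume * 10^-d` of the original sample.
#' @param countable_range Inclusive bounds on the mean spot count considered
#'   countable (default 3-30 colonies per spot).
#' @param spot_volume_ul Plated volume per spot in microliters (default 10).
#' @return A list: `cfu_per_ml`, `dilution` (chosen exponent), `mean_count`,
#'   `cv` (coefficient of variation across the spots of that dilution).
#' @export
cfu_per_ml <- function(counts, dilutions, countable_range = c(3, 30),
                       spot_volume_ul = 10) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(dilutions))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts", "must be nonnegative integers")
  }
  means <- rowMeans(counts)
  countable <- means >= countable_range[1] & means <= countable_range[2]
  if (!any(countable)) {
    if (all(means > countable_range[2])) {
      stop("no countable dilution: all spots too dense; extend the series",
           call. = FALSE)
    }
    if (all(means < countable_range[1])) {
      stop("no countable dilution: all spots too sparse; sample below detection",
           call. = FALSE)
    }
    stop("no countable dilution: series jumps over the countable range",
         call. = FALSE)
  }
  i <- which(countable)[which.min(dilutions[countable])]
  m <- means[i]
  list(
    cfu_per_ml = m * (1000 / spot_volume_ul) * 10^dilutions[i],
    dilution = dilutions[i],
    mean_count = m,
    cv = stats::sd(counts[i, ]) / m
  )
}
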