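## Statistical primitives (KS, Wilcoxon, BH), the structure-stratified
## linear model with stepwise AIC selection, and single-site equilibrium
## binding-curve fitting.

#' Construct a binding curve
#'
#' Fluorescence polarization (or analogous signal) measurements across a
#' protein titration, stored long-form (one row per concentration x
#' replicate).
#'
#' @param concentrations_nM positive protein concentrations, one per
#'   measurement row.
#' @param fp signal values, parallel to `concentrations_nM`.
#' @param replicate replicate labels (default all `1`).
#' @return data frame of class `binding_curve` with `conc_nM`, `fp`,
#'   `replicate`.
#' @export
binding_curve <- function(concentrations_nM, fp, replicate = 1L) {
  stopifnot(all(concentrations_nM > 0), length(fp) ==
              length(concentrations_nM))
  out <- data.frame(
    conc_nM = concentrations_nM, fp = fp,
    replicate = rep_len(replicate, length(fp))
  )
  if (length(unique(out$conc_nM)) < 5L) {
    stop("need at least 5 distinct concentrations for fitting")
  }
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' Delta-FP normalization of a binding curve
#'
#' Normalizes the curve to its own minimum and maximum signal (per-
#' concentration means) so the values run from 0 to 1.
#'
#' @param curve a [binding_curve()].
#' @return the curve with `fp` replaced by delta-FP values.
#' @export
delta_fp <- function(curve) {
  stopifnot(inherits(curve, "binding_curve"))
  m <- tapply(curve$fp, curve$conc_nM, mean)
  lo <- min(m)
  hi <- max(m)
  if (hi - lo <= 0) stop("flat curve: cannot normalize")
  curve$fp <- (curve$fp - lo) / (hi - lo)
  curve
}

#' Fit a single-site equilibrium binding model
#'
#' Least-squares fit of `FP(c) = fp_min + (fp_max - fp_min) * c /
#' (Kd + c)` to the pooled measurement points, via Levenberg-Marquardt.
#' The Kd confidence interval is profile-likelihood based
#' (via [stats::confint()] on a refitted `nls` object) when the profile
#' converges, `NA` otherwise. If the fitted Kd exceeds the largest
#' assayed concentration the fit is flagged as non-saturating.
#'
#' @param curve a [binding_curve()] (already delta-FP normalized or
#'   raw).
#' @param conf_level confidence level for the Kd interval (default
#'   0.95).
#' @return list of class `single_site_fit` with `Kd_nM`, `fp_min`,
#'   `fp_max`, `residual_norm`, `ci` (lower/upper), `saturated`
#'   (logical), `fit` (the `nls` object).
#' @export
fit_single_site <- function(curve, conf_level = 0.95) {
  stopifnot(inherits(curve, "binding_curve"))
  df <- data.frame(conc = curve$conc_nM, fp = curve$fp)
  if (sd(df$fp) < 1e-12 * max(1, abs(mean(df$fp)))) {
    stop("degenerate (flat) curve: no concentration dependence to fit")
  }
  rng <- range(df$fp)
  start <- list(
    fp_min = rng[1], fp_max = rng[2],
    Kd = median(df$conc)
  )
  fit <- minpack.lm::nlsLM(
    fp ~ fp_min + (fp_max - fp_min) * conc / (Kd + conc),
    data = df, start = start,
    lower = c(-Inf, -Inf, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  if (est[["fp_max"]] <= est[["fp_min"]]) {
    stop("degenerate fit: fp_max <= fp_min")
  }
  ci <- tryCatch(
    suppressWarnings(suppressMessages(
      stats::confint(fit, "Kd", level = conf_level)
    )),
    error = function(e) c(NA_real_, NA_real_)
  )
  saturated <- est[["Kd"]] <= max(df$conc)
  if (!saturated) {
    warning("non-saturating curve: max concentration below fitted Kd")
  }
  structure(
    list(
      Kd_nM = unname(est[["Kd"]]),
      fp_min = unname(est[["fp_min"]]),
      fp_max = unname(est[["fp_max"]]),
      residual_norm = sqrt(sum(stats::residuals(fit)^2)),
      ci = setNames(as.numeric(ci), c("lower", "upper")),
      saturated = saturated,
      fit = fit
    ),
    class = "single_site_fit"
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] (two-sided) returning the D
#' statistic and p value.
#'
#' @param x,y numeric samples (each `n >= 2`).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Wilcoxon test (paired signed-rank or rank-sum)
#'
#' Wrapper around [stats::wilcox.test()]. For paired data with all-zero
#' differences (no evidence either way) the p value is 1 with a warning,
#' rather than an error.
#'
#' @param x numeric sample (or paired first member).
#' @param y optional second sample.
#' @param paired paired test (default `FALSE`).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `p` and `statistic`.
#' @export
wilcoxon_test <- function(x, y = NULL, paired = FALSE,
                          alternative = "two.sided") {
  if (paired || is.null(y)) {
    d <- if (is.null(y)) x else x - y
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1")
      return(list(p = 1, statistic = NA_real_))
    }
    wt <- suppressWarnings(
      wilcox.test(d, alternative = alternative, exact = TRUE)
    )
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative)
    )
  }
  list(p = wt$p.value, statistic = unname(wt$statistic))
}

#' Benjamini-Hochberg adjustment
#'
#' Wrapper around [stats::p.adjust()] with `method = "BH"`.
#' @param p numeric vector of raw p values.
#' @return adjusted p values (same order as input).
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Structure-stratified kmer feature matrix
#'
#' Per oligo, counts each kmer identity separately in its
#' `more_structured` and `less_structured` occurrences (features named
#' `<kmer>_more` / `<kmer>_less`; `2 * 4^k` candidates). Zero-variance
#' features are dropped and tallied.
#'
#' @param enrichments an [oligo_enrichment()] (defines the oligo set and
#'   the response).
#' @param classes a [classify_kmer_structure()] table covering those
#'   oligos.
#' @param k kmer length (default 3, must match `classes`).
#' @return list with `features` (oligo x feature count matrix over
#'   retained oligos with finite `log2R`), `response` (named `log2R`
#'   vector), `n_dropped_zero_variance`.
#' @export
build_feature_matrix <- function(enrichments, classes, k = 3L) {
  stopifnot(inherits(classes, "structure_class_table"),
            attr(classes, "k") == k)
  ok <- enrichments$passed_filter & is.finite(enrichments$log2R)
  ids <- enrichments$oligo_id[ok]
  if (!all(ids %in% classes$oligo_id)) {
    stop("classes table does not cover all retained oligos")
  }
  feat_names <- c(paste0(all_kmers(k), "_more"),
                  paste0(all_kmers(k), "_less"))
  cls <- classes[classes$oligo_id %in% ids, , drop = FALSE]
  key <- paste0(cls$kmer, ifelse(cls$class == "more_structured",
                                 "_more", "_less"))
  tab <- table(factor(cls$oligo_id, levels = ids),
               factor(key, levels = feat_names))
  mat <- matrix(as.numeric(tab), nrow = length(ids),
                dimnames = list(ids, feat_names))
  keep <- apply(mat, 2, var) > 0
  list(
    features = mat[, keep, drop = FALSE],
    response = setNames(enrichments$log2R[ok], ids),
    n_dropped_zero_variance = sum(!keep)
  )
}

#' Stepwise-AIC linear model of binding
#'
#' Fits a linear model of the response on the candidate features and
#' performs bidirectional stepwise selection by Akaike information
#' criterion, starting from the full model after pruning rank-deficient
#' columns. Every accepted step strictly lowers the AIC and the search is
#' deterministic given the input column order.
#'
#' @param features numeric matrix (observations x features) with column
#'   names.
#' @param response numeric response vector.
#' @return list of class `linear_model_fit` with `selected` (feature
#'   names), `coefficients`, `aic_trace` (AIC after each accepted step,
#'   strictly decreasing), `dropped_rank_deficient`, `model` (the `lm`).
#' @export
stepwise_aic <- function(features, response) {
  stopifnot(nrow(features) == length(response))
  if (nrow(features) <= ncol(features)) {
    stop("need more observations than candidate features")
  }
  df <- data.frame(.y = response, features, check.names = TRUE)
  full <- lm(.y ~ ., data = df)
  dropped <- names(which(is.na(coef(full))))
  if (length(dropped)) {
    keep <- setdiff(colnames(features),
                    colnames(features)[make.names(colnames(features))
                                       %in% dropped])
    df <- data.frame(.y = response, features[, keep, drop = FALSE],
                     check.names = TRUE)
    full <- lm(.y ~ ., data = df)
  }
  sel <- step(full, direction = "both", trace = 0,
              scope = list(lower = .y ~ 1))
  trace <- sel$anova$AIC
  structure(
    list(
      selected = setdiff(names(coef(sel)), "(Intercept)"),
      coefficients = coef(sel),
      aic_trace = trace,
      dropped_rank_deficient = dropped,
      model = sel
    ),
    class = "linear_model_fit"
  )
}
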