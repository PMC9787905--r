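# Mixed-model significance screen, correlation matrix, feature selection.

# Coerce a GaitSampleTable or plain data.frame into the long screening
# frame: 18 feature columns + metadata columns.
.as_sample_df <- function(table) {
  if (is(table, "GaitSampleTable")) {
    df <- cbind(as.data.frame(t(SummarizedExperiment::assay(table,
                                                            "features"))),
                as.data.frame(SummarizedExperiment::colData(table)))
    rownames(df) <- NULL
    return(df)
  }
  df <- as.data.frame(table)
  miss <- setdiff(gaitFeatureNames(), names(df))
  if (length(miss))
    stopf("schema error: missing feature columns: %s",
          paste(miss, collapse = ", "))
  df
}

#' Mixed-model significance screen over the 18 gait features
#'
#' For each feature, fits a linear mixed model with the class variable as a
#' fixed factor and the participant as a random intercept
#' (`feature ~ factor + (1 | participant_id)`), on the rows of the given
#' test type. The fixed-factor p-value is a whole-factor test (the factor
#' can have up to three levels, so per-coefficient tests are not used):
#' by default the Satterthwaite-approximated F test on the REML fit, whose
#' type-I error holds at study-scale cohort sizes. P-values are
#' Bonferroni-adjusted across the 18 features within one (test type, factor)
#' family, and flagged significant at adjusted p < `alpha`. Singular or
#' failed mixed fits fall back to a fixed-effects ANOVA F-test and are
#' flagged `degenerate`.
#'
#' @param table A [GaitSampleTable-class] or a `data.frame` holding the 18
#'   features plus metadata columns.
#' @param fixedFactor Metadata column to test, e.g. `"group"`,
#'   `"medication_state"` or `"severity_level"`.
#' @param testType Optional test type to subset to (default: use all rows).
#' @param alpha Family-wise significance level (default 0.05).
#' @param features Feature subset to screen (default all 18); the Bonferroni
#'   multiplier is the number of screened features.
#' @param method `"satterthwaite"` (default): REML fit with the
#'   Satterthwaite-approximated F test of the fixed factor, which holds its
#'   level at study-scale cohort sizes; `"lrt"`: maximum-likelihood ratio
#'   test of full vs null model, whose asymptotic chi-square reference is
#'   anti-conservative in the Bonferroni tail at small n (kept for
#'   comparison).
#' @return `data.frame` with one row per feature: `feature`, `test_type`,
#'   `factor`, `p_raw`, `p_adj` (`min(1, m * p_raw)`), `significant`,
#'   `degenerate`.
#' @examples
#' tab <- simulateFeatureTable(c(A = 8, B = 8), seed = 1)
#' head(lmmScreen(tab, "group"))
#' @export
lmmScreen <- function(table, fixedFactor, testType = NULL, alpha = 0.05,
                      features = gaitFeatureNames(),
                      method = c("satterthwaite", "lrt")) {
  method <- match.arg(method)
  df <- .as_sample_df(table)
  if (!fixedFactor %in% names(df))
    stopf("unknown fixed factor '%s'", fixedFactor)
  if (!is.null(testType)) df <- df[df$test_type %in% testType, , drop = FALSE]
  df <- df[!is.na(df[[fixedFactor]]), , drop = FALSE]
  fac <- factor(df[[fixedFactor]])
  if (nlevels(droplevels(fac)) < 2L)
    stop("need at least 2 levels of the fixed factor", call. = FALSE)
  df$.factor <- droplevels(fac)
  df$.pid <- factor(df$participant_id)
  m <- length(features)

  fit_one <- function(feature) {
    d <- df
    d$.y <- d[[feature]]
    p <- NA_real_; degenerate <- FALSE
    ctrl <- lme4::lmerControl(
      calc.derivs = FALSE,
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
    fit <- tryCatch(suppressMessages({
      if (method == "satterthwaite") {
        full <- lmerTest::lmer(.y ~ .factor + (1 | .pid), data = d,
                               REML = TRUE, control = ctrl)
        if (lme4::isSingular(full, tol = 1e-5)) NULL
        else anova(full, ddf = "Satterthwaite")[1, "Pr(>F)"]
      } else {
        full <- lme4::lmer(.y ~ .factor + (1 | .pid), data = d,
                           REML = FALSE, control = ctrl)
        null <- lme4::lmer(.y ~ 1 + (1 | .pid), data = d, REML = FALSE,
                           control = ctrl)
        if (lme4::isSingular(full, tol = 1e-5)) NULL
        else anova(null, full)[2, "Pr(>Chisq)"]
      }
    }), error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      # degenerate random effect (e.g. zero within-participant variance or
      # one row per participant): refit without the random term, flag it
      degenerate <- TRUE
      p <- tryCatch(
        anova(lm(.y ~ 1, data = d), lm(.y ~ .factor, data = d))[2, "Pr(>F)"],
        error = function(e) NA_real_)
    } else p <- fit
    c(p = p, degenerate = degenerate)
  }

  res <- t(vapply(features, fit_one, numeric(2)))
  p_raw <- res[, "p"]
  out <- data.frame(
    feature = features,
    test_type = if (is.null(testType)) NA_character_ else testType[1],
    factor = fixedFactor,
    p_raw = p_raw,
    p_adj = pmin(1, m * p_raw),
    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$degenerate <- as.logical(res[, "degenerate"])
  rownames(out) <- NULL
  out
}

#' Feature-feature correlation matrix
#'
#' Product-moment correlations between the 18 gait features, a preliminary
#' interpretation tool and the redundancy input for [selectFeatures()].
#' A constant feature has undefined correlations; those entries are `NA`.
#'
#' @param table A [GaitSampleTable-class] or feature `data.frame` (>= 3
#'   rows).
#' @param features Feature columns to correlate (default all 18).
#' @return Symmetric numeric matrix with unit diagonal, entries in [-1, 1]
#'   or `NA`.
#' @export
correlationMatrix <- function(table, features = gaitFeatureNames()) {
  df <- .as_sample_df(table)
  if (nrow(df) < 3L) stop("need at least 3 rows", call. = FALSE)
  x <- as.matrix(df[, features, drop = FALSE])
  constant <- apply(x, 2, function(v) var(v) < 1e-24)
  r <- suppressWarnings(cor(x))
  r[constant, ] <- NA
  r[, constant] <- NA
  diag(r) <- ifelse(constant, NA, 1)
  r
}

#' Select features from the screen and the correlation matrix
#'
#' Keeps the features with Bonferroni-adjusted p < `alpha`; within any pair
#' of kept features with `|r| > rCut`, drops the one with the larger
#' adjusted p (ties broken towards the earlier feature in the canonical
#' order). If nothing is significant the full screened set is returned with
#' a warning, so downstream classification always has inputs.
#'
#' @param statResults Output of [lmmScreen()].
#' @param correlations Output of [correlationMatrix()].
#' @param rCut Absolute-correlation redundancy threshold (default 0.90).
#' @param alpha Significance level on the adjusted p-values.
#' @return Character vector of selected feature names (canonical order).
#' @export
selectFeatures <- function(statResults, correlations, rCut = 0.90,
                           alpha = 0.05) {
  stopifnot(all(c("feature", "p_adj", "significant") %in% names(statResults)))
  canon <- statResults$feature
  sig <- statResults$feature[statResults$significant]
  if (!length(sig)) {
    warning("no significant features; falling back to the full screened set",
            call. = FALSE)
    return(canon)
  }
  kept <- sig[order(match(sig, canon))]
  p_of <- setNames(statResults$p_adj, statResults$feature)
  repeat {
    if (length(kept) < 2L) break
    r <- abs(correlations[kept, kept, drop = FALSE])
    diag(r) <- 0
    r[is.na(r)] <- 0
    if (max(r) <= rCut) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    a <- kept[ij[1]]; b <- kept[ij[2]]
    drop <- if (p_of[a] > p_of[b]) a
      else if (p_of[b] > p_of[a]) b
      else kept[max(ij)]       # tie: keep the earlier canonical feature
    kept <- setdiff(kept, drop)
  }
  kept
}
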