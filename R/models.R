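#' Fixed-predictor set for a response
#'
#' SR and PD are modelled on the competition index plus six terrain
#' covariates (elevation, aspect, slope, TPI, TRI, flow); the NRI and NTI
#' models add species richness as an eighth predictor, since SES values are
#' mechanically related to richness.
#'
#' @param response one of `"SR"`, `"PD"`, `"NRI"`, `"NTI"`.
#' @return character vector of predictor column names.
#' @export
model_predictors <- function(response) {
  response <- match.arg(toupper(response), c("SR", "PD", "NRI", "NTI"))
  base <- c("ci", "elevation", "aspect", "slope", "tpi", "tri", "flowdir")
  if (response %in% c("NRI", "NTI")) c(base, "sr") else base
}

#' Assemble a model design for one response x scale x stage
#'
#' Filters the metric table to the requested scale and stage, drops quadrats
#' whose response or predictors are undefined (e.g. NRI where SR < 2),
#' z-scores every predictor within the design so coefficients are
#' comparable effect sizes, and attaches the random-effect grouping column.
#' Refuses to build a design with fewer than `min_rows_per_predictor` rows
#' per fixed predictor.
#'
#' @param metrics a metric table from [build_metric_table()].
#' @param response one of `"SR"`, `"PD"`, `"NRI"`, `"NTI"`.
#' @param scale analysis grain in metres.
#' @param stage `"all"` or a life stage.
#' @param group grouping column for the random intercept:
#'   `"dominant_species"` (the quadrat's highest-basal-area species — the
#'   quadrat-level reading of a species random effect) or `"block"` (the
#'   20 m census block, a spatial pseudo-replication control).
#' @param extra_predictors additional covariate columns (e.g. `"roughness"`)
#'   appended to the default predictor set.
#' @param min_rows_per_predictor minimum rows per predictor (default 10).
#' @return an object of class `"phylo_design"`: list with `data` (response
#'   `y`, z-scored predictors, `group`), `response`, `scale`, `stage`,
#'   `predictors`, `n_dropped`.
#' @export
build_design <- function(metrics, response, scale, stage = "all",
                         group = c("dominant_species", "block"),
                         extra_predictors = character(),
                         min_rows_per_predictor = 10) {
  response <- match.arg(toupper(response), c("SR", "PD", "NRI", "NTI"))
  group <- match.arg(group)
  preds <- unique(c(model_predictors(response), extra_predictors))
  ycol <- tolower(response)
  need <- c(ycol, preds, group, "scale", "stage")
  missing <- setdiff(need, names(metrics))
  if (length(missing)) {
    stop("metric table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- metrics[metrics$scale == scale & metrics$stage == stage, , drop = FALSE]
  if (!nrow(sub)) stop("no rows at scale ", scale, ", stage ", stage, call. = FALSE)
  ok <- is.finite(sub[[ycol]])
  for (p in preds) ok <- ok & is.finite(sub[[p]])
  n_dropped <- sum(!ok)
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) < min_rows_per_predictor * length(preds)) {
    stop("only ", nrow(sub), " usable quadrats for ", response, " at ",
         scale, " m / ", stage, "; need at least ",
         min_rows_per_predictor * length(preds), call. = FALSE)
  }
  dat <- data.frame(y = sub[[ycol]])
  dat[preds] <- sub[preds]
  dat <- zscore_covariates(dat, preds)
  dat$group <- factor(sub[[group]])
  structure(list(data = dat, response = response, scale = scale,
                 stage = stage, predictors = preds, grouping = group,
                 n_dropped = n_dropped),
            class = "phylo_design")
}

#' Fit the linear mixed-effects model for one design
#'
#' REML fit of `y ~ predictors + (1 | group)` via `lme4::lmer()`. Wald
#' t-tests per coefficient use residual-based degrees of freedom
#' (`n - p_fixed`). When the random-intercept variance converges to the
#' boundary (a singular fit) the model falls back to ordinary least squares
#' with a warning, since the mixed model then carries no grouping
#' information. Collinear predictors are an error naming the aliased
#' columns.
#'
#' @param design a `"phylo_design"` from [build_design()].
#' @return an object of class `"phylo_fit"`: list with `coefficients`
#'   (term, estimate, se, statistic, df, p), `group_var`, `residual_var`,
#'   `n`, `method` (`"lmm"` or `"ols"`), `converged`, plus the design
#'   metadata.
#' @export
fit_lmm <- function(design) {
  stopifnot(inherits(design, "phylo_design"))
  dat <- design$data
  preds <- design$predictors
  X <- as.matrix(cbind(1, dat[preds]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- c("(Intercept)", preds)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear predictors: ", paste(aliased, collapse = ", "), call. = FALSE)
  }
  fixed <- paste("y ~", paste(preds, collapse = " + "))
  n <- nrow(dat)
  p <- length(preds) + 1L

  use_ols <- nlevels(droplevels(dat$group)) < 2
  fit <- NULL
  group_var <- 0
  resid_var <- NA_real_
  converged <- TRUE
  if (!use_ols) {
    fit <- suppressMessages(lme4::lmer(
      as.formula(paste(fixed, "+ (1 | group)")), data = dat, REML = TRUE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    group_var <- vc$vcov[vc$grp == "group"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    converged <- length(fit@optinfo$conv$lme4) == 0
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("random-intercept variance at the boundary (0); ",
              "falling back to ordinary least squares")
      use_ols <- TRUE
    }
  }
  if (use_ols) {
    fit_ols <- stats::lm(as.formula(fixed), data = dat)
    est <- stats::coef(fit_ols)
    se <- sqrt(diag(stats::vcov(fit_ols)))
    resid_var <- summary(fit_ols)$sigma^2
    if (is.null(fit)) group_var <- 0
    method <- "ols"
  } else {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    method <- "lmm"
  }
  df <- n - p
  stat <- est / se
  pval <- 2 * pt(-abs(stat), df)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), statistic = unname(stat),
                      df = df, p = unname(pval), stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, group_var = group_var,
                 residual_var = resid_var, n = n, method = method,
                 converged = converged, response = design$response,
                 scale = design$scale, stage = design$stage,
                 grouping = design$grouping),
            class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("<phylo_fit> %s ~ %d predictors at %g m / %s (%s, n = %d)\n",
              x$response, nrow(x$coefficients) - 1L, x$scale, x$stage,
              x$method, x$n))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Significance tier of a p-value
#'
#' `"a"`: p < 0.05, `"b"`: p < 0.01, `"c"`: p < 0.001, `"ns"` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "c", ifelse(p < 0.01, "b",
                ifelse(p < 0.05, "a", "ns"))))
}

#' Tidy coefficient table over fits
#'
#' Long-format table across a list of fits — the tabular analogue of the
#' coefficient forest plots, one row per (response, scale, stage, term)
#' with estimate, SE, p and significance tier.
#'
#' @param fits a `"phylo_fit"` or list of them.
#' @return `data.frame` with columns `response`, `scale`, `stage`, `term`,
#'   `estimate`, `se`, `statistic`, `p`, `tier`, `method`, `n`.
#' @export
coefficient_grid <- function(fits) {
  if (inherits(fits, "phylo_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  rows <- lapply(fits, function(f) {
    cbind(data.frame(response = f$response, scale = f$scale, stage = f$stage,
                     stringsAsFactors = FALSE),
          f$coefficients,
          data.frame(tier = significance_tier(f$coefficients$p),
                     method = f$method, n = f$n, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
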