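#' Fit an ordinary least-squares regression with standardized coefficients
#'
#' Thin wrapper around [stats::lm()] that also reports standardized
#' coefficients (beta = B * sd(x) / sd(y)) and uses listwise deletion for
#' missing data. Two-level character or factor predictors are converted to a
#' 0/1 indicator of the second sorted level (so `gender` with levels
#' female/male becomes male = 1).
#'
#' @param data A data frame.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `ols_fit` with elements `model` (the lm fit),
#'   `coefficients` (tibble: term, B, se_B, beta, t, p), `n`, `r2`,
#'   `outcome`, `predictors`. `tidy()` and `glance()` methods apply.
#' @export
fit_ols <- function(data, outcome, predictors) {
  df <- encode_binary(as_tibble(data)[c(outcome, predictors)])
  df <- df[complete.cases(df), ]
  n <- nrow(df)
  k <- length(predictors)
  if (n <= k + 1) {
    abort(paste0("too few complete observations (n=", n, ") for ", k, " predictors"))
  }
  x <- as.matrix(df[predictors])
  if (qr(cbind(1, x))$rank < k + 1) abort("rank-deficient design matrix")

  fml <- reformulate(sprintf("`%s`", predictors), response = sprintf("`%s`", outcome))
  model <- lm(fml, data = df)
  sm <- summary(model)$coefficients
  term <- rownames(sm)
  term <- gsub("`", "", term)
  sd_y <- sd(df[[outcome]])
  beta <- c(NA_real_, coef(model)[-1] * apply(x, 2, sd) / sd_y)
  coefficients <- tibble(
    term = term, B = unname(sm[, 1]), se_B = unname(sm[, 2]),
    beta = unname(beta), t = unname(sm[, 3]), p = unname(sm[, 4])
  )
  structure(
    list(
      model = model, coefficients = coefficients, n = n,
      r2 = summary(model)$r.squared, outcome = outcome, predictors = predictors,
      data = df
    ),
    class = "ols_fit"
  )
}

encode_binary <- function(df) {
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.character(col) || is.factor(col)) {
      lev <- sort(unique(as.character(col)))
      if (length(lev) != 2) {
        abort(paste0("non-numeric predictor '", nm, "' must have exactly 2 levels"))
      }
      df[[nm]] <- as.numeric(as.character(col) == lev[2])
    }
  }
  df
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "<ols_fit> %s ~ %s  (n = %d, R2 = %.3f)\n",
    x$outcome, paste(x$predictors, collapse = " + "), x$n, x$r2
  ))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.ols_fit <- function(x, ...) x$coefficients

#' @export
glance.ols_fit <- function(x, ...) {
  k <- length(x$predictors)
  f <- model_f_from_r2(x$r2, k, x$n)
  tibble(
    r2 = x$r2, f = f, p_model = pf(f, k, x$n - k - 1, lower.tail = FALSE),
    n = x$n, df = x$n - k - 1
  )
}

#' Hierarchical (blockwise) regression
#'
#' Fits nested OLS models, entering predictor blocks cumulatively -- in the
#' assessment pipeline, block 1 holds the demographic controls (age, gender)
#' and block 2 the behavioral measures. Each block is summarized by its
#' R-squared, model F against the intercept-only model, R-squared change
#' over the previous block, and the F-change test
#' `dF = (dR2 / m) / ((1 - R2_full) / (n - k_full - 1))`
#' with m the number of added predictors.
#'
#' @param data A data frame.
#' @param outcome Name of the outcome column.
#' @param blocks A list of character vectors; block b is fit with all
#'   predictors of blocks 1..b. No predictor may repeat.
#' @return An object of class `hier_fit` with `fits` (list of [fit_ols()]
#'   results), `blocks`, `n`, `outcome`. `tidy()` returns the
#'   per-block coefficient table (columns model, term, B, se_B, beta, t, p)
#'   and `glance()` the block-level fit statistics (r2, f, p_model,
#'   delta_r2, delta_f, p_change).
#' @export
#' @examples
#' d <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
#' fit <- hierarchical_fit(d, "y", list("a", "b"))
#' glance(fit)
hierarchical_fit <- function(data, outcome, blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  all_pred <- unlist(blocks)
  if (anyDuplicated(all_pred)) abort("a predictor appears in more than one block")
  fits <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    fits[[b]] <- fit_ols(data, outcome, unlist(blocks[seq_len(b)]))
  }
  structure(
    list(
      fits = fits, blocks = blocks, outcome = outcome, n = fits[[1]]$n
    ),
    class = "hier_fit"
  )
}

#' @export
tidy.hier_fit <- function(x, ...) {
  bind_rows(lapply(seq_along(x$fits), function(b) {
    x$fits[[b]]$coefficients %>% mutate(model = paste0("H", b - 1), .before = 1)
  }))
}

#' @export
glance.hier_fit <- function(x, ...) {
  out <- bind_rows(lapply(x$fits, glance))
  out$block <- paste0("H", seq_along(x$fits) - 1)
  out$delta_r2 <- c(out$r2[1], diff(out$r2))
  m <- map_int(x$blocks, length)
  k_full <- cumsum(m)
  out$delta_f <- vapply(seq_along(x$fits), function(b) {
    fchange_from_r2(out$r2[b], out$delta_r2[b], x$n, m[b], k_full[b])
  }, numeric(1))
  out$p_change <- pf(out$delta_f, m, x$n - k_full - 1, lower.tail = FALSE)
  out[, c("block", "r2", "f", "p_model", "delta_r2", "delta_f", "p_change", "n", "df")]
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(format_regression_report(x), sep = "\n")
  invisible(x)
}

#' Format a hierarchical regression report as aligned text
#'
#' Renders the per-coefficient table (B, se B, beta, t, p) and the block fit
#' statistics (R2, F, p model, dR2, dF) in the layout used for published
#' regression tables.
#'
#' @param x A `hier_fit` object.
#' @return A character vector of report lines.
#' @export
format_regression_report <- function(x) {
  stopifnot(inherits(x, "hier_fit"))
  co <- tidy(x)
  gl <- glance(x)
  fmt <- function(v, d = 3) ifelse(is.na(v), "", formatC(v, format = "f", digits = d))
  fmtp <- function(p) ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", formatC(p, format = "f", digits = 3)))
  lines <- sprintf(
    "%-4s %-32s %10s %8s %8s %8s %8s",
    "", "", "B", "se B", "beta", "t", "p"
  )
  for (b in seq_along(x$fits)) {
    cf <- co[co$model == paste0("H", b - 1), ]
    for (i in seq_len(nrow(cf))) {
      lines <- c(lines, sprintf(
        "%-4s %-32s %10s %8s %8s %8s %8s",
        if (i == 1) paste0("H", b - 1) else "",
        cf$term[i], fmt(cf$B[i]), fmt(cf$se_B[i]), fmt(cf$beta[i]),
        fmt(cf$t[i]), fmtp(cf$p[i])
      ))
    }
    g <- gl[b, ]
    lines <- c(lines, sprintf(
      "     %-32s R2=%s F=%s p=%s dR2=%s dF=%s",
      "(model fit)", fmt(g$r2), fmt(g$f), fmtp(g$p_model),
      fmt(g$delta_r2), fmt(g$delta_f)
    ))
  }
  lines
}

#' Recompute an F-change statistic from R-squared values
#'
#' `(delta_r2 / m) / ((1 - r2_full) / (n - k_full - 1))`: the nested-model F
#' test expressed through the full model's R-squared, usable directly on
#' published values.
#'
#' @param r2_full R-squared of the full model.
#' @param delta_r2 R-squared change contributed by the added block.
#' @param n Sample size.
#' @param m Number of predictors added in the block.
#' @param k_full Total predictors in the full model.
#' @return The F-change statistic.
#' @export
#' @examples
#' fchange_from_r2(0.344, 0.261, n = 90, m = 3, k_full = 5)
fchange_from_r2 <- function(r2_full, delta_r2, n, m, k_full) {
  stopifnot(r2_full < 1, delta_r2 >= 0, n > k_full + 1)
  (delta_r2 / m) / ((1 - r2_full) / (n - k_full - 1))
}

#' Recompute a model F statistic from its R-squared
#'
#' @param r2 Model R-squared.
#' @param k Number of predictors.
#' @param n Sample size.
#' @return The model F statistic `(r2 / k) / ((1 - r2) / (n - k - 1))`.
#' @export
model_f_from_r2 <- function(r2, k, n) {
  stopifnot(r2 < 1, r2 >= 0, n > k + 1)
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j
#' on the remaining predictors.
#'
#' @param data A data frame, or an `ols_fit`.
#' @param predictors Character vector of at least two predictor columns
#'   (ignored when `data` is an `ols_fit`).
#' @return A named numeric vector of VIFs.
#' @export
vif <- function(data, predictors = NULL) {
  if (inherits(data, "ols_fit")) {
    predictors <- data$predictors
    data <- data$data
  }
  stopifnot(length(predictors) >= 2)
  df <- encode_binary(as_tibble(data)[predictors])
  df <- df[complete.cases(df), ]
  x <- as.matrix(df)
  if (qr(cbind(1, x))$rank < ncol(x) + 1) abort("rank-deficient design matrix")
  out <- vapply(predictors, function(p) {
    r2j <- summary(lm(
      reformulate(sprintf("`%s`", setdiff(predictors, p)), sprintf("`%s`", p)),
      data = df
    ))$r.squared
    1 / (1 - r2j)
  }, numeric(1))
  setNames(out, predictors)
}

#' Cohen's f-squared for a hierarchical block
#'
#' Local effect size of an added block. Two conventions are reported: the
#' standard `dR2 / (1 - R2_full)` and the variant `dR2 / (1 - dR2)`.
#'
#' @param delta_r2 R-squared change of the block.
#' @param r2_full R-squared of the full model.
#' @return A one-row tibble with `f2_cohen` and `f2_variant`.
#' @export
#' @examples
#' effect_size_f2(0.261, 0.344)
effect_size_f2 <- function(delta_r2, r2_full) {
  if (delta_r2 < 0 || delta_r2 > r2_full || r2_full >= 1) {
    abort("need 0 <= delta_r2 <= r2_full < 1")
  }
  tibble(
    f2_cohen = delta_r2 / (1 - r2_full),
    f2_variant = delta_r2 / (1 - delta_r2)
  )
}
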