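#' Linear polynomial-contrast coefficients for unequally spaced levels
#'
#' For ordered factor levels with unequal numeric spacing, the linear
#' contrast coefficients are the level values centred at their mean and
#' scaled to the smallest integer vector (so they sum to zero by
#' construction). The sign follows the centred levels themselves, so levels
#' given on the inoculum-volume scale (4, 2, 1 mL for low, mid, high
#' dilution rate) yield (5, -1, -4) — the coefficients used in the study —
#' while the same three treatments expressed as dilution rates in h^-1
#' yield (-4, -1, 5). Coefficients are invariant to affine transformations
#' of the levels up to overall sign.
#'
#' @param levels Ordered numeric level values (at least 2, not all equal).
#' @param max_denominator Largest multiplier searched when clearing
#'   denominators of the centred levels (default 1e5).
#' @return Integer vector of contrast coefficients summing to zero.
#' @examples
#' linear_contrast_coefficients(c(4, 2, 1))   # 5 -1 -4
#' linear_contrast_coefficients(c(1, 2, 3))   # -1 0 1
#' @export
linear_contrast_coefficients <- function(levels, max_denominator = 1e5) {
  if (length(levels) < 2L || !is.numeric(levels) || anyNA(levels))
    sr_stop("linear_contrast_coefficients: need >= 2 finite numeric levels")
  centred <- levels - mean(levels)
  if (all(abs(centred) < 1e-12 * max(1, abs(levels))))
    sr_stop("linear_contrast_coefficients: all levels equal, contrast degenerate",
            class = "sr_degenerate_contrast")
  # normalise scale, then find the smallest multiplier making all entries integer
  centred <- centred / min(abs(centred[abs(centred) > 1e-12 * max(abs(centred))]))
  mult <- NA_integer_
  for (m in seq_len(max_denominator)) {
    if (all(abs(centred * m - round(centred * m)) < 1e-8 * m)) {
      mult <- m
      break
    }
  }
  if (is.na(mult))
    sr_stop("linear_contrast_coefficients: could not rationalise levels; are they exact?")
  v <- as.integer(round(centred * mult))
  g <- Reduce(function(a, b) {
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    a
  }, abs(v[v != 0]))
  as.integer(v / g)
}

#' Fit the study's factorial mixed model
#'
#' Fits, by restricted maximum likelihood, the linear mixed model of the
#' serial-culture experiment: fixed effects of substrate (S), dilution rate
#' (D), transfer number (T), their three two-way interactions and the
#' three-way interaction; random effects of incubation (I), sequence nested
#' in incubation, and the random three-way interactions I x S x T and
#' I x D x T. The REML fit is delegated to [lmerTest::lmer()]; per-term
#' F-tests use Satterthwaite denominator degrees of freedom. Terms are
#' flagged significant at p < 0.05 and as tendencies at 0.05 <= p < 0.10.
#' With a single incubation the incubation-involving random terms are
#' inestimable and dropped with a warning, leaving `(1 | sequence)`.
#'
#' @param data Data frame with columns `substrate`, `dilution_level`,
#'   `transfer`, `incubation`, `sequence` and the response; factors are
#'   coerced (transfer is treated as a categorical fixed effect).
#' @param response Name of the response column.
#' @return An object of class `factorial_fit`: list with the `lmerTest`
#'   `model`, a `terms` data frame (`term`, `F`, `df1`, `df2`, `p`,
#'   `significant`, `tendency`) and the `response` name.
#' @export
fit_factorial_mixed_model <- function(data, response) {
  need <- c("substrate", "dilution_level", "transfer", "incubation",
            "sequence", response)
  miss <- setdiff(need, names(data))
  if (length(miss))
    sr_stop(paste("fit_factorial_mixed_model: missing columns:",
                  paste(miss, collapse = ", ")))
  d <- data
  d$S <- factor(d$substrate)
  d$D <- factor(d$dilution_level)
  d$T <- factor(d$transfer)
  d$incubation <- factor(d$incubation)
  d$sequence <- factor(d$sequence)
  d$.y <- d[[response]]
  if (anyNA(d$.y)) d <- d[!is.na(d$.y), ]
  if (stats::var(d$.y) == 0)
    warning("fit_factorial_mixed_model: response is constant; no term can be significant")
  one_incubation <- nlevels(droplevels(d$incubation)) < 2L
  if (one_incubation) {
    warning("fit_factorial_mixed_model: single incubation; dropping random terms involving incubation")
    form <- .y ~ S * D * T + (1 | sequence)
  } else {
    form <- .y ~ S * D * T + (1 | incubation) + (1 | incubation:sequence) +
      (1 | incubation:S:T) + (1 | incubation:D:T)
  }
  fit <- lmerTest::lmer(form, data = d,
                        control = lme4::lmerControl(check.conv.singular = "ignore",
                                                    calc.derivs = FALSE))
  # aliased fixed effects signal a rank-deficient design
  dropped <- attr(lme4::getME(fit, "X"), "col.dropped")
  if (!is.null(dropped) && length(dropped))
    sr_stop(paste("fit_factorial_mixed_model: rank-deficient design, aliased terms:",
                  paste(names(dropped), collapse = ", ")),
            class = "sr_rank_deficient")
  an <- suppressMessages(stats::anova(fit, type = 3))
  terms_tab <- data.frame(
    term = rownames(an),
    F = an[["F value"]],
    df1 = an[["NumDF"]],
    df2 = an[["DenDF"]],
    p = an[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  terms_tab$significant <- !is.na(terms_tab$p) & terms_tab$p < 0.05
  terms_tab$tendency <- !is.na(terms_tab$p) &
    terms_tab$p >= 0.05 & terms_tab$p < 0.10
  out <- list(model = fit, terms = terms_tab, response = response)
  class(out) <- "factorial_fit"
  out
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("Factorial mixed model for '%s' (REML, Satterthwaite df)\n",
              x$response))
  tab <- x$terms
  tab$flag <- ifelse(tab$significant, "*", ifelse(tab$tendency, ".", ""))
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "F", "df1", "df2", "p", "flag")], row.names = FALSE)
  cat("* p < 0.05, . tendency 0.05 <= p < 0.10\n")
  invisible(x)
}

#' Flag outliers by studentized residual
#'
#' Flags observations falling outside the central `1 - alpha` region of the
#' studentized-residual reference distribution: `|r| > q(1 - alpha/2)`, with
#' the standard normal as the default reference (for `alpha = 0.001` the
#' threshold is 3.2905) or, optionally, a t distribution with the residual
#' degrees of freedom. Flagged observations that cluster with other flagged
#' observations of the same treatment group are annotated as biological
#' results to be retained rather than removed, mirroring the study's
#' retention rule; the report is metadata, removal is left to the analyst
#' (see [outlier_influence()]).
#'
#' @param residuals Studentized residuals (finite).
#' @param alpha Two-sided flagging level, default 0.001.
#' @param distribution `"normal"` (default) or `"t"`.
#' @param df Degrees of freedom when `distribution = "t"`.
#' @param groups Optional treatment labels, same length as `residuals`;
#'   used for the clustered-outlier retention annotation.
#' @return An object of class `outlier_report`: list with `threshold` and a
#'   data frame `report` (`index`, `residual`, `flagged`, `retain_reason`).
#' @examples
#' flag_outliers(c(0.2, -3.5, 1.1))
#' @export
flag_outliers <- function(residuals, alpha = 0.001,
                          distribution = c("normal", "t"), df = NULL,
                          groups = NULL) {
  distribution <- match.arg(distribution)
  if (any(!is.finite(residuals)))
    sr_stop("flag_outliers: residuals must be finite")
  thr <- if (distribution == "normal") {
    stats::qnorm(1 - alpha / 2)
  } else {
    if (is.null(df)) sr_stop("flag_outliers: df required for the t reference")
    stats::qt(1 - alpha / 2, df)
  }
  flagged <- abs(residuals) > thr
  reason <- rep(NA_character_, length(residuals))
  if (!is.null(groups) && any(flagged)) {
    for (g in unique(groups[flagged])) {
      idx <- which(flagged & groups == g)
      reason[idx] <- if (length(idx) > 1L)
        "clustered in treatment: biological, retained" else "isolated: re-examine"
    }
  } else if (any(flagged)) {
    reason[flagged] <- "isolated: re-examine"
  }
  out <- list(threshold = thr,
              alpha = alpha,
              report = data.frame(index = seq_along(residuals),
                                  residual = residuals,
                                  flagged = flagged,
                                  retain_reason = reason,
                                  stringsAsFactors = FALSE))
  class(out) <- "outlier_report"
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  n <- sum(x$report$flagged)
  cat(sprintf("Outlier report: %d of %d flagged (|r| > %.4f, alpha = %g)\n",
              n, nrow(x$report), x$threshold, x$alpha))
  if (n) print(x$report[x$report$flagged, ], row.names = FALSE)
  invisible(x)
}

#' Leave-one-out influence of flagged outliers
#'
#' Refits the factorial mixed model with each flagged observation removed,
#' one at a time, and reports whether the pattern of term significance
#' (p < 0.05) changes relative to the full-data fit. An outlier is
#' influential if any term crosses the 0.05 boundary when it is removed;
#' only influential outliers would justify exclusion.
#'
#' @param data,response As in [fit_factorial_mixed_model()].
#' @param rows Row indices of the observations to test.
#' @return Data frame with `row`, `influential`, and `changed_terms`
#'   (comma-separated terms whose significance flipped; empty if none).
#' @export
outlier_influence <- function(data, response, rows) {
  base_fit <- fit_factorial_mixed_model(data, response)
  base_sig <- base_fit$terms$significant
  names(base_sig) <- base_fit$terms$term
  res <- lapply(rows, function(i) {
    fit_i <- fit_factorial_mixed_model(data[-i, , drop = FALSE], response)
    sig_i <- fit_i$terms$significant[match(names(base_sig), fit_i$terms$term)]
    changed <- names(base_sig)[!is.na(sig_i) & sig_i != base_sig]
    data.frame(row = i,
               influential = length(changed) > 0L,
               changed_terms = paste(changed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pearson correlations between response pairs
#'
#' Standard Pearson correlation with a two-sided test for each requested
#' pair of columns, as used to relate CH4, acetate, propionate and butyrate
#' production and lactate concentration to H2 partial pressure. Pairs with
#' zero variance are reported as missing with a warning.
#'
#' @param data Data frame holding the columns.
#' @param pairs Two-column character matrix (or list of length-2 character
#'   vectors) naming the x and y column of each pair.
#' @return Data frame with `x`, `y`, `n`, `r`, `p`.
#' @examples
#' pearson_correlations(data.frame(a = 1:10, b = (1:10)^2),
#'                      list(c("a", "b")))
#' @export
pearson_correlations <- function(data, pairs) {
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs)[, 1])
  res <- lapply(pairs, function(pr) {
    x <- data[[pr[1]]]
    y <- data[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      sr_stop("pearson_correlations: need >= 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("pearson_correlations: zero variance in pair (%s, %s), reported missing",
                      pr[1], pr[2]))
      return(data.frame(x = pr[1], y = pr[2], n = length(x),
                        r = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(x = pr[1], y = pr[2], n = length(x),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
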