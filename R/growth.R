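#' Baseline-normalize GFP competition time courses
#'
#' Within each (construct, replicate) series the GFP+ percentage at the
#' first measured day is set to 1 (`relative_value = gfp_pct / baseline`)
#' and the analysis response is `relative_value - 1`, which is 0 at baseline
#' by construction.
#'
#' @param raw data.frame with columns `construct`, `replicate`, `day`,
#'   `gfp_pct` (percentages in (0, 100]).
#' @return The data.frame with `relative_value` and `response` added, class
#'   `competition_series`.
#' @export
normalize_series <- function(raw) {
  stopifnot(is.data.frame(raw),
            all(c("construct", "replicate", "day", "gfp_pct") %in% names(raw)))
  if (any(raw$gfp_pct <= 0 | raw$gfp_pct > 100)) {
    stop("gfp_pct must lie in (0, 100]", call. = FALSE)
  }
  key <- interaction(raw$construct, raw$replicate, drop = TRUE)
  out <- raw
  out$relative_value <- NA_real_
  for (k in levels(key)) {
    idx <- which(key == k)
    days <- raw$day[idx]
    if (length(idx) < 2) stop("each replicate needs >= 2 time points", call. = FALSE)
    if (any(diff(days) <= 0)) {
      stop("days must be strictly increasing within each replicate series",
           call. = FALSE)
    }
    base <- raw$gfp_pct[idx[1]]
    if (base <= 0) stop("zero baseline GFP percentage", call. = FALSE)
    out$relative_value[idx] <- raw$gfp_pct[idx] / base
  }
  out$response <- out$relative_value - 1
  class(out) <- c("competition_series", "data.frame")
  out
}

#' Build the intercept-free interaction design for the growth model
#'
#' The fixed-effect design contains only construct-by-day interaction terms
#' (no intercept, no main effects): with categorical day coding, one column
#' per construct per post-baseline day; with linear coding, one
#' construct-specific slope column in `day - baseline day`. Baseline-day
#' rows carry all-zero fixed rows (their response is identically 0 by
#' construction).
#'
#' @param series A [normalize_series()] data.frame.
#' @param day_coding `"categorical"` or `"linear"`.
#' @return A list with `X` (fixed-effect matrix), `response`, `replicate_id`
#'   (grouping factor for random intercepts), `is_baseline` (logical row
#'   mask), `constructs`, `days`.
#' @export
growth_design_matrix <- function(series, day_coding = c("categorical", "linear")) {
  stopifnot(inherits(series, "competition_series"))
  day_coding <- match.arg(day_coding)
  constructs <- sort(unique(series$construct))
  if (length(constructs) < 2) {
    stop("need at least two constructs to form a contrast", call. = FALSE)
  }
  base_day <- min(series$day)
  days <- sort(unique(series$day))
  post_days <- setdiff(days, base_day)
  if (day_coding == "categorical") {
    X <- matrix(0, nrow(series), length(constructs) * length(post_days))
    colnames(X) <- as.vector(outer(constructs, post_days,
                                   function(c, d) sprintf("%s.d%d", c, d)))
    for (con in constructs) {
      for (d in post_days) {
        X[series$construct == con & series$day == d,
          sprintf("%s.d%d", con, d)] <- 1
      }
    }
  } else {
    X <- matrix(0, nrow(series), length(constructs))
    colnames(X) <- paste0(constructs, ".slope")
    for (con in constructs) {
      rows <- series$construct == con
      X[rows, paste0(con, ".slope")] <- series$day[rows] - base_day
    }
  }
  list(X = X, response = series$response,
       replicate_id = factor(paste(series$construct, series$replicate, sep = ":")),
       is_baseline = series$day == base_day,
       constructs = constructs, days = days)
}

#' Fit the baseline-normalized growth mixed model
#'
#' Fits, by REML, a random-intercept-per-replicate model to the
#' baseline-normalized response (`relative value - 1`) with the
#' intercept-free construct-by-day fixed-effect design of
#' [growth_design_matrix()], and tests the construct contrast
#' (test minus control trend) with a Satterthwaite F test: jointly across
#' post-baseline days for categorical coding, a 1-df slope difference for
#' linear coding. Baseline-day rows are deterministic zeros and are excluded
#' from the likelihood by default. If the random-intercept variance estimate
#' hits zero (singular fit) the model falls back to ordinary least squares
#' with a warning.
#'
#' @param series A [normalize_series()] data.frame with exactly two
#'   constructs.
#' @param day_coding `"categorical"` (default) or `"linear"`.
#' @param test_construct Construct treated as "test"; defaults to the
#'   lexicographically later construct (so "test" vs "control" works
#'   unconfigured).
#' @param include_baseline Include the all-zero baseline rows in the fit.
#' @return A list of class `growth_fit`: `coefficients` (estimate, se),
#'   `contrast_estimate` (mean test-minus-control effect; for linear coding
#'   the slope difference per day), `statistic` (F), `df`, `p_value`,
#'   `converged`, `singular_fallback`, `method`.
#' @export
fit_growth_model <- function(series, day_coding = c("categorical", "linear"),
                             test_construct = NULL, include_baseline = FALSE) {
  day_coding <- match.arg(day_coding)
  des <- growth_design_matrix(series, day_coding)
  if (length(des$constructs) != 2) {
    stop("growth contrast needs exactly two constructs", call. = FALSE)
  }
  if (is.null(test_construct)) test_construct <- des$constructs[2]
  ref_construct <- setdiff(des$constructs, test_construct)
  keep <- if (include_baseline) rep(TRUE, length(des$response)) else !des$is_baseline
  X <- des$X[keep, , drop = FALSE]
  dat <- data.frame(y = des$response[keep], grp = des$replicate_id[keep])
  dat$X <- X

  # contrast rows: test minus reference, per day (categorical) or slope (linear)
  if (day_coding == "categorical") {
    post <- sum(grepl(paste0("^", test_construct, "\\.d"), colnames(X)))
    L <- matrix(0, post, ncol(X), dimnames = list(NULL, colnames(X)))
    dd <- sub(paste0("^", test_construct, "\\."), "",
              grep(paste0("^", test_construct, "\\.d"), colnames(X), value = TRUE))
    for (i in seq_along(dd)) {
      L[i, sprintf("%s.%s", test_construct, dd[i])] <- 1
      L[i, sprintf("%s.%s", ref_construct, dd[i])] <- -1
    }
  } else {
    L <- matrix(0, 1, ncol(X), dimnames = list(NULL, colnames(X)))
    L[1, paste0(test_construct, ".slope")] <- 1
    L[1, paste0(ref_construct, ".slope")] <- -1
  }

  conv_warning <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(lmerTest::lmer(y ~ 0 + X + (1 | grp), data = dat,
                                      REML = TRUE)),
      warning = function(w) {
        conv_warning <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  converged <- !is.null(fit) && !conv_warning
  if (!singular) {
    beta <- lme4::fixef(fit)
    names(beta) <- sub("^X", "", names(beta))
    ct <- lmerTest::contest(fit, L, joint = TRUE)
    stat <- ct[["F value"]]
    df <- c(ct[["NumDF"]], ct[["DenDF"]])
    p <- ct[["Pr(>F)"]]
    se <- sqrt(diag(as.matrix(vcov(fit))))
    method <- "lmm_reml_satterthwaite"
  } else {
    if (converged) {
      warning("random-intercept variance estimated at zero; falling back to OLS",
              call. = FALSE)
    }
    ols <- lm(y ~ 0 + X, data = dat)
    beta <- coef(ols)
    names(beta) <- sub("^X", "", names(beta))
    V <- vcov(ols)
    lb <- drop(L %*% beta)
    M <- L %*% V %*% t(L)
    stat <- drop(crossprod(lb, solve(M, lb))) / nrow(L)
    df <- c(nrow(L), df.residual(ols))
    p <- pf(stat, df[1], df[2], lower.tail = FALSE)
    se <- sqrt(diag(V))
    method <- "ols_fallback"
    converged <- TRUE
  }
  structure(list(
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = unname(se), stringsAsFactors = FALSE),
    contrast_estimate = mean(drop(L %*% beta)),
    statistic = stat, df = df, p_value = p,
    converged = converged, singular_fallback = singular, method = method,
    day_coding = day_coding, test_construct = test_construct),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth mixed model (%s, %s): contrast %.4g, F(%g, %.1f) = %.3g, p = %.3g\n",
              x$day_coding, x$method, x$contrast_estimate, x$df[1], x$df[2],
              x$statistic, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups: exact enumeration p-value when
#' `n_a + n_b <= 16` and the data are tie-free, otherwise the normal
#' approximation with tie and continuity corrections
#' (via [stats::wilcox.test()]). `alternative = "greater"` tests whether
#' group a is stochastically greater than group b. When every value in both
#' groups is identical the test is degenerate and returns
#' `U = n_a * n_b / 2`, `p = 1`.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return A list with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0, length(b) > 0, is.numeric(a), is.numeric(b))
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  vals <- c(a, b)
  if (length(unique(vals)) == 1L) {
    return(list(U = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate (all values identical)"))
  }
  exact <- (length(a) + length(b) <= 16) && !anyDuplicated(vals)
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alt, exact = exact,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact enumeration" else "normal approximation")
}
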