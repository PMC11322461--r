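#' Factorial ANOVA (Type-III sums of squares)
#'
#' Full-factorial 2- or 3-way ANOVA of a per-animal response on
#' between-subject factors (genotype, sex, feeding time, time bin),
#' using Type-III sums of squares with sum-to-zero effects coding so
#' that unbalanced cells (the usual N = 3--8 per group) are handled
#' sensibly. F = MS_effect / MS_residual; p from the F distribution.
#'
#' @param data data.frame containing the response and factor columns.
#' @param response name of the numeric response column.
#' @param factors character vector of 2 or 3 factor column names.
#' @return data.frame with `term`, `df`, `sum_sq`, `F`, `p` (residual
#'   row included). A zero residual mean square yields infinite F,
#'   flagged via the `"flag"` attribute.
#' @export
factorial_anova <- function(data, response, factors) {
  stopifnot(response %in% names(data), all(factors %in% names(data)),
            length(factors) >= 1, length(factors) <= 3)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) stop("factor ", f, " has < 2 levels")
  }
  cells <- table(data[factors])
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, , drop = TRUE]
    nm <- mapply(function(f, i) dimnames(cells)[[f]][i],
                 seq_along(factors), idx)
    stop("empty design cell: ", paste(factors, nm, sep = "=",
                                      collapse = ", "))
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = "*")))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = data, contrasts = contr)
  a <- tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
  if (!is.null(a)) {
    out <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                      F = a$`F value`, p = a$`Pr(>F)`)
    out <- out[out$term != "(Intercept)", ]
  } else {
    # car refuses a (near-)perfect fit; compute the same Type-III SS
    # directly as the RSS increase from dropping each term's columns
    X <- stats::model.matrix(fit)
    asg <- attr(X, "assign")
    y <- stats::model.response(stats::model.frame(fit))
    rss_full <- sum(stats::residuals(fit)^2)
    labs <- attr(stats::terms(fit), "term.labels")
    rows <- lapply(seq_along(labs), function(k) {
      sub <- stats::lm.fit(X[, asg != k, drop = FALSE], y)
      data.frame(term = labs[k], df = sum(asg == k),
                 sum_sq = sum(sub$residuals^2) - rss_full)
    })
    df_res <- nrow(X) - ncol(X)
    out <- do.call(rbind, rows)
    ms_res <- rss_full / max(df_res, 1)
    out$F <- (out$sum_sq / out$df) / ms_res
    out$p <- stats::pf(out$F, out$df, df_res, lower.tail = FALSE)
    out <- rbind(out, data.frame(term = "Residuals", df = df_res,
                                 sum_sq = rss_full, F = NA, p = NA))
  }
  rownames(out) <- NULL
  res_ss <- out$sum_sq[out$term == "Residuals"]
  tot_ss <- sum(abs(out$sum_sq))
  if (res_ss <= 1e-10 * max(tot_ss, 1e-300)) {
    # residual variance zero to rounding: report infinite F for terms
    # with real SS rather than an astronomically large finite value
    eff <- out$term != "Residuals"
    out$F[eff] <- ifelse(out$sum_sq[eff] > 1e-10 * max(tot_ss, 1e-300),
                         Inf, 0)
    out$p[eff] <- ifelse(is.infinite(out$F[eff]), 0, 1)
    attr(out, "flag") <- "zero_residual_variance"
  }
  out
}

#' Two-sample Student's t-test (pooled variance, two-tailed)
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return data.frame with `t`, `df`, `p`, `mean_a`, `mean_b`.
#'   Degenerate zero pooled variance: equal means give `t = 0, p = 1`
#'   (flagged); unequal means give infinite t, `p = 0` (flagged).
#' @export
pairwise_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  dfree <- n1 + n2 - 2
  if (sp2 == 0) {
    eq <- mean(a) == mean(b)
    out <- data.frame(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                      df = dfree, p = if (eq) 1 else 0,
                      mean_a = mean(a), mean_b = mean(b))
    attr(out, "flag") <- "zero_pooled_variance"
    return(out)
  }
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  data.frame(t = tval, df = dfree, p = 2 * stats::pt(-abs(tval), dfree),
             mean_a = mean(a), mean_b = mean(b))
}

#' Sleep-by-cognition Pearson correlation matrix with Bonferroni
#' correction
#'
#' Pearson r for every (sleep metric, cognitive metric) column pair on
#' animal-matched rows; the Bonferroni-adjusted p is `min(1, m * p)`
#' where m is the number of pairs tested. Zero-variance columns are
#' skipped and flagged.
#'
#' @param sleep,cognitive data.frames of per-animal metrics (numeric
#'   columns; rows aligned to the same animals).
#' @return data.frame with `sleep_metric`, `cognitive_metric`, `n`, `r`,
#'   `p_raw`, `p_adj`; attribute `"skipped"` lists zero-variance pairs.
#' @export
correlation_matrix <- function(sleep, cognitive) {
  stopifnot(nrow(sleep) == nrow(cognitive), nrow(sleep) >= 3)
  out <- list(); skipped <- character(0)
  for (s in names(sleep)) for (c in names(cognitive)) {
    x <- sleep[[s]]; y <- cognitive[[c]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) { skipped <- c(skipped, paste(s, c, sep = "~")); next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      skipped <- c(skipped, paste(s, c, sep = "~")); next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    out[[length(out) + 1]] <- data.frame(
      sleep_metric = s, cognitive_metric = c, n = sum(ok),
      r = unname(ct$estimate), p_raw = ct$p.value)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable pairs")
  m <- nrow(res)
  res$p_adj <- pmin(1, m * res$p_raw)
  rownames(res) <- NULL
  if (length(skipped)) attr(res, "skipped") <- skipped
  res
}
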