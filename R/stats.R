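#' Kruskal-Wallis rank test
#'
#' Nonparametric comparison of two or more groups, implemented from the
#' rank formulas so it is directly checkable against hand computation:
#' mid-ranks over the pooled data, the statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_g R_g^2 / n_g - 3(N+1)}
#' divided by the tie correction \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)}, and
#' a p-value from the upper tail of the chi-square distribution with
#' `k - 1` degrees of freedom.  When all pooled values are identical the
#' statistic is 0 and p is 1.
#'
#' @param samples list of numeric vectors, one per group (>= 2 non-empty
#'   groups, total N >= 3).
#' @return List of class `kruskal_wallis_result` with `H`,
#'   `degrees_of_freedom`, `p_value`, `tie_correction_factor`, `n_total`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need a list of at least 2 groups")
  }
  n_g <- lengths(samples)
  if (any(n_g == 0L)) stop("group ", which(n_g == 0L)[1L], " is empty")
  x <- unlist(samples, use.names = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in samples")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations in total")
  k <- length(samples)
  if (length(unique(x)) == 1L) {
    return(structure(list(H = 0, degrees_of_freedom = k - 1L, p_value = 1,
                          tie_correction_factor = NA_real_, n_total = n),
                     class = "kruskal_wallis_result"))
  }
  r <- rank(x)  # mid-ranks
  grp <- rep.int(seq_len(k), n_g)
  rsum <- vapply(split(r, grp), sum, numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / n_g) - 3 * (n + 1)
  ties <- table(x)
  tie_c <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / tie_c
  structure(list(H = h, degrees_of_freedom = k - 1L,
                 p_value = stats::pchisq(h, df = k - 1L, lower.tail = FALSE),
                 tie_correction_factor = tie_c, n_total = n),
            class = "kruskal_wallis_result")
}

#' @export
print.kruskal_wallis_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Exact permutation p-value for the Kruskal-Wallis statistic
#'
#' Enumerates every assignment of the pooled observations to groups of
#' the observed sizes and returns the exact probability of a statistic at
#' least as large as observed.  Feasible for small samples (total N up to
#' about 10); used to quantify the chi-square approximation error on
#' small instances.
#'
#' @param samples list of numeric vectors as in [kruskal_wallis()].
#' @return List with `p_exact`, `p_chisq`, `H`, and `n_permutations`.
#' @export
kruskal_wallis_exact <- function(samples) {
  obs <- kruskal_wallis(samples)
  x <- unlist(samples, use.names = FALSE)
  n_g <- lengths(samples)
  n <- length(x)
  if (n > 10L) stop("exact enumeration limited to N <= 10")
  h_of <- function(assign_idx) {
    kruskal_wallis(split(x, assign_idx))$H
  }
  # enumerate multiset partitions: choose indices for group 1, then group
  # 2 from the remainder, ...
  assignments <- list(integer(0))
  remaining <- list(seq_len(n))
  acc <- list(list(pick = integer(n), left = seq_len(n)))
  for (g in seq_along(n_g)[-length(n_g)]) {
    acc <- do.call(c, lapply(acc, function(st) {
      ch <- utils::combn(st$left, n_g[g], simplify = FALSE)
      lapply(ch, function(sel) {
        pick <- st$pick
        pick[sel] <- g
        list(pick = pick, left = setdiff(st$left, sel))
      })
    }))
  }
  hs <- vapply(acc, function(st) {
    pick <- st$pick
    pick[st$left] <- length(n_g)
    h_of(pick)
  }, numeric(1))
  list(p_exact = mean(hs >= obs$H - 1e-12),
       p_chisq = obs$p_value, H = obs$H, n_permutations = length(hs))
}

#' Ordinary least-squares fit with slope test and confidence band
#'
#' Simple linear regression implemented from the closed-form OLS
#' expressions: slope and intercept, coefficient of determination, a
#' two-sided t-test on the slope (`n - 2` degrees of freedom), and the
#' pointwise 95% confidence band half-width for the mean response,
#' \deqn{t_{0.975, n-2}\, s \sqrt{1/n + (x_0 - \bar x)^2 / S_{xx}},}
#' which is minimized at the mean abscissa.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @param band_at abscissae at which to evaluate the confidence band
#'   half-width (default: the observed `x`).
#' @param conf_level confidence level for the band.
#' @return List of class `linear_fit_result`: `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `se_slope`, `df`, `band_at`,
#'   `band_halfwidth`.
#' @export
linear_fit <- function(x, y, band_at = NULL, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < 3L) stop("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  sxx <- sum((x - mean(x))^2)
  if (sxx < 1e-12 * max(1, mean(x)^2)) stop("x is constant; slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-300) 1 else 1 - ss_res / ss_tot
  df <- n - 2L
  s2 <- ss_res / df
  se_slope <- sqrt(s2 / sxx)
  t_stat <- if (se_slope > 0) slope / se_slope else Inf * sign(slope)
  p_slope <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  if (is.null(band_at)) band_at <- sort(unique(x))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  half <- tcrit * sqrt(s2) * sqrt(1 / n + (band_at - mean(x))^2 / sxx)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_slope = p_slope, se_slope = se_slope, df = df,
                 band_at = band_at, band_halfwidth = half),
            class = "linear_fit_result")
}

#' @export
print.linear_fit_result <- function(x, ...) {
  cat(sprintf("linear fit: y = %.4g + %.4g x, r^2 = %.4f, p(slope) = %.4g\n",
              x$intercept, x$slope, x$r_squared, x$p_slope))
  invisible(x)
}

#' Per-group summary and pairwise rank tests for a cohort metric
#'
#' Summarizes one motion metric across subject groups in the conventional
#' cohort-table layout: per-group mean, sample (n-1) standard deviation
#' and range, the omnibus Kruskal-Wallis p-value, and unadjusted pairwise
#' two-group Kruskal-Wallis p-values (an optional Holm adjustment is
#' available).  Pairs are flagged significant at p < 0.05.
#'
#' @param records data frame with a `group` column and the metric columns
#'   (typically the metrics CSV joined to subject metadata).
#' @param metric_name name of the metric column to summarize.
#' @param groups group labels defining the order (default: order of
#'   appearance).
#' @param adjust `"none"` (default) or `"holm"` for the pairwise p-values.
#' @param alpha significance threshold.
#' @return List of class `group_summary`: `summary` (one row per group:
#'   `group`, `n`, `mean`, `sd`, `min`, `max`), `omnibus_p`, `pairwise`
#'   (rows `group1`, `group2`, `p_value`, `significant`), `metric`.
#' @export
group_summary <- function(records, metric_name, groups = NULL,
                          adjust = c("none", "holm"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  if (!is.data.frame(records) || !"group" %in% names(records)) {
    stop("records must be a data frame with a 'group' column")
  }
  if (!metric_name %in% names(records)) {
    stop("unknown metric '", metric_name, "'; available: ",
         paste(setdiff(names(records), c("id", "group")), collapse = ", "))
  }
  if (is.null(groups)) groups <- unique(as.character(records$group))
  bad <- setdiff(unique(as.character(records$group)), groups)
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  vals <- lapply(groups, function(g) {
    v <- records[[metric_name]][records$group == g]
    v[is.finite(v)]
  })
  names(vals) <- groups
  if (any(lengths(vals) == 0L)) {
    stop("no records for group: ",
         paste(groups[lengths(vals) == 0L], collapse = ", "))
  }
  summ <- data.frame(
    group = groups,
    n = lengths(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1)),
    min = vapply(vals, min, numeric(1)),
    max = vapply(vals, max, numeric(1)),
    row.names = NULL)
  omnibus <- if (length(groups) >= 2L) kruskal_wallis(vals)$p_value else NA_real_
  pairs <- if (length(groups) >= 2L) utils::combn(groups, 2L) else NULL
  pw <- NULL
  if (!is.null(pairs)) {
    p <- apply(pairs, 2L, function(gg)
      kruskal_wallis(vals[gg])$p_value)
    if (adjust == "holm") p <- stats::p.adjust(p, method = "holm")
    pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     p_value = p, significant = p < alpha,
                     row.names = NULL)
  }
  structure(list(summary = summ, omnibus_p = omnibus, pairwise = pw,
                 metric = metric_name, alpha = alpha),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group summary for", x$metric, "\n")
  print(transform(x$summary,
                  `mean_sd` = sprintf("%.3g ± %.3g", mean, sd)), ...)
  cat(sprintf("omnibus Kruskal-Wallis p = %.4g\n", x$omnibus_p))
  if (!is.null(x$pairwise)) print(x$pairwise, ...)
  invisible(x)
}

#' Simulate a synthetic cohort metrics table
#'
#' Draws per-group Gaussian metric values around prescribed group means --
#' a lightweight stand-in for a patient cohort used to exercise the
#' cohort statistics and the command-line `cohort` pipeline.  This does
#' not emulate the correlation structure of real root-motion metrics;
#' it only provides group-labelled numbers with known shifts.
#'
#' @param group_means named list: group label -> mean of the simulated
#'   metric.
#' @param n_per_group subjects per group.
#' @param sd common within-group standard deviation.
#' @param metric_name column name for the simulated metric.
#' @param seed integer seed.
#' @return Data frame with `id`, `group` and the metric column.
#' @export
simulate_metric_groups <- function(group_means, n_per_group = 12L, sd = 1,
                                   metric_name = "total_disp", seed = 1L) {
  set.seed(as.integer(seed))
  rows <- lapply(names(group_means), function(g) {
    v <- stats::rnorm(n_per_group, mean = group_means[[g]], sd = sd)
    data.frame(group = g, value = v)
  })
  df <- do.call(rbind, rows)
  df <- data.frame(id = sprintf("S%03d", seq_len(nrow(df))),
                   group = df$group, value = df$value)
  names(df)[names(df) == "value"] <- metric_name
  df
}
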