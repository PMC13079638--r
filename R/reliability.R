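#' Cronbach's alpha with a Feldt confidence interval
#'
#' `alpha = m/(m-1) * (1 - sum of item variances / variance of item sums)`
#' with sample variances (divisor n - 1). The confidence interval uses
#' Feldt's F-distribution method with df1 = n - 1 and
#' df2 = (n - 1)(m - 1). A zero-variance total yields `NA` with a warning.
#'
#' @param items n x m matrix of item responses (m >= 2, n >= 3).
#' @param conf confidence level.
#' @return list with `alpha`, `ci` (length 2), `n`, `m`.
#' @export
cronbach_alpha <- function(items, conf = 0.95) {
  items <- as.matrix(items)
  n <- nrow(items); m <- ncol(items)
  if (m < 2) stop_ohs("Cronbach's alpha needs at least 2 items")
  if (n < 3) stop_ohs("Cronbach's alpha needs at least 3 respondents")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) {
    warning("total score has zero variance; alpha undefined", call. = FALSE)
    return(list(alpha = NA_real_, ci = c(NA_real_, NA_real_), n = n, m = m))
  }
  alpha <- m / (m - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
  lo_q <- 1 - (1 - conf) / 2
  ci <- 1 - (1 - alpha) * stats::qf(c(lo_q, 1 - lo_q), df1 = n - 1,
                                    df2 = (n - 1) * (m - 1))
  list(alpha = alpha, ci = ci, n = n, m = m)
}

reliability_band <- function(alpha) {
  cut(alpha, breaks = c(-Inf, 0.6, 0.7, 0.8, 1),
      labels = c("Poor", "Adequate", "Acceptable", "Good"), right = FALSE)
}

#' Per-system scale reliability report
#'
#' Cronbach's alpha with 95% Feldt interval for each physiological system's
#' item set, plus a qualitative band (Good >= 0.8, Acceptable >= 0.7,
#' Adequate >= 0.6, else Poor).
#'
#' @param symptoms n x m severity matrix, columns named by item id.
#' @param cb the matching codebook.
#' @return data.frame with `system`, `n_items`, `alpha`, `ci_low`, `ci_high`,
#'   `band`.
#' @export
reliability_report <- function(symptoms, cb) {
  doms <- item_domains(cb, "symptom")
  rows <- lapply(cb$systems, function(s) {
    ids <- intersect(names(doms)[doms == s], colnames(symptoms))
    a <- suppressWarnings(cronbach_alpha(symptoms[, ids, drop = FALSE]))
    data.frame(system = s, n_items = length(ids), alpha = a$alpha,
               ci_low = a$ci[1], ci_high = a$ci[2],
               band = as.character(reliability_band(a$alpha)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Post-hoc power of a two-sample t-test
#'
#' Power to detect a standardized mean difference `d` with realized group
#' sizes, via the noncentral t distribution with noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom.
#' At d = 0 the power equals `alpha` exactly.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d standardized effect size (Cohen's d, >= 0).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return power in (0, 1).
#' @export
posthoc_power <- function(n1, n2, d, alpha = 0.05, tails = 2) {
  if (n1 < 2 || n2 < 2) stop_ohs("group sizes must be at least 2")
  if (d < 0) stop_ohs("effect size d must be nonnegative")
  if (!tails %in% c(1, 2)) stop_ohs("tails must be 1 or 2")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp = ncp)
  }
}

#' Required total sample size for a target power
#'
#' Smallest even total n (1:1 allocation) whose two-sample t-test power at
#' effect size `d` reaches `target_power`.
#'
#' @param target_power desired power in (0, 1).
#' @param d standardized effect size (> 0).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return integer total sample size.
#' @export
required_sample_size <- function(target_power = 0.80, d, alpha = 0.05,
                                 tails = 2) {
  if (d <= 0) stop_ohs("target power is unattainable at d = 0")
  if (target_power <= 0 || target_power >= 1)
    stop_ohs("target_power must lie in (0, 1)")
  n_per <- 2
  while (posthoc_power(n_per, n_per, d, alpha = alpha, tails = tails) <
         target_power) {
    n_per <- n_per + 1
    if (n_per > 1e6) stop_ohs("sample-size search did not converge")
  }
  as.integer(2 * n_per)
}
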