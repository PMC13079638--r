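#' Risk-factor exposure prevalence
#'
#' @param risks n x m binary exposure matrix (0/1), columns named by item.
#' @return data.frame with `item`, `n_exposed`, `ep` (column mean).
#' @export
exposure_prevalence <- function(risks) {
  risks <- as.matrix(risks)
  if (nrow(risks) == 0) stop_ohs("risk matrix has no respondents")
  if (any(is.na(risks)) || !all(risks %in% c(0, 1)))
    stop_ohs("risk matrix must be binary 0/1")
  data.frame(item = colnames(risks), n_exposed = as.integer(colSums(risks)),
             ep = colMeans(risks), row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohen's d for burden by exposure
#'
#' Standardized mean difference of total symptom burden between exposed and
#' unexposed respondents, using the pooled standard deviation with
#' (n1 - 1, n2 - 1) weighting. `NA` with a warning when either group is
#' empty or the pooled SD is zero.
#'
#' @param tsb per-respondent burden vector.
#' @param exposure binary 0/1 vector aligned with `tsb`.
#' @return Cohen's d (exposed minus unexposed), or `NA`.
#' @export
effect_size <- function(tsb, exposure) {
  stopifnot(length(tsb) == length(exposure))
  x <- tsb[exposure == 1]
  y <- tsb[exposure == 0]
  if (length(x) < 2 || length(y) < 2) {
    warning("effect size undefined: a group has fewer than 2 respondents",
            call. = FALSE)
    return(NA_real_)
  }
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    warning("effect size undefined: pooled standard deviation is zero",
            call. = FALSE)
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Two-sided Mann-Whitney U test
#'
#' U counts pairs where an `x` value exceeds a `y` value (ties count 1/2).
#' When both groups have at most `exact_max` observations the two-sided
#' p-value is computed by full enumeration of all group assignments
#' (arrangements with |U - n1 n2 / 2| at least the observed), which is valid
#' under ties. Otherwise a tie-corrected normal approximation (no continuity
#' correction) is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest group size for the enumeration path.
#' @return list with `U`, `p`, and `method` (`"exact"`/`"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_ohs("both groups must be nonempty")
  u_stat <- function(xv, yv) {
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    dev <- abs(U - mu)
    hits <- sum(apply(combos, 2, function(ix) {
      abs(u_stat(pool[ix], pool[-ix]) - mu) >= dev - 1e-9
    }))
    return(list(U = U, p = hits / ncol(combos), method = "exact"))
  }
  r <- rank(c(x, y))
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Breadth of affected physiological systems
#'
#' For each system, compares exposed vs unexposed per-respondent system
#' burden with a two-sided Mann-Whitney U test; BAPS is the count of systems
#' with p below `alpha`. No multiple-testing correction is applied by
#' default (`p_adjust = "none"`); a Holm option is available.
#'
#' @param system_scores n x n_systems burden matrix (see [system_scores()]).
#' @param exposure binary 0/1 vector.
#' @param alpha per-system significance level.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return list with `baps` (integer, or `NA` if a group is empty) and
#'   `p_values` (named per-system vector).
#' @export
baps <- function(system_scores, exposure, alpha = 0.05, p_adjust = "none") {
  system_scores <- as.matrix(system_scores)
  stopifnot(nrow(system_scores) == length(exposure))
  if (!any(exposure == 1) || !any(exposure == 0)) {
    warning("breadth undefined: one exposure group is empty", call. = FALSE)
    return(list(baps = NA_integer_,
                p_values = stats::setNames(rep(NA_real_, ncol(system_scores)),
                                           colnames(system_scores))))
  }
  p <- vapply(seq_len(ncol(system_scores)), function(j) {
    mann_whitney_u(system_scores[exposure == 1, j],
                   system_scores[exposure == 0, j])$p
  }, numeric(1))
  p <- stats::p.adjust(p, method = p_adjust)
  names(p) <- colnames(system_scores)
  list(baps = as.integer(sum(p < alpha)), p_values = p)
}

#' Composite risk-importance score
#'
#' Weighted aggregate `CRS = w_es * |ES|/max|ES| + w_baps * BAPS/n_systems +
#' w_ep * EP` with default weights (0.5, 0.3, 0.2) prioritizing effect size,
#' then breadth, then exposure prevalence. The absolute effect size enters
#' (direction is flagged separately); the normalizer is the cohort maximum
#' |ES| unless supplied.
#'
#' @param ep,es,baps component vectors (one entry per factor).
#' @param weights named weights `c(es=, baps=, ep=)` summing to 1.
#' @param n_systems number of physiological systems (breadth normalizer).
#' @param es_max optional fixed |ES| normalizer; defaults to the maximum
#'   finite |es|.
#' @return numeric CRS vector in \[0, 1\], `NA` where `es` is `NA`.
#' @export
composite_risk_score <- function(ep, es, baps,
                                 weights = c(es = 0.5, baps = 0.3, ep = 0.2),
                                 n_systems = 10, es_max = NULL) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop_ohs("composite weights must sum to 1")
  if (is.null(es_max)) {
    es_max <- suppressWarnings(max(abs(es), na.rm = TRUE))
    if (!is.finite(es_max)) es_max <- 0
  }
  es_norm <- if (es_max > 0) abs(es) / es_max else ifelse(is.na(es), NA, 0)
  unname(weights["es"] * es_norm + weights["baps"] * baps / n_systems +
           weights["ep"] * ep)
}

#' Rank risk factors by composite importance
#'
#' Computes, for every risk item, the exposure prevalence, Cohen's d effect
#' size on total symptom burden, breadth of affected systems, and the
#' composite score, returned sorted by CRS (descending; ties broken by item
#' id). Factors with undefined ES (e.g. nobody exposed) keep an `NA` CRS and
#' sort last. Negative effect sizes (exposure associated with lower burden)
#' are flagged in `protective_direction`. The long-format per-system
#' p-values are attached as attribute `"system_p"`.
#'
#' @param ds an `ohs_survey`.
#' @param cb the matching codebook.
#' @param alpha significance level for the breadth tests.
#' @param weights,es_max passed to [composite_risk_score()].
#' @param p_adjust passed to [baps()].
#' @return data.frame with `item`, `label`, `category`, `ep`, `es`, `baps`,
#'   `crs`, `protective_direction`, `rank`.
#' @export
rank_risk_factors <- function(ds, cb, alpha = 0.05,
                              weights = c(es = 0.5, baps = 0.3, ep = 0.2),
                              es_max = NULL, p_adjust = "none") {
  stopifnot(inherits(ds, "ohs_survey"))
  tsb <- total_symptom_burden(ds$symptoms)
  sys <- system_scores(ds$symptoms, cb)
  ep_tab <- exposure_prevalence(ds$risks)
  items <- ep_tab$item

  es <- numeric(length(items)); bp <- integer(length(items))
  plist <- vector("list", length(items))
  for (j in seq_along(items)) {
    expo <- ds$risks[, j]
    es[j] <- if (length(unique(expo)) < 2) NA_real_ else
      suppressWarnings(effect_size(tsb, expo))
    b <- if (length(unique(expo)) < 2)
      list(baps = NA_integer_,
           p_values = stats::setNames(rep(NA_real_, ncol(sys)), colnames(sys)))
    else baps(sys, expo, alpha = alpha, p_adjust = p_adjust)
    bp[j] <- b$baps
    plist[[j]] <- data.frame(item = items[j], system = colnames(sys),
                             p = unname(b$p_values), row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  crs <- composite_risk_score(ep_tab$ep, es, bp, weights = weights,
                              n_systems = length(cb$systems), es_max = es_max)
  meta <- cb$items[match(items, cb$items$id), ]
  out <- data.frame(item = items, label = meta$label, category = meta$domain,
                    ep = ep_tab$ep, es = es, baps = bp, crs = crs,
                    protective_direction = !is.na(es) & es < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$crs), -Inf, out$crs), out$item), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "system_p") <- do.call(rbind, plist)
  out
}
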