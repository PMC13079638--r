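#' Protective-measure implementation rate
#'
#' Fraction of respondents using each measure (effectiveness code >= 1;
#' 0 means "not used").
#'
#' @param protections n x m matrix of codes 0-3, columns named by item.
#' @return data.frame with `item`, `n_users`, `ir`.
#' @export
implementation_rate <- function(protections) {
  protections <- check_protection_matrix(protections)
  n_users <- colSums(protections >= 1)
  data.frame(item = colnames(protections), n_users = as.integer(n_users),
             ir = n_users / nrow(protections), row.names = NULL,
             stringsAsFactors = FALSE)
}

check_protection_matrix <- function(protections) {
  protections <- as.matrix(protections)
  if (nrow(protections) == 0) stop_ohs("protection matrix has no respondents")
  if (any(is.na(protections)) || any(protections < 0 | protections > 3))
    stop_ohs("protection matrix must contain codes 0..3 only")
  protections
}

#' Mean protective effectiveness among users
#'
#' Mean effectiveness code (1 = poor, 2 = moderate, 3 = high) over
#' respondents actually using the measure; `NA` with a warning when nobody
#' uses it.
#'
#' @inheritParams implementation_rate
#' @return data.frame with `item`, `n_users`, `mpe`.
#' @export
mean_protective_effectiveness <- function(protections) {
  protections <- check_protection_matrix(protections)
  mpe <- vapply(seq_len(ncol(protections)), function(j) {
    v <- protections[, j]
    v <- v[v >= 1]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(mpe))
    warning("effectiveness undefined (no users) for: ",
            paste(colnames(protections)[is.na(mpe)], collapse = ", "),
            call. = FALSE)
  data.frame(item = colnames(protections),
             n_users = as.integer(colSums(protections >= 1)), mpe = mpe,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Composite protective effectiveness
#'
#' `CPE = w_ir * IR + w_mpe * MPE / 3`, combining how widely a measure is
#' implemented with how effective its users rate it (effectiveness
#' normalized by its scale maximum 3). The default weights (0.4, 0.6) were
#' identified by a grid search reproducing the published composite table and
#' remain configurable. Values lie in \[0, 1\]; report tables round
#' half-up to 2 decimals while full precision is retained here.
#'
#' @param ir implementation rate(s) in \[0, 1\].
#' @param mpe mean effectiveness in \[1, 3\] (`NA` propagates).
#' @param weights named weights `c(ir=, mpe=)` summing to 1.
#' @return numeric CPE vector.
#' @export
composite_protective_effectiveness <- function(ir, mpe,
                                               weights = c(ir = 0.4, mpe = 0.6)) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop_ohs("composite weights must sum to 1")
  unname(weights["ir"] * ir + weights["mpe"] * mpe / 3)
}

#' Rank protective measures by composite effectiveness
#'
#' Per-item implementation rate, mean effectiveness, and composite score,
#' sorted by CPE descending with ties broken by item id; measures nobody
#' uses keep `NA` MPE/CPE and sort last. Category-level mean IR and mean MPE
#' (per control-hierarchy level) are attached as attribute
#' `"category_summary"`.
#'
#' @param ds an `ohs_survey`.
#' @param cb the matching codebook.
#' @param weights passed to [composite_protective_effectiveness()].
#' @return data.frame with `item`, `label`, `category`, `ir`, `mpe`, `cpe`,
#'   `rank`.
#' @export
rank_measures <- function(ds, cb, weights = c(ir = 0.4, mpe = 0.6)) {
  stopifnot(inherits(ds, "ohs_survey"))
  ir_tab <- implementation_rate(ds$protections)
  mpe_tab <- suppressWarnings(mean_protective_effectiveness(ds$protections))
  cpe <- composite_protective_effectiveness(ir_tab$ir, mpe_tab$mpe,
                                            weights = weights)
  meta <- cb$items[match(ir_tab$item, cb$items$id), ]
  out <- data.frame(item = ir_tab$item, label = meta$label,
                    category = meta$domain, ir = ir_tab$ir, mpe = mpe_tab$mpe,
                    cpe = cpe, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$cpe), -Inf, out$cpe), out$item), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  cats <- split(out, factor(out$category, levels = cb$protection_categories))
  attr(out, "category_summary") <- data.frame(
    category = names(cats),
    mean_ir = vapply(cats, function(d) mean(d$ir), numeric(1)),
    mean_mpe = vapply(cats, function(d) mean(d$mpe, na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
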