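#' Per-item symptom prevalence
#'
#' A symptom is present when its severity code is at least 1 (the scale
#' defines 0 = none). Prevalence is the fraction of respondents reporting
#' the symptom.
#'
#' @param symptoms n x m severity matrix with codes 0-3, columns named by
#'   item id.
#' @return data.frame with `item`, `n_positive`, `prevalence`.
#' @export
item_prevalence <- function(symptoms) {
  symptoms <- check_severity_matrix(symptoms)
  n_pos <- colSums(symptoms >= 1)
  data.frame(item = colnames(symptoms), n_positive = as.integer(n_pos),
             prevalence = n_pos / nrow(symptoms), row.names = NULL,
             stringsAsFactors = FALSE)
}

check_severity_matrix <- function(symptoms) {
  symptoms <- as.matrix(symptoms)
  if (nrow(symptoms) == 0) stop_ohs("symptom matrix has no respondents")
  if (any(is.na(symptoms)) || any(symptoms < 0 | symptoms > 3))
    stop_ohs("symptom matrix must contain severity codes 0..3 only")
  symptoms
}

#' Per-system symptom prevalence
#'
#' A respondent counts toward a physiological system when any item of that
#' system has code >= 1; multiple symptoms in the same system count once.
#'
#' @param symptoms n x m severity matrix, columns named by item id.
#' @param cb codebook mapping every column to a system.
#' @return data.frame with `system`, `n_affected`, `prevalence`, in codebook
#'   system order.
#' @export
system_prevalence <- function(symptoms, cb) {
  symptoms <- check_severity_matrix(symptoms)
  doms <- item_domains(cb, "symptom")
  unmapped <- setdiff(colnames(symptoms), names(doms))
  if (length(unmapped))
    stop_ohs("symptom columns not mapped to a system: ",
             paste(unmapped, collapse = ", "))
  n_aff <- vapply(cb$systems, function(s) {
    ids <- intersect(names(doms)[doms == s], colnames(symptoms))
    if (!length(ids)) return(0L)
    sum(rowSums(symptoms[, ids, drop = FALSE] >= 1) > 0)
  }, integer(1))
  data.frame(system = cb$systems, n_affected = as.integer(n_aff),
             prevalence = n_aff / nrow(symptoms), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Symptomatic-only mean severity per item
#'
#' The severity score of an item is the mean code among respondents with
#' code >= 1, so it ranges over \[1, 3\]. Items nobody reports get `NA` with
#' a warning.
#'
#' @inheritParams item_prevalence
#' @return data.frame with `item`, `n_positive`, `severity`.
#' @export
severity_scores <- function(symptoms) {
  symptoms <- check_severity_matrix(symptoms)
  sev <- vapply(seq_len(ncol(symptoms)), function(j) {
    v <- symptoms[, j]
    v <- v[v >= 1]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(sev))
    warning("severity undefined (no positive respondents) for: ",
            paste(colnames(symptoms)[is.na(sev)], collapse = ", "),
            call. = FALSE)
  data.frame(item = colnames(symptoms),
             n_positive = as.integer(colSums(symptoms >= 1)),
             severity = sev, row.names = NULL, stringsAsFactors = FALSE)
}

#' Total symptom burden per respondent
#'
#' Row sum of severity codes over all items; bounded by 3 times the item
#' count.
#'
#' @inheritParams item_prevalence
#' @return numeric vector of length n.
#' @export
total_symptom_burden <- function(symptoms) {
  symptoms <- check_severity_matrix(symptoms)
  as.numeric(rowSums(symptoms))
}

#' Per-respondent system burden matrix
#'
#' Sums severity codes within each physiological system; row sums equal the
#' total symptom burden. This n x n_systems matrix feeds the breadth tests
#' and the clustering stage.
#'
#' @inheritParams system_prevalence
#' @return numeric matrix n x n_systems with system names as columns.
#' @export
system_scores <- function(symptoms, cb) {
  symptoms <- check_severity_matrix(symptoms)
  doms <- item_domains(cb, "symptom")
  out <- vapply(cb$systems, function(s) {
    ids <- intersect(names(doms)[doms == s], colnames(symptoms))
    if (!length(ids)) return(numeric(nrow(symptoms)))
    rowSums(symptoms[, ids, drop = FALSE])
  }, numeric(nrow(symptoms)))
  matrix(out, nrow = nrow(symptoms), dimnames = list(NULL, cb$systems))
}
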