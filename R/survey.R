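#' Survey dataset container
#'
#' Aligned respondent-level matrices in codebook item order: `symptoms`
#' (severity codes 0-3), `risks` (0/1), `protections` (0-3), and a
#' `demographics` data.frame of categorical fields. All share row order with
#' `respondent_ids`.
#'
#' @name ohs_survey
NULL

new_survey <- function(respondent_ids, symptoms, risks, protections,
                       demographics, latent_class = NULL) {
  structure(list(respondent_ids = as.character(respondent_ids),
                 symptoms = symptoms, risks = risks, protections = protections,
                 demographics = demographics, latent_class = latent_class),
            class = "ohs_survey")
}

#' @export
print.ohs_survey <- function(x, ...) {
  cat("<ohs_survey> n =", length(x$respondent_ids), "respondents;",
      ncol(x$symptoms), "symptom /", ncol(x$risks), "risk /",
      ncol(x$protections), "protection items\n")
  invisible(x)
}

# Textual response labels accepted in survey CSVs, per scale.
label_maps <- list(
  symptom = c(none = 0, mild = 1, moderate = 2, severe = 3),
  risk = c(absent = 0, present = 1),
  protection = c("not used" = 0, "poor" = 1, "moderate" = 2, "high" = 3))

decode_column <- function(vals, section) {
  out <- suppressWarnings(as.integer(vals))
  txt <- is.na(out) & !is.na(vals) & trimws(vals) != ""
  if (any(txt)) {
    map <- label_maps[[section]]
    key <- tolower(trimws(vals[txt]))
    out[txt] <- as.integer(unname(map[key]))
  }
  out[!is.na(vals) & trimws(vals) == ""] <- NA_integer_
  out
}

#' Load a wide survey CSV against a codebook
#'
#' Expects one row per respondent, a `respondent_id` column, one column per
#' codebook item id, and one per demographic variable. Textual codes
#' ("mild", "present", "high", ...) are mapped to integers via the scale of
#' the item's section. Columns are reordered to codebook order; unknown
#' columns trigger a warning listing them; missing item columns are an error.
#'
#' Validation is total: every cell either passes or is named (row, column)
#' in an error. Missing cells follow `missing`:
#' `"error"` (default) refuses them, `"drop"` removes respondents with any
#' missing item (complete-case analysis) and reports them, `"impute_zero"`
#' fills 0 (symptom/protection: none/not used; risk: absent).
#'
#' @param path CSV path (UTF-8, header row of item ids).
#' @param cb an `ohs_codebook`.
#' @param missing missingness policy.
#' @return An `ohs_survey`.
#' @export
load_survey <- function(path, cb, missing = c("error", "drop", "impute_zero")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop_ohs("survey file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!"respondent_id" %in% names(df))
    stop_ohs("survey CSV lacks a 'respondent_id' column")
  demo_ids <- item_ids(cb, "demographic")
  need <- c(item_ids(cb, "symptom"), item_ids(cb, "risk"),
            item_ids(cb, "protection"), demo_ids)
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_ohs("survey CSV is missing item columns: ",
             paste(absent, collapse = ", "))
  extra <- setdiff(names(df), c("respondent_id", need))
  if (length(extra))
    warning("ignoring unknown survey columns: ", paste(extra, collapse = ", "),
            call. = FALSE)

  build_matrix <- function(section) {
    ids <- item_ids(cb, section)
    m <- vapply(ids, function(id) decode_column(df[[id]], section),
                integer(nrow(df)))
    m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, ids))
    ranges <- cb$items[match(ids, cb$items$id), c("scale_min", "scale_max")]
    for (j in seq_along(ids)) {
      v <- m[, j]
      bad <- which(!is.na(v) & (v < ranges$scale_min[j] | v > ranges$scale_max[j]))
      undecoded <- which(is.na(v) & !is.na(df[[ids[j]]]) &
                           trimws(df[[ids[j]]]) != "")
      bad <- sort(unique(c(bad, undecoded)))
      if (length(bad))
        stop_ohs("value out of range for item '", ids[j], "' (scale ",
                 ranges$scale_min[j], "..", ranges$scale_max[j], ") at row",
                 if (length(bad) > 1) "s" else "", " ",
                 paste(bad, collapse = ", "))
    }
    m
  }

  sym <- build_matrix("symptom")
  rsk <- build_matrix("risk")
  prt <- build_matrix("protection")

  demo <- df[, demo_ids, drop = FALSE]
  for (id in demo_ids) {
    lev <- cb$demographic_levels[[id]]
    if (!is.null(lev)) {
      bad <- which(!is.na(demo[[id]]) & !demo[[id]] %in% lev)
      if (length(bad))
        stop_ohs("demographic '", id, "' has values outside its vocabulary ",
                 "at rows ", paste(bad, collapse = ", "))
    }
  }

  any_na <- rowSums(is.na(sym)) + rowSums(is.na(rsk)) + rowSums(is.na(prt))
  if (any(any_na > 0)) {
    if (missing == "error") {
      stop_ohs("missing cells for respondents at rows ",
               paste(which(any_na > 0), collapse = ", "),
               "; set a missingness policy ('drop' or 'impute_zero')")
    } else if (missing == "drop") {
      keep <- any_na == 0
      message("dropping ", sum(!keep), " respondent(s) with missing items: ",
              paste(df$respondent_id[!keep], collapse = ", "))
      sym <- sym[keep, , drop = FALSE]; rsk <- rsk[keep, , drop = FALSE]
      prt <- prt[keep, , drop = FALSE]; demo <- demo[keep, , drop = FALSE]
      df <- df[keep, , drop = FALSE]
    } else {
      sym[is.na(sym)] <- 0L; rsk[is.na(rsk)] <- 0L; prt[is.na(prt)] <- 0L
    }
  }

  new_survey(df$respondent_id, sym, rsk, prt, demo)
}

#' Write a survey dataset as a wide CSV
#'
#' Inverse of [load_survey()]: `load_survey(write_survey(ds, f), cb)`
#' reproduces `ds` exactly.
#'
#' @param ds an `ohs_survey`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(ds, path) {
  out <- data.frame(respondent_id = ds$respondent_ids,
                    ds$symptoms, ds$risks, ds$protections,
                    ds$demographics, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write named result tables with a JSON manifest
#'
#' Each table is written as `<name>.csv` with its column order preserved; the
#' manifest (`manifest.json`) lists file names, row counts, and the supplied
#' configuration hash. Reruns with identical inputs produce byte-identical
#' files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config_hash optional hash string recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, out_dir, config_hash = NULL) {
  if (length(tables) && is.null(names(tables)))
    stop_ohs("result tables must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop_ohs("output directory is not writable: ", out_dir)
  files <- lapply(names(tables), function(nm) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    list(name = paste0(nm, ".csv"), rows = nrow(tables[[nm]]))
  })
  manifest <- list(files = files, n_tables = length(tables),
                   config_hash = config_hash)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
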