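#' Read a clinical variable table
#'
#' CSV with a `patient_id` column and one numeric column per clinical
#' variable (missing values permitted).
#'
#' @param path Path to the CSV file.
#' @return Data frame with unique `patient_id` and numeric variables.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_rtc("clinical file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop_rtc("clinical table needs a patient_id column")
  if (anyDuplicated(df$patient_id)) {
    stop_rtc("duplicate patient id: ",
             df$patient_id[duplicated(df$patient_id)][1])
  }
  for (v in setdiff(names(df), "patient_id")) df[[v]] <- as.numeric(df[[v]])
  df
}

#' Correlate a network feature with a clinical variable
#'
#' Pearson r (two-sided t-approximation p) or Spearman rho (exact permutation
#' p for n <= 8, t-approximation otherwise). Pairs with missing data are
#' excluded pairwise and counted.
#'
#' @param feature Named numeric vector: patient id -> feature value.
#' @param clinical Clinical data frame (see [read_clinical()]).
#' @param variable_name Column of `clinical` to correlate against.
#' @param method `"pearson"` (default) or `"spearman"`. The choice is an
#'   explicit analyst decision; no automatic normality gating is applied.
#' @return List: `coefficient`, `p`, `n_used`, `method`. Zero variance in
#'   either vector gives `coefficient = NA` (undefined) rather than an error.
#' @export
associate <- function(feature, clinical, variable_name,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!variable_name %in% names(clinical)) {
    stop_rtc("variable not in clinical table: ", variable_name)
  }
  ids <- intersect(names(feature), clinical$patient_id)
  dropped <- length(feature) - length(ids)
  if (dropped > 0L) message(dropped, " patient(s) without clinical record dropped")
  x <- as.numeric(feature[ids])
  y <- clinical[[variable_name]][match(ids, clinical$patient_id)]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_rtc("fewer than 3 complete pairs for ", variable_name)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("zero variance: correlation undefined for ", variable_name)
    return(list(coefficient = NA_real_, p = NA_real_, n_used = n,
                method = method))
  }
  ct <- if (method == "spearman") {
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = n <= 8))
  } else {
    stats::cor.test(x, y, method = "pearson")
  }
  list(coefficient = unname(ct$estimate), p = ct$p.value, n_used = n,
       method = method)
}

#' Associate unique-feature-edge counts with clinical variables
#'
#' One row per requested clinical variable, correlating the per-patient
#' number of unique feature edges (e.g. unique fibrosis edges) with that
#' variable. Patients missing from either table are dropped pairwise; a
#' variable absent from the table or entirely missing yields a flagged row
#' rather than an error.
#'
#' @param unique_edge_reports Data frame from [unique_feature_edges()].
#' @param clinical Clinical data frame.
#' @param variables Character vector of clinical variable names.
#' @param method Correlation method passed to [associate()]; either a single
#'   value or one per variable.
#' @return Data frame: `variable`, `method`, `coefficient`, `p`, `n`,
#'   `status` ("ok", "missing_variable", or "no_data").
#' @export
association_report <- function(unique_edge_reports, clinical, variables,
                               method = "pearson") {
  feature <- stats::setNames(unique_edge_reports$n_unique_feature_edges,
                             unique_edge_reports$patient_id)
  method <- rep_len(method, length(variables))
  rows <- lapply(seq_along(variables), function(i) {
    v <- variables[i]
    if (!v %in% names(clinical)) {
      return(data.frame(variable = v, method = method[i],
                        coefficient = NA_real_, p = NA_real_, n = NA_integer_,
                        status = "missing_variable", stringsAsFactors = FALSE))
    }
    res <- tryCatch(associate(feature, clinical, v, method = method[i]),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(variable = v, method = method[i],
                        coefficient = NA_real_, p = NA_real_, n = NA_integer_,
                        status = "no_data", stringsAsFactors = FALSE))
    }
    data.frame(variable = v, method = res$method,
               coefficient = res$coefficient, p = res$p, n = res$n_used,
               status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
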