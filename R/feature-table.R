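#' Radiomic feature tables
#'
#' A feature table is an ordinary tibble with one row per adrenal sample:
#' a `sample_id` column (unique character ids), a `label` column
#' (1 = CT-negative adrenal confirmed dominant-secretion side by adrenal
#' venous sampling, 0 = CT-negative non-dominant side) and one numeric
#' column per radiomic feature. Feature columns carry their class as a
#' name prefix (`shape_`, `firstorder_`, `glcm_`, `glrlm_`, `glszm_`,
#' `gldm_`, `ngtdm_`), mirroring standard radiomics naming.
#'
#' `validate_feature_table()` checks the contract and returns the table
#' invisibly; all pipeline stages call it on entry.
#'
#' @param table A tibble/data frame in feature-table layout.
#' @param require_label Set `FALSE` for tables used only for scoring.
#' @return `table`, invisibly, with `label` coerced to integer.
#' @export
validate_feature_table <- function(table, require_label = TRUE) {
  if (!is.data.frame(table)) abort("feature table must be a data frame")
  if (!"sample_id" %in% names(table)) abort("feature table needs a `sample_id` column")
  if (anyDuplicated(table$sample_id)) {
    dup <- table$sample_id[duplicated(table$sample_id)][1]
    abort(sprintf("duplicate sample_id '%s'", dup))
  }
  if (require_label) {
    if (!"label" %in% names(table)) abort("feature table needs a `label` column")
    bad <- which(!(table$label %in% c(0, 1)) | is.na(table$label))
    if (length(bad)) {
      abort(sprintf("labels must be 0/1; row %d has label %s",
                    bad[1], as.character(table$label[bad[1]])))
    }
  }
  feats <- feature_names(table)
  if (anyDuplicated(feats)) abort("duplicate feature names")
  nonnum <- feats[!vapply(table[feats], is.numeric, logical(1))]
  if (length(nonnum)) {
    abort(sprintf("feature column '%s' is not numeric", nonnum[1]))
  }
  out <- as_tibble(table)
  if ("label" %in% names(out)) out$label <- as.integer(out$label)
  invisible(out)
}

#' @rdname validate_feature_table
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("sample_id", "label"))
}

#' @rdname validate_feature_table
#' @export
feature_classes <- function(table) {
  feats <- feature_names(table)
  sub("_.*$", "", feats)
}

feature_matrix <- function(table) {
  m <- as.matrix(table[feature_names(table)])
  rownames(m) <- table$sample_id
  m
}

#' Read and write feature tables
#'
#' CSV layout: header row, columns `sample_id,label,<features...>`, comma
#' separated, `.` decimal, `NA` for missing. Values are written at full
#' double precision so `read_feature_table(write_feature_table(x))`
#' round-trips exactly.
#'
#' @param path Path to a CSV file.
#' @param table A validated feature table.
#' @return `read_feature_table()` a tibble; `write_feature_table()` the
#'   path, invisibly.
#' @export
read_feature_table <- function(path) {
  raw <- read_csv_exact(path)
  raw$sample_id <- as.character(raw$sample_id)
  validate_feature_table(raw, require_label = "label" %in% names(raw))
  as_tibble(raw)
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table, require_label = "label" %in% names(table))
  readr::write_csv(format_full_precision(table), path)
  invisible(path)
}

# strtod-based parse: doubles written at 17 significant digits come back
# bit-identical (the fast float path of readr can be off by one ulp)
read_csv_exact <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("malformed CSV '%s': %s", path,
                                      conditionMessage(e))))
  as_tibble(raw)
}

# 17 significant digits round-trip any double exactly through text
format_full_precision <- function(table) {
  out <- as_tibble(table)
  for (v in setdiff(names(out), c("sample_id", "label"))) {
    if (is.double(out[[v]])) {
      s <- formatC(out[[v]], digits = 17, format = "g")
      s[is.na(out[[v]])] <- NA_character_
      out[[v]] <- s
    }
  }
  out
}

#' Clinical covariate tables
#'
#' Clinical tables hold the 24 per-patient covariates recorded for each
#' adrenal sample (`clinical_variables()` lists the canonical names and
#' declared types), next to `sample_id` and `label`. Gender is encoded
#' 0/1; all other variables are continuous on their natural units.
#'
#' @return A tibble with columns `variable` and `type`
#'   (`"continuous"`/`"categorical"`).
#' @export
clinical_variables <- function() {
  vars <- c("Age", "Gender", "Height", "Weight", "BMI", "SBP", "DBP",
            "HTN Duration", "Aldo-max", "Renin", "K+(Min.)", "Echo-IVSd",
            "Echo-LVEF", "RF-UA", "RF-Cr", "RF-EGFR", "U-MA/Cr", "U-K 24h",
            "U-K", "BL-TC", "BL-TG", "BL-LDL", "BL-HDL", "24h AE(Max.)")
  tibble(variable = vars,
         type = ifelse(vars == "Gender", "categorical", "continuous"))
}

#' @rdname clinical_variables
#' @param table A clinical table.
#' @param extra_ok Allow variables beyond the canonical 24.
#' @export
validate_clinical_table <- function(table, extra_ok = TRUE) {
  if (!is.data.frame(table)) abort("clinical table must be a data frame")
  if (!all(c("sample_id", "label") %in% names(table))) {
    abort("clinical table needs `sample_id` and `label` columns")
  }
  if (anyDuplicated(table$sample_id)) abort("duplicate sample_id")
  assert_binary_labels(table$label, "label")
  vars <- setdiff(names(table), c("sample_id", "label"))
  if (!extra_ok) {
    unknown <- setdiff(vars, clinical_variables()$variable)
    if (length(unknown)) abort(sprintf("unknown clinical variable '%s'", unknown[1]))
  }
  out <- as_tibble(table)
  out$label <- as.integer(out$label)
  invisible(out)
}

#' @rdname read_feature_table
#' @export
read_clinical_table <- function(path) {
  raw <- read_csv_exact(path)
  raw$sample_id <- as.character(raw$sample_id)
  validate_clinical_table(raw)
  as_tibble(raw)
}

#' @rdname read_feature_table
#' @export
write_clinical_table <- function(table, path) {
  readr::write_csv(format_full_precision(table), path)
  invisible(path)
}
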