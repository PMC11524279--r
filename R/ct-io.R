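# Ct table I/O and validation.

.ct_roles <- c("target_region", "genomic_reference", "cas9_transcript",
               "transcript_reference", "invitro_target", "invitro_reference")
.ct_templates <- c("genomic_dna", "cdna", "purified_dna")
.ct_groups <- c("test", "control")
.ct_columns <- c("sample_id", "target_id", "assay_id", "role", "template",
                 "group", "condition", "replicate", "ct")

# role -> required template
.role_template <- c(target_region = "genomic_dna",
                    genomic_reference = "genomic_dna",
                    cas9_transcript = "cdna",
                    transcript_reference = "cdna",
                    invitro_target = "purified_dna",
                    invitro_reference = "purified_dna")

#' Validate a table of Ct records
#'
#' Checks the well-level Ct table that every quantification function
#' consumes: one row per qPCR well, with the columns
#' `sample_id, target_id, assay_id, role, template, group, condition,
#' replicate, ct`. An undetermined (non-amplifying) well is an `NA` in the
#' `ct` column; any numeric `ct` must be finite and positive. Each `role`
#' must sit on its biologically possible template: genomic-DNA assays for
#' the target region and its genomic reference, cDNA for the Cas9
#' transcript and its reference, purified DNA for in vitro digests.
#'
#' @param records A data frame of Ct records.
#' @return The validated data frame (invisibly), with `role`, `template`
#'   and `group` as character and `replicate` as integer.
#' @export
validate_ct_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.ct_columns, names(records))
  if (length(missing_cols)) {
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records$role <- as.character(records$role)
  records$template <- as.character(records$template)
  records$group <- as.character(records$group)
  bad <- which(!records$role %in% .ct_roles)
  if (length(bad)) {
    stop(sprintf("invalid role '%s' in row %d", records$role[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(!records$template %in% .ct_templates)
  if (length(bad)) {
    stop(sprintf("invalid template '%s' in row %d", records$template[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(!records$group %in% .ct_groups)
  if (length(bad)) {
    stop(sprintf("invalid group '%s' in row %d", records$group[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(records$template != .role_template[records$role])
  if (length(bad)) {
    stop(sprintf("row %d: role '%s' requires template '%s', got '%s'",
                 bad[1], records$role[bad[1]],
                 .role_template[[records$role[bad[1]]]], records$template[bad[1]]),
         call. = FALSE)
  }
  rep <- suppressWarnings(as.integer(records$replicate))
  bad <- which(is.na(rep) | rep < 1)
  if (length(bad)) {
    stop(sprintf("column 'replicate' must be a positive integer (row %d)", bad[1]),
         call. = FALSE)
  }
  records$replicate <- rep
  ct <- suppressWarnings(as.numeric(records$ct))
  bad <- which(!is.na(records$ct) & !is.na(as.character(records$ct)) &
                 nzchar(trimws(as.character(records$ct))) & is.na(ct))
  if (length(bad)) {
    stop(sprintf("column 'ct' has a non-numeric value in row %d", bad[1]), call. = FALSE)
  }
  bad <- which(!is.na(ct) & (!is.finite(ct) | ct <= 0))
  if (length(bad)) {
    stop(sprintf("column 'ct' must be finite and > 0, or empty for an undetermined well (row %d)",
                 bad[1]), call. = FALSE)
  }
  records$ct <- ct
  invisible(records)
}

#' Read a Ct table from CSV
#'
#' Reads the long-format well table written by [write_ct_table()] or by the
#' simulator. An empty `ct` field denotes an undetermined well and becomes
#' `NA`.
#'
#' @param path CSV file path.
#' @return A validated data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  missing_cols <- setdiff(.ct_columns, names(df))
  if (length(missing_cols)) {
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ct <- as.character(df$ct)
  ct[is.na(ct) | !nzchar(trimws(ct))] <- NA
  num <- suppressWarnings(as.numeric(ct))
  bad <- which(!is.na(ct) & is.na(num))
  if (length(bad)) {
    stop(sprintf("column 'ct' has a non-numeric value in row %d", bad[1]),
         call. = FALSE)
  }
  df$ct <- num
  validate_ct_records(df)
}

#' Write a Ct table to CSV
#'
#' Undetermined wells (`NA` Ct) are written as an empty field so that
#' read/write round-trips preserve them.
#'
#' @param records Data frame of Ct records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(records, path) {
  records <- validate_ct_records(records)
  out <- records[, .ct_columns]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write per-target quantification results to CSV
#'
#' @param object A [tcep_quantify()] result (or its `$results` data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quant_results <- function(object, path) {
  res <- if (inherits(object, "tcep_quant")) object$results else object
  cols <- c("target_id", "mode", "ddct", "broken_fraction", "cas9_abundance",
            "relative_efficiency", "normalized_efficiency", "sd", "n", "p_value")
  if ("condition" %in% names(res) && length(unique(res$condition)) > 1) {
    cols <- append(cols, "condition", after = 1)
  }
  utils::write.csv(res[, cols], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a results CSV written by [write_quant_results()]
#'
#' @param path CSV file path.
#' @return A data frame of per-target results.
#' @export
read_quant_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_id", "relative_efficiency", "sd", "n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("results table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Default run configuration
#'
#' All command-line and file-driven runs share one flat configuration whose
#' fields all have defaults; a config file overrides the defaults and
#' command-line flags override the file.
#'
#' @return Named list of defaults: estimator settings (`mode`, `pairing`,
#'   `alpha`, `clamp_floor`), readout settings (`ct_baseline`,
#'   `amp_efficiency`, `ct_noise_sd`, `seed`, `n_replicates`) and kinetic
#'   parameters (`k_cut`, `rho_repair`, `mu_mut`, `t_end`, `cas9_level`,
#'   `delivery_scale`, `step`).
#' @export
default_config <- function() {
  list(mode = "canonical", pairing = "mean_control", alpha = 0.05,
       clamp_floor = 1e-6,
       ct_baseline = 20, amp_efficiency = 1, ct_noise_sd = 0.2,
       seed = 1L, n_replicates = 3L,
       k_cut = 0.1, rho_repair = 0.2, mu_mut = 0.3, t_end = 48,
       cas9_level = 1, delivery_scale = 1, step = 0.1)
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment;
#' blank lines ignored. Unknown keys are an error so typos do not silently
#' fall back to defaults.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Named list: [default_config()] overridden by the file.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    cfg[[key]] <- if (key %in% c("mode", "pairing")) {
      val
    } else if (key %in% c("seed", "n_replicates")) {
      as.integer(val)
    } else {
      as.numeric(val)
    }
  }
  cfg
}
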