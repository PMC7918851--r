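#' Validate pipeline input tables
#'
#' Schema and vocabulary checks for the four table kinds the pipeline
#' consumes. Row-level problems are collected into an error report rather
#' than failing on the first one, so a whole file can be fixed in one
#' pass.
#'
#' @param tables Named list with any of `ct`, `platinum`, `measurements`,
#'   `clinical`.
#' @return Data frame `table`, `row` (NA for table-level problems),
#'   `field`, `message`; zero rows when everything checks out.
#' @export
validate_tables <- function(tables) {
  stopifnot(is.list(tables))
  reports <- list()
  checkers <- list(ct = validate_ct_table,
                   platinum = validate_platinum_table,
                   measurements = validate_measurements,
                   clinical = validate_clinical)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]]) || !nm %in% names(checkers)) next
    rep <- checkers[[nm]](tables[[nm]])
    if (nrow(rep)) {
      rep$table <- nm
      reports[[nm]] <- rep[, c("table", "row", "field", "message")]
    }
  }
  if (!length(reports)) {
    return(data.frame(table = character(), row = integer(),
                      field = character(), message = character()))
  }
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}

error_report <- function() {
  data.frame(row = integer(), field = character(), message = character(),
             stringsAsFactors = FALSE)
}

add_error <- function(report, row, field, message) {
  rbind(report, data.frame(row = row, field = field, message = message))
}

check_columns <- function(df, required) {
  missing <- setdiff(required, names(df))
  rep <- error_report()
  for (m in missing) rep <- add_error(rep, NA_integer_, m, "missing column")
  rep
}

#' @rdname validate_tables
#' @param ct Data frame of Ct records.
#' @export
validate_ct_table <- function(ct) {
  rep <- check_columns(ct, c("cell_line", "caf_id", "cisplatin",
                             "medium_kind", "gene", "replicate", "ct",
                             "undetected"))
  if (nrow(rep)) return(rep)
  for (i in seq_len(nrow(ct))) {
    if (!is.na(ct$ct[i]) && (ct$ct[i] <= 0 || ct$ct[i] > 45))
      rep <- add_error(rep, i, "ct",
                       "Ct outside (0, 45]: 45-cycle program maximum")
    if (!ct$gene[i] %in% gene_panel)
      rep <- add_error(rep, i, "gene", paste0("unknown gene '", ct$gene[i],
                                              "' (not in the assay panel)"))
    if (!ct$medium_kind[i] %in% medium_kinds)
      rep <- add_error(rep, i, "medium_kind",
                       paste0("unknown medium_kind '", ct$medium_kind[i], "'"))
    if (isTRUE(ct$undetected[i]) && !is.na(ct$ct[i]) && ct$ct[i] != 45)
      rep <- add_error(rep, i, "undetected",
                       "undetected rows must carry Ct = 45")
  }
  rep
}

#' @rdname validate_tables
#' @param platinum Data frame of platinum concentration records.
#' @export
validate_platinum_table <- function(platinum) {
  rep <- check_columns(platinum, c("caf_id", "medium_kind",
                                   "concentration_um", "dilution_factor",
                                   "volume_ml", "added_um"))
  if (nrow(rep)) return(rep)
  for (i in seq_len(nrow(platinum))) {
    if (!platinum$medium_kind[i] %in% medium_kinds)
      rep <- add_error(rep, i, "medium_kind",
                       paste0("unknown medium_kind '",
                              platinum$medium_kind[i], "'"))
    if (!is.na(platinum$concentration_um[i]) &&
        platinum$concentration_um[i] < 0)
      rep <- add_error(rep, i, "concentration_um",
                       "negative concentration")
    if (platinum$dilution_factor[i] < 1)
      rep <- add_error(rep, i, "dilution_factor", "dilution factor below 1")
    if (platinum$volume_ml[i] <= 0)
      rep <- add_error(rep, i, "volume_ml", "non-positive volume")
  }
  rep
}

#' @rdname validate_tables
#' @param measurements Data frame of colony measurements.
#' @export
validate_measurements <- function(measurements) {
  rep <- check_columns(measurements,
                       c("well_id", "caf_id", "cisplatin", "medium_kind",
                         "colony_pixels", "well_pixels", "area_fraction"))
  if (nrow(rep)) return(rep)
  for (i in seq_len(nrow(measurements))) {
    af <- measurements$area_fraction[i]
    if (!is.na(af) && (af < 0 || af > 1))
      rep <- add_error(rep, i, "area_fraction", "outside [0, 1]")
    if (measurements$colony_pixels[i] > measurements$well_pixels[i])
      rep <- add_error(rep, i, "colony_pixels",
                       "colony pixels exceed well pixels")
    if (!measurements$medium_kind[i] %in% medium_kinds)
      rep <- add_error(rep, i, "medium_kind",
                       paste0("unknown medium_kind '",
                              measurements$medium_kind[i], "'"))
  }
  rep
}

#' @rdname validate_tables
#' @param clinical Data frame of clinical records.
#' @export
validate_clinical <- function(clinical) {
  rep <- check_columns(clinical, c("patient", "p16", "recurrence"))
  if (nrow(rep)) return(rep)
  for (i in seq_len(nrow(clinical))) {
    for (f in c("p16", "recurrence")) {
      if (!clinical[[f]][i] %in% c(0L, 1L))
        rep <- add_error(rep, i, f, "must be 0 or 1")
    }
  }
  rep
}
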