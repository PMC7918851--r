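#' Sensitizing ratio of a CAF coculture
#'
#' Quantifies how much a CAF coculture shifts the cisplatin response of the
#' cancer cells relative to the non-cocultured control, on the colony-area
#' scale:
#'
#' \deqn{-\log_2\left(\frac{a_{cis+CAF}/a_{cis-CAF}}
#'                         {a_{cis+nc}/a_{cis-nc}}\right)}
#'
#' where the numerator is the treated/untreated colony-area ratio under
#' coculture and the denominator the same ratio for non-cocultured cells.
#' The non-cocultured control therefore scores exactly 0; positive values
#' mean the CAF sensitizes the cells to cisplatin, negative values that it
#' supports resistance. The score is invariant to rescaling all four areas
#' by a common factor.
#'
#' @param a_cis_caf,a_nocis_caf Colony-area fractions of cocultured cells
#'   with and without cisplatin.
#' @param a_cis_nc,a_nocis_nc The same for non-cocultured cells.
#' @return Numeric sensitizing ratio in log2 units (vectorized over the
#'   inputs).
#' @examples
#' sensitizing_ratio(0.05, 0.4, 0.1, 0.4)  # strong sensitization: +1
#' sensitizing_ratio(0.2, 0.4, 0.2, 0.4)   # control identity: 0
#' @export
sensitizing_ratio <- function(a_cis_caf, a_nocis_caf, a_cis_nc, a_nocis_nc) {
  areas <- cbind(a_cis_caf = a_cis_caf, a_nocis_caf = a_nocis_caf,
                 a_cis_nc = a_cis_nc, a_nocis_nc = a_nocis_nc)
  bad <- which(!(areas > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("sensitizing ratio undefined: non-positive area in ",
         paste(unique(colnames(areas)[bad[, "col"]]), collapse = ", "),
         call. = FALSE)
  }
  -log2((a_cis_caf / a_nocis_caf) / (a_cis_nc / a_nocis_nc))
}

#' Classify a sensitizing ratio
#'
#' Sign determines the call; scores within `tie_tolerance` of 0 are called
#' neutral, since the sign alone is not meaningful at the measurement
#' noise floor.
#'
#' @param ratio Numeric sensitizing ratio(s), log2 units.
#' @param tie_tolerance Half-width of the neutral band (default 0.05 log2
#'   units).
#' @return Character vector: `"sensitizing"`, `"resistance_supporting"` or
#'   `"neutral"`.
#' @export
classify_sensitizing <- function(ratio, tie_tolerance = 0.05) {
  ifelse(abs(ratio) < tie_tolerance, "neutral",
         ifelse(ratio > 0, "sensitizing", "resistance_supporting"))
}

#' Per-CAF sensitizing ratios from a measurement table
#'
#' Computes one sensitizing ratio per CAF from a table of colony-area
#' measurements (as produced by [batch_measure()]). Area fractions are
#' averaged per condition before entering the score, so replicate wells
#' are supported; the non-cocultured arms (`caf_id == "none"`) provide the
#' control ratio shared by all CAFs.
#'
#' @param measurements Data frame with columns `caf_id`, `cisplatin`,
#'   `area_fraction`.
#' @param tie_tolerance Passed to [classify_sensitizing()].
#' @return Data frame with columns `caf_id`, `ratio`, `classification`.
#' @export
sensitizing_table <- function(measurements, tie_tolerance = 0.05) {
  stopifnot(all(c("caf_id", "cisplatin", "area_fraction") %in%
                  names(measurements)))
  mean_area <- function(caf, cis) {
    v <- measurements$area_fraction[measurements$caf_id == caf &
                                      measurements$cisplatin == cis]
    if (!length(v)) stop("no wells for caf_id = ", caf,
                         ", cisplatin = ", cis, call. = FALSE)
    mean(v)
  }
  a_cis_nc <- mean_area("none", TRUE)
  a_nocis_nc <- mean_area("none", FALSE)
  cafs <- setdiff(unique(measurements$caf_id), "none")
  ratio <- vapply(cafs, function(caf) {
    sensitizing_ratio(mean_area(caf, TRUE), mean_area(caf, FALSE),
                      a_cis_nc, a_nocis_nc)
  }, numeric(1))
  data.frame(caf_id = cafs, ratio = unname(ratio),
             classification = classify_sensitizing(unname(ratio),
                                                   tie_tolerance),
             row.names = NULL)
}

#' Undo the pre-analysis dilution of an ICP-MS reading
#'
#' @param c_raw Measured concentration on the diluted sample, uM.
#' @param dilution_factor Fold dilution applied before analysis (10 for
#'   the standard protocol).
#' @return Concentration in the original sample, uM.
#' @examples
#' correct_dilution(0.35, 10)  # 3.5 uM
#' @export
correct_dilution <- function(c_raw, dilution_factor) {
  stopifnot(all(dilution_factor >= 1))
  c_raw * dilution_factor
}

#' Cisplatin taken up by CAFs from the treatment medium
#'
#' Mass balance over the treatment window: the amount absent from the
#' medium after 24 h must have entered the cells,
#' `n_uptake = added * V - measured * V` (uM times mL gives nmol).
#' Small negative balances (within `tolerance` of the added dose) are
#' measurement noise and clamped to 0; larger violations indicate an
#' inconsistent measurement and raise an error.
#'
#' @param added_conc Dosed concentration, uM.
#' @param measured_conc Concentration measured in the medium after
#'   treatment (dilution-corrected), uM.
#' @param volume Medium volume, mL.
#' @param tolerance Fraction of the added dose tolerated below zero
#'   (default 0.05).
#' @return Uptaken amount, nmol (vectorized).
#' @examples
#' cisplatin_uptake(5, 3, 2)  # 4 nmol
#' @export
cisplatin_uptake <- function(added_conc, measured_conc, volume,
                             tolerance = 0.05) {
  stopifnot(all(added_conc >= 0), all(measured_conc >= 0), all(volume > 0))
  n_added <- added_conc * volume
  uptake <- n_added - measured_conc * volume
  floor_nmol <- -tolerance * n_added
  if (any(uptake < floor_nmol)) {
    stop("mass-balance violation: measured amount exceeds the added dose ",
         "by more than ", tolerance * 100, "% (",
         paste(format(uptake[uptake < floor_nmol], digits = 3),
               collapse = ", "), " nmol)", call. = FALSE)
  }
  pmax(uptake, 0)
}

#' Cisplatin released (effluxed) from CAFs
#'
#' Platinum found in fresh medium conditioned after the treatment ended can
#' only have been effluxed by the cells, so the released amount is the
#' measured concentration times the medium volume.
#'
#' @param c_released Dilution-corrected concentration in the
#'   post-treatment conditioned medium, uM.
#' @param volume Medium volume, mL.
#' @return Released amount, nmol (vectorized).
#' @export
cisplatin_release <- function(c_released, volume) {
  stopifnot(all(c_released >= 0), all(volume > 0))
  c_released * volume
}

#' Close the platinum mass balance for a concentration table
#'
#' Takes raw (diluted) ICP-MS readings for the treatment medium
#' (`CMCAF+cisplatin`) and the post-treatment conditioned medium
#' (`CMCAF_post-cisplatin`), undoes the dilution and derives per-CAF
#' uptaken and released amounts in nmol alongside the corrected
#' concentrations in uM.
#'
#' @param platinum Data frame as from [generate_platinum_table()]: columns
#'   `caf_id`, `medium_kind`, `concentration_um`, `dilution_factor`,
#'   `volume_ml`, `added_um`.
#' @param tolerance Passed to [cisplatin_uptake()].
#' @return Data frame with one row per CAF: `caf_id`, `n_added_nmol`,
#'   `c_post_um`, `c_released_um`, `n_uptake_nmol`, `n_released_nmol`.
#' @export
platinum_mass_balance <- function(platinum, tolerance = 0.05) {
  need <- c("caf_id", "medium_kind", "concentration_um", "dilution_factor",
            "volume_ml", "added_um")
  stopifnot(all(need %in% names(platinum)))
  post <- platinum[platinum$medium_kind == "CMCAF+cisplatin", ]
  rel <- platinum[platinum$medium_kind == "CMCAF_post-cisplatin", ]
  if (!nrow(post)) stop("no CMCAF+cisplatin rows in platinum table",
                        call. = FALSE)
  rel <- rel[match(post$caf_id, rel$caf_id), ]

  c_post <- correct_dilution(post$concentration_um, post$dilution_factor)
  c_rel <- correct_dilution(rel$concentration_um, rel$dilution_factor)
  data.frame(
    caf_id = post$caf_id,
    n_added_nmol = post$added_um * post$volume_ml,
    c_post_um = c_post,
    c_released_um = c_rel,
    n_uptake_nmol = cisplatin_uptake(post$added_um, c_post, post$volume_ml,
                                     tolerance = tolerance),
    n_released_nmol = ifelse(is.na(c_rel), NA_real_,
                             cisplatin_release(ifelse(is.na(c_rel), 0, c_rel),
                                               rel$volume_ml)),
    row.names = NULL
  )
}

#' Compare a per-CAF quantity between two groups
#'
#' Pooled-variance two-sample t-test of a per-CAF measurement (uptake,
#' release, colony area, ...) split by a binary grouping such as patient
#' recurrence. With cohorts this small (2 vs 5 donors) the pooled test is
#' the standard choice; Welch's correction would leave almost no degrees
#' of freedom.
#'
#' @param values Numeric vector, one value per CAF.
#' @param grouping Logical (or 0/1) vector of the same length.
#' @return List with `mean_in`, `mean_out` (group means for `TRUE` and
#'   `FALSE`), `difference`, `t`, `df`, `p`, `n` (pair of group sizes).
#' @export
compare_by_group <- function(values, grouping) {
  grouping <- as.logical(grouping)
  stopifnot(length(values) == length(grouping), !anyNA(grouping))
  x <- values[grouping]
  y <- values[!grouping]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two observations", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    # constant groups: t.test() errors, but the limiting answer is clear
    d <- mean(x) - mean(y)
    return(list(mean_in = mean(x), mean_out = mean(y), difference = d,
                t = if (d == 0) 0 else sign(d) * Inf,
                df = length(values) - 2, p = if (d == 0) 1 else 0,
                n = c(length(x), length(y))))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(mean_in = mean(x), mean_out = mean(y),
       difference = unname(mean(x) - mean(y)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = c(length(x), length(y)))
}
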