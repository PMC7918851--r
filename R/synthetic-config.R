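#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic experiment: plate-image geometry and
#' colors, qPCR baseline and noise, planted log2 fold changes, planted
#' per-CAF cisplatin uptake fractions, and the dosing constants (added
#' concentration, medium volume, dilution). Identical configurations give
#' byte-identical outputs from all generators; each generator derives its
#' own stream from `seed`, never touching global RNG state.
#'
#' @param seed Integer master seed.
#' @param caf_ids Character vector of CAF identifiers; defaults to the
#'   seven-donor cohort of [clinical_fixture()].
#' @param image_size Side length of the square plate image in pixels.
#' @param well_radius Radius of the circular well region, pixels; must fit
#'   inside the image (`<= image_size / 2`).
#' @param colony_count_range Integer pair; untreated-well colony counts are
#'   drawn uniformly from this range.
#' @param colony_radius_meanlog,colony_radius_sdlog Log-normal parameters
#'   (mu, sigma) of colony radii in pixels.
#' @param stain_color,background_color RGB triples in 0..255. The defaults
#'   (blue-dominant stain on near-white background) guarantee clear
#'   separation on the CIELAB b channel.
#' @param pixel_noise_sd Gaussian pixel noise, 8-bit intensity units.
#' @param ct_baseline Baseline qPCR cycle threshold, cycles.
#' @param ct_noise_sd Replicate noise on Ct values, cycles.
#' @param n_replicates qPCR replicates per gene and condition.
#' @param planted_log2fc Data frame (`gene`, `caf_id`, `medium_kind`,
#'   `log2fc`) of planted expression effects relative to the fresh-medium
#'   calibrator; unlisted combinations are 0. `caf_id = "none"` plants an
#'   effect in non-cocultured conditions.
#' @param planted_uptake_fraction Named numeric in \[0, 1\] per CAF id:
#'   fraction of the added cisplatin taken up within 24 h.
#' @param release_fraction Fraction of the uptaken platinum effluxed into
#'   the post-treatment medium; scalar or named per CAF.
#' @param conc_noise_sd ICP-MS concentration noise, uM (pre-dilution scale).
#' @param added_concentration Cisplatin dose added to the medium, uM.
#' @param medium_volume Medium volume per well, mL.
#' @param dilution_factor Dilution applied to samples before ICP-MS.
#' @param cisplatin_survival Multiplicative colony-count survival under
#'   cisplatin for non-cocultured cells.
#' @param caf_area_effect Named log2 modifiers of untreated colony counts
#'   per CAF (coculture promoting/inhibiting colony formation); scalar 0
#'   means no effect.
#' @param caf_sensitizing Named planted sensitizing effects per CAF, log2
#'   units: the treated/untreated survival ratio under coculture is scaled
#'   by `2^-caf_sensitizing` relative to the control, so positive values
#'   sensitize.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' cfg$added_concentration  # 5 uM dosing
#' @export
synthetic_config <- function(seed = 1L,
                             caf_ids = NULL,
                             image_size = 192L,
                             well_radius = 88,
                             colony_count_range = c(30L, 60L),
                             colony_radius_meanlog = log(5),
                             colony_radius_sdlog = 0.25,
                             stain_color = c(70, 80, 160),
                             background_color = c(245, 245, 245),
                             pixel_noise_sd = 3,
                             ct_baseline = 25,
                             ct_noise_sd = 0.2,
                             n_replicates = 3L,
                             planted_log2fc = NULL,
                             planted_uptake_fraction = NULL,
                             release_fraction = 0.2,
                             conc_noise_sd = 0.05,
                             added_concentration = 5,
                             medium_volume = 2,
                             dilution_factor = 10,
                             cisplatin_survival = 0.4,
                             caf_area_effect = NULL,
                             caf_sensitizing = NULL) {
  if (is.null(caf_ids)) caf_ids <- caf_ids()
  caf_ids <- as.character(caf_ids)

  clin <- tryCatch(clinical_fixture(), error = function(e) NULL)
  recurrent <- if (!is.null(clin)) {
    caf_ids %in% clin$patient[clin$recurrence == 1]
  } else {
    rep(FALSE, length(caf_ids))
  }

  if (is.null(planted_uptake_fraction)) {
    # recurrence-associated CAFs accumulate more platinum by default
    planted_uptake_fraction <- setNames(ifelse(recurrent, 0.6, 0.3), caf_ids)
  }
  if (is.null(caf_area_effect)) {
    caf_area_effect <- setNames(rep(0, length(caf_ids)), caf_ids)
  }
  if (is.null(caf_sensitizing)) {
    # alternating sensitizing / resistance-supporting effects across the cohort
    eff <- rep(c(1, 0.7, 0.3, 0, -0.5, -0.8, -0.4), length.out = length(caf_ids))
    caf_sensitizing <- setNames(eff, caf_ids)
  }
  if (is.null(planted_log2fc)) {
    planted_log2fc <- default_planted_log2fc(caf_ids, caf_sensitizing)
  }
  if (length(release_fraction) == 1L && is.null(names(release_fraction))) {
    release_fraction <- setNames(rep(release_fraction, length(caf_ids)), caf_ids)
  }

  cfg <- structure(list(
    seed = as.integer(seed),
    caf_ids = caf_ids,
    n_cafs = length(caf_ids),
    image_size = as.integer(image_size),
    well_radius = well_radius,
    colony_count_range = as.integer(colony_count_range),
    colony_radius_meanlog = colony_radius_meanlog,
    colony_radius_sdlog = colony_radius_sdlog,
    stain_color = stain_color,
    background_color = background_color,
    pixel_noise_sd = pixel_noise_sd,
    ct_baseline = ct_baseline,
    ct_noise_sd = ct_noise_sd,
    n_replicates = as.integer(n_replicates),
    planted_log2fc = planted_log2fc,
    planted_uptake_fraction = planted_uptake_fraction,
    release_fraction = release_fraction,
    conc_noise_sd = conc_noise_sd,
    added_concentration = added_concentration,
    medium_volume = medium_volume,
    dilution_factor = dilution_factor,
    cisplatin_survival = cisplatin_survival,
    caf_area_effect = caf_area_effect,
    caf_sensitizing = caf_sensitizing
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, is.finite(cfg$seed),
    cfg$image_size >= 8L,
    cfg$well_radius > 0, cfg$well_radius <= cfg$image_size / 2,
    length(cfg$colony_count_range) == 2L,
    all(cfg$colony_count_range >= 0L),
    cfg$colony_count_range[1] <= cfg$colony_count_range[2],
    is.finite(cfg$colony_radius_meanlog), cfg$colony_radius_sdlog >= 0,
    length(cfg$stain_color) == 3L, all(cfg$stain_color >= 0),
    all(cfg$stain_color <= 255),
    length(cfg$background_color) == 3L, all(cfg$background_color >= 0),
    all(cfg$background_color <= 255),
    cfg$pixel_noise_sd >= 0, cfg$ct_noise_sd >= 0, cfg$conc_noise_sd >= 0,
    cfg$n_replicates >= 1L,
    cfg$added_concentration >= 0, cfg$medium_volume > 0,
    cfg$dilution_factor >= 1,
    cfg$cisplatin_survival > 0, cfg$cisplatin_survival <= 1
  )
  if (any(cfg$planted_uptake_fraction < 0 | cfg$planted_uptake_fraction > 1)) {
    stop("planted_uptake_fraction values must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$release_fraction < 0 | cfg$release_fraction > 1)) {
    stop("release_fraction values must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("planted_uptake_fraction", "release_fraction",
               "caf_area_effect", "caf_sensitizing")) {
    missing <- setdiff(cfg$caf_ids, names(cfg[[nm]]))
    if (length(missing)) {
      stop(nm, " missing entries for CAF(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  lfc <- cfg$planted_log2fc
  stopifnot(is.data.frame(lfc),
            all(c("gene", "caf_id", "medium_kind", "log2fc") %in% names(lfc)))
  bad <- setdiff(lfc$gene, gene_panel)
  if (length(bad)) {
    stop("planted_log2fc contains genes absent from the assay panel: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

# Default expression effects: resistance-associated genes rise where the
# planted sensitizing effect is negative, CCL2 tracks sensitization.
default_planted_log2fc <- function(caf_ids, caf_sensitizing) {
  resistance_genes <- c("VEGFA", "PGE2S", "COX2", "EGFR", "NANOG")
  rows <- list()
  for (caf in caf_ids) {
    s <- caf_sensitizing[[caf]]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = resistance_genes, caf_id = caf,
      medium_kind = "CMCAF_post-cisplatin", log2fc = -1.2 * s
    )
    rows[[length(rows) + 1L]] <- data.frame(
      gene = "CCL2", caf_id = caf,
      medium_kind = "CMCAF_post-cisplatin", log2fc = 1.2 * s
    )
    # mild coculture effect without cisplatin, shared across CAFs
    rows[[length(rows) + 1L]] <- data.frame(
      gene = c("IL6", "VEGFA"), caf_id = caf,
      medium_kind = "CMCAF", log2fc = c(0.5, 0.3)
    )
  }
  do.call(rbind, rows)
}

# Deterministic per-task seed stream: DJB-style hash of a label folded with
# the master seed, kept inside the 32-bit signed range.
derive_seed <- function(seed, key) {
  h <- (as.numeric(seed) %% 2147483647) + 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  seed:", x$seed, " CAFs:", paste(x$caf_ids, collapse = ", "), "\n")
  cat("  image:", x$image_size, "px, well radius", x$well_radius, "px\n")
  cat("  dosing:", x$added_concentration, "uM x", x$medium_volume,
      "mL, dilution", x$dilution_factor, "\n")
  invisible(x)
}
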