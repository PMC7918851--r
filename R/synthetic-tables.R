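#' Generate a synthetic qPCR Ct table
#'
#' Emulates the 20-assay TaqMan panel across the conditioned-media
#' conditions: a fresh-medium and a depleted-medium non-cocultured control,
#' and, per CAF, a no-cisplatin coculture arm (`CMCAF`) and a
#' cisplatin-influenced arm (`CMCAF_post-cisplatin`, flagged
#' `cisplatin = TRUE`). Target Ct values are planted as
#' `ct_baseline - log2fc + noise` (one PCR cycle = one doubling), while the
#' housekeepers ACTB and PSMB2 sit at `ct_baseline + noise` in every
#' sample; replicates receive independent noise. With all noise at zero the
#' comparative-Ct pipeline recovers the planted log2 fold changes exactly.
#'
#' @param config A [synthetic_config()]; `config$planted_log2fc` defines
#'   the effects relative to the fresh-medium calibrator.
#' @param cell_line Label written into the `cell_line` column.
#' @return Data frame of Ct records (`cell_line`, `caf_id`, `cisplatin`,
#'   `medium_kind`, `gene`, `replicate`, `ct`, `undetected`) with the
#'   planted effect map attached as `attr(, "truth")`.
#' @export
generate_ct_table <- function(config, cell_line = "FaDu") {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)  # rejects planted genes outside the panel

  conditions <- rbind(
    data.frame(caf_id = "none", cisplatin = FALSE, medium_kind = "fresh"),
    data.frame(caf_id = "none", cisplatin = FALSE, medium_kind = "depleted"),
    data.frame(caf_id = rep(config$caf_ids, each = 2),
               cisplatin = rep(c(FALSE, TRUE), config$n_cafs),
               medium_kind = rep(c("CMCAF", "CMCAF_post-cisplatin"),
                                 config$n_cafs))
  )

  lfc <- config$planted_log2fc
  lookup_keys <- paste(lfc$gene, lfc$caf_id, lfc$medium_kind, sep = "\r")
  planted_for <- function(gene, caf, kind) {
    i <- match(paste(gene, caf, kind, sep = "\r"), lookup_keys)
    if (is.na(i)) 0 else lfc$log2fc[i]
  }

  grid <- expand.grid(row = seq_len(nrow(conditions)), gene = gene_panel,
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE)
  cond <- conditions[grid$row, ]
  planted <- mapply(planted_for, grid$gene, cond$caf_id, cond$medium_kind)
  planted[grid$gene %in% housekeeping_genes] <- 0

  ct <- withr::with_seed(derive_seed(config$seed, paste0("ct:", cell_line)), {
    config$ct_baseline - planted +
      rnorm(nrow(grid), sd = config$ct_noise_sd)
  })

  out <- data.frame(
    cell_line = cell_line,
    caf_id = cond$caf_id,
    cisplatin = cond$cisplatin,
    medium_kind = cond$medium_kind,
    gene = grid$gene,
    replicate = grid$replicate,
    ct = pmin(ct, 45),
    undetected = FALSE
  )
  rownames(out) <- NULL
  attr(out, "truth") <- lfc
  out
}

#' Generate a synthetic ICP-MS platinum concentration table
#'
#' Plants a per-CAF uptake fraction and efflux (release) fraction: the
#' medium measured after 24 h of treatment contains
#' `added * (1 - uptake_fraction)` uM of platinum, and the post-treatment
#' conditioned medium contains the effluxed share of the uptaken amount
#' divided by the medium volume. Gaussian concentration noise is added on
#' the undiluted scale and readings are then divided by `dilution_factor`,
#' mirroring the pre-analysis dilution of real samples; negative readings
#' are clipped at 0.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with one row per CAF and medium kind (`caf_id`,
#'   `medium_kind`, `concentration_um` as measured on the diluted sample,
#'   `dilution_factor`, `volume_ml`, `added_um`), with the planted
#'   per-CAF uptake and release amounts (nmol) as `attr(, "truth")`.
#' @export
generate_platinum_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_added <- config$added_concentration * config$medium_volume  # nmol

  truth <- data.frame(
    caf_id = config$caf_ids,
    true_uptake_nmol = n_added *
      unname(config$planted_uptake_fraction[config$caf_ids]),
    true_release_nmol = n_added *
      unname(config$planted_uptake_fraction[config$caf_ids]) *
      unname(config$release_fraction[config$caf_ids])
  )

  conc_post <- config$added_concentration - truth$true_uptake_nmol / config$medium_volume
  conc_release <- truth$true_release_nmol / config$medium_volume

  noisy <- withr::with_seed(derive_seed(config$seed, "platinum"), {
    c(conc_post, conc_release) +
      rnorm(2 * config$n_cafs, sd = config$conc_noise_sd)
  })
  noisy <- pmax(noisy, 0)

  out <- data.frame(
    caf_id = rep(config$caf_ids, 2),
    medium_kind = rep(c("CMCAF+cisplatin", "CMCAF_post-cisplatin"),
                      each = config$n_cafs),
    concentration_um = noisy / config$dilution_factor,
    dilution_factor = config$dilution_factor,
    volume_ml = config$medium_volume,
    added_um = config$added_concentration
  )
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}
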