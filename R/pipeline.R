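write_output_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cafsens seed=", seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Rolling polynomial hash over the JSON rendering of the configuration;
# enough to detect config drift between runs in the manifest.
config_digest <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (ch in utf8ToInt(as.character(txt))) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on synthetic or supplied inputs
#'
#' Drives every stage in order: input generation (when no tables are
#' supplied), schema validation, colony segmentation, sensitizing-ratio
#' scoring, comparative-Ct expression with the pairwise CAF baseline,
#' platinum mass balance with the recurrence group comparison, and the
#' statistical layer (paired treatment test, expression-area correlations,
#' two-component PCA over genes plus the sensitizing ratio, hierarchical
#' clustering). Stages whose inputs are absent are skipped with a warning,
#' never silently. With `out_dir` set, every table is written as CSV (with
#' the seed in a comment header) together with a JSON run manifest (seed,
#' configuration digest, package and R versions, stages run).
#'
#' @param config A [synthetic_config()]; also the source of the seed and
#'   dosing constants.
#' @param inputs Optional named list of pre-made inputs: `images` (list of
#'   [plate_image()]), `ct`, `platinum`, `clinical` data frames. `NULL`
#'   entries (or an entirely absent list) are synthesized from `config`;
#'   an entry set to `NA` skips that stage.
#' @param threshold,direction Segmentation parameters, see
#'   [segment_colonies()].
#' @param calibrator Calibrator condition for [relative_expression()].
#' @param out_dir Optional output directory, created if needed.
#' @return List with `measurements`, `sensitizing`, `expression`,
#'   `pairwise`, `platinum`, `stats` (paired test, correlations, PCA,
#'   clustering, recurrence comparison), `validation`, and `manifest`.
#' @export
run_pipeline <- function(config = synthetic_config(), inputs = list(),
                         threshold = -5, direction = "below",
                         calibrator = "fresh_medium", out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  skipped <- function(x) length(x) == 1L && !is.list(x) && is.na(x)
  stages <- character()

  get_input <- function(name, generator) {
    x <- inputs[[name]]
    if (skipped(x)) {
      warning("input '", name, "' marked unavailable; stage skipped",
              call. = FALSE)
      return(NULL)
    }
    if (is.null(x)) x <- generator()
    x
  }

  images <- get_input("images", function() {
    generate_colony_experiment(config)$images
  })
  ct <- get_input("ct", function() generate_ct_table(config))
  platinum <- get_input("platinum", function() generate_platinum_table(config))
  clinical <- get_input("clinical", clinical_fixture)

  validation <- validate_tables(list(ct = ct, platinum = platinum,
                                     clinical = clinical))
  if (nrow(validation)) {
    warning(nrow(validation), " validation problem(s) found; see the ",
            "'validation' element of the result", call. = FALSE)
  }

  measurements <- sensitizing <- NULL
  if (!is.null(images)) {
    measurements <- batch_measure(images, threshold = threshold,
                                  direction = direction)
    sensitizing <- sensitizing_table(measurements)
    stages <- c(stages, "segmentation", "scoring")
  }

  expression <- pairwise <- NULL
  if (!is.null(ct)) {
    expression <- relative_expression(ct, calibrator = calibrator)
    pairwise <- pairwise_baseline(expression)
    stages <- c(stages, "expression")
  }

  platinum_balance <- recurrence_cmp <- NULL
  if (!is.null(platinum)) {
    platinum_balance <- platinum_mass_balance(platinum)
    if (!is.null(clinical)) {
      rec <- clinical$recurrence[match(platinum_balance$caf_id,
                                       clinical$patient)]
      if (!anyNA(rec)) {
        recurrence_cmp <- list(
          uptake = compare_by_group(platinum_balance$n_uptake_nmol,
                                    rec == 1),
          release = compare_by_group(platinum_balance$n_released_nmol,
                                     rec == 1)
        )
      }
    }
    stages <- c(stages, "platinum")
  }

  stats_out <- list()
  if (!is.null(measurements)) {
    cc <- measurements[measurements$caf_id != "none", ]
    untreated <- cc$area_fraction[!cc$cisplatin][order(cc$caf_id[!cc$cisplatin])]
    treated <- cc$area_fraction[cc$cisplatin][order(cc$caf_id[cc$cisplatin])]
    if (length(untreated) >= 2L && length(untreated) == length(treated)) {
      stats_out$paired_cisplatin <- paired_test(untreated, treated)
    }
  }
  if (!is.null(pairwise) && !is.null(measurements)) {
    treated_arm <- pairwise[pairwise$arm == "treated", ]
    cis_areas <- measurements[measurements$caf_id != "none" &
                                measurements$cisplatin, ]
    if (nrow(cis_areas) >= 3L) {
      stats_out$correlations <- expression_area_correlation(
        treated_arm, cis_areas[, c("caf_id", "area_fraction")]
      )
    }
    mat <- expression_matrix(treated_arm)
    rownames(mat) <- sub(":treated$", "", rownames(mat))
    if (!is.null(sensitizing)) {
      mat <- cbind(mat, sensitizing_ratio =
                     sensitizing$ratio[match(rownames(mat),
                                             sensitizing$caf_id)])
    }
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) >= 3L) {
      stats_out$pca <- pca_two_components(mat, standardize = TRUE)
      stats_out$clustering <- cluster_heatmap(
        mat, file = if (!is.null(out_dir))
          file.path(out_dir, "expression_heatmap.png") else NULL)
      stats_out$expression_matrix <- mat
    }
    stages <- c(stages, "stats")
  }

  manifest <- list(
    seed = config$seed,
    config_digest = config_digest(config),
    package_version = as.character(packageVersion("cafsens")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    n_validation_problems = nrow(validation)
  )

  if (!is.null(out_dir)) {
    s <- config$seed
    if (!is.null(measurements))
      write_output_csv(measurements, file.path(out_dir, "measurements.csv"), s)
    if (!is.null(sensitizing))
      write_output_csv(sensitizing, file.path(out_dir, "sensitizing.csv"), s)
    if (!is.null(expression))
      write_output_csv(expression, file.path(out_dir, "expression_long.csv"), s)
    if (!is.null(pairwise))
      write_output_csv(pairwise, file.path(out_dir, "expression_pairwise.csv"), s)
    if (!is.null(platinum_balance))
      write_output_csv(platinum_balance, file.path(out_dir, "platinum.csv"), s)
    if (!is.null(stats_out$correlations))
      write_output_csv(stats_out$correlations,
                       file.path(out_dir, "correlations.csv"), s)
    if (!is.null(stats_out$pca)) {
      write_output_csv(as.data.frame(stats_out$pca$scores),
                       file.path(out_dir, "pca_scores.csv"), s)
      write_output_csv(as.data.frame(stats_out$pca$loadings),
                       file.path(out_dir, "pca_loadings.csv"), s)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(measurements = measurements, sensitizing = sensitizing,
       expression = expression, pairwise = pairwise,
       platinum = platinum_balance, recurrence = recurrence_cmp,
       stats = stats_out, validation = validation, manifest = manifest)
}
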