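#' Render a synthetic plate-well image with known colony mask
#'
#' Draws `n_colonies` filled stain-colored disks (log-normal radii, centers
#' uniform in the well) on a uniform background inside a circular well,
#' adds Gaussian pixel noise and clips to 0..255. The ground-truth colony
#' mask is taken before noise, so `true_area_fraction` is exactly the union
#' of colony disks intersected with the well, divided by the well area.
#' Overlapping disks merge; the area fraction is of the union.
#'
#' @param config A [synthetic_config()].
#' @param well_id Character label; also keys this well's RNG substream, so
#'   the same config and well id always reproduce the same raster.
#' @param n_colonies Number of colonies; default drawn uniformly from
#'   `config$colony_count_range`.
#' @param condition Optional [condition_label()] attached to the result.
#' @return A [plate_image] whose `truth` element holds the binary colony
#'   mask (`mask`) and `true_area_fraction`.
#' @examples
#' img <- generate_plate_image(synthetic_config(seed = 7), "demo")
#' img$truth$true_area_fraction
#' @export
generate_plate_image <- function(config, well_id, n_colonies = NULL,
                                 condition = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$image_size
  if (n <= 0) stop("image size must be positive", call. = FALSE)
  cx <- (n + 1) / 2
  r_well <- config$well_radius

  seed <- derive_seed(config$seed, paste0("plate:", well_id))
  withr::with_seed(seed, {
    if (is.null(n_colonies)) {
      rng <- config$colony_count_range
      n_colonies <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1L)
    }
    n_colonies <- as.integer(n_colonies)
    stopifnot(n_colonies >= 0L)

    # polar-uniform centers inside the well
    theta <- runif(n_colonies, 0, 2 * pi)
    rad <- r_well * sqrt(runif(n_colonies))
    centers_r <- cx + rad * sin(theta)
    centers_c <- cx + rad * cos(theta)
    radii <- rlnorm(n_colonies, config$colony_radius_meanlog,
                    config$colony_radius_sdlog)

    row_g <- matrix(seq_len(n), n, n)
    col_g <- matrix(seq_len(n), n, n, byrow = TRUE)
    well_mask <- (row_g - cx)^2 + (col_g - cx)^2 <= r_well^2

    mask <- matrix(FALSE, n, n)
    for (i in seq_len(n_colonies)) {
      mask <- mask |
        ((row_g - centers_r[i])^2 + (col_g - centers_c[i])^2 <= radii[i]^2)
    }
    mask <- mask & well_mask

    pixels <- array(0, dim = c(n, n, 3))
    for (k in 1:3) {
      plane <- matrix(config$background_color[k], n, n)
      plane[mask] <- config$stain_color[k]
      if (config$pixel_noise_sd > 0) {
        plane <- plane + rnorm(n * n, sd = config$pixel_noise_sd)
      }
      pixels[, , k] <- pmin(pmax(plane, 0), 255)
    }
  })

  img <- plate_image(pixels, well_mask = well_mask, well_id = well_id,
                     condition = condition)
  img$truth <- list(
    mask = mask,
    true_area_fraction = sum(mask) / sum(well_mask)
  )
  img
}

#' Generate a full synthetic clonogenic experiment
#'
#' Builds the well layout of the coculture assay: a non-cocultured control
#' pair (with / without cisplatin) plus one pair per CAF. Untreated colony
#' counts are drawn from `colony_count_range` and scaled by the per-CAF
#' `caf_area_effect`; treated counts are scaled by `cisplatin_survival`
#' and, under coculture, additionally by `2^-caf_sensitizing`, so each
#' CAF's planted sensitizing effect shapes the expected score. The planted
#' per-CAF sensitizing ratio reported in `$planted` is computed from the
#' realized ground-truth area fractions, so a noise-free analysis must
#' recover it exactly.
#'
#' @param config A [synthetic_config()].
#' @return List with `images` (list of [plate_image]), `truth` (data frame
#'   of per-well true area fractions and condition labels) and `planted`
#'   (data frame `caf_id`, `planted_ratio`).
#' @export
generate_colony_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- config$colony_count_range

  draw_n0 <- function(key) {
    withr::with_seed(derive_seed(config$seed, paste0("count:", key)), {
      if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    })
  }

  images <- list()
  rows <- list()
  add_well <- function(well_id, caf_id, cisplatin, medium_kind, n_colonies) {
    cond <- condition_label(caf_id, cisplatin, medium_kind)
    img <- generate_plate_image(config, well_id, n_colonies = n_colonies,
                                condition = cond)
    images[[well_id]] <<- img
    rows[[well_id]] <<- data.frame(
      well_id = well_id, caf_id = caf_id, cisplatin = cisplatin,
      medium_kind = medium_kind,
      true_area_fraction = img$truth$true_area_fraction
    )
  }

  n0_ctrl <- draw_n0("nc")
  add_well("nc_untreated", "none", FALSE, "fresh", n0_ctrl)
  add_well("nc_cisplatin", "none", TRUE, "fresh",
           max(1L, round(n0_ctrl * config$cisplatin_survival)))

  for (caf in config$caf_ids) {
    n0 <- round(draw_n0(caf) * 2^config$caf_area_effect[[caf]])
    surv <- config$cisplatin_survival * 2^(-config$caf_sensitizing[[caf]])
    add_well(paste0(caf, "_untreated"), caf, FALSE, "direct_coculture", max(1L, n0))
    add_well(paste0(caf, "_cisplatin"), caf, TRUE, "direct_coculture",
             max(1L, round(n0 * surv)))
  }

  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL

  frac <- setNames(truth$true_area_fraction, truth$well_id)
  planted <- data.frame(
    caf_id = config$caf_ids,
    planted_ratio = vapply(config$caf_ids, function(caf) {
      sensitizing_ratio(frac[[paste0(caf, "_cisplatin")]],
                        frac[[paste0(caf, "_untreated")]],
                        frac[["nc_cisplatin"]],
                        frac[["nc_untreated"]])
    }, numeric(1))
  )
  rownames(planted) <- NULL
  list(images = images, truth = truth, planted = planted)
}

#' Draw a synthetic one-dimensional flow-cytometry sample
#'
#' Emulates CD90 surface staining as log-normal fluorescence: an isotype
#' control centered at the background intensity and a stained sample in
#' which a planted fraction of events carries strong specific signal, the
#' rest following the background distribution.
#'
#' @param config A [synthetic_config()].
#' @param n_events Events per tube.
#' @param positive_fraction Planted fraction of marker-positive cells.
#' @param separation Log-intensity shift of the positive population.
#' @return List with `events`, `isotype_events` and
#'   `true_positive_fraction`.
#' @export
generate_flow_sample <- function(config, n_events = 10000,
                                 positive_fraction = 0.96,
                                 separation = 3) {
  stopifnot(inherits(config, "synthetic_config"),
            positive_fraction >= 0, positive_fraction <= 1)
  withr::with_seed(derive_seed(config$seed, "flow"), {
    iso <- rlnorm(n_events, meanlog = log(100), sdlog = 0.4)
    pos <- runif(n_events) < positive_fraction
    ev <- rlnorm(n_events, meanlog = log(100) + ifelse(pos, separation, 0),
                 sdlog = 0.4)
  })
  list(events = ev, isotype_events = iso,
       true_positive_fraction = mean(pos))
}
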