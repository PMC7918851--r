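#' Housekeeper reference Ct for one sample
#'
#' Aggregates the two housekeeping controls (ACTB, PSMB2) into a single
#' reference Ct by the arithmetic mean of their per-gene mean Ct values.
#' On the Ct (log2) scale this is equivalent to the geometric mean of the
#' two housekeepers' expression levels.
#'
#' @param records Data frame of Ct records for a single sample, with at
#'   least `gene` and `ct` columns.
#' @param sample_id Label used in error messages.
#' @return Reference Ct in cycles.
#' @examples
#' reference_ct(data.frame(gene = c("ACTB", "PSMB2"), ct = c(18, 22)))  # 20
#' @export
reference_ct <- function(records, sample_id = "sample") {
  missing <- setdiff(housekeeping_genes, records$gene)
  if (length(missing)) {
    stop("housekeeper(s) ", paste(missing, collapse = ", "),
         " not measured in ", sample_id, call. = FALSE)
  }
  per_gene <- vapply(housekeeping_genes, function(g) {
    mean(records$ct[records$gene == g])
  }, numeric(1))
  mean(per_gene)
}

#' Comparative-Ct log2 fold change
#'
#' Classic delta-delta-Ct with amplification efficiency fixed at 2: the
#' target's Ct is normalized to the housekeeper reference within the
#' sample and within the calibrator, and the difference of those deltas,
#' negated, is the log2 fold change (one cycle earlier = one doubling).
#'
#' @param target_ct_sample,ref_ct_sample Target and reference Ct in the
#'   sample of interest, cycles.
#' @param target_ct_cal,ref_ct_cal The same in the calibrator sample.
#' @return log2 fold change (vectorized).
#' @examples
#' log2_fold_change(19, 20, 20, 20)  # target one cycle earlier: +1
#' @export
log2_fold_change <- function(target_ct_sample, ref_ct_sample,
                             target_ct_cal, ref_ct_cal) {
  d_sample <- target_ct_sample - ref_ct_sample
  d_cal <- target_ct_cal - ref_ct_cal
  -(d_sample - d_cal)
}

#' Normalize undetected qPCR assays
#'
#' Undetected reactions (no amplification within the 45-cycle program) are
#' set to Ct = 45 and keep their `undetected` flag, so they enter replicate
#' means as a detection-limit censoring value rather than as missing data.
#' Ct values above 45 are invalid and rejected.
#'
#' @param records Data frame with `ct` and `undetected` columns.
#' @return The records with `ct` filled to 45 where undetected.
#' @export
handle_undetected <- function(records) {
  stopifnot(all(c("ct", "undetected") %in% names(records)))
  if (any(records$ct > 45, na.rm = TRUE))
    stop("Ct values above the 45-cycle maximum are invalid", call. = FALSE)
  records$undetected <- records$undetected | is.na(records$ct)
  records$ct[records$undetected] <- 45
  records
}

sample_key <- function(df) {
  paste(df$cell_line, df$caf_id, df$cisplatin, df$medium_kind, sep = "|")
}

#' Relative expression table by the comparative Ct method
#'
#' Computes per-gene log2 fold changes for every condition in a Ct table
#' against a chosen calibrator condition, using the dual-housekeeper
#' reference of [reference_ct()]. Replicates are averaged to a mean Ct per
#' gene and sample before the delta-delta step; a per-replicate breakdown
#' (replicate-wise delta Ct against the calibrator's mean delta) is kept
#' for the one-sample t-tests, and its spread provides the standard error.
#' Genes whose replicates are all undetected in a condition yield `NA`
#' (not infinite) fold changes.
#'
#' @param ct Data frame of Ct records: `cell_line`, `caf_id`, `cisplatin`,
#'   `medium_kind`, `gene`, `replicate`, `ct`, `undetected`.
#' @param calibrator `"fresh_medium"`, `"depleted_medium"`, or a
#'   one-row data frame (`caf_id`, `cisplatin`, `medium_kind`) naming any
#'   condition in the table.
#' @return Data frame with one row per condition and target gene:
#'   `cell_line`, `caf_id`, `cisplatin`, `medium_kind`, `gene`, `log2fc`,
#'   `se`, `n_replicates`, `n_undetected`, `calibrator`. Replicate-level
#'   fold changes are attached as `attr(, "replicates")`.
#' @export
relative_expression <- function(ct, calibrator = c("fresh_medium",
                                                   "depleted_medium")) {
  need <- c("cell_line", "caf_id", "cisplatin", "medium_kind", "gene",
            "replicate", "ct", "undetected")
  stopifnot(all(need %in% names(ct)))
  ct <- handle_undetected(ct)

  if (is.character(calibrator)) {
    calibrator <- match.arg(calibrator)
    cal_label <- calibrator
    cal_sel <- data.frame(
      caf_id = "none", cisplatin = FALSE,
      medium_kind = if (calibrator == "fresh_medium") "fresh" else "depleted"
    )
  } else {
    stopifnot(is.data.frame(calibrator), nrow(calibrator) == 1L)
    cal_sel <- calibrator
    cal_label <- with(cal_sel, paste0(caf_id, "/", medium_kind,
                                      if (cisplatin) "+cisplatin" else ""))
  }

  targets <- setdiff(unique(ct$gene), housekeeping_genes)
  out <- list()
  reps_out <- list()

  for (line in unique(ct$cell_line)) {
    sub <- ct[ct$cell_line == line, ]
    cal <- sub[sub$caf_id == cal_sel$caf_id &
                 sub$cisplatin == cal_sel$cisplatin &
                 sub$medium_kind == cal_sel$medium_kind, ]
    if (!nrow(cal))
      stop("calibrator condition (", cal_label, ") absent for cell line ",
           line, call. = FALSE)
    ref_cal <- reference_ct(cal, paste0(line, " calibrator"))
    cal_mean_ct <- vapply(targets, function(g) {
      v <- cal$ct[cal$gene == g]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))

    keys <- unique(sub[, c("caf_id", "cisplatin", "medium_kind")])
    for (i in seq_len(nrow(keys))) {
      smp <- sub[sub$caf_id == keys$caf_id[i] &
                   sub$cisplatin == keys$cisplatin[i] &
                   sub$medium_kind == keys$medium_kind[i], ]
      sid <- paste(line, keys$caf_id[i], keys$medium_kind[i],
                   if (keys$cisplatin[i]) "+cis" else "-cis")
      ref_smp <- reference_ct(smp, sid)

      for (g in targets) {
        rec <- smp[smp$gene == g, ]
        if (!nrow(rec) || is.na(cal_mean_ct[[g]])) next
        all_nd <- all(rec$undetected)
        lfc <- if (all_nd) NA_real_ else
          log2_fold_change(mean(rec$ct), ref_smp, cal_mean_ct[[g]], ref_cal)

        # replicate-wise: pair each target replicate with its replicate's
        # housekeeper mean where available, else the sample-level reference
        rep_ref <- vapply(rec$replicate, function(r) {
          hk <- smp[smp$gene %in% housekeeping_genes & smp$replicate == r, ]
          if (nrow(hk) == length(housekeeping_genes))
            reference_ct(hk, sid) else ref_smp
        }, numeric(1))
        rep_lfc <- log2_fold_change(rec$ct, rep_ref,
                                    cal_mean_ct[[g]], ref_cal)
        se <- if (all_nd || length(rep_lfc) < 2L) NA_real_ else
          sd(rep_lfc) / sqrt(length(rep_lfc))

        out[[length(out) + 1L]] <- data.frame(
          cell_line = line, caf_id = keys$caf_id[i],
          cisplatin = keys$cisplatin[i], medium_kind = keys$medium_kind[i],
          gene = g, log2fc = lfc, se = se,
          n_replicates = nrow(rec), n_undetected = sum(rec$undetected),
          calibrator = cal_label
        )
        if (!all_nd) {
          reps_out[[length(reps_out) + 1L]] <- data.frame(
            cell_line = line, caf_id = keys$caf_id[i],
            cisplatin = keys$cisplatin[i], medium_kind = keys$medium_kind[i],
            gene = g, replicate = rec$replicate, log2fc = rep_lfc
          )
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "replicates") <- {
    r <- do.call(rbind, reps_out)
    if (!is.null(r)) rownames(r) <- NULL
    r
  }
  res
}

#' Re-baseline expression pairwise against each CAF's untreated arm
#'
#' Removes the among-CAF coculture effect before asking what cisplatin
#' does: for every CAF and gene, the expression of the cisplatin-influenced
#' arm is expressed relative to the same CAF's no-cisplatin arm, so each
#' CAF's untreated condition maps to exactly 0 by construction. On the log2
#' scale this is simply the difference of the two arms' fold changes
#' (any common calibrator cancels).
#'
#' @param expr Expression table from [relative_expression()].
#' @param baseline_kind Medium kind of the untreated arm (default
#'   `"CMCAF"`).
#' @param treated_kind Medium kind of the cisplatin-influenced arm
#'   (default `"CMCAF_post-cisplatin"`).
#' @return Data frame with `cell_line`, `caf_id`, `arm` (`"baseline"` or
#'   `"treated"`), `gene`, `log2fc` (0 for every baseline row), and
#'   `calibrator = "caf_no_cisplatin_pairwise"`.
#' @export
pairwise_baseline <- function(expr, baseline_kind = "CMCAF",
                              treated_kind = "CMCAF_post-cisplatin") {
  stopifnot(all(c("caf_id", "medium_kind", "gene", "log2fc") %in% names(expr)))
  cafs <- setdiff(unique(expr$caf_id), "none")
  out <- list()
  for (line in unique(expr$cell_line)) {
    sub <- expr[expr$cell_line == line, ]
    for (caf in cafs) {
      base <- sub[sub$caf_id == caf & sub$medium_kind == baseline_kind, ]
      trt <- sub[sub$caf_id == caf & sub$medium_kind == treated_kind, ]
      if (!nrow(base) || !nrow(trt)) {
        stop("CAF ", caf, " is unpaired: needs both ", baseline_kind,
             " and ", treated_kind, " arms", call. = FALSE)
      }
      genes <- intersect(base$gene, trt$gene)
      b <- setNames(base$log2fc, base$gene)
      tr <- setNames(trt$log2fc, trt$gene)
      out[[length(out) + 1L]] <- data.frame(
        cell_line = line, caf_id = caf,
        arm = rep(c("baseline", "treated"), each = length(genes)),
        gene = rep(genes, 2),
        log2fc = c(rep(0, length(genes)), unname(tr[genes] - b[genes])),
        calibrator = "caf_no_cisplatin_pairwise"
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wide gene-by-condition matrix from a long expression table
#'
#' @param expr Long table with `caf_id` (plus optional `arm`), `gene`,
#'   `log2fc`.
#' @param rows `"caf"` for CAF-by-gene (samples in rows, the PCA/heatmap
#'   orientation) .
#' @return Numeric matrix, rownames = sample labels, colnames = genes.
#' @export
expression_matrix <- function(expr, rows = "caf") {
  lab <- if ("arm" %in% names(expr)) {
    paste(expr$caf_id, expr$arm, sep = ":")
  } else {
    paste(expr$caf_id, expr$medium_kind, sep = ":")
  }
  genes <- unique(expr$gene)
  labs <- unique(lab)
  m <- matrix(NA_real_, length(labs), length(genes),
              dimnames = list(labs, genes))
  m[cbind(match(lab, labs), match(expr$gene, genes))] <- expr$log2fc
  m
}
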