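#' One-sample t-test on replicate log2 fold changes
#'
#' Tests whether a gene's replicate fold changes differ from a null value
#' (0 = no change vs the calibrator).
#'
#' @param x Numeric replicates.
#' @param mu Null value (default 0).
#' @return List `t`, `df`, `p`, `estimate`, `n`.
#' @export
one_sample_test <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least two replicates", call. = FALSE)
  if (sd(x) == 0) stop("degenerate test: zero variance in replicates",
                       call. = FALSE)
  tt <- t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       estimate = mean(x), n = length(x))
}

#' Paired t-test on per-CAF condition pairs
#'
#' Compares a per-CAF quantity between two matched conditions (for example
#' colony area with and without cisplatin, pairing by CAF).
#'
#' @param x,y Numeric vectors of equal length, paired by position.
#' @return List `t`, `df`, `p`, `mean_difference`, `n`.
#' @export
paired_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0 && mean(d) == 0) {
    return(list(t = 0, df = length(d) - 1, p = 1, mean_difference = 0,
                n = length(d)))
  }
  if (sd(d) == 0) stop("degenerate test: zero variance in differences",
                       call. = FALSE)
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_difference = mean(d), n = length(d))
}

#' Floor zero area fractions before log transform
#'
#' Zero colony areas have no logarithm; they are floored at half the
#' smallest nonzero observed fraction and flagged, the standard small-count
#' treatment for log-scale phenotypes.
#'
#' @param area_fraction Numeric in \[0, 1\].
#' @return List `value` (floored fractions) and `floored` (logical flags).
#' @export
floor_area_fractions <- function(area_fraction) {
  nz <- area_fraction[area_fraction > 0 & !is.na(area_fraction)]
  if (!length(nz)) stop("all area fractions are zero", call. = FALSE)
  fl <- min(nz) / 2
  flag <- !is.na(area_fraction) & area_fraction == 0
  list(value = ifelse(flag, fl, area_fraction), floored = flag)
}

#' Correlate gene expression with log2 colony area across CAFs
#'
#' For each gene, computes the Pearson correlation between per-CAF log2
#' fold changes and the log2-transformed colony-area fraction of the
#' matching wells, dropping missing pairs. Optionally adjusts p-values by
#' Benjamini-Hochberg; by default raw p-values are reported.
#'
#' @param expr Long expression table (`caf_id`, `gene`, `log2fc`), e.g.
#'   from [relative_expression()] filtered to one condition set.
#' @param areas Data frame with `caf_id` and `area_fraction` (one row per
#'   CAF; replicate wells are averaged).
#' @param adjust Apply Benjamini-Hochberg across genes (default FALSE).
#' @return Data frame `gene`, `r`, `p`, `p_adj` (if requested), `n`.
#' @export
expression_area_correlation <- function(expr, areas, adjust = FALSE) {
  stopifnot(all(c("caf_id", "gene", "log2fc") %in% names(expr)),
            all(c("caf_id", "area_fraction") %in% names(areas)))
  shared <- intersect(unique(expr$caf_id), unique(areas$caf_id))
  if (!length(shared)) stop("no matching CAF ids between tables",
                            call. = FALSE)
  area_by_caf <- tapply(areas$area_fraction, areas$caf_id, mean)[shared]
  log_area <- log2(floor_area_fractions(area_by_caf)$value)

  genes <- unique(expr$gene)
  rows <- lapply(genes, function(g) {
    sub <- expr[expr$gene == g & expr$caf_id %in% shared, ]
    lfc <- setNames(sub$log2fc, sub$caf_id)[shared]
    keep <- !is.na(lfc) & !is.na(log_area)
    n <- sum(keep)
    if (n < 3L) {
      return(data.frame(gene = g, r = NA_real_, p = NA_real_, n = n))
    }
    if (sd(lfc[keep]) == 0 || sd(log_area[keep]) == 0) {
      return(data.frame(gene = g, r = NA_real_, p = NA_real_, n = n))
    }
    ct <- cor.test(lfc[keep], log_area[keep], method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value, n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Two-component principal component analysis
#'
#' Column-centered (optionally unit-scaled) SVD-based PCA truncated to the
#' first two components, the standard low-dimensional view of a
#' sample-by-gene expression matrix.
#'
#' @param m Numeric sample-by-variable matrix; rows with missing values
#'   are dropped.
#' @param standardize Scale columns to unit variance (default FALSE).
#' @return List of class `pca_result`: `scores` (samples x 2), `loadings`
#'   (variables x 2, orthonormal), `explained_variance` (proportions,
#'   non-increasing), `sdev`.
#' @export
pca_two_components <- function(m, standardize = FALSE) {
  m <- as.matrix(m)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least two complete samples", call. = FALSE)
  if (standardize) {
    v <- apply(m, 2, sd)
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = standardize)
  k <- min(2L, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance = ev[seq_len(k)],
    sdev = pc$sdev
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$scores), "samples,",
      nrow(x$loadings), "variables\n")
  cat("  explained variance:",
      paste0(format(100 * x$explained_variance, digits = 3), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of a matrix with optional heatmap
#'
#' Agglomerative clustering of rows and columns; leaf orders and the
#' dendrograms are returned so downstream code does not depend on the
#' plotting layer. When `file` is given and the pheatmap package is
#' available, a clustered heatmap is rendered.
#'
#' @param m Numeric matrix.
#' @param distance Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @param scale_rows Standardize rows before clustering/plotting
#'   (z-scores); default FALSE keeps raw log2 values.
#' @param file Optional PNG path for the heatmap.
#' @return List `row_order`, `col_order` (integer leaf orders),
#'   `row_hclust`, `col_hclust`, and `file` (or NULL).
#' @export
cluster_heatmap <- function(m, distance = "euclidean", linkage = "complete",
                            scale_rows = FALSE, file = NULL) {
  m <- as.matrix(m)
  if (scale_rows) {
    mu <- rowMeans(m, na.rm = TRUE)
    s <- apply(m, 1, sd, na.rm = TRUE)
    s[s == 0 | is.na(s)] <- 1
    m <- (m - mu) / s
  }
  rh <- hclust(dist(m, method = distance), method = linkage)
  ch <- hclust(dist(t(m), method = distance), method = linkage)
  rendered <- NULL
  if (!is.null(file)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(file, width = 900, height = 700, res = 110)
      pheatmap::pheatmap(m, clustering_distance_rows = distance,
                         clustering_distance_cols = distance,
                         clustering_method = linkage, silent = FALSE)
      grDevices::dev.off()
      rendered <- file
    } else {
      warning("pheatmap not available; heatmap figure skipped")
    }
  }
  list(row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch, file = rendered)
}

#' Cut a clustering into k groups
#'
#' Thin wrapper over [stats::cutree()] on the row dendrogram of
#' [cluster_heatmap()].
#'
#' @param clustering Result of [cluster_heatmap()].
#' @param k Number of groups.
#' @param what `"rows"` or `"cols"`.
#' @return Integer group memberships named by the matrix labels.
#' @export
cluster_cut <- function(clustering, k, what = c("rows", "cols")) {
  what <- match.arg(what)
  h <- if (what == "rows") clustering$row_hclust else clustering$col_hclust
  stats::cutree(h, k = k)
}

#' Marker positivity by isotype gating
#'
#' Reproduces the flow-cytometry gating convention: the positivity gate is
#' a high quantile of the isotype-control fluorescence, and the positive
#' fraction is the share of stained-sample events above it.
#'
#' @param events Fluorescence intensities of the stained sample.
#' @param isotype_events Intensities of the isotype control.
#' @param gate_quantile Quantile of the isotype distribution defining the
#'   gate (default 0.99, i.e. 1 percent false-positive allowance).
#' @return List `fraction`, `gate`, `n_events`.
#' @export
cd90_positivity <- function(events, isotype_events, gate_quantile = 0.99) {
  stopifnot(length(events) > 0, length(isotype_events) > 0,
            gate_quantile > 0, gate_quantile < 1)
  gate <- unname(quantile(isotype_events, gate_quantile, type = 7))
  list(fraction = mean(events > gate), gate = gate,
       n_events = length(events))
}

#' Significance stars for p-values
#'
#' Standard annotation: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' empty otherwise.
#'
#' @param p Numeric p-values.
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}
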