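# Per-cell 5fCpG identification: control-rate estimation, candidate/noise
# pools, SNP masking, exact binomial test against the lambda background with
# Holm-Bonferroni correction, unmodified-CpG calls, and false-positive
# accounting from untreated cells.

#' Calling thresholds
#'
#' Bundles the gates of the 5fCpG calling scheme. Defaults follow the
#' published scheme: candidate sites need a C-to-T ratio >= 0.65, unmodified
#' calls a ratio <= 0.25, per-cell calls depth >= 3, the lambda background
#' uses sites covered >= 4 times, pool membership requires the ratio gate in
#' at least 2 cells, and final calls need a Holm-Bonferroni adjusted
#' p < 0.01.
#'
#' @param ratio_min Minimum C-to-T ratio for candidate sites and pools.
#' @param ratio_unmod_max Maximum ratio for an unmodified-C call.
#' @param min_depth_call Minimum depth for per-cell candidate and unmodified
#'   calls.
#' @param min_depth_lambda Minimum depth for lambda C sites entering the
#'   background-rate estimate.
#' @param min_cells_pool Cells that must pass the ratio gate for pool
#'   membership.
#' @param adj_p_max Adjusted p-value cut-off.
#' @return A `calling_config` list.
#' @export
calling_config <- function(ratio_min = 0.65, ratio_unmod_max = 0.25,
                           min_depth_call = 3L, min_depth_lambda = 4L,
                           min_cells_pool = 2L, adj_p_max = 0.01) {
  check_prob(c(ratio_min, ratio_unmod_max, adj_p_max),
             "ratio_min/ratio_unmod_max/adj_p_max")
  if (!(ratio_unmod_max < ratio_min)) {
    stop_fcpg("invalid parameter: ratio_unmod_max must be < ratio_min")
  }
  if (min_depth_call < 1 || min_depth_lambda < 1 || min_cells_pool < 1) {
    stop_fcpg("invalid parameter: depth and cell-count gates must be >= 1")
  }
  structure(list(ratio_min = ratio_min, ratio_unmod_max = ratio_unmod_max,
                 min_depth_call = as.integer(min_depth_call),
                 min_depth_lambda = as.integer(min_depth_lambda),
                 min_cells_pool = as.integer(min_cells_pool),
                 adj_p_max = adj_p_max),
            class = "calling_config")
}

subset_control <- function(control, which_kind) {
  if ("kind" %in% names(control)) {
    control <- control[control$kind == which_kind, , drop = FALSE]
  }
  control
}

#' Estimate labeling (conversion) efficiency from spike-in model DNA
#'
#' The spike-in molecule carries known 5fC positions; the conversion rate is
#' the fraction of reads over those positions that read out T.
#'
#' @param spikein Control table with columns `pos`, `is_5fC`, `count_C`,
#'   `count_T` (and optionally `kind`, filtered to `"spike_in"`).
#' @return Conversion rate in `[0, 1]`.
#' @export
estimate_conversion_rate <- function(spikein) {
  sp <- subset_control(spikein, "spike_in")
  sp <- sp[as.logical(sp$is_5fC), , drop = FALSE]
  total <- sum(sp$count_C + sp$count_T)
  if (total < 1) {
    stop_fcpg("undefined rate: no reads over true-5fC spike-in positions")
  }
  sum(sp$count_T) / total
}

#' Estimate the random C-to-T background rate from lambda DNA
#'
#' Restricts to lambda C sites covered at least `min_depth_lambda` times
#' (default 4, to avoid sequencing errors at shallow sites) and returns total
#' T read-outs over total read-outs at those sites. This per-read error
#' probability is the binomial null parameter of the calling test.
#'
#' @param lambda_counts Control table with columns `pos`, `count_C`,
#'   `count_T` (and optionally `kind`, filtered to `"lambda"`).
#' @param cfg A [calling_config()].
#' @return Background rate in `[0, 1]`.
#' @export
estimate_background_rate <- function(lambda_counts, cfg = calling_config()) {
  la <- subset_control(lambda_counts, "lambda")
  depth <- la$count_C + la$count_T
  la <- la[depth >= cfg$min_depth_lambda, , drop = FALSE]
  total <- sum(la$count_C + la$count_T)
  if (total < 1) {
    stop_fcpg("undefined rate: no lambda C site covered >= ",
              cfg$min_depth_lambda, " times")
  }
  sum(la$count_T) / total
}

#' Build a candidate or noise site pool
#'
#' A CpG site enters the pool when its C-to-T ratio is at least
#' `ratio_min` in at least `min_cells_pool` of the supplied cells. The
#' candidate pool (treated cells) removes PCR amplification errors; the noise
#' pool (untreated cells) captures background artifacts to subtract. No depth
#' floor applies here beyond depth >= 1 (the ratio is undefined otherwise);
#' the depth >= 3 gate is applied later, per cell.
#'
#' @param cells List of per-cell count data.frames
#'   (`chrom,pos,count_C,count_T`). Use treated cells for the candidate
#'   pool, untreated for the noise pool.
#' @param kind `"candidate"` or `"noise"` (label only).
#' @param cfg A [calling_config()].
#' @return data.frame of pool sites (`chrom`, `pos`), attribute `kind`.
#' @export
build_pool <- function(cells, kind = c("candidate", "noise"),
                       cfg = calling_config()) {
  kind <- match.arg(kind)
  if (length(cells) == 0L) {
    warning("empty cell list: returning an empty ", kind, " pool",
            call. = FALSE)
    return(structure(empty_sites(), kind = kind))
  }
  passed <- lapply(cells, function(x) {
    depth <- x$count_C + x$count_T
    ok <- depth > 0 & x$count_T / pmax(depth, 1L) >= cfg$ratio_min
    site_key(x$chrom[ok], x$pos[ok])
  })
  tab <- table(unlist(passed, use.names = FALSE))
  keys <- names(tab)[tab >= cfg$min_cells_pool]
  if (!length(keys)) return(structure(empty_sites(), kind = kind))
  parts <- strsplit(keys, ":", fixed = TRUE)
  pool <- order_sites(data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L))))
  structure(pool, kind = kind)
}

#' Upper-tail binomial p-value for observed T read-outs
#'
#' Probability of observing at least `nt` T read-outs among `nt + nc` reads
#' when every read converts at the random background rate `p0`:
#' `P(X >= nt)` for `X ~ Binomial(nt + nc, p0)`. This is the chance of seeing
#' the site's conversion (or more) by background noise alone.
#'
#' @param nt Reads supporting T (vectorized).
#' @param nc Reads supporting C.
#' @param p0 Background conversion rate, strictly inside (0, 1).
#' @return Vector of p-values.
#' @export
binomial_pvalue <- function(nt, nc, p0) {
  check_counts(nt, "nt")
  check_counts(nc, "nc")
  check_prob(p0, "p0", open = TRUE)
  if (any(nt + nc < 1)) {
    stop_fcpg("invalid parameter: nt + nc must be >= 1")
  }
  pbinom(nt - 1, nt + nc, p0, lower.tail = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Adjusted p-values in input order: with p-values sorted ascending, the
#' i-th adjusted value is the running maximum of `(m - j + 1) * p_(j)` for
#' `j <= i`, capped at 1.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in input order (empty in, empty out).
#' @export
holm_bonferroni <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  check_prob(pvals, "pvals")
  p.adjust(pvals, method = "holm")
}

#' Call 5fCpG and unmodified CpG sites in one cell
#'
#' Candidate sites are CpGs covered at least `min_depth_call` times with
#' C-to-T ratio >= `ratio_min`, present in the candidate pool, absent from
#' the noise pool and not masked as SNPs. Each candidate gets an upper-tail
#' binomial p-value against the cell's lambda background rate;
#' Holm-Bonferroni adjustment runs across this cell's candidates only, and
#' sites with adjusted p below `adj_p_max` are the cell's final 5fCpG sites.
#' CpGs covered >= `min_depth_call` with ratio <= `ratio_unmod_max` (and not
#' SNP-masked) are called unmodified. Abundance is final 5fCpG sites over all
#' sequenced CpGs (depth >= 1). Untreated cells may be run through the same
#' procedure to model false positives.
#'
#' @param cell Count data.frame (`chrom,pos,count_C,count_T`).
#' @param candidate Candidate pool from [build_pool()].
#' @param noise Noise pool (or `NULL` when no untreated cells exist).
#' @param snp_mask data.frame of masked sites (`chrom`, `pos`) or `NULL`.
#' @param qc List or one-row data.frame carrying `background_rate`.
#' @param cfg A [calling_config()].
#' @param cell_id Identifier stored in the result.
#' @return An `fc_calls` object: `fc_sites` (with counts and raw/adjusted
#'   p-values), `unmod_sites`, `sequenced_cpg`, `abundance`, and per-gate
#'   attrition counters in `gates`.
#' @export
call_cell <- function(cell, candidate, noise = NULL, snp_mask = NULL,
                      qc, cfg = calling_config(),
                      cell_id = attr(cell, "cell_id") %||% "cell") {
  p0 <- qc$background_rate
  if (is.null(p0) || !is.finite(p0)) {
    stop_fcpg("configuration error: qc$background_rate is missing")
  }
  depth <- cell$count_C + cell$count_T
  cov <- cell[depth > 0, , drop = FALSE]
  depth <- depth[depth > 0]
  ratio <- cov$count_T / depth
  key <- site_key(cov$chrom, cov$pos)

  in_snp <- if (is.null(snp_mask) || nrow(snp_mask) == 0L) {
    rep(FALSE, nrow(cov))
  } else key %in% site_key(snp_mask$chrom, snp_mask$pos)
  deep <- depth >= cfg$min_depth_call
  high <- ratio >= cfg$ratio_min
  in_cand <- if (is.null(candidate) || nrow(candidate) == 0L) {
    rep(FALSE, nrow(cov))
  } else key %in% site_key(candidate$chrom, candidate$pos)
  in_noise <- if (is.null(noise) || nrow(noise) == 0L) {
    rep(FALSE, nrow(cov))
  } else key %in% site_key(noise$chrom, noise$pos)

  cand <- deep & high & in_cand & !in_noise & !in_snp
  fc <- cov[cand, c("chrom", "pos", "count_C", "count_T"), drop = FALSE]
  if (nrow(fc)) {
    fc$p_raw <- binomial_pvalue(fc$count_T, fc$count_C, p0)
    fc$p_adj <- holm_bonferroni(fc$p_raw)
    fc <- fc[fc$p_adj < cfg$adj_p_max, , drop = FALSE]
  } else {
    fc$p_raw <- numeric(0)
    fc$p_adj <- numeric(0)
  }
  rownames(fc) <- NULL

  unmod <- order_sites(
    cov[deep & ratio <= cfg$ratio_unmod_max & !in_snp, c("chrom", "pos"),
        drop = FALSE])

  sequenced <- nrow(cov)
  gates <- c(sequenced = sequenced, depth_pass = sum(deep),
             ratio_pass = sum(deep & high),
             in_pool = sum(deep & high & in_cand),
             after_noise = sum(deep & high & in_cand & !in_noise),
             candidates = sum(cand), hb_pass = nrow(fc))

  structure(list(cell_id = cell_id, fc_sites = fc, unmod_sites = unmod,
                 sequenced_cpg = sequenced,
                 abundance = if (sequenced > 0) nrow(fc) / sequenced
                             else NA_real_,
                 gates = gates),
            class = "fc_calls")
}

#' @export
print.fc_calls <- function(x, ...) {
  cat("fc_calls <", x$cell_id, ">: ", nrow(x$fc_sites), " 5fCpG, ",
      nrow(x$unmod_sites), " unmodified, ", x$sequenced_cpg,
      " sequenced CpG (abundance ",
      formatC(x$abundance, digits = 4, format = "g"), ")\n", sep = "")
  invisible(x)
}

#' False-positive detection rate
#'
#' Untreated (negative control) cells run through the identical calling
#' procedure still accrue some calls; the ratio of their mean 5fCpG abundance
#' to the treated cells' mean abundance measures the scheme's false-positive
#' detection rate.
#'
#' @param treated,untreated Lists of `fc_calls` objects.
#' @return Mean untreated abundance divided by mean treated abundance.
#' @export
false_positive_detection_rate <- function(treated, untreated) {
  if (!length(treated) || !length(untreated)) {
    stop_fcpg("both treated and untreated call sets are required")
  }
  ab <- function(x) vapply(x, function(c) c$abundance, numeric(1))
  mt <- mean(ab(treated))
  mu <- mean(ab(untreated))
  if (!is.finite(mt) || mt <= 0) {
    stop_fcpg("undefined rate: mean treated abundance is zero")
  }
  mu / mt
}

#' Per-cell QC: conversion and background rates
#'
#' Computes each cell's spike-in conversion rate and lambda background rate.
#' Cells without qualifying lambda sites fall back to the rate pooled across
#' all cells' qualifying lambda sites. A treated cell is flagged unusable
#' when its background rate is not below its conversion rate.
#'
#' @param controls Named list of per-cell control tables (as produced by
#'   [simulate_cells()] or [read_controls()]).
#' @param manifest data.frame with `cell_id` and `treatment`.
#' @param cfg A [calling_config()].
#' @return data.frame: cell_id, treatment, conversion_rate, background_rate,
#'   background_source ("cell" or "pooled"), flagged.
#' @export
compute_qc <- function(controls, manifest, cfg = calling_config()) {
  stopifnot(all(manifest$cell_id %in% names(controls)))
  pooled <- tryCatch({
    qual <- lapply(controls, function(x) {
      la <- subset_control(x, "lambda")
      la[la$count_C + la$count_T >= cfg$min_depth_lambda, , drop = FALSE]
    })
    all_la <- do.call(rbind, qual)
    if (is.null(all_la) || sum(all_la$count_C + all_la$count_T) < 1) {
      NA_real_
    } else sum(all_la$count_T) / sum(all_la$count_C + all_la$count_T)
  }, error = function(e) NA_real_)

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$cell_id[i]
    ctl <- controls[[id]]
    conv <- tryCatch(estimate_conversion_rate(ctl),
                     error = function(e) NA_real_)
    bg <- tryCatch(estimate_background_rate(ctl, cfg),
                   error = function(e) NA_real_)
    src <- if (is.na(bg)) "pooled" else "cell"
    if (is.na(bg)) bg <- pooled
    data.frame(cell_id = id, treatment = manifest$treatment[i],
               conversion_rate = conv, background_rate = bg,
               background_source = src,
               flagged = is.na(bg) ||
                 (manifest$treatment[i] == "treated" &&
                    (is.na(conv) || bg >= conv)))
  })
  do.call(rbind, rows)
}
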