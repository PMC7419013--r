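spike <- function(nt, nc, is_fc = TRUE) {
  data.frame(kind = "spike_in", pos = seq_along(nt), is_5fC = is_fc,
             count_C = as.integer(nc), count_T = as.integer(nt))
}
lambda <- function(nt, nc) {
  data.frame(kind = "lambda", pos = seq_along(nt), is_5fC = FALSE,
             count_C = as.integer(nc), count_T = as.integer(nt))
}

test_that("conversion rate is the T fraction at true-5fC spike positions", {
  expect_equal(estimate_conversion_rate(spike(16, 4)), 0.8)
  expect_equal(estimate_conversion_rate(spike(c(5, 7), c(0, 0))), 1.0)
  expect_equal(estimate_conversion_rate(spike(c(3, 2), c(1, 2))), 5 / 8)
  # non-5fC positions never contribute
  mixed <- rbind(spike(10, 0, TRUE), spike(0, 50, FALSE))
  expect_equal(estimate_conversion_rate(mixed), 1.0)
  expect_error(estimate_conversion_rate(spike(0, 0)), "undefined rate")
})

test_that("background rate uses only lambda sites covered >= 4 times", {
  expect_equal(estimate_background_rate(lambda(23, 1977)), 0.0115)
  # a depth-3 site is excluded from numerator and denominator alike
  la <- lambda(c(2, 3), c(2, 0))
  expect_equal(estimate_background_rate(la), 2 / 4)
  expect_equal(estimate_background_rate(lambda(0, 2000)), 0.0)
  expect_error(estimate_background_rate(lambda(1, 2)), "undefined rate")
})

test_that("pool membership needs the ratio gate in >= 2 cells", {
  cells <- list(make_cell(100, 7, 3),    # ratio 0.70
                make_cell(100, 5, 5),    # ratio 0.50
                make_cell(100, 33, 17))  # ratio 0.66
  pool <- build_pool(cells, "candidate")
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$pos, 100L)
  cells[[3]] <- make_cell(100, 6, 4)     # ratio 0.60: only one cell passes
  expect_equal(nrow(build_pool(cells, "candidate")), 0L)
  expect_warning(empty <- build_pool(list(), "noise"), "empty cell list")
  expect_equal(nrow(empty), 0L)
})

test_that("binomial p-value matches hand-derived cases", {
  expect_equal(binomial_pvalue(0, 5, 0.0115), 1.0)
  expect_equal(binomial_pvalue(2, 1, 0.1), 0.028, tolerance = 1e-12)
  expect_equal(binomial_pvalue(5, 0, 0.0115), 0.0115^5, tolerance = 1e-12)
  expect_error(binomial_pvalue(1, 1, 0), "invalid parameter")
  expect_error(binomial_pvalue(1, 1, 1), "invalid parameter")
  expect_error(binomial_pvalue(0, 0, 0.5), "invalid parameter")
})

test_that("Holm-Bonferroni adjustment follows the stepwise definition", {
  expect_equal(holm_bonferroni(0.02), 0.02)
  expect_equal(holm_bonferroni(c(0.004, 0.003, 0.02)),
               c(0.009, 0.009, 0.02))
  expect_equal(holm_bonferroni(rep(1, 5)), rep(1, 5))
  expect_identical(holm_bonferroni(numeric(0)), numeric(0))
})

test_that("per-cell calling applies every gate of the scheme", {
  qc <- list(background_rate = 0.0115)
  pool <- data.frame(chrom = "chr1", pos = c(100L, 300L))

  # sole candidate: NT=3, NC=0 -> raw p = p0^3, single-test HB identity
  cell <- make_cell(100, 3, 0)
  res <- call_cell(cell, pool, NULL, NULL, qc)
  expect_equal(nrow(res$fc_sites), 1L)
  expect_equal(res$fc_sites$p_raw, 0.0115^3, tolerance = 1e-12)
  expect_equal(res$fc_sites$p_adj, res$fc_sites$p_raw)
  expect_equal(res$abundance, 1.0)

  # NT=0, NC=3 is an unmodified call, never a 5fC call
  res <- call_cell(make_cell(100, 0, 3), pool, NULL, NULL, qc)
  expect_equal(nrow(res$fc_sites), 0L)
  expect_equal(res$unmod_sites$pos, 100L)

  # ratio 0.667 but not in the candidate pool -> not called
  res <- call_cell(make_cell(500, 2, 1), pool, NULL, NULL, qc)
  expect_equal(nrow(res$fc_sites), 0L)

  # noise-pool membership vetoes an otherwise perfect site
  res <- call_cell(make_cell(100, 5, 0), pool,
                   noise = data.frame(chrom = "chr1", pos = 100L),
                   NULL, qc)
  expect_equal(nrow(res$fc_sites), 0L)

  # SNP-masked sites are excluded from 5fC and unmodified calls
  cell <- make_cell(c(100, 300), c(5, 0), c(0, 5))
  res <- call_cell(cell, pool, NULL,
                   snp_mask = data.frame(chrom = "chr1",
                                         pos = c(100L, 300L)), qc)
  expect_equal(nrow(res$fc_sites), 0L)
  expect_equal(nrow(res$unmod_sites), 0L)

  # depth gate: 2 reads never support a call
  res <- call_cell(make_cell(100, 2, 0), pool, NULL, NULL, qc)
  expect_equal(nrow(res$fc_sites), 0L)

  expect_error(call_cell(make_cell(100, 3, 0), pool, NULL, NULL,
                         list(background_rate = NULL)),
               "configuration error")
})

test_that("no site is called both formylated and unmodified", {
  w <- small_world(seed = 31)
  res <- call_all(w)
  for (cl in res$calls) {
    overlap <- intersect(paste(cl$fc_sites$chrom, cl$fc_sites$pos),
                         paste(cl$unmod_sites$chrom, cl$unmod_sites$pos))
    expect_length(overlap, 0)
  }
})

test_that("false-positive detection rate is the abundance ratio", {
  fc <- function(a) structure(list(abundance = a), class = "fc_calls")
  expect_equal(false_positive_detection_rate(list(fc(0.05)),
                                             list(fc(0.004))), 0.08)
  expect_equal(false_positive_detection_rate(list(fc(0.05)),
                                             list(fc(0))), 0.0)
  expect_equal(false_positive_detection_rate(list(fc(0.04), fc(0.04)),
                                             list(fc(0.002), fc(0.006))),
               0.1)
  expect_error(false_positive_detection_rate(list(fc(0)), list(fc(0.01))),
               "undefined rate")
  expect_error(false_positive_detection_rate(list(), list(fc(0.01))),
               "required")
})

test_that("QC falls back to the pooled lambda rate when a cell lacks
           qualifying sites", {
  controls <- list(
    a = rbind(spike(16, 4), lambda(23, 1977)),
    b = rbind(spike(15, 5), lambda(1, 2)))  # depth 3: no qualifying site
  manifest <- data.frame(cell_id = c("a", "b"),
                         treatment = c("treated", "treated"))
  qc <- compute_qc(controls, manifest)
  expect_equal(qc$background_rate[qc$cell_id == "a"], 0.0115)
  expect_equal(qc$background_source, c("cell", "pooled"))
  expect_equal(qc$background_rate[qc$cell_id == "b"], 0.0115)
  expect_false(any(qc$flagged))
})
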