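test_that("5fCpG level is fc / (fc + unmodified), scoped or global", {
  expect_equal(fc_level(fake_calls(1:2, 11:18)), 0.2)
  expect_equal(fc_level(fake_calls(integer(0), 1:100)), 0.0)
  expect_true(is.na(fc_level(fake_calls(integer(0), integer(0)))))
  # scope restriction: 3 fc + 997 unmod inside the scoped half
  calls <- fake_calls(c(10L, 20L, 30L, 5000L, 6000L),
                      c(31:1027, 7000:7500))
  scope <- data.frame(chrom = "chr1", start = 0L, end = 2000L)
  expect_equal(fc_level(calls, scope), 3 / 1000)
})

test_that("whole-genome level equals the weighted mix over a partition", {
  w <- small_world(seed = 41)
  res <- call_all(w)
  cl <- res$calls[["treated_1"]]
  len <- w$genome$chrom_sizes[["chr1"]]
  cut <- len %/% 3
  parts <- list(data.frame(chrom = "chr1", start = 0L, end = cut),
                data.frame(chrom = "chr1", start = cut, end = 2L * cut),
                data.frame(chrom = "chr1", start = 2L * cut, end = len))
  counts <- vapply(parts, function(sc) {
    fc <- sum(fcpg:::overlap_count(cl$fc_sites, sc) > 0)
    un <- sum(fcpg:::overlap_count(cl$unmod_sites, sc) > 0)
    c(fc, fc + un)
  }, numeric(2))
  expect_equal(fc_level(cl), sum(counts[1, ]) / sum(counts[2, ]))
})

test_that("relative enrichment is the log2 fraction ratio", {
  bg <- data.frame(chrom = "chr1", pos = 1:1000)
  ann <- data.frame(chrom = "chr1", start = c(0L, 0L),
                    end = c(100L, 50L), class = c("X", "Y"))
  fc <- data.frame(chrom = "chr1", pos = c(30L, 501:509))
  enr <- relative_enrichment(fc, bg, ann)
  # X holds 10% of background and 10% of fc -> 0; Y 5% vs 10% -> +1
  expect_equal(enr$log2_enrichment[enr$class == "X"], 0)
  expect_equal(enr$log2_enrichment[enr$class == "Y"], 1)
  expect_error(relative_enrichment(fc[0, ], bg, ann), "no 5fCpG sites")
  expect_error(relative_enrichment(data.frame(chrom = "chr1", pos = 5000L),
                                   bg, ann), "subset")
  # class absent from the background is undefined, not infinite
  ann2 <- rbind(ann, data.frame(chrom = "chr1", start = 5000L,
                                end = 5100L, class = "Z"))
  expect_true(is.na(
    relative_enrichment(fc, bg, ann2)$log2_enrichment[3]))
})

test_that("windowed variance uses the n-1 convention over retained
           windows", {
  grid <- window_grid(c(chr1 = 10000L), 1000L)
  same <- list(fake_profile(c(0.2, 0.4, 0.8), "a"),
               fake_profile(c(0.2, 0.4, 0.8), "b"))
  ws <- window_stats(same, grid)
  expect_true(all(ws$per_window$variance == 0))
  two <- list(fake_profile(0, "a"), fake_profile(1, "b"))
  expect_equal(window_stats(two, grid)$per_window$variance, 0.5)
  three <- list(fake_profile(0.1, "a"), fake_profile(0.2, "b"),
                fake_profile(0.6, "c"))
  expect_equal(window_stats(three, grid)$per_window$variance, 0.07)
  expect_error(window_stats(three[1], grid), "at least two")
  # class medians
  cm <- data.frame(chrom = "chr1", start = 0L, class = "L1")
  byc <- window_stats(three, grid, class_map = cm)$by_class
  expect_equal(byc$median_variance[byc$class == "L1"], 0.07)
})

test_that("windows without 5fCpG in any profile are not retained", {
  grid <- window_grid(c(chr1 = 10000L), 1000L)
  p1 <- fake_profile(c(0.5, 0.5), "a", n_fc = c(1L, 0L))
  p2 <- fake_profile(c(0.1, 0.9), "b", n_fc = c(1L, 0L))
  ws <- window_stats(list(p1, p2), grid)
  expect_equal(nrow(ws$per_window), 1L)
  expect_equal(ws$per_window$start, 0L)
})

test_that("stage transitions partition the later merged set", {
  earlier <- fake_stage(
    fc = data.frame(chrom = "chr1", pos = c(10L, 20L)),
    unmod = data.frame(chrom = "chr1", pos = c(30L, 40L)))
  later <- fake_stage(
    fc = data.frame(chrom = "chr1", pos = c(10L, 30L, 99L)),
    unmod = data.frame(chrom = character(0), pos = integer(0)))
  tr <- stage_transition(earlier, later)
  expect_equal(tr$counts,
               c(inherited = 1L, newly_generated = 1L, undetermined = 1L))
  expect_equal(sum(tr$counts), nrow(later$merged_fc))
  expect_equal(tr$sites$inherited$pos, 10L)
  expect_equal(tr$sites$newly_generated$pos, 30L)
  expect_equal(tr$sites$undetermined$pos, 99L)
})

test_that("stage merging produces union calls over a common backbone", {
  w <- small_world(seed = 43, base_rate = 2e-2)
  res <- call_all(w)
  st <- stage_callset("s", res$calls[res$treated],
                      w$counts[res$treated])
  per_cell <- unlist(lapply(res$calls[res$treated], function(c) {
    paste(c$fc_sites$chrom, c$fc_sites$pos)
  }))
  expect_setequal(paste(st$merged_fc$chrom, st$merged_fc$pos),
                  unique(per_cell))
  # every commonly covered site has depth >= 3 in every member cell
  ck <- paste(st$common_covered$chrom, st$common_covered$pos)
  for (id in res$treated) {
    x <- w$counts[[id]]
    deep <- paste(x$chrom, x$pos)[x$count_C + x$count_T >= 3]
    expect_true(all(ck %in% deep))
  }
  expect_true(st$stage_fc_fraction >= 0 && st$stage_fc_fraction <= 1)
})

test_that("shared marked regions form an exact three-way split", {
  mk <- function(starts) data.frame(chrom = "chr1",
                                    start = as.integer(starts))
  sr <- shared_regions(mk(c(0, 1000, 2000)), mk(c(1000, 5000)))
  expect_equal(sr$counts,
               c(a_specific = 2L, b_specific = 1L, shared = 1L))
  expect_equal(shared_regions(mk(0:4 * 1000), mk(5:11 * 1000))$counts[["shared"]],
               0L)
  same <- shared_regions(mk(0:4 * 1000), mk(0:4 * 1000))
  expect_equal(same$counts,
               c(a_specific = 0L, b_specific = 0L, shared = 5L))
  a <- structure(mk(0), window_size = 1000L)
  b <- structure(mk(0), window_size = 2000L)
  expect_error(shared_regions(a, b), "different grids")
})

test_that("paired differences mirror the pronucleus comparison and are
           antisymmetric", {
  male <- fake_calls(1:106, 107:100000)        # level 0.00106
  female <- fake_calls(1:109, 110:100000)      # level 0.00109
  pd <- paired_difference(male, female)
  expect_equal(pd$difference[pd$scope == "whole_genome"], -3e-5,
               tolerance = 1e-9)
  swapped <- paired_difference(female, male)
  expect_equal(swapped$difference, -pd$difference)
  zero <- paired_difference(male, male,
                            scopes = list(left = data.frame(
                              chrom = "chr1", start = 0L, end = 5e4)))
  expect_true(all(zero$difference == 0))
})

test_that("Spearman correlation and clustering behave on known profiles", {
  p <- function(levels, owner) fake_profile(levels, owner)
  ident <- correlation_cluster(list(p(c(.1, .2, .3, .4), "a"),
                                    p(c(.1, .2, .3, .4), "b")))
  expect_equal(ident$rho["a", "b"], 1)
  rev2 <- correlation_cluster(list(p(c(.1, .2, .3, .4), "a"),
                                   p(c(.4, .3, .2, .1), "b")))
  expect_equal(rev2$rho["a", "b"], -1)
  cc <- correlation_cluster(list(p(c(.1, .2, .3, .4), "a"),
                                 p(c(.1, .3, .2, .4), "b")))
  expect_equal(cc$rho["a", "b"], 0.8)
  expect_true(isSymmetric(cc$rho))
  expect_equal(unname(diag(cc$rho)), c(1, 1))
  expect_s3_class(cc$hclust, "hclust")
  # too few joint windows -> flagged NA
  expect_warning(
    und <- correlation_cluster(list(p(c(.1, .2), "a"), p(c(.2, .1), "b"))),
    "too few jointly defined")
  expect_true(is.na(und$rho["a", "b"]))
})

test_that("signal metaplots average the track within bins", {
  sites <- data.frame(chrom = "chr1", pos = 100L)
  const <- data.frame(chrom = "chr1", start = 0L, end = 10000L, value = 7)
  prof <- signal_profile(sites, const, flank = 50L, n_bins = 5L)
  expect_equal(unname(prof), rep(7, 5))
  # signal only under the center bin
  center <- data.frame(chrom = "chr1", start = 95L, end = 105L, value = 3)
  prof <- signal_profile(sites, center, flank = 50L, n_bins = 5L)
  expect_equal(unname(prof[3]), 3)
  expect_true(all(is.na(prof[-3])))
  # step track, 3 bins, hand-integrated overlap means
  step <- data.frame(chrom = "chr1", start = c(96L, 100L),
                     end = c(100L, 104L), value = c(1, 3))
  prof <- signal_profile(sites, step, flank = 3L, n_bins = 3L)
  expect_equal(unname(prof), c(1, 5 / 3, 3))
  # empty track -> all-missing profile
  expect_true(all(is.na(signal_profile(sites, const[0, ], 50L, 5L))))
  expect_error(signal_profile(sites, const, 50L, 4L), "odd")
})

test_that("matched repeat comparison draws seeded controls and a t test", {
  expect_equal(rpkm(10, 2000, 1e6), 5.0)
  marked <- c(2.0, 2.5, 3.0, 3.5, 4.0)
  ctrl_pool <- rep(c(2.0, 2.5, 3.0, 3.5, 4.0), 4)
  r1 <- matched_repeat_comparison(marked, ctrl_pool, seed = 9)
  r2 <- matched_repeat_comparison(marked, ctrl_pool, seed = 9)
  expect_identical(r1$control_idx, r2$control_idx)
  expect_equal(r1$n, 5L)
  expect_true(r1$p > 0 && r1$p <= 1)
  expect_lt(abs(r1$mean_marked - 3.0), 1e-12)
  expect_error(matched_repeat_comparison(marked, marked[1:3]),
               "at least as many")
})
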