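test_that("zeros become missing; positive values survive unchanged", {
  ab <- matrix(c(0, 0.0001, 5, 2, 0, 3), 3, 2)
  m <- zeros_to_missing(toy_pm(ab))
  expect_true(is.na(m$abundance[1, 1]))
  expect_true(is.na(m$abundance[2, 2]))
  expect_equal(m$abundance[2, 1], 0.0001)
  expect_equal(m$abundance[3, ], c(ch1 = 5, ch2 = 3))
  # no zeros -> identical matrix
  ab2 <- matrix(1:4, 2, 2)
  expect_equal(zeros_to_missing(toy_pm(ab2))$abundance,
               toy_pm(ab2)$abundance)
  expect_error(zeros_to_missing(toy_pm(matrix(c(-1, 1, 1, 1), 2, 2))),
               "negative")
})

test_that("an all-zero matrix yields no peptides after the present-call filter", {
  m <- zeros_to_missing(toy_pm(matrix(0, 3, 4)))
  expect_true(all(is.na(m$abundance)))
  expect_equal(nrow(present_call_filter(m, 1)$abundance), 0)
})

test_that("loading normalization equalizes channel totals to the grand mean", {
  ab <- matrix(c(40, 60, 100, 200), 2, 2)  # totals 100 and 300
  m <- sample_loading_normalize(toy_pm(ab))
  expect_equal(unname(attr(m, "factors")), c(2, 2 / 3))
  expect_equal(unname(colSums(m$abundance)), c(200, 200))
  # already-equal totals: unchanged
  ab2 <- matrix(c(1, 3, 2, 2), 2, 2)
  m2 <- sample_loading_normalize(toy_pm(ab2))
  expect_equal(m2$abundance, toy_pm(ab2)$abundance)
  # missing entries are excluded from totals
  ab3 <- matrix(c(10, NA, 5, 5), 2, 2)
  m3 <- sample_loading_normalize(toy_pm(ab3))
  expect_equal(m3$abundance, toy_pm(ab3)$abundance)
  # all-missing channel errors, naming the channel
  ab4 <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(sample_loading_normalize(toy_pm(ab4)), "ch2")
})

test_that("pooled-missing filter implements the at-least-half-of-plexes rule", {
  # 4 plexes x (1 subject + 2 pooled); peptide 1 missing in both pooled of 2 plexes
  pooled <- rep(c(FALSE, TRUE, TRUE), 4)
  plex <- rep(1:4, each = 3)
  ab <- matrix(1, 3, 12)
  ab[1, c(2, 3, 5, 6)] <- NA       # plexes 1 and 2: both pooled missing
  ab[2, c(2, 5, 8, 11)] <- NA      # one pooled channel missing in every plex
  res <- filter_pooled_missing(toy_pm(ab, plex, pooled))
  expect_equal(res$removed$peptide, "pep1")
  expect_equal(res$removed$reason, "pooled-missing")
  expect_setequal(rownames(res$matrix$abundance), c("pep2", "pep3"))
  # 3 plexes, both-pooled-missing in 1 plex: retained (1 < 1.5)
  ab2 <- matrix(1, 1, 9)
  ab2[1, c(2, 3)] <- NA
  res2 <- filter_pooled_missing(toy_pm(ab2, rep(1:3, each = 3),
                                       rep(c(FALSE, TRUE, TRUE), 3)))
  expect_equal(nrow(res2$matrix$abundance), 1)
  # a plex without pooled channels is a configuration error
  expect_error(filter_pooled_missing(toy_pm(matrix(1, 1, 2), c(1, 2),
                                            c(FALSE, TRUE))),
               "pooled")
})

test_that("multi-mapped peptides are removed and the survivor map is one-to-one", {
  ab <- matrix(1, 10, 2)
  prots <- as.list(paste0("P", 1:10))
  names(prots) <- paste0("pep", 1:10)
  prots[["pep2"]] <- c("P2", "P99")
  prots[["pep5"]] <- c("P5", "P6")
  prots[["pep9"]] <- c("P9", "P1", "P2")
  res <- drop_multimapped(toy_pm(ab, proteins = prots))
  expect_equal(nrow(res$matrix$abundance), 7)
  expect_setequal(res$removed$peptide, c("pep2", "pep5", "pep9"))
  expect_true(all(res$removed$reason == "multi-mapped"))
  expect_true(all(table(res$matrix$pep2prot$peptide) == 1))
  # all single-mapped: unchanged
  res2 <- drop_multimapped(toy_pm(ab))
  expect_equal(res2$matrix$abundance, toy_pm(ab)$abundance)
  expect_equal(nrow(res2$removed), 0)
})

test_that("outlier detection flags a low-total sample and respects k", {
  set.seed(1)
  ab <- matrix(2^rnorm(220, 10, 0.01), 20, 11)
  m <- toy_pm(ab)
  expect_length(detect_outlier_samples(m, k = 3), 0)
  # one sample at ~0.35/1.31 of the typical total
  ab2 <- ab
  ab2[, 4] <- ab2[, 4] * 0.35 / 1.31
  flagged <- detect_outlier_samples(toy_pm(ab2), k = 3)
  expect_equal(as.character(flagged), "ch4")
  expect_length(detect_outlier_samples(toy_pm(ab2), k = Inf), 0)
  # equal totals: no flags
  expect_length(detect_outlier_samples(toy_pm(matrix(1, 3, 11)), k = 3), 0)
})

test_that("IRS equalizes per-peptide pooled means across plexes", {
  # 1 peptide; plex 1 pooled (100, 120), plex 2 pooled (200, 220)
  ab <- matrix(c(90, 100, 120, 180, 200, 220), 1, 6)
  plex <- rep(1:2, each = 3)
  pooled <- rep(c(FALSE, TRUE, TRUE), 2)
  m <- irs_normalize(toy_pm(ab, plex, pooled))
  expect_equal(unname(m$abundance[1, ]),
               c(c(90, 100, 120) * 160 / 110, c(180, 200, 220) * 160 / 210),
               tolerance = 1e-12)
  expect_equal(mean(m$abundance[1, c(2, 3)]), 160)
  expect_equal(mean(m$abundance[1, c(5, 6)]), 160)
})

test_that("single-plex IRS is the identity and undefined plexes go missing", {
  ab <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  m <- toy_pm(ab, pooled = c(FALSE, TRUE, TRUE))
  expect_equal(irs_normalize(m)$abundance, m$abundance)
  # peptide with both pooled missing in plex 2 of 2: plex-2 values set missing
  ab2 <- matrix(c(1, 2, 2, 5, NA, NA), 1, 6)
  m2 <- irs_normalize(toy_pm(ab2, rep(1:2, each = 3),
                             rep(c(FALSE, TRUE, TRUE), 2)))
  expect_true(is.na(m2$abundance[1, 4]))
})

test_that("median normalization equalizes channel medians at the overall median", {
  ab <- matrix(c(5, 10, 20, 20, 40, 80), 3, 2)  # medians 10 and 40
  m <- median_normalize(toy_pm(ab))
  target <- median(ab)
  expect_equal(unname(attr(m, "factors")), target / c(10, 40))
  expect_equal(unname(apply(m$abundance, 2, median)), rep(target, 2))
  # equal medians: unchanged; rank order preserved
  ab2 <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2)
  expect_equal(median_normalize(toy_pm(ab2))$abundance,
               toy_pm(ab2)$abundance)
  expect_equal(order(m$abundance[, 1]), order(ab[, 1]))
})

test_that("present-call filter thresholds the subject-present fraction", {
  ab <- matrix(1, 3, 10)
  ab[1, 1:5] <- NA            # 50% present
  ab[2, 1] <- NA              # 90% present
  m <- toy_pm(ab)
  expect_setequal(rownames(present_call_filter(m, 1)$abundance), "pep3")
  expect_setequal(rownames(present_call_filter(m, 0.5)$abundance),
                  c("pep1", "pep2", "pep3"))
  expect_setequal(rownames(present_call_filter(m, 0.6)$abundance),
                  c("pep2", "pep3"))
  # threshold 1 with no missing values is the identity
  full <- toy_pm(matrix(1:6, 2, 3))
  expect_equal(present_call_filter(full, 1)$abundance, full$abundance)
  expect_error(present_call_filter(full, 0), "0, 1")
})

test_that("pooled channels are excluded from the present-call denominator", {
  ab <- matrix(1, 1, 4)
  ab[1, 3:4] <- NA  # missing only in pooled channels
  m <- toy_pm(ab, pooled = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nrow(present_call_filter(m, 1)$abundance), 1)
})

test_that("full pipeline runs stages in the prescribed order and removes a batch effect", {
  study <- small_study(seed = 21, batch_sd = 1)
  res <- normalize_psd(study$raw, present_call = 0.5)
  expect_equal(res$report$stages,
               c("zeros_to_missing", "sample_loading_normalize",
                 "filter_pooled_missing", "drop_multimapped",
                 "detect_outlier_samples", "irs_normalize",
                 "median_normalize", "present_call_filter"))
  m <- res$matrix
  # post-IRS + median: between-plex variance of pooled channels ~ 0 per peptide
  # (median rescales each channel but IRS equality is on plex means; check
  # on a run without the median stage)
  m2 <- irs_normalize(zeros_to_missing(study$raw))
  ch <- m2$channels
  for (p in unique(ch$plex)) {
    cols <- ch$channel[ch$plex == p & ch$pooled]
    pm_p <- rowMeans(m2$abundance[, cols, drop = FALSE], na.rm = TRUE)
    overall <- rowMeans(m2$abundance[, ch$channel[ch$pooled], drop = FALSE],
                        na.rm = TRUE)
    ok <- is.finite(pm_p) & is.finite(overall)
    expect_lt(max(abs(pm_p[ok] - overall[ok]) / pmax(overall[ok], 1e-12)),
              1e-9)
  }
})

test_that("pipeline removes low-loading samples judged on raw totals", {
  set.seed(3)
  ab <- matrix(2^rnorm(20 * 13, 10, 0.05), 20, 13)
  ab[, 2] <- ab[, 2] * 0.35 / 1.31       # low-yield sample
  m <- toy_pm(ab, pooled = c(rep(FALSE, 11), TRUE, TRUE))
  res <- normalize_psd(m, present_call = 1)
  expect_equal(res$report$outlier_channels, "ch2")
  expect_false("ch2" %in% res$matrix$channels$channel)
})

test_that("loading and median normalization preserve within-channel peptide ratios", {
  set.seed(5)
  ab <- matrix(2^rnorm(40, 10, 1), 8, 5)
  m <- toy_pm(ab)
  r0 <- unname(ab[1, ] / ab[2, ])
  m1 <- sample_loading_normalize(m)
  m2 <- median_normalize(m)
  expect_equal(unname(m1$abundance[1, ] / m1$abundance[2, ]), r0)
  expect_equal(unname(m2$abundance[1, ] / m2$abundance[2, ]), r0)
})
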