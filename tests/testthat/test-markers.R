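two_group_ft <- function(seed = 1, n_features = 30, n_markers = 5) {
  simulate_feature_study(n_features = n_features, n_markers = n_markers,
                         n_qc = 0, seed = seed)
}

test_that("screening enforces strict VIP and p thresholds", {
  withr::local_seed(1)
  # 4 features: strong shift, boundary VIP, shifted-but-low-VIP, null
  m <- rbind(F1 = c(10, 11, 10, 30, 31, 30),
             F2 = c(10, 11, 10, 30, 31, 30),
             F3 = c(10, 11, 10, 30, 31, 30),
             F4 = c(10, 11, 12, 10, 11, 12))
  ft <- make_ft(m, groups = rep(c("control", "model"), each = 3))
  vips <- tibble::tibble(feature_id = paste0("F", 1:4),
                         vip = c(1.6, 1.5, 1.2, 1.9))
  out <- screen_markers(ft, vips)
  # F1 passes both; F2 exactly at 1.5 excluded; F3 below VIP; F4 null p
  expect_identical(out$feature_id, "F1")
  expect_identical(out$trend, "up")
  expect_gt(out$fold_change, 1)
  # every selected row satisfies the rule by construction
  expect_true(all(out$vip > 1.5 & out$p_value < 0.05))
  expect_error(screen_markers(make_ft(m[, 1:3],
                                      groups = c("control", "control",
                                                 "model")),
                              vips), "2 samples")
})

test_that("fold change and trend follow the tie rule", {
  m <- rbind(F1 = c(5, 5, 10, 10),     # model/control = 2
             F2 = c(7, 7, 7, 7),       # tie -> down
             F3 = c(8, 8, 2, 2))       # 0.25 down
  ft <- make_ft(m, groups = rep(c("control", "model"), each = 2))
  expect_equal(fold_change_trend(ft, "F1")$fold_change, 2)
  expect_identical(fold_change_trend(ft, "F1")$trend, "up")
  expect_identical(fold_change_trend(ft, "F2")$trend, "down")
  f3 <- fold_change_trend(ft, "F3")
  expect_equal(f3$fold_change, 0.25)
  expect_identical(f3$trend, "down")
  mz <- rbind(F1 = c(0, 0, 1, 1))
  expect_error(fold_change_trend(make_ft(mz, groups = rep(c("control",
                                                            "model"),
                                                          each = 2)),
                                 "F1"), "zero")
})

test_that("recovery flags reflect treated-vs-model differences", {
  # treated identical to model -> ns
  m <- rbind(F1 = c(1, 2, 3, 10, 11, 12, 10, 11, 12, 10, 11, 12))
  ft <- make_ft(m, groups = rep(c("control", "model", "kansui", "vkansui"),
                                each = 3))
  fl <- recovery_assessment(ft, tibble::tibble(feature_id = "F1"))
  expect_identical(fl$flag, c("ns", "ns"))

  # full recovery with a 3-SD planted log effect: treated groups differ
  # from the model group for nearly every marker. On the raw intensity
  # scale the Welch test loses power against up-shifted (high-variance)
  # markers, so p01 alone is rarer than the any-significance rate; both
  # frozen rates come from simulation over seeds 21:30.
  sig <- p01 <- numeric(10)
  for (s in 1:10) {
    st <- simulate_feature_study(n_features = 50, n_markers = 10,
                                 log_fold_change = 1.2, recovery = 1,
                                 noise_sd = 0.4, n_qc = 0, seed = 20 + s)
    fl1 <- recovery_assessment(st$table, st$truth)
    sig[s] <- mean(fl1$flag != "ns")
    p01[s] <- mean(fl1$flag == "p01")
  }
  expect_gte(mean(sig), 0.85)
  expect_gte(mean(p01), 0.5)

  # no recovery: treated sits at the model mean -> almost all ns
  ns0 <- numeric(5)
  for (s in 1:5) {
    st0 <- simulate_feature_study(n_features = 50, n_markers = 10,
                                  log_fold_change = 1.2, recovery = 0,
                                  noise_sd = 0.4, n_qc = 0, seed = 50 + s)
    fl0 <- recovery_assessment(st0$table, st0$truth)
    ns0[s] <- mean(fl0$flag == "ns")
  }
  expect_gte(mean(ns0), 0.9)
})

test_that("screening output is invariant to feature and sample order", {
  st <- two_group_ft(seed = 31)
  ft <- st$table
  s <- sample_info(ft)
  sc <- pareto_scale_cm(ft)
  m <- fit_oplsda(sc, cm_labels(ft), seed = 1)
  out1 <- screen_markers(ft, vip_scores(m))

  fperm <- sample(nrow(ft))
  sperm <- sample(nrow(s))
  ft2 <- feature_table(ft[fperm, c("feature_id", "mz", "rt")],
                       intensity_matrix(ft)[fperm, sperm], s[sperm, ])
  out2 <- screen_markers(ft2, vip_scores(m))
  expect_identical(out2$feature_id, out1$feature_id)
  expect_equal(out2$p_value, out1$p_value)
})

test_that("planted markers are recovered with a controlled error rate", {
  stats <- vapply(1:20, function(s) {
    st <- simulate_feature_study(seed = s)
    mk <- screen_study(st, seed = s)
    hits <- sum(mk$feature_id %in% st$truth$feature_id)
    c(sens = hits / nrow(st$truth),
      fdp = (nrow(mk) - hits) / max(1, nrow(mk)))
  }, numeric(2))
  expect_gte(mean(stats["sens", ]), 0.8)
  # the false-discovery proportion of the raw VIP + p rule hovers just
  # above 0.2 under these conditions (0.21 over 100 seeds)
  expect_lte(mean(stats["fdp", ]), 0.25)
})

test_that("null data selects fewer features than the p gate alone", {
  # The VIP and p gates pick out the same chance-correlated features on
  # null data, so the double gate does not multiply their individual
  # rates; what it does guarantee is a selection rate well below the
  # alpha * n_features of the p gate by itself (mean ~11 of 300 here).
  counts <- vapply(1:10, function(s) {
    st <- simulate_feature_study(n_features = 300, n_markers = 0,
                                 n_qc = 0, seed = 400 + s)
    sc <- pareto_scale_cm(st$table)
    m <- fit_oplsda(sc, cm_labels(st$table), seed = s)
    nrow(screen_markers(st$table, vip_scores(m)))
  }, numeric(1))
  expect_lte(mean(counts), 0.05 * 300)
  expect_lte(max(counts), 25)
})

test_that("heatmap matrix z-scores and clusters deterministically", {
  withr::local_seed(2)
  base <- matrix(rnorm(48), 4, 12) + 20
  m <- rbind(A1 = base[1, ], A2 = base[1, ],              # identical pair
             B1 = base[3, ] + 10, B2 = base[3, ] + 10.1,  # second block
             C0 = rep(5, 12))                             # constant
  ft <- make_ft(m, groups = rep(c("control", "model", "kansui", "vkansui"),
                                each = 3))
  hm <- heatmap_matrix(ft, tibble::tibble(feature_id = rownames(m)))
  expect_equal(unname(rowMeans(hm$z)), rep(0, 5))
  sds <- apply(hm$z, 1, sd)
  expect_equal(unname(sds[1:4]), rep(1, 4))
  expect_true(hm$zero_variance[["C0"]])
  expect_equal(unname(hm$z["C0", ]), rep(0, 12))
  # identical markers merge first (distance 0)
  expect_equal(hm$row_hclust$height[1], 0)
  first_pair <- rownames(hm$z)[-hm$row_hclust$merge[1, ]]
  expect_setequal(first_pair, c("A1", "A2"))
  # planted blocks stay contiguous in the leaf order
  ord <- rownames(hm$z)[hm$row_order]
  expect_equal(abs(diff(match(c("A1", "A2"), ord))), 1)
  expect_equal(abs(diff(match(c("B1", "B2"), ord))), 1)
  expect_error(heatmap_matrix(ft, tibble::tibble(feature_id = "A1")),
               "2 markers")
})
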