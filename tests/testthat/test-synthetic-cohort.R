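test_that("config validation enforces the documented invariants", {
  expect_error(generator_config(n_reference = 0), "positive")
  expect_error(generator_config(latent_loading = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(correlated_genes = c("MAGEA3", "MLANA")),
               "disjoint")
  expect_error(generator_config(arm_split = c(combination = 100L,
                                              monotherapy = 100L)),
               "arm_split")
  expect_error(generator_config(tumor_type_freq = c(Widget = 10)),
               "activation probability")
  expect_silent(validate_generator_config(generator_config()))
})

test_that("reference respects size, ordering and determinism contracts", {
  cfg <- generator_config(seed = 1)
  ref <- generate_reference(cfg)
  expect_identical(length(ref$values), 17L)
  expect_true(all(lengths(ref$values) == 735L))
  expect_true(all(vapply(ref$values, function(v) !is.unsorted(v),
                         logical(1))))
  expect_true(all(unlist(ref$values) >= 0))
  ref2 <- generate_reference(cfg)
  expect_identical(ref, ref2)
})

test_that("reference zero-inflation separates background from the active component", {
  cfg <- small_config(seed = 2, zero_inflation = 0.8)
  ref <- generate_reference(cfg)
  gp <- ctabr:::.gene_params(cfg)
  sd_act <- sqrt(cfg$magnitude_loading^2 + ctabr:::.SIGMA_ACTIVE^2)
  for (j in seq_len(nrow(gp))) {
    q01 <- qlnorm(0.01, gp$mu[j], sd_act)
    expect_gte(mean(ref$values[[gp$gene[j]]] < q01), 0.70)
  }
})

test_that("discovery cohort honors its size and panel contract", {
  cfg <- small_config(seed = 3)
  d <- generate_discovery(cfg)
  expect_identical(nrow(d$expression), 400L)
  expect_identical(ncol(d$expression), 17L)
  expect_setequal(colnames(d$expression), default_ctab_panel()$genes)
  expect_identical(nrow(d$clinical), 400L)
  expect_identical(d$clinical$sample_id, rownames(d$expression))
  expect_true(all(d$expression >= 0))
  expect_true(all(d$clinical$pdl1_tps >= 0 & d$clinical$pdl1_tps <= 100))
  expect_true(all(d$clinical$tmb >= 0))
  # identical config + seed -> identical cohort
  d2 <- generate_discovery(cfg)
  expect_identical(d, d2)
})

test_that("serialized cohorts are byte-identical across regeneration", {
  cfg <- small_config(seed = 8)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_cohort(generate_discovery(cfg), dir1)
  write_cohort(generate_discovery(cfg), dir2)
  for (f in c("expression.tsv", "clinical.csv", "config.yaml"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("retrospective cohort has exact arm sizes and proper censoring", {
  cfg <- generator_config(seed = 4)
  retro <- generate_retrospective(cfg)
  cl <- retro$clinical
  expect_identical(nrow(cl), 250L)
  expect_identical(sum(cl$arm == "combination"), 148L)
  expect_identical(sum(cl$arm == "monotherapy"), 102L)
  expect_identical(sum(cl$histology == "non-squamous"), 213L)
  expect_true(all(cl$os_months <= 24))
  expect_true(all(cl$os_event[cl$os_months == 24 &
                                cl$os_months < 24 + 1e-9] %in% c(0L, 1L)))
  # administratively censored records carry event = 0
  expect_true(all(cl$os_event == 0 | cl$os_months < 24 |
                    abs(cl$os_months - 24) < 1e-9))
  expect_true(all(cl$recist %in% c("CR", "PR", "SD", "PD")))
  expect_true(all(cl$tumor_type == "Lung cancer"))
})

test_that("monotherapy CTAB-low is the poorest-survival stratum", {
  meds <- vapply(1:5, function(s) {
    cfg <- generator_config(seed = s)
    retro <- generate_retrospective(cfg)
    ref <- generate_reference(cfg)
    cls <- classify_ctab(ctab_score(rank_matrix(retro$expression, ref)))
    sel <- retro$clinical$arm == "monotherapy" & cls == "low"
    km_fit(retro$clinical$os_months[sel],
           retro$clinical$os_event[sel])$median
  }, numeric(1))
  expect_gt(mean(meds), 9)
  expect_lt(mean(meds), 13)
})

test_that("equal hazards and outcome probabilities give a null cohort", {
  probs <- matrix(0.25, 4, 4,
                  dimnames = list(c("monotherapy.high", "monotherapy.low",
                                    "combination.high", "combination.low"),
                                  c("CR", "PR", "SD", "PD")))
  ps <- vapply(1:60, function(s) {
    cfg <- generator_config(
      seed = 7000 + s, n_reference = 100L,
      os_median_months = c("monotherapy.high" = 18, "monotherapy.low" = 18,
                           "combination.high" = 18, "combination.low" = 18),
      recist_probs = probs)
    retro <- generate_retrospective(cfg)
    logrank_test(retro$clinical$os_months, retro$clinical$os_event,
                 retro$clinical$arm)$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("biomarker independence holds across seeds", {
  stats <- t(vapply(1:8, function(s) {
    cfg <- generator_config(seed = 100 + s, n_discovery = 1500L)
    d <- generate_discovery(cfg)
    ref <- generate_reference(cfg)
    sc <- ctab_score(rank_matrix(d$expression, ref))
    c(tps = cor(sc, d$clinical$pdl1_tps, method = "spearman"),
      tmb = cor(sc, d$clinical$tmb, method = "spearman"))
  }, numeric(2)))
  expect_lt(mean(abs(stats[, "tps"])), 0.05)
  expect_gt(mean(stats[, "tmb"]), 0.05)
  expect_lt(mean(stats[, "tmb"]), 0.20)
})

test_that("tumor-type activation shifts order the CTAB distributions", {
  cfg <- generator_config(seed = 10)
  d <- generate_discovery(cfg)
  ref <- generate_reference(cfg)
  sc <- ctab_score(rank_matrix(d$expression, ref))
  med <- tapply(sc, d$clinical$tumor_type, median)
  expect_gt(med["Melanoma"], med["Colorectal cancer"])
})
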