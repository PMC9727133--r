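test_that("blood pressure averaging handles pairs and missing second readings", {
  bp <- mean_bp(c(120, 130, 118), c(120, 120, 126),
                c(80, 90, 76), c(80, 80, 84))
  expect_equal(bp$sbp, c(120, 125, 122))
  expect_equal(bp$dbp, c(80, 85, 80))
  expect_warning(single <- mean_bp(140, NA, 90, NA), "single reading")
  expect_equal(unlist(single), c(sbp = 140, dbp = 90))
})

test_that("every ATP III criterion is inclusive at its printed threshold", {
  eps <- 1e-9
  grid <- dplyr::bind_rows(
    make_record("wc_m_at", "male", wc = 102),
    make_record("wc_m_below", "male", wc = 102 - eps),
    make_record("wc_f_at", "female", wc = 88),
    make_record("wc_f_below", "female", wc = 88 - eps),
    make_record("fpg_at", fpg = 100),
    make_record("fpg_below", fpg = 100 - eps),
    make_record("sbp_at", sbp = 130),
    make_record("sbp_below", sbp = 130 - eps),
    make_record("dbp_at", dbp = 85),
    make_record("dbp_below", dbp = 85 - eps),
    make_record("tg_at", tg = 150),
    make_record("tg_below", tg = 150 - eps),
    make_record("hdl_m_at", "male", hdl = 40),
    make_record("hdl_m_above", "male", hdl = 40 + eps),
    make_record("hdl_f_at", "female", hdl = 50),
    make_record("hdl_f_above", "female", hdl = 50 + eps)
  )
  flags <- classify_atp3(grid)
  at <- grepl("_at$", flags$id)
  expect_equal(flags$count[at], rep(1, sum(at)))
  expect_equal(flags$count[!at], rep(0, sum(!at)))
  expect_true(flags$wc_abn[flags$id == "wc_f_at"])
})

test_that("drug treatment forces the matching component abnormal", {
  rec <- dplyr::bind_rows(
    make_record("t_glu", treat_glucose = TRUE),
    make_record("t_bp", treat_bp = TRUE),
    make_record("t_tg", treat_tg = TRUE),
    make_record("t_hdl", treat_hdl = TRUE),
    make_record("none")
  )
  flags <- classify_atp3(rec)
  expect_equal(flags$fpg_abn, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(flags$bp_abn, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(flags$tg_abn, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(flags$hdl_abn, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(flags$count, c(1, 1, 1, 1, 0))
})

test_that("three abnormal components diagnose MSyn", {
  rec <- make_record("three", "male", wc = 103, fpg = 101, tg = 151,
                     hdl = 45, sbp = 120, dbp = 80)
  flags <- classify_atp3(rec)
  expect_true(flags$wc_abn && flags$fpg_abn && flags$tg_abn)
  expect_false(flags$bp_abn || flags$hdl_abn)
  expect_equal(flags$count, 3)
  expect_true(flags$msyn)
})

test_that("classification is deterministic and monotone under worsening values", {
  withr::with_seed(99, {
    rec <- random_records(1000)
    f1 <- classify_atp3(rec)
    f2 <- classify_atp3(rec)
    expect_identical(f1, f2)
    expect_equal(f1$count,
                 rowSums(f1[, c("wc_abn", "fpg_abn", "bp_abn", "tg_abn",
                                "hdl_abn")]))
    expect_equal(f1$msyn, f1$count >= 3)
    worse <- rec
    worse$wc_cm <- worse$wc_cm + 20
    worse$fpg_mgdl <- worse$fpg_mgdl + 40
    worse$tg_mgdl <- worse$tg_mgdl + 80
    worse$hdl_mgdl <- pmax(worse$hdl_mgdl - 15, 1)
    worse$sbp1 <- worse$sbp1 + 25
    worse$sbp2 <- worse$sbp2 + 25
    f3 <- classify_atp3(worse)
    expect_true(all(f3$count >= f1$count))
  })
})

test_that("records with missing component inputs are dropped with a warning", {
  rec <- dplyr::bind_rows(make_record("ok"), make_record("gap"))
  rec$hdl_mgdl[2] <- NA
  expect_warning(flags <- classify_atp3(rec), "gap")
  expect_equal(flags$id, "ok")
})

test_that("component distribution partitions the cohort", {
  four <- dplyr::bind_rows(
    make_record("c0"),
    make_record("c1", wc = 120, sex = "male"),
    make_record("c2", wc = 120, fpg = 130, sex = "male"),
    make_record("c3", wc = 120, fpg = 130, tg = 200, sex = "male")
  )
  dist <- component_distribution(classify_atp3(four))
  expect_equal(dist$n, rep(1L, 4))
  expect_equal(dist$pct, rep(25, 4))
  expect_equal(sum(dist$n), 4)

  withr::with_seed(3, {
    flags <- classify_atp3(random_records(500))
    dist <- component_distribution(flags)
    expect_equal(sum(dist$n), nrow(flags))
    expect_equal(sum(dist$pct), 100, tolerance = 1e-10)
  })
  expect_error(component_distribution(classify_atp3(make_record())[0, ]),
               "empty")
})

test_that("classification reproduces the frozen fixture baseline", {
  flags <- classify_atp3(fixture_cohort())
  exp <- fixture_expected()$flags
  expect_equal(as.data.frame(flags[, names(exp)]), as.data.frame(exp))
})
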