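test_that("target selection enforces the organ and total caps", {
  base <- data.frame(
    lesion_id = sprintf("b%d", 1:7), organ = "lymph_node",
    suv_max = c(9, 8, 7, 6, 5, 4, 3), sul_peak = c(9, 8, 7, 6, 5, 4, 3) * 0.7,
    stringsAsFactors = FALSE
  )
  pair <- scan_pair("x", base,
                    cbind(base[0, ], mapped_baseline_id = character(0)),
                    liver_followup = liver_reference_values(2, 0.1))
  expect_equal(select_targets_eortc(pair), c("b1", "b2"))  # 2-per-organ cap
  base$organ <- c("a", "b", "c", "a", "b", "c", "a")
  pair2 <- scan_pair("x", base,
                     cbind(base[0, ], mapped_baseline_id = character(0)),
                     liver_followup = liver_reference_values(2, 0.1))
  expect_length(select_targets_eortc(pair2), 5)  # total cap
  # three nodal lesions across distinct stations: all selected
  b3 <- data.frame(lesion_id = c("l1", "l2", "l3"),
                   organ = c("iliac_common", "iliac_external", "inguinal"),
                   suv_max = c(14.67, 13.09, 16.19),
                   sul_peak = c(9.6, 9.37, 11.55), stringsAsFactors = FALSE)
  pair3 <- scan_pair("x", b3,
                     cbind(b3[0, ], mapped_baseline_id = character(0)),
                     liver_followup = liver_reference_values(2, 0.1))
  expect_setequal(select_targets_eortc(pair3), c("l1", "l2", "l3"))
})

test_that("greedy selection equals exhaustive enumeration up to 8 lesions", {
  set.seed(17)
  params <- criteria_params()
  for (rep in 1:40) {
    n <- sample(1:8, 1)
    frame <- data.frame(
      lesion_id = sprintf("L%02d", 1:n),
      organ = sample(letters[1:3], n, replace = TRUE),
      suv_max = round(runif(n, 1, 20), 2),
      stringsAsFactors = FALSE
    )
    frame$sul_peak <- 0.7 * frame$suv_max
    picked <- select_targets_hottest(frame, params)
    greedy_sum <- sum(frame$sul_peak[match(picked, frame$lesion_id)])
    oracle <- brute_best_target_sum(frame$sul_peak, frame$organ)
    expect_equal(greedy_sum, oracle)
  }
  # tie in hotness: lower lesion_id wins
  tied <- data.frame(lesion_id = c("L2", "L1"), organ = c("a", "b"),
                     suv_max = c(5, 5), sul_peak = c(3.5, 3.5),
                     stringsAsFactors = FALSE)
  expect_equal(select_targets_hottest(tied, criteria_params(max_targets = 1)),
               "L1")
})

test_that("percent_change matches the worked sums and rejects bad input", {
  expect_equal(percent_change(43.95, 7.33), -83.3, tolerance = 0.05)
  expect_equal(percent_change(3.87, 5.6), 44.7, tolerance = 0.05)
  expect_equal(percent_change(12, 12), 0)
  expect_error(percent_change(0, 5), "> 0")
})

test_that("new-lesion detection honors the measurability floor", {
  # liver mean 2, sd 0.1 -> floor = 3.2
  p_hot <- toy_pair(new_sul = 3.5)
  expect_equal(nrow(detect_new_lesions(p_hot)), 1)
  p_cold <- toy_pair(new_sul = 3.0)
  expect_equal(nrow(detect_new_lesions(p_cold)), 0)
  expect_equal(nrow(detect_new_lesions(toy_pair())), 0)
})

test_that("threshold boundaries are inclusive as the rules state", {
  # exactly -25%: PMR under EORTC
  p <- toy_pair(baseline_suv = c(10, 10), factor = 0.75)
  expect_equal(as.character(classify_eortc(p)$category), "PMR")
  # exactly +30%: PMD under PERCIST (TLG change +30% stays below 75%);
  # sums 10 -> 13 so 100 * (13 - 10) / 10 is an exact 30 in floating point
  base <- data.frame(lesion_id = "b1", organ = "lung", suv_max = 15,
                     suv_mean = 9, suv_peak = 12, sul_peak = 10,
                     mtv_ml = 5, tlg = 45, stringsAsFactors = FALSE)
  fu <- data.frame(lesion_id = "f1", mapped_baseline_id = "b1",
                   organ = "lung", suv_max = 19.5, suv_mean = 11.7,
                   suv_peak = 15.6, sul_peak = 13, mtv_ml = 5, tlg = 58.5,
                   stringsAsFactors = FALSE)
  p2 <- scan_pair("x", base, fu,
                  liver_followup = liver_reference_values(2, 0.1))
  expect_equal(classify_percist(p2)$percent_change, 30)
  expect_equal(as.character(classify_percist(p2)$category), "PMD")
  # just inside the stable band on both sides
  p3 <- toy_pair(baseline_suv = c(10, 10), factor = 0.751)
  expect_equal(as.character(classify_eortc(p3)$category), "SMD")
  p4 <- toy_pair(baseline_suv = c(10, 10), factor = 1.299)
  expect_equal(as.character(classify_percist(p4)$category), "SMD")
})

test_that("rule precedence: new lesions, then resolution, then thresholds", {
  # a responding pair with a measurable new lesion is PMD under EORTC and
  # PERCIST but judged on the sum under imPERCIST
  p <- toy_pair(baseline_suv = c(20, 18), factor = 0.6, new_sul = 3.5)
  a <- classify_all(p)
  expect_equal(as.character(a$eortc$category), "PMD")
  expect_equal(as.character(a$percist$category), "PMD")
  # sum: baseline 0.7*38 = 26.6 -> 0.6*26.6 + 3.5 = 19.46, -26.8%: SMD
  expect_equal(as.character(a$impercist$category), "SMD")
  expect_equal(a$impercist$percent_change,
               100 * ((0.6 * 26.6 + 3.5) - 26.6) / 26.6)
  # identical scans, uptake above liver: SMD everywhere
  same <- classify_all(toy_pair(factor = 1))
  expect_true(all(vapply(same, function(x) as.character(x$category), "") ==
                    "SMD"))
})

test_that("EORTC complete response requires resolution to background", {
  # follow-up values at background (mean 1, sd 0.1 -> ceiling 1.2)
  base <- data.frame(lesion_id = "b1", organ = "lung", suv_max = 8,
                     suv_mean = 5, suv_peak = 7, sul_peak = 5.5,
                     mtv_ml = 4, tlg = 20, stringsAsFactors = FALSE)
  fu <- data.frame(lesion_id = "f1", mapped_baseline_id = "b1",
                   organ = "lung", suv_max = 1.1, suv_mean = 0.9,
                   suv_peak = 1.0, sul_peak = 0.8, mtv_ml = 0, tlg = 0,
                   stringsAsFactors = FALSE)
  p <- scan_pair("x", base, fu,
                 liver_followup = liver_reference_values(2, 0.1),
                 background_mean = 1, background_sd = 0.1)
  a <- classify_all(p)
  expect_equal(as.character(a$eortc$category), "CMR")
  expect_equal(as.character(a$percist$category), "CMR")
  expect_equal(as.character(a$impercist$category), "CMR")
  # residual just above background: PMR, not CMR, despite -86% change
  fu$suv_max <- 1.3
  p2 <- scan_pair("x", base, fu,
                  liver_followup = liver_reference_values(2, 0.1),
                  background_mean = 1, background_sd = 0.1)
  expect_equal(as.character(classify_eortc(p2)$category), "PMR")
})

test_that("PERCIST escalates on whole-body TLG increase", {
  # SUL sum change +10% (stable band) but TLG +80%: PMD under PERCIST only
  base <- data.frame(lesion_id = "b1", organ = "lung", suv_max = 10,
                     suv_mean = 6, suv_peak = 8.5, sul_peak = 7,
                     mtv_ml = 10, tlg = 60, stringsAsFactors = FALSE)
  fu <- data.frame(lesion_id = "f1", mapped_baseline_id = "b1",
                   organ = "lung", suv_max = 11, suv_mean = 6.0,
                   suv_peak = 9.3, sul_peak = 7.7, mtv_ml = 18, tlg = 108,
                   stringsAsFactors = FALSE)
  p <- scan_pair("x", base, fu,
                 liver_followup = liver_reference_values(2, 0.1))
  expect_equal(as.character(classify_percist(p)$category), "PMD")
  expect_match(classify_percist(p)$fired_rule, "TLG")
  expect_equal(as.character(classify_impercist(p)$category), "SMD")
})

test_that("PERCIST and imPERCIST coincide without new lesions or TLG surge", {
  set.seed(23)
  for (rep in 1:25) {
    f <- runif(1, 0.3, 1.6)
    p <- toy_pair(baseline_suv = runif(3, 4, 15), factor = f,
                  organs = c("a", "b", "c"))
    # toy TLG scales with the factor, so its change stays below +75% here
    expect_equal(as.character(classify_percist(p)$category),
                 as.character(classify_impercist(p)$category))
  }
})

test_that("category worsens monotonically with percent change", {
  cats <- vapply(c(0.4, 0.74, 0.76, 1.0, 1.24, 1.35, 2.0), function(f) {
    as.character(classify_percist(toy_pair(baseline_suv = c(12, 10),
                                           factor = f))$category)
  }, "")
  idx <- match(cats, RESPONSE_LEVELS)
  # CMR cannot occur here (uptake stays above liver), so index runs PMR..PMD
  expect_true(all(diff(idx) >= 0))
})

test_that("the worked example cases reproduce their published assessments", {
  a1 <- classify_all(example_scan_pair("nodal-regression"))
  expect_equal(as.character(a1$eortc$category), "PMR")
  expect_equal(as.character(a1$percist$category), "CMR")
  expect_equal(as.character(a1$impercist$category), "CMR")
  expect_equal(round(a1$eortc$percent_change, 1), -83.3)
  a2 <- classify_all(example_scan_pair("new-lesion"))
  expect_equal(as.character(a2$eortc$category), "PMD")
  expect_equal(as.character(a2$percist$category), "PMD")
  expect_equal(as.character(a2$impercist$category), "PMD")
  expect_equal(round(a2$impercist$percent_change, 1), 44.7)
  expect_equal(a2$impercist$baseline_sum, 3.87)
  expect_equal(a2$impercist$followup_sum, 5.60)
})

test_that("classification requires baseline disease and a liver reference", {
  base <- data.frame(lesion_id = character(0), organ = character(0),
                     suv_max = numeric(0), sul_peak = numeric(0),
                     stringsAsFactors = FALSE)
  p <- scan_pair("x", base, cbind(base, mapped_baseline_id = character(0)),
                 liver_followup = liver_reference_values(2, 0.1))
  expect_error(classify_eortc(p), "baseline lesion")
  expect_error(classify_percist(p), "baseline lesion")
})
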