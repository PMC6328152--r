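test_that("both frequency scales satisfy the validity contract", {
  scales <- ffq_scales()
  expect_named(scales, c("standard8", "meat6"))
  expect_length(scales$standard8$options, 8)
  expect_length(scales$meat6$options, 6)
  for (sc in scales) {
    expect_identical(unname(sc$weights[1]), 0)
    expect_true(all(diff(sc$weights) >= 0))
    expect_identical(sc$options[1], "Rarely or Never")
  }
  expect_gte(unname(rev(scales$standard8$weights)[1]), 5)
  expect_identical(rev(scales$standard8$options)[1], "5+ a day")
  expect_identical(rev(scales$meat6$options)[1], "At least everyday")
})

test_that("frequency weights honor the conversion protocol anchors", {
  expect_identical(frequency_weight("Rarely or Never", "standard8"), 0)
  expect_equal(frequency_weight("Once per week", "standard8"), 1 / 7)
  expect_equal(round(frequency_weight("Once per week", "standard8"), 5),
               0.14286)
  expect_identical(frequency_weight("1-2 times a day", "standard8"), 1.5)
  expect_identical(frequency_weight("Rarely or Never", "meat6"), 0)
  expect_error(frequency_weight("Twice a fortnight", "standard8"),
               "standard8")
})

test_that("the packaged instrument has 23 categories with 7 on the meat scale", {
  inst <- default_ffq_instrument()
  expect_equal(nrow(inst$categories), 23)
  expect_equal(sum(inst$categories$scale_id == "meat6"), 7)
  expect_equal(sum(inst$categories$scale_id == "standard8"), 16)
  cheese <- inst$categories[inst$categories$label == "Cheese and yoghurt", ]
  expect_equal(cheese$kcal_100g, 245.5)
})

test_that("daily conversion multiplies weights by per-100g category means", {
  inst <- tiny_instrument()
  # worked example: one category at 1.5 occasions/day and 245.5 kcal/100g
  resp <- data.frame(
    category_label = c("Cheese and yoghurt", "Fresh fruit",
                       "Beef, lamb or pork"),
    option_label = c("1-2 times a day", "Rarely or Never", "Rarely or Never")
  )
  prof <- ffq_daily_nutrients(resp, inst)
  expect_equal(prof[["calories"]], 1.5 * 245.5)
  expect_equal(prof[["calories"]], 368.25)
  expect_equal(prof[["fat"]], 1.5 * 18.5)

  # all rarely/never is an all-zero day
  zero <- data.frame(category_label = inst$categories$label,
                     option_label = "Rarely or Never")
  expect_true(all(unclass(ffq_daily_nutrients(zero, inst)) == 0))

  # two categories once a week: (70 + 140) / 7 = 30 kcal/day
  inst2 <- ffq_instrument(data.frame(
    label = c("a", "b"), scale_id = "standard8", kcal_100g = c(70, 140)
  ))
  resp2 <- data.frame(category_label = c("a", "b"),
                      option_label = "Once per week")
  expect_equal(ffq_daily_nutrients(resp2, inst2)[["calories"]], 30)
})

test_that("conversion is monotone in the scale and linear over categories", {
  inst <- tiny_instrument()
  scales <- inst$scales
  base <- data.frame(category_label = inst$categories$label,
                     option_label = "Once per week")
  base_prof <- ffq_daily_nutrients(base, inst)
  for (k in seq_len(nrow(inst$categories))) {
    sc <- scales[[inst$categories$scale_id[k]]]
    for (opt in sc$options) {
      resp <- base
      resp$option_label[k] <- opt
      prof <- ffq_daily_nutrients(resp, inst)
      cmp <- if (frequency_weight(opt, sc) >= 1 / 7) expect_gte else expect_lte
      for (nut in c("calories", "fat", "sugar", "protein")) {
        cmp(prof[[nut]], base_prof[[nut]])
      }
    }
  }
  # the multi-category estimate is the sum of single-category estimates
  single <- lapply(seq_len(nrow(inst$categories)), function(k) {
    resp <- data.frame(category_label = inst$categories$label,
                       option_label = "Rarely or Never")
    resp$option_label[k] <- "Once per week"
    ffq_daily_nutrients(resp, inst)[["calories"]]
  })
  expect_equal(base_prof[["calories"]], sum(unlist(single)))
})

test_that("incomplete or invalid responses are rejected with names", {
  inst <- tiny_instrument()
  partial <- data.frame(category_label = "Fresh fruit",
                        option_label = "Once per week")
  expect_error(ffq_daily_nutrients(partial, inst), "Cheese and yoghurt")
  # a meat category cannot use a standard-only option
  bad <- data.frame(
    category_label = inst$categories$label,
    option_label = c("Once per week", "Once per week", "5+ a day")
  )
  expect_error(ffq_daily_nutrients(bad, inst), "meat6")
})

test_that("the portion multiplier rescales single categories", {
  inst <- tiny_instrument()
  resp <- data.frame(category_label = inst$categories$label,
                     option_label = c("1-2 times a day", "Rarely or Never",
                                      "Rarely or Never"))
  prof <- ffq_daily_nutrients(resp, inst,
                              portion_multiplier = c("Cheese and yoghurt" = 0.5))
  expect_equal(prof[["calories"]], 0.5 * 368.25)
})

test_that("responses round-trip through the CSV interface", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,category_label,option_label",
               "P1,Cheese and yoghurt,1-2 times a day",
               "P1,Fresh fruit,Rarely or Never",
               "P1,\"Beef, lamb or pork\",Rarely or Never"), path)
  resp <- read_ffq_responses(path)
  expect_named(resp, "P1")
  expect_equal(ffq_daily_nutrients(resp$P1, tiny_instrument())[["calories"]],
               368.25)
  unlink(path)
})
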