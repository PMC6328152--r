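test_that("packaged fixture covers all six categories with valid items", {
  catalog <- default_catalog()
  expect_equal(nrow(catalog), 117)
  expect_setequal(unique(catalog$category), food_categories())
  expect_true(all(catalog$price_pence > 0))
  expect_true(all(is.na(catalog$salt_100g)))
  expect_true(all(catalog$satfat_100g <= catalog$fat_100g))
  expect_true(all(catalog$sugar_100g <= catalog$carb_100g))
})

test_that("nutrient profile invariants are enforced", {
  expect_error(nutrient_profile(calories = -1), "negative")
  expect_error(nutrient_profile(fat = 1, saturated_fat = 2), "saturated_fat")
  expect_error(nutrient_profile(carbohydrates = 5, sugar = 6), "sugar")
  p <- nutrient_profile(calories = 100, fat = 2, saturated_fat = 1)
  expect_s3_class(p, "nutrient_profile")
  expect_true(is.na(p[["salt"]]))
})

test_that("category means average per-item values and respect bounds", {
  catalog <- tiny_catalog()
  means <- category_nutrient_means(catalog)
  # single item per category: the mean is the item itself
  expect_equal(means$calories[means$category == "meat_fish"], 233.2)
  expect_equal(means$calories[means$category == "confectionery"], 480)

  full <- default_catalog()
  fm <- category_nutrient_means(full)
  for (cc in food_categories()) {
    sub <- full[full$category == cc, ]
    row <- fm[fm$category == cc, ]
    for (nut in c("calories", "fat", "carbohydrates", "protein")) {
      col <- c(calories = "kcal_100g", fat = "fat_100g",
               carbohydrates = "carb_100g", protein = "protein_100g")[[nut]]
      expect_gte(row[[nut]], min(sub[[col]]))
      expect_lte(row[[nut]], max(sub[[col]]))
    }
  }
  # absent categories are absent from the result
  part <- category_nutrient_means(tiny_catalog()[1:2, ])
  expect_setequal(part$category, c("fruit_veg", "meat_fish"))
})

test_that("empty catalogs are valid and give empty means", {
  empty <- tiny_catalog()[0, ]
  expect_silent(validate_catalog(empty))
  expect_equal(nrow(category_nutrient_means(empty)), 0)
})

test_that("schema and invariant violations are rejected with named causes", {
  catalog <- as.data.frame(tiny_catalog())
  expect_error(validate_catalog(catalog[, -3]), "category")
  dup <- rbind(catalog, catalog[1, ])
  expect_error(validate_catalog(dup), "itemA")
  bad_price <- catalog
  bad_price$price_pence[2] <- -5
  expect_error(validate_catalog(bad_price), "price")
  bad_cat <- catalog
  bad_cat$category[1] <- "sweets"
  expect_error(validate_catalog(bad_cat), "sweets")
  bad_nut <- catalog
  bad_nut$kcal_100g[3] <- -1
  expect_error(validate_catalog(bad_nut), "itemC")
})

test_that("catalog round-trips through CSV and JSON field for field", {
  catalog <- tiny_catalog()
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_catalog(catalog, path)
    back <- load_catalog(path)
    expect_equal(as.data.frame(back), as.data.frame(catalog),
                 ignore_attr = TRUE)
    # unavailable nutrients stay flagged
    expect_true(all(is.na(back$salt_100g)))
    unlink(path)
  }
  # empty catalog round-trips too
  path <- tempfile(fileext = ".csv")
  write_catalog(tiny_catalog()[0, ], path)
  expect_equal(nrow(load_catalog(path)), 0)
  unlink(path)
})

test_that("pack nutrient totals scale per-100g values by pack size", {
  catalog <- tiny_catalog()
  pk <- item_pack_nutrients(catalog, "itemB")
  expect_equal(pk[["calories"]], 233.2 * 460 / 100)
  expect_equal(pk[["protein"]], 19 * 4.6)
  expect_error(item_pack_nutrients(catalog, "nope"), "unknown")
})
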