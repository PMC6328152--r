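test_that("set_quantity adds, updates and removes lines", {
  catalog <- tiny_catalog()
  b <- new_basket("P1")
  b <- set_quantity(b, "itemA", 3, catalog)
  expect_equal(b$lines$quantity, 3L)
  b <- set_quantity(b, "itemA", 1, catalog)
  expect_equal(b$lines$quantity, 1L)
  b <- set_quantity(b, "itemA", 0, catalog)
  expect_equal(nrow(b$lines), 0)
  expect_error(set_quantity(b, "ghost", 1, catalog), "unknown item_id")
  expect_error(set_quantity(b, "itemA", -1, catalog), "non-negative")
  expect_error(set_quantity(b, "itemA", 1.5, catalog), "integer")
})

test_that("total cost sums quantity times price in integer pence", {
  catalog <- tiny_catalog()
  b <- new_basket("P1")
  expect_identical(total_cost(b, catalog), 0L)
  b <- set_quantity(b, "itemF", 2, catalog) # 2 x 120p
  expect_identical(total_cost(b, catalog), 240L)
  b2 <- new_basket("P2")
  b2 <- set_quantity(b2, "itemA", 2, catalog) # 2 x 199p
  b2 <- set_quantity(b2, "itemB", 1, catalog) # 1 x 350p
  expect_identical(total_cost(b2, catalog), 748L)
})

test_that("nutrient totals scale with packs and add over disjoint baskets", {
  catalog <- tiny_catalog()
  b <- new_basket("P1")
  expect_equal(unname(unclass(nutrient_totals(b, catalog))), rep(0, 8))
  b <- set_quantity(b, "itemB", 2, catalog) # 2 x 460 g at 233.2 kcal/100g
  expect_equal(nutrient_totals(b, catalog)[["calories"]], 2145.44)
  # unavailable salt stays flagged while others compute
  expect_true(is.na(nutrient_totals(b, catalog)[["salt"]]))

  b1 <- set_quantity(new_basket("P1"), "itemA", 2, catalog)
  b2 <- set_quantity(new_basket("P1"), "itemD", 3, catalog)
  both <- set_quantity(set_quantity(new_basket("P1"), "itemA", 2, catalog),
                       "itemD", 3, catalog)
  for (nut in c("calories", "fat", "sugar", "protein")) {
    expect_equal(nutrient_totals(both, catalog)[[nut]],
                 nutrient_totals(b1, catalog)[[nut]] +
                   nutrient_totals(b2, catalog)[[nut]])
  }
})

test_that("checkout enforces the budget ceiling and advisory margin", {
  catalog <- tiny_catalog()
  # exact boundary: cost == budget accepted with zero change
  b <- set_quantity(new_basket("P1", budget = 398L), "itemA", 2, catalog)
  res <- checkout(b, catalog)
  expect_true(res$accepted)
  expect_identical(res$change, 0L)
  expect_false(res$underspend_warning)

  # overspend rejected, reason names the excess, basket stays open
  b <- set_quantity(new_basket("P2", budget = 348L), "itemA", 2, catalog)
  res <- checkout(b, catalog)
  expect_false(res$accepted)
  expect_match(res$reason, "50p")
  expect_identical(res$basket$status, "open")

  # underspend beyond the margin warns but is accepted
  b <- set_quantity(new_basket("P3", budget = 3000L, margin = 100L),
                    "itemA", 2, catalog) # cost 398, change 2602
  res <- checkout(b, catalog)
  expect_true(res$accepted)
  expect_true(res$underspend_warning)
  expect_identical(res$change, 2602L)
})

test_that("a checked-out basket is frozen and re-checkout is idempotent", {
  catalog <- tiny_catalog()
  b <- set_quantity(new_basket("P1"), "itemC", 2, catalog)
  res <- checkout(b, catalog)
  expect_true(res$accepted)
  frozen <- res$basket
  expect_error(set_quantity(frozen, "itemA", 1, catalog), "checked out")
  again <- checkout(frozen, catalog)
  expect_true(again$accepted)
  expect_identical(again$total_cost, res$total_cost)
  expect_identical(again$change, res$change)
})

test_that("category vectors conserve cost and counts on random baskets", {
  catalog <- default_catalog()
  set.seed(401)
  for (i in 1:50) {
    b <- random_basket(catalog)
    expect_identical(sum(spend_by_category(b, catalog)),
                     as.numeric(total_cost(b, catalog)))
    expect_identical(sum(items_by_category(b, catalog)),
                     as.numeric(sum(b$lines$quantity)))
  }
  # a basket entirely of confectionery lands entirely in that slot
  sweets <- catalog$item_id[catalog$category == "confectionery"][1:3]
  b <- new_basket("P1")
  for (iid in sweets) b <- set_quantity(b, iid, 1, catalog)
  spend <- spend_by_category(b, catalog)
  expect_equal(unname(spend["confectionery"]), as.numeric(total_cost(b, catalog)))
  expect_equal(sum(spend[names(spend) != "confectionery"]), 0)
})

test_that("cost and nutrients are monotone and linear in quantities", {
  catalog <- tiny_catalog()
  set.seed(77)
  for (i in 1:20) {
    b <- random_basket(catalog, budget = 10000L)
    iid <- sample(catalog$item_id, 1)
    q0 <- if (iid %in% b$lines$item_id) {
      b$lines$quantity[b$lines$item_id == iid]
    } else 0L
    b_up <- set_quantity(b, iid, q0 + 2L, catalog)
    expect_gte(total_cost(b_up, catalog), total_cost(b, catalog))
    n0 <- nutrient_totals(b, catalog)
    n1 <- nutrient_totals(b_up, catalog)
    for (nut in c("calories", "fat", "carbohydrates", "protein")) {
      expect_gte(n1[[nut]], n0[[nut]])
    }
    # doubling all quantities doubles every available nutrient
    b2 <- b
    for (j in seq_len(nrow(b$lines))) {
      b2 <- set_quantity(b2, b$lines$item_id[j], 2L * b$lines$quantity[j],
                         catalog)
    }
    for (nut in c("calories", "sugar", "protein")) {
      expect_equal(nutrient_totals(b2, catalog)[[nut]],
                   2 * nutrient_totals(b, catalog)[[nut]])
    }
  }
})

test_that("baskets read from CSV resolve against the catalog", {
  catalog <- tiny_catalog()
  path <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,item_id,quantity",
               "P1,itemA,2", "P1,itemB,1", "P2,itemF,3"), path)
  baskets <- read_baskets(path, catalog)
  expect_named(baskets, c("P1", "P2"))
  expect_identical(total_cost(baskets$P1, catalog), 748L)
  expect_identical(total_cost(baskets$P2, catalog), 360L)
  writeLines(c("participant_id,item_id", "P1,itemA"), path)
  expect_error(read_baskets(path, catalog), "quantity")
  unlink(path)
})
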