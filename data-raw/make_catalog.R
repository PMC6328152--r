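# Builds inst/extdata/catalog_synthetic.csv — the packaged catalog fixture.
#
# The item list (names, categories, pack sizes) follows the instrument's
# published 117-item listing; prices are plausible March-2016 UK supermarket
# prices in pence; per-item per-100g nutrient values are SYNTHETIC, drawn
# around each category's published per-100g mean and then renormalized so the
# unweighted category means reproduce those published values exactly:
#   calories / fat / satfat / carbs / sugar / protein
#   fruit_veg      47.4 / 0.5 / 0.1 / 9.7 / 7.2 / 1.4
#   meat_fish     233.2 / 13.9 / 4.9 / 7.5 / 0.8 / 19.4
#   bread_grains  212.1 / 1.9 / 0.4 / 40.6 / 2.4 / 7.0
#   confectionery 471.9 / 22.5 / 9.1 / 59.4 / 33.1 / 6.4
#   ready_meals   157.7 / 6.9 / 2.6 / 15.3 / 2.6 / 7.1
#   drinks         40.5 / 0.2 / 0.1 / 9.9 / 9.2 / 0.6
# Salt and fibre are carried in the schema but left unavailable.
# Item-count packs ("x6") are converted to grams with per-item unit weights;
# liquids use mL = g. Run from the package root: Rscript data-raw/make_catalog.R

items_csv <- '
item_id,name,category,price_pence,pack_size_g
FV01,"Royal Gala Apples, x5",fruit_veg,170,750
FV02,"Fairtrade Bananas, x5",fruit_veg,90,600
FV03,"Oranges, x6",fruit_veg,150,900
FV04,"Red Grapes, 500g",fruit_veg,200,500
FV05,"Conference Pears, x4",fruit_veg,140,640
FV06,"Raspberries, 150g",fruit_veg,200,150
FV07,"Strawberries, 400g",fruit_veg,250,400
FV08,"Peaches, x4",fruit_veg,150,440
FV09,"Kiwi Fruit, x4",fruit_veg,100,300
FV10,"Lemons, x5",fruit_veg,130,350
FV11,"Cherry Tomatoes, 650g",fruit_veg,220,650
FV12,"White Mushrooms, 300g",fruit_veg,100,300
FV13,"Maris Piper Potatoes, 2.5kg",fruit_veg,200,2500
FV14,"Sweet Potatoes, 1.25kg",fruit_veg,150,1250
FV15,"Mixed Peppers, x3",fruit_veg,150,480
FV16,"Carrots, 1kg",fruit_veg,70,1000
FV17,"Onions, 1kg",fruit_veg,85,1000
FV18,"Fine Beans, 200g",fruit_veg,120,200
FV19,"Broccoli, 335g",fruit_veg,70,335
FV20,"Sweetcorn, x2",fruit_veg,120,400
MF01,"Chicken Breast Fillets, 460g",meat_fish,380,460
MF02,"Chicken Kiev, Garlic, x2",meat_fish,250,260
MF03,"Chicken Goujons, 245g",meat_fish,250,245
MF04,"Chicken Pie, 550g",meat_fish,300,550
MF05,"Beef Rump Steak, 250g",meat_fish,400,250
MF06,"Beef Mince, 500g",meat_fish,330,500
MF07,"Steak Burgers, 340g",meat_fish,280,340
MF08,"Steak and Ale Pie, 550g",meat_fish,320,550
MF09,"Pork Chops, 450g",meat_fish,350,450
MF10,"Pork Sausages, 400g",meat_fish,200,400
MF11,"Mini Pork Pies, 300g",meat_fish,180,300
MF12,"Smoked Bacon, 300g",meat_fish,220,300
MF13,"Lamb Chops, 275g",meat_fish,450,275
MF14,"Salmon fillets, 240g",meat_fish,400,240
MF15,"Cod fillets, 250g",meat_fish,380,250
MF16,"Sea Bass Fillets, 180g",meat_fish,420,180
MF17,"King Prawns, 150g",meat_fish,350,150
MF18,"Breaded Cod, 350g",meat_fish,300,350
MF19,"Smoked Haddock with Cheese, 400g",meat_fish,350,400
MF20,"Salmon en Croute, 380g",meat_fish,375,380
MF21,"Cod Fish Fingers, 480g",meat_fish,230,480
MF22,"Mackerel in Garlic Butter, 340g",meat_fish,250,340
BG01,"Sliced White Bread, 800g",bread_grains,100,800
BG02,"Sliced 50/50 Bread, 800g",bread_grains,110,800
BG03,"Sliced Wholemeal Bread, 800g",bread_grains,110,800
BG04,"White Baguettes, x2",bread_grains,85,400
BG05,"Brown Baguettes, x2",bread_grains,90,400
BG06,"White Rolls, x8",bread_grains,100,480
BG07,"Wholemeal Rolls, x8",bread_grains,110,480
BG08,"Crumpets, 400g",bread_grains,100,400
BG09,"Plain Naan Bread, 260g",bread_grains,120,260
BG10,"Brown Soda Bread, 400g",bread_grains,150,400
BG11,"Tortilla Wraps, x8",bread_grains,130,500
BG12,"Basmati Rice, 1kg",bread_grains,180,1000
BG13,"Brown Basmati Rice, 1kg",bread_grains,200,1000
BG14,"Penne Pasta, 1kg",bread_grains,100,1000
BG15,"Wholewheat Penne, 1kg",bread_grains,120,1000
BG16,"Spaghetti, 500g",bread_grains,70,500
BG17,"Wholewheat Spaghetti, 500g",bread_grains,85,500
BG18,"Cous Cous, 1kg",bread_grains,160,1000
BG19,"Quinoa, 300g",bread_grains,250,300
BG20,"Egg Noodles, 375g",bread_grains,120,375
CS01,"Dairy Milk Chocolate, 200g",confectionery,200,200
CS02,"70% Dark Chocolate, 100g",confectionery,150,100
CS03,"Mars Bars, x4",confectionery,150,180
CS04,"Snickers, x4",confectionery,150,180
CS05,"M&Ms Peanut, 165g",confectionery,180,165
CS06,"Nutella, 400g",confectionery,300,400
CS07,"Starmix Candy, 215g",confectionery,130,215
CS08,"Jelly Babies, 190g",confectionery,130,190
CS09,"Marshmallows, 200g",confectionery,100,200
CS10,"Chocolate Chip Brioche, x8",confectionery,150,280
CS11,"Chocolate Digestives, 300g",confectionery,150,300
CS12,"Chocolate HobNobs, 262g",confectionery,160,262
CS13,"Shortbread Fingers, 400g",confectionery,180,400
CS14,"Custard Creams, 400g",confectionery,80,400
CS15,"Chocolate Cookies, 175g",confectionery,120,175
CS16,"Pringles Original, 190g",confectionery,200,190
CS17,"Salt & Vinegar Chips, 150g",confectionery,150,150
CS18,"Cheese & Onion Crisps, 6x25g",confectionery,130,150
CS19,"Corn Chips, 200g",confectionery,120,200
CS20,"Croissants, x8",confectionery,160,320
RM01,"Cheese & Tomato Pizza, 10in",ready_meals,200,330
RM02,"Pepperoni Pizza, 10in",ready_meals,250,340
RM03,"Beef Lasagne, 430g",ready_meals,250,430
RM04,"Macaroni Cheese, 430g",ready_meals,200,430
RM05,"Chicken & Bacon Pasta Bake, 430g",ready_meals,220,430
RM06,"Cottage Pie, 450g",ready_meals,250,450
RM07,"Beef Stew, 450g",ready_meals,300,450
RM08,"Chicken Tikka & Rice, 500g",ready_meals,280,500
RM09,"Beef Burrito, 400g",ready_meals,280,400
RM10,"Chicken Chow Mein, 450g",ready_meals,250,450
RM11,"Beef Satay, 380g",ready_meals,300,380
RM12,"Chicken Ramen, 380g",ready_meals,280,380
RM13,"Pigs in Blankets, 260g",ready_meals,220,260
RM14,"Vegetarian Cannelloni, 430g",ready_meals,220,430
RM15,"Vegetable Spring Rolls, 60g",ready_meals,90,60
RM16,"Vegetable Biryani, 500g",ready_meals,250,500
RM17,"Tomato & Mozzarella Bake, 430g",ready_meals,220,430
RM18,"Lentil Cottage Pie, 400g",ready_meals,220,400
RM19,"Mushroom Risotto, 430g",ready_meals,220,430
RM20,"Tomato Soup, 600g",ready_meals,150,600
DR01,"Blackcurrant Squash, 850ml",drinks,180,850
DR02,"Orange & Passion Fruit Drink, 4x275ml",drinks,200,1100
DR03,"Coconut Water, 1L",drinks,250,1000
DR04,"Sports Drink, 1L",drinks,120,1000
DR05,"Energy Drink, 1L",drinks,180,1000
DR06,"Ginger Beer, 1.5L",drinks,150,1500
DR07,"Tonic Water, 1L",drinks,100,1000
DR08,"Coke, 1.75L",drinks,180,1750
DR09,"Irn Bru, 2L",drinks,180,2000
DR10,"Fanta, 2L",drinks,170,2000
DR11,"Orange Juice, 1L",drinks,150,1000
DR12,"Mango & Passion Fruit Smoothie, 750ml",drinks,250,750
DR13,"Still Water, 6x500ml",drinks,110,3000
DR14,"Chocolate Milkshake, 1L",drinks,150,1000
DR15,"Soya Milk, 1L",drinks,140,1000
'

items <- read.csv(text = items_csv, stringsAsFactors = FALSE)
stopifnot(nrow(items) == 117, !anyDuplicated(items$item_id))

targets <- data.frame(
  category = c("fruit_veg", "meat_fish", "bread_grains", "confectionery",
               "ready_meals", "drinks"),
  kcal = c(47.4, 233.2, 212.1, 471.9, 157.7, 40.5),
  fat = c(0.5, 13.9, 1.9, 22.5, 6.9, 0.2),
  satfat = c(0.1, 4.9, 0.4, 9.1, 2.6, 0.1),
  carb = c(9.7, 7.5, 40.6, 59.4, 15.3, 9.9),
  sugar = c(7.2, 0.8, 2.4, 33.1, 2.6, 9.2),
  protein = c(1.4, 19.4, 7.0, 6.4, 7.1, 0.6)
)

set.seed(20160301)

# multiplicative spread with exact unit mean, so column means hit targets
spread <- function(n, sd) {
  u <- exp(rnorm(n, 0, sd))
  u / mean(u)
}
# bounded spread for the satfat/fat and sugar/carb ratios, so renormalizing
# the child column can never push a ratio above 1
bounded <- function(n, lo, hi) {
  v <- runif(n, lo, hi)
  v / mean(v)
}

cols <- c("kcal_100g", "fat_100g", "satfat_100g", "carb_100g", "sugar_100g",
          "protein_100g")
for (col in cols) items[[col]] <- NA_real_

for (i in seq_len(nrow(targets))) {
  tg <- targets[i, ]
  idx <- which(items$category == tg$category)
  n <- length(idx)
  kcal <- tg$kcal * spread(n, 0.25)
  fat <- tg$fat * spread(n, 0.30)
  carb <- tg$carb * spread(n, 0.25)
  protein <- tg$protein * spread(n, 0.30)
  sf_ratio_range <- c(0.85, 1.15)
  su_ratio_range <- if (tg$sugar / tg$carb > 0.85) c(0.98, 1.02) else c(0.85, 1.15)
  satfat <- fat * (tg$satfat / tg$fat) * bounded(n, sf_ratio_range[1], sf_ratio_range[2])
  sugar <- carb * (tg$sugar / tg$carb) * bounded(n, su_ratio_range[1], su_ratio_range[2])
  satfat <- satfat * tg$satfat / mean(satfat)
  sugar <- sugar * tg$sugar / mean(sugar)
  stopifnot(all(satfat <= fat), all(sugar <= carb))
  items$kcal_100g[idx] <- round(kcal, 4)
  items$fat_100g[idx] <- round(fat, 4)
  items$satfat_100g[idx] <- round(satfat, 4)
  items$carb_100g[idx] <- round(carb, 4)
  items$sugar_100g[idx] <- round(sugar, 4)
  items$protein_100g[idx] <- round(protein, 4)
}

items$salt_100g <- NA_real_
items$fibre_100g <- NA_real_

# calibration contract: unweighted category means reproduce the published
# per-100g table to 1 decimal place
for (i in seq_len(nrow(targets))) {
  idx <- which(items$category == targets$category[i])
  got <- sapply(items[idx, cols], mean)
  want <- as.numeric(targets[i, c("kcal", "fat", "satfat", "carb", "sugar",
                                  "protein")])
  stopifnot(all(round(got, 1) == round(want, 1)))
}
stopifnot(all(items$satfat_100g <= items$fat_100g),
          all(items$sugar_100g <= items$carb_100g))

out <- items[, c("item_id", "name", "category", "price_pence", "pack_size_g",
                 "kcal_100g", "fat_100g", "satfat_100g", "carb_100g",
                 "sugar_100g", "salt_100g", "protein_100g", "fibre_100g")]
write.csv(out, "inst/extdata/catalog_synthetic.csv", row.names = FALSE,
          na = "")
cat("wrote", nrow(out), "items\n")
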