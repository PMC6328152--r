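# 23-category dietary screener instrument: 16 categories on the standard
# 8-option scale, 7 meat and fish categories on the 6-option scale.
#
# SYNTHETIC nutrient table: the deployed screener's per-category average
# nutrient values (per 100g, derived from popular supermarket products) were
# not published. The values below are plausible stand-ins; the cheese/yoghurt
# category carries 245.5 kcal/100g, the value used in the conversion
# protocol's worked example. Salt and fibre are unavailable.
categories:
  - label: "Breakfast cereal"
    scale: standard8
    per_100g: {calories: 380, fat: 3.0, saturated_fat: 0.8, carbohydrates: 75, sugar: 20, protein: 8.0}
  - label: "Milk"
    scale: standard8
    per_100g: {calories: 64, fat: 3.6, saturated_fat: 2.3, carbohydrates: 4.7, sugar: 4.7, protein: 3.4}
  - label: "Fizzy soft drinks"
    scale: standard8
    per_100g: {calories: 42, fat: 0.0, saturated_fat: 0.0, carbohydrates: 10.5, sugar: 10.5, protein: 0.0}
  - label: "Fruit juice"
    scale: standard8
    per_100g: {calories: 45, fat: 0.1, saturated_fat: 0.0, carbohydrates: 10.3, sugar: 9.8, protein: 0.5}
  - label: "Fresh fruit"
    scale: standard8
    per_100g: {calories: 52, fat: 0.3, saturated_fat: 0.1, carbohydrates: 12, sugar: 10, protein: 0.6}
  - label: "Green leafy salad"
    scale: standard8
    per_100g: {calories: 18, fat: 0.3, saturated_fat: 0.1, carbohydrates: 2.5, sugar: 1.8, protein: 1.4}
  - label: "Chips and fried potatoes"
    scale: standard8
    per_100g: {calories: 270, fat: 13, saturated_fat: 3.5, carbohydrates: 34, sugar: 0.7, protein: 3.5}
  - label: "Other potatoes"
    scale: standard8
    per_100g: {calories: 90, fat: 0.2, saturated_fat: 0.1, carbohydrates: 20, sugar: 1.0, protein: 2.0}
  - label: "Beans and pulses"
    scale: standard8
    per_100g: {calories: 95, fat: 0.6, saturated_fat: 0.1, carbohydrates: 15, sugar: 3.0, protein: 5.5}
  - label: "Other vegetables"
    scale: standard8
    per_100g: {calories: 35, fat: 0.4, saturated_fat: 0.1, carbohydrates: 6.0, sugar: 4.0, protein: 1.5}
  - label: "Bread and rolls"
    scale: standard8
    per_100g: {calories: 250, fat: 2.0, saturated_fat: 0.4, carbohydrates: 47, sugar: 3.5, protein: 9.0}
  - label: "Rice, pasta and grains"
    scale: standard8
    per_100g: {calories: 140, fat: 1.0, saturated_fat: 0.2, carbohydrates: 29, sugar: 0.5, protein: 3.5}
  - label: "Cheese and yoghurt"
    scale: standard8
    per_100g: {calories: 245.5, fat: 18.5, saturated_fat: 11.5, carbohydrates: 5.5, sugar: 5.2, protein: 14}
  - label: "Chocolate and sweets"
    scale: standard8
    per_100g: {calories: 480, fat: 22, saturated_fat: 13, carbohydrates: 62, sugar: 55, protein: 5.0}
  - label: "Cakes, biscuits and pastries"
    scale: standard8
    per_100g: {calories: 430, fat: 19, saturated_fat: 9.0, carbohydrates: 58, sugar: 32, protein: 5.5}
  - label: "Ice cream and desserts"
    scale: standard8
    per_100g: {calories: 210, fat: 10, saturated_fat: 6.5, carbohydrates: 26, sugar: 22, protein: 3.5}
  - label: "Beef, lamb or pork"
    scale: meat6
    per_100g: {calories: 230, fat: 14, saturated_fat: 5.5, carbohydrates: 1.0, sugar: 0.5, protein: 25}
  - label: "Chicken or turkey"
    scale: meat6
    per_100g: {calories: 160, fat: 6.0, saturated_fat: 1.7, carbohydrates: 0.5, sugar: 0.3, protein: 26}
  - label: "Ham and lunch meats"
    scale: meat6
    per_100g: {calories: 200, fat: 12, saturated_fat: 4.5, carbohydrates: 2.0, sugar: 1.5, protein: 20}
  - label: "Sausages and bacon"
    scale: meat6
    per_100g: {calories: 290, fat: 24, saturated_fat: 9.0, carbohydrates: 3.0, sugar: 1.0, protein: 16}
  - label: "White fish in batter or breadcrumbs"
    scale: meat6
    per_100g: {calories: 220, fat: 11, saturated_fat: 1.5, carbohydrates: 16, sugar: 0.8, protein: 13}
  - label: "Other fish and seafood"
    scale: meat6
    per_100g: {calories: 150, fat: 7.0, saturated_fat: 1.5, carbohydrates: 0.5, sugar: 0.3, protein: 21}
  - label: "Burgers and kebabs"
    scale: meat6
    per_100g: {calories: 260, fat: 17, saturated_fat: 7.0, carbohydrates: 8.0, sugar: 1.5, protein: 18}
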