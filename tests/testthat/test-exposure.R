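# catalogue whose four items realise the worked example: per 100 g energies
# chosen so that 100 g servings give 2000/1500/500/400 kJ
worked_catalogue <- function() {
  make_items(
    list(item_id = "lh_food", item_class = "food", energy_kj = 2000,
         satfat_g = 10, sugars_g = 30, sodium_mg = 700),
    list(item_id = "ok_food", item_class = "food", energy_kj = 1500,
         fibre_g = 3, protein_g = 6, fvn_pct = 50),
    list(item_id = "lh_bev", item_class = "beverage", energy_kj = 500,
         sugars_g = 10),
    list(item_id = "beer", item_class = "alcoholic_beverage", energy_kj = 400)
  )
}

worked_diary <- function(days = 1L) {
  tibble::tibble(
    participant_id = "P1",
    day_index = rep_len(seq_len(days), 4),
    item_id = c("lh_food", "ok_food", "lh_bev", "beer"),
    grams = 100
  )
}

test_that("the proportion-of-energy formula gives 0.625 on the worked diary", {
  cat0 <- worked_catalogue()
  scored <- score_catalogue(cat0, quiet = TRUE)
  expect_identical(scored$classification,
                   c("less_healthy", "healthy", "less_healthy", "unscored"))
  ex <- build_exposure(worked_diary(), scored, cat0)
  expect_identical(ex$prop_lh_energy, (2000 + 500) / (4400 - 400))
  expect_identical(ex$energy_total, 4400)
  expect_identical(ex$energy_alcoholic, 400)
  expect_identical(ex$energy_lh_food + ex$energy_lh_bev, 2500)
})

test_that("exposure proportions ignore diary-day partitioning; per-day energies scale", {
  cat0 <- worked_catalogue()
  scored <- score_catalogue(cat0, quiet = TRUE)
  one <- build_exposure(worked_diary(1L), scored, cat0)
  two <- build_exposure(worked_diary(2L), scored, cat0)
  expect_identical(one$prop_lh_energy, two$prop_lh_energy)
  expect_identical(two$n_diary_days, 2L)
  expect_equal(two$energy_total, one$energy_total / 2)
})

test_that("record order never matters", {
  cat0 <- random_catalogue(40, seed = 5)
  scored <- score_catalogue(cat0, quiet = TRUE)
  set.seed(31)
  diary <- tibble::tibble(
    participant_id = sample(sprintf("P%02d", 1:8), 300, replace = TRUE),
    day_index = sample(1:7, 300, replace = TRUE),
    item_id = sample(cat0$item_id, 300, replace = TRUE),
    grams = runif(300, 5, 400)
  )
  a <- build_exposure(diary, scored, cat0)
  b <- build_exposure(diary[sample(nrow(diary)), ], scored, cat0)
  expect_equal(a, b)
})

test_that("routed energies re-add to the total and proportions stay in [0,1]", {
  cat0 <- random_catalogue(60, seed = 6)
  scored <- score_catalogue(cat0, quiet = TRUE)
  set.seed(32)
  diary <- tibble::tibble(
    participant_id = sample(sprintf("P%02d", 1:20), 1500, replace = TRUE),
    day_index = sample(1:7, 1500, replace = TRUE),
    item_id = sample(cat0$item_id, 1500, replace = TRUE),
    grams = runif(1500, 5, 400)
  )
  ex <- build_exposure(diary, scored, cat0)
  expect_equal(
    ex$energy_lh_food + ex$energy_lh_bev + ex$energy_healthy + ex$energy_alcoholic,
    ex$energy_total,
    tolerance = 1e-9
  )
  expect_true(all(ex$prop_lh_energy >= 0 & ex$prop_lh_energy <= 1))
  expect_true(all(ex$prop_lh_weight >= 0 & ex$prop_lh_weight <= 1))
  # energy-weighted mean score lies within the consumed score range
  rng <- range(scored$score[scored$classification != "unscored"])
  expect_true(all(ex$mean_weighted_score >= rng[1] &
                    ex$mean_weighted_score <= rng[2]))
})

test_that("an all-healthy diary has zero less-healthy exposure", {
  cat0 <- worked_catalogue()
  scored <- score_catalogue(cat0, quiet = TRUE)
  diary <- tibble::tibble(participant_id = "P1", day_index = 1L,
                          item_id = "ok_food", grams = 250)
  expect_identical(build_exposure(diary, scored, cat0)$prop_lh_energy, 0)
})

test_that("the energy-weighted mean score averages scores by energy share", {
  cat0 <- make_items(
    list(item_id = "a", energy_kj = 1000),
    list(item_id = "b", energy_kj = 3000),
    list(item_id = "z", item_class = "alcoholic_beverage", energy_kj = 2000)
  )
  scored <- score_catalogue(cat0, quiet = TRUE)
  scored$score <- c(2L, 10L, 0L)

  single <- tibble::tibble(participant_id = "P1", day_index = 1L,
                           item_id = "b", grams = 40)
  expect_identical(
    mean_energy_weighted_score(single, scored, cat0)$mean_weighted_score, 10
  )
  both <- tibble::tibble(participant_id = "P1", day_index = 1L,
                         item_id = c("a", "b"), grams = 100)
  expect_identical(
    mean_energy_weighted_score(both, scored, cat0)$mean_weighted_score,
    (2 * 1000 + 10 * 3000) / 4000
  )
  # alcoholic beverages enter neither numerator nor denominator
  with_alc <- dplyr::bind_rows(
    both,
    tibble::tibble(participant_id = "P1", day_index = 1L, item_id = "z",
                   grams = 500)
  )
  expect_identical(
    mean_energy_weighted_score(with_alc, scored, cat0)$mean_weighted_score, 8
  )
})

test_that("diary validation rejects unknown items and bad records", {
  cat0 <- worked_catalogue()
  scored <- score_catalogue(cat0, quiet = TRUE)
  bad <- worked_diary()
  bad$item_id[1] <- "pizza"
  expect_error(build_exposure(bad, scored, cat0), "pizza")
  neg <- worked_diary()
  neg$grams[2] <- 0
  expect_error(build_exposure(neg, scored, cat0), "grams")
  day8 <- worked_diary()
  day8$day_index[1] <- 8L
  expect_error(build_exposure(day8, scored, cat0), "day_index")
})

test_that("quintile labels split fifths with deterministic remainders and ties", {
  expect_identical(assign_quintiles(1:10),
                   structure(rep(1:5, each = 2), boundaries = c(2L, 4L, 6L, 8L)),
                   ignore_attr = FALSE)
  q <- assign_quintiles(rnorm(1000))
  expect_identical(as.integer(table(q)), rep(200L, 5))
  # all-ties: stable input order, sizes still within one
  tied <- assign_quintiles(rep(1, 11), ids = 1:11)
  expect_identical(as.integer(tied), rep(1:5, times = c(3, 2, 2, 2, 2)))
  # labels monotone in the underlying value
  set.seed(8)
  x <- rnorm(501)
  lab <- assign_quintiles(x)
  expect_true(all(diff(lab[order(x)]) >= 0))
  expect_error(assign_quintiles(c(1, NA, 3)), "finite")
  expect_error(assign_quintiles(1:3), "at least 5")
})

test_that("add_quintiles attaches labels and boundary values", {
  set.seed(9)
  ex <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:50),
    prop_lh_energy = runif(50), prop_lh_weight = runif(50),
    mean_weighted_score = rnorm(50), fv_weight = runif(50, 0, 500)
  )
  out <- add_quintiles(ex)
  expect_true(all(c("quintile_energy", "quintile_weight", "quintile_score",
                    "quintile_fv") %in% names(out)))
  b <- attr(out, "quintile_boundaries")
  expect_length(b$quintile_energy, 4L)
  expect_true(all(diff(b$quintile_energy) > 0))
})
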