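# Independent brute-force scoring oracle: explicit loops over the cut-point
# tables, written separately from the package's findInterval-based path.

oracle_component <- function(value, thresholds) {
  pts <- 0L
  for (t in thresholds) {
    if (value > t) pts <- pts + 1L
  }
  pts
}

oracle_score_item <- function(item, tables = default_scoring_tables()) {
  a <- oracle_component(item$energy_kj, tables$energy_kj) +
    oracle_component(item$satfat_g, tables$satfat_g) +
    oracle_component(item$sugars_g, tables$sugars_g) +
    oracle_component(item$sodium_mg, tables$sodium_mg)
  fvn_n <- oracle_component(item$fvn_pct, tables$fvn_pct)
  fvn <- c(0L, 1L, 2L, 5L)[fvn_n + 1L]
  fibre <- oracle_component(item$fibre_g, tables$fibre_g)
  protein <- oracle_component(item$protein_g, tables$protein_g)
  protein_counted <- !(a >= 11L && fvn < 5L)
  score <- a - fvn - fibre - if (protein_counted) protein else 0L
  classification <- if (item$item_class == "alcoholic_beverage") {
    "unscored"
  } else if (item$item_class == "food" && score >= 4) {
    "less_healthy"
  } else if (item$item_class == "beverage" && score >= 1) {
    "less_healthy"
  } else {
    "healthy"
  }
  list(a_total = a, score = score, protein_counted = protein_counted,
       classification = classification)
}

# random compositions with deliberate mass exactly on the cut-points
random_catalogue <- function(n, seed = 1) {
  set.seed(seed)
  tables <- default_scoring_tables()
  draw <- function(n, max, thresholds) {
    v <- runif(n, 0, max)
    on_cut <- runif(n) < 0.15
    v[on_cut] <- sample(thresholds, sum(on_cut), replace = TRUE)
    v
  }
  tibble::tibble(
    item_id = sprintf("item_%05d", seq_len(n)),
    name = item_id,
    item_class = sample(c("food", "beverage", "alcoholic_beverage"), n,
                        replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    energy_kj = draw(n, 4000, tables$energy_kj),
    satfat_g = draw(n, 12, tables$satfat_g),
    sugars_g = draw(n, 50, tables$sugars_g),
    sodium_mg = draw(n, 1100, tables$sodium_mg),
    fibre_g = draw(n, 4.5, tables$fibre_g),
    protein_g = draw(n, 10, tables$protein_g),
    fvn_pct = pmin(draw(n, 100, tables$fvn_pct), 100)
  )
}

# minimal scored-catalogue + diary builders for exposure tests
make_items <- function(...) {
  rows <- list(...)
  defaults <- list(name = "x", item_class = "food", energy_kj = 0, satfat_g = 0,
                   sugars_g = 0, sodium_mg = 0, fibre_g = 0, protein_g = 0,
                   fvn_pct = 0)
  purrr::map_dfr(rows, function(r) {
    out <- utils::modifyList(defaults, r)
    tibble::as_tibble(out)
  })
}
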