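test_that("curated census reproduces the printed per-age and shape counts", {
  counts <- vapply(c(newborn = "newborn", `1y` = "1y", `5y` = "5y",
                     `10y` = "10y", `15y` = "15y", adult = "adult"),
                   function(a) segment_count(DB, a), 1L)
  expect_equal(unname(counts), c(34L, 39L, 43L, 38L, 64L, 71L))
  expect_identical(segment_count(DB), 289L)
  expect_equal(shape_census(DB),
               c(b = 142L, c = 83L, dc = 56L, p = 5L, e = 1L, t = 2L))
  expect_identical(segment_shared_count(DB, "15y"), 28L)
  expect_identical(segment_shared_count(DB, "adult"), 23L)
  expect_equal(sum(shape_census(DB)), segment_count(DB))
})

test_that("raw and curated modes differ exactly on the curated rows", {
  raw <- spsd_db("raw")
  cur_keys <- unique(paste(DB$curation$age, DB$curation$site,
                           DB$curation$segment))
  row_key <- paste(raw$segments$age, raw$segments$site, raw$segments$segment)
  differs <- vapply(seq_len(nrow(raw$segments)), function(i) {
    a <- raw$segments[i, setdiff(names(raw$segments), c("cortical", "key"))]
    b <- DB$segments[i, setdiff(names(DB$segments), c("cortical", "key"))]
    !isTRUE(all.equal(a, b, check.attributes = FALSE)) ||
      !identical(raw$segments$cortical[[i]], DB$segments$cortical[[i]])
  }, TRUE)
  # every differing row is named by a curation entry, and vice versa every
  # curation target matches at least one (possibly unchanged-value) row
  expect_true(all(row_key[differs] %in%
                    c(cur_keys, sub("Humery", "Humerus", cur_keys))))
  expect_lt(segment_count(raw), segment_count(DB))
})

test_that("active-marrow lookups return site values, groups, and no-AM signals", {
  x <- am_fraction(DB, "newborn", site = "Skull")
  expect_equal(as.numeric(x), 28.2)
  expect_false(attr(x, "grouped"))

  g <- am_fraction(DB, "adult", "male", "Clavicle")
  expect_equal(as.numeric(g), 15.3)
  expect_true(attr(g, "grouped"))
  expect_setequal(attr(g, "group"), c("Clavicle", "Scapula", "Ribs"))

  expect_error(am_fraction(DB, "adult", "male", "Tibia and fibula"),
               class = "spsd_no_am")
  expect_error(am_fraction(DB, "1y", "male", "Hand and foot"),
               class = "spsd_no_am")
  expect_error(am_fraction(DB, "adult", "male", "Coccyx"),
               class = "spsd_no_am")
})

test_that("AM fractions sum to 100 +/- 0.1 for every phantom", {
  for (a in c("newborn", "1y", "5y", "10y", "15y", "adult")) {
    expect_lt(abs(sum(DB$am$am_fraction[DB$am$age == a]) - 100), 0.1 + 1e-9)
  }
})

test_that("validate_db passes every check in curated mode and flags raw mode", {
  rep <- validate_db(DB)
  expect_true(all(rep$pass), info = paste(rep$check[!rep$pass], collapse = ", "))
  raw_rep <- validate_db(spsd_db("raw"))
  expect_false(all(raw_rep$pass))
  expect_false(raw_rep$pass[raw_rep$check == "max_linear_dim_88"])
})

test_that("segment keys resolve uniquely and ambiguity is reported", {
  i <- spsd:::.resolve_key(DB, "adult/male/Femur/Neck")
  expect_identical(DB$segments$key[i], "adult/male/Femur/Neck")
  expect_error(spsd:::.resolve_key(DB, "Femur"), "ambiguous")
  expect_error(spsd:::.resolve_key(DB, "no/such/segment"), "no segment")
})

test_that("media densities are age-monotone and composition sums close", {
  d <- vapply(c("newborn", "1y", "5y", "10y", "15y", "adult"),
              function(a) media_density(DB, a)[["bone"]], 1.0)
  expect_equal(unname(d), c(1.65, 1.70, 1.80, 1.83, 1.85, 1.90))
  expect_false(is.unsorted(d))
  cs <- tapply(DB$composition$mass_fraction, DB$composition$medium, sum)
  expect_true(all(abs(cs - 100) <= 0.5))
})
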