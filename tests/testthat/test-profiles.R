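test_that("fractional contributions are proportional shares of the layer total", {
  p <- six_layer_profile(c(50, 20, 10, 10, 5, 5))
  fv <- fractional_contributions(p)
  expect_equal(unname(fv$r), c(0.50, 0.20, 0.10, 0.10, 0.05, 0.05))

  uniform <- fractional_contributions(six_layer_profile(rep(10, 6)))
  expect_equal(unname(uniform$r), rep(1 / 6, 6))
})

test_that("fractional contributions sum to 1 for any positive profile", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_activity()
    fv <- fractional_contributions(six_layer_profile(a))
    expect_equal(sum(fv$r), 1, tolerance = 1e-12)
    # direct summation oracle over the six layers
    expect_equal(unname(fv$r), a / (a[1] + a[2] + a[3] + a[4] + a[5] + a[6]))
  }
})

test_that("degenerate profiles are rejected with informative errors", {
  expect_error(fractional_contributions(six_layer_profile(rep(0, 6))), "empty profile")
  expect_error(six_layer_profile(c(-1, 2, 3, 4, 5, 6)), "non-negative")
  expect_error(soil_profile("2023-04-15", c(1, 2), top_cm = c(0, 10), bottom_cm = c(5, 15)),
               "contiguous")
  expect_error(soil_profile("not-a-date", 1:6), "unparsable")
  expect_error(soil_profile("2023-04-15", 1:6, density = -1), "density")
})

test_that("backdating multiplies by 2^(elapsed/half-life)", {
  expect_identical(backdate_activity(100, 0, 30.08), 100)
  expect_equal(backdate_activity(100, 30.08, 30.08), 200)
  expect_equal(backdate_activity(100, 36.95, 30.08), 234.3055, tolerance = 1e-6)
  expect_error(backdate_activity(100, -1, 30.08), "precedes")
})

test_that("forward decay then backdating is the identity", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 1, 500)
    dt <- runif(1, 0, 60)
    decayed <- a * 2^(-dt / 30.08)
    expect_equal(backdate_activity(decayed, dt, 30.08), a, tolerance = 1e-12)
  }
})

test_that("total deposition converts mass activity via density and thickness", {
  expect_equal(total_deposition(six_layer_profile(rep(0, 6))), 0)
  one <- soil_profile("2023-04-15", 100, top_cm = 0, bottom_cm = 5, density = 1.3)
  expect_equal(total_deposition(one), 6.5)   # 100 Bq/kg x 1300 kg/m3 x 0.05 m

  # a backdated layer total of 286.2 Bq/kg corresponds to ~18.6 kBq/m2
  w <- c(0.71, 0.11, 0.06, 0.05, 0.04, 0.02)
  a <- 286.2 * w / sum(w)
  expect_equal(total_deposition(six_layer_profile(a)), 18.603, tolerance = 1e-3)
})

test_that("total deposition is linear in activity and density", {
  set.seed(31)
  a <- random_activity()
  p1 <- six_layer_profile(a)
  p2 <- six_layer_profile(2 * a)
  expect_equal(total_deposition(p2), 2 * total_deposition(p1), tolerance = 1e-12)
  p3 <- six_layer_profile(a, density = 2.6)
  expect_equal(total_deposition(p3), 2 * total_deposition(p1), tolerance = 1e-12)
})

test_that("profile files round-trip and parse errors cite line numbers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(41)
  profs <- list(six_layer_profile(random_activity(), date = "1987-07-01"),
                six_layer_profile(random_activity(), date = "2023-04-15"))
  write_profiles(profs, tmp, comment = "round-trip fixture")
  back <- read_profiles(tmp)
  expect_length(back, 2)
  expect_equal(back[[1]]$layers$activity, profs[[1]]$layers$activity, tolerance = 1e-9)
  expect_equal(back[[2]]$sample_date, as.Date("2023-04-15"))
  expect_equal(back[[1]]$layers$rel_sigma, profs[[1]]$layers$rel_sigma)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("# only comments here", empty)
  expect_length(read_profiles(empty), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,top_cm,bottom_cm,activity_Bq_per_kg,rel_sigma",
               "2023-04-15,0,5,12.5,0.1",
               "2023-04-15,5,10,oops,0.1"), bad)
  expect_error(read_profiles(bad), "line 3.*non-numeric")

  baddate <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,top_cm,bottom_cm,activity_Bq_per_kg,rel_sigma",
               "15/04/2023,0,5,12.5,0.1"), baddate)
  expect_error(read_profiles(baddate), "line 2.*date")
})

test_that("deposition report carries measured and backdated inventories", {
  p <- six_layer_profile(rep(10, 6), date = "2016-04-25")  # ~30 y after reference
  rep_ <- deposition_report(list(p))
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$t_years, 30, tolerance = 0.01)
  expect_gt(rep_$deposition_backdated_kBq_m2, rep_$deposition_kBq_m2)
  ratio <- rep_$deposition_backdated_kBq_m2 / rep_$deposition_kBq_m2
  expect_equal(ratio, 2^(rep_$t_years / cs137_half_life()), tolerance = 1e-9)
})
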