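fx <- study_fixture()
uc <- fx$unit_costs
uc_unenh <- list(cxr = uc$cxr, dts = uc$dts, ct = uc$ct_unenhanced)
uc_ce <- list(cxr = uc$cxr, dts = uc$dts, ct = uc$ct_contrast)

test_that("straight-line depreciation divides price by useful life", {
  expect_equal(annual_depreciation(30000, 10), 3000)
  expect_equal(annual_depreciation(1242000, 8), 155250)
  expect_equal(annual_depreciation(0, 10), 0)
  expect_error(annual_depreciation(1000, 0), "positive")
  expect_error(annual_depreciation(1000, -3), "positive")
})

test_that("capacity-cost allocation follows occupation time", {
  expect_equal(allocate_capacity_cost(13000, 2600, 60), 5)
  expect_equal(allocate_capacity_cost(13000, 2600, 0), 0)
  expect_error(allocate_capacity_cost(13000, 0, 10), "positive")
  set.seed(8)
  for (i in 1:25) {
    annual <- runif(1, 0, 2e5)
    cap <- runif(1, 100, 4000)
    occ <- runif(1, 0, 40)
    expect_equal(allocate_capacity_cost(annual, cap, occ),
                 (annual * occ) / (cap * 60), tolerance = 1e-9)
  }
})

test_that("unit full costs sum components exactly in cents", {
  expect_equal(uc$cxr$total, 15.15)
  expect_equal(uc$dts$total, 41.55)
  expect_equal(uc$ct_unenhanced$total, 65.35)
  expect_equal(uc$ct_contrast$total, 113.66)
  expect_error(unit_cost(medical = -1), "nonnegative")
})

test_that("scenario costs are exact cent-level sums over utilisation", {
  before <- scenario("before", fx$utilisation_before, uc_unenh, "unenhanced")
  expect_equal(scenario_cost(before), 17709.85)
  after <- scenario("after", fx$utilisation_after, uc_unenh, "unenhanced")
  expect_equal(scenario_cost(after), 9619.65)
  empty <- scenario("none", utilisation(), uc_unenh, "unenhanced")
  expect_equal(scenario_cost(empty), 0)
  expect_error(scenario("x", utilisation(ct = 5), list(cxr = uc$cxr),
                        "unenhanced"),
               "no unit cost")
})

test_that("scenario cost is linear in counts and unit costs", {
  u1 <- utilisation(cxr = 3, dts = 5, dts_subdiagnostic = 1, ct = 2)
  u2 <- utilisation(cxr = 6, dts = 10, dts_subdiagnostic = 2, ct = 4)
  c1 <- scenario_cost(scenario("a", u1, uc_unenh, "unenhanced"))
  c2 <- scenario_cost(scenario("b", u2, uc_unenh, "unenhanced"))
  expect_equal(c2, 2 * c1)
  doubled <- lapply(uc_unenh, function(x) {
    unit_cost(2 * x$contrast, 2 * x$medical, 2 * x$radiographer,
              2 * x$nursing, 2 * x$depreciation)
  })
  expect_equal(scenario_cost(scenario("c", u1, doubled, "unenhanced")), 2 * c1)
})

test_that("differential savings reproduce both CT variants and are antisymmetric", {
  before <- scenario("before", fx$utilisation_before, uc_unenh, "unenhanced")
  after <- scenario("after", fx$utilisation_after, uc_unenh, "unenhanced")
  expect_equal(differential_saving(before, after), 8090.20)
  expect_equal(differential_saving(after, before), -8090.20)
  expect_equal(differential_saving(before, before), 0)

  before_ce <- scenario("before", fx$utilisation_before, uc_ce,
                        "contrast_enhanced")
  after_ce <- scenario("after", fx$utilisation_after, uc_ce,
                       "contrast_enhanced")
  expect_equal(scenario_cost(before_ce), 30801.86)
  expect_equal(scenario_cost(after_ce), 11503.74)
  expect_equal(differential_saving(before_ce, after_ce), 19298.12)

  expect_error(differential_saving(before, after_ce), "CT variants")
})

test_that("break-even is the ceiling of fixed cost over contribution margin", {
  expect_equal(break_even(30000, 62.7, 0), 479L)
  expect_equal(break_even(0, 62.7), 0L)
  expect_equal(break_even(10000, 50, 0), 200L)
  expect_error(break_even(1000, 10, 10), "margin")
  expect_error(break_even(1000, 10, 15), "margin")
})

test_that("break-even satisfies the smallest-covering-count property on random inputs", {
  set.seed(19)
  for (i in 1:100) {
    fixed <- round(runif(1, 0.01, 1e5), 2)
    variable <- round(runif(1, 0, 50), 2)
    reimb <- variable + round(runif(1, 0.01, 200), 2)
    margin <- round(reimb - variable, 2)
    if (margin <= 0) next
    n <- break_even(fixed, reimb, variable)
    expect_gte(round(n * margin, 2), fixed)
    expect_lt(round((n - 1) * margin, 2), fixed)
  }
})
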