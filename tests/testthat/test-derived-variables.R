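test_that("wealth index matches a direct eigen-decomposition oracle", {
  set.seed(11)
  a <- data.frame(radio = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1),
                  tv    = c(1, 0, 0, 1, 0, 0, 1, 0, 0, 1),
                  bike  = c(0, 0, 1, 1, 0, 1, 1, 0, 0, 1))
  w <- wealth_index(a)
  # oracle: standardise, eigen-decompose the correlation matrix, project
  xs <- scale(as.matrix(a))
  e <- eigen(cor(as.matrix(a)))
  v1 <- e$vectors[, 1]
  score <- drop(xs %*% v1)
  if (cor(score, rowSums(xs)) < 0) score <- -score
  expect_lt(max(abs(w$pc1_score - score)), 1e-8)
})

test_that("wealth index orientation, quintiles and tertile collapse", {
  set.seed(12)
  n <- 100
  a <- data.frame(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.4),
                  x3 = rbinom(n, 1, 0.6), x4 = rbinom(n, 1, 0.3))
  w <- wealth_index(a)
  # owning more assets raises the score
  expect_gt(cor(w$pc1_score, rowSums(a)), 0)
  # quintiles partition into five near-equal groups when scores are untied
  ac <- data.frame(v1 = runif(n), v2 = runif(n), v3 = runif(n))
  wc <- wealth_index(ac)
  expect_true(all(abs(table(wc$quintile) - n / 5) <= 1))
  # tertile is a deterministic collapse of quintile: {1,2}->poor, 3->middle, {4,5}->rich
  expect_true(all(w$tertile[w$quintile <= 2] == "poor"))
  expect_true(all(w$tertile[w$quintile == 3] == "middle"))
  expect_true(all(w$tertile[w$quintile >= 4] == "rich"))
  # single informative asset: owners strictly higher
  b <- data.frame(asset = c(1, 0, 1, 0, 1))
  w1 <- wealth_index(b)
  expect_true(min(w1$pc1_score[b$asset == 1]) > max(w1$pc1_score[b$asset == 0]))
})

test_that("wealth index is invariant to affine rescaling of an indicator", {
  set.seed(13)
  a <- data.frame(x1 = rbinom(60, 1, 0.5), x2 = rbinom(60, 1, 0.4),
                  x3 = rbinom(60, 1, 0.6))
  w0 <- wealth_index(a)
  a2 <- a
  a2$x2 <- 10 * a2$x2 + 3
  w2 <- wealth_index(a2)
  expect_identical(w0$quintile, w2$quintile)
})

test_that("wealth index degenerate inputs error or warn as documented", {
  same <- data.frame(x1 = rep(1, 5), x2 = rep(0, 5))
  expect_error(wealth_index(same), "constant")
  expect_error(wealth_index(data.frame(x1 = c(1, 0), x2 = c(0, 1))),
               "at least 3 households")
  wide <- data.frame(matrix(rbinom(12, 1, 0.5), nrow = 3))
  expect_error(wealth_index(wide), "fewer households")
  set.seed(14)
  a <- data.frame(x1 = rbinom(30, 1, 0.5), x2 = rbinom(30, 1, 0.5),
                  konst = rep(1, 30))
  expect_warning(w <- wealth_index(a), "constant asset column")
  expect_equal(ncol(w), 3)
})

test_that("CHE flags match a hand-executed capacity-to-pay computation", {
  # Six households, worked by hand through the Xu procedure:
  #   food shares: .5 .4 .4 .3 .5833 .4 -> 45th & 55th pctile (type 7) both .4
  #   -> band = households 2, 3, 6
  #   equivalent sizes: 1, 4^.56, 1, 4^.56, 2^.56, 3^.56
  #   line = mean(80/4^.56, 60/1, 100/3^.56)
  tab <- data.frame(
    total_expenditure = c(100, 200, 150, 300, 120, 250),
    food_expenditure  = c(50, 80, 60, 90, 70, 100),
    oop_health        = c(0, 30, 20, 100, 20, 60),
    household_size    = c(1, 4, 1, 4, 2, 3))
  eq <- c(1, 4^0.56, 1, 4^0.56, 2^0.56, 3^0.56)
  line <- mean(c(80 / 4^0.56, 60 / 1, 100 / 3^0.56))    # 50.2614...
  sub <- line * eq
  # capacity to pay: total - subsistence where food >= subsistence, else total - food
  #   h1: food 50 <  50.26 -> 100 - 50  = 50      ratio 0      -> no
  #   h2: food 80 < 109.46 -> 200 - 80  = 120     ratio 0.25   -> no
  #   h3: food 60 >= 50.26 -> 150 - sub = 99.74   ratio 0.2005 -> no
  #   h4: food 90 < 109.46 -> 300 - 90  = 210     ratio 0.476  -> yes
  #   h5: food 70 <  74.10 -> 120 - 70  = 50      ratio 0.40   -> yes (inclusive)
  #   h6: food 100 >= 92.99 -> 250 - sub = 157.0  ratio 0.382  -> no
  ctp_hand <- c(50, 120, 150 - sub[3], 210, 50, 250 - sub[6])

  che <- compute_che(tab)
  expect_equal(attr(che, "subsistence_line"), line, tolerance = 1e-12)
  expect_equal(che$capacity_to_pay, ctp_hand, tolerance = 1e-12)
  expect_identical(as.character(che$che_flag),
                   c("no", "no", "no", "yes", "yes", "no"))
  # h5 sits exactly at oop / ctp = 20 / 50 = 0.40: the boundary is inclusive
  expect_identical(tab$oop_health[5] / che$capacity_to_pay[5], 0.4)
})

test_that("CHE is monotone in OOP spending and flags unusable records", {
  set.seed(15)
  base <- simulate_expenditure(200, expenditure_params(), seed = 15)
  f1 <- compute_che(base)
  base2 <- base
  base2$oop_health <- base2$oop_health * 2
  f2 <- compute_che(base2)
  # capacity to pay does not depend on OOP, so doubling OOP never flips yes -> no
  was_yes <- which(f1$che_flag == "yes")
  expect_true(all(f2$che_flag[was_yes] == "yes"))

  # all-zero OOP -> all flags no
  base3 <- base
  base3$oop_health <- 0
  expect_true(all(compute_che(base3)$che_flag == "no", na.rm = TRUE))

  # a household below subsistence gets excluded, not flagged
  tiny <- data.frame(total_expenditure = c(10, 500, 600, 550, 480),
                     food_expenditure = c(10, 250, 300, 270, 240),
                     oop_health = c(5, 10, 10, 10, 10),
                     household_size = c(6, 2, 2, 2, 2))
  expect_message(out <- compute_che(tiny), "non-positive capacity to pay")
  expect_true(is.na(out$che_flag[1]))
  expect_identical(attr(out, "n_unusable"), 1L)
})

test_that("raw fields recode to the documented analysis categories", {
  raw <- data.frame(
    child_age_months = c(5, 23, 24, 48, 60, 80),
    mother_age_years = c(17, 18, 19, 35, 49, 23),
    head_age_years   = c(17, 24, 25, 34, 35, 60),
    stay_years       = c(0.5, 2, 2.01, 10, NA, 3),
    head_ethnicity   = c("Kamba", "Luo", "Luhya", "Kikuyu", "other", "Wrong")
  )
  expect_warning(rec <- recode_variables(raw), "invalid")
  expect_identical(as.character(rec$child_age),
                   c(rep("1 year and less", 2), rep("2-5 years", 3), NA))
  expect_identical(as.character(rec$mother_age)[1:3],
                   c("18 years and less", "18 years and less", "19-49 years"))
  expect_identical(as.character(rec$head_age),
                   c("17-24", "17-24", "25-34", "25-34", "35 and over",
                     "35 and over"))
  # stay of exactly 2 years is still a new migrant; NA maps to its own level
  expect_identical(as.character(rec$length_of_stay),
                   c("new migrants", "new migrants", "old migrants",
                     "old migrants", "missing/not applicable", "old migrants"))
  expect_true(is.na(rec$head_ethnicity[6]))
  expect_identical(attr(rec, "invalid_rows"), 6L)
})

test_that("recode of a mixed toy reproduces hand-tabulated counts", {
  raw <- data.frame(
    child_age_months = c(3, 10, 18, 23, 24, 30, 36, 42, 50, 55, 60, 70),
    stay_years = c(1, 1, 2, 2, 2, 3, 3, 4, NA, NA, 0.5, 8))
  rec <- recode_variables(raw)
  expect_identical(as.integer(table(rec$child_age)), c(4L, 8L))
  expect_identical(as.integer(table(rec$length_of_stay)), c(6L, 4L, 2L))
})

test_that("complete-case filter accounts for every dropped row", {
  d <- data.frame(y = c(NA, NA, 1, 0, 1, 0, 1, 0, 1, 1),
                  a = c("p", "q", NA, "p", "q", NA, NA, "p", "q", "p"),
                  b = c("u", "v", "u", "v", "u", "v", "u", "v", "u", "v"),
                  stringsAsFactors = FALSE)
  rep10 <- complete_case_filter(d, "y", c("a", "b"))
  expect_identical(rep10$n_dropped_outcome, 2L)
  expect_identical(rep10$n_dropped_covariate, 3L)
  expect_identical(rep10$n_kept, 5L)
  # conservation: input = kept + dropped-outcome + dropped-covariate
  expect_identical(rep10$n_input,
                   rep10$n_kept + rep10$n_dropped_outcome + rep10$n_dropped_covariate)

  # identity on complete data
  clean <- d[!is.na(d$y) & !is.na(d$a), ]
  rep0 <- complete_case_filter(clean, "y", c("a", "b"))
  expect_identical(rep0$data, clean)
  expect_identical(rep0$n_dropped_outcome + rep0$n_dropped_covariate, 0L)

  # all outcomes missing
  allna <- d
  allna$y <- NA
  expect_error(complete_case_filter(allna, "y", c("a", "b")),
               "empty analysis set")

  # report prints in the survey accounting style
  expect_output(print(rep10), "2 \\(20\\.0%\\)")
})
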