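toy_patients <- data.frame(
  patient_id = c("P1", "P2"), sex = c("F", "M"),
  age_at_diagnosis = c(60, 70), inclusion_age = c(61, 71),
  form = c("spinal", "bulbar"), follow_up_days = c(100, 300),
  n_events = c(4L, 10L), social_status = c("married", "single"),
  lifestyle = c("family", "alone"), stringsAsFactors = FALSE)

test_that("population description matches hand-computed values on a toy table", {
  d <- describe_population(toy_patients)
  tot <- d$numeric[d$numeric$field == "age_at_diagnosis" & d$numeric$group == "total", ]
  expect_equal(tot$mean, 65)
  expect_equal(tot$sd, sd(c(60, 70)))
  expect_equal(c(tot$min, tot$max), c(60, 70))
  women <- d$numeric[d$numeric$field == "age_at_diagnosis" & d$numeric$group == "F", ]
  expect_equal(women$mean, 60)
  expect_equal(women$sd, 0)          # single observation: SD reported as 0
  cats <- d$categorical[d$categorical$field == "social_status" &
                        d$categorical$group == "total", ]
  expect_equal(sort(cats$pct), c(50, 50))
})

test_that("categorical percentages sum to 100 within rounding", {
  set.seed(61)
  pts <- draw_patients(200L, sim_config(seed = 61))
  d <- describe_population(pts)
  for (f in unique(d$categorical$field)) for (g in c("F", "M", "total")) {
    p <- d$categorical$pct[d$categorical$field == f & d$categorical$group == g]
    expect_equal(sum(p), 100, tolerance = 1e-9)
  }
})

test_that("presence table agrees with a direct recount", {
  set.seed(62)
  m <- matrix(rpois(300, 0.7), nrow = 100,
              dimnames = list(sprintf("P%03d", 1:100), c("A", "B", "C")))
  tab <- presence_table(m)
  expect_equal(tab$present_n, unname(colSums(m >= 1)))
  expect_equal(tab$present_pct, unname(100 * colMeans(m >= 1)))
  expect_equal(tab$mean, unname(colMeans(m)))
  expect_equal(tab$present_n + tab$absent_n, rep(100L, 3))
})

test_that("Benjamini-Hochberg and LogWorth behave as the closed forms dictate", {
  expect_equal(logworth(0.001), 3)
  # BH step-up on an evenly spaced p-vector collapses to the largest
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(63)
  p <- sort(runif(20))
  adj <- p.adjust(p, method = "BH")
  expect_true(all(diff(adj) >= -1e-12))       # monotone in rank order
  expect_true(all(adj >= p) && all(adj <= 1)) # adjusted >= raw, bounded
  expect_true(all(diff(logworth(sort(adj))) <= 1e-12))  # decreasing in p
})

test_that("the association scan recovers a planted effect and orders by LogWorth", {
  set.seed(64)
  n <- 400
  pts <- data.frame(patient_id = sprintf("P%03d", 1:n),
                    motor = rpois(n, 4), age = rnorm(n, 65, 10),
                    noise = rnorm(n), stringsAsFactors = FALSE)
  y <- rpois(n, exp(0.3 + 0.25 * pts$motor))
  m <- matrix(as.integer(y), ncol = 1, dimnames = list(pts$patient_id, "out"))
  sc <- association_scan(m, pts, outcomes = "out",
                         predictors = c("motor", "age", "noise"))
  expect_s3_class(sc, "scan_result")
  res <- sc$out
  expect_equal(res$predictor[1], "motor")
  expect_true(all(diff(res$logworth) <= 1e-12))
  expect_equal(res$logworth, -log10(res$p_fdr))
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  # single-predictor variant also flags the planted effect first
  sc1 <- association_scan(m, pts, "out", c("motor", "age", "noise"), joint = FALSE)
  expect_equal(sc1$out$predictor[1], "motor")
})

test_that("constant outcomes are flagged without p-values", {
  pts <- data.frame(patient_id = c("P1", "P2", "P3", "P4"), x = 1:4,
                    stringsAsFactors = FALSE)
  m <- matrix(2L, nrow = 4, ncol = 1, dimnames = list(pts$patient_id, "flat"))
  sc <- association_scan(m, pts, "flat", "x")
  expect_true(isTRUE(attr(sc$flat, "constant")))
  expect_true(all(is.na(sc$flat$p)))
})

test_that("group contrasts agree with a direct t-test", {
  set.seed(65)
  pts <- toy_patients[rep(1:2, each = 20), ]
  pts$patient_id <- sprintf("P%02d", 1:40)
  y <- c(rnorm(20, 5), rnorm(20, 3))
  m <- matrix(y, ncol = 1, dimnames = list(pts$patient_id, "out"))
  gc <- group_contrast(m, pts, "out", "social_status",
                       levels = c("married", "single"))
  expect_equal(unname(gc$means["married"]), mean(y[1:20]))
  expect_equal(gc$difference, mean(y[1:20]) - mean(y[21:40]))
  tt <- t.test(y[1:20], y[21:40])
  expect_equal(gc$p, tt$p.value)
  expect_equal(gc$t, unname(tt$statistic))
})

test_that("correlation matches known cases and sampling error bounds", {
  x <- 1:50
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  set.seed(66)
  n <- 1e4
  z <- rnorm(n); x <- z + rnorm(n); y <- z + rnorm(n)   # rho = 0.5
  r <- correlate(x, y)$r
  expect_lt(abs(r - 0.5), 0.03)
})
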