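test_that("phase classification uses the threshold bands", {
  expect_true(all(classify_phase(uniform_field(1, N = 8))$labels == "solid"))
  expect_true(all(classify_phase(uniform_field(0.5, N = 8))$labels ==
                    "intermediate"))
  v <- matrix(0.5, 9, 9)
  v[1:3, ] <- 0.05
  v[7:9, ] <- 0.95
  m <- classify_phase(order_parameter_field(v))
  expect_true(all(m$labels[1:3, ] == "void"))
  expect_true(all(m$labels[4:6, ] == "intermediate"))
  expect_true(all(m$labels[7:9, ] == "solid"))
  # boundary values belong to the extreme classes (phi <= / >= theta)
  b <- classify_phase(uniform_field(0.1, N = 8))
  expect_true(all(b$labels == "void"))
  expect_error(classify_phase(uniform_field(0.5, N = 8), c(0.9, 0.1)),
               "void < solid")
})

test_that("label counts always partition the grid", {
  for (sd in 1:5) {
    f <- noisy_uniform_field(noise_spec(amplitude_fraction = 2,
                                        base_value = 0.5, seed = sd),
                             N = 10)
    m <- classify_phase(f)
    counts <- table(factor(m$labels,
                           levels = c("void", "intermediate", "solid")))
    expect_identical(sum(counts), 100L)
  }
})

test_that("void area fraction is the void cell count over N^2", {
  expect_identical(void_area_fraction(classify_phase(uniform_field(1, N = 8))),
                   0)
  expect_identical(
    void_area_fraction(classify_phase(uniform_field(0.01, N = 8))), 1)
  v <- matrix(1, 8, 8)
  v[1:4, 1:4] <- 0.0  # one quarter void
  expect_identical(
    void_area_fraction(classify_phase(order_parameter_field(v))), 0.25)
})

test_that("widening the void band never shrinks the void fraction", {
  f <- noisy_uniform_field(noise_spec(amplitude_fraction = 3, seed = 2),
                           N = 16)
  fracs <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.4), function(th) {
    void_area_fraction(classify_phase(f, c(th, 0.9)))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("void component counting matches the construction cases", {
  v <- matrix(1, 12, 12)
  m0 <- classify_phase(order_parameter_field(v))
  expect_identical(connected_void_components(m0), 0L)
  # two disjoint 3x3 void blocks
  v[2:4, 2:4] <- 0
  v[8:10, 8:10] <- 0
  m <- classify_phase(order_parameter_field(v))
  expect_identical(connected_void_components(m, min_cells = 4), 2L)
  expect_identical(connected_void_components(m, min_cells = 10), 0L)
  # diagonal contact does not merge (4-connectivity)
  w <- matrix(1, 12, 12)
  w[2:4, 2:4] <- 0
  w[5:7, 5:7] <- 0
  mw <- classify_phase(order_parameter_field(w))
  expect_identical(connected_void_components(mw, min_cells = 4), 2L)
})

test_that("component counts agree with a brute-force flood fill", {
  for (sd in 1:20) {
    set.seed(sd)
    v <- matrix(ifelse(runif(64) < 0.5, 0.0, 1.0), 8, 8)
    m <- classify_phase(order_parameter_field(v))
    for (mc in c(1, 4)) {
      expect_identical(connected_void_components(m, min_cells = mc),
                       flood_fill_count(v <= 0.1, min_cells = mc))
    }
  }
})

make_series <- function(frames, times = seq(0.2, by = 0.2,
                                            length.out = length(frames))) {
  fields <- c(list(uniform_field(0.5, N = 12, t = 0)),
              lapply(seq_along(frames), function(i) {
                order_parameter_field(frames[[i]], t = times[i])
              }))
  structure(list(times = c(0, times), fields = fields,
                 params = model_parameters(),
                 config = numerics_config(N = 12), seed = NA_integer_,
                 steps = 0),
            class = "cpc_snapshots")
}

test_that("void timeline reduces snapshots to onset/vanish/verdict", {
  solid <- matrix(1, 12, 12)
  voided <- matrix(1, 12, 12)
  voided[3:6, 3:6] <- 0
  # no void ever: indeterminate
  r0 <- void_timeline(make_series(rep(list(solid), 5)))
  expect_identical(r0$verdict, "indeterminate")
  expect_true(is.na(r0$onset_time) && is.na(r0$vanish_time))
  # void at 0.4/0.6/0.8 only: onset 0.4, vanish 1.0, non-fragmentation
  r1 <- void_timeline(make_series(list(solid, voided, voided, voided,
                                       solid)))
  expect_identical(r1$onset_time, 0.4)
  expect_identical(r1$vanish_time, 1.0)
  expect_identical(r1$verdict, "non-fragmentation")
  # void persisting to the end: fragmentation, no vanish time
  r2 <- void_timeline(make_series(list(solid, voided, voided, voided,
                                       voided)))
  expect_identical(r2$onset_time, 0.4)
  expect_true(is.na(r2$vanish_time))
  expect_identical(r2$verdict, "fragmentation")
  # exactly one verdict per run
  for (r in list(r0, r1, r2)) {
    expect_identical(
      sum(r$verdict == c("fragmentation", "non-fragmentation",
                         "indeterminate")), 1L)
  }
})

test_that("speckle below min_cells does not count as a void", {
  speck <- matrix(1, 12, 12)
  speck[5, 5] <- 0
  speck[9, 2] <- 0
  r <- void_timeline(make_series(rep(list(speck), 5)))
  expect_identical(r$verdict, "indeterminate")
  expect_gt(r$per_snapshot$void_area_fraction[1], 0)
})

test_that("setting time is the first measurement at exactly 0 mm", {
  s <- penetration_series(c(0, 10, 20, 30), c(15, 8, 2, 0))
  expect_identical(estimate_setting_time(s), 30)
  s2 <- penetration_series(c(5, 10), c(0, 0))
  expect_identical(estimate_setting_time(s2), 5)
  s3 <- penetration_series(c(0, 10, 20), c(15, 8, 1))
  expect_warning(T3 <- estimate_setting_time(s3), "did not set")
  expect_true(is.na(T3))
  expect_error(penetration_series(c(0, 10), c(5, -1)), "nonnegative")
  expect_error(penetration_series(c(10, 0), c(5, 1)), "increasing")
})

test_that("penetration tables round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tdepth", "0\t15", "10\t8", "20\t0", "30\t0"), path)
  s <- read_penetration_series(path)
  expect_identical(estimate_setting_time(s), 20)
})

test_that("a measured setting time wires into the diffusion schedule", {
  s <- penetration_series(c(0, 10, 20, 30), c(15, 8, 2, 0))
  Tset <- estimate_setting_time(s)
  p <- build_setting_schedule(Tset, D0 = 0.01)
  expect_identical(diffusion_coefficient(Tset - 1e-9, p), 0.01)
  expect_identical(diffusion_coefficient(Tset, p), 0)
  # reference schedule
  q <- build_setting_schedule(0.8, 0.01)
  expect_identical(q$T, 0.8)
  expect_identical(q$D0, 0.01)
  expect_error(build_setting_schedule(0, 0.01), "positive")
})
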