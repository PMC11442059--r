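test_that("wide and long CSV dialects round-trip", {
  wl <- rnl_grid()
  a <- 0.1 + 0.3 * exp(-(wl - 500)^2 / 5000)
  b <- 0.05 + 0.002 * (wl - 300) / 4
  wide <- tempfile(fileext = ".csv")
  write.csv(data.frame(wl = wl, frogA = a, frogB = b), wide, row.names = FALSE)
  set <- read_spectra(wide, "wide")
  expect_length(set, 2)
  expect_equal(set$spectra[[1]]$value, a)
  expect_equal(set$spectra[[2]]$label, "frogB")
  expect_length(set$spectra[[1]]$wl, 401)

  long <- tempfile(fileext = ".csv")
  write.csv(data.frame(label = rep(c("x", "y", "z"), each = 401),
                       wavelength = rep(wl, 3),
                       value = c(a, b, a)), long, row.names = FALSE)
  setl <- read_spectra(long, "long")
  expect_length(setl, 3)
  expect_equal(setl$spectra[[which(vapply(setl$spectra, `[[`, "", "label") == "y")]]$value, b)
})

test_that("read_spectra errors and warnings", {
  wl <- rnl_grid()
  bad <- tempfile(fileext = ".csv")
  df <- data.frame(wl = as.character(wl), s = 0.3)
  df$wl[5] <- "oops"
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_spectra(bad, "wide"), "non-numeric wavelength")

  dup <- tempfile(fileext = ".csv")
  write.csv(data.frame(label = "a", wavelength = c(400, 400, 401),
                       value = 0.1), dup, row.names = FALSE)
  expect_error(read_spectra(dup, "long"), "duplicate")

  # shuffled wavelengths are re-sorted with a warning (sort-then-compare)
  shuf <- tempfile(fileext = ".csv")
  o <- sample(seq_along(wl))
  write.csv(data.frame(wl = wl[o], s = (0.1 + wl / 2000)[o]), shuf,
            row.names = FALSE)
  expect_warning(set <- read_spectra(shuf, "wide"), "re-sorting")
  expect_equal(set$spectra[[1]]$wl, wl)
  expect_equal(set$spectra[[1]]$value, 0.1 + wl / 2000)

  # percent-scale auto-detection
  pct <- tempfile(fileext = ".csv")
  write.csv(data.frame(wl = wl, s = 35 + wl / 100), pct, row.names = FALSE)
  expect_warning(setp <- read_spectra(pct, "wide"), "percent")
  expect_lt(max(setp$spectra[[1]]$value), 1.2)
})

test_that("trim_spectrum obeys inclusive bounds and coverage", {
  s <- spectrum(250:750, rep(0.3, 501), label = "t")
  tr <- trim_spectrum(s)
  expect_equal(range(tr$wl), c(300, 700))
  expect_length(tr$wl, 401)
  already <- spectrum(rnl_grid(), rep(0.3, 401))
  expect_equal(trim_spectrum(already)$value, already$value)
  short <- spectrum(350:700, rep(0.3, 351))
  expect_error(trim_spectrum(short), "cannot trim")
})

test_that("clip_negatives zeroes noise and is idempotent", {
  s <- spectrum(c(400, 500), c(-0.01, 0.2))
  expect_equal(clip_negatives(s)$value, c(0, 0.2))
  allneg <- spectrum(400:410, rep(-0.05, 11))
  expect_equal(clip_negatives(allneg)$value, rep(0, 11))
  nonneg <- smooth_refl()
  expect_equal(clip_negatives(nonneg)$value, nonneg$value)
  expect_equal(clip_negatives(clip_negatives(s))$value,
               clip_negatives(s)$value)
  expect_error(clip_negatives(flat_illum()), "reflectance")
})

test_that("loess_smooth reproduces polynomials and denoises", {
  wl <- rnl_grid()
  const <- spectrum(wl, rep(0.3, 401))
  expect_lt(max(abs(loess_smooth(const)$value - 0.3)), 1e-8)
  line <- spectrum(wl, 0.1 + 0.001 * (wl - 300))
  expect_lt(max(abs(loess_smooth(line)$value - line$value)), 1e-8)

  set.seed(11)
  clean <- 0.3 + 0.15 * sin(wl / 50)
  noisy <- spectrum(wl, clean + rnorm(401, 0, 0.01))
  sm <- loess_smooth(noisy)
  expect_lt(sqrt(mean((sm$value - clean)^2)),
            sqrt(mean((noisy$value - clean)^2)))

  # direct tricube local-quadratic oracle at 5 probe wavelengths
  span <- 0.2
  n <- 401
  oracle <- function(x0) {
    q <- floor(span * n)
    d <- abs(wl - x0)
    o <- order(d)[1:q]
    dmax <- max(d[o])
    w <- (1 - (d[o] / dmax)^3)^3
    X <- cbind(1, wl[o] - x0, (wl[o] - x0)^2)
    as.numeric(solve(t(X) %*% (w * X), t(X) %*% (w * noisy$value[o])))[1]
  }
  probes <- c(350, 450, 500, 600, 650)
  got <- sm$value[match(probes, wl)]
  expect_equal(got, vapply(probes, oracle, numeric(1)), tolerance = 1e-8)

  expect_error(loess_smooth(spectrum(1:9, rep(0.1, 9))), "at least 10")
  expect_error(loess_smooth(spectrum(1:12, rep(0.1, 12)), span = 0.1),
               "fewer than 4")
})

test_that("interpolate_to_grid is linear and refuses extrapolation", {
  s <- spectrum(rnl_grid(), runif(401))
  expect_equal(interpolate_to_grid(s)$value, s$value)
  two <- spectrum(c(300, 700), c(0, 1))
  it <- interpolate_to_grid(two)
  expect_equal(it$value[it$wl == 500], 0.5)
  fine <- spectrum(seq(300, 700, by = 0.5), 0.1 + seq(300, 700, by = 0.5) / 1000)
  coarse <- interpolate_to_grid(fine)
  expect_equal(coarse$value, 0.1 + rnl_grid() / 1000)  # direct evaluation
  expect_error(interpolate_to_grid(spectrum(350:700, rep(1, 351))),
               "extrapolate")
})

test_that("average_replicates means by group and validates grids", {
  wl <- rnl_grid()
  mk <- function(v, lab) spectrum(wl, rep(v, 401), label = lab)
  set <- spectrum_set(list(mk(0.2, "a1"), mk(0.4, "a2"),
                           mk(0.3, "b1"), mk(0.3, "b2")),
                      data.frame(label = c("a1", "a2", "b1", "b2"),
                                 individual = c("a", "a", "b", "b")))
  avg <- average_replicates(set, "individual")
  expect_length(avg, 2)
  ia <- which(avg$design$individual == "a")
  expect_equal(avg$spectra[[ia]]$value, rep(0.3, 401))
  expect_equal(avg$design$n_averaged, c(2, 2))

  # idempotence: averaging identical spectra returns the same spectrum
  same <- spectrum_set(rep(list(mk(0.25, "x")), 4),
                       data.frame(label = rep("x", 4), individual = "x"))
  expect_equal(average_replicates(same, "individual")$spectra[[1]]$value,
               rep(0.25, 401))

  # 9-locality substrate set grouped by type -> exactly 3 mean spectra
  st <- generate_study(seed = 3)
  subs <- average_replicates(st$substrates, "type")
  expect_length(subs, 3)
  expect_setequal(subs$design$type, c("green_leaf", "leaf_litter", "trunk"))

  bad <- spectrum_set(list(mk(0.2, "a1"), spectrum(400:700, rep(0.2, 301),
                                                   label = "a2")),
                      data.frame(label = c("a1", "a2"),
                                 individual = c("a", "a")))
  expect_error(average_replicates(bad, "individual"), "mismatched")
})

test_that("averaging commutes with pointwise affine rescaling", {
  set.seed(5)
  wl <- rnl_grid()
  sp <- lapply(1:4, function(i) spectrum(wl, runif(401, 0, 0.5),
                                         label = paste0("r", i)))
  des <- data.frame(label = paste0("r", 1:4), individual = "f")
  base <- average_replicates(spectrum_set(sp, des), "individual")
  resc <- lapply(sp, function(s) spectrum(s$wl, 2 * s$value + 0.1,
                                          label = s$label))
  avg2 <- average_replicates(spectrum_set(resc, des), "individual")
  expect_equal(avg2$spectra[[1]]$value, 2 * base$spectra[[1]]$value + 0.1)
})

test_that("preprocessing is stable on its own output", {
  set.seed(21)
  wl <- seq(250, 750, by = 1)
  noisy <- spectrum(wl, 0.25 + 0.2 * exp(-(wl - 560)^2 / 8000) +
                      rnorm(length(wl), 0, 0.01), label = "n")
  set <- spectrum_set(list(noisy))
  once <- preprocess_spectra(set)
  twice <- preprocess_spectra(once)
  expect_lt(max(abs(once$spectra[[1]]$value - twice$spectra[[1]]$value)), 0.02)
})
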