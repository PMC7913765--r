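test_that("noiseless decays are recovered exactly at both delay schedules", {
  for (kind in c("T1", "T1rho")) {
    dl <- delaySchedule(kind)
    for (Tt in c(10, 100, 1200, 10000)) {
      s <- relaxationSeries(1, kind, dl, 2.5 * exp(-dl / Tt))
      f <- fitDecay(s)
      expect_equal(f$T, Tt, tolerance = 1e-6)
      expect_equal(f$I0, 2.5, tolerance = 1e-6)
    }
  }
})

test_that("duplicate delays are reported as a reproducibility check", {
  dl <- delaySchedule("T1")
  y <- exp(-dl / 900); y[dl == 120] <- y[dl == 120] + c(0, 0.01)
  f <- fitDecay(relaxationSeries(1, "T1", dl, y))
  expect_setequal(f$reproducibility$delay, c(120, 1200))
  expect_equal(f$reproducibility$diff[f$reproducibility$delay == 120], 0.01,
               tolerance = 1e-9)
})

test_that("degenerate decay input raises errors", {
  dl <- delaySchedule("T1")
  expect_error(fitDecay(relaxationSeries(1, "T1", dl, rep(1, length(dl)))))
  expect_error(fitDecay(relaxationSeries(1, "T1", dl,
                                         c(-1, exp(-dl[-1] / 500)))),
               "leading intensity")
  expect_error(relaxationSeries(1, "T1", c(0, 1, 1, 2), c(1, 1, 1, 1)),
               "4 distinct")
})

test_that("Monte-Carlo: noisy fits are unbiased and errors calibrated", {
  mc <- makeDecaySeries(1200, noiseSigma = 0.02, nReplicates = 200, seed = 42)
  fits <- lapply(mc$series, fitDecay)
  Ts <- vapply(fits, `[[`, 0, "T")
  errs <- vapply(fits, `[[`, 0, "Terr")
  se <- sd(Ts) / sqrt(length(Ts))
  expect_lt(abs(mean(Ts) - 1200), 3 * se)               # unbiased
  coverage <- mean(abs(Ts - 1200) <= 1.96 * errs)
  expect_gte(coverage, 0.91)                            # 95% +/- 4%
  expect_lte(coverage, 0.99)
})

test_that("offset correction is identity on resonance and matches hand values", {
  fc <- fieldContext()
  # on resonance: residue shift equals the carrier
  expect_equal(correctT1rho(40, 1500, fc@carrierPpm, fc), 40,
               tolerance = 1e-12)
  # theta = 45 deg: place the residue offset equal to the spin-lock strength
  off45 <- fc@carrierPpm + (fc@b1kHz * 1e3) / (fc@nuNHz * 1e-6)
  # R1rho,obs = 20/s, R1 = 1/s -> R2eff = (20 - 0.5)/0.5 = 39/s
  expect_equal(correctT1rho(50, 1000, off45, fc), 1000 / 39,
               tolerance = 1e-9)
  # far off resonance the correction is undefined, not an error
  farField <- fieldContext(b1kHz = 1e-7)
  expect_true(is.na(correctT1rho(50, 1000, 400, farField)))
})

test_that("corrected T1rho never exceeds the observed value when R1 < R1rho", {
  fc <- fieldContext()
  set.seed(13)
  for (rep in 1:20) {
    t1 <- runif(1, 800, 3000)
    t1r <- runif(1, 10, 100)            # R1rho,obs >> R1
    dN <- runif(1, 100, 135)
    corr <- correctT1rho(t1r, t1, dN, fc)
    if (!is.na(corr)) expect_lte(corr, t1r + 1e-9)
  }
})

test_that("tau_c formula: boundary, hand value, round-trip and monotonicity", {
  fc81 <- suppressWarnings(fieldContext(nuNHz = 81.08e6))
  # 6 T1/T1rho = 7 exactly -> tau_c = 0
  expect_equal(estimateTauC(7, 6, fc81), 0)
  # hand evaluation: T1 = 2000 ms, T1rho = 30 ms, nuN = 81.08 MHz -> ~19.5 ns
  expect_equal(estimateTauC(2000, 30, fc81), 19.5, tolerance = 0.01)
  # below the boundary the estimate is undefined
  expect_true(is.na(estimateTauC(6, 6, fc81)))
  # algebraic round-trip to 1e-9 relative
  fc <- fieldContext()
  for (tauc in c(0.5, 5, 25, 60)) {
    ratio <- ((4 * pi * fc@nuNHz * tauc * 1e-9)^2 + 7) / 6
    expect_equal(estimateTauC(1000 * ratio, 1000, fc), tauc,
                 tolerance = 1e-9)
  }
  # strictly increasing in T1/T1rho on the defined domain
  ratios <- seq(1.2, 400, length.out = 50)
  taus <- vapply(ratios, function(r) estimateTauC(1000 * r, 1000, fc), 0)
  expect_true(all(diff(taus) > 0))
})

test_that("fieldContext warns when nuN violates the gyromagnetic ratio", {
  expect_warning(fieldContext(h1MHz = 800, nuNHz = 70e6), "0.10137")
  expect_silent(fieldContext(h1MHz = 800))
  expect_equal(fieldContext(h1MHz = 800)@nuNHz, 0.10137 * 800e6)
})

test_that("heteronuclear NOE ratio and propagated error", {
  expect_equal(hetNoe(1, 1, 0.01)$ratio, 1)
  r <- hetNoe(0.8, 1.0, 0.01)
  expect_equal(r$ratio, 0.8)
  expect_equal(r$error, 0.8 * sqrt((0.01 / 0.8)^2 + (0.01 / 1)^2),
               tolerance = 1e-9)         # ~0.0128
  expect_true(is.na(hetNoe(0.5, 0.02, 0.01)$ratio))  # unsaturated ~ 0 at 3 sigma
})

test_that("rigid-limit simulation yields NOE ratios near 0.8", {
  set.seed(77)
  sat <- 0.8 + rnorm(50, 0, 0.01); uns <- 1 + rnorm(50, 0, 0.01)
  ratios <- mapply(function(s, u) hetNoe(s, u, 0.01)$ratio, sat, uns)
  expect_equal(mean(ratios), 0.8, tolerance = 0.02)
})

test_that("subdomain summary flags planted tumbling differences", {
  resHD <- 666:721; resART <- 790:936
  mk <- function(hdVal, artVal, sdv = 0.8, seed = 3) {
    withr::with_seed(seed, data.frame(
      resno = c(resHD, resART),
      tauc = c(rnorm(length(resHD), hdVal, sdv),
               rnorm(length(resART), artVal, sdv))))
  }
  # identical values: no separation
  same <- subdomainSummary(data.frame(resno = c(resHD, resART), tauc = 25))
  expect_equal(same$summary$mean, c(25, 25))
  expect_false(same$separated)
  # both subdomains planted at 25 ns: tumble as a single unit
  single <- subdomainSummary(mk(25, 25))
  expect_false(single$separated)
  expect_equal(single$summary$mean, c(25, 25), tolerance = 0.5)
  # HD at 15 ns vs ART at 25 ns: clearly separated
  split <- subdomainSummary(mk(15, 25))
  expect_true(split$separated)
  expect_error(subdomainSummary(data.frame(resno = 666:667, tauc = c(1, 2))),
               "fewer than 3")
})

test_that("relaxation TSV reader groups rows into per-residue series", {
  f <- tempfile(fileext = ".tsv")
  dl <- delaySchedule("T1rho")
  df <- do.call(rbind, lapply(c(700, 701), function(r)
    data.frame(residue = r, delay_ms = dl, intensity = exp(-dl / 45))))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  series <- readRelaxationTable(f, "T1rho", noise = 0.01)
  expect_length(series, 2L)
  expect_equal(fitDecay(series[["700"]])$T, 45, tolerance = 1e-6)
  expect_equal(series[["701"]]@noise, 0.01)
})
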