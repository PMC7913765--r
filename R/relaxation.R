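#' Construct a RelaxationSeries
#'
#' @param resno residue number.
#' @param kind `"T1"` or `"T1rho"`.
#' @param delays delay times in ms (duplicates allowed; they check
#'   reproducibility and are fitted as independent observations).
#' @param intensities one intensity per delay.
#' @param noise spectrum RMS noise (default 0).
#' @return a [RelaxationSeries-class].
#' @export
relaxationSeries <- function(resno, kind, delays, intensities, noise = 0) {
  new("RelaxationSeries", resno = as.integer(resno), kind = kind,
      delays = as.numeric(delays), intensities = as.numeric(intensities),
      noise = as.numeric(noise))
}

setMethod("show", "RelaxationSeries", function(object) {
  cat(sprintf("RelaxationSeries: residue %d, %s, %d delays (%g-%g ms)\n",
              object@resno, object@kind, length(object@delays),
              min(object@delays), max(object@delays)))
})

#' The T1 and T1rho delay schedules used in the study
#'
#' T1: 0, 120, 120, 280, 480, 800, 1200, 1200, 2000, 3200, 4800, 6800 ms.
#' T1rho: 0.15, 2, 4, 4, 7, 12, 20, 34, 34, 50, 70, 100 ms. The duplicated
#' delays are deliberate reproducibility checks.
#'
#' @param kind `"T1"` or `"T1rho"`.
#' @return numeric vector of delays in ms.
#' @export
delaySchedule <- function(kind = c("T1", "T1rho")) {
  kind <- match.arg(kind)
  if (kind == "T1") c(0, 120, 120, 280, 480, 800, 1200, 1200,
                      2000, 3200, 4800, 6800)
  else c(0.15, 2, 4, 4, 7, 12, 20, 34, 34, 50, 70, 100)
}

#' Fit a mono-exponential relaxation decay
#'
#' Non-linear least-squares fit of `I(t) = I0 * exp(-t / T)`. Parameter
#' errors come from the fit covariance scaled by the residual variance (the
#' standard errors reported by the nls machinery). Duplicate delays enter the
#' fit as independent observations; their intensity differences are returned
#' as a reproducibility check.
#'
#' @param series a [RelaxationSeries-class].
#' @return list with `T` (ms), `Terr`, `I0`, `I0err`, `reproducibility`
#'   (data.frame of duplicated delays and their absolute intensity
#'   differences) and `fit` (the underlying nls object).
#' @examples
#' s <- relaxationSeries(700, "T1", delaySchedule("T1"),
#'                       exp(-delaySchedule("T1") / 1200))
#' fitDecay(s)$T
#' @export
fitDecay <- function(series) {
  stopifnot(is(series, "RelaxationSeries"))
  t <- series@delays; y <- series@intensities
  if (y[which.min(t)] <= 0)
    stop("non-positive leading intensity: decay amplitude ill-defined")
  span <- diff(range(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-t / T),
                      start = list(I0 = max(y), T = span / 3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("decay fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- summary(fit)$coefficients
  Tfit <- co["T", "Estimate"]
  if (!is.finite(Tfit) || Tfit <= 0)
    stop("fitted relaxation time is not positive (T = ", format(Tfit),
         " ms); decay is degenerate")
  dup <- unique(t[duplicated(t)])
  rep <- data.frame(delay = dup,
                    diff = vapply(dup, function(d) {
                      v <- y[t == d]
                      max(v) - min(v)
                    }, numeric(1)))
  list(T = Tfit, Terr = co["T", "Std. Error"],
       I0 = co["I0", "Estimate"], I0err = co["I0", "Std. Error"],
       reproducibility = rep, fit = fit)
}

#' Spectrometer field context
#'
#' Defaults are the study conditions: 800 MHz 1H, spin-lock B1 = 1.56 kHz at
#' a carrier offset of 117.074 ppm. The 15N frequency defaults to
#' 0.10137 * (1H frequency); supplying a value violating that gyromagnetic
#' ratio by more than 1% triggers a warning.
#'
#' @param h1MHz 1H resonance frequency, MHz.
#' @param b1kHz spin-lock field strength, kHz.
#' @param carrierPpm spin-lock carrier position, ppm.
#' @param nuNHz 15N resonance frequency, Hz (default derived from `h1MHz`).
#' @return a [FieldContext-class].
#' @export
fieldContext <- function(h1MHz = 800, b1kHz = 1.56, carrierPpm = 117.074,
                         nuNHz = NULL) {
  if (is.null(nuNHz)) nuNHz <- 0.10137 * h1MHz * 1e6
  else if (abs(nuNHz / (0.10137 * h1MHz * 1e6) - 1) > 0.01)
    warning("nuN deviates from 0.10137 x 1H frequency by more than 1%")
  new("FieldContext", h1MHz = h1MHz, nuNHz = nuNHz, b1kHz = b1kHz,
      carrierPpm = carrierPpm)
}

setMethod("show", "FieldContext", function(object) {
  cat(sprintf(
    "FieldContext: 1H %g MHz (15N %.3f MHz), B1 %g kHz, carrier %g ppm\n",
    object@h1MHz, object@nuNHz / 1e6, object@b1kHz, object@carrierPpm))
})

#' Correct an observed T1rho for 15N resonance offset
#'
#' Standard tilted-rotating-frame correction: with spin-lock amplitude
#' omega1 = 2*pi*B1 and residue offset Omega = 2*pi*(delta - carrier)*nuN*1e-6
#' from the spin-lock carrier, the tilt angle is theta = atan(omega1/Omega)
#' and
#' \deqn{R_2^{eff} = (R_{1\rho,obs} - R_1 cos^2\theta) / sin^2\theta.}
#' On resonance (theta = 90 deg) the observed value is returned unchanged.
#' Residues so far off resonance that sin^2(theta) < 1e-6 get `NA` (the
#' correction would amplify noise without bound), reported as a flag rather
#' than raised as an error.
#'
#' @param t1rhoObs observed T1rho, ms.
#' @param t1 fitted T1 of the same residue, ms.
#' @param deltaN the residue's 15N shift, ppm.
#' @param field a [FieldContext-class].
#' @return offset-corrected T1rho in ms, or `NA` when undefined.
#' @export
correctT1rho <- function(t1rhoObs, t1, deltaN, field = fieldContext()) {
  .assertScalarPositive(t1rhoObs, "t1rhoObs")
  .assertScalarPositive(t1, "t1")
  stopifnot(is(field, "FieldContext"))
  omega1 <- 2 * pi * field@b1kHz * 1e3
  Omega <- 2 * pi * (deltaN - field@carrierPpm) * field@nuNHz * 1e-6
  theta <- atan2(omega1, Omega)
  s2 <- sin(theta)^2
  if (s2 < 1e-6) return(NA_real_)
  r1 <- 1000 / t1
  r1rObs <- 1000 / t1rhoObs
  r2eff <- (r1rObs - r1 * cos(theta)^2) / s2
  if (r2eff <= 0) return(NA_real_)
  1000 / r2eff
}

#' Rotational correlation time from the T1/T1rho ratio
#'
#' \deqn{\tau_c \approx \frac{1}{4\pi\nu_N}\sqrt{6 T_1/T_{1\rho} - 7}}
#' with nuN the 15N resonance frequency in Hz. The estimate assumes
#' isotropic tumbling dominated by dipolar/CSA relaxation; it is undefined
#' (returns `NA`) when the radicand is negative, i.e. 6*T1/T1rho < 7, which
#' happens for highly flexible residues.
#'
#' @param t1 longitudinal relaxation time, ms.
#' @param t1rho (offset-corrected) rotating-frame relaxation time, ms.
#' @param field a [FieldContext-class].
#' @return tau_c in ns, or `NA` when undefined.
#' @examples
#' estimateTauC(2000, 30, fieldContext(nuNHz = 81.08e6))  # ~19.5 ns
#' @export
estimateTauC <- function(t1, t1rho, field = fieldContext()) {
  .assertScalarPositive(t1, "t1")
  if (is.na(t1rho)) return(NA_real_)
  .assertScalarPositive(t1rho, "t1rho")
  stopifnot(is(field, "FieldContext"))
  rad <- 6 * t1 / t1rho - 7
  if (rad < 0) return(NA_real_)
  1e9 * sqrt(rad) / (4 * pi * field@nuNHz)
}

# algebraic inverse used by the synthetic generator: the T1/T1rho ratio
# implied by a given tau_c (ns)
tauCToRatio <- function(taucNs, field = fieldContext()) {
  ((4 * pi * field@nuNHz * taucNs * 1e-9)^2 + 7) / 6
}

#' Steady-state heteronuclear NOE ratio with propagated error
#'
#' `ratio = I_sat / I_unsat`; the error combines the two spectra's RMS noise
#' in quadrature, `err = |ratio| * sqrt((sigma/I_sat)^2 + (sigma/I_unsat)^2)`.
#' Rigid backbone amides are expected near 0.8 at high field; lower values
#' flag fast internal motion. When the unsaturated intensity is consistent
#' with zero at 3 sigma the ratio is undefined (`NA`).
#'
#' @param saturated,unsaturated peak intensities from the saturated and
#'   reference spectra.
#' @param noise RMS spectrum noise (applied to both intensities).
#' @return list with `ratio` and `error` (both `NA` when undefined).
#' @export
hetNoe <- function(saturated, unsaturated, noise = 0) {
  if (abs(unsaturated) <= 3 * noise)
    return(list(ratio = NA_real_, error = NA_real_))
  ratio <- saturated / unsaturated
  err <- if (noise > 0 && saturated != 0)
    abs(ratio) * sqrt((noise / saturated)^2 + (noise / unsaturated)^2)
  else 0
  list(ratio = ratio, error = err)
}

#' Subdomain-averaged rotational correlation times
#'
#' Averages per-residue tau_c over the HD and ART residue ranges (or any
#' named ranges) using a 10% two-sided trimmed mean — per-residue tau_c
#' estimates have heavy tails from flexible residues, so a plain mean would
#' be dragged around by a handful of outliers. Also reports whether the two
#' selections' means differ by more than the pooled standard deviation: when
#' they do not, the two subdomains tumble as a single unit on the relaxation
#' timescale.
#'
#' @param tauc data.frame with columns `resno` and `tauc` (ns; `NA` allowed).
#' @param selections named list of range lists, default the built-in HD and
#'   ART subdomain definitions.
#' @return list with `summary` (data.frame: selection, n, mean, sd) and
#'   `separated` (logical flag; only set when exactly two selections are
#'   given).
#' @export
subdomainSummary <- function(tauc,
                             selections = list(
                               HD = .builtinRanges$HD,
                               ART = .builtinRanges$ART)) {
  stopifnot(is.data.frame(tauc), all(c("resno", "tauc") %in% names(tauc)))
  rows <- lapply(names(selections), function(nm) {
    rng <- selections[[nm]]
    inSel <- rep(FALSE, nrow(tauc))
    for (r in rng) inSel <- inSel | (tauc$resno >= r[1] & tauc$resno <= r[2])
    v <- tauc$tauc[inSel & !is.na(tauc$tauc)]
    if (length(v) < 3L)
      stop("fewer than 3 defined tau_c values in selection '", nm, "'")
    data.frame(selection = nm, n = length(v),
               mean = mean(v, trim = 0.1), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  })
  s <- do.call(rbind, rows)
  separated <- NA
  if (nrow(s) == 2L) {
    pooled <- sqrt(((s$n[1] - 1) * s$sd[1]^2 + (s$n[2] - 1) * s$sd[2]^2) /
                     (s$n[1] + s$n[2] - 2))
    separated <- abs(s$mean[1] - s$mean[2]) > pooled
  }
  list(summary = s, separated = separated)
}

#' Read relaxation decay tables
#'
#' Expects tab/whitespace-separated columns `residue` (or `resno`),
#' `delay_ms` (or `delay`) and `intensity`, one row per (residue, delay)
#' observation; duplicate delays are independent observations.
#'
#' @param path input TSV.
#' @param kind `"T1"` or `"T1rho"`.
#' @param noise spectrum RMS noise attached to every series.
#' @return list of [RelaxationSeries-class], one per residue.
#' @export
readRelaxationTable <- function(path, kind = c("T1", "T1rho"), noise = 0) {
  kind <- match.arg(kind)
  d <- utils::read.table(path, header = TRUE, sep = "",
                         stringsAsFactors = FALSE)
  nm <- tolower(names(d))
  ri <- which(nm %in% c("residue", "resno", "res"))[1L]
  di <- which(nm %in% c("delay_ms", "delay", "t_ms"))[1L]
  ii <- which(nm %in% c("intensity", "i"))[1L]
  if (anyNA(c(ri, di, ii)))
    stop("expected columns residue, delay_ms, intensity in ", path)
  lapply(split(d, d[[ri]]), function(s)
    relaxationSeries(s[[ri]][1L], kind, s[[di]], s[[ii]], noise))
}
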