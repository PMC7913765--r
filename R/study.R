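#' Fold change between two dissociation constants
#'
#' Ratio of the larger to the smaller KD, with a direction flag relative to
#' the first argument: `"tighter"` when the second KD is smaller (stronger
#' binding in condition B), `"weaker"` when it is larger, `"equal"`
#' otherwise. Used to quantify allosteric tightening or weakening of
#' DNA-damage binding across inhibitor complexes.
#'
#' @param kdA reference-condition dissociation constant (molar, > 0).
#' @param kdB comparison-condition dissociation constant (molar, > 0).
#' @return list with `fold` (>= 1) and `direction`.
#' @examples
#' foldChange(2.1e-9, 1.3e-10)   # ~16-fold tighter
#' @export
foldChange <- function(kdA, kdB) {
  .assertScalarPositive(kdA, "kdA")
  .assertScalarPositive(kdB, "kdB")
  list(fold = max(kdA, kdB) / min(kdA, kdB),
       direction = if (kdB < kdA) "tighter"
       else if (kdB > kdA) "weaker" else "equal")
}

#' Read a study configuration
#'
#' A flat declarative YAML file describing the samples and shared
#' parameters of a study:
#' \preformatted{
#' out_dir: results
#' seed: 1
#' reference: WT
#' field: {h1_mhz: 800, b1_khz: 1.56, carrier_ppm: 117.074}
#' kd_table: kd.tsv          # optional: columns label, kd
#' samples:
#'   - label: WT
#'     shifts: wt_shifts.tsv         # optional per stage
#'     shifts_dialect: tsv
#'     structure: wt.pdb
#'     chain: A
#'     t1: wt_t1.tsv                 # residue, delay_ms, intensity
#'     t1rho: wt_t1rho.tsv
#'     noise: 0.02
#'     cleanex: wt_cleanex.tsv       # resno, intensity
#'     cleanex_ref: wt_trosy.tsv
#'     realtime_3: wt_3h.tsv         # resno, intensity
#'     realtime_12: wt_12h.tsv
#'     realtime_39: wt_39h.tsv
#' }
#' Validation (unique labels, files exist, reference present) happens here,
#' before any computation.
#'
#' @param path YAML configuration file.
#' @return a validated config list.
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$samples) || !length(cfg$samples))
    stop("config lists no samples")
  labels <- vapply(cfg$samples, function(s) s$label %||% "", "")
  if (any(labels == "")) stop("every sample needs a label")
  if (anyDuplicated(labels))
    stop("duplicate sample labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (is.null(cfg$reference)) cfg$reference <- labels[1L]
  if (!cfg$reference %in% labels)
    stop("reference sample '", cfg$reference, "' is not in the sample list")
  base <- dirname(normalizePath(path))
  fileKeys <- c("shifts", "structure", "t1", "t1rho", "noe", "cleanex",
                "cleanex_ref", "realtime_3", "realtime_12", "realtime_39")
  cfg$samples <- lapply(cfg$samples, function(s) {
    for (k in fileKeys) {
      if (is.null(s[[k]])) next
      p <- s[[k]]
      if (!file.exists(p)) p <- file.path(base, s[[k]])
      if (!file.exists(p))
        stop("sample '", s$label, "': file for '", k, "' not found: ", s[[k]])
      s[[k]] <- p
    }
    s
  })
  if (!is.null(cfg$kd_table) && !file.exists(cfg$kd_table)) {
    p <- file.path(base, cfg$kd_table)
    if (!file.exists(p)) stop("kd_table not found: ", cfg$kd_table)
    cfg$kd_table <- p
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- "study-out"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  f <- cfg$field %||% list()
  cfg$fieldContext <- fieldContext(
    h1MHz = f$h1_mhz %||% 800, b1kHz = f$b1_khz %||% 1.56,
    carrierPpm = f$carrier_ppm %||% 117.074)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

readIntensityTable <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "",
                         stringsAsFactors = FALSE)
  nm <- tolower(names(d))
  ri <- which(nm %in% c("resno", "residue", "res"))[1L]
  ii <- which(nm %in% c("intensity", "i"))[1L]
  if (anyNA(c(ri, ii)))
    stop("expected columns resno, intensity in ", path)
  data.frame(resno = as.integer(d[[ri]]), intensity = as.numeric(d[[ii]]))
}

# run one sample's stages; any stage error is caught and flagged
.runSample <- function(s, refSample, cfg, outDir) {
  res <- list(label = s$label, warnings = character())
  note <- function(...) res$warnings <<- c(res$warnings, paste0(...))
  tryStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
  }
  dialect <- s$shifts_dialect %||% "tsv"
  # chemical shifts / CSP vs the reference sample
  if (!is.null(s$shifts)) {
    res$shifts <- tryStage("shifts",
      readShiftTable(s$shifts, dialect, label = s$label))
  }
  if (!is.null(res$shifts) && !is.null(refSample$shifts) &&
      !identical(s$label, refSample$label)) {
    res$csp <- tryStage("csp", {
      prof <- computeCsp(refSample$shifts, res$shifts)
      exportResidueAttributes(
        prof, file.path(outDir, paste0(s$label, "_csp.tsv")))
      prof
    })
  }
  # relaxation: decay fits, offset correction, per-residue tau_c
  if (!is.null(s$t1) && !is.null(s$t1rho)) {
    res$relax <- tryStage("relaxation", {
      noise <- s$noise %||% 0
      fit <- function(series) vapply(series, function(x) fitDecay(x)$T,
                                     numeric(1))
      t1s <- readRelaxationTable(s$t1, "T1", noise)
      t1rs <- readRelaxationTable(s$t1rho, "T1rho", noise)
      common <- intersect(names(t1s), names(t1rs))
      t1 <- fit(t1s[common]); t1r <- fit(t1rs[common])
      resno <- as.integer(common)
      shiftsN <- if (!is.null(res$shifts)) shifts(res$shifts) else NULL
      tauc <- vapply(seq_along(common), function(i) {
        dN <- if (!is.null(shiftsN)) {
          j <- match(resno[i], shiftsN$resno)
          if (!is.na(j) && is.finite(shiftsN$dN[j])) shiftsN$dN[j]
          else cfg$fieldContext@carrierPpm
        } else cfg$fieldContext@carrierPpm
        corr <- correctT1rho(t1r[i], t1[i], dN, cfg$fieldContext)
        estimateTauC(t1[i], corr, cfg$fieldContext)
      }, numeric(1))
      if (anyNA(tauc)) note(sum(is.na(tauc)), " residue(s) with undefined tau_c")
      df <- data.frame(resno = resno, t1 = t1, t1rho_obs = t1r, tauc = tauc)
      utils::write.table(df, file.path(outDir, paste0(s$label, "_tauc.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      df
    })
  }
  # solvent exchange classification
  if (!is.null(s$realtime_3)) {
    res$exchange <- tryStage("exchange", {
      rt <- list()
      for (h in c("3", "12", "39")) {
        key <- paste0("realtime_", h)
        if (!is.null(s[[key]])) rt[[h]] <- readIntensityTable(s[[key]])
      }
      tbl <- exchangeTable(
        cleanex = if (!is.null(s$cleanex)) readIntensityTable(s$cleanex),
        reference = if (!is.null(s$cleanex_ref))
          readIntensityTable(s$cleanex_ref),
        realtime = rt, noise = s$noise %||% 0)
      tbl <- classifyTable(tbl)
      exportExchangeAttributes(
        tbl, file.path(outDir, paste0(s$label, "_exchange.tsv")))
      tbl
    })
  }
  if (!is.null(s$structure))
    res$structure <- tryStage("structure",
      readStructure(s$structure, id = s$label))
  res$chain <- s$chain %||% "A"
  res
}

#' Run a configured study end to end
#'
#' Executes every stage for which a sample provides inputs — CSP profiles
#' against the reference sample (globally normalised across samples),
#' relaxation fits through to subdomain tau_c means, exchange
#' classification, and Table-2-style superposition statistics of every
#' structure against the reference structure — then writes per-stage TSVs,
#' a manifest and a human-readable summary into the output directory.
#' A failure in one sample is logged and flagged in the report; other
#' samples are unaffected. Identical config and seed give a byte-identical
#' report.
#'
#' @param config path to a YAML config or the list from [readStudyConfig()].
#' @return a [ComparisonReport-class], invisibly; side effect: files under
#'   `out_dir`.
#' @export
runStudy <- function(config) {
  cfg <- if (is.character(config)) readStudyConfig(config) else config
  if (is.null(cfg$samples) || !length(cfg$samples))
    stop("config lists no samples")
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  labels <- vapply(cfg$samples, `[[`, "", "label")
  refIdx <- match(cfg$reference, labels)
  refSample <- .runSample(cfg$samples[[refIdx]], list(label = NULL), cfg,
                          outDir)
  results <- lapply(cfg$samples, function(s)
    if (s$label == cfg$reference) refSample
    else .runSample(s, refSample, cfg, outDir))
  names(results) <- labels
  warningsAll <- unlist(lapply(results, function(r)
    if (length(r$warnings)) paste0(r$label, ": ", r$warnings)))
  # global CSP normalisation across all comparisons
  profs <- Filter(Negate(is.null), lapply(results, `[[`, "csp"))
  cspTab <- data.frame()
  if (length(profs)) {
    nms <- names(profs)
    profs <- normaliseProfiles(profs)
    names(profs) <- nms
    for (nm in nms)   # re-export with the shared global colour scale
      exportResidueAttributes(profs[[nm]],
                              file.path(outDir, paste0(nm, "_csp.tsv")))
    cspTab <- do.call(rbind, lapply(names(profs), function(nm) {
      p <- profs[[nm]]
      d <- p@data
      imax <- which.max(ifelse(is.na(d$csp), -Inf, d$csp))
      data.frame(sample = nm, n_assigned = sum(!is.na(d$csp)),
                 csp_max = d$csp[imax], csp_max_residue = d$resno[imax],
                 threshold = p@threshold, stringsAsFactors = FALSE)
    }))
  }
  relaxTab <- do.call(rbind, c(list(data.frame()),
    lapply(names(results), function(nm) {
      r <- results[[nm]]
      if (is.null(r$relax)) return(NULL)
      sm <- tryCatch(subdomainSummary(r$relax), error = function(e) NULL)
      if (is.null(sm)) return(NULL)
      data.frame(sample = nm,
                 hd_mean = sm$summary$mean[sm$summary$selection == "HD"],
                 hd_sd = sm$summary$sd[sm$summary$selection == "HD"],
                 art_mean = sm$summary$mean[sm$summary$selection == "ART"],
                 art_sd = sm$summary$sd[sm$summary$selection == "ART"],
                 separated = sm$separated, stringsAsFactors = FALSE)
    })))
  exchTab <- do.call(rbind, c(list(data.frame()),
    lapply(names(results), function(nm) {
      r <- results[[nm]]
      if (is.null(r$exchange)) return(NULL)
      cls <- r$exchange@data$class
      data.frame(sample = nm,
                 fast = sum(cls == "fast"),
                 slow_light = sum(cls == "slow-light"),
                 slow_medium = sum(cls == "slow-medium"),
                 slow_dark = sum(cls == "slow-dark"),
                 unobserved = sum(cls == "unobserved"),
                 stringsAsFactors = FALSE)
    })))
  # Table-2-style rmsd matrix against the reference structure
  rmsdTab <- data.frame()
  if (!is.null(refSample$structure)) {
    combos <- list(c("CAT", "CAT"), c("ART", "ART"), c("HD", "HD"),
                   c("ART", "HD"), c("HD", "ART"))
    rows <- list()
    for (nm in names(results)) {
      r <- results[[nm]]
      if (is.null(r$structure) || nm == cfg$reference) next
      for (cm in combos) {
        row <- tryCatch({
          sup <- twoSetRmsd(refSample$structure, r$structure,
                            builtinSelection(cm[1L]),
                            builtinSelection(cm[2L]),
                            chainA = refSample$chain, chainB = r$chain)
          data.frame(structure = nm, chain = r$chain, fit_set = cm[1L],
                     measure_set = cm[2L], n_fit = sup@nFit,
                     n_measure = sup@nMeasure, rmsd_fit = sup@rmsdFit,
                     rmsd_measure = sup@rmsdMeasure, stringsAsFactors = FALSE)
        }, error = function(e) {
          warningsAll <<- c(warningsAll, paste0(
            nm, ": superposition ", cm[1L], "/", cm[2L], " failed: ",
            conditionMessage(e)))
          NULL
        })
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
    if (length(rows)) rmsdTab <- do.call(rbind, rows)
  }
  # affinity fold changes vs the reference label, when KDs are supplied
  affTab <- data.frame()
  if (!is.null(cfg$kd_table)) {
    kd <- utils::read.table(cfg$kd_table, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    iref <- match(cfg$reference, kd$label)
    if (is.na(iref)) {
      warningsAll <- c(warningsAll,
                       paste0("kd_table lacks reference label '",
                              cfg$reference, "'"))
    } else {
      others <- kd[-iref, , drop = FALSE]
      affTab <- do.call(rbind, lapply(seq_len(nrow(others)), function(i) {
        fc <- foldChange(kd$kd[iref], others$kd[i])
        data.frame(sample = others$label[i], kd = others$kd[i],
                   kd_reference = kd$kd[iref], fold = fc$fold,
                   direction = fc$direction, stringsAsFactors = FALSE)
      }))
    }
  }
  if (is.null(warningsAll)) warningsAll <- character()
  report <- new("ComparisonReport", reference = cfg$reference,
                csp = cspTab, relaxation = relaxTab, exchange = exchTab,
                rmsd = rmsdTab, affinity = affTab, warnings = warningsAll)
  writeReport(report, outDir)
  invisible(report)
}

#' Write a ComparisonReport as TSV tables plus a text summary
#'
#' @param report a [ComparisonReport-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (nrow(df)) {
      num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
      df[num] <- lapply(df[num], fmtNum)
    }
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report@csp, "csp_summary.tsv")
  wt(report@relaxation, "relaxation_summary.tsv")
  wt(report@exchange, "exchange_summary.tsv")
  wt(report@rmsd, "rmsd_table.tsv")
  wt(report@affinity, "affinity_summary.tsv")
  lines <- c(paste0("Study report (reference sample: ", report@reference, ")"),
             "",
             paste0("CSP comparisons: ", nrow(report@csp)),
             paste0("Relaxation summaries: ", nrow(report@relaxation)),
             paste0("Exchange tables: ", nrow(report@exchange)),
             paste0("Superposition rows: ", nrow(report@rmsd)),
             paste0("Affinity fold changes: ", nrow(report@affinity)),
             "",
             if (length(report@warnings))
               c("Warnings/flags:", paste0("  - ", report@warnings))
             else "No warnings.")
  writeLines(lines, file.path(dir, "summary.txt"))
  manifest <- c("csp_summary.tsv", "relaxation_summary.tsv",
                "exchange_summary.tsv", "rmsd_table.tsv",
                "affinity_summary.tsv", "summary.txt")
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport (reference '", object@reference, "'): ",
      nrow(object@csp), " CSP, ", nrow(object@relaxation), " relaxation, ",
      nrow(object@exchange), " exchange, ", nrow(object@rmsd),
      " rmsd rows, ", length(object@warnings), " warning(s)\n", sep = "")
})
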