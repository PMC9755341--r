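# End-to-end study replication: synthetic cohort -> simulated raters x two
# ROI methods -> early/late H/M ratios -> pathological classification ->
# full agreement panel (ICC, Fleiss kappa, pairwise Cohen kappa, per-rater
# Spearman between methods, chi-square on pathological proportions).

#' Study configuration
#'
#' @param n_subjects Cohort size (default 35).
#' @param phantom A [phantom_params()].
#' @param profiles Named list of at least two [rater_profile()]s (default
#'   [default_rater_profiles()]).
#' @param cutoffs Named cut-off vector, see [default_cutoffs()].
#' @param methods Methods to run (`"manual"`, `"semiautomatic"` or both).
#' @param hm_spec Cohort uptake specification, see [generate_cohort()].
#' @param washout_spec Per-subject myocardial washout spec, see
#'   [generate_cohort()].
#' @param seed Master seed; every stage derives its own stream from it.
#' @param fleiss_B Bootstrap resamples for Fleiss kappa CIs (default 2000).
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 35L,
                         phantom = phantom_params(),
                         profiles = default_rater_profiles(),
                         cutoffs = default_cutoffs(),
                         methods = c("manual", "semiautomatic"),
                         hm_spec = default_hm_spec(),
                         washout_spec = list(mean = 0.85, sd = 0.06,
                                             min = 0.60, max = 1.05),
                         seed = 1L,
                         fleiss_B = 2000L) {
  methods <- match.arg(methods, c("manual", "semiautomatic"),
                       several.ok = TRUE)
  if (length(profiles) < 2L) {
    stop_mibg("mibg_params", "need at least two rater profiles")
  }
  if (!all(cutoffs > 0)) stop_mibg("mibg_params", "cut-offs must be positive")
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, `[[`, "", "label")
  }
  structure(
    list(n_subjects = n_subjects, phantom = phantom, profiles = profiles,
         cutoffs = cutoffs, methods = methods, hm_spec = hm_spec,
         washout_spec = washout_spec, seed = seed, fleiss_B = fleiss_B),
    class = "study_config"
  )
}

#' Run the full simulated study
#'
#' Generates a cohort, simulates every configured rater applying every
#' configured ROI method to every subject, computes early/late H/M ratios
#' and pathological classifications, and assembles the complete agreement
#' panel.  Deterministic given the config seed.
#'
#' @param config A [study_config()].
#' @param verbose Print one progress line per subject (default `FALSE`).
#' @return A `study_report`: list with `results` (per subject/rater/method
#'   data frame), `panel` (agreement statistics per method and phase),
#'   `summary` (mean +/- SD and pathological counts), and `config`.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(
    n = config$n_subjects, hm_spec = config$hm_spec,
    params = config$phantom, seed = derive_seed(config$seed, 1L),
    washout_spec = config$washout_spec
  )
  results <- rate_cohort(cohort, config, verbose = verbose)
  report_from_results(results, config)
}

# simulate every rater x method on an existing cohort
rate_cohort <- function(cohort, config, verbose = FALSE) {
  raters <- names(config$profiles)
  rows <- list()
  for (si in seq_along(cohort)) {
    rec <- cohort[[si]]
    for (ri in seq_along(raters)) {
      for (mi in seq_along(config$methods)) {
        method <- config$methods[mi]
        rois <- tryCatch(
          simulate_rater_rois(
            rec, config$profiles[[ri]], method,
            seed = derive_seed(config$seed, 2L, si, ri, mi)
          ),
          mibg_error = function(e) {
            stop_mibg("mibg_stage",
                      "ROI simulation failed [subject=%s rater=%s method=%s]: %s",
                      rec$subject, raters[ri], method, conditionMessage(e))
          }
        )
        row <- tryCatch(
          quantify_roiset(rec, rois, config$cutoffs),
          mibg_error = function(e) {
            stop_mibg("mibg_stage",
                      "H/M computation failed [subject=%s rater=%s method=%s]: %s",
                      rec$subject, raters[ri], method, conditionMessage(e))
          }
        )
        rows[[length(rows) + 1L]] <- row
      }
    }
    if (verbose) {
      message(sprintf("subject %s: done (%d raters x %d methods)",
                      rec$subject, length(raters), length(config$methods)))
    }
  }
  do.call(rbind, rows)
}

quantify_roiset <- function(rec, rois, cutoffs) {
  e_hm <- hm_ratio(rec$early, rois$cardiac, rois$mediastinal)
  l_hm <- if (!is.null(rec$late)) {
    hm_ratio(rec$late, rois$cardiac, rois$mediastinal)
  } else {
    NA_real_
  }
  cls <- classify_hm(e_hm, l_hm, cutoffs)
  data.frame(
    subject = rec$subject, rater = rois$rater, method = rois$method,
    early_hm = e_hm, late_hm = l_hm,
    early_path = cls$early_pathological, late_path = cls$late_pathological,
    stringsAsFactors = FALSE
  )
}

ratings_matrix <- function(results, method, value_col) {
  sub <- results[results$method == method, , drop = FALSE]
  raters <- unique(results$rater)
  subjects <- unique(results$subject)
  m <- matrix(NA, length(subjects), length(raters),
              dimnames = list(subjects, raters))
  for (r in raters) {
    rr <- sub[sub$rater == r, , drop = FALSE]
    m[match(rr$subject, subjects), match(r, raters)] <- rr[[value_col]]
  }
  m
}

panel_for <- function(results, method, phase, config) {
  cont <- ratings_matrix(results, method, paste0(phase, "_hm"))
  cat_ <- ratings_matrix(results, method, paste0(phase, "_path"))
  raters <- colnames(cont)
  icc_res <- tryCatch(icc(cont), mibg_degenerate = function(e) {
    list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         label = NA_character_, degenerate = TRUE)
  })
  fk <- fleiss_kappa(cat_, B = config$fleiss_B,
                     seed = derive_seed(config$seed, 3L))
  pairs <- utils::combn(seq_along(raters), 2L, simplify = FALSE)
  cohen <- lapply(pairs, function(p) {
    ck <- cohens_kappa(cat_[, p[1L]], cat_[, p[2L]])
    c(list(raters = paste(raters[p], collapse = "-")), ck)
  })
  chisq <- lapply(pairs, function(p) {
    tab <- rbind(
      c(sum(cat_[, p[1L]]), sum(!cat_[, p[1L]])),
      c(sum(cat_[, p[2L]]), sum(!cat_[, p[2L]]))
    )
    res <- tryCatch(chi_square_2x2(tab), mibg_degenerate = function(e) {
      list(statistic = NA_real_, p = NA_real_, df = 1L)
    })
    c(list(raters = paste(raters[p], collapse = "-")), res)
  })
  list(method = method, phase = phase,
       icc = icc_res, fleiss = fk, cohen = cohen, chi_square = chisq,
       pathological = colSums(cat_), n = nrow(cat_))
}

report_from_results <- function(results, config) {
  raters <- unique(results$rater)
  methods <- unique(results$method)
  phases <- c("early", if (!all(is.na(results$late_hm))) "late")

  panel <- list()
  for (m in methods) {
    for (ph in phases) {
      panel[[paste(m, ph, sep = ".")]] <- panel_for(results, m, ph, config)
    }
  }

  spearman <- list()
  if (length(methods) == 2L) {
    for (r in raters) {
      for (ph in phases) {
        x <- ratings_matrix(results, methods[1L], paste0(ph, "_hm"))[, r]
        y <- ratings_matrix(results, methods[2L], paste0(ph, "_hm"))[, r]
        spearman[[paste(r, ph, sep = ".")]] <-
          c(list(rater = r, phase = ph,
                 methods = paste(methods, collapse = " vs ")),
            spearman_rho(x, y))
      }
    }
  }

  summary <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(raters, function(r) {
      sub <- results[results$method == m & results$rater == r, ]
      data.frame(
        method = m, rater = r,
        early_mean = mean(sub$early_hm), early_sd = stats::sd(sub$early_hm),
        late_mean = mean(sub$late_hm), late_sd = stats::sd(sub$late_hm),
        early_pathological = sum(sub$early_path),
        late_pathological = sum(sub$late_path),
        n = nrow(sub), stringsAsFactors = FALSE
      )
    }))
  }))

  structure(
    list(results = results, panel = panel, spearman = spearman,
         summary = summary, config = config),
    class = "study_report"
  )
}

#' Analyze externally supplied images and ROI sets
#'
#' Runs the identical quantification and agreement analysis on user data
#' instead of simulated raters.
#'
#' @param images Named list (by subject) of lists with elements `early` and
#'   optionally `late` ([planar_image()]s).
#' @param roisets Nested named list `roisets[[subject]][[rater]][[method]]`
#'   of ROI sets (as from [read_roiset()]).
#' @param config A [study_config()] (cut-offs, Fleiss bootstrap size and
#'   seed are used; the phantom settings are ignored).
#' @return A `study_report`.
#' @export
analyze_external <- function(images, roisets, config = study_config()) {
  subjects <- names(images)
  if (is.null(subjects) || !length(subjects)) {
    stop_mibg("mibg_argument", "images must be a named list of subjects")
  }
  raters <- unique(unlist(lapply(roisets, names)))
  methods <- unique(unlist(lapply(roisets, function(r) {
    unlist(lapply(r, names))
  })))
  missing <- character(0)
  for (s in subjects) {
    for (r in raters) {
      for (m in methods) {
        if (is.null(roisets[[s]][[r]][[m]])) {
          missing <- c(missing, sprintf("%s/%s/%s", s, r, m))
        }
      }
    }
  }
  if (length(missing)) {
    stop_mibg("mibg_completeness",
              "missing ROI sets for: %s", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (s in subjects) {
    rec <- list(subject = s, early = images[[s]]$early,
                late = images[[s]]$late)
    for (r in raters) {
      for (m in methods) {
        rs <- roisets[[s]][[r]][[m]]
        rs$rater <- r
        rs$method <- m
        row <- tryCatch(
          quantify_roiset(rec, rs, config$cutoffs),
          mibg_error = function(e) {
            stop_mibg("mibg_stage",
                      "H/M computation failed [subject=%s rater=%s method=%s]: %s",
                      s, r, m, conditionMessage(e))
          }
        )
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  report_from_results(do.call(rbind, rows), config)
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  methods <- unique(x$results$method)
  phases <- unique(unlist(lapply(x$panel, `[[`, "phase")))
  cat("Inter- and intra-rater indices on simulated MIBG parameters\n")
  cat(sprintf("subjects: %d, raters: %s\n\n",
              length(unique(x$results$subject)),
              paste(unique(x$results$rater), collapse = ", ")))
  for (ph in phases) {
    cat(sprintf("== %s H/M ratio ==\n", ph))
    for (m in methods) {
      p <- x$panel[[paste(m, ph, sep = ".")]]
      cat(sprintf("-- %s method --\n", m))
      s <- x$summary[x$summary$method == m, ]
      for (i in seq_len(nrow(s))) {
        cat(sprintf("  %-10s %s +/- %s   pathological %d/%d\n",
                    s$rater[i], fmt(s[[paste0(ph, "_mean")]][i]),
                    fmt(s[[paste0(ph, "_sd")]][i]),
                    s[[paste0(ph, "_pathological")]][i], p$n))
      }
      cat(sprintf("  ICC (95%% CI): %s (%s-%s) [%s]\n",
                  fmt(p$icc$estimate), fmt(p$icc$ci_low),
                  fmt(p$icc$ci_high), p$icc$label))
      if (isTRUE(p$fleiss$degenerate)) {
        cat("  Fleiss kappa: degenerate (single category)\n")
      } else {
        cat(sprintf("  Fleiss kappa (95%% CI): %s (%s-%s) [%s]\n",
                    fmt(p$fleiss$estimate), fmt(p$fleiss$ci_low),
                    fmt(p$fleiss$ci_high), p$fleiss$label))
      }
      for (ck in p$cohen) {
        cat(sprintf("  Cohen kappa %s: %s [%s]\n", ck$raters,
                    if (isTRUE(ck$degenerate)) "degenerate" else
                      fmt(ck$estimate),
                    if (isTRUE(ck$degenerate)) "-" else ck$label))
      }
      for (cs in p$chi_square) {
        cat(sprintf("  chi-square %s: %s (p = %s)\n", cs$raters,
                    fmt(cs$statistic), format.pval(cs$p, digits = 3)))
      }
    }
  }
  if (length(x$spearman)) {
    cat("\n== intra-rater agreement (between methods) ==\n")
    for (sp in x$spearman) {
      cat(sprintf("  %s, %s: rho = %s (p = %s)\n", sp$rater, sp$phase,
                  fmt(sp$rho), format.pval(sp$p, digits = 3)))
    }
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the per-subject results as CSV, the full panel as JSON, and the
#' human-readable table as plain text.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(panel = report$panel, spearman = report$spearman),
    file.path(dir, "panel.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Read a study configuration from JSON or YAML
#'
#' Recognised top-level keys mirror the [study_config()] arguments; phantom
#' and profile entries are passed to [phantom_params()] and
#' [rater_profile()].
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_mibg("mibg_format", "the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  for (k in c("n_subjects", "seed", "fleiss_B", "methods")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$cutoffs)) args$cutoffs <- unlist(raw$cutoffs)
  if (!is.null(raw$phantom)) {
    args$phantom <- do.call(phantom_params, raw$phantom)
  }
  if (!is.null(raw$hm_spec)) args$hm_spec <- raw$hm_spec
  if (!is.null(raw$washout_spec)) args$washout_spec <- raw$washout_spec
  if (!is.null(raw$profiles)) {
    args$profiles <- lapply(names(raw$profiles), function(nm) {
      do.call(rater_profile, c(list(label = nm), raw$profiles[[nm]]))
    })
    names(args$profiles) <- names(raw$profiles)
  }
  do.call(study_config, args)
}
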