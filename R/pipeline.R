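#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: gravity, optional
#' pelvis pre-smoothing, flight threshold, load binning, significance
#' level, and the full set of REBA thresholds.
#'
#' @param gravity Gravitational acceleration (m/s^2).
#' @param smooth,cutoff_hz Pelvis pre-smoothing (off by default; see
#'   [second_derivative()]).
#' @param flight_threshold_bw Loads below this count as flight.
#' @param bin_width,max_bw Load histogram graduation (BW).
#' @param alpha Significance level of the comparison battery.
#' @param reba A [reba_config()].
#' @return A `session_config` list.
#' @export
session_config <- function(gravity = 9.81, smooth = FALSE, cutoff_hz = 12,
                           flight_threshold_bw = 0.25, bin_width = 0.5,
                           max_bw = 5, alpha = 0.05, reba = reba_config()) {
  structure(
    list(gravity = gravity, smooth = smooth, cutoff_hz = cutoff_hz,
         flight_threshold_bw = flight_threshold_bw, bin_width = bin_width,
         max_bw = max_bw, alpha = alpha, reba = reba),
    class = "session_config")
}

subject_weighted_mean <- function(values, weights) {
  sum(values * weights) / sum(weights)
}

#' Run the end-to-end session analysis
#'
#' Scores every recording (vertical load from the pelvis trajectory, then
#' frame-wise REBA with the load feeding the force score), aggregates
#' duration-normalised histograms per sequence, per phase and for the whole
#' session, derives risk-band summaries, and runs the nonparametric
#' comparison battery on per-subject duration-weighted summary scores:
#' gender overall, gender per phase, gender per sequence, gender per REBA
#' score (the 12-score detailed family, Holm-corrected), and pairwise phase
#' comparisons for both REBA and load.
#'
#' @param recordings List of [motion_recording()]s; every sequence label
#'   must map to a plan row applicable to the recording's gender, and all
#'   sample rates must agree.
#' @param plan A [training_plan()].
#' @param config A [session_config()].
#' @return A `session_result` with elements `per_recording` (data.frame of
#'   per-recording summaries), `sequence_histograms`, `phase_histograms`,
#'   `session_histogram` (+ `_load` analogues), `risk_bands`, `subjects`
#'   (per-subject summary table), and `comparisons`.
#' @export
run_session <- function(recordings, plan, config = session_config()) {
  if (!length(recordings)) stop("no recordings supplied", call. = FALSE)
  rates <- vapply(recordings, `[[`, 0, "sample_rate_hz")
  if (length(unique(rates)) != 1L) {
    stop("mixed sample rates across recordings: ",
         paste(unique(rates), collapse = ", "), call. = FALSE)
  }
  for (rec in recordings) {
    ok <- plan_for_gender(plan, rec$gender)
    if (!rec$sequence_label %in% ok$label) {
      stop("sequence label '", rec$sequence_label,
           "' does not map to a plan row for gender '", rec$gender, "'",
           call. = FALSE)
    }
  }

  scored <- lapply(recordings, function(rec) {
    load <- pelvis_load(rec, smooth = config$smooth,
                        cutoff_hz = config$cutoff_hz,
                        gravity = config$gravity)
    reba <- compute_reba_series(rec, load = load, config = config$reba)
    list(rec = rec, load = load, reba = reba,
         hist = reba_histogram(reba),
         load_hist = load_histogram(load, config$bin_width, config$max_bw))
  })

  per_recording <- do.call(rbind, lapply(scored, function(s) {
    data.frame(subject_id = s$rec$subject_id, gender = s$rec$gender,
               sequence_label = s$rec$sequence_label, phase = s$rec$phase,
               n_frames = s$rec$n_frames,
               mean_reba = s$hist$mean_reba,
               mean_load_bw = s$load_hist$mean_load_bw,
               flight_fraction = flight_fraction(
                 s$load, config$flight_threshold_bw))
  }))

  merge_by <- function(key, what = c("hist", "load_hist")) {
    what <- match.arg(what)
    keys <- unique(key)
    out <- lapply(keys, function(k) {
      hs <- lapply(scored[key == k], `[[`, what)
      if (what == "hist") merge_reba_histograms(hs, source = as.character(k))
      else merge_load_histograms(hs)
    })
    names(out) <- keys
    out
  }
  seq_key <- per_recording$sequence_label
  phase_key <- per_recording$phase
  sequence_histograms <- merge_by(seq_key, "hist")
  phase_histograms <- merge_by(phase_key, "hist")
  sequence_load <- merge_by(seq_key, "load_hist")
  phase_load <- merge_by(phase_key, "load_hist")
  session_histogram <- merge_reba_histograms(lapply(scored, `[[`, "hist"),
                                             source = "session")
  session_load <- merge_load_histograms(lapply(scored, `[[`, "load_hist"))

  bands <- c(lapply(phase_histograms, risk_bands),
             list(session = risk_bands(session_histogram)))

  ## per-subject duration-weighted summaries (unit of analysis for tests)
  subjects <- stats::aggregate(
    cbind(n_frames) ~ subject_id + gender, per_recording, sum)
  subjects$mean_reba <- vapply(subjects$subject_id, function(id) {
    d <- per_recording[per_recording$subject_id == id, ]
    subject_weighted_mean(d$mean_reba, d$n_frames)
  }, 0)
  subjects$mean_load_bw <- vapply(subjects$subject_id, function(id) {
    d <- per_recording[per_recording$subject_id == id, ]
    subject_weighted_mean(d$mean_load_bw, d$n_frames)
  }, 0)

  comparisons <- build_comparisons(per_recording, subjects, scored, config)

  structure(
    list(per_recording = per_recording,
         sequence_histograms = sequence_histograms,
         phase_histograms = phase_histograms,
         session_histogram = session_histogram,
         sequence_load = sequence_load, phase_load = phase_load,
         session_load = session_load,
         risk_bands = bands, subjects = subjects,
         comparisons = comparisons,
         config = config,
         total_frames = sum(per_recording$n_frames)),
    class = "session_result")
}

merge_load_histograms <- function(hs) {
  w <- vapply(hs, `[[`, 0, "total_frames")
  rel <- Reduce(`+`, Map(function(h, wi) h$rel_freq * wi, hs, w)) / sum(w)
  structure(
    list(bin_centers_bw = hs[[1]]$bin_centers_bw, rel_freq = rel,
         mean_load_bw = sum(hs[[1]]$bin_centers_bw * rel),
         total_frames = sum(w)),
    class = "load_histogram")
}

## Per-subject summary of one quantity within a subset of recordings.
subject_summary <- function(per_recording, keep, col) {
  d <- per_recording[keep, ]
  ids <- unique(d$subject_id)
  out <- data.frame(
    subject_id = ids,
    gender = d$gender[match(ids, d$subject_id)],
    value = vapply(ids, function(id) {
      di <- d[d$subject_id == id, ]
      subject_weighted_mean(di[[col]], di$n_frames)
    }, 0))
  out
}

safe_mwu <- function(a, b, alpha, adjusted_alpha = alpha) {
  if (length(a) < 2L || length(b) < 2L) return(NULL)
  tryCatch(mwu_test(a, b, alpha = alpha, adjusted_alpha = adjusted_alpha),
           error = function(e) NULL)
}

build_comparisons <- function(per_recording, subjects, scored, config) {
  alpha <- config$alpha
  both <- length(unique(subjects$gender)) == 2L
  g_split <- function(df) {
    list(male = df$value[df$gender == "male"],
         female = df$value[df$gender == "female"])
  }
  out <- list()
  if (both) {
    s <- g_split(data.frame(gender = subjects$gender,
                            value = subjects$mean_reba))
    out$gender_overall <- safe_mwu(s$male, s$female, alpha)
    s <- g_split(data.frame(gender = subjects$gender,
                            value = subjects$mean_load_bw))
    out$gender_overall_load <- safe_mwu(s$male, s$female, alpha)
    out$gender_per_phase <- lapply(sort(unique(per_recording$phase)),
                                   function(ph) {
      s <- g_split(subject_summary(per_recording,
                                   per_recording$phase == ph, "mean_reba"))
      safe_mwu(s$male, s$female, alpha)
    })
    names(out$gender_per_phase) <- paste0("phase", sort(unique(per_recording$phase)))
    shared <- names(which(table(unique(per_recording[c("sequence_label", "gender")])$sequence_label) == 2L))
    out$gender_per_sequence <- lapply(shared, function(lab) {
      s <- g_split(subject_summary(per_recording,
                                   per_recording$sequence_label == lab,
                                   "mean_reba"))
      safe_mwu(s$male, s$female, alpha)
    })
    names(out$gender_per_sequence) <- shared
    ## detailed 12-score family: per-subject relative time at each score
    score_freq <- function(sc, gender) {
      keep <- vapply(scored, function(s) s$rec$gender == gender, TRUE)
      vapply(unique(vapply(scored[keep], function(s) s$rec$subject_id, "")),
             function(id) {
               sel <- scored[keep][vapply(scored[keep], function(s)
                 s$rec$subject_id == id, TRUE)]
               fr <- vapply(sel, function(s) s$rec$n_frames, 0)
               f <- vapply(sel, function(s) s$hist$rel_freq[as.character(sc)], 0)
               sum(f * fr) / sum(fr)
             }, 0)
    }
    fam <- lapply(1:12, function(sc) {
      safe_mwu(score_freq(sc, "male"), score_freq(sc, "female"), alpha)
    })
    names(fam) <- paste0("score", 1:12)
    ps <- vapply(fam, function(x) if (is.null(x)) NA_real_ else x$p_value, 0)
    if (any(!is.na(ps))) {
      bh <- bonferroni_holm(ps[!is.na(ps)], alpha = alpha)
      k <- 1L
      for (i in which(!is.na(ps))) {
        fam[[i]]$adjusted_alpha <- bh$threshold[k]
        fam[[i]]$significant <- bh$reject[k]
        k <- k + 1L
      }
    }
    out$gender_per_score <- fam
  }
  phases <- sort(unique(per_recording$phase))
  if (length(phases) == 3L) {
    by_phase <- function(col) {
      lapply(phases, function(ph) {
        subject_summary(per_recording, per_recording$phase == ph, col)$value
      })
    }
    gr <- by_phase("mean_reba")
    names(gr) <- paste0("phase", phases)
    gl <- by_phase("mean_load_bw")
    names(gl) <- paste0("phase", phases)
    if (all(lengths(gr) >= 2L)) {
      out$phase_kw_reba <- kruskal_wallis(gr, alpha = alpha)
      out$phase_pairwise_reba <- pairwise_phase_comparison(gr, alpha = alpha)
      out$phase_kw_load <- kruskal_wallis(gl, alpha = alpha)
      out$phase_pairwise_load <- pairwise_phase_comparison(gl, alpha = alpha)
    }
  }
  if (nrow(subjects) >= 5L) {
    out$normality_gate <- ks_normality_gate(subjects$mean_reba, alpha)
  }
  out
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result> ", nrow(x$per_recording), " recordings, ",
      nrow(x$subjects), " subject(s), ", x$total_frames, " frames\n", sep = "")
  cat(sprintf("  session mean REBA %.2f, mean load %.2f BW\n",
              x$session_histogram$mean_reba, x$session_load$mean_load_bw))
  cat("  risk bands (session):\n")
  print(round(unclass(x$risk_bands$session), 3))
  invisible(x)
}

#' @export
summary.session_result <- function(object, ...) {
  print(object)
  if (!is.null(object$comparisons$gender_overall)) {
    cat("\nGender comparison (overall mean REBA):\n")
    print(object$comparisons$gender_overall)
  }
  if (!is.null(object$comparisons$phase_kw_reba)) {
    cat("\nPhases (mean REBA):\n")
    print(object$comparisons$phase_kw_reba)
    print(object$comparisons$phase_pairwise_reba, digits = 3)
  }
  invisible(object)
}

## ---- reporting ------------------------------------------------------------

comparison_row <- function(name, x) {
  if (is.null(x)) {
    return(data.frame(comparison = name, statistic = NA_real_,
                      p_value = NA_real_, adjusted_alpha = NA_real_,
                      significant = NA, cliffs_delta = NA_real_,
                      effect_band = NA_character_))
  }
  data.frame(comparison = name,
             statistic = if (x$method == "mwu") x$statistic_z else x$statistic_h,
             p_value = x$p_value, adjusted_alpha = x$adjusted_alpha,
             significant = x$significant, cliffs_delta = x$cliffs_delta,
             effect_band = x$effect_band)
}

comparisons_table <- function(cmp) {
  rows <- list()
  push <- function(name, x) rows[[length(rows) + 1L]] <<- comparison_row(name, x)
  if (!is.null(cmp$gender_overall)) push("gender_overall_reba", cmp$gender_overall)
  if (!is.null(cmp$gender_overall_load)) push("gender_overall_load", cmp$gender_overall_load)
  for (nm in names(cmp$gender_per_phase)) {
    push(paste0("gender_", nm), cmp$gender_per_phase[[nm]])
  }
  for (nm in names(cmp$gender_per_sequence)) {
    push(paste0("gender_seq_", nm), cmp$gender_per_sequence[[nm]])
  }
  for (nm in names(cmp$gender_per_score)) {
    push(paste0("gender_", nm), cmp$gender_per_score[[nm]])
  }
  if (!is.null(cmp$phase_kw_reba)) push("phase_kw_reba", cmp$phase_kw_reba)
  if (!is.null(cmp$phase_kw_load)) push("phase_kw_load", cmp$phase_kw_load)
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

md_table <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "g") else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Write session reports to disk
#'
#' Emits CSV tables (histograms, risk bands, comparison battery), a
#' Markdown summary with the risk-band colour key, and (optionally) PNG
#' histogram figures. Output is deterministic: re-rendering the same
#' result writes byte-identical text files.
#'
#' @param result A [run_session()] result.
#' @param outdir Output directory (created if needed).
#' @param plots Also write PNG figures (requires a PNG-capable device).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(result, outdir, plots = FALSE) {
  stopifnot(inherits(result, "session_result"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop("cannot create output directory '", outdir, "'", call. = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  hist_df <- function(hs) {
    do.call(rbind, lapply(names(hs), function(k) {
      data.frame(source = k, score = REBA_SCORE_RANGE,
                 rel_freq = unname(hs[[k]]$rel_freq))
    }))
  }
  emit(hist_df(result$sequence_histograms), "sequence_histograms.csv")
  emit(hist_df(result$phase_histograms), "phase_histograms.csv")
  emit(data.frame(source = "session", score = REBA_SCORE_RANGE,
                  rel_freq = unname(result$session_histogram$rel_freq)),
       "session_histogram.csv")
  emit(do.call(rbind, lapply(names(result$phase_load), function(k) {
    h <- result$phase_load[[k]]
    data.frame(source = k, bin_center_bw = h$bin_centers_bw,
               rel_freq = unname(h$rel_freq))
  })), "phase_load_histograms.csv")
  emit(do.call(rbind, lapply(names(result$risk_bands), function(k) {
    b <- result$risk_bands[[k]]
    data.frame(source = k, band = names(b), rel_freq = unname(unclass(b)))
  })), "risk_bands.csv")
  emit(result$per_recording, "per_recording.csv")
  emit(result$subjects, "subjects.csv")
  cmp <- comparisons_table(result$comparisons)
  if (!is.null(cmp)) emit(cmp, "comparisons.csv")

  md <- c("# Session report", "",
          sprintf("Recordings: %d; subjects: %d; frames: %d",
                  nrow(result$per_recording), nrow(result$subjects),
                  result$total_frames),
          sprintf("Session mean REBA: %.3f; mean load: %.3f BW",
                  result$session_histogram$mean_reba,
                  result$session_load$mean_load_bw),
          "",
          "Risk-band colour key: 1 green (negligible) | 2-3 yellow (low) | 4-7 orange (medium) | 8-10 apricot (high) | >= 11 red (very high)",
          "", "## Risk bands", "",
          md_table(do.call(rbind, lapply(names(result$risk_bands), function(k) {
            b <- result$risk_bands[[k]]
            cbind(data.frame(source = k), as.data.frame(as.list(unclass(b))))
          }))),
          "", "## Comparisons", "")
  md <- c(md, if (is.null(cmp)) "no comparisons" else md_table(cmp))
  md_path <- file.path(outdir, "report.md")
  writeLines(md, md_path)
  files <- c(files, md_path)

  if (plots && capabilities("png")) {
    png_path <- file.path(outdir, "session_histogram.png")
    grDevices::png(png_path, width = 900, height = 500)
    plot(result$session_histogram, main = "Session REBA distribution")
    grDevices::dev.off()
    files <- c(files, png_path)
  }
  invisible(files)
}
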