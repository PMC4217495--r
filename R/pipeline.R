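#' Run the full analysis pipeline on simulated cells
#'
#' End-to-end orchestration: for each cell a movie is simulated under a seed
#' derived from `config$seed`, photobleaching is corrected on the raw movie,
#' a background-subtracted copy is used for event detection, spot traces are
#' extracted from the bleach-corrected movie (which retains the background
#' level the dwell threshold is defined against), events are classified, the
#' observed consecutive-event fraction is computed per cell, and the
#' random-placement null model is evaluated on the cell mask at the observed
#' event count. Per-cell tables and an aggregate summary are returned and,
#' optionally, written as CSV/JSON.
#'
#' @param config a [sim_config()]; cell `i` runs under a seed derived from
#'   `config$seed` and `i`.
#' @param kinetics a [vesicle_kinetics()].
#' @param n_cells number of cells (movies) to simulate and analyse.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param detect_args list of overrides passed to [detect_events()].
#' @param null_replicates Monte Carlo replicates for the per-run null model
#'   (0 skips it).
#' @return object of class `tirfex_report`: list with `cells` (per-cell
#'   data.frame), `classifications` (all events), `summary` (pooled
#'   statistics), `null_model`, `manifest`.
#' @export
run_pipeline <- function(config, kinetics = vesicle_kinetics(), n_cells = 10,
                         out_dir = NULL, detect_args = list(),
                         null_replicates = 0) {
  t_start <- Sys.time()
  cell_rows <- list(); cls_rows <- list(); masks <- list()
  for (i in seq_len(n_cells)) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, 1000 + i)
    res <- analyze_simulated_cell(cfg, kinetics, detect_args)
    res$cell$cell_id <- i
    if (nrow(res$classifications) > 0) res$classifications$cell_id <- i
    cell_rows[[i]] <- res$cell
    cls_rows[[i]] <- res$classifications
    masks[[i]] <- res$mask
  }
  cells <- do.call(rbind, cell_rows)
  cls <- do.call(rbind, cls_rows)

  n_pers <- sum(cells$n_persistent)
  n_tot <- sum(cells$n_classified)
  summary <- list(
    n_cells = n_cells,
    total_events_detected = sum(cells$n_detected),
    total_events_classified = n_tot,
    pooled_persistent_fraction = if (n_tot > 0) n_pers / n_tot else NA_real_,
    mean_events_per_cell = mean(cells$n_detected),
    pooled_consecutive_fraction =
      if (n_pers > 0) sum(cells$n_consecutive) / n_pers else NA_real_,
    mean_bleach_fraction_est = mean(cells$bleach_est)
  )

  null_model <- NULL
  if (null_replicates > 0) {
    ncfg <- null_model_config(N = max(2, round(summary$mean_events_per_cell)),
                              persistent_fraction = 0.10,
                              replicates = null_replicates,
                              seed = child_seed(config$seed, 77))
    null_model <- estimate_probability(masks[[1]], ncfg)
  }

  manifest <- list(config = unclass(config), kinetics = unclass(kinetics),
                   n_cells = n_cells,
                   cell_seeds = vapply(seq_len(n_cells), function(i)
                     child_seed(config$seed, 1000 + i), numeric(1)),
                   detect_args = detect_args,
                   package_version = as.character(utils::packageVersion("tirfex")),
                   elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs")))
  report <- structure(list(cells = cells, classifications = cls,
                           summary = summary, null_model = null_model,
                           manifest = manifest),
                      class = "tirfex_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    utils::write.csv(cls, file.path(out_dir, "classifications.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summary, manifest = manifest),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Simulate and analyse one cell; shared by run_pipeline and the CLI.
analyze_simulated_cell <- function(config, kinetics, detect_args = list()) {
  sim <- simulate_movie(config, kinetics)
  bc <- correct_bleaching(sim$movie)
  sub <- subtract_background(bc$movie, clip = FALSE)
  det <- do.call(detect_events, c(list(movie = sub), detect_args))

  cls_list <- list()
  for (j in seq_len(nrow(det))) {
    # classification reads the event's own spot: a 1 um^2 ROI spans >2x the
    # PSF, and pixels owned by other detections are excluded so that a
    # neighbouring event cannot masquerade as this one
    others <- det[-j, c("x_px", "y_px"), drop = FALSE]
    dd <- pmax(abs(others$x_px - det$x_px[j]), abs(others$y_px - det$y_px[j]))
    others <- as.matrix(others[dd > 2 & dd <= 12, , drop = FALSE])
    tr <- tryCatch(extract_trace(bc$movie, det[j, ], roi_small_um2 = 1,
                                 exclude_px = others),
                   error = function(e) NULL)
    if (is.null(tr)) next
    cls_list[[length(cls_list) + 1L]] <-
      c(classify_event(tr), list(x_px = det$x_px[j], y_px = det$y_px[j],
                                 t_on_s = det$t_on_s[j]))
  }
  cls_tab <- if (length(cls_list)) {
    tab <- classification_table(lapply(cls_list, function(x) {
      class(x) <- "event_classification"; x
    }))
    tab$x_px <- vapply(cls_list, `[[`, numeric(1), "x_px")
    tab$y_px <- vapply(cls_list, `[[`, numeric(1), "y_px")
    tab$t_on_s <- vapply(cls_list, `[[`, numeric(1), "t_on_s")
    tab
  } else {
    data.frame(event_id = integer(), label = character(), dwell_s = numeric(),
               censored = logical(), half_life_s = numeric(),
               k_per_s = numeric(), t0_s = numeric(), converged = logical(),
               x_px = numeric(), y_px = numeric(), t_on_s = numeric())
  }

  classified <- cls_tab[cls_tab$label != "unclassified", , drop = FALSE]
  n_pers <- sum(classified$label %in% c("persistent", "biphasic_persistent"))
  consec <- if (n_pers > 0) {
    suppressWarnings(observed_consecutive_fraction(
      classified, pixel_pitch_um = config$pixel_pitch_um))
  } else list(fraction = NA_real_, n_paired = 0L)

  cell <- data.frame(
    n_true = nrow(sim$events), n_detected = nrow(det),
    n_classified = nrow(classified), n_persistent = n_pers,
    persistent_fraction = if (nrow(classified) > 0) n_pers / nrow(classified)
                          else NA_real_,
    n_consecutive = consec$n_paired,
    consecutive_fraction = consec$fraction,
    bleach_est = unname(bc$bleach_fraction_est["SEP"]))
  list(cell = cell, classifications = cls_tab, mask = sim$mask,
       events_true = sim$events)
}

#' @export
print.tirfex_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("tirfex pipeline report: %d cells\n", s$n_cells))
  cat(sprintf("  events detected: %d (%.1f per cell)\n",
              s$total_events_detected, s$mean_events_per_cell))
  cat(sprintf("  pooled persistent fraction: %.3f\n",
              s$pooled_persistent_fraction))
  cat(sprintf("  pooled consecutive fraction: %.3f\n",
              s$pooled_consecutive_fraction))
  if (!is.null(x$null_model))
    cat(sprintf("  null-model p(consecutive): %.4f (MC SE %.4f)\n",
                x$null_model$p_hat, x$null_model$mc_se))
  invisible(x)
}

#' Unpaired two-sample comparison with normality check
#'
#' Classical pooled-variance Student's t-test (two-tailed), computed from
#' its textbook formulas, preceded by a D'Agostino-Pearson omnibus normality
#' check on each group when it has at least 8 values. A Welch-corrected
#' variant is available via `welch = TRUE`.
#'
#' @param values_a,values_b numeric vectors (n >= 2 each).
#' @param welch use the Welch (unequal-variance) correction.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `group_comparison`: group sizes, means, SDs,
#'   `t`, `df`, `p` (two-tailed), `significant`, `normality_p` (per group,
#'   NA when n < 8), `degenerate` flag for zero pooled variance.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE, alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)

  norm_p <- c(a = NA_real_, b = NA_real_)
  for (g in c("a", "b")) {
    x <- if (g == "a") a else b
    if (length(x) >= 8) norm_p[g] <- dagostino_pearson_test(x)$p.value
    else warning("group ", g, " has n < 8; normality test skipped")
  }

  degenerate <- FALSE
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      degenerate <- TRUE
      t_stat <- 0; df <- n1 + n2 - 2
      p <- if (m1 == m2) 1 else 0
    } else {
      t_stat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      p <- 2 * stats::pt(-abs(t_stat), df)
    }
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
      degenerate <- TRUE
      if (m1 == m2) { t_stat <- 0; p <- 1 } else { t_stat <- Inf * sign(m1 - m2); p <- 0 }
      if (p == 0) warning("zero pooled variance with unequal means; degenerate comparison")
    } else {
      t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * stats::pt(-abs(t_stat), df)
    }
  }

  structure(list(n = c(n1, n2), means = c(m1, m2),
                 sds = c(sqrt(v1), sqrt(v2)),
                 t = t_stat, df = df, p = p,
                 significant = is.finite(p) && p < alpha,
                 normality_p = norm_p, welch = welch,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s two-sample t-test: t = %.4f, df = %.2f, p = %.4g%s\n",
              if (x$welch) "Welch" else "Student (pooled-variance)",
              x$t, x$df, x$p, if (x$significant) " *" else ""))
  cat(sprintf("  group means %.4g vs %.4g (n = %d, %d)\n",
              x$means[1], x$means[2], x$n[1], x$n[2]))
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K^2 omnibus statistic combining the transformed sample skewness
#' (D'Agostino's Z1) and kurtosis (Anscombe-Glynn's Z2):
#' `K^2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. Computed from the moment formulas; requires n >= 8.
#'
#' @param x numeric vector (n >= 8).
#' @return list with `statistic` (K^2), `p.value`, `z_skewness`,
#'   `z_kurtosis`, `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance")
  b1 <- m3 / m2^1.5          # sample skewness g1
  b2 <- m4 / m2^2            # sample kurtosis b2

  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
         ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n)
}
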