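## ensemble_stats: presentation statistics over per-frame observations --
## 2-D histograms (|kappa| or |J| versus R), H-/J-like classification, and
## multi-trial summaries.

# pool one or several observation data.frames into one
pool_observations <- function(observations) {
  if (is.data.frame(observations)) return(observations)
  stopifnot(is.list(observations), length(observations) >= 1L)
  do.call(rbind, observations)
}

#' 2-D orientation/coupling histogram
#'
#' Bins pooled observations on (R, |kappa|) or (R, |J|); counts are
#' normalized by the total number of in-range observations so the bin
#' masses sum to 1.  Observations from multiple trials are pooled before
#' normalization, so pooling is order-independent.
#'
#' Default bins resolve the peak scales seen for closely spaced dimers
#' (a few tenths of a nm, tens to ~150 meV): R in [0, 5] nm at 0.05 nm,
#' |kappa| in [0, 2] at 0.05, |J| in [0, 200] meV at 2.5 meV.
#'
#' @param observations a data.frame from [observe_dimer()] or a list of
#'   them (trials to pool).
#' @param y which quantity to bin against R: `"abs_kappa"` or `"abs_J"`.
#' @param r_breaks,y_breaks bin edge vectors (strictly increasing).
#' @return An object of class `dimer_histogram`: list with `r_breaks`,
#'   `y_breaks`, normalized count matrix `density` (rows = R bins),
#'   `n_in_range`, `n_total`, `y`.
#' @export
dimer_heatmap <- function(observations, y = c("abs_kappa", "abs_J"),
                          r_breaks = seq(0, 5, by = 0.05),
                          y_breaks = NULL) {
  y <- match.arg(y)
  obs <- pool_observations(observations)
  if (nrow(obs) == 0L) stop("analysis error: no observations to bin")
  if (!y %in% names(obs))
    stop("analysis error: observations lack column ", y)
  if (is.null(y_breaks))
    y_breaks <- if (y == "abs_kappa") seq(0, 2, by = 0.05) else
      seq(0, 200, by = 2.5)
  stopifnot(all(diff(r_breaks) > 0), all(diff(y_breaks) > 0))
  xi <- findInterval(obs$R_nm, r_breaks, rightmost.closed = TRUE)
  yi <- findInterval(obs[[y]], y_breaks, rightmost.closed = TRUE)
  nx <- length(r_breaks) - 1L; ny <- length(y_breaks) - 1L
  ok <- xi >= 1L & xi <= nx & yi >= 1L & yi <= ny
  counts <- matrix(0, nx, ny)
  if (any(ok)) {
    tab <- table(factor(xi[ok], levels = seq_len(nx)),
                 factor(yi[ok], levels = seq_len(ny)))
    counts <- matrix(as.numeric(tab), nx, ny) / sum(ok)
  }
  out <- list(r_breaks = r_breaks, y_breaks = y_breaks, density = counts,
              n_in_range = sum(ok), n_total = nrow(obs), y = y)
  class(out) <- "dimer_histogram"
  out
}

#' Write a 2-D histogram as TSV
#'
#' Long format: `R_lo R_hi y_lo y_hi density`, with a commented header
#' carrying the axis name and totals.
#'
#' @param h a `dimer_histogram`.
#' @param path output path.
#' @param meta optional named character vector of extra header lines.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(h, path, meta = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# y: %s", h$y),
               sprintf("# n_in_range: %d", h$n_in_range),
               sprintf("# n_total: %d", h$n_total),
               if (!is.null(meta)) sprintf("# %s: %s", names(meta), meta),
               "R_lo\tR_hi\ty_lo\ty_hi\tdensity"), con)
  nx <- length(h$r_breaks) - 1L; ny <- length(h$y_breaks) - 1L
  for (i in seq_len(nx))
    for (j in seq_len(ny))
      if (h$density[i, j] > 0)
        writeLines(sprintf("%.6g\t%.6g\t%.6g\t%.6g\t%.8g",
                           h$r_breaks[i], h$r_breaks[i + 1L],
                           h$y_breaks[j], h$y_breaks[j + 1L],
                           h$density[i, j]), con)
  invisible(path)
}

#' Classify a dimer geometry from |kappa| and R
#'
#' H-like when `|kappa| <= kappa_boundary` (stacked), J-like otherwise
#' (end-to-end); the boundary value itself classifies as H-like.  The
#' `_dimer` suffix applies when `R <= dimer_r_max` (closely spaced),
#' `_separated` otherwise.
#'
#' @param kappa_abs |kappa| value(s).
#' @param R_nm centre distance(s), nm (> 0).
#' @param kappa_boundary stacked/end-to-end boundary (default 1).
#' @param dimer_r_max maximum centre distance still counted as a dimer,
#'   nm (default 1.5).
#' @return character vector of labels in `H_like_dimer`, `J_like_dimer`,
#'   `H_like_separated`, `J_like_separated`.
#' @export
classify_dimer <- function(kappa_abs, R_nm, kappa_boundary = 1.0,
                           dimer_r_max = 1.5) {
  stopifnot(all(is.finite(kappa_abs)), all(is.finite(R_nm)), all(R_nm > 0))
  hk <- ifelse(kappa_abs <= kappa_boundary, "H_like", "J_like")
  suf <- ifelse(R_nm <= dimer_r_max, "_dimer", "_separated")
  paste0(hk, suf)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize observations across trials
#'
#' Pools the per-frame observations of all trials and reports, per
#' quantity (R, |kappa|, and |J| when present), the pooled mean and the
#' pooled population standard deviation, the per-trial means, and the
#' (sample) standard deviation across trial means.  Both spreads are
#' reported because a "mean +- SD over trials" table can mean either.
#'
#' @param trials list of observation data.frames (one per trial), or a
#'   single data.frame.
#' @return An object of class `trial_summary`: list with `quantities`
#'   (each: `mean`, `sd_pooled`, `sd_across_trials`, `per_trial_mean`),
#'   `n_observations`, `n_trials`.
#' @export
summarize_trials <- function(trials) {
  if (is.data.frame(trials)) trials <- list(trials)
  stopifnot(length(trials) >= 1L)
  if (any(vapply(trials, nrow, 0L) == 0L))
    stop("analysis error: empty trial in summarize_trials")
  pooled <- do.call(rbind, trials)
  qn <- intersect(c("R_nm", "abs_kappa", "abs_J"), names(pooled))
  quantities <- lapply(qn, function(q) {
    ptm <- vapply(trials, function(tr) mean(tr[[q]]), 0)
    list(mean = mean(pooled[[q]]),
         sd_pooled = pop_sd(pooled[[q]]),
         sd_across_trials = if (length(trials) > 1L) sd(ptm) else 0,
         per_trial_mean = ptm)
  })
  names(quantities) <- qn
  out <- list(quantities = quantities, n_observations = nrow(pooled),
              n_trials = length(trials))
  class(out) <- "trial_summary"
  out
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("trial_summary over", x$n_trials, "trial(s),", x$n_observations,
      "observations\n")
  for (q in names(x$quantities)) {
    s <- x$quantities[[q]]
    cat(sprintf("  %-9s %.4f +- %.4f (pooled sd; across-trial sd %.4f)\n",
                q, s$mean, s$sd_pooled, s$sd_across_trials))
  }
  invisible(x)
}
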