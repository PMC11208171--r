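#' @title Quantitative analysis of growth and conversion experiments
#' @description Endpoint substrate:product ratios, enzyme-activity fold
#'   changes, exponential growth-rate fitting on OD600 series, specific
#'   conversion rates in resting-cell suspensions, and SNP
#'   population-frequency reporting.
#' @name timecourse_analysis
NULL

#' Construct a timecourse
#'
#' A (time, value) series in hours, holding either metabolite concentrations
#' (mM) or optical density (OD600), optionally annotated with the protein
#' concentration of the suspension (mg/mL) for specific-rate calculations.
#'
#' @param times hours; strictly increasing, finite, length >= 2.
#' @param values concentrations (mM, must be >= 0) or OD600 readings.
#' @param series series label.
#' @param unit `"mM"` or `"OD600"`.
#' @param protein_conc optional protein concentration (mg/mL).
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(times, values, series = "", unit = c("mM", "OD600"),
                       protein_conc = NULL) {
  unit <- match.arg(unit)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) < 2) stop("a timecourse needs at least 2 points")
  if (length(values) != length(times)) stop("times/values length mismatch")
  if (any(!is.finite(times))) stop("times must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (unit == "mM" && any(values < 0)) {
    stop("concentrations must be non-negative")
  }
  if (!is.null(protein_conc)) {
    protein_conc <- as.numeric(protein_conc)
    if (!is.finite(protein_conc) || protein_conc <= 0) {
      stop("protein_conc must be a positive number (mg/mL)")
    }
  }
  structure(list(times = times, values = values,
                 series = as.character(series), unit = unit,
                 protein_conc = protein_conc),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("Timecourse", if (nzchar(x$series)) paste0("'", x$series, "'"),
      "(", x$unit, "), ", length(x$times), " points, t = ",
      min(x$times), "..", max(x$times), " h\n", sep = "")
  if (!is.null(x$protein_conc)) {
    cat("  protein:", x$protein_conc, "mg/mL\n")
  }
  invisible(x)
}

#' @export
plot.timecourse <- function(x, ...) {
  graphics::plot(x$times, x$values, xlab = "time (h)", ylab = x$unit,
                 type = "b", main = x$series, ...)
  invisible(x)
}

#' Read / write timecourse CSV
#'
#' Dialect: optional `# key: value` metadata comment lines
#' (`# protein_mg_per_ml: 1.0`, `# unit: mM`, `# series: acetate`) followed
#' by a header `time_h,value`.
#'
#' @param path file path.
#' @return for `read_timecourse`, a `timecourse`.
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  if (!all(c("time_h", "value") %in% names(df))) {
    stop("timecourse CSV needs columns 'time_h' and 'value'")
  }
  timecourse(df$time_h, df$value,
             series = if (!is.null(meta$series)) meta$series
                      else if ("series" %in% names(df)) df$series[1] else "",
             unit = if (!is.null(meta$unit)) meta$unit else "mM",
             protein_conc = if (!is.null(meta$protein_mg_per_ml))
               as.numeric(meta$protein_mg_per_ml) else NULL)
}

#' @rdname read_timecourse
#' @param tc a `timecourse` to write.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", tc$unit), con)
  if (nzchar(tc$series)) writeLines(paste0("# series: ", tc$series), con)
  if (!is.null(tc$protein_conc)) {
    writeLines(paste0("# protein_mg_per_ml: ", tc$protein_conc), con)
  }
  utils::write.csv(data.frame(time_h = tc$times, value = tc$values),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Endpoint substrate:product ratio
#'
#' The ratio the conversion experiments report: how much product was formed
#' per substrate consumed (or the reverse orientation, e.g. CO:formate).
#'
#' @param consumed substrate consumed (mM), > 0.
#' @param produced product formed (mM), > 0.
#' @param decimals reporting precision (round half-up), default 1.
#' @param orientation `"produced_per_consumed"` (fructose:acetate = 1:2.6
#'   reads 2.6 acetate per fructose) or `"consumed_per_produced"`
#'   (CO:formate = 1.1:1 reads 1.1 CO per formate).
#' @return list with `raw` (exact quotient) and `reported` (rounded).
#' @examples
#' endpoint_ratio(22.9, 58.6)$reported                                  # 2.6
#' endpoint_ratio(35.3, 31.9, orientation = "consumed_per_produced")$reported
#' @export
endpoint_ratio <- function(consumed, produced, decimals = 1,
                           orientation = c("produced_per_consumed",
                                           "consumed_per_produced")) {
  orientation <- match.arg(orientation)
  if (!is.finite(consumed) || consumed <= 0) {
    stop("'consumed' must be a positive amount")
  }
  if (!is.finite(produced) || produced <= 0) {
    stop("'produced' must be a positive amount")
  }
  raw <- if (orientation == "produced_per_consumed") produced / consumed
         else consumed / produced
  list(raw = raw, reported = round_half_up(raw, decimals))
}

#' Fold change between two activities or rates
#'
#' @param a numerator (same units as `b`).
#' @param b reference, > 0.
#' @param decimals reporting precision below 10; fold changes >= 10 are
#'   reported to the nearest integer (the printed convention).
#' @return list with `raw` and `reported`.
#' @examples
#' fold_change(27.3, 4.1)$reported   # 6.7
#' fold_change(55.3, 2.2)$reported   # 25
#' @export
fold_change <- function(a, b, decimals = 1) {
  if (!is.finite(b) || b <= 0) stop("reference 'b' must be > 0")
  if (!is.finite(a)) stop("'a' must be finite")
  raw <- a / b
  reported <- if (abs(raw) >= 10) round_half_up(raw, 0)
              else round_half_up(raw, decimals)
  list(raw = raw, reported = reported)
}

#' Exponential growth rate from an OD timecourse
#'
#' Fits ln(OD) ~ time by least squares over contiguous windows of at least
#' `window_min_points` positive-OD points and reports the slope of the
#' selected window as the specific growth rate mu (1/h).
#'
#' Window selection: among windows spanning at least `min_span` on the
#' log-OD axis (one doubling by default, which excludes flat lag and
#' stationary stretches), the *longest* window whose residual variance is
#' consistent with the measurement noise is taken; ties go to the smaller
#' residual variance, then the earlier window. The noise scale is estimated
#' from the second differences of log-OD, which are curvature-free on
#' exponential, lag and stationary segments, so the criterion reduces to
#' "the longest stretch that is log-linear to within noise". On noiseless
#' data this selects exactly the maximal perfectly log-linear window and
#' recovers mu exactly. A series with no usable variation (e.g. constant
#' OD) yields mu = 0 with an undefined R-squared, flagged as degenerate.
#'
#' @param od a `timecourse` of OD600 readings.
#' @param window_min_points minimum window length (default 4, to avoid
#'   two-point artefacts).
#' @param min_span minimum |Delta log OD| a window must span (default
#'   `log(2)`, one doubling).
#' @param var_factor admissible ratio of a window's residual variance to
#'   the estimated noise variance (default 1.6).
#' @return An object of class `growth_fit`: `mu` (1/h), `r_squared`,
#'   `window` (index range), `window_times`, `degenerate`, and the input.
#' @examples
#' od <- simulate_growth(mu = 0.05, lag = 0, od0 = 0.02, od_max = Inf,
#'                       noise_cv = 0, seed = 1, times = 0:40)
#' growth_rate(od)$mu
#' @export
growth_rate <- function(od, window_min_points = 4, min_span = log(2),
                        var_factor = 1.6) {
  stopifnot(inherits(od, "timecourse"))
  if (window_min_points < 3) stop("window_min_points must be >= 3")
  pos <- od$values > 0
  if (sum(pos) < window_min_points) {
    stop("need at least ", window_min_points, " positive OD values")
  }
  t <- od$times; y <- log(od$values)
  n <- length(t)

  # noise variance of log-OD from second differences (var 6 sigma^2 where
  # the curve is locally straight; median for robustness to corners)
  d2 <- diff(y[pos], differences = 2)
  sigma2 <- if (length(d2)) stats::median(d2^2) / (6 * 0.4549) else 0

  cands <- list()
  for (i in seq_len(n)) {
    if (!pos[i] || i + window_min_points - 1 > n) next
    for (j in seq(i + window_min_points - 1, n)) {
      if (!all(pos[i:j])) break
      tt <- t[i:j]; yy <- y[i:j]
      fit <- stats::lm.fit(cbind(1, tt), yy)
      sst <- sum((yy - mean(yy))^2)
      sse <- sum(fit$residuals^2)
      cands[[length(cands) + 1L]] <- list(
        i = i, j = j, mu = unname(fit$coefficients[2]),
        s2 = sse / (j - i - 1),
        r2 = if (sst > 0) 1 - sse / sst else NA_real_,
        span = abs(unname(fit$coefficients[2])) * (t[j] - t[i]))
    }
  }
  if (!length(cands)) {
    stop("no contiguous run of ", window_min_points,
         " positive OD values to fit")
  }
  spans <- vapply(cands, `[[`, numeric(1), "span")
  eligible <- cands[spans >= min_span]
  if (!length(eligible)) eligible <- cands  # flat series: degenerate path
  thr <- max(var_factor * sigma2, 1e-18)
  s2 <- vapply(eligible, `[[`, numeric(1), "s2")
  within <- eligible[s2 <= thr]
  if (!length(within)) within <- eligible[which.min(s2)]
  lens <- vapply(within, function(w) w$j - w$i, numeric(1))
  s2w <- vapply(within, `[[`, numeric(1), "s2")
  starts <- vapply(within, `[[`, numeric(1), "i")
  best <- within[[order(-lens, s2w, starts)[1]]]

  degenerate <- is.na(best$r2) || best$span < min_span
  structure(list(mu = if (degenerate) 0 else best$mu,
                 r_squared = best$r2,
                 window = c(best$i, best$j),
                 window_times = c(t[best$i], t[best$j]),
                 degenerate = degenerate,
                 n_points = best$j - best$i + 1,
                 noise_sd = sqrt(sigma2),
                 timecourse = od),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate growth fit: no variation in OD; mu = 0, R^2 undefined\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Growth rate mu = %.4g 1/h (R^2 = %.4f, window %g..%g h, %d points)\n",
    x$mu, x$r_squared, x$window_times[1], x$window_times[2], x$n_points))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) c(mu = object$mu)

#' @export
plot.growth_fit <- function(x, ...) {
  od <- x$timecourse
  graphics::plot(od$times, od$values, log = "y", xlab = "time (h)",
                 ylab = "OD600", type = "b", ...)
  if (!x$degenerate) {
    idx <- x$window[1]:x$window[2]
    graphics::points(od$times[idx], od$values[idx], pch = 19)
  }
  invisible(x)
}

#' Specific conversion rate of a resting-cell suspension
#'
#' Concentration change across a time window, converted from mM/h to
#' nmol min^-1 (mg protein)^-1 on the suspension-volume basis (1 mM is
#' 1000 nmol/mL, divided by 60 min/h and by the protein concentration in
#' mg/mL).
#'
#' @param tc a `timecourse` with `protein_conc` set.
#' @param window `c(t_start, t_end)` in hours, within the series; defaults
#'   to the full series.
#' @return list: `rate` (nmol min^-1 mg^-1, magnitude of the change),
#'   `slope_mM_per_h` (signed), `window`.
#' @examples
#' tc <- timecourse(c(0, 1), c(60, 0), protein_conc = 1)
#' specific_rate(tc)$rate   # 1000
#' @export
specific_rate <- function(tc, window = range(tc$times)) {
  stopifnot(inherits(tc, "timecourse"))
  if (is.null(tc$protein_conc)) {
    stop("specific_rate() needs protein_conc (mg/mL) on the timecourse")
  }
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(t_start, t_end) with t_start < t_end")
  }
  inside <- tc$times >= window[1] & tc$times <= window[2]
  if (sum(inside) < 2) stop("window contains fewer than 2 points")
  idx <- range(which(inside))
  slope <- (tc$values[idx[2]] - tc$values[idx[1]]) /
    (tc$times[idx[2]] - tc$times[idx[1]])
  list(rate = abs(slope) * 1000 / 60 / tc$protein_conc,
       slope_mM_per_h = slope,
       window = tc$times[idx])
}

# --- SNP tables -------------------------------------------------------------

.canonical_tp <- c(freq_before = "before adaptation",
                   freq_adapted = "after adaptation",
                   freq_10th = "10th transfer")

#' Read a SNP frequency table
#'
#' Tab-separated dialect mirroring a resequencing variant table: columns
#' `position`, `mutation`, one `freq_*` column per sampled timepoint,
#' `aa_change`, `gene`, `annotation`. The canonical columns `freq_before`,
#' `freq_adapted` and `freq_10th` map to the timepoint labels "before
#' adaptation", "after adaptation" and "10th transfer"; any other `freq_x_y`
#' column becomes the label "x y". Blank frequency cells mean the variant
#' was not detected at that timepoint and are recorded as 0% with
#' `detected = FALSE` provenance.
#'
#' @param path TSV file.
#' @return An object of class `snp_table`: a data.frame with variant
#'   metadata, a `frequencies` matrix attribute (rows = variants, columns =
#'   timepoint labels, percent) and a parallel logical `detected` attribute.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = "character")
  need <- c("position", "mutation", "gene")
  if (!all(need %in% names(df))) {
    stop("SNP table needs columns: ", paste(need, collapse = ", "))
  }
  fcols <- grep("^freq_", names(df), value = TRUE)
  if (!length(fcols)) stop("SNP table has no freq_* columns")
  labels <- ifelse(fcols %in% names(.canonical_tp),
                   .canonical_tp[fcols],
                   gsub("_", " ", sub("^freq_", "", fcols)))
  nrow_ <- nrow(df)
  freq <- matrix(0, nrow_, length(fcols),
                 dimnames = list(NULL, labels))
  det <- matrix(FALSE, nrow_, length(fcols), dimnames = list(NULL, labels))
  for (k in seq_along(fcols)) {
    raw <- trimws(df[[fcols[k]]])
    raw <- sub("%$", "", raw)
    blank <- raw == "" | is.na(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & (is.na(val) | val < 0 | val > 100))
    if (length(bad)) {
      stop("malformed frequency '", df[[fcols[k]]][bad[1]], "' in column ",
           fcols[k], ", row ", bad[1])
    }
    freq[!blank, k] <- val[!blank]
    det[, k] <- !blank
  }
  pos <- suppressWarnings(as.numeric(df$position))
  badp <- which(is.na(pos) | pos <= 0)
  if (length(badp)) stop("malformed position in row ", badp[1])
  out <- data.frame(position = pos,
                    mutation = df$mutation,
                    aa_change = if ("aa_change" %in% names(df)) df$aa_change
                                else "",
                    gene = df$gene,
                    annotation = if ("annotation" %in% names(df))
                      df$annotation else "",
                    stringsAsFactors = FALSE)
  .snp_table(out, freq, det)
}

.snp_table <- function(df, freq, det) {
  rownames(df) <- NULL
  rownames(freq) <- NULL
  rownames(det) <- NULL
  structure(df, frequencies = freq, detected = det,
            class = c("snp_table", "data.frame"))
}

#' @export
snp_frequencies <- function(x) attr(x, "frequencies")

#' @export
snp_timepoints <- function(x) colnames(attr(x, "frequencies"))

#' Write a SNP table in the TSV dialect `read_snp_table()` reads
#' @param x a `snp_table`.
#' @param path output file.
#' @export
write_snp_table <- function(x, path) {
  freq <- snp_frequencies(x)
  det <- attr(x, "detected")
  labels <- colnames(freq)
  inv <- stats::setNames(names(.canonical_tp), .canonical_tp)
  cols <- ifelse(labels %in% names(inv), inv[labels],
                 paste0("freq_", gsub(" ", "_", labels)))
  out <- data.frame(position = x$position, mutation = x$mutation,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_along(cols)) {
    out[[cols[k]]] <- ifelse(det[, k], format(freq[, k], trim = TRUE), "")
  }
  out$aa_change <- x$aa_change
  out$gene <- x$gene
  out$annotation <- x$annotation
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter and rank SNP records by population frequency
#'
#' Keeps the variants whose population frequency at the given timepoint is
#' at least `min_frequency` percent, ordered by descending frequency and
#' then ascending genome position (a total, deterministic order). A variant
#' with no call at the timepoint counts as 0%.
#'
#' @param records a `snp_table`.
#' @param timepoint a timepoint label of the table (see
#'   [snp_timepoints()]).
#' @param min_frequency percent in \[0, 100\].
#' @return the filtered, sorted `snp_table`, with a `frequency` column
#'   (percent at the chosen timepoint) prepended to the metadata.
#' @export
snp_report <- function(records, timepoint, min_frequency = 0) {
  stopifnot(inherits(records, "snp_table"))
  freq <- snp_frequencies(records)
  if (nrow(records) == 0) {
    out <- records
    out$frequency <- numeric(0)
    return(out)
  }
  if (!timepoint %in% colnames(freq)) {
    stop("unknown timepoint '", timepoint, "'; table has: ",
         paste(colnames(freq), collapse = ", "))
  }
  f <- freq[, timepoint]
  keep <- which(f >= min_frequency)
  ord <- keep[order(-f[keep], records$position[keep])]
  out <- records[ord, , drop = FALSE]
  out$frequency <- f[ord]
  .snp_table(out, freq[ord, , drop = FALSE],
             attr(records, "detected")[ord, , drop = FALSE])
}

#' @export
`[.snp_table` <- function(x, ...) {
  # subsetting returns a plain data.frame (the frequency matrices no longer
  # line up once columns are dropped)
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.snp_table <- function(x, ...) {
  freq <- snp_frequencies(x)
  if (is.null(freq)) return(NextMethod())
  cat("SNP table: ", nrow(x), " variant(s), timepoints: ",
      paste(colnames(freq), collapse = ", "), "\n", sep = "")
  df <- as.data.frame(x)
  if (nrow(df)) print(utils::head(cbind(df, freq), 20))
  invisible(x)
}
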