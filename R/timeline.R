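#' Strip fluorophore tags from labeled-protein names
#'
#' `"EGFP-Emp46"` and `"Emp46-EGFP"` both refer to the protein Emp46;
#' markers measured with different tag variants (e.g. Sec7-iRFP, Sec7-tagRFP,
#' Sec7-mRFP) collapse to one label so that delays measured against any
#' variant share a node in the timeline graph.
#'
#' @param labels Character vector of labeled-protein names.
#' @return Character vector of protein names.
#' @export
strip_fluorophore_tags <- function(labels) {
  tag <- "(2x)?(y?EGFP|GFP|mCherry|tagRFP|mRFP|iRFP|mScarlet-I)"
  out <- sub(paste0("^", tag, "-"), "", labels)
  sub(paste0("-", tag, "$"), "", out)
}

#' Read a table of pairwise peak-to-peak delays
#'
#' Expects columns `early`, `late`, `mean_s`, `sd_s`, `n` (extra columns are
#' kept). The package ships a transcription of the measured peak-to-peak
#' durations between labeled marker pairs as
#' `system.file("extdata", "peak_to_peak_delays.csv", package = "golgitrace")`.
#'
#' @param path CSV file path.
#' @param merge_tags Collapse fluorophore-tag variants with
#'   [strip_fluorophore_tags()] (default TRUE).
#' @return Data frame of pairwise delays.
#' @export
read_delay_table <- function(path, merge_tags = TRUE) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("early", "late", "mean_s", "sd_s", "n")
  if (!all(need %in% names(d))) {
    stop("delay table needs columns early, late, mean_s, sd_s, n",
         call. = FALSE)
  }
  if (merge_tags) {
    d$early <- strip_fluorophore_tags(d$early)
    d$late <- strip_fluorophore_tags(d$late)
  }
  bad <- d$early == d$late
  if (any(bad)) stop("early and late labels must differ", call. = FALSE)
  d
}

#' Assemble a common-axis timeline from pairwise peak-to-peak delays
#'
#' Pairwise delays only constrain differences of peak times, so marker peak
#' times are estimated by weighted least squares on the pairwise-offset
#' graph: within the anchor's connected component, minimize
#' sum w_ij (t_j - t_i - delta_ij)^2 subject to t_anchor = 0. With
#' consistent delays the true assignment is recovered exactly; with
#' inconsistent ones the residuals quantify the tension between
#' measurements.
#'
#' @param delays Data frame from [read_delay_table()] (columns `early`,
#'   `late`, `mean_s`, and for `weighting = "invvar"` also `sd_s`, `n`).
#' @param anchor Marker fixed at time 0 (must appear in some delay).
#' @param weighting `"invvar"` (default): w = n / max(sd, sd_floor)^2;
#'   `"equal"`: w = 1.
#' @param sd_floor Floor on the SD used in inverse-variance weights, seconds
#'   (default 5 s, one frame interval of the 4D maturation regime), so a
#'   near-zero printed SD cannot dominate the fit.
#' @return A `timeline`: list with `times` (named vector, anchor = 0, sorted
#'   by value), `residuals` (per-edge data frame with `residual_s`),
#'   `rms_residual_s` (weighted), `unplaced` (markers outside the anchor's
#'   component), `anchor`.
#' @export
assemble_timeline <- function(delays, anchor,
                              weighting = c("invvar", "equal"),
                              sd_floor = 5) {
  weighting <- match.arg(weighting)
  markers <- unique(c(delays$early, delays$late))
  if (!anchor %in% markers) {
    stop(sprintf("anchor '%s' does not appear in any delay", anchor),
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(delays[, c("early", "late")],
                                     directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  inside <- markers[comp$membership == comp$membership[match(anchor, markers)]]
  unplaced <- setdiff(markers, inside)
  sub <- delays[delays$early %in% inside & delays$late %in% inside, ,
                drop = FALSE]
  w <- if (weighting == "invvar") {
    if (!all(c("sd_s", "n") %in% names(sub))) {
      stop("inverse-variance weighting needs sd_s and n columns", call. = FALSE)
    }
    sub$n / pmax(sub$sd_s, sd_floor)^2
  } else rep(1, nrow(sub))
  free <- setdiff(inside, anchor)
  # normal equations for t_free; incidence row: +1 late, -1 early
  X <- matrix(0, nrow(sub), length(free), dimnames = list(NULL, free))
  for (i in seq_len(nrow(sub))) {
    if (sub$late[i] != anchor) X[i, sub$late[i]] <- 1
    if (sub$early[i] != anchor) X[i, sub$early[i]] <- -1
  }
  y <- sub$mean_s
  WX <- X * w
  t_free <- solve(crossprod(X, WX), crossprod(WX, y))[, 1]
  times <- c(setNames(0, anchor), t_free)
  resid <- times[sub$late] - times[sub$early] - sub$mean_s
  res_tab <- data.frame(early = sub$early, late = sub$late,
                        mean_s = sub$mean_s, weight = w,
                        residual_s = unname(resid))
  structure(list(times = sort(times), residuals = res_tab,
                 rms_residual_s = sqrt(sum(w * resid^2) / sum(w)),
                 unplaced = unplaced, anchor = anchor),
            class = "timeline")
}

#' Temporal order of markers in a timeline
#'
#' @param timeline A [assemble_timeline()] result.
#' @return Character vector of marker labels sorted by inferred peak time;
#'   exact ties are broken alphabetically and reported with a warning.
#' @export
order_markers <- function(timeline) {
  tt <- timeline$times
  ord <- order(tt, names(tt))
  if (anyDuplicated(tt)) {
    warning("tied peak times broken alphabetically")
  }
  names(tt)[ord]
}

#' @export
print.timeline <- function(x, ...) {
  cat(sprintf("timeline anchored at %s = 0 s (weighted RMS residual %.1f s)\n",
              x$anchor, x$rms_residual_s))
  print(round(x$times, 1))
  if (length(x$unplaced)) {
    cat("unplaced (disconnected):", paste(x$unplaced, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a timeline as horizontal peak-time markers
#'
#' @param x A `timeline`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.timeline <- function(x, ...) {
  tt <- x$times
  n <- length(tt)
  graphics::plot(range(tt), c(1, n), type = "n", xlab = "peak time (s)",
                 ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(n), labels = names(tt), las = 2,
                 cex.axis = 0.7)
  graphics::abline(v = 0, col = "grey70", lty = 2)
  graphics::segments(0, seq_len(n), tt, seq_len(n), col = "grey50")
  graphics::points(tt, seq_len(n), pch = 16)
  invisible(x)
}
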