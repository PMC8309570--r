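PARAM_COLUMNS <- c(frequency = "f_central_hz", psd = "psd_max",
                   duration = "duration_periods", bandwidth = "bandwidth_hz")

#' Default bound grids of the four diagram types
#'
#' Frequency 1-50 Hz in 1 Hz steps, maximal PSD 0-1000 uV^2/Hz in 10
#' uV^2/Hz steps, duration 0-10 periods in 0.1 period steps, bandwidth
#' 0-50 Hz in 0.1 Hz steps; lower and upper bounds share the grid.
#'
#' @return Named list of `list(lower, upper)` grids.
#' @export
default_diagram_grids <- function() {
  g <- list(frequency = seq(1, 50, by = 1),
            psd = seq(0, 1000, by = 10),
            duration = seq(0, 10, by = 0.1),
            bandwidth = seq(0, 50, by = 0.1))
  lapply(g, function(v) list(lower = v, upper = v))
}

# strip the bounds of `parameter` itself from a box: diagram constraints
# apply to the other three parameters only
strip_own_bounds <- function(box, parameter) {
  key <- c(frequency = "freq", psd = "psd", duration = "duration",
           bandwidth = "bandwidth")[[parameter]]
  box[[paste0("min_", key)]] <- -Inf
  box[[paste0("max_", key)]] <- Inf
  box
}

# per-subject rate matrices over the (lower, upper) grid: element (i, j) is
# the subject's rate of events with parameter value in [lower_i, upper_j]
subject_rate_matrices <- function(cohort, parameter, lower, upper,
                                  constraints) {
  ev <- select_box(cohort$events, strip_own_bounds(constraints, parameter))
  col <- PARAM_COLUMNS[[parameter]]
  lapply(seq_len(nrow(cohort$subjects)), function(k) {
    x <- sort(ev[[col]][ev$subject_id == cohort$subjects$subject_id[k]])
    n_le_up <- findInterval(upper, x)                  # #{x <= upper_j}
    n_lt_lo <- findInterval(lower, x, left.open = TRUE) # #{x < lower_i}
    outer(-n_lt_lo, n_le_up, "+") / cohort$subjects$duration_s[k]
  })
}

#' 2D AUC diagram of one wave-train parameter
#'
#' For every admissible range `[lower_i, upper_j]` (closed; defined only
#' where `lower_i <= upper_j`, giving the diagram its triangular shape)
#' the per-subject rates of wave trains whose parameter falls in the range
#' - after applying `constraints` to the other three parameters - are
#' compared between patients and controls by [roc_auc()]. Red cells
#' (AUC > 0.5) mean more wave trains in the patients.
#'
#' @param cohort A [wavetrain_cohort()].
#' @param parameter One of `"frequency"`, `"psd"`, `"duration"`,
#'   `"bandwidth"`.
#' @param lower_bounds,upper_bounds Bound grids; default from
#'   [default_diagram_grids()].
#' @param constraints A [parameter_box()] restricting the other three
#'   parameters.
#' @param positive,negative Group labels compared (positive class first).
#' @param with_p Also compute a Mann-Whitney p-value per cell (quadratic
#'   in the grid size; intended for modest grids).
#' @param cells `"value"` (default): cell (i, j) is admissible whenever
#'   `lower_i <= upper_j`, which on a shared grid includes the zero-width
#'   diagonal; `"index"`: admissible whenever `i <= j`, the convention of
#'   the resolution-`R` bin-edge grids of [auc_diagram_3d()], where the
#'   slice then has exactly `R*(R+1)/2` cells.
#' @return Object of class `auc_diagram_2d` with the AUC matrix (`NA`
#'   below the diagonal), the grids and the group sizes.
#' @export
auc_diagram_2d <- function(cohort, parameter = c("frequency", "psd",
                                                 "duration", "bandwidth"),
                           lower_bounds = NULL, upper_bounds = NULL,
                           constraints = parameter_box(),
                           positive = "patient", negative = "control",
                           with_p = FALSE, cells = c("value", "index")) {
  parameter <- match.arg(parameter)
  cells <- match.arg(cells)
  stopifnot(inherits(cohort, "wavetrain_cohort"))
  if (is.null(lower_bounds)) {
    g <- default_diagram_grids()[[parameter]]
    lower_bounds <- g$lower
    upper_bounds <- g$upper
  }
  if (is.null(upper_bounds)) upper_bounds <- lower_bounds
  ia <- which(cohort$subjects$group == positive)
  ib <- which(cohort$subjects$group == negative)
  if (!length(ia) || !length(ib))
    stop("both groups must be present in the cohort")
  rates <- subject_rate_matrices(cohort, parameter, lower_bounds,
                                 upper_bounds, constraints)
  nlo <- length(lower_bounds)
  nup <- length(upper_bounds)
  auc <- matrix(0, nlo, nup)
  for (p in ia) for (q in ib) {
    d <- rates[[p]] - rates[[q]]
    auc <- auc + (d > 0) + 0.5 * (d == 0)
  }
  auc <- auc / (length(ia) * length(ib))
  defined <- if (cells == "index") {
    outer(seq_len(nlo), seq_len(nup), "<=")
  } else {
    outer(lower_bounds, upper_bounds, "<=")
  }
  auc[!defined] <- NA_real_
  pmat <- NULL
  if (with_p) {
    pmat <- matrix(NA_real_, nlo, nup)
    for (i in seq_len(nlo)) for (j in seq_len(nup)) {
      if (!defined[i, j]) next
      ra <- vapply(rates[ia], `[`, 0, i, j)
      rb <- vapply(rates[ib], `[`, 0, i, j)
      pmat[i, j] <- mann_whitney_p(ra, rb)$p
    }
  }
  structure(list(parameter = parameter, lower_bounds = lower_bounds,
                 upper_bounds = upper_bounds, auc = auc, p = pmat,
                 constraints = constraints, n_positive = length(ia),
                 n_negative = length(ib), positive = positive,
                 negative = negative),
            class = "auc_diagram_2d")
}

#' @export
print.auc_diagram_2d <- function(x, ...) {
  b <- best_cell(x)
  cat(sprintf("<auc_diagram_2d> %s, %d x %d bounds, %s(%d) vs %s(%d)\n",
              x$parameter, length(x$lower_bounds), length(x$upper_bounds),
              x$positive, x$n_positive, x$negative, x$n_negative))
  cat(sprintf("  best cell: [%g, %g] AUC = %.3f\n", b$lower, b$upper, b$auc))
  invisible(x)
}

#' @export
as.data.frame.auc_diagram_2d <- function(x, ...) {
  idx <- which(!is.na(x$auc), arr.ind = TRUE)
  out <- data.frame(parameter = x$parameter,
                    lower = x$lower_bounds[idx[, 1L]],
                    upper = x$upper_bounds[idx[, 2L]],
                    auc = x$auc[idx], stringsAsFactors = FALSE)
  if (!is.null(x$p)) out$p <- x$p[idx]
  out[order(out$lower, out$upper), , drop = FALSE]
}

#' Best cell of a 2D AUC diagram
#'
#' The cell with the most pronounced group difference, formalized as the
#' largest `|AUC - 0.5|`; ties are broken toward the widest range, then
#' the smallest lower bound, so an uninformative all-0.5 diagram returns
#' its full-range cell.
#'
#' @param d An `auc_diagram_2d`.
#' @return List `parameter`, `lower`, `upper`, `auc`, `score`.
#' @export
best_cell <- function(d) {
  stopifnot(inherits(d, "auc_diagram_2d"))
  score <- abs(d$auc - 0.5)
  smax <- max(score, na.rm = TRUE)
  idx <- which(!is.na(score) & score >= smax - 1e-12, arr.ind = TRUE)
  lo <- d$lower_bounds[idx[, 1L]]
  up <- d$upper_bounds[idx[, 2L]]
  width <- up - lo
  pick <- order(-width, lo)[1L]
  list(parameter = d$parameter, lower = lo[pick], upper = up[pick],
       auc = d$auc[idx[pick, 1L], idx[pick, 2L]], score = smax)
}

#' Characteristic-range cell of a 2D AUC diagram (diagonal reading)
#'
#' Formalizes how the diagrams are read: the near-diagonal cells (the
#' narrowest admissible ranges) locate the frequencies - or PSD,
#' duration, bandwidth values - where the groups differ, and the
#' characteristic range is the contiguous run of same-colored
#' near-diagonal cells around the strongest one. The run keeps cells on
#' the dominant side of 0.5 whose score `|AUC - 0.5|` stays above half
#' the peak score. Unlike [best_cell()], this reading stays informative
#' when whole nested families of wide cells saturate at AUC 0 or 1. A
#' flat diagram (no near-diagonal contrast) falls back to [best_cell()].
#'
#' @param d An `auc_diagram_2d`.
#' @param run_threshold Fraction of the peak near-diagonal score above
#'   which neighbouring cells still count as part of the band.
#' @return List `parameter`, `lower`, `upper`, `auc` (of the run-spanning
#'   cell), `score` (the peak near-diagonal score).
#' @export
core_cell <- function(d, run_threshold = 0.5) {
  stopifnot(inherits(d, "auc_diagram_2d"))
  # near-diagonal cell for each lower bound: the narrowest range with
  # positive width (zero-width cells catch nothing for continuous
  # attributes)
  jd <- vapply(d$lower_bounds, function(lo) {
    j <- which(d$upper_bounds > lo)
    if (length(j)) j[1L] else NA_integer_
  }, 0L)
  ii <- which(!is.na(jd))
  s <- d$auc[cbind(ii, jd[ii])] - 0.5
  if (all(is.na(s)) || max(abs(s), na.rm = TRUE) < 1e-12)
    return(best_cell(d))
  k <- which.max(abs(s))
  side <- sign(s[k])
  thr <- abs(s[k]) * run_threshold
  in_run <- !is.na(s) & sign(s) == side & abs(s) >= thr
  left <- k
  while (left > 1L && in_run[left - 1L]) left <- left - 1L
  right <- k
  while (right < length(ii) && in_run[right + 1L]) right <- right + 1L
  lo <- d$lower_bounds[ii[left]]
  up <- d$upper_bounds[jd[ii[right]]]
  i <- ii[left]
  j <- jd[ii[right]]
  list(parameter = d$parameter, lower = lo, upper = up,
       auc = d$auc[i, j], score = abs(s[k]))
}

#' 3D AUC diagram: resolution-stacked significance-masked slices
#'
#' For each resolution `R` the parameter range is split into `R` equal
#' bins; the lower-bound grid is the left bin edges and the upper-bound
#' grid the right bin edges, so the slice has `C = R*(R+1)/2` admissible
#' cells. Each cell carries the [roc_auc()] of the per-subject rates and a
#' Mann-Whitney p-value; the slice's significance mask keeps the cells
#' with `p <= alpha_B(R)` where `alpha_B` is the Sidak-form corrected
#' level ([bonferroni_alpha()]) for that slice's comparison count. A
#' horizontal slice of the stack therefore reproduces the 2D diagram
#' built at that resolution, and the mask stack is the isosurface data of
#' `p <= alpha_B`.
#'
#' @inheritParams auc_diagram_2d
#' @param range Length-2 parameter range `c(lo, hi)`.
#' @param resolutions Integer vector of resolutions (stack levels).
#' @param alpha0 Family-wise level per slice.
#' @return Object of class `auc_diagram_3d`; element `slices` holds one
#'   record per resolution (`diagram`, `alpha_b`, `significant` mask).
#' @export
auc_diagram_3d <- function(cohort, parameter = c("frequency", "psd",
                                                 "duration", "bandwidth"),
                           range = c(1, 50), resolutions = 1:15,
                           constraints = parameter_box(), alpha0 = 0.05,
                           positive = "patient", negative = "control") {
  parameter <- match.arg(parameter)
  slices <- lapply(resolutions, function(R) {
    edges <- seq(range[1L], range[2L], length.out = R + 1L)
    d <- auc_diagram_2d(cohort, parameter, lower_bounds = edges[1:R],
                        upper_bounds = edges[2:(R + 1L)],
                        constraints = constraints, positive = positive,
                        negative = negative, with_p = TRUE,
                        cells = "index")
    ab <- bonferroni_alpha(alpha0, correction_count(R))
    sig <- !is.na(d$p) & d$p <= ab
    list(R = R, diagram = d, alpha_b = ab, significant = sig)
  })
  structure(list(parameter = parameter, range = range,
                 resolutions = resolutions, alpha0 = alpha0,
                 slices = slices),
            class = "auc_diagram_3d")
}

#' @export
print.auc_diagram_3d <- function(x, ...) {
  nsig <- vapply(x$slices, function(s) sum(s$significant), 0L)
  cat(sprintf("<auc_diagram_3d> %s over [%g, %g], R = %s\n", x$parameter,
              x$range[1L], x$range[2L],
              paste(range(x$resolutions), collapse = "-")))
  cat(sprintf("  significant cells per slice: %s (alpha0 = %g)\n",
              paste(nsig, collapse = ", "), x$alpha0))
  invisible(x)
}

#' @export
as.data.frame.auc_diagram_3d <- function(x, ...) {
  rows <- lapply(x$slices, function(s) {
    df <- as.data.frame(s$diagram)
    idx <- which(!is.na(s$diagram$auc), arr.ind = TRUE)
    idx <- idx[order(s$diagram$lower_bounds[idx[, 1L]],
                     s$diagram$upper_bounds[idx[, 2L]]), , drop = FALSE]
    df$R <- s$R
    df$alpha_b <- s$alpha_b
    df$significant <- s$significant[idx]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# update one parameter's bounds of a box from a chosen diagram cell
apply_cell <- function(box, cell) {
  key <- c(frequency = "freq", psd = "psd", duration = "duration",
           bandwidth = "bandwidth")[[cell$parameter]]
  box[[paste0("min_", key)]] <- cell$lower
  box[[paste0("max_", key)]] <- cell$upper
  box
}

#' Iterative refinement of the wave-train parameter box
#'
#' Formalizes the exploratory loop of reading the four diagram types: at
#' each step all four 2D diagrams are built under the current constraints
#' (the scanned parameter's own bounds are never applied to its diagram),
#' the overall best cell - largest `|AUC - 0.5|` across the four - is
#' applied as that parameter's new bounds, and the loop stops when the
#' best score no longer improves by more than `eps` (`no_change`), when
#' it drops by more than `delta` (the last restriction is reverted and the
#' state reported as `degraded`), or after `max_iter` applied steps.
#' Finally, the characteristic range of every parameter is read off its
#' diagram under the final constraints (the [core_cell()] diagonal
#' reading), so the returned box always carries bounds for all four
#' wave-train parameters, the way the method's result tables report them.
#'
#' @inheritParams auc_diagram_2d
#' @param grids Bound grids per parameter, as [default_diagram_grids()].
#' @param max_iter Maximum number of applied refinement steps.
#' @param eps Minimum score improvement counted as progress.
#' @param delta Score drop treated as degradation.
#' @return Object of class `wt_refinement`: final `box`, step `history`,
#'   `stop_reason` and the four final diagrams.
#' @export
refine_wavetrains <- function(cohort, constraints = parameter_box(),
                              grids = default_diagram_grids(),
                              positive = "patient", negative = "control",
                              max_iter = 10L, eps = 0.01, delta = 0.05) {
  stopifnot(inherits(cohort, "wavetrain_cohort"))
  tb <- table(cohort$subjects$group)
  if (!all(c(positive, negative) %in% names(tb)) ||
      any(tb[c(positive, negative)] < 2L))
    stop("need at least 2 subjects per group")
  build_all <- function(box)
    lapply(names(grids), function(p)
      auc_diagram_2d(cohort, p, grids[[p]]$lower, grids[[p]]$upper,
                     constraints = box, positive = positive,
                     negative = negative))
  overall_best <- function(ds) {
    cells <- lapply(ds, best_cell)
    scores <- vapply(cells, `[[`, 0, "score")
    # cross-diagram ties compare the fraction of the parameter's grid
    # span covered (widths in Hz, uV^2/Hz and periods are incommensurable)
    spans <- vapply(names(grids), function(p)
      max(grids[[p]]$upper) - min(grids[[p]]$lower), 0)
    relw <- vapply(seq_along(cells), function(i)
      (cells[[i]]$upper - cells[[i]]$lower) / spans[[i]], 0)
    lowers <- vapply(cells, `[[`, 0, "lower")
    ok <- scores >= max(scores) - 1e-12
    pick <- which(ok)[order(-relw[ok], lowers[ok])[1L]]
    cells[[pick]]
  }
  history <- data.frame(iter = integer(0), parameter = character(0),
                        lower = numeric(0), upper = numeric(0),
                        auc = numeric(0), score = numeric(0),
                        stringsAsFactors = FALSE)
  box <- constraints
  box_prev <- box
  diagrams <- build_all(box)
  best <- overall_best(diagrams)
  prev_score <- best$score
  box_prev <- box
  box <- apply_cell(box, best)
  history[1L, ] <- list(1L, best$parameter, best$lower, best$upper,
                        best$auc, best$score)
  stop_reason <- "max_iter"
  for (iter in seq_len(max_iter)[-1L]) {
    diagrams <- build_all(box)
    best <- overall_best(diagrams)
    if (best$score > prev_score + eps) {
      box_prev <- box
      box <- apply_cell(box, best)
      history[nrow(history) + 1L, ] <-
        list(iter, best$parameter, best$lower, best$upper, best$auc,
             best$score)
      prev_score <- best$score
    } else if (best$score < prev_score - delta) {
      box <- box_prev
      stop_reason <- "degraded"
      break
    } else {
      stop_reason <- "no_change"
      break
    }
  }
  # read-off of the characteristic ranges of the parameters the loop
  # never constrained explicitly (the loop's own cells stand). The
  # maximal-PSD range is read and applied first when the loop did not
  # constrain it - it separates signal events from the background
  # texture maxima sitting at the noise floor - and the remaining
  # parameters are then read in parallel from the diagrams under the
  # accumulated constraints, the way the final result tables quote one
  # range per attribute from the final set of diagrams.
  final_cells <- list()
  remaining <- setdiff(names(grids), history$parameter)
  if ("psd" %in% remaining) {
    dpsd <- auc_diagram_2d(cohort, "psd", grids$psd$lower, grids$psd$upper,
                           constraints = box, positive = positive,
                           negative = negative)
    final_cells$psd <- core_cell(dpsd)
    box <- apply_cell(box, final_cells$psd)
    remaining <- setdiff(remaining, "psd")
  }
  diagrams <- build_all(box)
  names(diagrams) <- names(grids)
  for (p in remaining) {
    final_cells[[p]] <- core_cell(diagrams[[p]])
    box <- apply_cell(box, final_cells[[p]])
  }
  final_cells <- final_cells[intersect(names(grids), names(final_cells))]
  structure(list(box = box, history = history, stop_reason = stop_reason,
                 diagrams = diagrams, final_cells = final_cells,
                 initial = constraints, eps = eps, delta = delta),
            class = "wt_refinement")
}

#' @export
print.wt_refinement <- function(x, ...) {
  cat(sprintf("<wt_refinement> %d applied step(s), stopped: %s\n",
              nrow(x$history), x$stop_reason))
  print(x$box)
  invisible(x)
}

#' @export
summary.wt_refinement <- function(object, ...) {
  print(object)
  cat("history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
coef.wt_refinement <- function(object, ...) {
  unlist(object$box)
}

#' @export
plot.wt_refinement <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(old))
  for (d in x$diagrams) plot(d, ...)
  invisible(x)
}

#' Jet colormap
#'
#' @param n Number of colors.
#' @return Vector of `n` colors from dark blue through green to dark red.
#' @export
jet_colors <- function(n = 256) {
  grDevices::colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan",
                                "#7FFF7F", "yellow", "#FF7F00", "red",
                                "#7F0000"))(n)
}

#' @export
plot.auc_diagram_2d <- function(x, ...) {
  graphics::image(x$lower_bounds, x$upper_bounds, x$auc,
                  col = jet_colors(256), zlim = c(0, 1),
                  xlab = paste(x$parameter, "lower bound"),
                  ylab = paste(x$parameter, "upper bound"),
                  main = paste(x$parameter, "AUC diagram"), ...)
  invisible(x)
}

# map an AUC matrix to an RGB raster (rows flipped so the largest upper
# bound is at the top); NA cells are white
auc_raster <- function(auc, scale) {
  cols <- jet_colors(256)
  arr <- array(1, dim = c(nrow(auc), ncol(auc), 3L))
  ok <- which(!is.na(auc))
  if (length(ok)) {
    idx <- pmin(255L, pmax(0L, floor(auc[ok] * 256))) + 1L
    rgb <- grDevices::col2rgb(cols[idx]) / 255
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[ok] <- rgb[ch, ]
      arr[, , ch] <- plane
    }
  }
  # image rows run top to bottom; diagram upper bound should increase upward
  arr <- arr[, rev(seq_len(ncol(auc))), , drop = FALSE]
  arr <- aperm(arr, c(2L, 1L, 3L))
  if (scale > 1L) {
    up <- function(m) m[rep(seq_len(nrow(m)), each = scale),
                        rep(seq_len(ncol(m)), each = scale)]
    arr2 <- array(0, dim = c(nrow(arr) * scale, ncol(arr) * scale, 3L))
    for (ch in 1:3) arr2[, , ch] <- up(arr[, , ch])
    arr <- arr2
  }
  arr
}

#' Render an AUC diagram to a PNG file
#'
#' Heatmap with the lower bound on the abscissa, the upper bound on the
#' ordinate, the jet colormap over the full AUC range `[0, 1]` and white
#' undefined cells. A 3D diagram is exported as one PNG per resolution
#' slice (suffix `_R<nn>`), with non-significant cells blanked.
#'
#' @param d An `auc_diagram_2d` or `auc_diagram_3d`.
#' @param path Output PNG path.
#' @param scale Integer pixel size per cell (default targets ~400 px).
#' @return Invisibly, the written file path(s).
#' @export
render_diagram <- function(d, path, scale = NULL) {
  if (inherits(d, "auc_diagram_3d")) {
    base <- sub("\\.png$", "", path)
    paths <- character(0)
    for (s in d$slices) {
      auc <- s$diagram$auc
      auc[!s$significant] <- NA_real_
      p <- sprintf("%s_R%02d.png", base, s$R)
      sc <- if (is.null(scale)) max(1L, 400L %/% max(dim(auc))) else scale
      png::writePNG(auc_raster(auc, sc), p)
      paths <- c(paths, p)
    }
    return(invisible(paths))
  }
  stopifnot(inherits(d, "auc_diagram_2d"))
  sc <- if (is.null(scale)) max(1L, 400L %/% max(dim(d$auc))) else scale
  png::writePNG(auc_raster(d$auc, sc), path)
  invisible(path)
}
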