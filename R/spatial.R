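#' Construct a spatial dataset
#'
#' An expression matrix over spots plus per-spot 2-D coordinates and,
#' for synthetic data, the ground-truth mixing proportions and planted
#' region mask.
#'
#' @param em `ExpressionMatrix`, genes x spots.
#' @param coords data.frame with columns `obs_id`, `x`, `y`, one row per
#'   spot, aligned with `em$obs_ids`.
#' @param truth_mixing optional spots x clusters matrix with rows summing
#'   to 1.
#' @param truth_region optional named logical vector marking planted-region
#'   spots.
#' @return A `SpatialDataset`.
#' @export
spatial_dataset <- function(em, coords, truth_mixing = NULL,
                            truth_region = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  req <- c("obs_id", "x", "y")
  if (!all(req %in% names(coords))) {
    stop_regenmac("coords must have columns: ", paste(req, collapse = ", "))
  }
  if (!identical(as.character(coords$obs_id), em$obs_ids)) {
    stop_regenmac("coords rows must align one-to-one with em$obs_ids")
  }
  if (!is.null(truth_mixing)) {
    if (nrow(truth_mixing) != length(em$obs_ids)) {
      stop_regenmac("truth_mixing must have one row per spot")
    }
    if (any(abs(rowSums(truth_mixing) - 1) > 1e-9)) {
      stop_regenmac("truth_mixing rows must sum to 1")
    }
  }
  structure(list(em = em, coords = coords, truth_mixing = truth_mixing,
                 truth_region = truth_region),
            class = "SpatialDataset")
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat(sprintf("SpatialDataset: %d genes x %d spots%s\n",
              length(x$em$gene_ids), length(x$em$obs_ids),
              if (is.null(x$truth_mixing)) "" else " (with ground truth)"))
  invisible(x)
}

#' Score spatial spots with a cell-population signature
#'
#' Applies the identical bin-matched [module_score()] used on cells to the
#' spot matrix (bin statistics come from the spatial matrix itself); the
#' score over the coordinates is the predictive map of population position.
#'
#' @param sd a `SpatialDataset` whose matrix has a normalized layer.
#' @param signature a `GeneSet`, typically from [top_signature()].
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return Named numeric vector of per-spot scores.
#' @export
spot_scores <- function(sd, signature, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(sd, "SpatialDataset"))
  module_score(sd$em, signature, n_bins = n_bins, n_ctrl = n_ctrl,
               seed = seed)$scores
}

#' Classify spots as positive or negative for a population
#'
#' @param scores named per-spot scores from [spot_scores()].
#' @param rule `"score_gt_zero"` (default; module scores are
#'   background-centered so 0 is the natural null) or `"quantile"`
#'   (positive = above the `1 - threshold` quantile).
#' @param threshold for the quantile rule, a fraction in (0, 1).
#' @return A `SpotPrediction` data.frame with columns `obs_id`, `score`,
#'   `positive`, `threshold_used`, `rule`.
#' @export
classify_spots <- function(scores, rule = c("score_gt_zero", "quantile"),
                           threshold = NULL) {
  rule <- match.arg(rule)
  if (rule == "score_gt_zero") {
    thr <- 0
  } else {
    if (is.null(threshold) || threshold <= 0 || threshold >= 1) {
      stop_regenmac("quantile rule needs threshold in (0, 1)")
    }
    thr <- unname(stats::quantile(scores, 1 - threshold, type = 7))
  }
  out <- data.frame(obs_id = names(scores), score = unname(scores),
                    positive = unname(scores) > thr,
                    threshold_used = thr, rule = rule,
                    stringsAsFactors = FALSE)
  class(out) <- c("SpotPrediction", "data.frame")
  out
}

#' Compare pathway activity between predicted-positive and -negative spots
#'
#' Scores the pathway per spot with [module_score()] and contrasts the
#' positive against the negative class: mean and SD per class, Welch t
#' statistic and p-value, and the rank-based effect size (AUC of the
#' pathway score for separating positive spots).
#'
#' @param sd a `SpatialDataset` with a normalized layer.
#' @param prediction a `SpotPrediction` from [classify_spots()].
#' @param pathway a `GeneSet` (e.g. a BMP pathway list).
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return list with per-class summaries, `t`, `p`, `auc`, and the
#'   per-spot `pathway_scores`; when a class is empty the test fields are
#'   `NA` and `note` says so.
#' @export
conditional_pathway <- function(sd, prediction, pathway,
                                n_bins = 24, n_ctrl = 100, seed = 0) {
  ps <- module_score(sd$em, pathway, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed)$scores
  pos <- prediction$positive[match(names(ps), prediction$obs_id)]
  out <- list(set_name = pathway$name,
              n_pos = sum(pos), n_neg = sum(!pos),
              mean_pos = mean(ps[pos]), sd_pos = stats::sd(ps[pos]),
              mean_neg = mean(ps[!pos]), sd_neg = stats::sd(ps[!pos]),
              t = NA_real_, p = NA_real_, auc = NA_real_,
              pathway_scores = ps, note = NULL)
  if (out$n_pos == 0 || out$n_neg == 0) {
    out$note <- "a prediction class is empty; no test performed"
    return(out)
  }
  tt <- stats::t.test(ps[pos], ps[!pos])
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out$auc <- rank_auc(ps, pos)
  out
}

#' Export a presence map of populations over spots
#'
#' Writes a CSV of (obs_id, x, y, population, score, positive) rows and,
#' optionally, a PNG raster whose dimensions are proportional to the
#' coordinate bounding box.
#'
#' @param sd a `SpatialDataset`.
#' @param predictions named list of `SpotPrediction`s, one per population.
#' @param csv_path output CSV path.
#' @param png_path optional output PNG path.
#' @param px_per_unit raster pixels per coordinate unit.
#' @return Invisibly, the exported data.frame.
#' @export
presence_map_export <- function(sd, predictions, csv_path, png_path = NULL,
                                px_per_unit = 20) {
  stopifnot(inherits(sd, "SpatialDataset"))
  rows <- do.call(rbind, lapply(names(predictions), function(pop) {
    p <- predictions[[pop]]
    data.frame(obs_id = p$obs_id,
               x = sd$coords$x[match(p$obs_id, sd$coords$obs_id)],
               y = sd$coords$y[match(p$obs_id, sd$coords$obs_id)],
               population = pop, score = p$score, positive = p$positive,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    bx <- range(sd$coords$x)
    by <- range(sd$coords$y)
    w <- (diff(bx) + 1) * px_per_unit
    h <- (diff(by) + 1) * px_per_unit
    grDevices::png(png_path, width = w, height = h)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    graphics::plot(NA, xlim = bx + c(-0.5, 0.5), ylim = by + c(-0.5, 0.5),
                   axes = FALSE, xlab = "", ylab = "", asp = NA)
    first <- predictions[[1]]
    cols <- ifelse(first$positive, "#d73027", "#4575b4")
    graphics::points(sd$coords$x, sd$coords$y, pch = 15, col = cols,
                     cex = 1.2)
  }
  invisible(rows)
}
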