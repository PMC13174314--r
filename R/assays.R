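#' Construct an injection-annotated rate trace
#'
#' One well's extracellular-flux time series (OCR, ECAR or PER in
#' already-converted rate units) with the injection events that partition
#' it into phases.
#'
#' @param well well identifier.
#' @param group treatment group label.
#' @param time measurement times in minutes, strictly increasing.
#' @param value rate measurements.
#' @param injections data.frame with columns `time` (minutes) and `agent`
#'   (e.g. `"oligomycin"`, `"FCCP"`, `"rot/AA"`, `"etomoxir"`, `"saline"`);
#'   every injection time must fall within the measurement span.
#' @return A `RateTrace`.
#' @export
rate_trace <- function(well, group, time, value, injections = NULL) {
  if (length(time) != length(value)) {
    stop_regenmac("time and value lengths differ")
  }
  if (any(diff(time) <= 0)) stop_regenmac("times must be strictly increasing")
  if (is.null(injections)) {
    injections <- data.frame(time = numeric(0), agent = character(0))
  }
  injections <- data.frame(time = as.numeric(injections$time),
                           agent = as.character(injections$agent),
                           stringsAsFactors = FALSE)
  if (nrow(injections) > 1 && any(diff(injections$time) <= 0)) {
    stop_regenmac("injection times must be strictly increasing")
  }
  if (nrow(injections) > 0) {
    if (min(injections$time) <= min(time)) {
      stop_regenmac("injection before first measurement")
    }
    if (max(injections$time) >= max(time)) {
      stop_regenmac("injection at or after last measurement")
    }
  }
  structure(list(well = as.character(well), group = as.character(group),
                 time = as.numeric(time), value = as.numeric(value),
                 injections = injections),
            class = "RateTrace")
}

#' Partition a trace into injection phases
#'
#' Measurements are split into half-open phases `[start, next injection)`:
#' a baseline phase, then one phase per injection labeled by its agent.
#'
#' @param trace a `RateTrace`.
#' @return data.frame with columns `time`, `value`, `phase` (factor in
#'   phase order).
#' @export
phase_segment <- function(trace) {
  stopifnot(inherits(trace, "RateTrace"))
  breaks <- c(-Inf, trace$injections$time, Inf)
  labels <- make.unique(c("baseline", as.character(trace$injections$agent)))
  phase <- labels[findInterval(trace$time, breaks, left.open = FALSE)]
  data.frame(time = trace$time, value = trace$value,
             phase = factor(phase, levels = labels),
             stringsAsFactors = FALSE)
}

phase_values <- function(trace, phase_name) {
  seg <- phase_segment(trace)
  seg$value[seg$phase == phase_name]
}

find_agent_phase <- function(trace, pattern) {
  agents <- as.character(trace$injections$agent)
  hit <- grepl(pattern, tolower(agents))
  if (!any(hit)) return(NULL)
  agents[which(hit)[sum(hit)]]  # last matching injection
}

# Mean of the final rot/AA (non-mitochondrial) phase, or NULL.
nonmito_rate <- function(trace) {
  ph <- find_agent_phase(trace, "rot")
  if (is.null(ph)) return(NULL)
  mean(phase_values(trace, ph))
}

#' Basal respiration rate of a trace
#'
#' Mean of the last up-to-3 baseline measurements, minus the
#' non-mitochondrial rate (mean of the final rot/AA phase) when a rot/AA
#' injection exists; otherwise the raw baseline mean, flagged via
#' `attr(, "corrected") = FALSE`.
#'
#' @param trace a `RateTrace`.
#' @param n_baseline_cycles baseline window length (default 3).
#' @return Basal rate (numeric) with attribute `corrected`.
#' @export
basal_rate <- function(trace, n_baseline_cycles = 3) {
  base <- phase_values(trace, "baseline")
  if (length(base) == 0L) stop_regenmac("empty baseline phase")
  base <- utils::tail(base, n_baseline_cycles)
  nm <- nonmito_rate(trace)
  out <- mean(base) - (nm %||% 0)
  attr(out, "corrected") <- !is.null(nm)
  out
}

#' Maximal (FCCP-stimulated) respiration rate of a trace
#'
#' Maximum single measurement in the FCCP phase minus the
#' non-mitochondrial rate (when available, flagged as for [basal_rate()]).
#'
#' @param trace a `RateTrace`.
#' @return Maximal rate with attribute `corrected`.
#' @export
maximal_rate <- function(trace) {
  ph <- find_agent_phase(trace, "fccp")
  if (is.null(ph)) stop_regenmac("no FCCP injection in trace")
  vals <- phase_values(trace, ph)
  nm <- nonmito_rate(trace)
  out <- max(vals) - (nm %||% 0)
  attr(out, "corrected") <- !is.null(nm)
  out
}

#' Percent change in rate after an injection
#'
#' `100 * (mean(agent phase) - mean(preceding phase)) / mean(preceding
#' phase)` — scale-invariant by construction.
#'
#' @param trace a `RateTrace`.
#' @param agent injection agent (matched case-insensitively).
#' @return Percent change.
#' @export
percent_change_post_injection <- function(trace, agent) {
  agents <- as.character(trace$injections$agent)
  i <- which(tolower(agents) == tolower(agent))
  if (length(i) == 0L) stop_regenmac("agent '", agent, "' not injected")
  i <- i[1]
  seg <- phase_segment(trace)
  lv <- levels(seg$phase)
  post <- seg$value[seg$phase == lv[i + 1]]
  pre <- seg$value[seg$phase == lv[i]]  # baseline or previous agent
  100 * (mean(post) - mean(pre)) / mean(pre)
}

#' Compare a metric across treatment groups
#'
#' Pairwise Welch t-tests across all group pairs; with `dunnett_control`
#' set, Dunnett's many-to-one comparisons against that control group are
#' reported as well (adjusted p-values are never smaller than the
#' unadjusted pairwise p).
#'
#' @param values named list of numeric vectors, one per group (each n >= 2).
#' @param dunnett_control optional control group label.
#' @return list with `welch` (data.frame of pairwise tests) and `dunnett`
#'   (data.frame or NULL).
#' @export
group_compare <- function(values, dunnett_control = NULL) {
  if (any(vapply(values, length, integer(1)) < 2)) {
    stop_regenmac("every group needs n >= 2")
  }
  groups <- names(values)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  welch <- do.call(rbind, lapply(pairs, function(pr) {
    a <- values[[pr[1]]]
    b <- values[[pr[2]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # both groups constant: no within-group variability to test against
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      return(data.frame(group_1 = pr[1], group_2 = pr[2],
                        mean_1 = mean(a), mean_2 = mean(b),
                        t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                        df = NA_real_, p_value = if (eq) 1 else 0,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b)
    data.frame(group_1 = pr[1], group_2 = pr[2],
               mean_1 = mean(a), mean_2 = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  }))
  dunnett <- NULL
  if (!is.null(dunnett_control)) {
    if (!dunnett_control %in% groups) {
      stop_regenmac("control group '", dunnett_control, "' not found")
    }
    df <- data.frame(
      y = unlist(values, use.names = FALSE),
      g = factor(rep(groups, vapply(values, length, integer(1))),
                 levels = c(dunnett_control,
                            setdiff(groups, dunnett_control))))
    fit <- stats::aov(y ~ g, data = df)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    dunnett <- data.frame(comparison = names(sm$test$coefficients),
                          estimate = unname(sm$test$coefficients),
                          adj_p = unname(sm$test$pvalues),
                          stringsAsFactors = FALSE)
  }
  list(welch = welch, dunnett = dunnett)
}

#' Relative expression from qPCR Cq values (2^dCq)
#'
#' Per sample and target: `dCq = mean Cq(housekeeping) - mean Cq(target)`
#' and relative expression `2^dCq`, so higher expression gives a larger
#' value. Technical-replicate Cq means are taken per (sample, gene).
#'
#' @param cq data.frame with columns `sample`, `gene`, `cq` (one row per
#'   technical replicate; Cq in (0, 45)).
#' @param housekeeping housekeeping gene id (e.g. `"B2M"`).
#' @param cv_threshold replicate coefficient of variation above which a
#'   (sample, gene) is flagged in the `flag` column.
#' @return data.frame with `sample`, `gene`, `delta_cq`, `rel_expr`,
#'   `flag`.
#' @export
ddcq <- function(cq, housekeeping, cv_threshold = 0.05) {
  req <- c("sample", "gene", "cq")
  if (!all(req %in% names(cq))) {
    stop_regenmac("cq table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(cq$cq <= 0 | cq$cq >= 45)) {
    stop_regenmac("Cq values must lie in (0, 45)")
  }
  agg <- stats::aggregate(cq$cq, by = list(sample = cq$sample,
                                           gene = cq$gene),
                          FUN = function(v) c(mean = mean(v),
                                              cv = stats::sd(v) / mean(v)))
  agg <- data.frame(sample = agg$sample, gene = agg$gene,
                    mean_cq = agg$x[, "mean"], cv = agg$x[, "cv"],
                    stringsAsFactors = FALSE)
  hk <- agg[agg$gene == housekeeping, c("sample", "mean_cq")]
  names(hk)[2] <- "hk_cq"
  targets <- agg[agg$gene != housekeeping, , drop = FALSE]
  missing_hk <- setdiff(unique(targets$sample), hk$sample)
  if (length(missing_hk)) {
    stop_regenmac("missing housekeeping Cq for samples: ",
                  paste(missing_hk, collapse = ", "))
  }
  out <- merge(targets, hk, by = "sample")
  out$delta_cq <- out$hk_cq - out$mean_cq
  out$rel_expr <- 2^out$delta_cq
  out$flag <- !is.na(out$cv) & out$cv > cv_threshold
  out[order(out$sample, out$gene),
      c("sample", "gene", "delta_cq", "rel_expr", "flag")]
}

#' Read rate traces from CSV
#'
#' @param traces_path CSV with columns `well`, `group`, `time_min`,
#'   `value` (and optionally `measurement_type`).
#' @param injections_path CSV with columns `time_min`, `agent`.
#' @return list of `RateTrace` objects.
#' @export
read_traces <- function(traces_path, injections_path) {
  tr <- utils::read.csv(traces_path, stringsAsFactors = FALSE)
  inj <- utils::read.csv(injections_path, stringsAsFactors = FALSE)
  injections <- data.frame(time = inj$time_min, agent = inj$agent,
                           stringsAsFactors = FALSE)
  lapply(split(tr, tr$well), function(d) {
    d <- d[order(d$time_min), ]
    rate_trace(d$well[1], d$group[1], d$time_min, d$value, injections)
  })
}

#' Per-trace flux metric table
#'
#' Convenience wrapper computing [basal_rate()], [maximal_rate()] (when an
#' FCCP phase exists) and [percent_change_post_injection()] for each trace.
#'
#' @param traces list of `RateTrace` objects.
#' @param percent_change_agent agent for the percent-change metric, or
#'   `NULL`.
#' @return data.frame with one row per well.
#' @export
flux_metrics <- function(traces, percent_change_agent = NULL) {
  do.call(rbind, lapply(traces, function(tr) {
    has_fccp <- !is.null(find_agent_phase(tr, "fccp"))
    data.frame(
      well = tr$well, group = tr$group,
      basal = as.numeric(basal_rate(tr)),
      maximal = if (has_fccp) as.numeric(maximal_rate(tr)) else NA_real_,
      percent_change = if (!is.null(percent_change_agent)) {
        percent_change_post_injection(tr, percent_change_agent)
      } else NA_real_,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}
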