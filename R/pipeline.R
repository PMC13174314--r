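# End-to-end orchestration: simulate -> score -> signatures -> metabolic
# profile -> spatial map -> communication -> metabolomics -> flux -> report,
# under one seeded configuration.

#' Default pipeline configuration
#'
#' One block per stage; every parameter is echoed into the run report.
#'
#' @param seed global seed; all stage streams derive from it.
#' @return A nested list (`RunConfig`).
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulation = list(n_genes = 600, n_cells_per_group = 60,
                      marker_logfc = 2, baseline_mean = 0.3,
                      nb_dispersion = 10),
    scoring = list(n_bins = 24, n_ctrl = 100, k_signature = 50,
                   score_seed = 0),
    spatial = list(n_spots = 300, region_fraction = 0.25,
                   inside_weight = 0.6, outside_weight = 0.05,
                   depth = 5000),
    communication = list(min_frac = 0.1, n_perm = 1000, alpha = 0.05),
    metabolomics = list(n_metabolites = 60, n_per_group = 3, n_ortho = 1,
                        n_perm = 200),
    flux = list(n_wells = 8, noise_sd = 4, eto_time = 14)
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or inside a stage block) are rejected
#' before any stage runs; omitted keys take their defaults.
#'
#' @param path YAML file path.
#' @return A validated `RunConfig` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_run_config(user)
}

#' Merge a partial configuration into the defaults, rejecting unknown keys
#'
#' @param user named list of overrides (possibly nested).
#' @param defaults the full default configuration.
#' @export
merge_run_config <- function(user, defaults = default_run_config()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_regenmac("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      bad <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(bad)) {
        stop_regenmac("unknown config keys in '", k, "': ",
                      paste(bad, collapse = ", "))
      }
      defaults[[k]][names(user[[k]])] <- user[[k]]
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

run_stage <- function(name, expr) {
  message("[stage ", name, "] running")
  tryCatch(expr, error = function(e) {
    stop_regenmac("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order, writes all tabular outputs,
#' a JSON + text report and an md5 manifest under `out_dir`, and returns
#' the report. Two runs with the same config produce byte-identical
#' outputs.
#'
#' @param config a `RunConfig` (see [default_run_config()] /
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  config <- merge_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scoring
  checks <- list()
  add_check <- function(name, value, pass) {
    checks[[length(checks) + 1L]] <<- list(name = name, value = value,
                                           pass = isTRUE(pass))
  }

  # --- single-cell simulation -------------------------------------------
  sim <- run_stage("simulate_scrna", {
    cfg <- default_sim_config(
      seed = config$seed,
      n_genes = config$simulation$n_genes,
      n_cells_per_group = config$simulation$n_cells_per_group,
      marker_logfc = config$simulation$marker_logfc,
      baseline_mean = config$simulation$baseline_mean,
      nb_dispersion = config$simulation$nb_dispersion)
    out <- simulate_scrna(cfg)
    out$em <- normalize_counts(out$em)
    out$cfg <- cfg
    out
  })
  inflam <- sim$cfg$inflammatory_cluster
  resol <- sim$cfg$resolution_cluster
  mac_clusters <- c(inflam, resol)

  # --- cluster signatures ------------------------------------------------
  signatures <- run_stage("signatures", {
    sig <- lapply(stats::setNames(nm = mac_clusters), function(cl) {
      top_signature(rank_markers(sim$em, sim$annotations, cl),
                    k = sc$k_signature)
    })
    write_gmt(sig, file.path(out_dir, "signatures.gmt"))
    sig
  })
  planted <- sim$truth$marker_genes[[inflam]]
  recovered <- mean(planted %in% signatures[[inflam]]$genes)
  add_check("inflammatory_marker_recovery", recovered, recovered >= 0.9)

  # --- metabolic state ---------------------------------------------------
  metabolic <- run_stage("metabolic_state", {
    sets <- list(glyco = gene_set("glyco", sim$truth$program_genes$glyco),
                 oxphos = gene_set("oxphos", sim$truth$program_genes$oxphos),
                 famet = gene_set("famet", sim$truth$program_genes$famet))
    prof <- pathway_scores(sim$em, sets, sim$annotations,
                           n_bins = sc$n_bins, n_ctrl = sc$n_ctrl,
                           seed = sc$score_seed)
    utils::write.csv(prof$groups, file.path(out_dir, "metabolic_groups.csv"),
                     row.names = FALSE)
    ratio_p2 <- metabolic_ratio(prof, list(cluster = mac_clusters,
                                           injury = "P2", timepoint = "D10"))
    ratio_p3 <- metabolic_ratio(prof, list(cluster = mac_clusters,
                                           injury = "P3", timepoint = "D10"))
    # variance partition in the injury-dominant regime (broad injury
    # program, weak cluster markers) over P2/P3 myeloid cells
    vsim <- simulate_scrna(injury_dominant_sim_config(
      seed = config$seed,
      n_cells_per_group = config$simulation$n_cells_per_group))
    vsim$em <- normalize_counts(vsim$em)
    vp <- variance_partition(vsim$em, vsim$annotations)
    list(profile = prof, ratio_p2 = ratio_p2, ratio_p3 = ratio_p3, vp = vp)
  })
  add_check("metabolic_ratio_P2_D10_positive", metabolic$ratio_p2,
            metabolic$ratio_p2 > 0)
  add_check("metabolic_ratio_P3_D10_negative", metabolic$ratio_p3,
            metabolic$ratio_p3 < 0)
  vs <- metabolic$vp$summary
  eta_gap <- vs$mean_eta_sq[vs$factor == "injury"] -
    vs$mean_eta_sq[vs$factor == "cluster"]
  add_check("injury_eta_sq_dominates_cluster", eta_gap, eta_gap > 0)

  # --- spatial mapping ---------------------------------------------------
  spatial <- run_stage("spatial_mapping", {
    sd <- simulate_spatial(sim$cfg, sim$truth,
                           n_spots = config$spatial$n_spots,
                           region_fraction = config$spatial$region_fraction,
                           inside_weight = config$spatial$inside_weight,
                           outside_weight = config$spatial$outside_weight,
                           depth = config$spatial$depth)
    sd$em <- normalize_counts(sd$em)
    preds <- lapply(signatures, function(sig) {
      classify_spots(spot_scores(sd, sig, n_bins = sc$n_bins,
                                 n_ctrl = sc$n_ctrl, seed = sc$score_seed))
    })
    bmp_set <- gene_set("BMP", sim$truth$program_genes$bmp)
    cond <- lapply(preds, function(p) {
      conditional_pathway(sd, p, bmp_set, n_bins = sc$n_bins,
                          n_ctrl = sc$n_ctrl, seed = sc$score_seed)
    })
    presence_map_export(sd, preds, file.path(out_dir, "spatial_map.csv"))
    auc <- rank_auc(preds[[inflam]]$score, sd$truth_region)
    list(sd = sd, predictions = preds, conditional = cond, auc = auc)
  })
  add_check("spatial_region_auc", spatial$auc, spatial$auc >= 0.9)
  bmp_inflam <- spatial$conditional[[inflam]]
  bmp_res <- spatial$conditional[[resol]]
  add_check("bmp_higher_in_inflammatory_spots",
            bmp_inflam$p,
            !is.na(bmp_inflam$p) && bmp_inflam$p < 0.01 && bmp_inflam$t > 0)
  add_check("bmp_not_higher_in_resolution_spots",
            bmp_res$p,
            is.na(bmp_res$p) || bmp_res$p >= 0.01 || bmp_res$t < 0)

  # --- cell-cell communication ------------------------------------------
  comm <- run_stage("cell_comm", {
    lr <- read_lr_pairs()
    res <- lapply(stats::setNames(nm = c("P2", "P3")), function(cond) {
      communication_score(sim$em, sim$annotations, lr, condition = cond,
                          min_frac = config$communication$min_frac,
                          n_perm = config$communication$n_perm,
                          seed = derive_seed(config$seed, 5L))
    })
    for (cond in names(res)) {
      utils::write.csv(res[[cond]]$table,
                       file.path(out_dir, sprintf("comm_%s.csv",
                                                  tolower(cond))),
                       row.names = FALSE)
    }
    edges <- pathway_network(res, "BMP", alpha = config$communication$alpha)
    utils::write.csv(edges, file.path(out_dir, "bmp_edges.csv"),
                     row.names = FALSE)
    list(results = res, bmp_edges = edges)
  })
  p3_edge <- any(comm$bmp_edges$condition == "P3" &
                   comm$bmp_edges$sender == inflam &
                   comm$bmp_edges$receiver == sim$cfg$fibroblast_cluster)
  p2_empty <- !any(comm$bmp_edges$condition == "P2")
  add_check("bmp_edge_inflam_to_fibro_in_P3", as.numeric(p3_edge), p3_edge)
  add_check("bmp_network_empty_in_P2", as.numeric(p2_empty), p2_empty)

  # --- metabolomics ------------------------------------------------------
  metab <- run_stage("metabolomics", {
    simm <- simulate_metabolomics(
      n_metabolites = config$metabolomics$n_metabolites,
      n_per_group = config$metabolomics$n_per_group,
      seed = config$seed)
    x <- preprocess(simm$table)
    pc <- pca(x, k = 2)
    op <- oplsda(x, attr(x, "groups"),
                 n_ortho = config$metabolomics$n_ortho,
                 n_perm = config$metabolomics$n_perm,
                 seed = derive_seed(config$seed, 6L))
    diff <- differential_metabolites(simm$table)
    utils::write.csv(data.frame(metabolite = names(op$vip),
                                vip = unname(op$vip)),
                     file.path(out_dir, "metabolomics_vip.csv"),
                     row.names = FALSE)
    utils::write.csv(diff, file.path(out_dir, "metabolite_diff.csv"),
                     row.names = FALSE)
    list(sim = simm, pca = pc, opls = op, diff = diff)
  })
  affected <- metab$sim$truth$metabolite
  vip_rank <- rank(-metab$opls$vip)[affected]
  frac_top <- mean(vip_rank <= max(10, length(affected)))
  add_check("planted_metabolites_in_top_vip", frac_top, frac_top >= 0.5)

  # --- flux traces -------------------------------------------------------
  flux <- run_stage("assays", {
    eto_params <- list(
      control = list(basal = 100, mult = c(etomoxir = 0.7)),
      P2 = list(basal = 100, mult = c(etomoxir = 1.0)),
      P3 = list(basal = 100, mult = c(etomoxir = 0.7)))
    eto <- simulate_traces(eto_params, n_wells = config$flux$n_wells,
                           injections = data.frame(time = config$flux$eto_time,
                                                   agent = "etomoxir"),
                           noise_sd = config$flux$noise_sd,
                           seed = config$seed)
    metrics <- flux_metrics(eto$traces, percent_change_agent = "etomoxir")
    utils::write.csv(metrics, file.path(out_dir, "flux_metrics.csv"),
                     row.names = FALSE)
    cmp <- group_compare(split(metrics$percent_change, metrics$group))
    list(metrics = metrics, compare = cmp)
  })
  pc_means <- tapply(flux$metrics$percent_change, flux$metrics$group, mean)
  add_check("etomoxir_drop_in_P3_not_P2",
            unname(pc_means["P3"] - pc_means["P2"]),
            pc_means["P3"] < -10 && abs(pc_means["P2"]) < 10)

  # --- report ------------------------------------------------------------
  report <- run_stage("report", {
    rep <- list(
      schema_version = "1.0",
      config = config,
      headline = list(
        n_cells = length(sim$em$obs_ids),
        n_genes = length(sim$em$gene_ids),
        n_spots = length(spatial$sd$em$obs_ids),
        spatial_auc = spatial$auc,
        metabolic_ratio_P2_D10 = metabolic$ratio_p2,
        metabolic_ratio_P3_D10 = metabolic$ratio_p3,
        mean_eta_sq = stats::setNames(
          as.list(metabolic$vp$summary$mean_eta_sq),
          metabolic$vp$summary$factor),
        bmp_edges_P3 = sum(comm$bmp_edges$condition == "P3"),
        bmp_edges_P2 = sum(comm$bmp_edges$condition == "P2"),
        oplsda_r2y = metab$opls$r2y,
        oplsda_q2 = metab$opls$q2),
      checks = checks,
      verdict = if (all(vapply(checks, `[[`, logical(1), "pass")))
        "PASS" else "FAIL")
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- c(sprintf("regenmac pipeline report (seed %d)", config$seed),
             sprintf("verdict: %s", rep$verdict), "",
             vapply(checks, function(ck) {
               sprintf("  [%s] %s = %.6g",
                       if (ck$pass) "ok" else "FAIL", ck$name,
                       as.numeric(ck$value))
             }, character(1)))
    writeLines(txt, file.path(out_dir, "report.txt"))
    rep
  })

  files <- setdiff(list.files(out_dir), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(report)
}
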