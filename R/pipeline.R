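#' Configuration of the end-to-end pipeline
#'
#' Collects the tunables of every stage. The master `seed` derives all
#' stage seeds deterministically, so a rerun with the same inputs and
#' seed reproduces every number.
#'
#' @param clustering_phase phase whose control-group connectivity drives
#'   community detection.
#' @param gamma,n_runs,tau consensus Louvain settings.
#' @param compare_n_perm permutations for the mean-connectivity group
#'   tests.
#' @param nbs_threshold_t primary NBS threshold (`NULL`: two-sided
#'   p = 0.01 t-quantile).
#' @param nbs_n_perm,nbs_alpha NBS permutations and component FWER
#'   level.
#' @param nbs_networks `"auto"` (networks with a significant
#'   within-network deficit; falls back to Network 1) or explicit
#'   community ids.
#' @param entropy_enabled,entropy_phase,entropy_m,entropy_r_factor,entropy_sd_scope,entropy_n_perm
#'   node-wise sample-entropy stage settings.
#' @param mediation_enabled,mediation_phase,mediation_n_boot,mediation_ci,mediation_covariates
#'   mediation stage settings; the mediator is the mean within-Network-1
#'   connectivity in `mediation_phase`.
#' @param alpha significance level for deficit flags.
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(clustering_phase = "maintenance",
                            gamma = 1, n_runs = 100L, tau = 0.5,
                            compare_n_perm = 10000L,
                            nbs_threshold_t = NULL, nbs_n_perm = 5000L,
                            nbs_alpha = 0.05, nbs_networks = "auto",
                            entropy_enabled = TRUE,
                            entropy_phase = "retrieval",
                            entropy_m = 2L, entropy_r_factor = 0.2,
                            entropy_sd_scope = "all_timecourses",
                            entropy_n_perm = 10000L,
                            mediation_enabled = TRUE,
                            mediation_phase = "retrieval",
                            mediation_n_boot = 10000L,
                            mediation_ci = "bca",
                            mediation_covariates = c("age", "sex", "education"),
                            alpha = 0.05,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  cfg <- config
  cfg$parcellation <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full phase-resolved connectivity pipeline
#'
#' Orchestrates the analysis on a loaded or generated cohort:
#' per-subject, per-phase Fisher-z connectivity; data-driven empirical
#' networks from the control group's clustering-phase connectivity
#' (consensus Louvain on the restricted node set); permutation tests of
#' mean within- and between-network connectivity per phase; NBS
#' component inference per phase on the deficit network; node-wise
#' sample-entropy comparison; amyloid-connectivity associations and the
#' mediation of the amyloid-memory effect through network connectivity.
#'
#' @param cohort a `memnet_cohort` (from [generate_cohort()] or
#'   [load_cohort()]), or a [cohort_config()] to simulate from.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @param keep_fc keep the per-subject connectivity matrices on the
#'   returned object.
#' @return object of class `memnet_report`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         keep_fc = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "memnet_cohort"))
  subs <- cohort$subjects
  if (!length(subs)) stop("stage load_cohort: empty cohort")
  parc <- cohort$parcellation
  if (is.null(parc)) stop("stage load_cohort: cohort lacks a parcellation")
  grp <- vapply(subs, `[[`, character(1), "group")
  phases <- names(subs[[1L]]$phases)
  pt <- participants(cohort)
  seed <- as.integer(config$seed)
  message(sprintf("pipeline: %d subjects (%d AD / %d CN), %d nodes, phases: %s",
                  length(subs), sum(grp == "AD"), sum(grp == "CN"),
                  nrow(parc), paste(phases, collapse = ", ")))

  # --- connectivity -------------------------------------------------------
  fc <- lapply(phases, function(ph)
    lapply(subs, function(s) compute_fc(s$phases[[ph]])))
  names(fc) <- phases

  # --- empirical networks -------------------------------------------------
  ctrl_fc <- fc[[config$clustering_phase]][grp == "CN"]
  if (!length(ctrl_fc)) stop("stage community: no control subjects")
  partition <- restrict_and_cluster(ctrl_fc, parc, gamma = config$gamma,
                                    n_runs = config$n_runs, tau = config$tau,
                                    seed = seed + 11L)
  assign <- partition$assignment
  net_ids <- sort(unique(assign))
  message(sprintf("community: %d empirical networks (Q = %.3f), sizes %s",
                  partition$n_communities, partition$modularity_q,
                  paste(table(assign), collapse = "/")))

  # --- mean-connectivity group tests --------------------------------------
  net_nodes <- lapply(net_ids, function(k) names(assign)[assign == k])
  names(net_nodes) <- paste0("N", net_ids)
  mean_fc <- function(ph, a, b = NULL) vapply(fc[[ph]], mean_connectivity,
                                              numeric(1), set_a = a, set_b = b)
  within_tests <- do.call(rbind, lapply(names(net_nodes), function(nm) {
    if (length(net_nodes[[nm]]) < 2L) return(NULL)
    do.call(rbind, lapply(phases, function(ph) {
      v <- mean_fc(ph, net_nodes[[nm]])
      tst <- permutation_mean_test(v[grp == "AD"], v[grp == "CN"],
                                   n_perm = config$compare_n_perm,
                                   seed = seed + 23L)
      data.frame(network = nm, phase = ph, mean_ad = tst$mean_a,
                 mean_cn = tst$mean_b, p = tst$p,
                 deficit = tst$p <= config$alpha && tst$diff < 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs <- if (length(net_nodes) >= 2L) utils::combn(names(net_nodes), 2L) else NULL
  between_tests <- if (!is.null(pairs)) do.call(rbind, lapply(
    seq_len(ncol(pairs)), function(j) {
      do.call(rbind, lapply(phases, function(ph) {
        v <- mean_fc(ph, net_nodes[[pairs[1L, j]]], net_nodes[[pairs[2L, j]]])
        tst <- permutation_mean_test(v[grp == "AD"], v[grp == "CN"],
                                     n_perm = config$compare_n_perm,
                                     seed = seed + 37L)
        data.frame(pair = paste(pairs[, j], collapse = "-"), phase = ph,
                   mean_ad = tst$mean_a, mean_cn = tst$mean_b, p = tst$p,
                   stringsAsFactors = FALSE)
      }))
    })) else NULL

  # --- NBS on the deficit network(s) --------------------------------------
  covars <- pt[, c("age", "sex")]
  if (identical(config$nbs_networks, "auto")) {
    defic <- unique(within_tests$network[within_tests$deficit])
    nbs_nets <- if (length(defic)) defic else "N1"
  } else nbs_nets <- paste0("N", config$nbs_networks)
  nbs_results <- list()
  for (nm in nbs_nets) {
    stacks <- lapply(phases, function(ph) fc_stack(fc[[ph]], net_nodes[[nm]]))
    names(stacks) <- phases
    nbs_results[[nm]] <- lapply(phases, function(ph)
      nbs(stacks[[ph]], grp, covariates = covars,
          threshold_t = config$nbs_threshold_t, n_perm = config$nbs_n_perm,
          alpha = config$nbs_alpha, seed = seed + 53L, phase = ph))
    names(nbs_results[[nm]]) <- phases
  }
  reduced_summary <- do.call(rbind, lapply(names(nbs_results), function(nm) {
    df <- do.call(rbind, lapply(nbs_results[[nm]], count_reduced))
    df$network <- nm
    df
  }))
  rownames(reduced_summary) <- NULL

  # --- cross-phase chi-square on reduced-node counts ----------------------
  chi <- NULL
  first_net <- reduced_summary[reduced_summary$network == nbs_nets[1L], ]
  if (nrow(first_net) >= 2L) {
    cmb <- utils::combn(nrow(first_net), 2L)
    chi <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      i1 <- cmb[1L, j]; i2 <- cmb[2L, j]
      ct <- tryCatch(chi_square_counts(first_net$n_reduced_nodes[i1],
                                       first_net$n_total_nodes[i1],
                                       first_net$n_reduced_nodes[i2],
                                       first_net$n_total_nodes[i2]),
                     error = function(e) NULL)
      if (is.null(ct)) return(NULL)
      data.frame(phase_1 = first_net$phase[i1], phase_2 = first_net$phase[i2],
                 chi2 = ct$chi2, p = ct$p, stringsAsFactors = FALSE)
    }))
  }

  # --- sample entropy -----------------------------------------------------
  entropy <- NULL
  if (isTRUE(config$entropy_enabled)) {
    red_nodes <- nbs_results[[nbs_nets[1L]]][[config$entropy_phase]]$reduced_nodes
    entropy <- entropy_group_compare(
      cohort, phase = config$entropy_phase, nodes = net_nodes[[nbs_nets[1L]]],
      m = config$entropy_m, r_factor = config$entropy_r_factor,
      sd_scope = config$entropy_sd_scope, n_perm = config$entropy_n_perm,
      seed = seed + 71L, reduced_nodes = red_nodes, alpha = config$alpha)
  }

  # --- associations and mediation -----------------------------------------
  assoc <- NULL; mediation <- NULL
  if (isTRUE(config$mediation_enabled)) {
    med_net <- nbs_nets[1L]
    assoc <- do.call(rbind, lapply(phases, function(ph) {
      v <- mean_fc(ph, net_nodes[[med_net]])
      cp <- corr_perm(pt$suvr, v, n_perm = config$compare_n_perm,
                      seed = seed + 89L)
      data.frame(network = med_net, phase = ph, r = cp$r, p = cp$p,
                 stringsAsFactors = FALSE)
    }))
    med_df <- pt
    med_df$net_fc <- mean_fc(config$mediation_phase, net_nodes[[med_net]])
    mediation <- mediate_fc(med_df, treatment = "suvr", mediator = "net_fc",
                            outcome = "memory",
                            covariates = config$mediation_covariates,
                            n_boot = config$mediation_n_boot,
                            seed = seed + 97L, ci = config$mediation_ci)
  }

  provenance <- list(seed = seed, config_hash = config_hash(config),
                     n_subjects = length(subs),
                     n_ad = sum(grp == "AD"), n_cn = sum(grp == "CN"))
  report <- structure(list(partition = partition, net_nodes = net_nodes,
                           within_tests = within_tests,
                           between_tests = between_tests,
                           nbs = nbs_results, reduced_summary = reduced_summary,
                           chi_square = chi, entropy = entropy, assoc = assoc,
                           mediation = mediation, provenance = provenance,
                           fc = if (keep_fc) fc else NULL,
                           config = config),
                      class = "memnet_report")
  if (!is.null(out_dir)) write_report(report, out_dir, parcellation = parc)
  report
}

#' @export
print.memnet_report <- function(x, ...) {
  cat(sprintf("<memnet_report> %d subjects (%d AD / %d CN), seed %d\n",
              x$provenance$n_subjects, x$provenance$n_ad, x$provenance$n_cn,
              x$provenance$seed))
  cat(sprintf("empirical networks: %d (sizes %s), Q = %.3f\n",
              x$partition$n_communities,
              paste(lengths(x$net_nodes), collapse = "/"),
              x$partition$modularity_q))
  cat("\nwithin-network mean connectivity (AD vs CN):\n")
  print(x$within_tests, row.names = FALSE, digits = 3)
  if (!is.null(x$reduced_summary)) {
    cat("\nreduced nodes/edges (NBS):\n")
    print(x$reduced_summary, row.names = FALSE)
  }
  if (!is.null(x$chi_square)) {
    cat("\ncross-phase chi-square on reduced-node counts:\n")
    print(x$chi_square, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$entropy))
    cat(sprintf("\nentropy: %d node(s) with reduced sample entropy in AD\n",
                sum(x$entropy$significant, na.rm = TRUE)))
  if (!is.null(x$mediation)) {
    cat("\nmediation (amyloid -> network connectivity -> memory):\n")
    print(x$mediation)
  }
  invisible(x)
}

report_summary_list <- function(report) {
  rn <- function(df) if (is.null(df)) NULL else {
    rownames(df) <- NULL
    df
  }
  list(provenance = report$provenance,
       networks = lapply(report$net_nodes, length),
       modularity_q = report$partition$modularity_q,
       within_tests = rn(report$within_tests),
       between_tests = rn(report$between_tests),
       reduced_summary = rn(report$reduced_summary),
       chi_square = rn(report$chi_square),
       entropy_reduced_nodes =
         if (is.null(report$entropy)) NULL
         else report$entropy$node_id[which(report$entropy$significant)],
       assoc = rn(report$assoc),
       mediation = if (is.null(report$mediation)) NULL else
         list(acme = report$mediation$acme, ade = report$mediation$ade,
              total = report$mediation$total,
              ci = report$mediation$ci, p = as.list(report$mediation$p)))
}

#' Write the pipeline report artifacts
#'
#' Emits `partition.tsv`, `within_tests.tsv`, `reduced_summary.tsv`,
#' per-phase NBS edge tables, `entropy.tsv` and a machine-readable
#' `summary.json` (which embeds the seed and a config hash). The JSON is
#' byte-identical across reruns with the same inputs and seed.
#'
#' @param report a `memnet_report`.
#' @param out_dir output directory.
#' @param parcellation optional parcellation for the partition table.
#' @export
write_report <- function(report, out_dir, parcellation = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_partition(report$partition, file.path(out_dir, "partition.tsv"),
                  parcellation)
  utils::write.table(report$within_tests,
                     file.path(out_dir, "within_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$reduced_summary,
                     file.path(out_dir, "reduced_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(report$nbs))
    for (ph in names(report$nbs[[nm]]))
      write_nbs(report$nbs[[nm]][[ph]],
                file.path(out_dir, sprintf("nbs_%s_%s_edges.tsv", nm, ph)),
                file.path(out_dir, sprintf("nbs_%s_%s.node", nm, ph)),
                communities = report$partition$assignment)
  if (!is.null(report$entropy))
    utils::write.table(report$entropy, file.path(out_dir, "entropy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_summary_list(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
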