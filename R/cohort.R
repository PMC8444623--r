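#' Default 200-node, seven-network parcellation table
#'
#' A Schaefer-style cortical parcellation: 200 nodes split evenly across
#' hemispheres, each assigned to one of the seven canonical a-priori
#' networks (visual, somatomotor, DAN, VAN, limbic, FPN, DMN). Nodes
#' labelled limbic/DMN/DAN/VAN/FPN form the 136-node restricted set used
#' for data-driven community detection.
#'
#' @param n_nodes total node count; only the default 200 gives the
#'   canonical 136-node restricted set.
#' @return data.frame with columns `node_id`, `a_priori_network`,
#'   `hemisphere`, `in_restricted_set`.
#' @export
default_parcellation <- function(n_nodes = 200L) {
  if (n_nodes != 200L) stop("the default parcellation is defined for 200 nodes")
  # per-hemisphere counts; restricted networks sum to 68 per hemisphere
  per_hemi <- c(visual = 15L, somatomotor = 17L, DAN = 13L, VAN = 11L,
                limbic = 6L, FPN = 13L, DMN = 25L)
  restricted <- c("limbic", "DMN", "DAN", "VAN", "FPN")
  one_hemi <- function(h) {
    net <- rep(names(per_hemi), per_hemi)
    data.frame(node_id = sprintf("%s_%03d", h, seq_along(net)),
               a_priori_network = net,
               hemisphere = h,
               in_restricted_set = net %in% restricted,
               stringsAsFactors = FALSE)
  }
  rbind(one_hemi("LH"), one_hemi("RH"))
}

#' Default planted community partition over the parcellation
#'
#' Three planted communities over the 136 restricted nodes with sizes
#' 56/50/30 (largest first), mimicking the shape of empirical networks
#' found on real maintenance-phase control data; visual and somatomotor
#' nodes form two further communities of their own so that every node
#' belongs to a block.
#'
#' @param parcellation a table from [default_parcellation()].
#' @return named integer vector node_id -> community id.
#' @export
default_planted_partition <- function(parcellation = default_parcellation()) {
  p <- parcellation
  comm <- integer(nrow(p))
  names(comm) <- p$node_id
  restricted <- which(p$in_restricted_set)
  # order restricted nodes DMN, limbic, FPN, DAN, VAN and cut at 56/50/30
  ord <- restricted[order(match(p$a_priori_network[restricted],
                                c("DMN", "limbic", "FPN", "DAN", "VAN")))]
  sizes <- c(56L, 50L, 30L)
  comm[ord] <- rep(1:3, sizes)
  comm[p$a_priori_network == "visual"] <- 4L
  comm[p$a_priori_network == "somatomotor"] <- 5L
  comm
}

#' Block-structured correlation matrix from a planted partition
#'
#' Builds a node-by-node correlation matrix with `within_r` on
#' within-community off-diagonal entries (optionally per community),
#' `between_r` across communities, and a unit diagonal. If the result is
#' not positive semidefinite it is repaired by convex shrinkage toward
#' the identity in steps of 0.05 until the smallest eigenvalue is
#' non-negative; the shrinkage actually applied is recorded in the
#' `"shrinkage"` attribute.
#'
#' @param partition named vector node -> community id.
#' @param within_r within-community correlation; scalar or named vector
#'   keyed by community id.
#' @param between_r between-community correlation (scalar).
#' @param max_steps maximum shrinkage steps before giving up.
#' @return symmetric correlation matrix with node names as dimnames.
#' @export
build_block_covariance <- function(partition, within_r, between_r,
                                   max_steps = 19L) {
  comm <- as.integer(factor(partition))
  ids <- unique(sort(comm))
  n <- length(comm)
  if (any(abs(within_r) >= 1) || abs(between_r) >= 1)
    stop("|within_r| and |between_r| must be < 1")
  wr <- if (length(within_r) == 1L) {
    stats::setNames(rep(within_r, length(ids)), ids)
  } else {
    w <- within_r[as.character(sort(unique(partition)))]
    if (anyNA(w)) stop("within_r must name every community")
    stats::setNames(as.numeric(w), ids)
  }
  S <- matrix(between_r, n, n)
  for (k in ids) {
    members <- comm == k
    S[members, members] <- wr[as.character(k)]
  }
  diag(S) <- 1
  if (!is.null(names(partition))) dimnames(S) <- list(names(partition), names(partition))
  shrink <- 0
  repeat {
    Ss <- (1 - shrink) * S + shrink * diag(n)
    ev <- eigen(Ss, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= -1e-10) break
    shrink <- shrink + 0.05
    if (shrink > max_steps * 0.05) {
      worst <- which.min(vapply(ids, function(k) {
        members <- comm == k
        min(eigen(S[members, members, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values)
      }, numeric(1)))
      stop("covariance not positive semidefinite after maximum shrinkage; ",
           "offending block: community ", ids[worst])
    }
  }
  attr(Ss, "shrinkage") <- shrink
  Ss
}

#' Configuration of the synthetic memory-task cohort
#'
#' Defaults emulate a 36 + 36 patient/control cohort with 200 parcels at
#' TR = 3 s, three memory phases (encoding 100, maintenance 40,
#' retrieval 120 volumes; the 2-minute maintenance delay at TR 3 s is 40
#' volumes), planted block-correlation communities (within r = 0.23,
#' between r = 0.05, the tanh scale of a control within-network Fisher z
#' near 0.236), a patient-group within-community correlation reduction
#' of 0.03 in the maintenance and retrieval phases, five designated
#' low-entropy nodes driven by AR(1) dynamics in patients, and a linear
#' standardized mediation path amyloid -> retrieval connectivity ->
#' memory with coefficients (a, b, c') = (-0.25, 0.2, -0.2), so the true
#' average causal mediation effect is a*b = -0.05.
#'
#' @param n_per_group subjects per group.
#' @param n_nodes number of parcels.
#' @param tr_seconds repetition time.
#' @param phase_lengths named vector of volume counts per phase.
#' @param parcellation parcellation table ([default_parcellation()]).
#' @param planted_partition named node -> community vector.
#' @param within_r,between_r target block correlations.
#' @param ad_within_delta within-community correlation reduction applied
#'   to patient subjects in `ad_deficit_phases`.
#' @param ad_deficit_phases phases carrying the patient deficit.
#' @param entropy_nodes node ids given high-autocorrelation signals in
#'   patients; `NULL` picks the first 5 nodes of planted community 1.
#' @param entropy_phi AR(1) coefficient for those nodes in patients.
#' @param entropy_phases phases in which the patient entropy deficit is
#'   expressed (default: the phases that also carry the connectivity
#'   deficit). Autocorrelation shrinks the correlation estimator's
#'   effective sample size, so confining it to these phases keeps
#'   unaffected phases exactly group-null.
#' @param mediation_coeffs named vector `c(a=, b=, cprime=)` of
#'   standardized path coefficients.
#' @param mediation_phase phase whose within-community correlation
#'   carries the amyloid effect.
#' @param fc_scale correlation-scale displacement per standard deviation
#'   of the structural mediator.
#' @param suvr_mean,suvr_sd length-2 vectors (control, patient) for the
#'   truncated-normal amyloid SUVR draw.
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param edu_mean,edu_sd education years (truncated normal, 6-20).
#' @param seed integer seed; the whole cohort is a deterministic
#'   function of the config including the seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 36L,
                          n_nodes = 200L,
                          tr_seconds = 3,
                          phase_lengths = c(encoding = 100L, maintenance = 40L,
                                            retrieval = 120L),
                          parcellation = default_parcellation(n_nodes),
                          planted_partition = default_planted_partition(parcellation),
                          within_r = 0.23,
                          between_r = 0.05,
                          ad_within_delta = 0.03,
                          ad_deficit_phases = c("maintenance", "retrieval"),
                          entropy_nodes = NULL,
                          entropy_phi = 0.9,
                          entropy_phases = c("maintenance", "retrieval"),
                          mediation_coeffs = c(a = -0.25, b = 0.2, cprime = -0.2),
                          mediation_phase = "retrieval",
                          fc_scale = 0.05,
                          suvr_mean = c(cn = 1.1, ad = 1.4),
                          suvr_sd = c(cn = 0.1, ad = 0.15),
                          age_mean = 69, age_sd = 7, age_range = c(50, 90),
                          edu_mean = 12, edu_sd = 3,
                          seed = 1L) {
  if (any(phase_lengths < 4L))
    stop("every phase must have at least 4 volumes (entropy with m = 2 needs m + 2)")
  if (any(abs(within_r) >= 1) || abs(between_r) >= 1)
    stop("|within_r| and |between_r| must be < 1")
  if (nrow(parcellation) != n_nodes)
    stop("parcellation has ", nrow(parcellation), " rows for n_nodes = ", n_nodes)
  if (length(planted_partition) != n_nodes)
    stop("planted_partition must cover all nodes")
  if (is.null(entropy_nodes))
    entropy_nodes <- names(planted_partition)[planted_partition == 1L][1:5]
  stopifnot(all(entropy_nodes %in% parcellation$node_id))
  cfg <- list(n_per_group = as.integer(n_per_group), n_nodes = as.integer(n_nodes),
              tr_seconds = tr_seconds, phase_lengths = phase_lengths,
              parcellation = parcellation, planted_partition = planted_partition,
              within_r = within_r, between_r = between_r,
              ad_within_delta = ad_within_delta,
              ad_deficit_phases = ad_deficit_phases,
              entropy_nodes = entropy_nodes, entropy_phi = entropy_phi,
              entropy_phases = entropy_phases,
              mediation_coeffs = mediation_coeffs,
              mediation_phase = mediation_phase, fc_scale = fc_scale,
              suvr_mean = suvr_mean, suvr_sd = suvr_sd,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              edu_mean = edu_mean, edu_sd = edu_sd, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic memory-task cohort
#'
#' Draws a seeded cohort under the configured statistical structure:
#' temporally white multivariate Gaussian node signals with planted
#' block correlations; a within-community correlation reduction for the
#' patient group in the designated phases; AR(1) dynamics (predictable,
#' low sample entropy) in the designated entropy nodes of patients; and
#' a linear-Gaussian mediation path in which standardized amyloid SUVR
#' shifts each subject's within-community correlation in the mediation
#' phase, and the standardized memory score is
#' `c' * SUVR_z + b * M_z + noise` where `M_z` is the structural
#' (noise-free) mediator. Ground truth (planted partition, expected
#' group FC, true ACME = a*b, entropy nodes) is emitted alongside and is
#' never consumed by the analysis code.
#'
#' @param config a [cohort_config()].
#' @return object of class `memnet_cohort`: list with `subjects` (each a
#'   list with demographics, SUVR, memory, accuracy and a `phases` list
#'   of [phase_bold]), `truth`, `parcellation` and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  npg <- config$n_per_group
  n_sub <- 2L * npg
  phases <- names(config$phase_lengths)
  cf <- config$mediation_coeffs
  a <- cf[["a"]]; b <- cf[["b"]]; cp <- cf[["cprime"]]

  group <- rep(c("AD", "CN"), each = npg)
  subject <- sprintf("sub-%03d", seq_len(n_sub))

  truth <- list(planted_partition = config$planted_partition,
                entropy_nodes = config$entropy_nodes,
                true_acme = unname(a * b),
                expected_fc = NULL, seed = config$seed)

  if (npg == 0L) {
    cohort <- list(subjects = list(), truth = truth,
                   parcellation = config$parcellation, config = config)
    class(cohort) <- "memnet_cohort"
    return(cohort)
  }

  age <- round(rtrunc_norm(n_sub, config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2]), 1)
  sex <- sample(c("F", "M"), n_sub, replace = TRUE)
  education <- round(rtrunc_norm(n_sub, config$edu_mean, config$edu_sd, 6, 20))
  suvr <- numeric(n_sub)
  is_ad <- group == "AD"
  suvr[is_ad] <- rtrunc_norm(npg, config$suvr_mean[["ad"]],
                             config$suvr_sd[["ad"]], lower = 0)
  suvr[!is_ad] <- rtrunc_norm(npg, config$suvr_mean[["cn"]],
                              config$suvr_sd[["cn"]], lower = 0)
  t_z <- as.numeric(scale(suvr))
  m_z <- a * t_z + sqrt(max(0, 1 - a^2)) * stats::rnorm(n_sub)
  eps_sd <- sqrt(max(0, 1 - b^2 - cp^2 - 2 * a * b * cp))
  memory <- cp * t_z + b * m_z + eps_sd * stats::rnorm(n_sub)
  accuracy <- pmin(1, pmax(0, 0.8 + 0.08 * memory + stats::rnorm(n_sub, 0, 0.05)))

  part <- config$planted_partition
  comm_ids <- sort(unique(part))
  ent_idx <- match(config$entropy_nodes, config$parcellation$node_id)
  phi <- config$entropy_phi

  # expected within-community Fisher z per group and phase (truth bookkeeping)
  exp_fc <- expand.grid(group = c("AD", "CN"), phase = phases,
                        stringsAsFactors = FALSE)
  exp_fc$within_z <- vapply(seq_len(nrow(exp_fc)), function(i) {
    r <- config$within_r -
      if (exp_fc$group[i] == "AD" && exp_fc$phase[i] %in% config$ad_deficit_phases)
        config$ad_within_delta else 0
    atanh(r)
  }, numeric(1))
  truth$expected_fc <- exp_fc

  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    ph_list <- vector("list", length(phases))
    names(ph_list) <- phases
    for (ph in phases) {
      r_w <- config$within_r
      if (is_ad[s] && ph %in% config$ad_deficit_phases)
        r_w <- r_w - config$ad_within_delta
      if (ph == config$mediation_phase)
        r_w <- r_w + config$fc_scale * m_z[s]
      r_w <- max(-0.99, min(0.99, r_w))
      S <- build_block_covariance(part, within_r = r_w,
                                  between_r = config$between_r)
      # order entropy nodes last in the Cholesky factorisation: replacing
      # their own (final) innovation by a unit-variance AR(1) process makes
      # them temporally predictable in patients while every lag-0
      # covariance stays exactly at S, and the shared components driving
      # other nodes remain temporally white
      ord <- c(setdiff(seq_len(config$n_nodes), ent_idx), ent_idx)
      L <- chol(S[ord, ord])
      nv <- config$phase_lengths[[ph]]
      W <- matrix(stats::rnorm(nv * config$n_nodes), nv)
      if (is_ad[s] && length(ent_idx) && ph %in% config$entropy_phases) {
        for (j in config$n_nodes - seq_along(ent_idx) + 1L) {
          x <- W[, j]
          for (t in 2:nv) x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * W[t, j]
          W[, j] <- x
        }
      }
      Z <- matrix(0, nv, config$n_nodes)
      Z[, ord] <- W %*% L  # volumes x nodes
      dat <- t(Z)
      rownames(dat) <- config$parcellation$node_id
      ph_list[[ph]] <- phase_bold(dat, phase = ph,
                                  tr_seconds = config$tr_seconds,
                                  subject = subject[s])
    }
    subjects[[s]] <- list(subject = subject[s], group = group[s],
                          age = age[s], sex = sex[s],
                          education = education[s], suvr = suvr[s],
                          memory = memory[s], accuracy = accuracy[s],
                          phases = ph_list)
  }
  cohort <- list(subjects = subjects, truth = truth,
                 parcellation = config$parcellation, config = config)
  class(cohort) <- "memnet_cohort"
  cohort
}

#' @export
print.memnet_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("<memnet_cohort> %d subjects (%d AD, %d CN), %d nodes, phases: %s\n",
              length(x$subjects), sum(grp == "AD"), sum(grp == "CN"),
              x$config$n_nodes,
              paste(names(x$config$phase_lengths), collapse = ", ")))
  invisible(x)
}

#' Participant table of a cohort
#'
#' @param cohort a `memnet_cohort` (or a list of subject records).
#' @return data.frame with one row per subject: subject, group, age,
#'   sex, education, suvr, memory, accuracy.
#' @export
participants <- function(cohort) {
  subs <- if (inherits(cohort, "memnet_cohort")) cohort$subjects else cohort
  do.call(rbind, lapply(subs, function(s)
    data.frame(subject = s$subject, group = s$group, age = s$age, sex = s$sex,
               education = s$education, suvr = s$suvr, memory = s$memory,
               accuracy = s$accuracy, stringsAsFactors = FALSE)))
}
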