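# Seeded cohort simulator: block-structured population covariance over the
# five modeled networks, Gaussian time series per subject, empirical Pearson
# correlations. The atypical group's population covariance perturbs the
# within-network correlations of designated "hub" ROIs, giving a ground truth
# the explanation stage can be checked against.

#' Configuration for the synthetic connectivity cohort
#'
#' The defaults emulate the scale of a community pediatric resting-state
#' cohort: ~180 imaging volumes per subject, 377 neurotypical and 126
#' neuroatypical participants, and five network blocks whose smallest has 24
#' ROIs (hence 276 within-network features). Within-network correlations are
#' stronger than between-network ones; atypical subjects have the
#' within-network correlations of the first `ceil(hub_fraction * n)` ROIs of
#' each network shifted by `perturbation_delta`.
#'
#' @param network_sizes Named integer vector: ROI count per RSBFN (names must
#'   be the five canonical names, see [RSBFN_NAMES]).
#' @param n_typical,n_atypical,n_unlabeled Cohort sizes per group.
#' @param timepoints Time-series length per subject (imaging volumes).
#' @param within_r Population correlation inside a network block.
#' @param between_r Population correlation between networks.
#' @param hub_fraction Fraction of each network's ROIs designated hubs.
#' @param perturbation_delta Additive shift of hub within-network population
#'   correlations in the atypical group (negative = dysconnectivity).
#' @param seed Integer seed controlling the whole simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(network_sizes = c(Default = 40, DorsalAttn = 30,
                                         VentralAttn = 24,
                                         FrontoParietal = 26, "CO+SN" = 28),
                       n_typical = 377, n_atypical = 126, n_unlabeled = 0,
                       timepoints = 180,
                       within_r = 0.35, between_r = 0.10,
                       hub_fraction = 0.2, perturbation_delta = -0.3,
                       seed = 1L) {
  if (is.null(names(network_sizes)) || any(!nzchar(names(network_sizes))))
    stop("`network_sizes` must be a named vector", call. = FALSE)
  if (any(network_sizes < 1)) stop("network sizes must be >= 1",
                                   call. = FALSE)
  if (abs(within_r) >= 1 || abs(between_r) >= 1)
    stop("|within_r| and |between_r| must be < 1", call. = FALSE)
  if (hub_fraction < 0 || hub_fraction > 1)
    stop("hub_fraction must lie in [0, 1]", call. = FALSE)
  cfg <- structure(list(network_sizes = network_sizes,
                        n_typical = n_typical, n_atypical = n_atypical,
                        n_unlabeled = n_unlabeled, timepoints = timepoints,
                        within_r = within_r, between_r = between_r,
                        hub_fraction = hub_fraction,
                        perturbation_delta = perturbation_delta,
                        seed = as.integer(seed)),
                   class = "sim_config")
  # fail early if the implied population covariance is not positive definite
  build_typical_covariance(cfg)
  cfg
}

#' Population covariance of the typical group
#'
#' Block-compound-symmetric correlation matrix: `within_r` inside each
#' network block, `between_r` elsewhere, unit variances.
#'
#' @param cfg A [sim_config()].
#' @return List with `cov` (p x p matrix) and `parcellation`.
#' @export
build_typical_covariance <- function(cfg) {
  sizes <- cfg$network_sizes
  nets <- rep(names(sizes), times = sizes)
  p <- sum(sizes)
  roi_ids <- unlist(lapply(names(sizes), function(nm)
    sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", nm), seq_len(sizes[[nm]]))))
  cov <- matrix(cfg$between_r, p, p)
  same <- outer(nets, nets, `==`)
  cov[same] <- cfg$within_r
  diag(cov) <- 1
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(paste0("population covariance is not positive definite ",
                        "(min eigenvalue %.3g); reduce |within_r| or ",
                        "|between_r|"), min(ev)), call. = FALSE)
  list(cov = cov, parcellation = parcellation(roi_ids, nets))
}

# Nearest-PD repair: floor eigenvalues at `floor`, rebuild, renormalize to
# unit diagonal so the perturbation ground truth stays approximately as
# configured.
repair_pd <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) > 0) return(m)
  v <- pmax(e$values, floor)
  m2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor((m2 + t(m2)) / 2)
}

#' Perturb hub ROIs to build the atypical population covariance
#'
#' For each network, the first `ceil(hub_fraction * n)` ROIs are designated
#' hubs; every within-network correlation involving a hub is shifted by
#' `perturbation_delta` (clipped to (-0.99, 0.99) with a warning if the shift
#' would leave the correlation range). The result is re-projected to the
#' nearest positive-definite correlation matrix if needed.
#'
#' @param cov Typical-group covariance from [build_typical_covariance()].
#' @param parc The matching `parcellation`.
#' @param cfg The [sim_config()].
#' @return List with `cov` (atypical covariance) and `hubs` (character vector
#'   of ground-truth hub roi_ids).
#' @export
perturb_hubs <- function(cov, parc, cfg) {
  nets <- parc$network
  p <- nrow(cov)
  hub <- logical(p)
  for (nm in unique(nets)) {
    idx <- which(nets == nm)
    n_hub <- ceiling(cfg$hub_fraction * length(idx))
    if (n_hub > 0) hub[idx[seq_len(n_hub)]] <- TRUE
  }
  out <- cov
  same <- outer(nets, nets, `==`)
  touched <- (outer(hub, rep(TRUE, p), `&`) | outer(rep(TRUE, p), hub, `&`)) &
    same & row(cov) != col(cov)
  out[touched] <- out[touched] + cfg$perturbation_delta
  if (any(abs(out[touched]) >= 1)) {
    warning("perturbation pushed |r| >= 1; clipping to +/-0.99")
    out[touched] <- pmin(pmax(out[touched], -0.99), 0.99)
  }
  out <- repair_pd(out)
  list(cov = out, hubs = parc$roi_id[hub])
}

# Draw one subject's empirical correlation matrix: timepoints x p Gaussian
# series with population covariance given by its Cholesky factor.
draw_correlation <- function(chol_upper, timepoints) {
  p <- ncol(chol_upper)
  z <- matrix(stats::rnorm(timepoints * p), timepoints, p)
  stats::cor(z %*% chol_upper)
}

#' Simulate a typical/atypical connectivity cohort
#'
#' Draws, for every subject, a Gaussian multivariate time series from the
#' group's population covariance, computes the empirical Pearson correlation
#' matrix, and returns raw-r connectivity matrices with cohort and
#' parcellation tables plus the hub ground truth. Fully reproducible given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `matrices` (named list of
#'   `connectivity_matrix`, state raw-r), `cohort` (a `cohort_table`),
#'   `parcellation`, `hubs` (ground-truth hub roi_ids), and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  typ <- build_typical_covariance(cfg)
  aty <- perturb_hubs(typ$cov, typ$parcellation, cfg)
  p <- nrow(typ$cov)
  if (cfg$timepoints <= p)
    warning(sprintf(paste0("timepoints (%d) <= n_rois (%d): empirical ",
                           "correlation matrices are rank deficient"),
                    cfg$timepoints, p))
  ids <- c(sprintf("typ%04d", seq_len(cfg$n_typical)),
           sprintf("atyp%04d", seq_len(cfg$n_atypical)),
           if (cfg$n_unlabeled > 0) sprintf("unl%04d",
                                            seq_len(cfg$n_unlabeled)))
  groups <- c(rep("neurotypical", cfg$n_typical),
              rep("neuroatypical", cfg$n_atypical),
              rep("unlabeled", cfg$n_unlabeled))
  ch_typ <- chol(typ$cov)
  ch_aty <- chol(aty$cov)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  mats <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ch <- if (groups[i] == "neuroatypical") ch_aty else ch_typ
    r <- draw_correlation(ch, cfg$timepoints)
    dimnames(r) <- NULL
    mats[[i]] <- connectivity_matrix(r, ids[i], state = "raw-r")
  }
  names(mats) <- ids
  list(matrices = mats,
       cohort = cohort_table(ids, groups),
       parcellation = typ$parcellation,
       hubs = aty$hubs,
       config = cfg)
}
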