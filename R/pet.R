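centiloid_coefs <- function() {
  # tracer-specific linear SUVR -> Centiloid maps (published calibrations,
  # SUVR windows 40-60 / 50-70 / 90-110 min post-injection respectively)
  list(
    PiB         = c(slope = 132.53, intercept = -147.64),
    NAV4694     = c(slope = 107.78, intercept = -114.71),
    florbetaben = c(slope = 147.00, intercept = -166.50)
  )
}

#' Convert an amyloid SUVR to the Centiloid scale
#'
#' Exact tracer-specific linear maps: `CL = slope * SUVR + intercept` with
#' the published coefficients for 11C-PiB, 18F-NAV4694 and 18F-florbetaben.
#'
#' @param suvr Standardized uptake value ratio (> 0); vectorised.
#' @param tracer One of `"PiB"`, `"NAV4694"`, `"florbetaben"`
#'   (case-insensitive).
#' @return Centiloid value(s).
#' @examples
#' suvr_to_centiloid(1.0, "PiB")      # -15.11
#' suvr_to_centiloid(2.0, "florbetaben")  # 127.5
#' @export
suvr_to_centiloid <- function(suvr, tracer) {
  coefs <- centiloid_coefs()
  key <- match(tolower(tracer), tolower(names(coefs)))
  if (anyNA(key)) {
    stop("unknown tracer '", tracer[which(is.na(key))[1]],
         "'; supported: ", paste(names(coefs), collapse = ", "))
  }
  if (any(suvr <= 0)) stop("suvr must be > 0")
  if (length(key) == 1) key <- rep(key, length(suvr))
  slopes <- vapply(key, function(i) coefs[[i]]["slope"], 0)
  inters <- vapply(key, function(i) coefs[[i]]["intercept"], 0)
  unname(slopes * suvr + inters)
}

#' Binary amyloid classification on the Centiloid scale
#'
#' Positive iff `cl > cutoff`; the boundary value itself classifies negative
#' (documented tie rule; CL is continuous so ties are measure-zero).
#'
#' @param cl Centiloid value(s).
#' @param cutoff Pathologically validated positivity cut-off (default 23.5).
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_amyloid <- function(cl, cutoff = 23.5) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  ifelse(cl > cutoff, "positive", "negative")
}

#' Composite volume-of-interest definitions
#'
#' The early metaVOI covers the earliest tau-vulnerable medial temporal
#' territory (entorhinal, perirhinal, caudal + rostral hippocampus,
#' lateral + medial parahippocampus, fusiform); the neocortical VOI covers
#' inferior/lateral temporal and inferior/medial parietal cortex.
#'
#' @param name `"early_metaVOI"`, `"neocortical_VOI"`, `"hippocampus"`,
#'   `"parahippocampus"`, or a single region name.
#' @return List with `name` and `members` (region labels).
#' @export
voi_definition <- function(name) {
  members <- switch(
    name,
    early_metaVOI = c("entorhinal", "perirhinal", "hippocampus_caudal",
                      "hippocampus_rostral", "parahippocampus_lateral",
                      "parahippocampus_medial", "fusiform"),
    neocortical_VOI = c("temporal_inferior", "temporal_lateral",
                        "parietal_inferior", "parietal_medial"),
    hippocampus = c("hippocampus_caudal", "hippocampus_rostral"),
    parahippocampus = c("parahippocampus_lateral", "parahippocampus_medial"),
    name)
  list(name = name, members = members)
}

#' Default relative region sizes for synthetic VOI aggregation
#'
#' Plausible relative voxel counts per Brainnetome-style region, used by the
#' synthetic cohort; real voxel counts are user-supplied with the tau table.
#'
#' @return Named integer vector of voxel counts.
#' @export
default_voxel_counts <- function() {
  c(entorhinal = 450L, perirhinal = 400L,
    hippocampus_caudal = 450L, hippocampus_rostral = 500L,
    parahippocampus_lateral = 380L, parahippocampus_medial = 350L,
    fusiform = 900L,
    temporal_inferior = 1200L, temporal_lateral = 1400L,
    parietal_inferior = 1300L, parietal_medial = 1100L)
}

#' Voxel-count-weighted VOI aggregation of regional tau values
#'
#' \eqn{DVR_{VOI} = \sum_r DVR_r v_r / \sum_r v_r} over the member regions.
#'
#' @param regions A `data.frame` with columns `region`, `dvr`, `voxel_count`.
#' @param voi A [voi_definition()] (or list with `name`, `members`).
#' @return The aggregated DVR (scalar).
#' @export
aggregate_voi <- function(regions, voi) {
  stopifnot(is.data.frame(regions),
            all(c("region", "dvr", "voxel_count") %in% names(regions)))
  idx <- match(voi$members, regions$region)
  if (anyNA(idx)) {
    stop("missing member region(s) for ", voi$name, ": ",
         paste(voi$members[is.na(idx)], collapse = ", "))
  }
  dvr <- regions$dvr[idx]
  v <- regions$voxel_count[idx]
  if (any(v < 0)) stop("voxel counts must be nonnegative")
  if (sum(v) == 0) stop("all voxel counts zero in ", voi$name)
  sum(dvr * v) / sum(v)
}

#' Normative tau-positivity threshold: mean + 1 SD of a reference sample
#'
#' The threshold is the arithmetic mean plus one sample standard deviation
#' (n-1 denominator) of the amyloid-negative cognitively unimpaired reference
#' values; the reference sample size is recorded in the `"n"` attribute.
#'
#' @param cu_neg_dvr Numeric vector of reference DVR values (n >= 2).
#' @return Threshold (scalar) with attributes `n`, `mean`, `sd`.
#' @export
tau_positivity_threshold <- function(cu_neg_dvr) {
  cu_neg_dvr <- cu_neg_dvr[!is.na(cu_neg_dvr)]
  if (length(cu_neg_dvr) < 2) stop("need at least 2 reference values")
  m <- mean(cu_neg_dvr); s <- stats::sd(cu_neg_dvr)
  structure(m + s, n = length(cu_neg_dvr), mean = m, sd = s)
}

#' Binary tau classification against a normative threshold
#'
#' Positive iff `dvr > threshold` (tie classifies negative).
#'
#' @param dvr DVR value(s).
#' @param threshold Normative threshold from [tau_positivity_threshold()].
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_tau <- function(dvr, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  ifelse(dvr > as.numeric(threshold), "positive", "negative")
}

#' Per-subject PET summary table
#'
#' Joins the amyloid table (subject_id, tracer, suvr) and the long tau table
#' (subject_id, region, dvr, voxel_count) into one row per subject with
#' Centiloid, amyloid status, composite-VOI DVRs, per-region DVRs and tau
#' positivity calls for the early metaVOI and neocortical VOI.
#'
#' @param amyloid `data.frame(subject_id, tracer, suvr)`.
#' @param tau `data.frame(subject_id, region, dvr, voxel_count)`.
#' @param cl_cutoff Amyloid positivity cut-off in Centiloid (default 23.5).
#' @param tau_thresholds Optional named list with `early_metaVOI` and
#'   `neocortical_VOI` thresholds; when `NULL` the tau status columns are
#'   omitted (thresholds require a reference sample, see
#'   [tau_positivity_threshold()]).
#' @return One row per subject.
#' @export
pet_summary <- function(amyloid, tau, cl_cutoff = 23.5,
                        tau_thresholds = NULL) {
  cl <- suvr_to_centiloid(amyloid$suvr, amyloid$tracer)
  out <- data.frame(subject_id = amyloid$subject_id,
                    cl = cl,
                    amyloid_status = classify_amyloid(cl, cl_cutoff),
                    stringsAsFactors = FALSE)
  regions <- unique(tau$region)
  per_subj <- split(tau, tau$subject_id)
  voi_early <- voi_definition("early_metaVOI")
  voi_neo <- voi_definition("neocortical_VOI")
  agg <- lapply(per_subj, function(d) {
    row <- as.list(stats::setNames(d$dvr[match(regions, d$region)],
                                   paste0("tau_", regions)))
    row$dvr_early_metaVOI <- aggregate_voi(d, voi_early)
    row$dvr_neocortical <- aggregate_voi(d, voi_neo)
    as.data.frame(row)
  })
  agg <- do.call(rbind, agg)
  agg$subject_id <- names(per_subj)
  out <- merge(out, agg, by = "subject_id", sort = FALSE)
  if (!is.null(tau_thresholds)) {
    out$tau_status_early <- classify_tau(out$dvr_early_metaVOI,
                                         tau_thresholds$early_metaVOI)
    out$tau_status_neocortical <- classify_tau(out$dvr_neocortical,
                                               tau_thresholds$neocortical_VOI)
  }
  out
}
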