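#' Region vocabulary
#'
#' Fixed region names: whole brain, gray matter, white matter, and the seven
#' cortical regions (cingulate gyrus, juxtapositional lobule cortex,
#' paracingulate gyrus, frontal pole, middle frontal gyrus, precentral
#' gyrus, postcentral gyrus).
#' @return Character vector of the ten region names.
#' @export
region_names <- function() {
  c("WholeBrain", "GM", "WM",
    "CG", "JLC", "ParaG", "FP", "MFG", "PreG", "PostG")
}

# label codes of the seven cortical patches, in region_names() order
region_label_codes <- function() {
  stats::setNames(3:9, region_names()[-(1:3)])
}

#' Cohort configuration
#'
#' Study design for the synthetic cohort: two groups recruited one female
#' and one male per age decade (20-69), with one smoker's data unusable,
#' giving 10 non-smokers and 9 usable smokers. Per-subject regional
#' glutamate is
#' `base + group_effect + age_slope * (age - 45) + N(0, subject_sd)`.
#'
#' @param n_per_group Subjects recruited per group.
#' @param n_unusable_smokers Smokers excluded for artifacts.
#' @param group_effect_mM Glutamate offset (mM) added for smokers; scalar or
#'   named per-region vector.
#' @param age_slope_ns,age_slope_s Glutamate-vs-age slope (mM/year) for
#'   non-smokers / smokers; scalar or named per-region vector.
#' @param subject_sd_mM Between-subject glutamate SD (mM).
#' @param phantom A [phantom_config()] shared by all subjects (its regional
#'   glutamate entries are overridden per subject).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10, n_unusable_smokers = 1,
                          group_effect_mM = 0,
                          age_slope_ns = 0, age_slope_s = 0,
                          subject_sd_mM = 0.5,
                          phantom = phantom_config()) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (n_unusable_smokers < 0 || n_unusable_smokers >= n_per_group)
    stop("n_unusable_smokers must be in [0, n_per_group)", call. = FALSE)
  structure(list(n_per_group = n_per_group,
                 n_unusable_smokers = n_unusable_smokers,
                 group_effect_mM = group_effect_mM,
                 age_slope_ns = age_slope_ns, age_slope_s = age_slope_s,
                 subject_sd_mM = subject_sd_mM, phantom = phantom),
            class = "cohort_config")
}

# expand a scalar-or-named-vector effect to the 9 tissue/region entries
# (GM, WM, then the 7 patches)
.expand_effect <- function(x) {
  regions <- region_names()[-1]
  out <- stats::setNames(rep(0, length(regions)), regions)
  if (length(x) == 1L && is.null(names(x))) {
    out[] <- x
  } else {
    bad <- setdiff(names(x), regions)
    if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    out[names(x)] <- x
  }
  out
}

#' Generate a synthetic study cohort
#'
#' Draws the subject manifest (group, age, sex, per-subject seed) following
#' the one-female-and-one-male-per-decade recruitment rule, marks
#' `n_unusable_smokers` randomly chosen smokers unusable, and assigns each
#' usable subject its true regional glutamate levels. Phantom images are
#' generated lazily by [cohort_phantom()] so replicate studies can share
#' a dictionary engine.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for the cohort draw.
#' @return List with `manifest` (data.frame: subject_id, group, age, sex,
#'   seed, usable) and `glu_truth` (usable-subject rows x 9 region columns
#'   of true glutamate, mM).
#' @export
make_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  decades <- seq(20, 60, by = 10)
  n_dec <- length(decades)
  draw_group <- function(group, offset) {
    n <- config$n_per_group
    # cycle decade x sex cells so each decade gets one F and one M when
    # n_per_group == 2 * n_dec (the default design)
    cells <- expand.grid(sex = c("F", "M"), decade = decades,
                         stringsAsFactors = FALSE)
    idx <- rep_len(seq_len(nrow(cells)), n)
    data.frame(
      subject_id = sprintf("%s%02d", if (group == "smoker") "S" else "NS",
                           seq_len(n)),
      group = group,
      age = cells$decade[idx] + sample(0:9, n, replace = TRUE),
      sex = cells$sex[idx],
      seed = offset + sample.int(1e6, n),
      stringsAsFactors = FALSE
    )
  }
  ns <- draw_group("non-smoker", 0L)
  sm <- draw_group("smoker", 2e6L)
  sm$usable <- TRUE
  if (config$n_unusable_smokers > 0)
    sm$usable[sample.int(nrow(sm), config$n_unusable_smokers)] <- FALSE
  ns$usable <- TRUE
  manifest <- rbind(ns, sm)

  base <- c(GM = config$phantom$glu_gm, WM = config$phantom$glu_wm,
            config$phantom$glu_regions)
  geff <- .expand_effect(config$group_effect_mM)
  slope_ns <- .expand_effect(config$age_slope_ns)
  slope_s <- .expand_effect(config$age_slope_s)

  usable <- manifest[manifest$usable, ]
  glu <- matrix(NA_real_, nrow(usable), length(base),
                dimnames = list(usable$subject_id, names(base)))
  for (i in seq_len(nrow(usable))) {
    smoker <- usable$group[i] == "smoker"
    slope <- if (smoker) slope_s else slope_ns
    mu <- base + (if (smoker) geff else 0) + slope * (usable$age[i] - 45)
    glu[i, ] <- pmax(0, mu + stats::rnorm(length(base), 0, config$subject_sd_mM))
  }
  list(manifest = manifest, glu_truth = glu, config = config)
}

#' Phantom acquisition for one cohort subject
#'
#' @param cohort Output of [make_cohort()].
#' @param subject_id A usable subject's id.
#' @inheritParams make_phantom
#' @return A [make_phantom()] bundle for that subject.
#' @export
cohort_phantom <- function(cohort, subject_id, pools = pool_system(),
                           cest_sat = cest_scheme(), wassr_sat = wassr_scheme(),
                           engine = c("exact", "dictionary"), dicts = NULL) {
  engine <- match.arg(engine)
  row <- cohort$manifest[cohort$manifest$subject_id == subject_id, ]
  if (nrow(row) != 1L || !row$usable)
    stop("unknown or unusable subject: ", subject_id, call. = FALSE)
  g <- cohort$glu_truth[subject_id, ]
  cfg <- cohort$config$phantom
  cfg$glu_gm <- g[["GM"]]
  cfg$glu_wm <- g[["WM"]]
  cfg$glu_regions[] <- g[names(cfg$glu_regions)]
  make_phantom(cfg, pools, cest_sat, wassr_sat, seed = row$seed,
               engine = engine, dicts = dicts)
}
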