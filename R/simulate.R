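#' Specify a synthetic cohort design
#'
#' Describes a two-group cohort (controls vs. patients) of regional
#' grey-matter voxel-value sets. Each of the 90 regions draws its voxels
#' from a two-component Gaussian mixture truncated at zero; regions are
#' organized into six communities sharing mixture parameters (plus a
#' small per-region jitter), so that distribution-shape similarity — and
#' hence the KLS network — has a modular structure. The patient group
#' receives a planted effect in a chosen region set, scaled per subject
#' by a latent severity factor that also drives the UPDRS-III score, so
#' clinical correlations downstream have a known sign.
#'
#' @param n_per_group subjects per group (default 20).
#' @param voxels_per_region voxels drawn per region (default 300, min 30).
#' @param effect_regions integer indices (1-90) of the affected regions;
#'   defaults to a sensorimotor-analog set (bilateral pre/postcentral
#'   gyri and supplementary motor areas).
#' @param effect_magnitude non-negative scalar controlling the planted
#'   effect strength; 0 makes the groups statistically exchangeable.
#' @param effect_mode `"cohere"` pulls affected regions' mixture
#'   parameters toward a shared target (raising their mutual similarity
#'   and hence local clustering in patients), `"disperse"` pushes them
#'   apart (weakening within-set edges), `"shift"` translates them by a
#'   common offset.
#' @param clinical_link list with elements `region` (index), `metric`
#'   (nodal metric name, informational), `slope` and `noise_sd` tying
#'   patients' UPDRS-III to the latent severity factor.
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   cohorts.
#' @return an object of class `simulation_design` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_design <- function(n_per_group = 20L,
                              voxels_per_region = 300L,
                              effect_regions = sensorimotor_regions(),
                              effect_magnitude = 1,
                              effect_mode = c("cohere", "disperse", "shift"),
                              clinical_link = list(region = 58L,
                                                   metric = "efficiency",
                                                   slope = 20,
                                                   noise_sd = 4),
                              seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  if (!is.numeric(n_per_group) || n_per_group < 1)
    stop("invalid design: n_per_group must be a positive count")
  if (!is.numeric(voxels_per_region) || voxels_per_region < 30)
    stop("invalid design: voxels_per_region must be >= 30")
  if (length(effect_regions) &&
      (any(effect_regions < 1) || any(effect_regions > 90)))
    stop("invalid design: effect_regions must lie in 1..90")
  if (effect_magnitude < 0)
    stop("invalid design: effect_magnitude must be >= 0")
  if (!is.null(clinical_link$noise_sd) && clinical_link$noise_sd <= 0)
    stop("invalid design: clinical_link noise_sd must be > 0")
  structure(list(
    n_per_group       = as.integer(n_per_group),
    voxels_per_region = as.integer(voxels_per_region),
    effect_regions    = as.integer(sort(unique(effect_regions))),
    effect_magnitude  = effect_magnitude,
    effect_mode       = effect_mode,
    clinical_link     = clinical_link,
    seed              = as.integer(seed)),
    class = "simulation_design")
}

#' Read / write a simulation design as JSON
#' @param design a [simulation_design()] object.
#' @param path file path.
#' @return `read_design` returns a `simulation_design`;
#'   `write_design` returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "simulation_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulation_design, x)
}

# per-region base mixture parameters shared within six communities of 15
# regions; jitter differentiates regions within a community
region_base_params <- function() {
  comm <- rep(1:6, each = 15L)
  mu1 <- 0.25 + 0.08 * (comm - 1)
  list(community = comm,
       mu1 = mu1, mu2 = mu1 + 0.18,
       sd1 = rep(0.08, 90), sd2 = rep(0.12, 90),
       w1 = rep(0.6, 90))
}

# draw one region's voxel bag from its truncated two-component mixture
draw_region_values <- function(n, mu1, mu2, sd1, sd2, w1) {
  k <- rbinom(n, 1L, w1)
  v <- ifelse(k == 1L, rnorm(n, mu1, sd1), rnorm(n, mu2, sd2))
  abs(v)  # reflect the rare negative draw back into the support
}

#' Simulate a two-group cohort of regional voxel-value sets
#'
#' Generates `2 * n_per_group` subjects; the first half are controls,
#' the second half patients. Region-level jitter is drawn once per
#' cohort (both groups share base parameters); each subject additionally
#' gets small random perturbations of region means and spreads. Patients
#' receive the design's planted effect scaled by a per-subject severity
#' factor uniform on \[0.5, 1.5\]; their UPDRS-III score is
#' `slope * severity + noise`, so downstream correlations between
#' severity-driven network changes and UPDRS-III have a known sign.
#'
#' @param design a [simulation_design()].
#' @return a list with components `subjects` (list of per-subject lists
#'   with `subject_id`, `region_values` — 90 numeric vectors — and
#'   `region_labels`) and `meta` (a data.frame of subject metadata:
#'   group, subtype, age, gender, education, updrs3, hoehn_yahr, mmse,
#'   severity), of class `morph_cohort`.
#' @examples
#' co <- simulate_cohort(simulation_design(n_per_group = 2,
#'                                         voxels_per_region = 50))
#' length(co$subjects); table(co$meta$group)
#' @export
simulate_cohort <- function(design) {
  if (!inherits(design, "simulation_design"))
    design <- do.call(simulation_design, design)
  set.seed(design$seed)
  n <- design$n_per_group
  vpr <- design$voxels_per_region
  base <- region_base_params()

  # cohort-level region jitter (shared by both groups); its scale is
  # comparable to the mixture component SDs, so within-community
  # similarity is high but far from saturated
  jit1 <- rnorm(90, 0, 0.05)
  jit2 <- rnorm(90, 0, 0.05)
  mu1 <- base$mu1 + jit1
  mu2 <- base$mu2 + jit2

  eff <- design$effect_regions
  mag <- design$effect_magnitude
  # "cohere" targets: each affected region's community base parameters,
  # so the planted effect strengthens within-module similarity (regions
  # of one community collapse onto a shared distribution shape)
  t1 <- base$mu1[eff]
  t2 <- base$mu2[eff]
  # symmetric per-region offsets for the "disperse" mode
  disp <- if (length(eff)) seq(-1, 1, length.out = length(eff)) else numeric()

  n_tot <- 2L * n
  group <- rep(c("control", "patient"), each = n)
  severity <- runif(n_tot, 0.5, 1.5)

  subjects <- vector("list", n_tot)
  for (s in seq_len(n_tot)) {
    m1 <- mu1 + rnorm(90, 0, 0.01)
    m2 <- mu2 + rnorm(90, 0, 0.01)
    s1 <- base$sd1 * exp(rnorm(90, 0, 0.05))
    s2 <- base$sd2 * exp(rnorm(90, 0, 0.05))
    if (group[s] == "patient" && length(eff) && mag > 0) {
      a <- min(1, mag * severity[s])
      if (design$effect_mode == "cohere") {
        m1[eff] <- (1 - a) * m1[eff] + a * t1
        m2[eff] <- (1 - a) * m2[eff] + a * t2
        # subject-level noise is damped the same way, so strongly
        # affected subjects' module regions become near-identical
        s1[eff] <- (1 - a) * s1[eff] + a * 0.08
        s2[eff] <- (1 - a) * s2[eff] + a * 0.12
      } else if (design$effect_mode == "disperse") {
        m1[eff] <- m1[eff] + 0.06 * a * disp
        m2[eff] <- m2[eff] + 0.06 * a * disp
      } else {  # shift
        m1[eff] <- m1[eff] + 0.05 * a
        m2[eff] <- m2[eff] + 0.05 * a
      }
    }
    vals <- lapply(seq_len(90), function(r)
      draw_region_values(vpr, m1[r], m2[r], s1[r], s2[r], base$w1[r]))
    subjects[[s]] <- list(subject_id = sprintf("sub-%03d", s),
                          region_values = vals,
                          region_labels = aal90_labels())
  }

  link <- design$clinical_link
  updrs3 <- ifelse(group == "patient",
                   pmin(108, pmax(0, link$slope * severity +
                                    rnorm(n_tot, 0, link$noise_sd))),
                   pmin(108, pmax(0, rnorm(n_tot, 1, 1))))
  hy <- ifelse(group == "patient",
               pmin(5, pmax(0.5, round(severity * 3) / 2)), 0)
  subtype <- ifelse(group == "control", "none",
                    sample(c("tremor", "akinetic_rigid", "mixed"),
                           n_tot, TRUE, prob = c(0.4, 0.4, 0.2)))
  meta <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n_tot)),
    group = group,
    subtype = subtype,
    age = round(pmin(85, pmax(40, rnorm(n_tot, 60, 8)))),
    gender = rbinom(n_tot, 1L, 0.5),
    education = round(pmin(22, pmax(3, rnorm(n_tot, 10, 3)))),
    updrs3 = round(updrs3, 1),
    hoehn_yahr = hy,
    mmse = round(pmin(30, pmax(24, rnorm(n_tot, 28.5, 1.2)))),
    severity = severity,
    stringsAsFactors = FALSE)

  structure(list(subjects = subjects, meta = meta, design = design),
            class = "morph_cohort")
}

#' @export
print.morph_cohort <- function(x, ...) {
  cat("Synthetic morphological cohort\n")
  cat(sprintf("  %d subjects (%d control / %d patient), %d regions, %d voxels/region\n",
              length(x$subjects), sum(x$meta$group == "control"),
              sum(x$meta$group == "patient"), 90L,
              x$design$voxels_per_region))
  if (length(x$design$effect_regions) && x$design$effect_magnitude > 0)
    cat(sprintf("  planted %s effect (magnitude %.2f) in: %s\n",
                x$design$effect_mode, x$design$effect_magnitude,
                paste(aal90_abbrev()[x$design$effect_regions],
                      collapse = ", ")))
  invisible(x)
}
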