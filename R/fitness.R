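#' Nectar energy model
#'
#' The artificial nectar reward: volume, sucrose concentration (% w/v,
#' i.e. grams of sucrose per 100 mL of solution) and the energy density of
#' sucrose.
#'
#' @param volume_ul Reward volume in microlitres (default 20).
#' @param concentration_pct Sucrose concentration, % w/v (default 20).
#' @param energy_density_kj_g Energy density of sucrose, kJ/g (default 16.2).
#' @return An `energy_model` list.
#' @export
energy_model <- function(volume_ul = 20, concentration_pct = 20,
                         energy_density_kj_g = 16.2) {
  stopifnot(volume_ul >= 0, concentration_pct >= 0, energy_density_kj_g > 0)
  structure(list(volume_ul = volume_ul, concentration_pct = concentration_pct,
                 energy_density_kj_g = energy_density_kj_g),
            class = "energy_model")
}

#' Sucrose mass and chemical energy of a nectar reward
#'
#' `mass = volume_mL * concentration / 100` grams;
#' `energy = mass * energy_density * 1000` joules. The default 20 uL of
#' 20% w/v sucrose carries 0.004 g of sucrose and 64.8 J.
#'
#' @param model An [energy_model()].
#' @return List with `sucrose_g` and `energy_j`.
#' @examples
#' nectar_energy(energy_model())  # $sucrose_g 0.004, $energy_j 64.8
#' @export
nectar_energy <- function(model = energy_model()) {
  stopifnot(inherits(model, "energy_model"))
  mass <- (model$volume_ul / 1000) * model$concentration_pct / 100
  list(sucrose_g = mass, energy_j = mass * model$energy_density_kj_g * 1000)
}

#' Energy-gain rate of a flower visit
#'
#' Nectar acquisition is all-or-none: a visit that reaches the nectar
#' acquires the reservoir's full chemical energy, otherwise 0 J. The rate is
#' that energy divided by the total time spent within the presence radius
#' during the visit. Metabolic expenditure (2-3% of acquired energy) is
#' ignored by default; `expenditure_frac` subtracts a fixed fraction.
#'
#' @param duration_s Visit duration, s (> 0); vectorised.
#' @param emptied Logical; did the visit empty the reservoir? Vectorised.
#' @param model An [energy_model()].
#' @param expenditure_frac Fraction of acquired energy spent foraging
#'   (default 0).
#' @return Energy-gain rate(s), J/s.
#' @examples
#' energy_gain_rate(10.2, TRUE)   # 64.8 / 10.2 = 6.35 J/s
#' energy_gain_rate(8, FALSE)     # 0
#' @export
energy_gain_rate <- function(duration_s, emptied, model = energy_model(),
                             expenditure_frac = 0) {
  if (any(!is.finite(duration_s)) || any(duration_s <= 0))
    stop("visit duration must be positive", call. = FALSE)
  e <- nectar_energy(model)$energy_j * (1 - expenditure_frac)
  ifelse(emptied, e, 0) / duration_s
}

sem <- function(x) {
  n <- sum(!is.na(x))
  if (n <= 1) return(0)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Per-morph foraging success rate across stage-1 trials
#'
#' For each trial and morph the success rate is emptied flowers divided by
#' visits to that morph; morphs receiving zero visits in a trial contribute
#' nothing from that trial. The per-morph mean and SEM are taken across the
#' contributing trials (`pooled = FALSE`, default) or computed from counts
#' pooled over all trials (`pooled = TRUE`, SEM then binomial).
#'
#' @param trials A `stage1_trials` data.frame (columns `trial_id`, `morph`,
#'   `c`, `diameter`, `visits`, `emptied`).
#' @param pooled Pool counts across trials instead of averaging per-trial
#'   rates.
#' @return data.frame with one row per morph: `morph`, `c`, `diameter`,
#'   `success_rate`, `sem`, `n` (contributing trials, or pooled visits), and
#'   `undefined` flag for morphs never visited.
#' @export
success_rate_table <- function(trials, pooled = FALSE) {
  stopifnot(nrow(trials) >= 1)
  sp <- split(trials, trials$morph)
  out <- do.call(rbind, lapply(sp, function(d) {
    base <- data.frame(morph = d$morph[1], c = d$c[1], diameter = d$diameter[1])
    if (pooled) {
      v <- sum(d$visits); e <- sum(d$emptied)
      if (v == 0)
        return(cbind(base, success_rate = NA_real_, sem = NA_real_, n = 0L,
                     undefined = TRUE))
      p <- e / v
      cbind(base, success_rate = p, sem = sqrt(p * (1 - p) / v), n = v,
            undefined = FALSE)
    } else {
      r <- d$emptied[d$visits > 0] / d$visits[d$visits > 0]
      if (length(r) == 0)
        return(cbind(base, success_rate = NA_real_, sem = NA_real_, n = 0L,
                     undefined = TRUE))
      cbind(base, success_rate = mean(r), sem = sem(r), n = length(r),
            undefined = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Per-morph flower visitation frequency across stage-1 trials
#'
#' Mean and SEM across trials of the per-trial visit count to each morph
#' (all trials contribute, including zero-visit trials). With a single
#' trial the SEM is reported as 0 and `n = 1` flags it.
#'
#' @param trials A `stage1_trials` data.frame.
#' @return data.frame with `morph`, `c`, `diameter`, `visit_rate`
#'   (visits/trial), `sem`, `n`.
#' @export
visitation_frequency <- function(trials) {
  stopifnot(nrow(trials) >= 1)
  sp <- split(trials, trials$morph)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(morph = d$morph[1], c = d$c[1], diameter = d$diameter[1],
               visit_rate = mean(d$visits), sem = sem(d$visits),
               n = nrow(d))))
  rownames(out) <- NULL
  out
}

#' Per-morph visit-quality metrics for stage-2 trials
#'
#' Aggregates per-visit energy-gain rates and accelerometer hit counts by
#' morphology. The sampling unit is the visit (means and SEMs are across
#' visits, `n` = number of visits).
#'
#' @param visits data.frame with one row per visit: `morph` (label, e.g.
#'   curvature), `duration`, `emptied`, `hits`.
#' @param model An [energy_model()].
#' @param expenditure_frac Passed to [energy_gain_rate()].
#' @return data.frame of class `fitness_table` with `morph`, `energy_rate`,
#'   `energy_rate_sem`, `hits_per_visit`, `hits_sem`, `n`.
#' @export
visit_quality_table <- function(visits, model = energy_model(),
                                expenditure_frac = 0) {
  stopifnot(all(c("morph", "duration", "emptied", "hits") %in% names(visits)))
  visits$energy_rate <- energy_gain_rate(visits$duration, visits$emptied,
                                         model, expenditure_frac)
  sp <- split(visits, visits$morph)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(morph = d$morph[1],
               energy_rate = mean(d$energy_rate),
               energy_rate_sem = sem(d$energy_rate),
               hits_per_visit = mean(d$hits),
               hits_sem = sem(d$hits),
               n = nrow(d))))
  rownames(out) <- NULL
  class(out) <- c("fitness_table", "data.frame")
  out
}
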