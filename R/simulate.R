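#' @title Stochastic replication of the crossover evaluation study
#'
#' @description
#' An in-silico counterpart of the evaluation design: 32 early-pregnancy
#' cases (18 intrauterine, 14 tubal ectopic), scanned by 2 simulated
#' operators in 2 modes (128 scans). Each case carries a map of which signs
#' are truly demonstrable in which echographic view; each operator detects a
#' demonstrable sign spontaneously with probability `p_detect_spontaneous`,
#' and -- in assisted mode -- gets a guided second look wherever the
#' personalized protocol points, lifting the per-sign detection probability
#' to `p_detect_prompted`. When `p_detect_prompted` equals
#' `p_detect_spontaneous`, the guided look adds nothing and both arms have
#' identical outcome distributions by construction.
#'
#' Every scan draws from its own pseudo-random stream keyed by
#' (seed, case, operator, mode), so arms are comparable and evaluation order
#' is irrelevant.
#'
#' @name fixtures_sim
NULL

#' Simulated operator behavior model
#'
#' @param operator_id Identifier.
#' @param p_detect_spontaneous Probability that a demonstrable sign is
#'   reported during the operator's usual scan of a view.
#' @param p_detect_prompted Probability that a demonstrable sign is reported
#'   once the protocol directs attention to it; must be at least
#'   `p_detect_spontaneous`.
#' @param base_views Views the operator always scans (the standard emergency
#'   protocol).
#' @param base_min,per_image_min Duration model: fixed setup time plus cost
#'   per reported image, in minutes.
#' @param import_per_image_min Extra per-image cost of importing images into
#'   the assistant (assisted mode only).
#' @param per_step_min Time per guided protocol step (assisted mode only).
#' @param extra_images_assisted,extra_images_nonassisted Poisson means for
#'   non-informative extra images kept in the report.
#' @return An object of class `operator_model`.
#' @export
operator_model <- function(operator_id,
                           p_detect_spontaneous = 0.5,
                           p_detect_prompted = 0.95,
                           base_views = c("epo:uterus_sagittal_view",
                                          "epo:uterus_transverse_view",
                                          "epo:right_adnexal_view",
                                          "epo:left_adnexal_view",
                                          "epo:pouch_of_douglas_view"),
                           base_min = 2.8, per_image_min = 0.55,
                           import_per_image_min = 1.4, per_step_min = 1.0,
                           extra_images_assisted = 1.2,
                           extra_images_nonassisted = 3.0) {
  for (p in list(p_detect_spontaneous = p_detect_spontaneous,
                 p_detect_prompted = p_detect_prompted))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  if (p_detect_prompted < p_detect_spontaneous)
    stop("p_detect_prompted must be >= p_detect_spontaneous", call. = FALSE)
  structure(list(operator_id = operator_id,
                 p_detect_spontaneous = p_detect_spontaneous,
                 p_detect_prompted = p_detect_prompted,
                 base_views = base_views,
                 base_min = base_min, per_image_min = per_image_min,
                 import_per_image_min = import_per_image_min,
                 per_step_min = per_step_min,
                 extra_images_assisted = extra_images_assisted,
                 extra_images_nonassisted = extra_images_nonassisted),
            class = "operator_model")
}

#' Crossover study design
#'
#' @param seed Integer seed driving every random draw of the study.
#' @param n_intrauterine,n_tubal_ep Case mix (defaults: the 18/14 mix of the
#'   evaluation series).
#' @param n_operators Number of operators (study default 2).
#' @return An object of class `study_design`.
#' @export
study_design <- function(seed, n_intrauterine = 18L, n_tubal_ep = 14L,
                         n_operators = 2L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  structure(list(seed = as.integer(seed),
                 n_intrauterine = as.integer(n_intrauterine),
                 n_tubal_ep = as.integer(n_tubal_ep),
                 n_cases = as.integer(n_intrauterine + n_tubal_ep),
                 n_operators = as.integer(n_operators),
                 modes = c("assisted", "nonassisted")),
            class = "study_design")
}

# derive a per-scan seed below 2^31 from the study seed and scan coordinates
.scan_seed <- function(seed, case_idx, op_idx, mode) {
  m <- if (mode == "assisted") 1 else 2
  as.integer((abs(seed) * 96557 + case_idx * 7919 + op_idx * 611953 +
                m * 2716057) %% 2147483629)
}

.rng_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the simulated case series
#'
#' Draws the per-case map of demonstrable signs. Intrauterine cases always
#' demonstrate the intrauterine gestational sac; other supporting signs
#' (yolk sac, cardiac activity, double decidual sac sign) appear with fixed
#' probabilities, and a minority of cases show physiologic free fluid or a
#' corpus-luteum-like adnexal blob that can mislead toward ectopic
#' pregnancy. Tubal cases always demonstrate an empty uterine cavity and at
#' least one adnexal sign on the affected side. The bilateral sign "empty
#' adnexa" is never demonstrable in this series: with a tubal mass present,
#' it does not hold, and no gold pregnancy of unknown location occurs in the
#' study mix.
#'
#' @param seed Integer seed.
#' @param n_intrauterine,n_tubal_ep Case mix.
#' @return List of `sim_case` objects, each with `case_id`, `gold` (a
#'   [diagnosis()]), `gold_disorder` (IRI) and `sign_visibility` (named list
#'   view IRI -> character vector of demonstrable sign IRIs).
#' @export
#' @examples
#' length(case_series(1)) # 32
case_series <- function(seed, n_intrauterine = 18L, n_tubal_ep = 14L) {
  .rng_local(as.integer(seed) * 7L + 3L, {
    golds <- sample(c(rep("iup", n_intrauterine), rep("ep", n_tubal_ep)))
    lapply(seq_along(golds), function(i) {
      vis <- list()
      add <- function(vis, view, sign) {
        vis[[view]] <- sort(unique(c(vis[[view]], sign)), method = "radix")
        vis
      }
      if (golds[i] == "iup") {
        vis <- add(vis, "epo:uterus_sagittal_view", "epo:intrauterine_gestational_sac")
        vis <- add(vis, "epo:uterus_transverse_view", "epo:intrauterine_gestational_sac")
        if (stats::runif(1) < 0.8)
          vis <- add(vis, "epo:uterus_sagittal_view", "epo:yolk_sac_visible")
        if (stats::runif(1) < 0.7)
          vis <- add(vis, "epo:uterus_sagittal_view", "epo:embryo_with_cardiac_activity")
        if (stats::runif(1) < 0.6)
          vis <- add(vis, "epo:uterus_sagittal_view", "epo:double_decidual_sac_sign")
        # confounders: physiologic fluid / corpus luteum read as a blob
        if (stats::runif(1) < 0.25)
          vis <- add(vis, "epo:pouch_of_douglas_view", "epo:free_fluid_pouch_of_douglas")
        if (stats::runif(1) < 0.15) {
          side <- sample(c("epo:right_adnexal_view", "epo:left_adnexal_view"), 1L)
          vis <- add(vis, side, "epo:adnexal_blob_sign")
        }
        gold <- diagnosis("intrauterine")
        gold_disorder <- "epo:intrauterine_pregnancy"
      } else {
        side <- sample(c("epo:right_adnexal_view", "epo:left_adnexal_view"), 1L)
        vis <- add(vis, "epo:uterus_sagittal_view", "epo:empty_uterine_cavity")
        vis <- add(vis, "epo:uterus_transverse_view", "epo:empty_uterine_cavity")
        vis <- add(vis, side, "epo:adnexal_blob_sign") # anchor adnexal sign
        if (stats::runif(1) < 0.45)
          vis <- add(vis, side, "epo:bagel_sign")
        if (stats::runif(1) < 0.55)
          vis <- add(vis, side, "epo:adnexal_mass_separate_from_ovary")
        if (stats::runif(1) < 0.25)
          vis <- add(vis, "epo:uterus_sagittal_view", "epo:pseudogestational_sac")
        if (stats::runif(1) < 0.6)
          vis <- add(vis, "epo:pouch_of_douglas_view", "epo:free_fluid_pouch_of_douglas")
        gold <- diagnosis("ectopic", "tubal")
        gold_disorder <- "epo:tubal_ectopic_pregnancy"
      }
      structure(list(case_id = sprintf("case_%02d", i), gold = gold,
                     gold_disorder = gold_disorder, sign_visibility = vis),
                class = "sim_case")
    })
  })
}

#' Conclusion rule for simulated operators
#'
#' Top-ranked disorder of the differential when it is unique with support of
#' at least one sign; ties or no identified signs yield pregnancy of unknown
#' location. An ectopic conclusion states the precise site only when
#' supported by at least two signs; single-sign ectopic conclusions are
#' reported site-unspecified.
#'
#' @param kb An `epo_kb`.
#' @param signs Identified sign IRIs.
#' @param diagnosis_map Named list from disorder IRI to [diagnosis()].
#' @return A [diagnosis()].
#' @export
conclusion_from_signs <- function(kb, signs, diagnosis_map = demo_diagnosis_map()) {
  if (length(signs) == 0L) return(diagnosis("pregnancy_of_unknown_location"))
  dd <- differential(kb, signs)
  if (nrow(dd) == 0L) return(diagnosis("pregnancy_of_unknown_location"))
  top <- dd$support[1]
  if (top < 1L || (nrow(dd) > 1L && dd$support[2] == top))
    return(diagnosis("pregnancy_of_unknown_location"))
  concl <- diagnosis_map[[dd$disorder[1]]]
  if (is.null(concl))
    stop(sprintf("no diagnosis mapping for disorder '%s'", dd$disorder[1]),
         call. = FALSE)
  if (concl$location_class == "ectopic" && top < 2L)
    concl <- diagnosis("ectopic", "unspecified")
  concl
}

# one simulated scan; assumes the RNG is already seeded for this scan
.simulate_scan <- function(case, op, mode, kb, diagnosis_map,
                           quality_probs, trust_probs) {
  vis <- case$sign_visibility
  p_sp <- op$p_detect_spontaneous
  # conditional success probability of a guided look at a sign already
  # examined spontaneously; lifts per-sign detection from p_spontaneous to
  # p_prompted, and vanishes when the two probabilities coincide
  q <- if (p_sp >= 1) 0 else
    max(0, (op$p_detect_prompted - p_sp) / (1 - p_sp))
  s <- new_session(kb, case$case_id)
  img <- 0L

  # spontaneous pass over the standard views; only informative images
  # (those with at least one finding) are kept and annotated. In assisted
  # mode the entry view's image goes through the guided keyword analysis,
  # which grants missed signs there a conditional second look.
  for (v in op$base_views) {
    dem <- vis[[v]]
    if (is.null(dem) || length(dem) == 0L) next
    found <- dem[stats::runif(length(dem)) < p_sp]
    if (mode == "assisted" && v == op$base_views[[1L]]) {
      missed <- setdiff(dem, found)
      found <- c(found, missed[stats::runif(length(missed)) < q])
    }
    if (length(found) > 0L) {
      img <- img + 1L
      add_image(s, image_annotation(sprintf("%s_img%02d", case$case_id, img),
                                    view = v, signs_present = found,
                                    route = "epo:transvaginal_route",
                                    mode = "epo:b_mode"))
    }
  }

  steps <- 0L
  if (mode == "assisted") {
    # protocol loop: the guided second look at sought signs uses the same
    # conditional probability q
    repeat {
      g <- next_guidance(s)
      if (length(g) == 0L || steps >= 25L) break
      it <- g[[1L]]
      dem <- vis[[it$view]]
      if (is.null(dem)) dem <- character()
      sought <- it$sought_signs
      candidates <- intersect(sought, dem)
      found <- candidates[stats::runif(length(candidates)) < q]
      # a sign is declared absent only once every view where it could be
      # demonstrated has been examined (side-specific signs must not be
      # retired after checking a single side)
      seen <- c(completed_views(s), it$view)
      not_found <- setdiff(sought, found)
      absent <- not_found[vapply(not_found, function(x)
        all(views_for(kb, x) %in% seen), logical(1))]
      img <- img + 1L
      add_image(s, image_annotation(sprintf("%s_img%02d", case$case_id, img),
                                    view = it$view, signs_present = found,
                                    signs_absent = absent,
                                    route = "epo:transvaginal_route",
                                    mode = "epo:b_mode"))
      steps <- steps + 1L
    }
  }

  ident <- identified_signs(s)
  concl <- conclusion_from_signs(kb, ident, diagnosis_map)

  extra <- stats::rpois(1L, if (mode == "assisted") op$extra_images_assisted
                            else op$extra_images_nonassisted)
  image_count <- max(1L, img) + extra
  duration <- op$base_min + op$per_image_min * image_count +
    if (mode == "assisted")
      op$import_per_image_min * image_count + op$per_step_min * steps
    else 0
  duration <- round(max(1, duration + stats::rnorm(1L, sd = 0.5)), 1)

  quality <- stats::rbinom(1L, 15L, quality_probs[[mode]])
  trust <- sample.int(5L, 1L, prob = trust_probs[[mode]])

  report <- finalize_session(s, op$operator_id, mode, concl, duration)

  data.frame(case_id = case$case_id, operator_id = op$operator_id, mode = mode,
             gold_location = case$gold$location_class,
             gold_site = if (is.null(case$gold$ectopic_site)) "" else case$gold$ectopic_site,
             concl_location = report$conclusion$location_class,
             concl_site = if (is.null(report$conclusion$ectopic_site)) ""
                          else report$conclusion$ectopic_site,
             image_count = image_count, duration_min = duration,
             quality_score = quality, trust_level = trust,
             stringsAsFactors = FALSE)
}

#' Run the simulated crossover study
#'
#' Emits one scan record per case, operator and mode. Each scan uses its own
#' random stream keyed by (seed, case, operator, mode), so identical seeds
#' yield identical record sets regardless of evaluation order.
#'
#' @param design A [study_design()].
#' @param operators List of [operator_model()] objects (one per operator).
#' @param kb Knowledge base to reason over (default [demo_kb()]).
#' @param diagnosis_map Disorder-to-diagnosis mapping.
#' @param quality_probs Per-mode success probability of each of the 15
#'   quality items (binomial model of the expert quality score).
#' @param trust_probs Per-mode probability vectors over trust levels 1--5.
#' @return Scan-record data frame with
#'   `design$n_cases * n_operators * 2` rows.
#' @export
#' @examples
#' recs <- run_study(study_design(seed = 1))
#' nrow(recs) # 128
run_study <- function(design, operators = NULL, kb = demo_kb(),
                      diagnosis_map = demo_diagnosis_map(),
                      quality_probs = c(assisted = 0.83, nonassisted = 0.68),
                      trust_probs = list(assisted = c(0.01, 0.03, 0.14, 0.47, 0.35),
                                         nonassisted = c(0.05, 0.12, 0.33, 0.36, 0.14))) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(operators))
    operators <- lapply(seq_len(design$n_operators), function(i)
      operator_model(paste0("trainee_", i)))
  stopifnot(length(operators) == design$n_operators)
  cases <- case_series(design$seed, design$n_intrauterine, design$n_tubal_ep)
  rows <- list()
  for (ci in seq_along(cases)) {
    for (oi in seq_along(operators)) {
      for (mode in design$modes) {
        rows[[length(rows) + 1L]] <- .rng_local(
          .scan_seed(design$seed, ci, oi, mode),
          .simulate_scan(cases[[ci]], operators[[oi]], mode, kb,
                         diagnosis_map, quality_probs, trust_probs))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
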