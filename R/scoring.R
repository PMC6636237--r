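#' @title Image-set quality score and report trust scale
#'
#' @description
#' An early-pregnancy image set is scored against a 15-item checklist: five
#' criteria on the sagittal view of the uterus and five on each ovary view
#' (one point per satisfied criterion, maximum 15). Separately, expert
#' reviewers grade their trust in a report's conclusion on a 5-level scale;
#' levels 1--3 call for a supervisor examination, levels 4--5 do not.
#' The criteria are boolean judgments supplied as data: this module scores,
#' it does not judge images.
#'
#' @name scoring
NULL

.logical1 <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

#' Quality checklist for the sagittal uterus view
#'
#' @param cervix_visible Uterine cervix visible.
#' @param fundus_visible Uterine fundus visible.
#' @param endometrial_midline_visible Endometrial midline echo visible.
#' @param endocervix_visible Endocervix visible.
#' @param uterus_over_half_image Uterus occupies more than half the image.
#' @return An object of class `uterus_checklist` (five booleans).
#' @export
uterus_checklist <- function(cervix_visible = FALSE, fundus_visible = FALSE,
                             endometrial_midline_visible = FALSE,
                             endocervix_visible = FALSE,
                             uterus_over_half_image = FALSE) {
  items <- c(cervix_visible = .logical1(cervix_visible, "cervix_visible"),
             fundus_visible = .logical1(fundus_visible, "fundus_visible"),
             endometrial_midline_visible =
               .logical1(endometrial_midline_visible, "endometrial_midline_visible"),
             endocervix_visible = .logical1(endocervix_visible, "endocervix_visible"),
             uterus_over_half_image =
               .logical1(uterus_over_half_image, "uterus_over_half_image"))
  structure(as.list(items), class = "uterus_checklist")
}

#' Quality checklist for one ovary view
#'
#' @param side `"left"` or `"right"`.
#' @param side_stated Side stated on the image.
#' @param follicles_visible Follicle(s) visible.
#' @param iliac_vein_visible Iliac vein visible.
#' @param long_axis_under_30_deg Long axis of the ovary under 30 degrees
#'   with the horizontal.
#' @param ovary_over_quarter_image Ovary occupies more than a quarter of the
#'   image.
#' @return An object of class `ovary_checklist` (side + five booleans).
#' @export
ovary_checklist <- function(side = c("left", "right"), side_stated = FALSE,
                            follicles_visible = FALSE, iliac_vein_visible = FALSE,
                            long_axis_under_30_deg = FALSE,
                            ovary_over_quarter_image = FALSE) {
  side <- match.arg(side)
  structure(list(side = side,
                 side_stated = .logical1(side_stated, "side_stated"),
                 follicles_visible = .logical1(follicles_visible, "follicles_visible"),
                 iliac_vein_visible = .logical1(iliac_vein_visible, "iliac_vein_visible"),
                 long_axis_under_30_deg =
                   .logical1(long_axis_under_30_deg, "long_axis_under_30_deg"),
                 ovary_over_quarter_image =
                   .logical1(ovary_over_quarter_image, "ovary_over_quarter_image")),
            class = "ovary_checklist")
}

#' Full 15-item quality assessment of an image set
#'
#' Missing views are scored against an all-false checklist: items that could
#' not be assessed earn no point.
#'
#' @param uterus A [uterus_checklist()].
#' @param left_ovary,right_ovary [ovary_checklist()] objects for the left and
#'   right ovary views.
#' @return An object of class `quality_assessment`; its `score` element is
#'   the derived 0--15 score.
#' @export
#' @examples
#' qa <- quality_assessment(
#'   uterus_checklist(TRUE, TRUE, TRUE, TRUE, TRUE),
#'   ovary_checklist("left"), ovary_checklist("right"))
#' quality_score(qa) # 5
quality_assessment <- function(uterus = uterus_checklist(),
                               left_ovary = ovary_checklist("left"),
                               right_ovary = ovary_checklist("right")) {
  stopifnot(inherits(uterus, "uterus_checklist"),
            inherits(left_ovary, "ovary_checklist"),
            inherits(right_ovary, "ovary_checklist"))
  if (left_ovary$side != "left" || right_ovary$side != "right")
    stop("ovary checklists must carry matching sides", call. = FALSE)
  qa <- structure(list(uterus = uterus, left_ovary = left_ovary,
                       right_ovary = right_ovary, score = NA_integer_),
                  class = "quality_assessment")
  qa$score <- quality_score(qa)
  qa
}

.checklist_points <- function(cl) {
  items <- cl[vapply(cl, is.logical, logical(1))]
  sum(vapply(items, isTRUE, logical(1)))
}

#' Compute the 15-item image-set quality score
#'
#' One point per satisfied criterion: 5 uterus items + 5 items per ovary.
#'
#' @param assessment A [quality_assessment()].
#' @return Integer score between 0 and 15.
#' @export
quality_score <- function(assessment) {
  stopifnot(inherits(assessment, "quality_assessment"))
  as.integer(.checklist_points(assessment$uterus) +
             .checklist_points(assessment$left_ovary) +
             .checklist_points(assessment$right_ovary))
}

.trust_table <- function() {
  c(
    "1" = paste("No trust in the final diagnosis (incorrect): the diagnosis is",
                "most likely incorrect and the image set suggests another",
                "diagnosis. Immediate supervisor examination is needed."),
    "2" = paste("No trust in the final diagnosis (low quality): the image set",
                "quality is insufficient and/or does not support the final",
                "diagnosis. Immediate supervisor examination is needed."),
    "3" = paste("Moderate trust in the final diagnosis: although the diagnosis",
                "might be correct, the image set quality is insufficient, and",
                "a supervisor examination is needed."),
    "4" = paste("The image set quality could be improved; however, it is of",
                "sufficient quality to accurately support the final diagnosis.",
                "No supervisor examination is needed."),
    "5" = paste("Total trust in the final diagnosis: the image set effectively",
                "supports the diagnosis, and no supervisor examination is",
                "needed.")
  )
}

#' Canonical description of a trust level
#'
#' @param level Integer 1--5.
#' @return The canonical description text. Levels 1--3 imply that a
#'   supervisor examination is needed; levels 4--5 that none is needed.
#' @export
#' @examples
#' trust_description(5)
trust_description <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level != as.integer(level) || level < 1 || level > 5)
    stop("trust level must be an integer between 1 and 5", call. = FALSE)
  unname(.trust_table()[as.character(as.integer(level))])
}

#' Does a trust level call for a supervisor examination?
#' @param level Integer 1--5.
#' @return `TRUE` for levels 1--3, `FALSE` for 4--5.
#' @export
supervisor_needed <- function(level) {
  trust_description(level) # validates
  level <= 3
}

#' Band a kappa coefficient into an agreement category
#'
#' Values below 0.6 represent poor agreement, values between 0.6 and 0.8
#' moderate agreement, and values above 0.8 good agreement. The moderate
#' band is treated as the closed interval \[0.6, 0.8\]; good is (0.8, 1\].
#'
#' @param kappa Number in \[-1, 1\].
#' @return `"poor"`, `"moderate"`, or `"good"`.
#' @export
#' @examples
#' agreement_category(0.86) # "good"
agreement_category <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) ||
      kappa < -1 || kappa > 1)
    stop("kappa must be a number in [-1, 1]", call. = FALSE)
  if (kappa < 0.6) "poor" else if (kappa <= 0.8) "moderate" else "good"
}

#' Read a quality assessment from JSON
#'
#' Expects an object with fields `uterus`, `left_ovary`, `right_ovary`, each
#' mapping item names to booleans (ovary entries additionally carry `side`).
#'
#' @param x JSON text or a file path.
#' @return A [quality_assessment()].
#' @export
quality_assessment_from_json <- function(x) {
  if (length(x) == 1L && !grepl("[{]", x) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  ut <- do.call(uterus_checklist, as.list(obj$uterus))
  lo <- do.call(ovary_checklist, c(list(side = "left"),
                                   obj$left_ovary[setdiff(names(obj$left_ovary), "side")]))
  ro <- do.call(ovary_checklist, c(list(side = "right"),
                                   obj$right_ovary[setdiff(names(obj$right_ovary), "side")]))
  quality_assessment(ut, lo, ro)
}

#' Serialize a quality assessment to JSON
#' @param assessment A [quality_assessment()].
#' @param file Optional path to write to.
#' @return JSON text.
#' @export
quality_assessment_to_json <- function(assessment, file = NULL) {
  stopifnot(inherits(assessment, "quality_assessment"))
  x <- list(uterus = unclass(assessment$uterus),
            left_ovary = unclass(assessment$left_ovary),
            right_ovary = unclass(assessment$right_ovary),
            score = assessment$score)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
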